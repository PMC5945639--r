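# Seed grammar: derive canonical site words from a mature miRNA and scan
# 3'UTRs for their occurrences.

#' Site-class levels, from weakest to strongest
#'
#' Canonical seed-match classes on the mRNA, ordered by expected repression
#' strength: an 8mer (match to miRNA nt 2-8 plus an A opposite nt 1) beats a
#' 7mer-m8 (nt 2-8), which beats a 7mer-1A (nt 2-7 plus A), which beats a
#' 6mer (nt 2-7). `"none"` means no canonical site.
#'
#' @return Character vector of the five class labels in ascending strength.
#' @export
site_type_levels <- function() c("none", "6mer", "7mer-1A", "7mer-m8", "8mer")

.site_classes <- function() c("8mer", "7mer-m8", "7mer-1A", "6mer")

site_factor <- function(x) factor(x, levels = site_type_levels(), ordered = TRUE)

#' Construct a mature microRNA
#'
#' @param name miRNA name, e.g. `"hsa-miR-125b-5p"`.
#' @param mature_seq Mature sequence 5'->3'. RNA (`ACGU`) expected; `T` is
#'   normalized to `U` on input. Must be at least 8 nt so that all four seed
#'   site words can be derived.
#' @return An object of class `"mirna"` with elements `name` and `mature_seq`.
#' @examples
#' mir100 <- mirna("hsa-miR-100-5p", "AACCCGUAGAUCCGAACUUGUG")
#' seed_words(mir100)
#' @export
mirna <- function(name, mature_seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(mature_seq), length(mature_seq) == 1L)
  s <- chartr("tu", "TU", toupper(gsub("[[:space:]]", "", mature_seq)))
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s))
    stop("invalid miRNA '", name, "': mature sequence contains characters outside ACGU/T")
  if (nchar(s) < 8L)
    stop("invalid miRNA '", name, "': mature sequence must be at least 8 nt to derive seed site words")
  structure(list(name = name, mature_seq = s), class = "mirna")
}

#' @export
print.mirna <- function(x, ...) {
  cat("miRNA", x$name, " (", nchar(x$mature_seq), " nt): 5'-", x$mature_seq, "-3'\n", sep = "")
  invisible(x)
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Derive a seed-match site word
#'
#' Returns the mRNA-strand (5'->3', DNA alphabet) word that a perfect
#' seed match of the given class occupies in a 3'UTR:
#' \describe{
#'   \item{6mer}{reverse complement of miRNA nt 2-7}
#'   \item{7mer-m8}{reverse complement of miRNA nt 2-8}
#'   \item{7mer-1A}{6mer word followed by a literal `A`}
#'   \item{8mer}{7mer-m8 word followed by a literal `A`}
#' }
#' The A opposite miRNA position 1 is required as a literal A in the UTR.
#'
#' @param mirna A [mirna()] object.
#' @param site_type One of `"8mer"`, `"7mer-m8"`, `"7mer-1A"`, `"6mer"`.
#' @return A single DNA word (character).
#' @export
seed_site_word <- function(mirna, site_type) {
  stopifnot(inherits(mirna, "mirna"))
  site_type <- match.arg(site_type, .site_classes())
  dna <- chartr("U", "T", mirna$mature_seq)
  six <- revcomp_dna(substr(dna, 2L, 7L))
  sev <- revcomp_dna(substr(dna, 2L, 8L))
  switch(site_type,
         "6mer"    = six,
         "7mer-m8" = sev,
         "7mer-1A" = paste0(six, "A"),
         "8mer"    = paste0(sev, "A"))
}

#' All four site words of a miRNA
#'
#' @param mirna A [mirna()] object.
#' @return Named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-1A`, `6mer`.
#' @export
seed_words <- function(mirna) {
  vapply(.site_classes(), function(cl) seed_site_word(mirna, cl), character(1))
}

# Normalize UTR input to a named DNAStringSet (U -> T; case-folded).
as_utr_set <- function(utrs) {
  if (methods::is(utrs, "DNAStringSet")) return(utrs)
  if (is.character(utrs)) {
    if (is.null(names(utrs)) && length(utrs) == 1L) names(utrs) <- "utr"
    s <- chartr("u", "t", toupper(utrs))
    s <- chartr("U", "T", s)
    return(Biostrings::DNAStringSet(s))
  }
  stop("UTRs must be a character vector or a DNAStringSet")
}

#' Count (possibly overlapping) occurrences of a word
#'
#' Overlapping occurrences are counted; windows containing `N` (or any
#' non-ACGT character) never match.
#'
#' @param utrs Character vector or `DNAStringSet` of UTR sequences.
#' @param word A DNA word (length >= 1).
#' @return Integer vector of per-sequence occurrence counts.
#' @examples
#' count_word_occurrences("AAAA", "AA")  # 3
#' @export
count_word_occurrences <- function(utrs, word) {
  stopifnot(is.character(word), length(word) == 1L, nchar(word) >= 1L)
  set <- as_utr_set(utrs)
  n <- Biostrings::vcountPattern(word, set)
  names(n) <- names(set)
  n
}

#' Scan a set of 3'UTRs for seed-match sites of a miRNA
#'
#' All four canonical site words are located in each UTR. Occurrences that
#' overlap a higher-class occurrence are collapsed into it (an 8mer is not
#' additionally reported as its embedded 7mer-m8/7mer-1A/6mer). Coordinates
#' are 0-based, half-open, on the given UTR strand only.
#'
#' @param utrs Character vector or `DNAStringSet` of UTRs (DNA; `U`
#'   normalized to `T`).
#' @param mirna A [mirna()] object.
#' @return A data frame with columns `transcript_id`, `start`, `end`,
#'   `site_type` (ordered factor), `word`, `mirna_name`, sorted by
#'   transcript then start.
#' @export
scan_sites <- function(utrs, mirna) {
  stopifnot(inherits(mirna, "mirna"))
  set <- as_utr_set(utrs)
  words <- seed_words(mirna)
  hits <- vector("list", length(words))
  for (i in seq_along(words)) {
    m <- Biostrings::vmatchPattern(words[[i]], set)
    st <- unlist(lapply(m, BiocGenerics::start), use.names = FALSE)
    n_per <- lengths(m)
    hits[[i]] <- data.frame(
      seq_idx = rep(seq_along(set), n_per),
      start = if (length(st)) st - 1L else integer(0),  # 0-based
      site_type = rep(names(words)[i], sum(n_per)),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, hits)
  if (nrow(all) == 0L) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), site_type = site_factor(character(0)),
                      word = character(0), mirna_name = character(0),
                      stringsAsFactors = FALSE))
  }
  all$len <- nchar(words[all$site_type])
  all$end <- all$start + all$len
  # collapse: drop occurrences overlapping a kept higher-class occurrence
  prio <- match(all$site_type, .site_classes())  # 1 = strongest
  keep <- logical(nrow(all))
  for (idx in split(seq_len(nrow(all)), all$seq_idx)) {
    idx <- idx[order(prio[idx], all$start[idx])]
    ks <- integer(0); ke <- integer(0); kp <- integer(0)
    for (j in idx) {
      ov <- any(all$start[j] < ke & all$end[j] > ks & kp < prio[j])
      if (!ov) {
        keep[j] <- TRUE
        ks <- c(ks, all$start[j]); ke <- c(ke, all$end[j]); kp <- c(kp, prio[j])
      }
    }
  }
  out <- all[keep, , drop = FALSE]
  ids <- names(set)
  out <- data.frame(
    transcript_id = ids[out$seq_idx],
    start = out$start,
    end = out$end,
    site_type = site_factor(out$site_type),
    word = unname(words[out$site_type]),
    mirna_name = mirna$name,
    stringsAsFactors = FALSE)
  out <- out[order(match(out$transcript_id, ids), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strongest site class per UTR
#'
#' The maximum site class whose word occurs at least once in each UTR;
#' `"none"` if no site word occurs.
#'
#' @inheritParams scan_sites
#' @return Ordered factor (levels [site_type_levels()]), one per UTR, named
#'   by transcript id.
#' @export
best_site_type <- function(utrs, mirna) {
  stopifnot(inherits(mirna, "mirna"))
  set <- as_utr_set(utrs)
  words <- seed_words(mirna)  # strongest first
  best <- rep("none", length(set))
  for (cl in rev(.site_classes())) {  # weakest first; stronger overwrite
    present <- Biostrings::vcountPattern(words[[cl]], set) > 0L
    best[present] <- cl
  }
  out <- site_factor(best)
  names(out) <- names(set)
  out
}

#' Write site annotations as TSV
#'
#' Six tab-separated columns: transcript_id, start, end, site_type, word,
#' mirna_name. Coordinates are 0-based half-open on the UTR.
#'
#' @param annotations Data frame from [scan_sites()].
#' @param path Output file path.
#' @export
write_site_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
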