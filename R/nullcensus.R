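# Genome-wide seed-count census against a random-word null: is a given
# seed word over- or under-represented across all 3'UTRs relative to
# same-length words?

#' Total occurrence count of a word across a UTR set
#'
#' Occurrences are counted with overlap, summed over all sequences.
#'
#' @param utrs Character vector or `DNAStringSet`.
#' @param word DNA word over ACGT.
#' @return A single count.
#' @export
word_census <- function(utrs, word) {
  if (grepl("[^ACGT]", toupper(word))) stop("census word must be over ACGT")
  sum(count_word_occurrences(utrs, word))
}

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Null distribution of census counts over same-length words
#'
#' The exhaustive mode enumerates all `4^k` words (the uniform random-word
#' ensemble); the sampled mode draws `m` words uniformly and requires a
#' seed for reproducibility.
#'
#' @param utrs UTR set.
#' @param k Word length (6, 7 or 8).
#' @param mode `"exhaustive"` (default) or `"sampled"`.
#' @param m Number of words to draw in sampled mode.
#' @param seed RNG seed, mandatory in sampled mode.
#' @return List of class `"word_null"`: `census` (named count vector),
#'   `mean`, `sd`, `k`, `mode`.
#' @export
random_word_null <- function(utrs, k, mode = c("exhaustive", "sampled"),
                             m = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(k %in% 6:8)
  set <- as_utr_set(utrs)
  census <- colSums(Biostrings::oligonucleotideFrequency(set, width = k))
  if (mode == "sampled") {
    if (is.null(seed)) stop("sampled mode requires a seed (reproducibility contract)")
    if (is.null(m) || m < 1) stop("sampled mode requires m >= 1")
    idx <- with_seed(seed, sample.int(length(census), size = m, replace = FALSE))
    census <- census[idx]
  }
  structure(list(census = census, mean = mean(census), sd = stats::sd(census),
                 k = k, mode = mode),
            class = "word_null")
}

#' Seed over/under-representation versus the random-word null
#'
#' Compares the total occurrence count of a miRNA's site word (or an
#' arbitrary word) across all UTRs with the distribution of counts over all
#' same-length words: `z = (observed - null mean) / null sd`; the
#' percentile is the fraction of comparison words with census at most the
#' observed count, times 100.
#'
#' @param utrs UTR set.
#' @param mirna A [mirna()] object, or `NULL` when `word` is given.
#' @param site_type Site class whose word is queried (default `"7mer-m8"`).
#' @param word Optional explicit word (overrides `mirna`/`site_type`).
#' @param null Optional precomputed [random_word_null()] (must match the
#'   word length); default: exhaustive null.
#' @return Object of class `"null_summary"`: `word`, `observed`,
#'   `null_mean`, `null_sd`, `z` (NA with `z_defined = FALSE` when the null
#'   is degenerate), `percentile`, `k`, `n_words`.
#' @export
depletion_score <- function(utrs, mirna = NULL, site_type = "7mer-m8",
                            word = NULL, null = NULL) {
  if (is.null(word)) {
    stopifnot(inherits(mirna, "mirna"))
    word <- seed_site_word(mirna, site_type)
  }
  k <- nchar(word)
  if (!k %in% 6:8) stop("census word length must be 6, 7 or 8")
  if (is.null(null)) null <- random_word_null(utrs, k)
  if (null$k != k) stop("null word length (", null$k, ") does not match the query word")
  observed <- word_census(utrs, word)
  z_defined <- is.finite(null$sd) && null$sd > 0
  structure(list(word = word, observed = observed,
                 null_mean = null$mean, null_sd = null$sd,
                 z = if (z_defined) (observed - null$mean) / null$sd else NA_real_,
                 z_defined = z_defined,
                 percentile = 100 * mean(null$census <= observed),
                 k = k, n_words = length(null$census)),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("Word %s: observed %d vs null %.1f +/- %.1f over %d %d-mers\n",
              x$word, x$observed, x$null_mean, x$null_sd, x$n_words, x$k))
  if (x$z_defined) cat(sprintf("z = %+.2f, percentile = %.1f\n", x$z, x$percentile))
  else cat(sprintf("degenerate null (sd = 0); percentile = %.1f\n", x$percentile))
  invisible(x)
}

#' Write a word census as TSV (word, count)
#' @param null A `word_null`.
#' @param path Output path.
#' @export
write_census <- function(null, path) {
  out <- data.frame(word = names(null$census), count = unname(null$census))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
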