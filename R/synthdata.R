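# Synthetic experiment generator: UTR FASTA plus paired RIP/input and
# mimic/negative-control abundance tables with planted, class-stratified
# repression and AGO2-loading effects, and an exact truth manifest.

#' Synthetic experiment configuration
#'
#' Defaults describe the reference simulation used throughout the package:
#' 2000 transcripts with 500-1000 nt UTRs of uniform base composition,
#' seed sites of all four classes planted in disjoint strata
#' (8mer 10%, 7mer-m8 15%, 7mer-1A 10%, 6mer 10%), repression effects
#' -0.8/-0.6/-0.4/-0.2 log2 units by class, AGO2 loading +1.0 log2 units
#' for true targets, log-normal measurement noise of 0.4 log2 units, and
#' two replicates per condition.
#'
#' @param n_transcripts Number of transcripts.
#' @param utr_length Integer range (min, max) of UTR lengths in nt.
#' @param gc Base GC fraction of the background composition.
#' @param planting Named fractions of transcripts receiving a planted site,
#'   names among `8mer`, `7mer-m8`, `7mer-1A`, `6mer`; must sum to <= 1.
#' @param effects Named log2 repression effects (<= 0) per planted class.
#' @param true_target_fraction Fraction of planted transcripts that are
#'   functional targets (repressed and AGO2-loaded); the rest carry sites
#'   but no effect.
#' @param rip_loading AGO2-loading effect for true targets, log2 units (>= 0).
#' @param noise_sd Per-replicate log2 measurement noise sd (> 0).
#' @param replicates Replicates per condition.
#' @param mirna The planted [mirna()] (default hsa-miR-125b-5p).
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_transcripts = 2000,
                         utr_length = c(500, 1000),
                         gc = 0.5,
                         planting = c("8mer" = 0.10, "7mer-m8" = 0.15,
                                      "7mer-1A" = 0.10, "6mer" = 0.10),
                         effects = c("8mer" = -0.8, "7mer-m8" = -0.6,
                                     "7mer-1A" = -0.4, "6mer" = -0.2),
                         true_target_fraction = 1,
                         rip_loading = 1.0,
                         noise_sd = 0.4,
                         replicates = 2,
                         mirna = NULL,
                         seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for synthetic data")
  if (is.null(mirna)) mirna <- default_mirna()
  stopifnot(inherits(mirna, "mirna"),
            n_transcripts >= 1, length(utr_length) == 2,
            utr_length[1] >= 1, utr_length[2] >= utr_length[1],
            gc > 0, gc < 1, noise_sd > 0, replicates >= 1,
            rip_loading >= 0, true_target_fraction >= 0, true_target_fraction <= 1)
  planting <- planting[planting > 0]
  if (length(planting)) {
    if (!all(names(planting) %in% .site_classes()))
      stop("planting names must be site classes: ", paste(.site_classes(), collapse = ", "))
    if (any(planting < 0) || sum(planting) > 1)
      stop("planting fractions must be in [0,1] and sum to <= 1")
    if (!all(names(planting) %in% names(effects)))
      stop("every planted class needs an effect")
    if (any(effects[names(planting)] > 0)) stop("effects must be <= 0 (repression)")
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 utr_length = as.integer(utr_length), gc = gc,
                 planting = planting, effects = effects,
                 true_target_fraction = true_target_fraction,
                 rip_loading = rip_loading, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 mirna = mirna, seed = as.integer(seed)),
            class = "synth_config")
}

.rand_utr <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.contains_any <- function(utr, words) {
  any(vapply(words, function(w) grepl(w, utr, fixed = TRUE), logical(1)))
}

#' Random UTR sequences, optionally excluding words
#'
#' Draws per-base random sequences; when `exclude_words` is given, whole
#' sequences containing any excluded word are rejection-sampled.
#'
#' @param n Number of sequences.
#' @param length_range Integer (min, max) lengths.
#' @param gc GC fraction.
#' @param exclude_words Character vector of words none of which may occur.
#' @param seed Mandatory RNG seed.
#' @param max_tries Rejection bound per sequence.
#' @return Named `DNAStringSet`.
#' @export
random_utrs <- function(n, length_range = c(500, 1000), gc = 0.5,
                        exclude_words = NULL, seed, max_tries = 1000) {
  if (missing(seed)) stop("a seed is mandatory")
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      for (t in seq_len(max_tries)) {
        u <- .rand_utr(lens[i], gc)
        if (is.null(exclude_words) || !.contains_any(u, exclude_words)) break
        if (t == max_tries) stop("rejection sampling failed to exclude words")
      }
      seqs[i] <- u
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("T%05d", seq_len(n))
    out
  })
}

#' Plant extra occurrences of a word into every sequence
#'
#' Overwrites `per_seq` non-overlapping windows of each sequence with
#' `word` at random positions.
#'
#' @param utrs `DNAStringSet` or character vector.
#' @param word DNA word.
#' @param per_seq Occurrences to plant per sequence.
#' @param seed Mandatory RNG seed.
#' @return Named `DNAStringSet`.
#' @export
plant_occurrences <- function(utrs, word, per_seq, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set <- as_utr_set(utrs)
  seqs <- as.character(set)
  wl <- nchar(word)
  with_seed(seed, {
    for (i in seq_along(seqs)) {
      len <- nchar(seqs[i])
      if (len < per_seq * wl) stop("sequence too short to plant ", per_seq, " occurrences")
      slots <- floor(len / wl)
      at <- (sample(slots, per_seq) - 1L) * wl + 1L
      for (p in at) substr(seqs[i], p, p + wl - 1L) <- word
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(set)
    out
  })
}

.best_class_string <- function(utr, words) {
  for (cl in .site_classes()) if (grepl(words[[cl]], utr, fixed = TRUE)) return(cl)
  "none"
}

#' Generate a complete synthetic RIP-USE experiment
#'
#' Produces UTRs, the four abundance tables and an exact truth manifest.
#' Background sequences are drawn per-base from the configured composition
#' and rejection-sampled so that only planted transcripts carry any of the
#' miRNA's four site words; a planted transcript carries exactly its
#' intended class as its strongest site (insertion positions are
#' rejection-sampled so that flanking bases never upgrade the class).
#' Control and input abundances are log-normal; for true targets the mimic
#' condition is multiplied by `2^(class effect + noise)` and the RIP
#' condition by `2^(loading + noise)`; all other measurements carry noise
#' only. Deterministic given the configured seed.
#'
#' @param config A [synth_config()].
#' @return Object of class `"ripuse_simulation"`: `utrs` (named
#'   `DNAStringSet`), `rip`, `input`, `mimic`, `control` (matrices),
#'   `manifest` (data frame), `config`.
#' @export
simulate_ripuse_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  words <- seed_words(cfg$mirna)
  if (max(nchar(words)) > cfg$utr_length[1])
    stop("infeasible planting: site word longer than the shortest UTR")
  n <- cfg$n_transcripts
  ids <- sprintf("T%05d", seq_len(n))
  with_seed(cfg$seed, {
    # class assignment
    n_class <- round(cfg$planting * n)
    planted_class <- rep("none", n)
    if (length(n_class) && sum(n_class) > 0) {
      pick <- sample.int(n, sum(n_class))
      planted_class[pick] <- rep(names(n_class), n_class)
    }
    scrub <- length(n_class) > 0 && sum(n_class) > 0
    lens <- sample(seq(cfg$utr_length[1], cfg$utr_length[2]), n, replace = TRUE)
    seqs <- character(n)
    starts <- rep(NA_integer_, n)
    if (!scrub) {
      # no planted sites: draw all bases in one pass
      big <- paste(sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE,
                          prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2,
                                   (1 - cfg$gc) / 2)), collapse = "")
      ends <- cumsum(lens)
      seqs <- substring(big, ends - lens + 1L, ends)
    } else for (i in seq_len(n)) {
      cl <- planted_class[i]
      placed <- FALSE
      for (try_bg in 1:200) {
        u <- .rand_utr(lens[i], cfg$gc)
        if (scrub && .contains_any(u, words)) next
        if (cl == "none") { seqs[i] <- u; placed <- TRUE; break }
        w <- words[[cl]]; wl <- nchar(w)
        for (try_pos in 1:50) {
          pos <- sample.int(lens[i] - wl + 1L, 1L)
          cand <- u
          substr(cand, pos, pos + wl - 1L) <- w
          if (.best_class_string(cand, words) == cl) {
            seqs[i] <- cand
            starts[i] <- pos - 1L  # 0-based
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) stop("infeasible planting for transcript ", ids[i])
    }
    utrs <- Biostrings::DNAStringSet(seqs)
    names(utrs) <- ids

    # truth: which planted transcripts are functional targets
    is_planted <- planted_class != "none"
    is_true <- rep(FALSE, n)
    if (any(is_planted)) {
      for (cl in names(n_class)) {
        idx <- which(planted_class == cl)
        n_true <- round(cfg$true_target_fraction * length(idx))
        if (n_true > 0) is_true[sample(idx, n_true)] <- TRUE
      }
    }
    effect <- ifelse(is_true, cfg$effects[planted_class], 0)
    effect[is.na(effect)] <- 0
    loading <- ifelse(is_true, cfg$rip_loading, 0)

    base <- stats::rlnorm(n, meanlog = log(20), sdlog = 1.2)
    noise <- function() stats::rnorm(n, 0, cfg$noise_sd)
    mk <- function(mult, label) {
      m <- vapply(seq_len(cfg$replicates),
                  function(r) base * 2^(mult + noise()), numeric(n))
      dimnames(m) <- list(ids, paste0(label, "_", seq_len(cfg$replicates)))
      m
    }
    input <- mk(0, "input")
    rip <- mk(loading, "rip")
    control <- mk(0, "ctrl")
    mimic <- mk(effect, "mimic")

    manifest <- data.frame(
      transcript_id = ids,
      site_class = site_factor(planted_class),
      site_start = starts,
      word = ifelse(is_planted, words[planted_class], NA_character_),
      is_true_target = is_true,
      log2_effect = unname(effect),
      rip_loading = unname(loading),
      stringsAsFactors = FALSE)

    structure(list(utrs = utrs, rip = rip, input = input, mimic = mimic,
                   control = control, manifest = manifest, config = cfg),
              class = "ripuse_simulation")
  })
}

#' @export
print.ripuse_simulation <- function(x, ...) {
  cat("Synthetic RIP-USE experiment:", x$config$n_transcripts, "transcripts,",
      sum(x$manifest$site_class != "none"), "planted,",
      sum(x$manifest$is_true_target), "true targets (seed",
      x$config$seed, ")\n")
  print(table(planted = x$manifest$site_class))
  invisible(x)
}

#' Verify a truth manifest against the emitted sequences
#'
#' Every planted site must be re-found by [scan_sites()] at the recorded
#' position and class.
#'
#' @param utrs `DNAStringSet` from the simulation.
#' @param manifest Manifest data frame.
#' @param mirna The planted [mirna()].
#' @return List with `ok` (logical) and `failures` (data frame of
#'   offending transcripts).
#' @export
verify_manifest <- function(utrs, manifest, mirna) {
  set <- as_utr_set(utrs)
  planted <- manifest[!is.na(manifest$site_start), , drop = FALSE]
  fails <- NULL
  if (nrow(planted)) {
    ann <- scan_sites(set[planted$transcript_id], mirna)
    for (i in seq_len(nrow(planted))) {
      row <- planted[i, ]
      hit <- ann$transcript_id == row$transcript_id &
        ann$start == row$site_start &
        as.character(ann$site_type) == as.character(row$site_class)
      if (!any(hit))
        fails <- rbind(fails, data.frame(transcript_id = row$transcript_id,
                                         expected_class = as.character(row$site_class),
                                         expected_start = row$site_start))
    }
  }
  list(ok = is.null(fails), failures = if (is.null(fails)) data.frame() else fails)
}

#' Write a simulation to disk
#'
#' FASTA for the UTRs, one TSV per abundance table, a manifest TSV, and a
#' `config.txt` echo of the resolved configuration as `key = value` lines.
#'
#' @param sim A [simulate_ripuse_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ripuse_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$utrs, file.path(dir, "utrs.fa"))
  for (tab in c("rip", "input", "mimic", "control")) {
    out <- data.frame(transcript_id = rownames(sim[[tab]]),
                      signif(sim[[tab]], 6), check.names = FALSE)
    utils::write.table(out, file.path(dir, paste0(tab, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  lines <- c(
    paste("n_transcripts =", cfg$n_transcripts),
    paste("utr_length =", paste(cfg$utr_length, collapse = ",")),
    paste("gc =", cfg$gc),
    paste("planting =", paste(sprintf("%s:%g", names(cfg$planting), cfg$planting), collapse = ",")),
    paste("effects =", paste(sprintf("%s:%g", names(cfg$effects), cfg$effects), collapse = ",")),
    paste("true_target_fraction =", cfg$true_target_fraction),
    paste("rip_loading =", cfg$rip_loading),
    paste("noise_sd =", cfg$noise_sd),
    paste("replicates =", cfg$replicates),
    paste("mirna_name =", cfg$mirna$name),
    paste("mirna_seq =", cfg$mirna$mature_seq),
    paste("seed =", cfg$seed))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
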