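# Unbiased word-enrichment landscape: for every k-mer (k in 6..8) and every
# rank cutoff along a ranked transcript list, a signed -log10 hypergeometric
# p-value for over/under-representation of word-bearing transcripts in the
# leading set.

#' Per-transcript word-presence indicators
#'
#' @param utrs Character vector or `DNAStringSet` of UTRs.
#' @param k Word length, one of 6, 7, 8.
#' @return Integer 0/1 matrix, transcripts x 4^k words (columns named by
#'   word). A word counts as present if it occurs at least once; windows
#'   containing non-ACGT characters never match.
#' @export
word_presence <- function(utrs, k) {
  stopifnot(k %in% 6:8)
  set <- as_utr_set(utrs)
  of <- Biostrings::oligonucleotideFrequency(set, width = k)
  m <- (of > 0L) + 0L
  rownames(m) <- names(set)
  m
}

# colSums of presence indicators for a block of sequences
.presence_colsums <- function(set, k) {
  of <- Biostrings::oligonucleotideFrequency(set, width = k)
  colSums(of > 0L)
}

default_cutoffs <- function(n) {
  cuts <- unique(pmax(1L, pmin(n - 1L, round(seq(n / 20, n * 19 / 20, length.out = 20)))))
  sort(cuts)
}

#' Word-enrichment landscape along a ranked transcript list
#'
#' For each word `w` of each `k` and each cutoff `n`, tests whether
#' transcripts whose 3'UTR contains `w` are over- or under-represented in
#' the top-`n` of the ranking, with a one-sided hypergeometric test
#' (population = all ranked transcripts, successes = transcripts containing
#' `w`, draws = `n`). The stored score is `-log10(upper-tail p)` when the
#' leading presence rate exceeds the universe rate, else `log10(lower-tail
#' p)` (negative, depletion).
#'
#' @param ranked A `ranked_list` (see [rank_by_rip_enrichment()]).
#' @param utrs UTR set covering every ranked transcript id.
#' @param k_set Word lengths, subset of 6:8 (default all three).
#' @param cutoffs Strictly increasing rank cutoffs, each smaller than the
#'   universe size. Default: 20 evenly spaced cutoffs from N/20 to 19N/20.
#' @return An object of class `"enrichment_landscape"`: per `k`, matrices
#'   `score`, `raw_p` (the p of the reported tail) and `leading` (presence
#'   counts, words x cutoffs) plus the universe presence totals.
#' @export
word_landscape <- function(ranked, utrs, k_set = c(6, 7, 8), cutoffs = NULL) {
  stopifnot(inherits(ranked, "ranked_list"), all(k_set %in% 6:8), length(k_set) >= 1)
  set <- as_utr_set(utrs)
  ids <- ranked$transcript_id
  missing <- setdiff(ids, names(set))
  if (length(missing))
    stop("ranked transcripts without a UTR: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  N <- length(ids)
  if (is.null(cutoffs)) cutoffs <- default_cutoffs(N)
  cutoffs <- as.integer(cutoffs)
  if (any(diff(cutoffs) <= 0) || any(cutoffs < 1L) || any(cutoffs >= N))
    stop("cutoffs must be strictly increasing, in [1, universe size)")
  ordered_set <- set[ids]
  bounds <- c(0L, cutoffs, N)
  per_k <- list()
  for (k in sort(unique(k_set))) {
    block_sums <- NULL
    for (b in seq_len(length(bounds) - 1L)) {
      sel <- (bounds[b] + 1L):bounds[b + 1L]
      cs <- .presence_colsums(ordered_set[sel], k)
      block_sums <- cbind(block_sums, cs)
    }
    cum <- t(apply(block_sums, 1L, cumsum))
    total <- cum[, ncol(cum)]
    leading <- cum[, seq_along(cutoffs), drop = FALSE]
    colnames(leading) <- as.character(cutoffs)
    draws <- matrix(cutoffs, nrow = nrow(leading), ncol = length(cutoffs), byrow = TRUE)
    K <- matrix(total, nrow = nrow(leading), ncol = length(cutoffs))
    # log-scale tails keep extreme scores finite
    lup <- stats::phyper(leading - 1L, K, N - K, draws, lower.tail = FALSE, log.p = TRUE)
    llo <- stats::phyper(leading, K, N - K, draws, lower.tail = TRUE, log.p = TRUE)
    enriched <- leading / draws > K / N
    score <- ifelse(enriched, -lup / log(10), llo / log(10))
    raw_p <- exp(ifelse(enriched, lup, llo))
    dimnames(score) <- dimnames(raw_p) <- dimnames(leading)
    per_k[[as.character(k)]] <- list(k = k, score = score, raw_p = raw_p,
                                     leading = leading, total = total)
  }
  structure(list(per_k = per_k, cutoffs = cutoffs, universe_n = N,
                 direction = attr(ranked, "direction")),
            class = "enrichment_landscape")
}

#' @export
print.enrichment_landscape <- function(x, ...) {
  cat("Word-enrichment landscape: universe", x$universe_n, "transcripts,",
      length(x$cutoffs), "cutoffs, k =", paste(names(x$per_k), collapse = ","), "\n")
  cat("Ranking direction:", x$direction, "\n")
  tw <- top_words(x, m = 3)
  cat("Top words by corrected peak significance:\n")
  print.data.frame(tw, digits = 3)
  invisible(x)
}

#' Most significant words of a landscape
#'
#' Ranks words by their peak absolute score over cutoffs, with Bonferroni
#' correction over (number of words of that k) x (number of cutoffs).
#'
#' @param landscape An `enrichment_landscape`.
#' @param m Number of words to return (default 20).
#' @param correction Only `"bonferroni"` is implemented.
#' @return Data frame: `k`, `word`, `peak_cutoff`, `peak_score`, `raw_p`,
#'   `p_corrected`, sorted by corrected significance (ties by word).
#' @export
top_words <- function(landscape, m = 20, correction = c("bonferroni")) {
  stopifnot(inherits(landscape, "enrichment_landscape"), m >= 1)
  correction <- match.arg(correction)
  rows <- lapply(landscape$per_k, function(lk) {
    peak_j <- max.col(abs(lk$score), ties.method = "first")
    idx <- cbind(seq_len(nrow(lk$score)), peak_j)
    raw <- lk$raw_p[idx]
    factor <- nrow(lk$score) * ncol(lk$score)
    data.frame(k = lk$k, word = rownames(lk$score),
               peak_cutoff = landscape$cutoffs[peak_j],
               peak_score = lk$score[idx],
               raw_p = raw,
               p_corrected = pmin(1, raw * factor),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_corrected, -abs(out$peak_score), out$word), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, m)
}

#' Score-vs-cutoff profile of a miRNA's four site words
#'
#' @param landscape An `enrichment_landscape` whose `k_set` covers the site
#'   word lengths of interest (6, 7, 8).
#' @param mirna A [mirna()] object.
#' @return List with `curves` (long data frame: site_type, word, cutoff,
#'   score) and `peaks` (one row per site word: peak score and peak cutoff).
#' @export
seed_profile <- function(landscape, mirna) {
  stopifnot(inherits(landscape, "enrichment_landscape"), inherits(mirna, "mirna"))
  words <- seed_words(mirna)
  curves <- NULL; peaks <- NULL
  for (cl in names(words)) {
    w <- words[[cl]]
    kk <- as.character(nchar(w))
    lk <- landscape$per_k[[kk]]
    if (is.null(lk)) next
    sc <- lk$score[w, ]
    curves <- rbind(curves, data.frame(site_type = cl, word = w,
                                       cutoff = landscape$cutoffs,
                                       score = unname(sc),
                                       stringsAsFactors = FALSE))
    j <- which.max(abs(sc))
    peaks <- rbind(peaks, data.frame(site_type = cl, word = w,
                                     peak_cutoff = landscape$cutoffs[j],
                                     peak_score = unname(sc[j]),
                                     stringsAsFactors = FALSE))
  }
  if (is.null(curves)) stop("landscape contains none of the site-word lengths")
  structure(list(curves = curves, peaks = peaks, mirna = mirna$name),
            class = "seed_profile")
}

#' @export
print.seed_profile <- function(x, ...) {
  cat("Seed-word enrichment profile for", x$mirna, "\n")
  print.data.frame(x$peaks, digits = 3)
  invisible(x)
}

#' Write a landscape as long-format TSV
#'
#' Columns: k, word, cutoff, leading_count, universe_count, signed_score,
#' raw_p.
#'
#' @param landscape An `enrichment_landscape`.
#' @param path Output path.
#' @param words Optional character vector restricting the output to selected
#'   words (default: all, which can be large).
#' @export
write_landscape <- function(landscape, path, words = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("k\tword\tcutoff\tleading_count\tuniverse_count\tsigned_score\traw_p\n", file = con)
  for (lk in landscape$per_k) {
    ws <- rownames(lk$score)
    if (!is.null(words)) ws <- intersect(ws, words)
    for (w in ws) {
      lines <- paste(lk$k, w, landscape$cutoffs, lk$leading[w, ],
                     lk$total[[w]], signif(lk$score[w, ], 6),
                     signif(lk$raw_p[w, ], 6), sep = "\t")
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Plot landscape score curves for selected words
#'
#' @param x An `enrichment_landscape`.
#' @param words Words to draw (default: top 5 by corrected significance).
#' @param ... Passed to [graphics::matplot()].
#' @method plot enrichment_landscape
#' @export
plot.enrichment_landscape <- function(x, words = NULL, ...) {
  if (is.null(words)) words <- top_words(x, 5)$word
  curves <- sapply(words, function(w) {
    kk <- as.character(nchar(w))
    if (is.null(x$per_k[[kk]]) || !w %in% rownames(x$per_k[[kk]]$score))
      stop("word not in landscape: ", w)
    x$per_k[[kk]]$score[w, ]
  })
  graphics::matplot(x$cutoffs, curves, type = "l", lty = 1,
                    xlab = "rank cutoff", ylab = "signed -log10 p", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", legend = words, col = seq_along(words),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
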