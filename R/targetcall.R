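# Direct-target calling: overlap of the top AGO2-enriched and top
# down-regulated sets with exact hypergeometric significance, plus the
# GSEA-style motif-density walk used to choose the rank thresholds.

#' Exact hypergeometric overlap test
#'
#' For two sets of sizes `K` and `n` drawn from a universe of `N`, the
#' upper-tail probability of observing at least `x` common members:
#' `p = sum_{i>=x} C(K,i) C(N-K,n-i) / C(N,n)` (computed in log space), with
#' expected overlap `K n / N` and fold enrichment `x / expected`.
#'
#' @param N Universe size.
#' @param K,n Set sizes (each >= 1).
#' @param x Observed overlap, `0 <= x <= min(K, n)`.
#' @return List with `expected`, `fold`, `p`.
#' @export
hypergeom_overlap <- function(N, K, n, x) {
  vals <- c(N, K, n, x)
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0))
    stop("N, K, n, x must be non-negative integers")
  if (K < 1 || n < 1 || K > N || n > N || x > min(K, n))
    stop("inconsistent counts: need 0 <= x <= min(K, n) <= N and K, n >= 1")
  expected <- K * n / N
  p <- exp(stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  list(expected = expected, fold = x / expected, p = p)
}

new_target_call <- function(N, K, n, x, members, extra = list()) {
  h <- hypergeom_overlap(N, K, n, x)
  structure(c(list(N = N, K = K, n = n, x = x, expected = h$expected,
                   fold = h$fold, p = h$p, members = members), extra),
            class = "target_call")
}

#' @export
print.target_call <- function(x, ...) {
  cat(sprintf("Target-set overlap: %d of expected %.2f (fold %.2f) from sets of %d and %d in a universe of %d\n",
              x$x, x$expected, x$fold, x$K, x$n, x$N))
  cat(sprintf("Exact hypergeometric upper-tail p = %.3g\n", x$p))
  invisible(x)
}

#' Call direct targets from the two rankings
#'
#' Direct targets are the intersection of the top `n_rip` AGO2-enriched and
#' the top `n_dw` down-regulated transcripts, with exact hypergeometric
#' significance against the shared universe. Defaults follow the published
#' thresholds (4000 AGO2-loaded, 1300 down-regulated) for universes of at
#' least 20000 transcripts and scale proportionally (20% and 6.5% of the
#' universe) below that.
#'
#' @param rip_ranked Ranking from [rank_by_rip_enrichment()].
#' @param dw_ranked Ranking from [rank_by_regulation()].
#' @param n_rip,n_dw Prefix sizes; `NULL` for the scaled defaults.
#' @return Object of class `"target_call"` with members and their ranks in
#'   both lists.
#' @export
call_direct_targets <- function(rip_ranked, dw_ranked, n_rip = NULL, n_dw = NULL) {
  stopifnot(inherits(rip_ranked, "ranked_list"), inherits(dw_ranked, "ranked_list"))
  a <- rip_ranked$transcript_id
  b <- dw_ranked$transcript_id
  sym <- length(setdiff(a, b)) + length(setdiff(b, a))
  if (sym > 0)
    stop("ranked lists cover different universes (symmetric difference: ", sym, " transcripts)")
  N <- length(a)
  if (is.null(n_rip)) n_rip <- if (N >= 20000) 4000L else max(1L, ceiling(0.20 * N))
  if (is.null(n_dw)) n_dw <- if (N >= 20000) 1300L else max(1L, ceiling(0.065 * N))
  if (n_rip >= N || n_dw >= N) stop("prefix sizes must be smaller than the universe")
  top_rip <- a[seq_len(n_rip)]
  top_dw <- b[seq_len(n_dw)]
  members <- sort(intersect(top_rip, top_dw))
  new_target_call(N, n_rip, n_dw, length(members), members,
                  extra = list(rip_rank = match(members, a),
                               dw_rank = match(members, b)))
}

#' Overlap between the target sets of two miRNAs
#'
#' @param targets_a,targets_b Character vectors of target ids.
#' @param universe Universe size (integer) or character vector of universe
#'   ids (then both sets must be subsets).
#' @return A `"target_call"` object.
#' @export
mirna_set_overlap <- function(targets_a, targets_b, universe) {
  targets_a <- unique(targets_a); targets_b <- unique(targets_b)
  if (is.character(universe)) {
    if (!all(targets_a %in% universe) || !all(targets_b %in% universe))
      stop("target sets must be subsets of the universe")
    N <- length(unique(universe))
  } else {
    N <- as.integer(universe)
  }
  members <- sort(intersect(targets_a, targets_b))
  new_target_call(N, length(targets_a), length(targets_b), length(members), members)
}

#' GSEA-style site-density walk along a ranked list
#'
#' A running score walks along the ranking: +1/#hits at each transcript
#' whose UTR contains the site word of `site_class`, -1/#misses otherwise
#' (classic unweighted Kolmogorov-Smirnov-like walk, starting and ending at
#' 0). The argmax rank marks where site density is highest and is reported
#' as the suggested prefix size.
#'
#' @param ranked A `ranked_list`.
#' @param utrs UTR set covering the ranking.
#' @param mirna A [mirna()] object.
#' @param site_class Site class whose word defines a hit (default
#'   `"7mer-m8"`).
#' @return Object of class `"density_profile"`: `walk` data frame (rank,
#'   score), `argmax` rank, `n_hits`, `site_class`.
#' @export
density_profile <- function(ranked, utrs, mirna, site_class = "7mer-m8") {
  stopifnot(inherits(ranked, "ranked_list"))
  site_class <- match.arg(site_class, .site_classes())
  set <- as_utr_set(utrs)
  ids <- ranked$transcript_id
  missing <- setdiff(ids, names(set))
  if (length(missing)) stop("ranked transcripts without a UTR: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  word <- seed_site_word(mirna, site_class)
  hit <- Biostrings::vcountPattern(word, set[ids]) > 0L
  nh <- sum(hit); nm <- sum(!hit)
  if (nh == 0L) stop("no site-bearing transcript for ", site_class, " word ", word)
  step <- ifelse(hit, 1 / nh, -1 / nm)
  walk <- cumsum(step)
  argmax <- which.max(walk)
  structure(list(walk = data.frame(rank = seq_along(walk), score = walk),
                 argmax = argmax, n_hits = nh, site_class = site_class,
                 word = word, mirna = mirna$name),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Site-density walk (%s word %s, %d hits): peak at rank %d (score %.3f)\n",
              x$site_class, x$word, x$n_hits, x$argmax,
              x$walk$score[x$argmax]))
  invisible(x)
}

#' @method plot density_profile
#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$walk$rank, x$walk$score, type = "l",
                 xlab = "rank", ylab = "running enrichment score", ...)
  graphics::abline(v = x$argmax, lty = 2, col = "red3")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Write called targets as TSV (transcript_id, rip_rank, dw_rank)
#' @param call A `target_call` from [call_direct_targets()].
#' @param path Output path.
#' @export
write_target_call <- function(call, path) {
  stopifnot(inherits(call, "target_call"))
  out <- data.frame(transcript_id = call$members,
                    rip_rank = if (!is.null(call$rip_rank)) call$rip_rank else NA,
                    dw_rank = if (!is.null(call$dw_rank)) call$dw_rank else NA)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
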