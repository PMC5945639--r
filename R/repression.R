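# Cumulative-distribution validation: are transcripts carrying each seed
# site class more down-regulated than site-free transcripts?

#' Partition transcripts by strongest site class
#'
#' Each transcript is assigned to exactly one class by [best_site_type()]
#' (a transcript carrying both an 8mer and a 6mer counts as 8mer), together
#' with its log2 fold change.
#'
#' @param ids Transcript universe (unique ids).
#' @param utrs UTR set covering every id.
#' @param mirna A [mirna()] object.
#' @param log2fc Per-transcript log2 fold change, named by id or in `ids`
#'   order.
#' @return Object of class `"site_partition"`: data frame `transcript_id`,
#'   `site_class` (ordered factor), `log2fc`.
#' @export
partition_by_site <- function(ids, utrs, mirna, log2fc) {
  if (anyDuplicated(ids)) stop("duplicated transcript ids in the universe")
  set <- as_utr_set(utrs)
  missing <- setdiff(ids, names(set))
  if (length(missing))
    stop("transcripts without a UTR: ", paste(utils::head(missing, 5), collapse = ", "))
  if (!is.null(names(log2fc))) {
    if (!all(ids %in% names(log2fc))) stop("log2fc missing for some transcripts")
    log2fc <- log2fc[ids]
  }
  if (length(log2fc) != length(ids)) stop("log2fc must match the universe")
  if (anyNA(log2fc) || any(!is.finite(log2fc))) stop("log2fc must be finite")
  cls <- best_site_type(set[ids], mirna)
  out <- data.frame(transcript_id = ids, site_class = cls,
                    log2fc = unname(log2fc), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("site_partition", "data.frame")
  out
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_group - ECDF_background|`; the p-value uses the
#' asymptotic two-sample formula (effective size `n_g n_b / (n_g + n_b)`)
#' by default, or the exact distribution for small samples when
#' `exact = TRUE`.
#'
#' @param group,background Numeric samples (each non-empty; a warning is
#'   issued below 8 observations where p is not meaningful).
#' @param exact Logical, default `FALSE` (asymptotic).
#' @return Object of class `"ks_result"`: `D`, `p`, `n_group`,
#'   `n_background`, `mean_shift` (group mean minus background mean).
#' @export
ks_two_sided <- function(group, background, exact = FALSE) {
  if (length(group) < 1L || length(background) < 1L)
    stop("both samples must be non-empty")
  if (length(group) < 8L || length(background) < 8L)
    warning("KS p-value is unreliable for samples smaller than 8")
  kt <- suppressWarnings(stats::ks.test(group, background,
                                        alternative = "two.sided", exact = exact))
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 n_group = length(group), n_background = length(background),
                 mean_shift = mean(group) - mean(background)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sided KS: D = %.4f, p = %.3g (n = %d vs %d), mean shift = %+.3f\n",
              x$D, x$p, x$n_group, x$n_background, x$mean_shift))
  invisible(x)
}

#' Per-class repression report
#'
#' One KS test per non-empty site class against the site-free background,
#' plus a pooled "any site" row, and a flag for whether mean log2FC shifts
#' follow the canonical hierarchy 8mer <= 7mer-m8 <= 7mer-1A <= 6mer <= 0
#' (more negative = more repressed).
#'
#' @param partition A [partition_by_site()] result.
#' @param min_background Minimum size of the site-free group (default 8).
#' @param exact Passed to [ks_two_sided()].
#' @return Object of class `"repression_report"`: `table` (site_class, n,
#'   mean_shift, D, p), `hierarchy_ordered` flag, `background_n`.
#' @export
repression_report <- function(partition, min_background = 8, exact = FALSE) {
  stopifnot(inherits(partition, "site_partition"))
  bg <- partition$log2fc[partition$site_class == "none"]
  if (length(bg) < min_background)
    stop("site-free background too small (", length(bg), " < ", min_background, ")")
  classes <- c(.site_classes(), "any site")
  rows <- NULL
  for (cl in classes) {
    vals <- if (cl == "any site") partition$log2fc[partition$site_class != "none"]
            else partition$log2fc[partition$site_class == cl]
    if (length(vals) == 0L) next
    ks <- ks_two_sided(vals, bg, exact = exact)
    rows <- rbind(rows, data.frame(site_class = cl, n = ks$n_group,
                                   mean_shift = ks$mean_shift, D = ks$D,
                                   p = ks$p, stringsAsFactors = FALSE))
  }
  shifts <- rows$mean_shift[match(.site_classes(), rows$site_class)]
  present <- !is.na(shifts)
  ordered_flag <- all(diff(shifts[present]) >= 0) && all(shifts[present] <= 0)
  structure(list(table = rows, hierarchy_ordered = ordered_flag,
                 background_n = length(bg)),
            class = "repression_report")
}

#' @export
print.repression_report <- function(x, ...) {
  cat("Repression by site class (KS vs", x$background_n, "site-free transcripts)\n")
  print.data.frame(x$table, digits = 3)
  cat("Mean-shift hierarchy 8mer <= 7mer-m8 <= 7mer-1A <= 6mer <= 0:",
      if (x$hierarchy_ordered) "yes" else "no", "\n")
  invisible(x)
}

#' Write a repression report as TSV
#' @param report A `repression_report`.
#' @param path Output path.
#' @export
write_repression_report <- function(report, path) {
  out <- report$table
  for (col in c("mean_shift", "D", "p")) out[[col]] <- signif(out[[col]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cumulative-distribution plot of log2 fold change by site class
#'
#' Empirical CDFs of the log2 fold change for each site class and the
#' site-free background.
#'
#' @param x A `site_partition`.
#' @param ... Passed to [graphics::plot()].
#' @method plot site_partition
#' @export
plot.site_partition <- function(x, ...) {
  lv <- c("none", .site_classes())
  cols <- c("grey40", "red3", "orange3", "dodgerblue3", "seagreen4")
  rng <- range(x$log2fc)
  graphics::plot(NA, xlim = rng, ylim = c(0, 1), xlab = "log2 fold change",
                 ylab = "cumulative fraction", ...)
  for (i in seq_along(lv)) {
    vals <- x$log2fc[x$site_class == lv[i]]
    if (length(vals) < 2) next
    graphics::lines(stats::ecdf(vals), col = cols[i], do.points = FALSE, verticals = TRUE)
  }
  graphics::legend("bottomright", legend = lv, col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
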