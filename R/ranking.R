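# Abundance tables and the two ranked transcript lists the pipeline
# consumes: AGO2 enrichment (RIP vs input) and post-overexpression
# regulation (mimic vs negative control).

# Coerce to a non-negative numeric matrix with unique transcript-id rownames.
as_abundance <- function(x, what = "abundance table") {
  if (is.data.frame(x)) {
    idcol <- which(names(x) %in% c("transcript_id", "id"))[1]
    if (!is.na(idcol)) {
      rn <- as.character(x[[idcol]])
      x <- as.matrix(x[, -idcol, drop = FALSE])
      rownames(x) <- rn
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix or data frame")
  if (is.null(rownames(x)))
    stop(what, " must have transcript ids as rownames (or a transcript_id column)")
  if (anyDuplicated(rownames(x)))
    stop(what, " has duplicated transcript ids")
  if (ncol(x) < 1L)
    stop(what, " needs at least one sample column")
  if (anyNA(x) || any(x < 0))
    stop(what, " contains negative or missing abundances")
  x
}

#' Pseudocounted log2 abundance ratio
#'
#' `log2((treated + pseudocount) / (control + pseudocount))`; finite for any
#' non-negative abundances.
#'
#' @param treated,control Non-negative abundances (vectors, recycled).
#' @param pseudocount Positive stabilizer on the abundance (RPKM) scale;
#'   default 0.5.
#' @return Numeric vector of log2 ratios.
#' @export
log2_ratio <- function(treated, control, pseudocount = 0.5) {
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (anyNA(treated) || anyNA(control) || any(treated < 0) || any(control < 0))
    stop("abundances must be non-negative and non-missing")
  log2((treated + pseudocount) / (control + pseudocount))
}

#' Convert raw counts to RPKM
#'
#' `rpkm = count * 1e9 / (library_size * length)` where library size is the
#' per-column count total.
#'
#' @param counts Count matrix (transcripts x samples, rownames = ids).
#' @param lengths Transcript lengths in nt, named by transcript id or in row
#'   order.
#' @return RPKM matrix of the same shape.
#' @export
counts_to_rpkm <- function(counts, lengths) {
  counts <- as_abundance(counts, "count table")
  if (!is.null(names(lengths))) {
    if (!all(rownames(counts) %in% names(lengths)))
      stop("missing transcript length for: ",
           paste(utils::head(setdiff(rownames(counts), names(lengths)), 5), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop("lengths must match the number of transcripts")
  if (anyNA(lengths) || any(lengths <= 0)) stop("transcript lengths must be positive")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("per-column library size must be > 0")
  sweep(counts / lengths, 2L, lib, "/") * 1e9
}

new_ranked_list <- function(ids, statistic, direction, decreasing) {
  ord <- order(if (decreasing) -statistic else statistic, ids, method = "radix")
  out <- data.frame(rank = seq_along(ids),
                    transcript_id = ids[ord],
                    statistic = statistic[ord],
                    stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("ranked_list", "data.frame")
  out
}

rank_common <- function(a, b, what_a, what_b) {
  a <- as_abundance(a, what_a)
  b <- as_abundance(b, what_b)
  ids <- intersect(rownames(a), rownames(b))
  if (length(ids) == 0L) stop("no transcripts shared between ", what_a, " and ", what_b)
  list(a = rowMeans(a[ids, , drop = FALSE]),
       b = rowMeans(b[ids, , drop = FALSE]),
       ids = ids)
}

#' Rank transcripts by AGO2-RIP enrichment
#'
#' Replicate columns are averaged per condition, then transcripts shared by
#' both tables are sorted from the most to the least AGO2-enriched by
#' `log2((RIP + pc) / (reference + pc))`. Ties break lexicographically by
#' transcript id.
#'
#' @param rip,reference Abundance tables (matrix/data frame, rownames or
#'   `transcript_id` column) for the RIP and the input/control condition.
#' @param pseudocount See [log2_ratio()].
#' @return A `ranked_list` data frame (`rank`, `transcript_id`,
#'   `statistic`), direction `"rip_enrichment_desc"`.
#' @export
rank_by_rip_enrichment <- function(rip, reference, pseudocount = 0.5) {
  z <- rank_common(rip, reference, "RIP table", "reference table")
  stat <- log2_ratio(z$a, z$b, pseudocount)
  new_ranked_list(z$ids, stat, "rip_enrichment_desc", decreasing = TRUE)
}

#' Rank transcripts by post-overexpression regulation
#'
#' Sorts transcripts by `log2((mimic + pc) / (control + pc))` ascending, so
#' the most down-regulated transcripts lead the list and repressed-target
#' motif enrichment appears at the list head (mirroring the head of the RIP
#' ranking). Set `most_downregulated_first = FALSE` to reverse.
#'
#' @param overexpr,negctrl Abundance tables for the miRNA-mimic and the
#'   negative-control condition.
#' @param pseudocount See [log2_ratio()].
#' @param most_downregulated_first Logical; default `TRUE`.
#' @return A `ranked_list` data frame, direction `"downregulation_first"`
#'   (or `"upregulation_first"`).
#' @export
rank_by_regulation <- function(overexpr, negctrl, pseudocount = 0.5,
                               most_downregulated_first = TRUE) {
  z <- rank_common(overexpr, negctrl, "overexpression table", "negative-control table")
  stat <- log2_ratio(z$a, z$b, pseudocount)
  new_ranked_list(z$ids, stat,
                  if (most_downregulated_first) "downregulation_first" else "upregulation_first",
                  decreasing = !most_downregulated_first)
}

#' Reverse a ranked list
#'
#' @param ranked A `ranked_list`.
#' @return The same list in reverse order with rank renumbered.
#' @export
reverse_ranking <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_list"))
  out <- ranked[rev(seq_len(nrow(ranked))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "direction") <- paste0("reversed:", attr(ranked, "direction"))
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("Ranked transcript list (", nrow(x), " transcripts; direction: ",
      attr(x, "direction"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write a ranked list as 3-column TSV (rank, transcript_id, statistic)
#' @param ranked A `ranked_list`.
#' @param path Output file path.
#' @export
write_ranked_list <- function(ranked, path) {
  out <- as.data.frame(ranked)
  out$statistic <- signif(out$statistic, 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked list written by [write_ranked_list()]
#' @param path TSV path.
#' @param direction Direction tag to attach.
#' @return A `ranked_list`.
#' @export
read_ranked_list <- function(path, direction = "unknown") {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rank", "transcript_id", "statistic") %in% names(x)))
    stop("ranked-list file must have columns rank, transcript_id, statistic: ", path)
  x <- x[order(x$rank), c("rank", "transcript_id", "statistic")]
  rownames(x) <- NULL
  attr(x, "direction") <- direction
  class(x) <- c("ranked_list", "data.frame")
  x
}
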