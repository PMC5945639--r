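# End-to-end analysis: from UTRs + abundance tables to ranked lists,
# word-enrichment landscapes, repression validation and called targets.

#' The two miRNAs the package ships as references
#'
#' Mature sequences of hsa-miR-125b-5p and hsa-miR-100-5p.
#' @return [mirna()] objects.
#' @export
default_mirna <- function() mirna("hsa-miR-125b-5p", "UCCCUGAGACCCUAACUUGUGA")

#' @rdname default_mirna
#' @export
mir100_5p <- function() mirna("hsa-miR-100-5p", "AACCCGUAGAUCCGAACUUGUG")

#' @rdname default_mirna
#' @export
mir125b_5p <- function() default_mirna()

#' Run the full target-identification analysis
#'
#' Orchestrates the pipeline on one miRNA: (i) transcripts shared by all
#' abundance tables and the UTR set form the universe; (ii) they are ranked
#' by AGO2-RIP enrichment and by post-overexpression down-regulation;
#' (iii) word-enrichment landscapes and the miRNA's seed-word profiles are
#' computed on both rankings; (iv) transcripts are partitioned by strongest
#' site class and each class is tested against the site-free background
#' with a two-sided KS test on the log2 fold change; (v) direct targets are
#' called as the overlap of the top AGO2-enriched and top down-regulated
#' prefixes with an exact hypergeometric test.
#'
#' @param utrs 3'UTR set (named `DNAStringSet`, character vector, or a
#'   FASTA path).
#' @param mirna A [mirna()] object.
#' @param rip,rip_reference Abundance tables for AGO2-RIP and its
#'   input/reference condition.
#' @param overexpr,control Abundance tables for the miRNA-mimic and
#'   negative-control condition.
#' @param pseudocount See [log2_ratio()].
#' @param k_set Landscape word lengths (default 6:8).
#' @param cutoffs Landscape rank cutoffs (default: 20 evenly spaced).
#' @param n_rip,n_dw Target-call prefix sizes (default: published values,
#'   scaled for small universes; see [call_direct_targets()]).
#' @param landscapes Compute the word landscapes (the expensive step);
#'   default `TRUE`.
#' @return Object of class `"rip_use"` with components `universe`,
#'   `ranked_rip`, `ranked_dw`, `landscape_rip`, `landscape_dw`,
#'   `seed_profile_rip`, `seed_profile_dw`, `partition`, `repression`,
#'   `targets`, `mirna`, `params`.
#' @examples
#' sim <- simulate_ripuse_experiment(synth_config(n_transcripts = 300, seed = 42))
#' fit <- rip_use(sim$utrs, sim$config$mirna, sim$rip, sim$input,
#'                sim$mimic, sim$control, k_set = 7)
#' fit
#' @export
rip_use <- function(utrs, mirna, rip, rip_reference, overexpr, control,
                    pseudocount = 0.5, k_set = c(6, 7, 8), cutoffs = NULL,
                    n_rip = NULL, n_dw = NULL, landscapes = TRUE) {
  stopifnot(inherits(mirna, "mirna"))
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs))
    utrs <- read_utr_fasta(utrs)
  set <- as_utr_set(utrs)
  tabs <- list(rip = as_abundance(rip, "RIP table"),
               rip_reference = as_abundance(rip_reference, "RIP reference table"),
               overexpr = as_abundance(overexpr, "overexpression table"),
               control = as_abundance(control, "control table"))
  universe <- Reduce(intersect, c(lapply(tabs, rownames), list(names(set))))
  n_dropped <- length(unique(unlist(lapply(tabs, rownames)))) - length(universe)
  if (length(universe) < 10L)
    stop("universe too small after intersecting tables and UTRs (",
         length(universe), " transcripts)")
  tabs <- lapply(tabs, function(t) t[universe, , drop = FALSE])
  set <- set[universe]

  ranked_rip <- rank_by_rip_enrichment(tabs$rip, tabs$rip_reference, pseudocount)
  ranked_dw <- rank_by_regulation(tabs$overexpr, tabs$control, pseudocount)

  land_rip <- land_dw <- prof_rip <- prof_dw <- NULL
  if (landscapes) {
    land_rip <- word_landscape(ranked_rip, set, k_set = k_set, cutoffs = cutoffs)
    land_dw <- word_landscape(ranked_dw, set, k_set = k_set, cutoffs = cutoffs)
    prof_rip <- tryCatch(seed_profile(land_rip, mirna), error = function(e) NULL)
    prof_dw <- tryCatch(seed_profile(land_dw, mirna), error = function(e) NULL)
  }

  fc <- log2_ratio(rowMeans(tabs$overexpr), rowMeans(tabs$control), pseudocount)
  names(fc) <- universe
  partition <- partition_by_site(universe, set, mirna, fc)
  repression <- tryCatch(repression_report(partition), error = function(e) e)

  targets <- call_direct_targets(ranked_rip, ranked_dw, n_rip = n_rip, n_dw = n_dw)

  structure(list(universe = universe, n_dropped = n_dropped, utrs = set,
                 ranked_rip = ranked_rip, ranked_dw = ranked_dw,
                 landscape_rip = land_rip, landscape_dw = land_dw,
                 seed_profile_rip = prof_rip, seed_profile_dw = prof_dw,
                 partition = partition, repression = repression,
                 targets = targets, mirna = mirna,
                 params = list(pseudocount = pseudocount, k_set = k_set,
                               n_rip = targets$K, n_dw = targets$n)),
            class = "rip_use")
}

#' @export
print.rip_use <- function(x, ...) {
  cat("RIP-USE analysis for", x$mirna$name, "\n")
  cat("Universe:", length(x$universe), "transcripts (",
      x$n_dropped, "dropped by intersection )\n")
  cat(sprintf("Called targets: %d (expected %.1f, fold %.2f, p = %.3g) from top %d RIP x top %d down-regulated\n",
              x$targets$x, x$targets$expected, x$targets$fold, x$targets$p,
              x$targets$K, x$targets$n))
  invisible(x)
}

#' @method summary rip_use
#' @export
summary.rip_use <- function(object, ...) {
  structure(list(fit = object), class = "summary.rip_use")
}

#' @export
print.summary.rip_use <- function(x, ...) {
  f <- x$fit
  print(f)
  if (inherits(f$repression, "repression_report")) {
    cat("\n"); print(f$repression)
  }
  if (!is.null(f$seed_profile_dw)) {
    cat("\nSeed-word peaks (down-regulation ranking):\n")
    print.data.frame(f$seed_profile_dw$peaks, digits = 3)
  }
  if (!is.null(f$landscape_dw)) {
    cat("\nTop words (down-regulation ranking):\n")
    print.data.frame(top_words(f$landscape_dw, 5), digits = 3)
  }
  invisible(x)
}

#' Plot a fitted analysis
#'
#' @param x A `rip_use` object.
#' @param type `"cdf"` (repression cumulative distributions),
#'   `"landscape"` (seed-word enrichment curves on the chosen ranking), or
#'   `"density"` (site-density walk).
#' @param ranking `"dw"` or `"rip"` for landscape/density panels.
#' @param ... Passed to the underlying plot.
#' @method plot rip_use
#' @export
plot.rip_use <- function(x, type = c("cdf", "landscape", "density"),
                         ranking = c("dw", "rip"), ...) {
  type <- match.arg(type)
  ranking <- match.arg(ranking)
  if (type == "cdf") return(invisible(plot(x$partition, ...)))
  if (type == "landscape") {
    land <- if (ranking == "dw") x$landscape_dw else x$landscape_rip
    if (is.null(land)) stop("landscapes were not computed")
    words <- intersect(unname(seed_words(x$mirna)),
                       unlist(lapply(land$per_k, function(l) rownames(l$score))))
    return(invisible(plot(land, words = words, ...)))
  }
  ranked <- if (ranking == "dw") x$ranked_dw else x$ranked_rip
  prof <- density_profile(ranked, x$utrs, x$mirna)
  invisible(plot(prof, ...))
}
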