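# Shared fixtures and independent oracles.

mir100 <- mirna("hsa-miR-100-5p", "AACCCGUAGAUCCGAACUUGUG")
mir125b <- mirna("hsa-miR-125b-5p", "UCCCUGAGACCCUAACUUGUGA")

# independent reverse complement (no Biostrings) for cross-checks
rc_oracle <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# exhaustive hypergeometric point-mass summation (log-space), upper tail
# P(X >= x) for overlap x of sets K, n in universe N
hyper_upper_brute <- function(x, K, N, n) {
  i <- x:min(K, n)
  if (length(i) == 0L || x > min(K, n)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

hyper_lower_brute <- function(x, K, N, n) {
  i <- max(0, n - (N - K)):x
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

hyper_point_brute <- function(x, K, N, n) {
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}

# manual two-sample KS D statistic (sup over pooled support)
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# build a ranked_list directly from an ordered id vector (fixture shortcut;
# the structure is the documented data.frame contract)
make_ranked <- function(ids, statistic = seq_along(ids),
                        direction = "rip_enrichment_desc") {
  out <- data.frame(rank = seq_along(ids), transcript_id = ids,
                    statistic = statistic, stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("ranked_list", "data.frame")
  out
}

# random miRNA sequence of given length
random_mirna <- function(len = 22) {
  mirna("rnd", paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                     collapse = ""))
}

# reference simulation (generator defaults, seed 1), built once per test run
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_ripuse_experiment(synth_config(seed = 1))
  .sim_cache$sim
}

# single-stratum simulation: 15% planted 7mer-m8 true targets (seed 1)
seed_recovery_sim <- function() {
  if (is.null(.sim_cache$sim7))
    .sim_cache$sim7 <- simulate_ripuse_experiment(synth_config(
      planting = c("7mer-m8" = 0.15), effects = c("7mer-m8" = -0.6), seed = 1))
  .sim_cache$sim7
}
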