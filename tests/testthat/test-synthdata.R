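small_cfg <- function(seed, ...) {
  synth_config(n_transcripts = 300, utr_length = c(200, 300), seed = seed, ...)
}

test_that("identical seeds reproduce the experiment byte for byte", {
  s1 <- simulate_ripuse_experiment(small_cfg(7))
  s2 <- simulate_ripuse_experiment(small_cfg(7))
  expect_identical(as.character(s1$utrs), as.character(s2$utrs))
  expect_identical(s1$rip, s2$rip)
  expect_identical(s1$mimic, s2$mimic)
  expect_identical(s1$manifest, s2$manifest)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  s3 <- simulate_ripuse_experiment(small_cfg(8))
  expect_false(identical(as.character(s1$utrs), as.character(s3$utrs)))
})

test_that("without planting, site words occur at the random background rate", {
  cfg <- synth_config(n_transcripts = 400, utr_length = c(400, 500),
                      planting = c("7mer-m8" = 0), seed = 5)
  sim <- simulate_ripuse_experiment(cfg)
  word <- seed_site_word(cfg$mirna, "7mer-m8")
  lens <- Biostrings::width(sim$utrs)
  expected <- sum(lens - 7 + 1) / 4^7  # Poisson background mean
  observed <- word_census(sim$utrs, word)
  expect_lt(abs(observed - expected), 5 * sqrt(expected) + 3)
  expect_true(all(sim$manifest$site_class == "none"))
})

test_that("planted fractions and effects are realized as configured", {
  sim <- default_sim()
  cfg <- sim$config
  n <- cfg$n_transcripts
  tab <- table(sim$manifest$site_class)
  for (cl in names(cfg$planting))
    expect_lt(abs(tab[[cl]] / n - cfg$planting[[cl]]), 0.02)
  fc <- log2_ratio(rowMeans(sim$mimic), rowMeans(sim$control))
  dev <- numeric(0)
  for (cl in names(cfg$planting)) {
    sel <- sim$manifest$site_class == cl & sim$manifest$is_true_target
    expect_lt(abs(mean(fc[sel]) - cfg$effects[[cl]]), 0.1)
    dev <- c(dev, fc[sel] - cfg$effects[[cl]])
  }
  # noise-averaged over all true targets the bias is tight
  expect_lt(abs(mean(dev)), 0.05)
  rip_fc <- log2_ratio(rowMeans(sim$rip), rowMeans(sim$input))
  expect_lt(abs(mean(rip_fc[sim$manifest$is_true_target]) - cfg$rip_loading), 0.05)
})

test_that("planted classes are exact: no accidental upgrades, clean background", {
  sim <- default_sim()
  cls <- best_site_type(sim$utrs, sim$config$mirna)
  expect_identical(as.character(cls), as.character(sim$manifest$site_class))
  v <- verify_manifest(sim$utrs, sim$manifest, sim$config$mirna)
  expect_true(v$ok)
})

test_that("manifest verification flags corrupted sites", {
  sim <- simulate_ripuse_experiment(small_cfg(9))
  planted <- which(!is.na(sim$manifest$site_start))[1]
  id <- sim$manifest$transcript_id[planted]
  seqs <- as.character(sim$utrs)
  pos <- sim$manifest$site_start[planted] + 1L
  base <- substr(seqs[[id]], pos, pos)
  substr(seqs[[id]], pos, pos) <- if (base == "G") "C" else "G"
  v <- verify_manifest(seqs, sim$manifest, sim$config$mirna)
  expect_false(v$ok)
  expect_true(id %in% v$failures$transcript_id)
  # an empty manifest is vacuously verified
  empty <- sim$manifest[0, ]
  expect_true(verify_manifest(sim$utrs, empty, sim$config$mirna)$ok)
})

test_that("infeasible planting and invalid configurations are rejected", {
  expect_error(simulate_ripuse_experiment(
    synth_config(n_transcripts = 10, utr_length = c(4, 6), seed = 1)),
    "infeasible planting")
  expect_error(synth_config(seed = NULL), "seed is mandatory")
  expect_error(synth_config(planting = c("8mer" = 0.7, "6mer" = 0.6), seed = 1),
               "sum to <= 1")
  expect_error(synth_config(effects = c("8mer" = 0.5, "7mer-m8" = -0.6,
                                        "7mer-1A" = -0.4, "6mer" = -0.2), seed = 1),
               "repression")
})

test_that("abundance tables are consistent with the truth manifest", {
  sim <- simulate_ripuse_experiment(small_cfg(10))
  expect_identical(rownames(sim$rip), sim$manifest$transcript_id)
  expect_equal(ncol(sim$mimic), sim$config$replicates)
  expect_true(all(sim$rip >= 0) && all(sim$mimic >= 0))
  expect_equal(sum(sim$manifest$is_true_target),
               sum(sim$manifest$site_class != "none"))  # default fraction 1
})
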