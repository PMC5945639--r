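test_that("word presence indicators enumerate distinct k-mers", {
  p <- word_presence(c(u = "TACGGGTA"), 6)
  expect_equal(sum(p), 3L)  # TACGGG, ACGGGT, CGGGTA
  expect_equal(unname(p[1, c("TACGGG", "ACGGGT", "CGGGTA")]), c(1L, 1L, 1L))
  expect_equal(sum(word_presence(c(u = "ACG"), 6)), 0L)  # shorter than k
  expect_equal(max(word_presence(c(u = "ACGTACACGTAC"), 6)), 1L)  # presence, not count
})

test_that("landscape p-values match exact combinatorics on a toy universe", {
  word <- "ACGTCA"
  ids <- sprintf("t%02d", 1:10)
  utrs <- setNames(c(paste0("GGGGGGGGGG", word),  # word in exactly the top 5
                     paste0("CCCCCCCCCC", word),
                     paste0("GGGGCCCCGG", word),
                     paste0("CCGGCCGGCC", word),
                     paste0("GCGCGCGCGC", word),
                     rep("GGGGCCCCGGGGCCCC", 5)), ids)
  land <- word_landscape(make_ranked(ids), utrs, k_set = 6, cutoffs = 5)
  sc <- land$per_k[["6"]]$score[word, "5"]
  p <- land$per_k[["6"]]$raw_p[word, "5"]
  expect_equal(p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(unname(sc), -log10(1 / choose(10, 5)), tolerance = 1e-9)
  expect_equal(unname(p), hyper_upper_brute(5, K = 5, N = 10, n = 5), tolerance = 1e-12)
})

test_that("every landscape cell agrees with brute-force point-mass summation", {
  set.seed(13)
  ids <- sprintf("t%02d", 1:20)
  utrs <- setNames(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1)), ids)
  land <- word_landscape(make_ranked(ids), utrs, k_set = 6, cutoffs = c(3, 7, 12, 16))
  lk <- land$per_k[["6"]]
  # check all words present somewhere plus a sample of absent words
  words <- union(names(lk$total[lk$total > 0]), sample(rownames(lk$score), 50))
  for (w in words) {
    K <- lk$total[[w]]
    for (j in seq_along(land$cutoffs)) {
      n <- land$cutoffs[j]
      x <- lk$leading[w, j]
      up <- hyper_upper_brute(x, K, 20, n)
      lo <- hyper_lower_brute(x, K, 20, n)
      expect_equal(unname(lk$raw_p[w, j]),
                   if (x / n > K / 20) up else lo, tolerance = 1e-12)
      # tail sum rule
      expect_equal(up + lo - hyper_point_brute(x, K, 20, n), 1, tolerance = 1e-12)
    }
  }
})

test_that("degenerate words give p = 1 and score 0 everywhere", {
  ids <- c("a", "b", "c", "d")
  utrs <- setNames(rep("ACGTACGTAC", 4), ids)  # ACGTAC present in all
  land <- word_landscape(make_ranked(ids), utrs, k_set = 6, cutoffs = c(1, 2, 3))
  expect_equal(unname(land$per_k[["6"]]$raw_p["ACGTAC", ]), rep(1, 3))
  expect_equal(unname(land$per_k[["6"]]$score["ACGTAC", ]), rep(0, 3))
  # a word absent from every UTR likewise
  expect_equal(unname(land$per_k[["6"]]$raw_p["TTTTTT", ]), rep(1, 3))
})

test_that("reversing the ranked list flips the sign of the enrichment peak", {
  word <- "ACGTCA"
  ids <- sprintf("t%02d", 1:10)
  utrs <- setNames(c(rep(paste0("GGGGCCGGCC", word), 5),
                     rep("GGGGCCCCGGGGCCCC", 5)), ids)
  rk <- make_ranked(ids)
  land_f <- word_landscape(rk, utrs, k_set = 6, cutoffs = 5)
  land_r <- word_landscape(reverse_ranking(rk), utrs, k_set = 6, cutoffs = 5)
  expect_gt(land_f$per_k[["6"]]$score[word, "5"], 0)
  expect_lt(land_r$per_k[["6"]]$score[word, "5"], 0)
})

test_that("top_words applies the Bonferroni factor words-by-cutoffs", {
  word <- "ACGTCA"
  ids <- sprintf("t%02d", 1:10)
  utrs <- setNames(c(rep(paste0("GGGGCCGGCC", word), 5),
                     rep("GGGGCCCCGGGGCCCC", 5)), ids)
  land <- word_landscape(make_ranked(ids), utrs, k_set = 6, cutoffs = c(3, 5))
  tw <- top_words(land, m = 5)
  expect_equal(tw$word[1], word)
  i <- which(tw$word == word)
  expect_equal(tw$p_corrected[i], min(1, tw$raw_p[i] * 4^6 * 2))
})

test_that("a planted head-concentrated word is the top word of its class", {
  word <- "TAGCCGT"
  for (seed in 1:5) {
    utrs <- random_utrs(400, length_range = c(150, 250), seed = seed,
                        exclude_words = word)
    head_ids <- names(utrs)[1:60]
    utrs[head_ids] <- plant_occurrences(utrs[head_ids], word, 1, seed = seed + 100)
    land <- word_landscape(make_ranked(names(utrs)), utrs, k_set = 7)
    tw <- top_words(land, 1)
    expect_equal(tw$word, word)
    expect_lt(tw$p_corrected, 0.05)
  }
})

test_that("null landscapes stay below the Bonferroni threshold", {
  ok <- 0L
  for (seed in 1:5) {
    utrs <- random_utrs(300, length_range = c(150, 250), seed = seed)
    land <- word_landscape(make_ranked(names(utrs)), utrs, k_set = 7)
    ok <- ok + (min(top_words(land, 1)$p_corrected) >= 0.05)
  }
  expect_gte(ok, 4L)  # mirrors the 95%-of-replicates null property
})

test_that("seed_profile locates the planted target-set size", {
  sim <- seed_recovery_sim()  # 300 planted 7mer-m8 true targets
  rk <- rank_by_rip_enrichment(sim$rip, sim$input)
  land <- word_landscape(rk, sim$utrs, k_set = 7)
  prof <- seed_profile(land, sim$config$mirna)
  pk <- prof$peaks[prof$peaks$site_type == "7mer-m8", ]
  expect_gt(pk$peak_score, 10)
  # a ranking that separates the stratum puts the peak at its size;
  # the measured ranking smears the boundary (see the methods vignette)
  n_true <- sum(sim$manifest$is_true_target)
  ids <- sim$manifest$transcript_id
  truth_first <- c(ids[sim$manifest$is_true_target],
                   ids[!sim$manifest$is_true_target])
  land_t <- word_landscape(make_ranked(truth_first), sim$utrs, k_set = 7)
  prof_t <- seed_profile(land_t, sim$config$mirna)
  pk_t <- prof_t$peaks[prof_t$peaks$site_type == "7mer-m8", ]
  expect_lt(abs(pk_t$peak_cutoff - n_true) / n_true, 0.25)
  # one cutoff -> one point per word
  land1 <- word_landscape(rk, sim$utrs, k_set = 7, cutoffs = 400)
  prof1 <- seed_profile(land1, sim$config$mirna)
  expect_true(all(table(prof1$curves$word) == 1L))
})

test_that("landscape input validation is strict", {
  ids <- c("a", "b", "c")
  utrs <- setNames(rep("ACGTACGTAC", 2), c("a", "b"))
  expect_error(word_landscape(make_ranked(ids), utrs, k_set = 6),
               "without a UTR.*c")
  utrs3 <- setNames(rep("ACGTACGTAC", 3), ids)
  expect_error(word_landscape(make_ranked(ids), utrs3, k_set = 6, cutoffs = c(2, 5)),
               "cutoffs")
})
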