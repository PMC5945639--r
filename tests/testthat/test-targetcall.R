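test_that("hypergeometric overlap matches closed forms and the brute oracle", {
  r <- hypergeom_overlap(100, 20, 10, 5)
  expect_equal(r$expected, 2)
  expect_equal(r$fold, 2.5)
  expect_equal(r$p, hyper_upper_brute(5, 20, 100, 10), tolerance = 1e-12)
  expect_equal(hypergeom_overlap(100, 20, 10, 0)$p, 1)
  # x at its maximum: single point mass
  expect_equal(hypergeom_overlap(100, 20, 10, 10)$p,
               choose(20, 10) / choose(100, 10), tolerance = 1e-12)
  expect_error(hypergeom_overlap(10, 5, 5, 6), "inconsistent")
  expect_error(hypergeom_overlap(10, 0, 5, 0), "inconsistent")
})

test_that("upper-tail p equals brute-force summation over a parameter grid", {
  for (N in c(5, 9, 12)) {
    for (K in 1:N) for (n in 1:N) for (x in 0:min(K, n)) {
      expect_equal(hypergeom_overlap(N, K, n, x)$p,
                   hyper_upper_brute(x, K, N, n), tolerance = 1e-12)
    }
  }
})

test_that("fold times expected equals the observed overlap", {
  set.seed(3)
  for (i in 1:50) {
    N <- sample(20:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    x <- sample(0:min(K, n), 1)
    r <- hypergeom_overlap(N, K, n, x)
    expect_equal(r$fold * r$expected, x)
  }
})

test_that("identical rankings give perfect concordance", {
  ids <- sprintf("t%03d", 1:100)
  rk <- make_ranked(ids)
  dw <- make_ranked(ids, direction = "downregulation_first")
  call <- call_direct_targets(rk, dw, n_rip = 10, n_dw = 10)
  expect_equal(call$x, 10)
  expect_equal(call$fold, 100 / 10)
  expect_equal(call$members, sort(ids[1:10]))
})

test_that("prefix enlargement never shrinks the overlap; ids are immaterial", {
  set.seed(19)
  ids <- sprintf("t%03d", 1:200)
  rk <- make_ranked(ids)
  dw <- make_ranked(sample(ids), direction = "downregulation_first")
  x_prev <- 0
  for (n in c(10, 20, 50, 100, 150)) {
    x <- call_direct_targets(rk, dw, n_rip = n, n_dw = n)$x
    expect_gte(x, x_prev)
    x_prev <- x
  }
  relab <- setNames(sprintf("g%03d", 1:200), ids)
  rk2 <- make_ranked(unname(relab[rk$transcript_id]))
  dw2 <- make_ranked(unname(relab[dw$transcript_id]), direction = "downregulation_first")
  c1 <- call_direct_targets(rk, dw, n_rip = 40, n_dw = 40)
  c2 <- call_direct_targets(rk2, dw2, n_rip = 40, n_dw = 40)
  expect_equal(c2$x, c1$x)
  expect_equal(c2$members, sort(unname(relab[c1$members])))
})

test_that("independent rankings give near-chance fold enrichment", {
  set.seed(3)
  inside <- 0L
  for (i in 1:20) {
    ids <- sprintf("t%05d", 1:2000)
    rk <- make_ranked(ids)
    dw <- make_ranked(sample(ids), direction = "downregulation_first")
    call <- call_direct_targets(rk, dw)  # scaled defaults 400 x 130
    inside <- inside + (call$fold >= 0.6 && call$fold <= 1.6)
    expect_gt(call$p, 1e-6)
  }
  expect_gte(inside, 18L)
})

test_that("mismatched universes are rejected with the difference size", {
  rk <- make_ranked(c("a", "b", "c"))
  dw <- make_ranked(c("a", "b", "d"), direction = "downregulation_first")
  expect_error(call_direct_targets(rk, dw), "symmetric difference: 2")
})

test_that("the density walk peaks where the hits concentrate", {
  word <- seed_site_word(mir100, "7mer-m8")
  n <- 500
  utrs <- random_utrs(n, length_range = c(100, 150), seed = 8,
                      exclude_words = word)
  hit_ids <- names(utrs)[1:80]
  utrs[hit_ids] <- plant_occurrences(utrs[hit_ids], word, 1, seed = 9)
  prof <- density_profile(make_ranked(names(utrs)), utrs, mir100)
  expect_equal(prof$argmax, 80)
  expect_equal(prof$n_hits, 80)
  # uniformly scattered hits leave only a small excursion
  set.seed(10)
  small <- 0L
  for (i in 1:10) {
    perm <- sample(names(utrs))
    p2 <- density_profile(make_ranked(perm), utrs, mir100)
    small <- small + (max(abs(p2$walk$score)) <= 0.25)
  }
  expect_gte(small, 8L)
  sitefree <- random_utrs(20, c(50, 60), seed = 2, exclude_words = word)
  expect_error(density_profile(make_ranked(names(sitefree)), sitefree, mir100),
               "no site-bearing")
})

test_that("the walk suggests a prefix near the planted target-set size", {
  # a ranking that separates the planted stratum localizes it exactly; the
  # measured noisy ranking smears the boundary (see the methods vignette)
  sim <- seed_recovery_sim()
  n_true <- sum(sim$manifest$is_true_target)
  ids <- sim$manifest$transcript_id
  truth_first <- c(ids[sim$manifest$is_true_target],
                   ids[!sim$manifest$is_true_target])
  prof <- density_profile(make_ranked(truth_first), sim$utrs, sim$config$mirna)
  expect_lt(abs(prof$argmax - n_true) / n_true, 0.3)
})

test_that("between-miRNA target-set overlap behaves at its extremes", {
  u <- sprintf("t%03d", 1:100)
  a <- u[1:20]; b <- u[21:40]
  r <- mirna_set_overlap(a, b, u)
  expect_equal(r$fold, 0)
  expect_equal(r$p, 1)
  r2 <- mirna_set_overlap(a, a, 100)
  expect_equal(r2$fold, 100 / 20)
  # half-shared sets are significantly concordant
  c_shared <- mirna_set_overlap(u[1:20], u[11:30], u)
  expect_lt(c_shared$p, 0.01)
  expect_gt(c_shared$fold, 1)
  expect_error(mirna_set_overlap(c(a, "zz"), b, u), "subsets")
})
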