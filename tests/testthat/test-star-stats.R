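test_that("Poisson relative error and count cutoff match their anchors", {
  expect_equal(relative_error(16, 1), 25)
  expect_equal(relative_error(100, 1), 10)
  expect_equal(relative_error(16, 3), 75)
  expect_error(relative_error(0), "positive")
  expect_identical(cutoff_count(25, 1), 16L)
  expect_identical(cutoff_count(10, 1), 100L)
  expect_identical(cutoff_count(25, 2), 64L)
  expect_error(cutoff_count(0), "positive")
})

test_that("cutoff and relative error are mutual inverses", {
  set.seed(12)
  for (i in 1:50) {
    E <- runif(1, 2, 60)
    k <- sample(1:3, 1)
    N <- cutoff_count(E, k)
    expect_lte(relative_error(N, k), E)
    if (N > 1) expect_gt(relative_error(N - 1, k), E - 1e-9)
  }
})

test_that("the low-count filter sums early stages only, at the boundary", {
  m <- matrix(0L, 3, 8, dimnames = list(c("g15", "g16", "gInte"),
                                        STAGE_LABELS))
  m["g15", "2CELL"] <- 15L
  m["g16", c("2CELL", "TROC")] <- c(10L, 6L)
  m["gInte", "INTE"] <- 1000L
  cm <- count_matrix(m, setNames(rep(1e5, 8), STAGE_LABELS))
  kept <- filter_by_total(cm)
  expect_identical(rownames(kept$counts), "g16")
  expect_identical(nrow(filter_by_total(cm, op = ">")$counts), 0L)
  expect_error(filter_by_total(cm, stage_subset = "NOPE"), "unknown stage")
  empty <- count_matrix(m[0, , drop = FALSE],
                        setNames(rep(1e5, 8), STAGE_LABELS))
  expect_identical(nrow(filter_by_total(empty)$counts), 0L)
})

test_that("tau-sigma stars grade count depth with the weakest stage", {
  expect_identical(tau_sigma_stars(rep(16, 7)), 1L)
  expect_identical(tau_sigma_stars(rep(64, 7)), 2L)
  expect_identical(tau_sigma_stars(c(0, rep(1000, 6))), 0L)
  expect_identical(tau_sigma_stars(c(15, rep(1000, 6))), 0L)
  expect_error(tau_sigma_stars(rep(16, 6)), "seven")
  expect_identical(tau_sigma_stars(c(1, rep(10000, 6)), aggregate = "mean"),
                   as.integer(floor(sqrt(mean(c(1, rep(10000, 6)))) / 4)))
})

test_that("the Dixon Q test grades single outliers at the n=7 criticals", {
  q <- dixon_q(c(1, 2, 2, 3, 3, 3, 100))
  expect_equal(q$q_high, 97 / 99)
  expect_identical(q$confidence, "99")
  expect_identical(dixon_q(rep(5, 7))$confidence, "none")
  q0 <- dixon_q(c(0, 5, 5, 5, 5, 5, 5))
  expect_equal(q0$q_low, 1)
  expect_identical(q0$confidence, "99")
  expect_error(dixon_q(c(1, 2, 3, 4, 5, 6, NA)), "finite")
  # a value in the 90% band only
  q90 <- dixon_q(c(1, 2, 2, 3, 3, 3, 5.2553))
  expect_identical(q90$confidence, "90")
})

test_that("the Q statistic is permutation- and affine-invariant", {
  set.seed(21)
  for (i in 1:30) {
    x <- rnorm(7)
    q <- dixon_q(x)
    expect_equal(dixon_q(sample(x))$q_max, q$q_max)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(dixon_q(a * x + b)$q_max, q$q_max, tolerance = 1e-9)
  }
})

test_that("outlier stars are monotone in the deviating point's distance", {
  base <- c(1, 1.2, 1.4, 1.6, 1.8, 2, 3)
  stars <- vapply(seq(1, 60, by = 0.5), function(s) {
    q <- dixon_q(c(base[1:6], base[7] * s))
    c(none = 0L, `90` = 1L, `95` = 2L, `99` = 3L)[[q$confidence]]
  }, integer(1))
  expect_true(all(diff(stars) >= 0))
})

test_that("star assignment sums stars and flags candidates at the threshold", {
  c16 <- rep(16, 7)
  e90 <- c(1, 2, 2, 3, 3, 3, 5.2553)
  r <- assign_stars(e90, c16)
  expect_identical(r$tau_sigma_stars, 1L)
  expect_identical(r$q_stars, 1L)
  expect_true(r$candidate)

  c_low <- rep(15, 7)
  e99 <- c(1, 2, 2, 3, 3, 3, 100)
  r2 <- assign_stars(e99, c_low)
  expect_identical(r2$total_stars, 3L)
  expect_true(r2$candidate)

  r3 <- assign_stars(rep(5, 7), c16)
  expect_identical(r3$total_stars, 1L)
  expect_false(r3$candidate)
  expect_error(assign_stars(rep(1, 6), c16), "misaligned")
})

test_that("the star pipeline flags dynamic archetypes as candidates", {
  sim <- default_sim()
  st <- star_table(sim$cm)
  expect_true(all(st$total_count >= 16))
  arch <- sim$arch[st$gene_id]
  cand_rate <- tapply(st$candidate, arch, mean)
  expect_gte(cand_rate[["maternal_decay"]], 0.9)
  expect_gte(cand_rate[["trochophore_spike"]], 0.9)
  expect_gte(cand_rate[["postlarval_rise"]], 0.9)
  ce <- candidate_expression(st)
  expect_identical(nrow(ce), sum(st$candidate))
})
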