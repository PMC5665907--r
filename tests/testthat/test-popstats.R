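small_matrix <- function(alt, depth) {
  editing_matrix(matrix(alt, nrow = 1), matrix(depth, nrow = 1))
}

test_that("prevalence uses the testable denominator and the 10/90 cuts", {
  depth <- matrix(c(rep(20L, 10), rep(5L, 10)), 1, 20)
  alt <- matrix(c(rep(5L, 5), rep(0L, 15)), 1, 20)
  m <- editing_matrix(alt, depth)
  p <- prevalence(m)
  expect_equal(p$prevalence, 50)
  expect_equal(p$n_testable, 10L)
  expect_equal(p$class, "intermediate")

  depth2 <- matrix(20L, 1, 100)
  alt2 <- matrix(c(rep(5L, 91), rep(0L, 9)), 1, 100)
  expect_equal(prevalence(editing_matrix(alt2, depth2))$class, "prevalent")

  none <- editing_matrix(matrix(0L, 1, 4), matrix(3L, 1, 4))
  expect_equal(prevalence(none)$class, "untestable")

  # monotone: converting one testable-unedited individual to edited never
  # decreases prevalence
  for (k in 1:5) {
    alt3 <- alt2; alt3[1, 91 + k] <- 5L
    expect_gte(prevalence(editing_matrix(alt3, depth2))$prevalence,
               prevalence(editing_matrix(alt2, depth2))$prevalence)
    alt2 <- alt3
  }
})

test_that("mean editing and editing index differ only under unequal depth", {
  m1 <- small_matrix(c(2L, 18L), c(20L, 20L))
  expect_equal(unname(mean_editing_per_individual(m1)), c(0.1, 0.9))
  m <- editing_matrix(matrix(c(2L, 18L), 2, 1), matrix(c(20L, 20L), 2, 1))
  expect_equal(unname(mean_editing_per_individual(m)), 0.5)
  expect_equal(unname(editing_index(m)), 0.5)

  uneq <- editing_matrix(matrix(c(2L, 2L), 2, 1), matrix(c(10L, 100L), 2, 1))
  expect_equal(unname(editing_index(uneq)), 4 / 110)
  expect_equal(unname(mean_editing_per_individual(uneq)), mean(c(0.2, 0.02)))

  # equal depths: index equals the unweighted mean (property over seeds)
  for (s in 1:5) {
    withr::with_seed(s, {
      alt <- matrix(rbinom(40, 30, 0.3), 8, 5)
      depth <- matrix(30L, 8, 5)
    })
    em <- editing_matrix(alt, depth)
    expect_equal(editing_index(em), mean_editing_per_individual(em))
  }
})

test_that("hypergeometric overlap matches brute-force tail sums", {
  bg <- paste0("s", 1:20)
  A <- bg[1:8]; B <- bg[c(1:7, 9:11)]
  res <- overlap_test(A, B, bg)
  expect_equal(res$overlap, 7L)
  expect_equal(res$p, oracle_hyper_upper(7, 8, 10, 20), tolerance = 1e-12)

  expect_equal(overlap_test(bg[1:4], bg[5:8], bg)$p, 1)
  expect_equal(overlap_test(bg, bg, bg)$p, 1)
  expect_error(overlap_test(c(A, "zzz"), B, bg), "background")

  # brute force across random configurations with N <= 30
  withr::with_seed(99, {
    for (i in 1:20) {
      N <- sample(5:30, 1)
      bgN <- paste0("x", seq_len(N))
      a <- sample(bgN, sample.int(N, 1))
      b <- sample(bgN, sample.int(N, 1))
      r <- overlap_test(a, b, bgN)
      expect_equal(r$p, oracle_hyper_upper(r$overlap, length(a), length(b), N),
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-sum p equals exhaustive permutation enumeration for n <= 8", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      x <- sample(0:5, n1, TRUE) / 10   # plenty of ties
      y <- sample(0:5, n2, TRUE) / 10
      expect_equal(rank_sum_test(x, y)$p, oracle_ranksum_p(x, y),
                   tolerance = 1e-12)
    }
  })
  # large-sample approximation agrees with the standard implementation
  withr::with_seed(8, {
    x <- rnorm(30); y <- rnorm(25, 0.5)
    expect_equal(rank_sum_test(x, y)$p,
                 wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value,
                 tolerance = 1e-9)
  })
})

test_that("differential editing requires both significance and the level floor", {
  expect_equal(differential_level_floor(), 1 / 15)
  alt <- cbind(matrix(10L, 1, 8), matrix(2L, 1, 8))
  depth <- matrix(20L, 1, 16)
  m <- editing_matrix(alt, depth)
  res <- differential_editing(m, 1, 1:8, 9:16)
  expect_true(res$is_differential)
  expect_equal(res$delta, 0.4)

  same <- editing_matrix(matrix(5L, 1, 16), depth)
  res2 <- differential_editing(same, 1, 1:8, 9:16)
  expect_equal(res2$delta, 0)
  expect_false(res2$is_differential)

  # strongly significant but tiny effect: blocked by the floor
  alt3 <- cbind(matrix(10L, 1, 8), matrix(9L, 1, 8))
  m3 <- editing_matrix(alt3, matrix(200L, 1, 16))
  res3 <- differential_editing(m3, 1, 1:8, 9:16)
  expect_lt(res3$p, 0.01)
  expect_lt(res3$delta, 1 / 15)
  expect_false(res3$is_differential)

  tiny <- editing_matrix(matrix(5L, 1, 4), matrix(20L, 1, 4))
  expect_true(is.na(differential_editing(tiny, 1, 1:2, 3:4)$p))
})

test_that("variance explained by ADAR expression behaves at the identities", {
  withr::with_seed(31, {
    adar <- data.frame(a1 = rlnorm(1000), a2 = rlnorm(1000), a3 = rlnorm(1000))
    lin <- 0.1 + 0.2 * adar$a1
    expect_equal(suppressWarnings(variance_explained(lin, adar)$r_squared), 1)
    noise <- rnorm(1000)
    expect_lt(variance_explained(noise, adar)$r_squared, 0.02)
  })
  few <- variance_explained(rep(c(0.1, 0.2), 5), data.frame(a = 1:10, b = 1:10, c = 1:10))
  expect_true(is.na(few$r_squared))
  expect_match(few$reason, "too few")
  const <- variance_explained(rep(0.2, 20), data.frame(a = 1:20, b = 1:20, c = 1:20))
  expect_match(const$reason, "distinct")
})

test_that("context enrichment reports the UAG Fisher test exactly", {
  same <- rep(c("UAG", "CAG", "AAG"), 10)
  res <- context_enrichment(same, same)
  expect_true(all(res$position_diff == 0))
  expect_equal(res$fisher_p, 1)

  pv <- c(rep("UAG", 100), rep("CAC", 614))
  rr <- c(rep("UAG", 200), rep("CAC", 3418))
  res2 <- context_enrichment(pv, rr)
  expect_equal(res2$fisher_p, oracle_fisher_p(100, 614, 200, 3418),
               tolerance = 1e-9)
  expect_gt(res2$position_diff["U", "-1"], 0)
  expect_error(context_enrichment(character(0), rr), "empty")
  expect_error(context_enrichment(c("AAAA"), rr), "3-mers")
})

test_that("paired-window profile counts pairs and skips short windows", {
  unpaired <- fold_result("CCCCCCCCCCCCCCC", "...............")
  prof <- paired_window_profile(list(unpaired), 7L, offsets = -3:3)
  expect_true(all(prof$mean_paired == 0))

  helix <- fold_result(paste0(strrep("G", 9), "AAAA", strrep("C", 9)),
                       paste0(strrep("(", 9), "....", strrep(")", 9)))
  prof2 <- paired_window_profile(list(helix), 4L, offsets = 0L)  # centre of 5' arm
  expect_equal(prof2$mean_paired, 9)

  # windows that do not fit are skipped, not zero-filled
  edge <- paired_window_profile(list(helix), 0L, offsets = -5:0)
  expect_true(all(is.na(edge$mean_paired[edge$offset < -4])))

  # recount a hand-built pair table by brute force
  db <- "..((..((....))..))..."
  f <- fold_result(strrep("A", nchar(db)), db)
  pt <- pair_table(db)
  prof3 <- paired_window_profile(list(f), 10L, offsets = -6:6)
  for (j in seq_len(nrow(prof3))) {
    w <- (10L + 1L + prof3$offset[j]) + (-4:4)
    if (all(w >= 1 & w <= nchar(db))) {
      expect_equal(prof3$mean_paired[j], sum(!is.na(pt[w])))
    }
  }
})

test_that("RPKM follows its defining formula", {
  expect_equal(compute_rpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  expect_equal(compute_rpkm(100, 2000, 2e6), compute_rpkm(100, 2000, 1e6) / 2)
  expect_error(compute_rpkm(10, 0, 1e6), "positive")
})

test_that("editing profiles correlate more within than between populations", {
  cfg <- population_sim_config(
    populations = list(P1 = list(n = 30, adar1 = c(-0.4, 0.25)),
                       P2 = list(n = 30, adar1 = c(0.6, 0.25))),
    seed = 13L)
  ch <- simulate_cohort(cfg, n_genes = 20)
  lev <- ch$matrix$level[ch$genes$edited, , drop = FALSE]
  cc <- suppressWarnings(cor(lev, use = "pairwise.complete.obs"))
  pop <- ch$profiles$population
  same <- outer(pop, pop, "==") & upper.tri(cc)
  diff <- outer(pop, pop, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same], na.rm = TRUE), mean(cc[diff], na.rm = TRUE))
})
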