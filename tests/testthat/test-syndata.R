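test_that("population generator respects configured distributions and seed", {
  cfg <- population_sim_config(
    populations = list(P1 = list(n = 100, adar1 = c(0, 0.3)),
                       P2 = list(n = 100, adar1 = c(0.5, 0.3))),
    seed = 11L)
  prof <- generate_population(cfg)
  expect_equal(nrow(prof), 200L)
  tt <- t.test(log(adar1) ~ population, data = prof)
  expect_lt(tt$p.value, 0.01)
  expect_lt(mean(log(prof$adar1[prof$population == "P1"])),
            mean(log(prof$adar1[prof$population == "P2"])))

  tiny <- generate_population(population_sim_config(
    populations = list(A = list(n = 1), B = list(n = 1), C = list(n = 1)),
    seed = 2L))
  expect_equal(nrow(tiny), 3L)

  expect_identical(generate_population(cfg), generate_population(cfg))
  expect_error(population_sim_config(
    populations = list(P = list(n = 5, adar1 = c(0, -1)))), "scale")
})

test_that("hairpin UTR design places the editable A and the seed site", {
  for (opp in c("C", "U")) {
    tx <- generate_hairpin_utr(length = 130, stem_len = 12, edit_opposite = opp,
                               target_distance = 5, seed = 7)
    expect_s3_class(tx, "synthetic_transcript")
    expect_identical(substr(tx$sequence, tx$edit_pos + 1, tx$edit_pos + 1), "A")
    expect_equal(tx$distance, 5)
    seed7 <- substr(tx$sequence, tx$target_start + 1, tx$target_end)
    expect_identical(seed7, rna_revcomp(substr(tx$mirna_seq, 2, 8)))
    expect_true(tx$target_end <= nchar(tx$sequence))
  }
  expect_identical(generate_hairpin_utr(seed = 3)$sequence,
                   generate_hairpin_utr(seed = 3)$sequence)
  # editing site inside the seed heptamer or impossible stems are rejected
  expect_error(generate_hairpin_utr(target_distance = 0), "infeasible")
  expect_error(generate_hairpin_utr(length = 60, stem_len = 20), "infeasible")
  expect_error(generate_hairpin_utr(stem_len = 8, target_distance = 12),
               "infeasible")
})

test_that("degradation model matches its closed form and buffers differences", {
  d <- apply_degradation(0.2, s_u = 0.5, s_e = 1.0)
  expect_equal(d$observed, 1 / 3)
  expect_equal(d$abundance, 0.6)
  # no preference, no shift
  expect_equal(apply_degradation(0.37, 0.8, 0.8)$observed, 0.37)
  expect_equal(apply_degradation(0, 0.5, 1)$observed, 0)
  # observed >= true whenever edited molecules survive at least as well
  e <- seq(0.05, 0.95, by = 0.1)
  for (su in seq(0.1, 0.9, by = 0.2)) {
    expect_true(all(apply_degradation(e, su, 1)$observed >= e))
  }
  # ratio compression: observed2/observed1 < e2/e1 for e1 < e2, shared s_u < 1
  grid <- expand.grid(e1 = seq(0.05, 0.85, by = 0.1), su = seq(0.1, 0.9, by = 0.1))
  for (i in seq_len(nrow(grid))) {
    e1 <- grid$e1[i]; e2 <- e1 + 0.1; su <- grid$su[i]
    o1 <- apply_degradation(e1, su, 1)$observed
    o2 <- apply_degradation(e2, su, 1)$observed
    expect_lt(o2 / o1, e2 / e1)
  }
  expect_error(apply_degradation(1.2, 0.5, 1), "must be in")
})

test_that("survival link is the exponential in AGO2 x accessibility", {
  expect_equal(survival_from_accessibility(5, 0.9, k = 0), 1)
  expect_equal(survival_from_accessibility(1, 0.5, k = 1), exp(-0.5))
  s <- survival_from_accessibility(1, c(0.2, 0.5, 0.9), k = 1)
  expect_true(all(diff(s) < 0))
  # a more accessible unedited allele survives less
  expect_lt(survival_from_accessibility(1, 0.8), survival_from_accessibility(1, 0.3))
  expect_error(survival_from_accessibility(-1, 0.5), "nonnegative")
  expect_error(survival_from_accessibility(1, 0), "accessibility")
})

test_that("observed editing is nondecreasing in AGO2 when acc_u > acc_e", {
  acc_u <- 0.9; acc_e <- 0.2
  obs <- vapply(seq(0, 3, by = 0.25), function(ago2) {
    s_u <- survival_from_accessibility(ago2, acc_u)
    s_e <- survival_from_accessibility(ago2, acc_e)
    apply_degradation(0.3, s_u, s_e)$observed
  }, numeric(1))
  expect_true(all(diff(obs) >= 0))
})

test_that("pileup simulation is binomial in the observed level", {
  alts <- vapply(1:200, function(s) {
    simulate_pileup(0.5, 100, seed = s)$alt_count
  }, integer(1))
  expect_gte(mean(alts), 45)
  expect_lte(mean(alts), 55)

  clean <- simulate_pileup(0, 50, error_rate = 0, seed = 1)
  expect_identical(clean$alt_count, 0L)
  expect_false(clean$untestable)

  empty <- simulate_pileup(0.5, 0, seed = 1)
  expect_true(empty$untestable)
  expect_identical(empty$depth, 0L)

  expect_identical(simulate_pileup(0.3, 40, seed = 9),
                   simulate_pileup(0.3, 40, seed = 9))
  # qualities stay inside the clipped range
  q <- as.integer(strsplit(simulate_pileup(0.9, 200, seed = 4)$quals, ",")[[1]])
  expect_true(all(q >= 2 & q <= 41))
})

test_that("annotation tracks mark homopolymers and honour densities", {
  seqs <- c(t1 = "CCGGAAAAAGGUUCCGCAUCG")
  ann <- generate_annotation_tracks(seqs, snp_density = 0, seed = 5)
  hp <- ann$homopolymers
  run <- hp[hp$base == "A" & (hp$end - hp$start) == 5, ]
  expect_equal(nrow(run), 1L)
  expect_equal(run$start, 4L)  # "AAAAA" at 0-based 4..9
  expect_equal(nrow(ann$snps), 0L)

  dense <- generate_annotation_tracks(seqs, snp_density = 0.5, seed = 5)
  expect_gt(nrow(dense$snps), 0L)
  expect_identical(generate_annotation_tracks(seqs, snp_density = 0.5, seed = 5),
                   dense)
  expect_error(annotation_set(
    regions = data.frame(contig = "t1", start = c(0L, 0L), end = c(10L, 10L),
                         type = c("CDS", "UTR3"), strand = "+"),
    snps = dense$snps, repeats = dense$repeats,
    homopolymers = dense$homopolymers, splice = dense$splice),
    "contradictory")
})

test_that("cohort generator outputs are reproducible bit-for-bit", {
  cfg <- population_sim_config(populations = list(P = list(n = 12)), seed = 21L)
  a <- simulate_cohort(cfg, n_genes = 6)
  b <- simulate_cohort(cfg, n_genes = 6)
  expect_identical(a$genes, b$genes)
  expect_identical(a$alt, b$alt)
  expect_identical(a$expression, b$expression)
})
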