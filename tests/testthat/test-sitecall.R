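make_obs <- function(depth, alt, quals, gene = "gA", pos = 5L) {
  data.frame(gene = gene, pos0 = pos, strand = "+", ref = "A", alt = "G",
             depth = depth, alt_count = alt,
             quals = paste(quals, collapse = ","),
             read_pos = paste(rep(50L, length(quals)), collapse = ","),
             stringsAsFactors = FALSE)
}

test_that("LLR separates credible edits from sequencing errors", {
  good <- make_obs(10L, 5L, rep(40L, 5))
  expect_gt(compute_llr(good), 2)
  weak <- make_obs(10L, 1L, 3L)
  expect_lt(abs(compute_llr(weak)), 0.05)
  expect_identical(compute_llr(good), compute_llr(good))
  expect_error(compute_llr(make_obs(10L, 0L, integer(0))), "not a candidate")
  # agreement with a dense grid search over the variant fraction
  for (case in list(list(d = 10L, q = rep(40L, 5)),
                    list(d = 20L, q = c(10L, 20L, 35L)),
                    list(d = 50L, q = rep(25L, 10)),
                    list(d = 12L, q = c(3L, 3L)))) {
    obs <- make_obs(case$d, length(case$q), case$q)
    expect_equal(compute_llr(obs), oracle_llr(case$q, case$d), tolerance = 1e-4)
  }
})

test_that("filter cascade applies the eight rules with fixed order labels", {
  ann <- filter_test_annotations()
  obs <- rbind(
    make_obs(9L, 2L, c(40L, 40L), pos = 5L),      # fails coverage
    make_obs(20L, 3L, rep(40L, 3), pos = 72L),    # inside AAAAA run
    make_obs(20L, 3L, rep(40L, 3), pos = 5L),     # clean: retained
    make_obs(20L, 1L, 40L, pos = 5L),             # too few edited reads
    make_obs(100L, 4L, rep(40L, 4), pos = 5L),    # level 0.04 < 0.1
    make_obs(20L, 3L, rep(40L, 3), pos = 17L),    # at a SNP
    make_obs(20L, 3L, rep(40L, 3), pos = 45L),    # simple repeat
    make_obs(20L, 3L, rep(40L, 3), pos = 123L)    # intronic, 3 nt from junction
  )
  res <- filter_sites(obs, ann)
  expect_identical(res$retained,
                   c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(res$first_fail[1], "coverage")
  expect_identical(res$first_fail[2], "homopolymer")
  expect_true(is.na(res$first_fail[3]))
  expect_identical(res$first_fail[4], "edited_reads")
  expect_identical(res$first_fail[5], "level")
  expect_identical(res$first_fail[6], "snp")
  expect_identical(res$first_fail[7], "simple_repeat")
  expect_identical(res$first_fail[8], "splice_junction")
  # thresholds are closed on the passing side
  edge <- make_obs(10L, 2L, c(40L, 40L), pos = 5L)   # level 0.2, depth 10, alt 2
  expect_true(filter_sites(edge, ann)$retained)
  expect_error(filter_sites(obs, ann$snps), "annotation_set")
})

test_that("surviving set equals the brute-force predicate oracle and is
           invariant to rule order", {
  ann <- filter_test_annotations()
  rec <- random_filter_records(300L, seed = 42L)
  res <- filter_sites(rec, ann)
  oracle <- vapply(seq_len(nrow(rec)), function(i) {
    llr_i <- res$llr[i]
    oracle_site_pass(rec[i, ], ann, llr_i)
  }, logical(1))
  expect_identical(res$retained, oracle)
  # rule order cannot change the surviving set: recompute with permuted
  # threshold evaluation by shuffling rows (order of application is per-row
  # conjunctive) and by reversing the record order
  res_rev <- filter_sites(rec[rev(seq_len(nrow(rec))), ], ann)
  expect_identical(res_rev$retained, rev(res$retained))
})

test_that("genomic context uses the priority rule and the 300-nt intron split", {
  ann <- annotation_set(
    regions = data.frame(
      contig = "g", start = c(0L, 50L, 100L, 800L, 1500L, 2600L),
      end = c(60L, 120L, 800L, 1500L, 2600L, 2700L),
      type = c("CDS", "UTR3", "UTR5", "ncExon", "intron", "UTR3"),
      strand = "+", stringsAsFactors = FALSE),
    snps = data.frame(contig = character(), pos0 = integer()),
    repeats = data.frame(contig = character(), start = integer(), end = integer()),
    homopolymers = data.frame(contig = character(), start = integer(),
                              end = integer(), base = character()),
    splice = data.frame(contig = character(), pos0 = integer()))
  sites <- data.frame(gene = "g",
                      pos0 = c(55L,    # CDS and UTR3 overlap -> CDS
                               70L,    # UTR3 and UTR5 overlap -> UTR3
                               900L,   # ncExon
                               1799L,  # intron, 299 nt in -> close
                               1801L,  # intron, 301 nt in -> deep
                               2599L,  # intron, 0 nt from 3' boundary -> close
                               5000L)) # nothing -> Intergenic
  expect_identical(classify_context(sites, ann),
                   c("CDS", "UTR3", "ncExon", "Intron-close", "Intron-deep",
                     "Intron-close", "Intergenic"))
})

test_that("population-level selection applies both site criteria", {
  n <- 90L
  depth <- matrix(5L, 3, n, dimnames = list(paste0("s", 1:3), paste0("i", 1:n)))
  alt <- matrix(0L, 3, n, dimnames = dimnames(depth))
  # s1: edited in exactly 3 individuals, testable depth in 10 (>= 9 = 10%)
  depth[1, 1:10] <- 20L; alt[1, 1:3] <- 4L
  # s2: edited in 2 individuals only
  depth[2, 1:10] <- 20L; alt[2, 1:2] <- 4L
  # s3: edited in 5 but testable in only 8 of 90 (< 10%)
  depth[3, 1:8] <- 20L; alt[3, 1:5] <- 4L
  m <- editing_matrix(alt, depth)
  expect_identical(select_population_sites(m), "s1")
  expect_error(select_population_sites(m, population = "nope"), "no individuals")
})

test_that("A-to-G fraction is strand-resolved", {
  sites <- data.frame(ref = c(rep("A", 9), "C"), alt = c(rep("G", 9), "U"),
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(a2g_fraction(sites), 0.9)
  minus <- data.frame(ref = "T", alt = "C", strand = "-", stringsAsFactors = FALSE)
  expect_equal(a2g_fraction(minus), 1)
  none <- data.frame(ref = c("C", "G"), alt = c("U", "A"), strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(a2g_fraction(none), 0)
  expect_error(a2g_fraction(sites[0, ]), "empty")
})
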