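test_that("pair tables are involutive and balanced", {
  dbs <- c("((((....))))", "..((..((....))..))...", ".....",
           "((..((...))..((...))..))")
  for (db in dbs) {
    pt <- pair_table(db)
    paired <- which(!is.na(pt))
    expect_identical(pt[pt[paired]], paired)
    expect_equal(sum(!is.na(pt)) %% 2, 0)
  }
  expect_error(pair_table("((..)"), "unbalanced")
  expect_error(pair_table("(x)"), "characters")
  # the maximisation fallback produces valid structures too
  withr::with_seed(5, {
    for (i in 1:5) {
      s <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
      pt <- pair_table(fold_maxpair(s))
      paired <- which(!is.na(pt))
      expect_identical(pt[pt[paired]], paired)
    }
  })
})

test_that("fold_window folds both alleles under identical settings", {
  # an unstructured pyrimidine tract folds to nothing and is fully accessible
  pyr <- paste(rep(c("C", "U", "U", "C"), 30), collapse = "")
  pyrA <- paste0(substr(pyr, 1, 60), "A", substr(pyr, 62, nchar(pyr)))
  fw <- fold_window(pyrA, 60L, window = 1001L)
  expect_equal(sum(!is.na(fw$unedited$pairs)), 0)
  acc <- fw$unedited$accessibility
  expect_true(all(acc[!is.na(acc)] > 0.9))

  # a designed hairpin: the A is unpaired (A.C mismatch) until edited
  tx <- generate_hairpin_utr(length = 130, stem_len = 12, edit_opposite = "C",
                             target_distance = 5, seed = 41)
  fh <- fold_window(tx$sequence, tx$edit_pos)
  i <- fh$site_in_window + 1L
  expect_true(is.na(fh$unedited$pairs[i]))
  expect_false(is.na(fh$edited$pairs[i]))
  # G.U wobble after editing a designed A-U pair
  txu <- generate_hairpin_utr(length = 130, stem_len = 12, edit_opposite = "U",
                              target_distance = 5, seed = 42)
  fu <- fold_window(txu$sequence, txu$edit_pos)
  j <- fu$site_in_window + 1L
  expect_false(is.na(fu$edited$pairs[j]))
  expect_identical(substr(fu$edited$sequence, fu$edited$pairs[j],
                          fu$edited$pairs[j]), "U")

  expect_identical(fold_window(tx$sequence, tx$edit_pos),
                   fold_window(tx$sequence, tx$edit_pos))
  expect_error(fold_window(tx$sequence, tx$edit_pos + 1L), "not A")
})

test_that("relative accessibility is zero for the identity substitution", {
  tx <- generate_hairpin_utr(length = 120, seed = 17)
  fw <- fold_window(tx$sequence, tx$edit_pos)
  ra0 <- relative_accessibility(fw$unedited, fw$unedited, fw$site_in_window,
                                max_offset = 30)
  expect_true(all(ra0$log2_ratio[!is.na(ra0$log2_ratio)] == 0))
  ra <- relative_accessibility(fw$unedited, fw$edited, fw$site_in_window,
                               max_offset = 10)
  expect_lt(mean(ra$log2_ratio, na.rm = TRUE), 0)

  other <- fold_window(substr(tx$sequence, 1, 100), tx$edit_pos)
  expect_error(relative_accessibility(fw$unedited, other$edited,
                                      fw$site_in_window), "different windows")
})

test_that("opposite-nucleotide rule matches direct case analysis", {
  seq1 <- "GGCAGAAAACUGCC"
  db1 <- "(((((....)))))"
  f1 <- fold_result(seq1, db1)
  # paired site: read straight off the pair table
  expect_identical(opposite_nucleotide(f1, 2L), substr(seq1, 12, 12))
  # hand-written cases covering loop, bulge and both neighbour branches
  cases <- list(
    list(seq = "GGGAAAACCC", db = "(((....)))", site = 4L),   # loop, both nbrs unpaired -> N
    list(seq = "GGGAAAACCC", db = "(((....)))", site = 3L),   # 5' nbr paired
    list(seq = "GGGAAAACCC", db = "(((....)))", site = 6L),   # 3' nbr paired
    list(seq = "GGAGGAAAACCACC", db = "((.((....)).))", site = 2L),  # bulge
    list(seq = "AGGGAAAACCCA", db = ".(((....))).", site = 0L),
    list(seq = "AGGGAAAACCCA", db = ".(((....))).", site = 11L),
    list(seq = "AAAAA", db = ".....", site = 2L)               # no structure -> N
  )
  for (cs in cases) {
    f <- fold_result(cs$seq, cs$db)
    expect_identical(opposite_nucleotide(f, cs$site),
                     oracle_opposite(cs$seq, cs$db, cs$site),
                     info = paste(cs$db, cs$site))
  }
  # exhaustive: every position of several structures
  for (cs in cases[1:4]) {
    for (p in seq_len(nchar(cs$db)) - 1L) {
      f <- fold_result(cs$seq, cs$db)
      expect_identical(opposite_nucleotide(f, p), oracle_opposite(cs$seq, cs$db, p))
    }
  }
  # when both neighbours are paired the 5' rule wins
  seqb <- "GGAGGAAAACCACC"
  dbb  <- "((.((....)).))"
  fb <- fold_result(seqb, dbb)
  pt <- pair_table(dbb)
  expect_identical(opposite_nucleotide(fb, 2L), substr(seqb, pt[2] - 1, pt[2] - 1))
})

test_that("opposite-base spectrum shows increased pairing after editing", {
  folds <- lapply(1:10, function(s) {
    opp <- if (s <= 6) "C" else "U"
    tx <- generate_hairpin_utr(length = 120, stem_len = 12, edit_opposite = opp,
                               target_distance = 5, seed = 200 + s)
    fold_window(tx$sequence, tx$edit_pos)
  })
  sp <- opposite_base_spectrum(folds)
  expect_equal(colSums(sp$spectrum), c(unedited = 1, edited = 1))
  expect_gt(sp$paired_fraction["edited"], sp$paired_fraction["unedited"])
  # designed opposite bases dominate the edited spectrum
  expect_gt(sum(sp$spectrum[c("C", "U"), "edited"]), 0.8)
  expect_error(opposite_base_spectrum(list()), "empty")
})

test_that("control adenosines obey the distance constraint exactly", {
  withr::with_seed(3, {
    seqv <- paste(sample(c("A", "C", "G", "U"), 1200, TRUE), collapse = "")
  })
  picks <- select_control_adenosines(seqv, edit_sites = 600L,
                                     dist_range = c(300L, 500L), n = 20L, seed = 5)
  bases <- strsplit(seqv, "")[[1]]
  expect_true(all(bases[picks + 1] == "A"))
  d <- abs(picks - 600L)
  expect_true(all(d >= 300 & d <= 500))
  # brute-force candidate enumeration agrees
  cand <- which(bases == "A") - 1L
  cand <- cand[abs(cand - 600L) >= 300 & abs(cand - 600L) <= 500]
  expect_true(all(picks %in% cand))
  expect_error(select_control_adenosines(seqv, 600L, n = length(cand) + 1L,
                                         dist_range = c(300L, 500L)),
               "candidates")
  expect_identical(select_control_adenosines(seqv, 600L, n = 5L, seed = 9),
                   select_control_adenosines(seqv, 600L, n = 5L, seed = 9))
})

test_that("accessibility-expression correlation recovers a planted relation", {
  withr::with_seed(21, {
    distance <- sample(2:40, 120, TRUE)
    delta <- -3 * exp(-distance / 8) + rnorm(120, 0, 0.05)
    ratio <- -0.5 * delta + rnorm(120, 0, 1e-4)
  })
  res <- accessibility_expression_correlation(delta, ratio, distance)
  expect_identical(res$status, "ok")
  expect_lt(res$r, -0.99)

  flat <- accessibility_expression_correlation(rep(1, 50), rnorm(50),
                                               rep(c(5L, 20L, 40L), length.out = 50))
  expect_identical(flat$status, "zero variance")
  few <- accessibility_expression_correlation(c(1, 2), c(1, 2), c(5L, 6L))
  expect_identical(few$status, "too few windows")
})
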