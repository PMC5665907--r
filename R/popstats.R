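# Population editome statistics: the editing matrix container, prevalence,
# per-individual summaries, set-overlap and differential tests, variance in
# editing explained by ADAR expression, sequence-context enrichment, the
# paired-nucleotide window profile, and RPKM.

#' Editing matrix container
#'
#' Sites x individuals editing levels with depth-aware missingness: the level
#' is missing wherever depth < `testable_depth` (the "testable" rule).
#'
#' @param alt Integer matrix of edited-read counts (sites x individuals).
#' @param depth Integer matrix of read depths, same shape and dimnames.
#' @param individuals Data frame with `individual` and `population`,
#'   one row per column.
#' @param testable_depth Depth below which a site-individual pair is not
#'   testable (default 10).
#' @return Object of class `editing_matrix` with elements `level` (NA where
#'   untestable), `alt`, `depth`, `individuals`, `testable_depth`.
#' @export
editing_matrix <- function(alt, depth, individuals = NULL, testable_depth = 10L) {
  if (!all(dim(alt) == dim(depth))) stop("'alt' and 'depth' shapes disagree")
  if (any(alt > depth, na.rm = TRUE)) stop("alt count exceeds depth")
  if (is.null(rownames(depth))) rownames(depth) <- paste0("site", seq_len(nrow(depth)))
  if (is.null(colnames(depth))) colnames(depth) <- paste0("ind", seq_len(ncol(depth)))
  dimnames(alt) <- dimnames(depth)
  if (is.null(individuals)) {
    individuals <- data.frame(individual = colnames(depth), population = "POP1",
                              stringsAsFactors = FALSE)
  }
  if (nrow(individuals) != ncol(depth)) {
    stop("'individuals' rows must match matrix columns")
  }
  level <- ifelse(depth >= testable_depth & depth > 0, alt / depth, NA_real_)
  structure(list(level = level, alt = alt, depth = depth,
                 individuals = individuals,
                 testable_depth = as.integer(testable_depth)),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat("<editing_matrix> ", nrow(x$level), " sites x ", ncol(x$level),
      " individuals (", sum(!is.na(x$level)), " testable cells)\n", sep = "")
  invisible(x)
}

is_edited_cell <- function(matrix) {
  (matrix$alt >= 2L) & !is.na(matrix$level) & (matrix$level >= 0.1)
}

#' Prevalence of an editing site in a population
#'
#' Percentage of individuals with the site edited among those testable
#' (depth >= 10). Classes: rare (<= 10%), prevalent (> 90%), otherwise
#' intermediate.
#'
#' @param matrix An [editing_matrix()].
#' @param site Site id (rowname) or row index; if missing, all sites.
#' @param rare_cut,prevalent_cut Class cut points in percent.
#' @return Data frame with `site`, `prevalence` (percent), `n_testable`,
#'   `n_edited`, `class` (`untestable` when no individual is testable).
#' @export
prevalence <- function(matrix, site = NULL, rare_cut = 10, prevalent_cut = 90) {
  stopifnot(inherits(matrix, "editing_matrix"))
  rows <- if (is.null(site)) seq_len(nrow(matrix$level)) else site
  testable <- !is.na(matrix$level[rows, , drop = FALSE])
  edited <- is_edited_cell(matrix)[rows, , drop = FALSE]
  n_testable <- rowSums(testable)
  n_edited <- rowSums(edited & testable)
  pct <- ifelse(n_testable > 0, 100 * n_edited / n_testable, NA_real_)
  cls <- ifelse(n_testable == 0, "untestable",
         ifelse(pct <= rare_cut, "rare",
         ifelse(pct > prevalent_cut, "prevalent", "intermediate")))
  data.frame(site = rownames(matrix$level)[rows], prevalence = pct,
             n_testable = n_testable, n_edited = n_edited, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-individual mean editing level
#'
#' Unweighted mean of levels over the individual's testable sites.
#'
#' @param matrix An [editing_matrix()].
#' @param individual Column name or index; if missing, all individuals.
#' @return Named numeric vector (NA where an individual has no testable site).
#' @export
mean_editing_per_individual <- function(matrix, individual = NULL) {
  stopifnot(inherits(matrix, "editing_matrix"))
  cols <- if (is.null(individual)) seq_len(ncol(matrix$level)) else individual
  out <- colMeans(matrix$level[, cols, drop = FALSE], na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-individual editing index
#'
#' Depth-weighted editing level: total edited reads divided by total reads
#' across the individual's testable sites.
#'
#' @inheritParams mean_editing_per_individual
#' @return Named numeric vector.
#' @export
editing_index <- function(matrix, individual = NULL) {
  stopifnot(inherits(matrix, "editing_matrix"))
  cols <- if (is.null(individual)) seq_len(ncol(matrix$level)) else individual
  testable <- !is.na(matrix$level[, cols, drop = FALSE])
  alt <- matrix$alt[, cols, drop = FALSE]
  depth <- matrix$depth[, cols, drop = FALSE]
  alt[!testable] <- NA_integer_
  depth[!testable] <- NA_integer_
  num <- colSums(alt, na.rm = TRUE)
  den <- colSums(depth, na.rm = TRUE)
  ifelse(den > 0, num / den, NA_real_)
}

#' Hypergeometric overlap of two site sets
#'
#' Upper-tail probability P(X >= overlap) of drawing at least the observed
#' overlap when sets of the two observed sizes are drawn from a common
#' background.
#'
#' @param setA,setB Character vectors of site ids.
#' @param background Character vector (or its size) containing both sets.
#' @return List with `overlap` and `p`.
#' @export
overlap_test <- function(setA, setB, background) {
  bg_size <- if (is.numeric(background)) background else length(unique(background))
  if (!is.numeric(background)) {
    if (!all(setA %in% background) || !all(setB %in% background)) {
      stop("both sets must be contained in the background")
    }
  }
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) > bg_size || length(setB) > bg_size) {
    stop("set larger than the background")
  }
  ov <- length(intersect(setA, setB))
  p <- stats::phyper(ov - 1L, length(setA), bg_size - length(setA),
                     length(setB), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Rank-sum (Wilcoxon/Mann-Whitney) test
#'
#' Two-sided test on the midrank sum of the first sample. Exact by full
#' enumeration of group assignments when both groups have at most
#' `exact_max` observations (ties handled by midranks); otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest group size for which the exact enumeration is
#'   used (default 8).
#' @return List with `statistic` (rank sum of `x`), `p`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(list(statistic = w, p = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
    sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- w - mu
  correction <- sign(z) * 0.5
  z <- (z - correction) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p = p, method = "normal")
}

#' Differential editing between two groups at one site
#'
#' Two-sided rank-sum test on the testable levels, with an absolute
#' difference in mean editing level required to exceed `delta_min` — the
#' difference corresponding to one edited read at read coverage 15.
#'
#' @param matrix An [editing_matrix()].
#' @param site Site id or row index.
#' @param groupA,groupB Column names or indices of the two groups.
#' @param p_max Significance threshold (default 0.01).
#' @param delta_min Effect-size floor (default [differential_level_floor()]).
#' @param min_n Minimum testable individuals per group (default 3).
#' @return List with `p`, `delta`, `is_differential`, `n` (per-group
#'   testable counts); `p` is NA when a group is too small (untested).
#' @export
differential_editing <- function(matrix, site, groupA, groupB,
                                 p_max = 0.01, delta_min = differential_level_floor(),
                                 min_n = 3L) {
  stopifnot(inherits(matrix, "editing_matrix"))
  a <- matrix$level[site, groupA]
  b <- matrix$level[site, groupB]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < min_n || length(b) < min_n) {
    return(list(p = NA_real_, delta = NA_real_, is_differential = NA,
                n = c(length(a), length(b))))
  }
  delta <- abs(mean(a) - mean(b))
  p <- rank_sum_test(a, b)$p
  list(p = p, delta = delta,
       is_differential = (p < p_max) && (delta > delta_min),
       n = c(length(a), length(b)))
}

#' Minimum editing-level difference considered biologically meaningful
#'
#' The absolute editing-level difference produced by a single edited read at
#' the given read coverage; used as the effect-size floor of the
#' differential-editing test.
#'
#' @param coverage Read coverage (default 15).
#' @return `1 / coverage`.
#' @export
differential_level_floor <- function(coverage = 15L) {
  1 / assert_count(coverage, "coverage", min = 1L)
}

#' Variance in editing levels explained by ADAR expression
#'
#' Per-site least-squares fit of editing level on ADAR1, ADAR2 and ADAR3
#' expression (with intercept), over individuals where the site is testable.
#' Sites are eligible when testable in more than `min_testable` individuals
#' with at least two distinct levels.
#'
#' @param levels Numeric vector of editing levels (NA = untestable).
#' @param adar Matrix or data frame with three columns of ADAR1/2/3
#'   expression, rows matching `levels`.
#' @param min_testable Eligibility threshold (default 10; strictly more
#'   than this many testable individuals required).
#' @return List with `r_squared` and `n`; `r_squared` is NA with a `reason`
#'   when the site is ineligible.
#' @export
variance_explained <- function(levels, adar, min_testable = 10L) {
  adar <- as.data.frame(adar)
  if (ncol(adar) != 3L) stop("'adar' must have three columns (ADAR1/2/3)")
  ok <- !is.na(levels) & stats::complete.cases(adar)
  n <- sum(ok)
  if (n <= min_testable) {
    return(list(r_squared = NA_real_, n = n, reason = "too few testable individuals"))
  }
  if (length(unique(levels[ok])) < 2L) {
    return(list(r_squared = NA_real_, n = n, reason = "fewer than two distinct levels"))
  }
  fit <- stats::lm(levels[ok] ~ ., data = adar[ok, , drop = FALSE])
  list(r_squared = summary(fit)$r.squared, n = n, reason = NA_character_)
}

#' Sequence-context enrichment between prevalent and rare sites
#'
#' Compares the +/-1 nt contexts (3-mers centred on the edited A) of two
#' site groups: per-position nucleotide frequency differences and a 2x2
#' Fisher exact test on counts of the UAG motif.
#'
#' @param prevalent_contexts,rare_contexts Character vectors of 3-mers with
#'   a central A.
#' @param motif Motif tested in the 2x2 table (default "UAG").
#' @return List with `position_diff` (4 x 3 matrix of frequency differences,
#'   prevalent minus rare), `motif_counts`, `fisher_p`.
#' @export
context_enrichment <- function(prevalent_contexts, rare_contexts, motif = "UAG") {
  check <- function(x, nm) {
    if (length(x) == 0L) stop("'", nm, "' is empty")
    x <- as_rna(x)
    if (any(nchar(x) != 3L) || any(substr(x, 2L, 2L) != "A")) {
      stop("'", nm, "' must be 3-mers centred on A")
    }
    x
  }
  pv <- check(prevalent_contexts, "prevalent_contexts")
  rr <- check(rare_contexts, "rare_contexts")
  freq <- function(x, pos) {
    tab <- table(factor(substr(x, pos, pos), levels = RNA_BASES))
    as.numeric(tab) / length(x)
  }
  pos_diff <- sapply(1:3, function(p) freq(pv, p) - freq(rr, p))
  dimnames(pos_diff) <- list(RNA_BASES, c("-1", "0", "+1"))
  counts <- matrix(c(sum(pv == motif), length(pv) - sum(pv == motif),
                     sum(rr == motif), length(rr) - sum(rr == motif)),
                   nrow = 2L,
                   dimnames = list(c("motif", "other"), c("prevalent", "rare")))
  fisher_p <- stats::fisher.test(counts)$p.value
  list(position_diff = pos_diff, motif_counts = counts, fisher_p = fisher_p)
}

#' Paired-nucleotide profile in a sliding window around sites
#'
#' For each offset, the number of paired positions (from MFE pair tables) in
#' a `window`-nt window centred at that offset relative to the site, averaged
#' across sequences. Windows extending past a sequence end are skipped for
#' that sequence, not zero-filled.
#'
#' @param folds List of `fold_result` objects (unedited sequences).
#' @param site_pos Integer vector of 0-based site offsets, one per fold.
#' @param offsets Integer vector of window-centre offsets relative to the
#'   site (default -50..50).
#' @param window Window size in nt (default 9, odd).
#' @return Data frame with `offset`, `mean_paired`, `sem`, `n`.
#' @export
paired_window_profile <- function(folds, site_pos, offsets = -50:50, window = 9L) {
  stopifnot(length(folds) == length(site_pos), window %% 2L == 1L)
  half <- window %/% 2L
  counts <- matrix(NA_real_, length(folds), length(offsets))
  for (i in seq_along(folds)) {
    pt <- folds[[i]]$pairs
    n <- length(pt)
    centre <- site_pos[i] + 1L + offsets   # 1-based window centres
    lo <- centre - half
    hi <- centre + half
    ok <- lo >= 1L & hi <= n
    counts[i, ok] <- vapply(which(ok), function(j) {
      sum(!is.na(pt[lo[j]:hi[j]]))
    }, numeric(1))
  }
  n_obs <- colSums(!is.na(counts))
  m <- colMeans(counts, na.rm = TRUE)
  s <- apply(counts, 2L, stats::sd, na.rm = TRUE)
  data.frame(offset = offsets, mean_paired = ifelse(n_obs > 0, m, NA_real_),
             sem = ifelse(n_obs > 1, s / sqrt(n_obs), NA_real_), n = n_obs)
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts Read counts per gene.
#' @param lengths Gene lengths in nt (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Numeric vector of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths, total_mapped) {
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (total_mapped <= 0) stop("'total_mapped' must be positive")
  counts * 1e9 / (lengths * total_mapped)
}
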