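# miRNA seed-site matching, editing-to-target distance analyses, tertile
# stratification with covariate matching, and knockdown-vs-control contrasts.

#' Canonical seed matches of a miRNA in a 3' UTR
#'
#' Reports all 7mer-m8 (reverse complement of miRNA nt 2-8), 7mer-A1
#' (reverse complement of nt 2-7 followed by A) and 8mer (reverse complement
#' of nt 2-8 followed by A) matches with 0-based half-open coordinates on the
#' UTR. A 7mer match that is part of an 8mer site is reported once, as 8mer.
#'
#' @param utr_sequence 3' UTR sequence (RNA alphabet).
#' @param mirna_sequence miRNA sequence (>= 8 nt, RNA alphabet, 5' to 3').
#' @param mirna_id Identifier copied into the result.
#' @return Data frame with `mirna`, `start`, `end`, `site_type`.
#' @export
find_seed_matches <- function(utr_sequence, mirna_sequence, mirna_id = "mirna") {
  utr <- as_rna(utr_sequence)
  mir <- as_rna(mirna_sequence)
  if (nchar(mir) < 8L) stop("'mirna_sequence' must be at least 8 nt")
  m8 <- rna_revcomp(substr(mir, 2L, 8L))     # 7 nt
  a1 <- paste0(rna_revcomp(substr(mir, 2L, 7L)), "A")  # 7 nt
  mer8 <- paste0(m8, "A")                    # 8 nt

  find_all <- function(pattern) {
    hits <- gregexpr(pattern, utr, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L  # 0-based starts
  }
  s8 <- find_all(mer8)
  s_m8 <- setdiff(find_all(m8), s8)            # 7mer-m8 not extending to 8mer
  s_a1 <- setdiff(find_all(a1), s8 + 1L)       # 7mer-A1 not inside an 8mer
  out <- rbind(
    if (length(s8)) data.frame(start = s8, end = s8 + 8L, site_type = "8mer"),
    if (length(s_m8)) data.frame(start = s_m8, end = s_m8 + 7L, site_type = "7mer-m8"),
    if (length(s_a1)) data.frame(start = s_a1, end = s_a1 + 7L, site_type = "7mer-A1")
  )
  if (is.null(out)) {
    return(data.frame(mirna = character(), start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start), , drop = FALSE]
  data.frame(mirna = mirna_id, out, stringsAsFactors = FALSE, row.names = NULL)
}

#' Distance from an editing site to its nearest miRNA target site
#'
#' Edge-to-edge distance in nt between the site position and each target
#' interval (0 when the site lies inside the interval); the closest target
#' is returned, ties broken toward the 5' (smaller-start) site.
#'
#' @param site_pos 0-based editing-site offset.
#' @param targets Data frame of target sites with 0-based half-open `start`,
#'   `end` columns (e.g. from [find_seed_matches()]).
#' @return List with `distance`, `target` (the chosen row), and
#'   `seed_overlap` (TRUE when the site lies inside the seed interval);
#'   `distance` is NA with `target = NULL` when no targets exist.
#' @export
nearest_target_distance <- function(site_pos, targets) {
  if (is.null(targets) || nrow(targets) == 0L) {
    return(list(distance = NA_real_, target = NULL, seed_overlap = FALSE))
  }
  d <- pmax(0L, pmax(targets$start - site_pos, site_pos - (targets$end - 1L)))
  ord <- order(d, targets$start)
  best <- ord[1L]
  list(distance = d[best], target = targets[best, , drop = FALSE],
       seed_overlap = d[best] == 0L)
}

#' Cumulative editing level versus distance to the nearest target site
#'
#' For each grid value x, the mean editing level over all sites whose
#' distance to the nearest miRNA target site is at most x, with its standard
#' error; plus the rank-sum contrast of close (< `close_max`) versus far
#' (`far_range`) sites.
#'
#' @param levels Per-site editing levels.
#' @param distances Per-site distances to the nearest target site.
#' @param x_grid Distances at which the cumulative mean is evaluated.
#' @param close_max Upper bound of the "close" group (default 50).
#' @param far_range Inclusive range of the "far" group (default c(500, 1000)).
#' @return List with `profile` (data frame x/mean/sem/n; NA means no site
#'   within x) and `contrast` (rank-sum result with group means, or NULL
#'   when either group is empty).
#' @export
editing_vs_distance_profile <- function(levels, distances,
                                        x_grid = seq(10, 1000, by = 10),
                                        close_max = 50, far_range = c(500, 1000)) {
  ok <- !is.na(levels) & !is.na(distances)
  levels <- levels[ok]; distances <- distances[ok]
  if (length(levels) == 0L) stop("no sites with level and distance")
  prof <- t(vapply(x_grid, function(x) {
    sel <- distances <= x
    n <- sum(sel)
    if (n == 0L) return(c(NA_real_, NA_real_, 0))
    c(mean(levels[sel]),
      if (n > 1L) stats::sd(levels[sel]) / sqrt(n) else NA_real_, n)
  }, numeric(3)))
  profile <- data.frame(x = x_grid, mean = prof[, 1L], sem = prof[, 2L],
                        n = as.integer(prof[, 3L]))
  close <- levels[distances < close_max]
  far <- levels[distances >= far_range[1L] & distances <= far_range[2L]]
  contrast <- if (length(close) > 0L && length(far) > 0L) {
    rs <- rank_sum_test(close, far)
    list(p = rs$p, mean_close = mean(close), mean_far = mean(far),
         n_close = length(close), n_far = length(far))
  } else NULL
  list(profile = profile, contrast = contrast)
}

# rank-based tertiles with deterministic tie-breaking (first occurrence wins)
tertile <- function(x) {
  r <- rank(x, ties.method = "first")
  n <- length(x)
  cut(r, breaks = c(0, n / 3, 2 * n / 3, n) + 0.5, labels = FALSE)
}

#' Expression comparison across tertiles of a grouping variable
#'
#' Divides individuals into tertiles of the grouping variable (rank-based,
#' deterministic ties), optionally restricts to a covariate stratum, and
#' compares mean gene expression between the high and low tertiles. The
#' matched covariates must not differ between the compared groups (rank-sum
#' p > `match_p_min`), otherwise the comparison is reported infeasible.
#' Groups smaller than `min_group` are dropped (infeasible).
#'
#' @param expression Genes x individuals numeric matrix.
#' @param grouping Numeric vector (e.g. ADAR1 expression), one per individual.
#' @param covariates Data frame or matrix of covariates to match (e.g. AGO2
#'   and miRNA expression), one row per individual; NULL for none.
#' @param stratum Optional logical vector restricting the comparison to a
#'   subset of individuals (e.g. a covariate tertile).
#' @param match_p_min Matching threshold (default 0.1).
#' @param min_group Minimum individuals per group (default 3).
#' @return Object of class `group_comparison`: list with `feasible`,
#'   `reason`, `log2fc` (per-gene log2 high/low mean expression),
#'   `match_p` (per-covariate), `n_high`, `n_low`, `high`, `low` (indices).
#' @export
stratified_comparison <- function(expression, grouping, covariates = NULL,
                                  stratum = NULL, match_p_min = 0.1,
                                  min_group = 3L) {
  n <- length(grouping)
  if (ncol(expression) != n) stop("'expression' columns must match individuals")
  if (n < 9L) stop("need at least 9 individuals for non-degenerate tertiles")
  keep <- if (is.null(stratum)) rep(TRUE, n) else stratum
  ter <- tertile(grouping)
  hi <- which(keep & ter == 3L)
  lo <- which(keep & ter == 1L)
  fail <- function(reason) {
    structure(list(feasible = FALSE, reason = reason, log2fc = NULL,
                   match_p = NULL, n_high = length(hi), n_low = length(lo),
                   high = hi, low = lo),
              class = "group_comparison")
  }
  if (length(hi) < min_group || length(lo) < min_group) {
    return(fail("fewer than the minimum individuals in a group"))
  }
  match_p <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    match_p <- vapply(covariates, function(v) {
      rank_sum_test(v[hi], v[lo])$p
    }, numeric(1))
    if (any(match_p <= match_p_min)) {
      out <- fail("covariates differ between groups")
      out$match_p <- match_p
      return(out)
    }
  }
  mh <- rowMeans(expression[, hi, drop = FALSE])
  ml <- rowMeans(expression[, lo, drop = FALSE])
  structure(list(feasible = TRUE, reason = NA_character_,
                 log2fc = log2(mh / ml), match_p = match_p,
                 n_high = length(hi), n_low = length(lo),
                 high = hi, low = lo),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!x$feasible) {
    cat("<group_comparison> infeasible:", x$reason, "\n")
  } else {
    cat("<group_comparison> high n =", x$n_high, ", low n =", x$n_low,
        ", median log2FC =", round(stats::median(x$log2fc, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}

#' Knockdown-versus-control contrasts
#'
#' Averages the replicate columns of each condition first, then computes the
#' per-gene expression ratio (KD / control) and, when editing tables are
#' given, the per-site editing-level difference (KD minus control), with a
#' rank-sum comparison between a site group of interest (e.g. sites within
#' 500 nt of a target site) and its control group.
#'
#' @param kd_expr,ctrl_expr Genes x replicates matrices (same genes).
#' @param kd_edit,ctrl_edit Optional sites x replicates editing-level
#'   matrices (same sites).
#' @param group,control_group Optional logical/index vectors selecting the
#'   contrasted site groups (rows of the editing tables) or gene groups
#'   (rows of the expression tables when no editing tables are given).
#' @return List with `expr_ratio` (per-gene KD/control), `edit_diff`
#'   (per-site KD minus control, or NULL), and `contrast` (rank-sum p and
#'   group means over `group` vs `control_group`, or NULL).
#' @export
kd_contrast <- function(kd_expr, ctrl_expr, kd_edit = NULL, ctrl_edit = NULL,
                        group = NULL, control_group = NULL) {
  avg <- function(m, nm) {
    m <- as.matrix(m)
    if (ncol(m) < 1L) stop("missing replicate columns in ", nm)
    if (any(is.na(m))) stop("missing replicate values in ", nm)
    rowMeans(m)
  }
  ke <- avg(kd_expr, "kd_expr"); ce <- avg(ctrl_expr, "ctrl_expr")
  if (length(ke) != length(ce)) stop("expression tables have different genes")
  expr_ratio <- ke / ce
  edit_diff <- NULL
  if (!is.null(kd_edit) || !is.null(ctrl_edit)) {
    if (is.null(kd_edit) || is.null(ctrl_edit)) stop("both editing tables required")
    edit_diff <- avg(kd_edit, "kd_edit") - avg(ctrl_edit, "ctrl_edit")
  }
  contrast <- NULL
  if (!is.null(group) && !is.null(control_group)) {
    values <- if (!is.null(edit_diff)) edit_diff else log2(expr_ratio)
    a <- values[group]; b <- values[control_group]
    if (length(a) > 0L && length(b) > 0L) {
      rs <- rank_sum_test(a, b)
      contrast <- list(p = rs$p, mean_group = mean(a), mean_control = mean(b),
                       n_group = length(a), n_control = length(b))
    }
  }
  list(expr_ratio = expr_ratio, edit_diff = edit_diff, contrast = contrast)
}
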