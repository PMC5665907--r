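# Structure-level analyses: folding the editing-site neighbourhood in its
# unedited (A) and edited (G) versions, 7-mer accessibility profiles and
# their log2 ratio, the opposite-nucleotide rule in MFE structures, control
# adenosines, and the accessibility-expression correlation.

#' Fold the neighbourhood of an editing site, unedited and edited
#'
#' Extracts a window of `window` nt centred at the site (truncated at the
#' sequence ends), folds both the unedited sequence and the variant with the
#' site's A replaced by G under identical engine settings, and attaches
#' centred 7-mer unpaired probabilities (RNAplfold, `-u 7 -L 300 -W 400` by
#' default) and the MFE structure.
#'
#' @param sequence RNA sequence containing the site.
#' @param site_pos 0-based offset of the editing site (must be A).
#' @param window Window length in nt (default 1001).
#' @param u,L,W Accessibility engine parameters.
#' @return List with `unedited` and `edited` [fold_result()]s (each carries
#'   the 1-based window bounds on the input) and `site_in_window`
#'   (0-based offset of the site inside the window).
#' @export
fold_window <- function(sequence, site_pos, window = 1001L,
                        u = 7L, L = 300L, W = 400L) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  pos1 <- site_pos + 1L
  if (pos1 < 1L || pos1 > n) stop("'site_pos' outside the sequence")
  if (substr(sequence, pos1, pos1) != "A") {
    stop("base at 'site_pos' is ", substr(sequence, pos1, pos1), ", not A")
  }
  half <- window %/% 2L
  from <- max(1L, pos1 - half)
  to <- min(n, pos1 + half)
  sub_u <- substr(sequence, from, to)
  site_in <- pos1 - from            # 0-based within window
  sub_e <- sub_u
  substr(sub_e, site_in + 1L, site_in + 1L) <- "G"

  seqs <- c(unedited = sub_u, edited = sub_e)
  mfe <- fold_mfe(seqs)
  lunp <- plfold_unpaired(seqs, u = u, L = L, W = W)
  mk <- function(nm) {
    fold_result(seqs[[nm]], mfe$structure[mfe$name == nm],
                accessibility = centered_accessibility(lunp[[nm]], u = u),
                mfe = mfe$mfe[mfe$name == nm], window = c(from, to))
  }
  list(unedited = mk("unedited"), edited = mk("edited"), site_in_window = site_in)
}

#' Relative 7-mer accessibility profile around a site
#'
#' Per-offset log2 ratio of edited over unedited u-mer accessibility, with
#' the u-mer centred at each offset and the editing site at offset 0.
#' Identically zero when the two fold results are from the same sequence.
#'
#' @param unedited,edited [fold_result()]s from the same window and settings.
#' @param site_in_window 0-based site offset within the window.
#' @param max_offset Largest |offset| reported (default 500).
#' @return Data frame of class `accessibility_delta` with `offset` and
#'   `log2_ratio` (NA where a full centred u-mer does not fit).
#' @export
relative_accessibility <- function(unedited, edited, site_in_window,
                                   max_offset = 500L) {
  if (nchar(unedited$sequence) != nchar(edited$sequence)) {
    stop("fold results come from different windows")
  }
  if (!identical(unedited$window, edited$window)) {
    stop("fold results come from different windows")
  }
  n <- nchar(unedited$sequence)
  offsets <- (-max_offset):max_offset
  centre1 <- site_in_window + 1L + offsets
  ratio <- rep(NA_real_, length(offsets))
  ok <- centre1 >= 1L & centre1 <= n
  au <- unedited$accessibility[centre1[ok]]
  ae <- edited$accessibility[centre1[ok]]
  ratio[ok] <- log2(ae / au)
  out <- data.frame(offset = offsets, log2_ratio = ratio)
  class(out) <- c("accessibility_delta", class(out))
  out
}

#' Nucleotide opposite a site in an MFE structure
#'
#' If the site is paired, the partner base. If the site is unpaired but its
#' 5' neighbour pairs with position j, the base at j - 1; if instead its 3'
#' neighbour pairs with j, the base at j + 1 (antiparallel geometry). When
#' both neighbour rules would apply, the 5' neighbour is used. In all other
#' cases the opposite nucleotide is ambiguous and 'N' is returned, as it is
#' when a derived index falls outside the sequence.
#'
#' @param fold A [fold_result()].
#' @param site_pos 0-based site offset.
#' @return Single character: one of A, C, G, U or "N".
#' @export
opposite_nucleotide <- function(fold, site_pos) {
  pt <- fold$pairs
  s <- split_bases(fold$sequence)
  i <- site_pos + 1L
  if (i < 1L || i > length(pt)) stop("'site_pos' outside the structure")
  at <- function(j) if (!is.na(j) && j >= 1L && j <= length(s)) s[j] else "N"
  if (!is.na(pt[i])) return(at(pt[i]))
  if (i - 1L >= 1L && !is.na(pt[i - 1L])) return(at(pt[i - 1L] - 1L))
  if (i + 1L <= length(pt) && !is.na(pt[i + 1L])) return(at(pt[i + 1L] + 1L))
  "N"
}

#' Spectrum of opposite nucleotides across sites
#'
#' Frequencies of the base opposite each site in the unedited and edited MFE
#' structures, plus the fraction of sites whose editing-site base is
#' directly paired.
#'
#' @param folds List as returned by [fold_window()] (elements with
#'   `unedited`, `edited`, `site_in_window`).
#' @return List with `spectrum` (5 x 2 matrix over A/C/G/U/N) and
#'   `paired_fraction` (length-2 vector, unedited and edited).
#' @export
opposite_base_spectrum <- function(folds) {
  if (length(folds) == 0L) stop("empty site list")
  lev <- c(RNA_BASES, "N")
  get <- function(variant) {
    opp <- vapply(folds, function(f) opposite_nucleotide(f[[variant]], f$site_in_window),
                  character(1))
    paired <- vapply(folds, function(f) !is.na(f[[variant]]$pairs[f$site_in_window + 1L]),
                     logical(1))
    list(freq = as.numeric(table(factor(opp, levels = lev))) / length(folds),
         paired = mean(paired))
  }
  u <- get("unedited"); e <- get("edited")
  spectrum <- cbind(unedited = u$freq, edited = e$freq)
  rownames(spectrum) <- lev
  list(spectrum = spectrum, paired_fraction = c(unedited = u$paired, edited = e$paired))
}

#' Select control adenosines at a distance from editing sites
#'
#' Uniformly samples adenosine positions that are (1) not editing sites,
#' (2) inside 3' UTR regions, and (3) whose distance to the nearest editing
#' site lies within `dist_range`. Deterministic per seed.
#'
#' @param sequence RNA sequence of the transcript.
#' @param edit_sites Integer vector of 0-based editing-site offsets.
#' @param utr3 0-based half-open `[start, end)` of the 3' UTR on the
#'   sequence (default: the whole sequence).
#' @param dist_range Length-2 inclusive range of allowed distances in nt.
#' @param n Number of control positions to sample.
#' @param seed Integer seed.
#' @return Integer vector of 0-based control positions.
#' @export
select_control_adenosines <- function(sequence, edit_sites,
                                      utr3 = NULL, dist_range = c(300L, 500L),
                                      n = 1L, seed = 1L) {
  sequence <- as_rna(sequence)
  len <- nchar(sequence)
  if (is.null(utr3)) utr3 <- c(0L, len)
  a_pos <- which(split_bases(sequence) == "A") - 1L
  a_pos <- a_pos[a_pos >= utr3[1L] & a_pos < utr3[2L]]
  a_pos <- setdiff(a_pos, edit_sites)
  if (length(edit_sites) == 0L) stop("no editing sites to measure distance from")
  dist <- vapply(a_pos, function(p) min(abs(p - edit_sites)), numeric(1))
  cand <- a_pos[dist >= dist_range[1L] & dist <= dist_range[2L]]
  if (length(cand) == 0L) stop("no candidate adenosines in the distance range")
  if (n > length(cand)) {
    stop("requested ", n, " controls but only ", length(cand), " candidates exist")
  }
  withr::with_seed(seed, sort(sample(cand, n)))
}

#' Correlation between target-site accessibility change and expression change
#'
#' Genes are grouped by the distance between their editing site and closest
#' miRNA target site into sliding distance windows; within each window the
#' relative accessibility at the target site and the log2 expression ratio of
#' edited over unedited individuals are averaged, and the Pearson correlation
#' across window means is returned.
#'
#' @param delta Numeric vector: per-gene relative (log2) 7-mer accessibility
#'   at the closest target site.
#' @param expression_ratio Numeric vector: per-gene log2 expression ratio of
#'   edited over unedited individuals.
#' @param distance Integer vector: per-gene editing-site-to-target distance.
#' @param window Distance window size in nt (default 10).
#' @param slide Window step in nt (default 1).
#' @param min_windows Minimum usable windows for the correlation (default 3).
#' @return List with `r`, `p`, `n_windows`, `windows` (per-window means) and
#'   `status` ("ok", "too few windows", or "zero variance").
#' @export
accessibility_expression_correlation <- function(delta, expression_ratio, distance,
                                                 window = 10L, slide = 1L,
                                                 min_windows = 3L) {
  ok <- is.finite(delta) & is.finite(expression_ratio) & is.finite(distance)
  delta <- delta[ok]; expression_ratio <- expression_ratio[ok]; distance <- distance[ok]
  if (length(delta) == 0L) {
    return(list(r = NA_real_, p = NA_real_, n_windows = 0L,
                windows = NULL, status = "too few windows"))
  }
  starts <- seq(min(distance), max(max(distance) - window + 1L, min(distance)),
                by = slide)
  wins <- lapply(starts, function(s) which(distance >= s & distance < s + window))
  keep <- vapply(wins, length, integer(1)) > 0L
  wd <- vapply(wins[keep], function(ix) mean(delta[ix]), numeric(1))
  wr <- vapply(wins[keep], function(ix) mean(expression_ratio[ix]), numeric(1))
  windows <- data.frame(start = starts[keep], mean_delta = wd, mean_ratio = wr,
                        n = vapply(wins[keep], length, integer(1)))
  if (nrow(windows) < min_windows) {
    return(list(r = NA_real_, p = NA_real_, n_windows = nrow(windows),
                windows = windows, status = "too few windows"))
  }
  if (stats::sd(wd) == 0 || stats::sd(wr) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_windows = nrow(windows),
                windows = windows, status = "zero variance"))
  }
  ct <- stats::cor.test(wd, wr)
  list(r = unname(ct$estimate), p = ct$p.value, n_windows = nrow(windows),
       windows = windows, status = "ok")
}
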