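# Editing-site calling: per-site log-likelihood ratio against a
# sequencing-error-only model, the filter cascade, genomic-context
# classification, population-level site selection, and the A-to-G fraction.

# default thresholds; see default_run_config() for the full set
LLR_MIN <- 2
DEPTH_MIN <- 10L
ALT_MIN <- 2L
LEVEL_MIN <- 0.1
HOMOPOLYMER_MAX <- 4L
SPLICE_NT <- 4L
INTRON_CLOSE_NT <- 300L

parse_int_field <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
}

#' Log-likelihood ratio of a mismatch site against a sequencing-error model
#'
#' Compares the maximum likelihood of the alt-supporting reads under a
#' true-variant model (a variant fraction `f`, maximised over `[0, 1]`,
#' with per-read error probabilities `10^(-Q/10)`) against an errors-only
#' model (`f = 0`). Larger values indicate a more credible edit. Optionally
#' down-weights mismatches within 6 nt of the read ends by half.
#'
#' @param obs A one-row `mismatch_observation` (or data frame with `depth`,
#'   `alt_count`, `quals`, optionally `read_pos`).
#' @param base Logarithm base for the ratio; 10 by default.
#' @param position_weight Down-weight read-end mismatches (off by default).
#' @param read_length Read length used with `position_weight`.
#' @return The log-base-`base` likelihood ratio (a single number).
#' @export
compute_llr <- function(obs, base = 10, position_weight = FALSE,
                        read_length = 100L) {
  depth <- obs$depth[1L]
  alt <- obs$alt_count[1L]
  if (depth < 1L) stop("'depth' must be >= 1")
  if (alt < 1L) stop("site with no alt-supporting reads is not a candidate")
  quals <- parse_int_field(as.character(obs$quals[1L]))
  if (length(quals) != alt) {
    if (length(quals) == 0L) quals <- rep(30L, alt) else
      stop("number of qualities does not match alt_count")
  }
  p_err <- 10^(-quals / 10)
  w <- rep(1, alt)
  if (position_weight && "read_pos" %in% names(obs)) {
    rp <- parse_int_field(as.character(obs$read_pos[1L]))
    if (length(rp) == alt) {
      w[rp <= 6L | rp > (read_length - 6L)] <- 0.5
    }
  }
  n_ref <- depth - alt
  loglik <- function(f) {
    sum(w * log(f + (1 - f) * p_err)) + n_ref * log1p(-f)
  }
  ll0 <- loglik(0)
  opt <- stats::optimize(loglik, c(0, 1 - 1e-12), maximum = TRUE)
  ll1 <- max(opt$objective, ll0)
  (ll1 - ll0) / log(base)
}

# the eight filter predicates, each returning TRUE when the site PASSES
site_predicates <- function(obs, annotations, llr,
                            thresholds = list()) {
  th <- utils::modifyList(list(llr = LLR_MIN, depth = DEPTH_MIN, alt = ALT_MIN,
                               level = LEVEL_MIN, homopolymer = HOMOPOLYMER_MAX,
                               splice = SPLICE_NT), thresholds)
  level <- ifelse(obs$depth > 0, obs$alt_count / obs$depth, 0)
  pos <- obs$pos0
  contig <- obs$gene

  in_positions <- function(track, pad = 0L) {
    if (nrow(track) == 0L) return(rep(FALSE, nrow(obs)))
    mapply(function(cg, p) any(track$contig == cg & abs(track$pos0 - p) <= pad),
           contig, pos, USE.NAMES = FALSE)
  }
  in_intervals <- function(track) {
    if (nrow(track) == 0L) return(rep(FALSE, nrow(obs)))
    mapply(function(cg, p) {
      sel <- track$contig == cg
      any(sel & track$start <= p & p < track$end)
    }, contig, pos, USE.NAMES = FALSE)
  }
  homo <- annotations$homopolymers
  in_long_homopolymer <- if (nrow(homo) == 0L) rep(FALSE, nrow(obs)) else {
    long <- homo[homo$end - homo$start > th$homopolymer, , drop = FALSE]
    in_intervals(long)
  }
  intronic <- classify_context(obs, annotations)
  near_splice <- if (nrow(annotations$splice) == 0L) rep(FALSE, nrow(obs)) else {
    mapply(function(cg, p) {
      sel <- annotations$splice$contig == cg
      any(sel & abs(annotations$splice$pos0 - p) <= th$splice)
    }, contig, pos, USE.NAMES = FALSE)
  }
  is_intron <- intronic %in% c("Intron-close", "Intron-deep")

  cbind(
    llr = llr >= th$llr,
    coverage = obs$depth >= th$depth,
    edited_reads = obs$alt_count >= th$alt,
    level = level >= th$level,
    snp = !in_positions(annotations$snps),
    simple_repeat = !in_intervals(annotations$repeats),
    homopolymer = !in_long_homopolymer,
    splice_junction = !(is_intron & near_splice)
  )
}

#' Filter candidate editing sites through the full cascade
#'
#' Retains sites passing all of: LLR >= 2, depth >= 10, edited reads >= 2,
#' editing level >= 0.1, not at a known SNP, not in a simple repeat, not in a
#' homopolymer run longer than 4 nt, and not intronic within 4 nt of a splice
#' junction. Rejected sites carry the first failing rule (fixed evaluation
#' order: llr, coverage, edited_reads, level, snp, simple_repeat,
#' homopolymer, splice_junction) and the complete set of failing rules.
#'
#' @param observations Data frame of mismatch observations (rows as produced
#'   by [simulate_pileup()] or [read_pileup_tsv()]).
#' @param annotations An [annotation_set()]; all tracks must be present.
#' @param thresholds Optional named list overriding individual thresholds.
#' @param llr Optional precomputed LLR vector (otherwise computed per site;
#'   sites with `alt_count == 0` get `-Inf`).
#' @return Data frame with the input columns plus `level`, `llr`, `retained`,
#'   `first_fail`, `fails` (semicolon-joined failing rules).
#' @export
filter_sites <- function(observations, annotations, thresholds = list(),
                         llr = NULL) {
  if (!inherits(annotations, "annotation_set")) {
    stop("'annotations' must be an annotation_set (missing annotation tracks ",
         "are an error, not a silent pass)")
  }
  for (tr in c("snps", "repeats", "homopolymers", "splice", "regions")) {
    if (is.null(annotations[[tr]])) stop("annotation track '", tr, "' is missing")
  }
  obs <- as.data.frame(observations)
  if (is.null(llr)) {
    llr <- vapply(seq_len(nrow(obs)), function(i) {
      if (obs$alt_count[i] >= 1L && obs$depth[i] >= 1L) {
        compute_llr(obs[i, , drop = FALSE])
      } else -Inf
    }, numeric(1))
  }
  pass <- site_predicates(obs, annotations, llr, thresholds)
  rules <- colnames(pass)
  obs$level <- ifelse(obs$depth > 0, obs$alt_count / obs$depth, 0)
  obs$llr <- llr
  obs$retained <- apply(pass, 1L, all)
  obs$first_fail <- apply(pass, 1L, function(p) {
    f <- rules[!p]
    if (length(f) == 0L) NA_character_ else f[1L]
  })
  obs$fails <- apply(pass, 1L, function(p) paste(rules[!p], collapse = ";"))
  obs
}

CONTEXT_PRIORITY <- c("CDS", "UTR3", "UTR5", "ncExon", "Intron-close",
                      "Intron-deep", "Intergenic")

#' Genomic context of sites
#'
#' Assigns each site a single context label with the priority
#' CDS > 3' UTR > 5' UTR > ncExon > Intron-close > Intron-deep > Intergenic.
#' Intronic sites within 300 nt of an exon-intron boundary are Intron-close,
#' farther ones Intron-deep; sites overlapping nothing are Intergenic.
#'
#' @param sites Data frame with `gene` (contig) and `pos0` columns.
#' @param annotations An [annotation_set()] whose `regions` track uses types
#'   CDS, UTR3, UTR5, ncExon, intron.
#' @param intron_close_nt Distance defining Intron-close (default 300).
#' @return Character vector of context labels, one per site.
#' @export
classify_context <- function(sites, annotations, intron_close_nt = INTRON_CLOSE_NT) {
  reg <- annotations$regions
  vapply(seq_len(nrow(sites)), function(i) {
    cg <- sites$gene[i]
    p <- sites$pos0[i]
    sel <- reg[reg$contig == cg & reg$start <= p & p < reg$end, , drop = FALSE]
    if (nrow(sel) == 0L) return("Intergenic")
    types <- unique(sel$type)
    if ("intron" %in% types) {
      ir <- sel[sel$type == "intron", , drop = FALSE]
      dist_to_boundary <- min(pmin(p - ir$start, ir$end - 1L - p))
      lab <- if (dist_to_boundary <= intron_close_nt) "Intron-close" else "Intron-deep"
      types <- c(setdiff(types, "intron"), lab)
    }
    types <- intersect(CONTEXT_PRIORITY, types)
    if (length(types) == 0L) "Intergenic" else types[1L]
  }, character(1))
}

#' Population-level site selection
#'
#' Retains sites that are edited (alt count >= 2 and level >= 0.1) in at
#' least `min_edited_individuals` individuals and covered by >= 10 reads in
#' at least `min_testable_fraction` of the population's individuals.
#'
#' @param matrix An [editing_matrix()].
#' @param population Optional population label to restrict to.
#' @param min_edited_individuals Minimum edited individuals (default 3).
#' @param min_testable_fraction Minimum fraction with depth >= 10
#'   (default 0.1).
#' @return Character vector of retained site ids.
#' @export
select_population_sites <- function(matrix, population = NULL,
                                    min_edited_individuals = 3L,
                                    min_testable_fraction = 0.1) {
  stopifnot(inherits(matrix, "editing_matrix"))
  idx <- seq_len(ncol(matrix$depth))
  if (!is.null(population)) {
    idx <- which(matrix$individuals$population == population)
    if (length(idx) == 0L) stop("no individuals in population '", population, "'")
  }
  depth <- matrix$depth[, idx, drop = FALSE]
  alt <- matrix$alt[, idx, drop = FALSE]
  level <- ifelse(depth > 0, alt / depth, NA_real_)
  edited <- (alt >= 2L) & !is.na(level) & (level >= 0.1)
  n_edited <- rowSums(edited, na.rm = TRUE)
  n_testable <- rowSums(depth >= 10L)
  keep <- n_edited >= min_edited_individuals &
    n_testable >= min_testable_fraction * length(idx)
  rownames(depth)[keep]
}

#' Fraction of A-to-G mismatch sites
#'
#' Strand-resolved: a genomic T-to-C mismatch on the minus strand reflects
#' A-to-G on the transcript and is counted as A-to-G.
#'
#' @param sites Data frame with `ref`, `alt` and `strand` columns.
#' @return Fraction in `[0, 1]` of A-to-G sites among all sites.
#' @export
a2g_fraction <- function(sites) {
  if (nrow(sites) == 0L) stop("empty site set")
  comp <- c(A = "U", C = "G", G = "C", U = "A", T = "A")
  ref <- chartr("T", "U", toupper(sites$ref))
  alt <- chartr("T", "U", toupper(sites$alt))
  minus <- sites$strand == "-"
  ref[minus] <- comp[ref[minus]]
  alt[minus] <- comp[alt[minus]]
  mean(ref == "A" & alt == "G")
}
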