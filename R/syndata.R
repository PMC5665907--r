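# Synthetic-data generators: population expression profiles, hairpin-bearing
# 3' UTRs with an editable adenosine and a nearby miRNA seed site, the
# preferential-degradation model linking editing to transcript survival, and
# pileup-level read sampling.

# miR-24-3p; its nt 2-8 seed is the default miRNA used by the generators
DEFAULT_MIRNA <- c(mir24 = "UGGCUCAGUUCAGCAGGAACAG")

#' Configuration for population simulation
#'
#' Describes per-population log-normal expression distributions for the ADAR
#' enzymes, AGO2 and miRNAs, the logistic link from log ADAR1 expression to
#' true editing, the degradation scale, and the sequencing error rate.
#'
#' @param populations Named list; one entry per population label, each a list
#'   with `n` (individuals) and optionally `adar1`, `adar2`, `adar3`, `ago2`,
#'   `mirna` entries of the form `c(meanlog, sdlog)`.
#' @param editing_slope Slope of the logistic link from log ADAR1 to true
#'   editing level.
#' @param editing_midpoint Range (length 2) from which per-site logistic
#'   midpoints on the log ADAR1 scale are drawn.
#' @param editing_max Upper asymptote of the logistic editing level.
#' @param degradation_k Nonnegative degradation scale multiplying
#'   AGO2 activity times target-site accessibility.
#' @param error_rate Per-read sequencing error probability, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return Object of class `population_sim_config`.
#' @export
population_sim_config <- function(populations = list(
                                    POP1 = list(n = 100),
                                    POP2 = list(n = 100, adar1 = c(0.5, 0.4))),
                                  editing_slope = 2,
                                  editing_midpoint = c(0, 1),
                                  editing_max = 0.8,
                                  degradation_k = 1,
                                  error_rate = 0.001,
                                  seed = 1L) {
  defaults <- list(adar1 = c(0, 0.4), adar2 = c(-0.7, 0.4), adar3 = c(-2, 0.5),
                   ago2 = c(0, 0.5), mirna = c(0, 0.4))
  if (length(populations) == 0L || is.null(names(populations))) {
    stop("'populations' must be a named list with at least one population")
  }
  populations <- lapply(populations, function(p) {
    p$n <- assert_count(p$n, "n", min = 1L)
    for (nm in names(defaults)) {
      if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
      if (length(p[[nm]]) != 2L || !is.numeric(p[[nm]])) {
        stop("expression distribution '", nm, "' must be c(meanlog, sdlog)")
      }
      if (p[[nm]][2L] <= 0) stop("expression scale for '", nm, "' must be > 0")
    }
    p
  })
  assert_scalar_num(error_rate, "error_rate", 0, 0.5)
  assert_scalar_num(degradation_k, "degradation_k", 0, Inf)
  assert_scalar_num(editing_slope, "editing_slope")
  assert_scalar_num(editing_max, "editing_max", 0, 1)
  structure(
    list(populations = populations, editing_slope = editing_slope,
         editing_midpoint = editing_midpoint, editing_max = editing_max,
         degradation_k = degradation_k, error_rate = error_rate,
         seed = as.integer(seed)),
    class = "population_sim_config"
  )
}

#' Simulate per-individual expression profiles across populations
#'
#' Draws ADAR1/2/3, AGO2 and miRNA expression for every individual from the
#' configured per-population log-normal distributions. Deterministic for a
#' fixed config seed.
#'
#' @param config A [population_sim_config()].
#' @return Data frame with one row per individual: `individual`, `population`,
#'   `adar1`, `adar2`, `adar3`, `ago2`, `mirna`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_sim_config"))
  withr::with_seed(config$seed, {
    rows <- lapply(names(config$populations), function(lab) {
      p <- config$populations[[lab]]
      data.frame(
        individual = paste0(lab, "_", seq_len(p$n)),
        population = lab,
        adar1 = stats::rlnorm(p$n, p$adar1[1L], p$adar1[2L]),
        adar2 = stats::rlnorm(p$n, p$adar2[1L], p$adar2[2L]),
        adar3 = stats::rlnorm(p$n, p$adar3[1L], p$adar3[2L]),
        ago2 = stats::rlnorm(p$n, p$ago2[1L], p$ago2[2L]),
        mirna = stats::rlnorm(p$n, p$mirna[1L], p$mirna[2L]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate a hairpin-bearing synthetic 3' UTR
#'
#' Constructs an RNA sequence containing one hairpin whose 5' arm carries a
#' single editable adenosine. The base structurally opposite the A is set to
#' `edit_opposite`: with C the unedited A sits in an A.C mismatch and the
#' A-to-G edit completes a G-C pair; with U the unedited A-U pair becomes a
#' G.U wobble. A 7mer-m8 seed-match site for `mirna` is placed
#' `target_distance` nt 5' of the editing site; the stem's outer arm clasps
#' the last `seed_overlap` nt of the seed site, so stabilising the stem by
#' editing reduces the seed site's accessibility, most strongly at short
#' distances. Flanking sequence is pyrimidine-only and cannot base-pair with
#' itself, avoiding competing hairpins.
#'
#' @param length Total sequence length in nt.
#' @param stem_len Length of each stem arm in nt (>= 4).
#' @param edit_opposite Base opposite the editing site, `"C"` or `"U"`.
#' @param target_distance Edge-to-edge distance in nt between the editing
#'   site and the seed-site interval.
#' @param mirna miRNA sequence (>= 8 nt, RNA alphabet) whose nt 2-8 define
#'   the seed site.
#' @param seed_overlap How many 3'-terminal nt of the seed site are clasped
#'   by the stem (2-4).
#' @param seed Integer seed.
#' @return Object of class `synthetic_transcript`: a list with `gene_id`,
#'   `sequence`, `edit_pos` (0-based offset of the A), `opposite`,
#'   `target_start`/`target_end` (0-based half-open seed interval),
#'   `mirna_id`, `distance`.
#' @export
generate_hairpin_utr <- function(length = 120L, stem_len = 12L,
                                 edit_opposite = c("C", "U"),
                                 target_distance = 4L,
                                 mirna = DEFAULT_MIRNA,
                                 seed_overlap = 3L,
                                 seed = 1L) {
  edit_opposite <- match.arg(edit_opposite)
  stem_len <- assert_count(stem_len, "stem_len", min = 4L)
  target_distance <- assert_count(target_distance, "target_distance", min = 0L)
  seed_overlap <- assert_count(seed_overlap, "seed_overlap", min = 1L)
  if (seed_overlap > 4L) stop("'seed_overlap' must be at most 4")
  mirna_seq <- as_rna(mirna[[1L]])
  mirna_id <- if (!is.null(names(mirna))) names(mirna)[1L] else "mirna1"
  if (nchar(mirna_seq) < 8L) stop("'mirna' must be at least 8 nt")
  seed_site <- rna_revcomp(substr(mirna_seq, 2L, 8L))  # 7mer-m8 site

  # arm index (0-based) of the editing A, measured from the outer stem end
  a_idx <- target_distance + seed_overlap - 1L
  if (a_idx < seed_overlap) {
    stop("infeasible geometry: editing site would fall inside the seed heptamer ",
         "(target_distance too small for seed_overlap = ", seed_overlap, ")")
  }
  anchor_len <- stem_len - a_idx - 1L
  if (anchor_len < 3L) {
    stop("infeasible geometry: stem_len = ", stem_len,
         " leaves no inner anchor for target_distance = ", target_distance)
  }
  loop <- "GAAA"
  leader_len <- 25L
  core_len <- leader_len + (7L - seed_overlap) + 2L * stem_len + nchar(loop)
  trailer_len <- length - core_len
  if (trailer_len < 10L) {
    stop("infeasible geometry: 'length' too short for stem_len = ", stem_len,
         " (need at least ", core_len + 10L, ")")
  }

  withr::with_seed(seed, {
    leader <- paste(sample(c("C", "U"), leader_len, TRUE, prob = c(0.6, 0.4)),
                    collapse = "")
    trailer <- paste(sample(c("C", "U"), trailer_len, TRUE, prob = c(0.6, 0.4)),
                     collapse = "")
    seed_chars <- split_bases(seed_site)
    mid <- sample(c("A", "U"), a_idx - seed_overlap, TRUE)
    if (length(mid) > 0L) mid[1L] <- "U"  # keep the designed site a 7mer-m8, not 8mer
    anchor <- sample(c("G", "C"), anchor_len, TRUE)
    stem5 <- c(seed_chars[(7L - seed_overlap + 1L):7L], mid, "A", anchor)
    stem3 <- split_bases(rna_revcomp(paste(stem5, collapse = "")))
    stem3[stem_len - a_idx] <- edit_opposite
    sequence <- paste0(leader, paste(seed_chars[seq_len(7L - seed_overlap)], collapse = ""),
                       paste(stem5, collapse = ""), loop,
                       paste(stem3, collapse = ""), trailer)
  })

  target_start <- leader_len                      # 0-based
  target_end <- target_start + 7L
  edit_pos <- leader_len + (7L - seed_overlap) + a_idx
  stopifnot(substr(sequence, edit_pos + 1L, edit_pos + 1L) == "A",
            nchar(sequence) == length)
  structure(
    list(gene_id = sprintf("synutr_s%d", seed), sequence = sequence,
         edit_pos = edit_pos, opposite = edit_opposite,
         target_start = target_start, target_end = target_end,
         mirna_id = mirna_id, mirna_seq = mirna_seq,
         distance = edit_pos - (target_end - 1L),
         stem_len = stem_len, seed = seed),
    class = "synthetic_transcript"
  )
}

#' Edited variant of a synthetic transcript sequence
#'
#' @param transcript A [generate_hairpin_utr()] result (or any list with
#'   `sequence` and 0-based `edit_pos`).
#' @return The sequence with the editing-site A replaced by G.
#' @export
edited_sequence <- function(transcript) {
  s <- transcript$sequence
  pos <- transcript$edit_pos + 1L
  if (substr(s, pos, pos) != "A") stop("base at the editing site is not A")
  substr(s, pos, pos) <- "G"
  s
}

#' Preferential-degradation model
#'
#' Unedited molecules survive degradation with probability `s_u`, edited
#' molecules with `s_e`. With true editing level `e`, the surviving pool has
#' observed editing `e*s_e / (e*s_e + (1-e)*s_u)` and relative abundance
#' `e*s_e + (1-e)*s_u`. When `s_e > s_u` (the edited isoform escapes
#' AGO2-miRNA targeting) the observed level exceeds the true level, and
#' differences between sites with different true levels are compressed.
#'
#' @param e True editing level(s) in `[0, 1]`.
#' @param s_u Survival probability of unedited molecules, in `(0, 1]`.
#' @param s_e Survival probability of edited molecules, in `(0, 1]`.
#' @return List with numeric components `observed` and `abundance`,
#'   vectorised over the inputs.
#' @export
apply_degradation <- function(e, s_u, s_e) {
  if (any(e < 0 | e > 1, na.rm = TRUE)) stop("'e' must be in [0, 1]")
  if (any(s_u <= 0 | s_u > 1, na.rm = TRUE)) stop("'s_u' must be in (0, 1]")
  if (any(s_e <= 0 | s_e > 1, na.rm = TRUE)) stop("'s_e' must be in (0, 1]")
  abundance <- e * s_e + (1 - e) * s_u
  observed <- ifelse(abundance > 0, e * s_e / abundance, 0)
  list(observed = observed, abundance = abundance)
}

#' Survival probability from AGO2 activity and target accessibility
#'
#' `exp(-k * ago2 * accessibility)`: the simplest monotone link mapping
#' nonnegative degradation pressure to a survival probability in `(0, 1]`.
#'
#' @param ago2 Nonnegative AGO2-miRNA activity.
#' @param accessibility Target-site accessibility in `(0, 1]`.
#' @param k Nonnegative degradation scale.
#' @return Survival probabilities in `(0, 1]`, vectorised.
#' @export
survival_from_accessibility <- function(ago2, accessibility, k = 1) {
  if (any(ago2 < 0, na.rm = TRUE)) stop("'ago2' must be nonnegative")
  if (any(accessibility <= 0 | accessibility > 1, na.rm = TRUE)) {
    stop("'accessibility' must be in (0, 1]")
  }
  if (any(k < 0, na.rm = TRUE)) stop("'k' must be nonnegative")
  exp(-k * ago2 * accessibility)
}

#' Simulate a pileup observation at one site
#'
#' Draws `alt_count ~ Binomial(depth, observed)` edited (G) reads; each of
#' the remaining reads is mis-read with probability `error_rate`, the wrong
#' base drawn uniformly from the three alternatives (errors into G add to the
#' alt count). Phred qualities for alt-supporting reads come from a clipped
#' normal quality model; within-read positions are uniform.
#'
#' @param observed Observed editing level in `[0, 1]`.
#' @param depth Read depth (>= 0).
#' @param error_rate Per-read error probability.
#' @param quality_mean,quality_sd,quality_range Quality model: Phred scores
#'   are `round(rnorm(mean, sd))` clipped to `quality_range`.
#' @param read_length Read length used for within-read positions.
#' @param gene,pos,strand,ref Site identity fields copied into the record.
#' @param seed Integer seed.
#' @return A one-row data frame (class `mismatch_observation`) with columns
#'   `gene`, `pos0`, `strand`, `ref`, `alt`, `depth`, `alt_count`,
#'   `other_count`, `quals` (comma-joined), `read_pos` (comma-joined),
#'   `untestable`.
#' @export
simulate_pileup <- function(observed, depth, error_rate = 0.001,
                            quality_mean = 35, quality_sd = 5,
                            quality_range = c(2, 41), read_length = 100L,
                            gene = "gene1", pos = 0L, strand = "+", ref = "A",
                            seed = 1L) {
  assert_scalar_num(observed, "observed", 0, 1)
  depth <- assert_count(depth, "depth", min = 0L)
  if (depth == 0L) {
    return(new_mismatch_observation(gene, pos, strand, ref, "G", 0L, 0L, 0L,
                                    integer(0), integer(0), untestable = TRUE))
  }
  withr::with_seed(seed, {
    edited <- stats::rbinom(1L, depth, observed)
    unedited <- depth - edited
    err <- stats::rbinom(1L, unedited, error_rate)
    err_bases <- if (err > 0L) sample(setdiff(RNA_BASES, ref), err, TRUE) else character(0)
    err_to_g <- sum(err_bases == "G")
    alt_count <- edited + err_to_g
    other_count <- err - err_to_g
    quals <- pmin(pmax(round(stats::rnorm(alt_count, quality_mean, quality_sd)),
                       quality_range[1L]), quality_range[2L])
    read_pos <- if (alt_count > 0L) sample.int(read_length, alt_count, TRUE) else integer(0)
  })
  new_mismatch_observation(gene, pos, strand, ref, "G", depth, alt_count,
                           other_count, quals, read_pos, untestable = FALSE)
}

new_mismatch_observation <- function(gene, pos, strand, ref, alt, depth,
                                     alt_count, other_count, quals, read_pos,
                                     untestable = FALSE) {
  if (alt_count > depth) stop("alt_count exceeds depth")
  out <- data.frame(
    gene = gene, pos0 = as.integer(pos), strand = strand, ref = ref, alt = alt,
    depth = as.integer(depth), alt_count = as.integer(alt_count),
    other_count = as.integer(other_count),
    quals = paste(quals, collapse = ","),
    read_pos = paste(read_pos, collapse = ","),
    untestable = untestable,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mismatch_observation", class(out))
  out
}

#' Generate annotation tracks for synthetic transcripts
#'
#' Emits BED-convention (0-based, half-open) tracks: SNP positions drawn at
#' `snp_density` per nt, simple-repeat intervals, homopolymer runs (computed
#' from the sequence, not random), and region/splice-junction tracks.
#' Deterministic for a fixed seed.
#'
#' @param transcripts Named character vector of sequences, or a list of
#'   `synthetic_transcript` objects.
#' @param snp_density Expected SNPs per nt.
#' @param repeat_spec List with `n` (repeats per transcript) and `unit`
#'   (repeat unit, default "CU") describing planted simple repeats.
#' @param region_type Region label for whole transcripts (default UTR3).
#' @param seed Integer seed.
#' @return Object of class `annotation_set`: data frames `regions`
#'   (contig/start/end/type/strand), `snps` (contig/pos0), `repeats`,
#'   `homopolymers`, `splice` (contig/pos0 boundary positions).
#' @export
generate_annotation_tracks <- function(transcripts, snp_density = 0.002,
                                       repeat_spec = list(n = 0L, unit = "CU"),
                                       region_type = "UTR3", seed = 1L) {
  seqs <- if (is.list(transcripts) && inherits(transcripts[[1L]], "synthetic_transcript")) {
    stats::setNames(vapply(transcripts, `[[`, character(1), "sequence"),
                    vapply(transcripts, `[[`, character(1), "gene_id"))
  } else {
    as_rna(unlist(transcripts))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("tx", seq_along(seqs))
  assert_scalar_num(snp_density, "snp_density", 0, 1)

  regions <- data.frame(contig = names(seqs), start = 0L,
                        end = nchar(seqs), type = region_type, strand = "+",
                        stringsAsFactors = FALSE, row.names = NULL)
  withr::with_seed(seed, {
    snps <- do.call(rbind, lapply(names(seqs), function(nm) {
      n <- nchar(seqs[[nm]])
      hit <- which(stats::runif(n) < snp_density) - 1L
      if (length(hit) == 0L) return(NULL)
      data.frame(contig = nm, pos0 = hit, stringsAsFactors = FALSE)
    }))
    reps <- do.call(rbind, lapply(names(seqs), function(nm) {
      if (is.null(repeat_spec$n) || repeat_spec$n < 1L) return(NULL)
      n <- nchar(seqs[[nm]])
      unit <- repeat_spec$unit %||% "CU"
      len <- 4L * nchar(unit)
      if (n <= len) return(NULL)
      starts <- sort(sample.int(n - len, repeat_spec$n))
      data.frame(contig = nm, start = starts - 1L, end = starts - 1L + len,
                 stringsAsFactors = FALSE)
    }))
  })
  if (is.null(snps)) snps <- data.frame(contig = character(), pos0 = integer(),
                                        stringsAsFactors = FALSE)
  if (is.null(reps)) reps <- data.frame(contig = character(), start = integer(),
                                        end = integer(), stringsAsFactors = FALSE)
  homos <- do.call(rbind, lapply(names(seqs), function(nm) {
    h <- homopolymer_runs(seqs[[nm]], min_len = 2L)
    if (nrow(h) == 0L) return(NULL)
    cbind(data.frame(contig = nm, stringsAsFactors = FALSE), h)
  }))
  if (is.null(homos)) homos <- data.frame(contig = character(), start = integer(),
                                          end = integer(), base = character(),
                                          stringsAsFactors = FALSE)
  annotation_set(regions = regions, snps = snps, repeats = reps,
                 homopolymers = homos,
                 splice = data.frame(contig = character(), pos0 = integer(),
                                     stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an annotation set
#'
#' Validates and bundles the five tracks used by the site filters and the
#' genomic-context classifier. Region intervals of contradictory type are not
#' allowed to be byte-identical duplicates.
#'
#' @param regions Data frame `contig`, `start`, `end`, `type`, `strand`
#'   (0-based half-open; types from CDS, UTR3, UTR5, ncExon, intron).
#' @param snps Data frame `contig`, `pos0`.
#' @param repeats Data frame `contig`, `start`, `end`.
#' @param homopolymers Data frame `contig`, `start`, `end`, `base`.
#' @param splice Data frame `contig`, `pos0` of exon-intron boundaries.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(regions, snps, repeats, homopolymers, splice) {
  for (d in list(regions, snps, repeats, homopolymers, splice)) {
    if (!is.data.frame(d)) stop("all annotation tracks must be data frames")
  }
  if (nrow(regions) > 0L) {
    if (any(regions$end < regions$start)) stop("region with end < start")
    key <- paste(regions$contig, regions$start, regions$end)
    dup <- duplicated(key) & !duplicated(paste(key, regions$type))
    if (any(dup)) stop("contradictory region labels on identical intervals")
  }
  structure(list(regions = regions, snps = snps, repeats = repeats,
                 homopolymers = homopolymers, splice = splice),
            class = "annotation_set")
}
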