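# End-to-end synthetic cohort: hairpin 3' UTRs folded in both allelic
# versions, per-individual expression profiles, logistic ADAR1-driven true
# editing with per-site prevalence, AGO2-miRNA degradation that prefers the
# more accessible (usually unedited) allele, and pileup-level read sampling.

#' Simulate a population cohort under the preferential-degradation model
#'
#' Generates `n_genes` hairpin-bearing 3' UTRs (a fraction without editing
#' sites as negative controls), folds the unedited and edited version of
#' each, and measures 7-mer accessibility at the miRNA seed site. Each
#' individual's true editing level at a gene follows a logistic function of
#' log ADAR1 expression, gated by a per-gene prevalence (a Bernoulli editor
#' status, so every gene retains truly unedited individuals). Allele
#' survival is `exp(-k * AGO2 * accessibility)` where the accessibility fed
#' to the link is normalised to the more accessible allele of the gene, so
#' the fold-derived log2 accessibility ratio is the only structural signal.
#' Observed editing and relative abundance follow [apply_degradation()];
#' read counts are binomial at negative-binomial depths; expression is
#' abundance times a log-normal gene base and multiplicative noise.
#'
#' @param config A [population_sim_config()].
#' @param n_genes Number of genes (default 50).
#' @param edited_fraction Fraction of genes carrying an editing site
#'   (default 0.8; the remainder are no-editing controls).
#' @param no_target_fraction Fraction of the edited genes whose seed site is
#'   scrubbed (no miRNA target, hence no degradation; default 0.2). These
#'   are the control group for knockdown editing contrasts.
#' @param distance_range Editing-site-to-target distances are sampled from
#'   `distance_range[1]:distance_range[2]` with weight `distance_weight`
#'   on the first 5 values.
#' @param distance_weight Relative weight of the 5 shortest distances
#'   (default 3 vs 0.7).
#' @param prevalence_range Per-gene editor fraction range (default
#'   c(0.4, 0.9)).
#' @param opposite_probs Probabilities of designing C vs U opposite the
#'   editing site (default c(C = 0.7, U = 0.3)).
#' @param depth_mean,depth_size Negative-binomial read-depth model.
#' @param expr_base_meanlog,expr_base_sdlog Per-gene expression base.
#' @param expr_noise_sdlog Multiplicative expression noise.
#' @return Object of class `edit_cohort`: list with `genes` (per-gene
#'   design, accessibilities and delta), `profiles` (per-individual
#'   expression), matrices `true_editing`, `observed_editing`, `depth`,
#'   `alt`, `expression` (all individuals x genes except `expression`,
#'   genes x individuals), `matrix` (an [editing_matrix()]), `transcripts`
#'   (the synthetic transcripts), and `config`.
#' @export
simulate_cohort <- function(config = population_sim_config(),
                            n_genes = 50L, edited_fraction = 0.8,
                            no_target_fraction = 0.2,
                            distance_range = c(2L, 18L), distance_weight = 3,
                            prevalence_range = c(0.4, 0.9),
                            opposite_probs = c(C = 0.7, U = 0.3),
                            depth_mean = 50, depth_size = 5,
                            expr_base_meanlog = 3, expr_base_sdlog = 0.5,
                            expr_noise_sdlog = 0.1) {
  stopifnot(inherits(config, "population_sim_config"))
  n_genes <- assert_count(n_genes, "n_genes", min = 2L)
  profiles <- generate_population(config)
  n <- nrow(profiles)
  n_edited <- max(1L, round(n_genes * edited_fraction))

  dvals <- distance_range[1L]:distance_range[2L]
  dw <- c(rep(distance_weight, min(5L, length(dvals))),
          rep(0.7, max(0L, length(dvals) - 5L)))

  n_notarget <- round(n_edited * no_target_fraction)
  gene_design <- withr::with_seed(child_seed(config$seed, 1L), {
    data.frame(
      gene = sprintf("gene%03d", seq_len(n_genes)),
      edited = c(rep(TRUE, n_edited), rep(FALSE, n_genes - n_edited)),
      has_target = c(rep(c(TRUE, FALSE), c(n_edited - n_notarget, n_notarget)),
                     rep(TRUE, n_genes - n_edited)),
      distance = sample(dvals, n_genes, TRUE, prob = dw),
      seed_overlap = sample(2:4, n_genes, TRUE),
      opposite = sample(names(opposite_probs), n_genes, TRUE, prob = opposite_probs),
      prevalence = stats::runif(n_genes, prevalence_range[1L], prevalence_range[2L]),
      midpoint = stats::runif(n_genes, config$editing_midpoint[1L],
                              config$editing_midpoint[2L]),
      stringsAsFactors = FALSE
    )
  })

  transcripts <- lapply(seq_len(n_genes), function(g) {
    tx <- generate_hairpin_utr(
      length = 120L, stem_len = gene_design$distance[g] + gene_design$seed_overlap[g] + 5L,
      edit_opposite = gene_design$opposite[g],
      target_distance = gene_design$distance[g],
      seed_overlap = gene_design$seed_overlap[g],
      seed = child_seed(config$seed, 100L + g)
    )
    tx$gene_id <- gene_design$gene[g]
    if (!gene_design$has_target[g]) {
      # scrub the unpaired part of the seed so no match remains
      free <- 7L - gene_design$seed_overlap[g]
      substr(tx$sequence, tx$target_start + 1L, tx$target_start + free) <-
        paste(rep("U", free), collapse = "")
      tx$target_start <- NA_integer_
      tx$target_end <- NA_integer_
    }
    tx
  })

  # fold both alleles of every gene in one engine batch
  seqs <- c(
    stats::setNames(vapply(transcripts, `[[`, character(1), "sequence"),
                    paste0("U", seq_len(n_genes))),
    stats::setNames(vapply(transcripts, edited_sequence, character(1)),
                    paste0("E", seq_len(n_genes)))
  )
  lunp <- plfold_unpaired(seqs)
  acc_at_target <- function(nm, tx) {
    acc <- centered_accessibility(lunp[[nm]])
    centre <- (tx$target_start + tx$target_end + 1L) %/% 2L  # 1-based centre
    acc[centre]
  }
  gene_design$acc_unedited <- vapply(seq_len(n_genes), function(g) {
    if (!gene_design$has_target[g]) return(NA_real_)
    acc_at_target(paste0("U", g), transcripts[[g]])
  }, numeric(1))
  gene_design$acc_edited <- vapply(seq_len(n_genes), function(g) {
    if (!gene_design$has_target[g]) return(NA_real_)
    acc_at_target(paste0("E", g), transcripts[[g]])
  }, numeric(1))
  gene_design$delta <- log2(gene_design$acc_edited / gene_design$acc_unedited)

  # survival uses accessibility relative to the more accessible allele;
  # genes without a target site see no AGO2-miRNA degradation at all
  mx <- pmax(gene_design$acc_unedited, gene_design$acc_edited)
  rel_u <- ifelse(gene_design$has_target, gene_design$acc_unedited / mx, 0)
  rel_e <- ifelse(gene_design$has_target, gene_design$acc_edited / mx, 0)

  withr::with_seed(child_seed(config$seed, 2L), {
    editor <- vapply(seq_len(n_genes), function(g) {
      stats::rbinom(n, 1L, gene_design$prevalence[g])
    }, integer(n))
    e_true <- vapply(seq_len(n_genes), function(g) {
      stats::plogis(config$editing_slope *
                      (log(profiles$adar1) - gene_design$midpoint[g])) *
        config$editing_max
    }, numeric(n))
    e_true <- e_true * editor
    e_true[, !gene_design$edited] <- 0

    s_u <- exp(-config$degradation_k * outer(profiles$ago2 * profiles$mirna, rel_u))
    s_e <- exp(-config$degradation_k * outer(profiles$ago2 * profiles$mirna, rel_e))
    deg <- apply_degradation(e_true, s_u, s_e)
    observed <- matrix(deg$observed, n, n_genes)
    abundance <- matrix(deg$abundance, n, n_genes)

    depth <- matrix(stats::rnbinom(n * n_genes, mu = depth_mean, size = depth_size),
                    n, n_genes)
    err_extra <- matrix(stats::rbinom(n * n_genes, depth,
                                      config$error_rate / 3), n, n_genes)
    alt <- matrix(stats::rbinom(n * n_genes, depth, observed), n, n_genes)
    alt <- pmin(alt + err_extra, depth)   # errors read as G at the site

    base <- exp(stats::rnorm(n_genes, expr_base_meanlog, expr_base_sdlog))
    noise <- matrix(exp(stats::rnorm(n * n_genes, 0, expr_noise_sdlog)), n, n_genes)
    expression <- t(sweep(abundance, 2L, base, `*`) * noise)  # genes x individuals
  })

  dimnames(depth) <- dimnames(alt) <- dimnames(observed) <-
    dimnames(e_true) <- list(profiles$individual, gene_design$gene)
  dimnames(expression) <- list(gene_design$gene, profiles$individual)

  mat <- editing_matrix(t(alt), t(depth), individuals = profiles)
  structure(
    list(genes = gene_design, profiles = profiles, transcripts = transcripts,
         true_editing = e_true, observed_editing = observed,
         depth = depth, alt = alt, expression = expression,
         matrix = mat, config = config),
    class = "edit_cohort"
  )
}

#' @export
print.edit_cohort <- function(x, ...) {
  cat("<edit_cohort> ", nrow(x$profiles), " individuals x ", nrow(x$genes),
      " genes (", sum(x$genes$edited), " with editing sites)\n", sep = "")
  invisible(x)
}

#' Simulate an AGO2 knockdown experiment from a cohort design
#'
#' Re-simulates editing and expression for one reference individual profile
#' under the control condition (the cohort's degradation scale) and under
#' AGO2 knockdown (degradation scale multiplied by `kd_factor`), with
#' `n_replicates` independent read-sampling replicates per condition.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param kd_factor Multiplier on the degradation scale under knockdown
#'   (default 0: complete loss of AGO2-miRNA degradation).
#' @param n_replicates Replicates per condition (default 2).
#' @param ago2,adar1 Expression of the reference cell line (fixed, as for a
#'   clonal line; defaults 1.5 and 1).
#' @param depth_mean Sequencing depth of the knockdown libraries
#'   (default 150).
#' @param seed Integer seed.
#' @return List with matrices `kd_expr`, `ctrl_expr` (genes x replicates),
#'   `kd_edit`, `ctrl_edit` (genes x replicates editing levels, NA where
#'   depth is 0), and the per-gene `true_editing` used.
#' @export
simulate_kd_experiment <- function(cohort, kd_factor = 0, n_replicates = 2L,
                                   ago2 = 1.5, adar1 = 1, depth_mean = 150,
                                   seed = 1L) {
  stopifnot(inherits(cohort, "edit_cohort"))
  gd <- cohort$genes
  cfg <- cohort$config
  mx <- pmax(gd$acc_unedited, gd$acc_edited)
  rel_u <- ifelse(gd$has_target, gd$acc_unedited / mx, 0)
  rel_e <- ifelse(gd$has_target, gd$acc_edited / mx, 0)
  n_genes <- nrow(gd)
  withr::with_seed(seed, {
    e_true <- stats::plogis(cfg$editing_slope * (log(adar1) - gd$midpoint)) *
      cfg$editing_max
    e_true[!gd$edited] <- 0
    one_condition <- function(k) {
      s_u <- exp(-k * ago2 * rel_u)
      s_e <- exp(-k * ago2 * rel_e)
      deg <- apply_degradation(e_true, s_u, s_e)
      reps <- lapply(seq_len(n_replicates), function(r) {
        depth <- stats::rnbinom(n_genes, mu = depth_mean, size = 5)
        alt <- stats::rbinom(n_genes, depth, deg$observed)
        expr <- deg$abundance * exp(stats::rnorm(n_genes, 3, 0.05))
        list(edit = ifelse(depth > 0, alt / depth, NA_real_), expr = expr)
      })
      list(edit = vapply(reps, `[[`, numeric(n_genes), "edit"),
           expr = vapply(reps, `[[`, numeric(n_genes), "expr"))
    }
    ctrl <- one_condition(cfg$degradation_k)
    kd <- one_condition(cfg$degradation_k * kd_factor)
  })
  rn <- gd$gene
  out <- list(kd_expr = kd$expr, ctrl_expr = ctrl$expr,
              kd_edit = kd$edit, ctrl_edit = ctrl$edit,
              true_editing = e_true)
  for (nm in c("kd_expr", "ctrl_expr", "kd_edit", "ctrl_edit")) {
    rownames(out[[nm]]) <- rn
    colnames(out[[nm]]) <- paste0("rep", seq_len(ncol(out[[nm]])))
  }
  out
}
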