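# Pipeline orchestration: run configuration with the published default
# thresholds, the staged synthetic-scenario run, and the summary report.

#' Default run configuration
#'
#' All thresholds default to the published analysis values: LLR 2, depth 10,
#' edited reads 2, editing level 0.1, homopolymer 4 nt, splice distance 4 nt,
#' prevalence cuts 10/90%, differential p 0.01 with level-difference floor
#' 1/15, editing-to-target distance cap 500 nt, accessibility parameters
#' u = 7 / L = 300 / W = 400 with a 1001-nt fold window, and 10-nt distance
#' windows.
#'
#' @param seed Integer seed for the synthetic scenario.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    stages = list(syndata = TRUE, sitecall = TRUE, popstats = TRUE,
                  structacc = TRUE, mirtarget = TRUE),
    thresholds = list(
      llr = 2, depth = 10L, alt = 2L, level = 0.1,
      homopolymer = 4L, splice = 4L,
      prevalence_rare = 10, prevalence_prevalent = 90,
      differential_p = 0.01, differential_delta = 1 / 15,
      distance_cap = 500L,
      accessibility_u = 7L, accessibility_L = 300L, accessibility_W = 400L,
      fold_window = 1001L, distance_window = 10L
    ),
    scenario = list(n_individuals = 60L, n_genes = 24L),
    seed = as.integer(seed)
  ), class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages syndata -> sitecall -> popstats -> structacc ->
#' mirtarget on a packaged synthetic scenario, writing each stage's
#' artifacts into `out_dir` (FASTA transcripts, pileup TSV, BED tracks,
#' VCF-like site calls, TSV summaries) and a machine-readable
#' `summary.json`. Every output carries the configuration hash and seed in
#' its header. A stage failure aborts with the failing stage named; partial
#' outputs are retained.
#'
#' @param config A [default_run_config()]-style list.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  tag <- paste0("config=", hash, " seed=", config$seed)
  summary <- list(config_hash = hash, seed = config$seed, stages = list())
  write_run_config(unclass(config), file.path(out_dir, "run_config.yaml"))

  run_stage <- function(name, fn) {
    if (!isTRUE(config$stages[[name]])) {
      summary$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    summary$stages[[name]] <<- res$summary
    res$value
  }

  # --- syndata ---------------------------------------------------------
  cohort <- run_stage("syndata", function() {
    cfg <- population_sim_config(
      populations = list(POP1 = list(n = config$scenario$n_individuals %/% 2),
                         POP2 = list(n = config$scenario$n_individuals -
                                       config$scenario$n_individuals %/% 2,
                                     adar1 = c(0.5, 0.4))),
      seed = config$seed)
    ch <- simulate_cohort(cfg, n_genes = config$scenario$n_genes)
    write_fasta(stats::setNames(
      vapply(ch$transcripts, `[[`, character(1), "sequence"),
      ch$genes$gene), file.path(out_dir, "transcripts.fa"))
    write_expression_tsv(ch$expression, file.path(out_dir, "expression.tsv"),
                         header = tag)
    tracks <- generate_annotation_tracks(ch$transcripts,
                                         seed = child_seed(config$seed, 9L))
    write_bed(tracks$regions[, c("contig", "start", "end", "type")],
              file.path(out_dir, "regions.bed"), header = tag)
    pile <- cohort_pileup(ch)
    write_pileup_tsv(pile, file.path(out_dir, "pileup.tsv"), header = tag)
    list(value = list(cohort = ch, tracks = tracks, pileup = pile),
         summary = list(status = "ok", individuals = nrow(ch$profiles),
                        genes = nrow(ch$genes)))
  })

  # --- sitecall --------------------------------------------------------
  calls <- run_stage("sitecall", function() {
    if (is.null(cohort)) stop("no input: syndata stage disabled and no pileup given")
    filtered <- filter_sites(cohort$pileup, cohort$tracks,
                             thresholds = config$thresholds)
    filtered$context <- classify_context(filtered, cohort$tracks)
    write_sites_vcf(filtered, file.path(out_dir, "sites.vcf"), header = tag)
    retained <- filtered[filtered$retained, , drop = FALSE]
    if (nrow(retained) > 0L) {
      write_bed(data.frame(contig = retained$gene, start = retained$pos0,
                           end = retained$pos0 + 1L, name = "edit",
                           score = 0L, strand = retained$strand),
                file.path(out_dir, "sites.bed"), header = tag)
    }
    unique_sites <- filtered[!duplicated(paste(filtered$gene, filtered$pos0)), ]
    list(value = filtered,
         summary = list(status = "ok", candidates = nrow(filtered),
                        retained = sum(filtered$retained),
                        a2g = a2g_fraction(unique_sites),
                        context = as.list(table(filtered$context[filtered$retained]))))
  })

  # --- popstats --------------------------------------------------------
  pops <- run_stage("popstats", function() {
    ch <- cohort$cohort
    prev <- prevalence(ch$matrix)
    utils::write.table(prev, file.path(out_dir, "prevalence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pop_sites <- select_population_sites(ch$matrix)
    idx_a <- ch$profiles$population == "POP1"
    idx_b <- ch$profiles$population == "POP2"
    diff <- lapply(pop_sites, function(s) {
      differential_editing(ch$matrix, s, which(idx_a), which(idx_b),
                           p_max = config$thresholds$differential_p,
                           delta_min = config$thresholds$differential_delta)
    })
    ndiff <- sum(vapply(diff, function(d) isTRUE(d$is_differential), logical(1)))
    list(value = list(prevalence = prev, selected = pop_sites, n_differential = ndiff),
         summary = list(status = "ok", selected_sites = length(pop_sites),
                        differential = ndiff,
                        prevalence_classes = as.list(table(prev$class))))
  })

  # --- structacc -------------------------------------------------------
  struct <- run_stage("structacc", function() {
    ch <- cohort$cohort
    edited <- which(ch$genes$edited)
    delta_near <- vapply(edited, function(g) {
      tx <- ch$transcripts[[g]]
      fw <- fold_window(tx$sequence, tx$edit_pos,
                        window = config$thresholds$fold_window,
                        u = config$thresholds$accessibility_u,
                        L = config$thresholds$accessibility_L,
                        W = config$thresholds$accessibility_W)
      ra <- relative_accessibility(fw$unedited, fw$edited, fw$site_in_window,
                                   max_offset = 10L)
      mean(ra$log2_ratio, na.rm = TRUE)
    }, numeric(1))
    utils::write.table(
      data.frame(gene = ch$genes$gene[edited], mean_delta_pm10 = delta_near),
      file.path(out_dir, "accessibility_delta.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    list(value = delta_near,
         summary = list(status = "ok",
                        mean_delta_pm10 = mean(delta_near),
                        negative_fraction = mean(delta_near < 0)))
  })

  # --- mirtarget -------------------------------------------------------
  run_stage("mirtarget", function() {
    ch <- cohort$cohort
    ed <- which(ch$genes$edited)
    meanobs <- rowMeans(ch$matrix$level[ed, , drop = FALSE] |> t(), na.rm = TRUE)
    r_ago2 <- stats::cor(ch$profiles$ago2, meanobs, use = "complete.obs")
    ratio <- cohort_expression_ratio(ch)
    acorr <- accessibility_expression_correlation(
      ch$genes$delta[ed], ratio, ch$genes$distance[ed],
      window = config$thresholds$distance_window)
    utils::write.table(
      data.frame(gene = ch$genes$gene[ed], distance = ch$genes$distance[ed],
                 delta = ch$genes$delta[ed], log2_ratio = ratio),
      file.path(out_dir, "target_contrasts.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    list(value = NULL,
         summary = list(status = "ok", ago2_editing_r = r_ago2,
                        accessibility_expression_r = acorr$r))
  })

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(out_dir, "summary.json"))
  invisible(summary)
}

# pileup rows for every edited gene x individual in a cohort, plus a small
# complement of sequencing-error sites of non-A-to-G mismatch types
cohort_pileup <- function(cohort, error_site_fraction = 0.11) {
  ed <- which(cohort$genes$edited)
  rows <- lapply(ed, function(g) {
    tx <- cohort$transcripts[[g]]
    do.call(rbind, lapply(seq_len(nrow(cohort$profiles)), function(i) {
      d <- cohort$depth[i, g]
      obs <- simulate_pileup(
        observed = cohort$observed_editing[i, g], depth = d,
        error_rate = cohort$config$error_rate,
        gene = cohort$genes$gene[g], pos = tx$edit_pos,
        seed = child_seed(cohort$config$seed, g * 10000L + i))
      obs$individual <- cohort$profiles$individual[i]
      obs
    }))
  })
  n_err <- ceiling(error_site_fraction * length(ed))
  err_rows <- withr::with_seed(child_seed(cohort$config$seed, 777L), {
    lapply(seq_len(n_err), function(j) {
      g <- sample(ed, 1L)
      tx <- cohort$transcripts[[g]]
      pos <- sample(setdiff(seq_len(nchar(tx$sequence)) - 1L, tx$edit_pos), 1L)
      ref <- substr(tx$sequence, pos + 1L, pos + 1L)
      alt <- sample(setdiff(RNA_BASES, c(ref, if (ref == "A") "G")), 1L)
      ind <- sample(nrow(cohort$profiles), 1L)
      depth <- stats::rnbinom(1L, mu = 20, size = 5) + 1L
      alt_count <- min(depth, 1L + stats::rbinom(1L, 2L, 0.5))
      quals <- pmax(2L, round(stats::rnorm(alt_count, 12, 3)))
      obs <- new_mismatch_observation(cohort$genes$gene[g], pos, "+", ref, alt,
                                      depth, alt_count, 0L, quals,
                                      sample.int(100L, alt_count, TRUE))
      obs$individual <- cohort$profiles$individual[ind]
      obs
    })
  })
  do.call(rbind, c(rows, err_rows))
}

# per-gene log2 expression ratio: edited (level >= 0.3) over unedited
# (no edited reads) individuals, >= 3 individuals per side, mean
# expression >= min_expr
cohort_expression_ratio <- function(cohort, level_min = 0.3, min_expr = 0.1,
                                    min_n = 3L) {
  ed <- which(cohort$genes$edited)
  lev <- ifelse(cohort$depth > 0, cohort$alt / cohort$depth, NA_real_)
  vapply(ed, function(g) {
    expr <- cohort$expression[g, ]
    if (mean(expr) < min_expr) return(NA_real_)
    hi <- !is.na(lev[, g]) & lev[, g] >= level_min
    lo <- cohort$alt[, g] == 0L & cohort$depth[, g] > 0L
    if (sum(hi) < min_n || sum(lo) < min_n) return(NA_real_)
    log2(mean(expr[hi]) / mean(expr[lo]))
  }, numeric(1))
}

#' Human-readable report of a pipeline run
#'
#' Tabulates each analysis performed on the synthetic scenario with its
#' headline statistic and direction check; disabled stages are marked
#' skipped. Regeneration from the same run directory is idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
summary_report <- function(run_dir) {
  path <- file.path(run_dir, "summary.json")
  if (!file.exists(path)) stop("no summary.json in '", run_dir, "'")
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fmt <- function(x, digits = 3) {
    if (is.null(x) || length(x) == 0) return("NA")
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) "NA" else as.character(round(v, digits))
  }
  lines <- c(
    sprintf("editing pipeline run %s (seed %s)", s$config_hash, s$seed),
    "----------------------------------------------------------------")
  st <- s$stages
  stage_line <- function(name, detail) {
    status <- if (is.null(st[[name]])) "absent" else st[[name]]$status
    if (identical(status, "skipped")) return(sprintf("%-10s skipped", name))
    sprintf("%-10s %s", name, detail)
  }
  lines <- c(lines,
    stage_line("syndata", sprintf("%s individuals x %s genes simulated",
                                  st$syndata$individuals, st$syndata$genes)),
    stage_line("sitecall", sprintf(
      "%s/%s candidate sites retained; A-to-G fraction %s",
      st$sitecall$retained, st$sitecall$candidates, fmt(st$sitecall$a2g))),
    stage_line("popstats", sprintf(
      "%s population sites selected; %s differential between populations",
      st$popstats$selected_sites, st$popstats$differential)),
    stage_line("structacc", sprintf(
      "mean log2 accessibility change (+/-10 nt) %s; %s%% of sites negative",
      fmt(st$structacc$mean_delta_pm10),
      fmt(100 * as.numeric(st$structacc$negative_fraction), 1))),
    stage_line("mirtarget", sprintf(
      "AGO2 vs mean editing r = %s; accessibility-expression r = %s",
      fmt(st$mirtarget$ago2_editing_r), fmt(st$mirtarget$accessibility_expression_r)))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
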