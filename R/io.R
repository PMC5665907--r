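# File-format dialects: FASTA (via Biostrings), BED (0-based half-open),
# pileup and expression TSV, VCF-like site tables (1-based), dot-bracket
# structure files, and YAML run configuration. Readers reject malformed
# lines with their line numbers; CRLF input is accepted and normalised.

read_lines_normalised <- function(path) {
  x <- readLines(path, warn = FALSE)
  sub("\r$", "", x)
}

#' Read/write FASTA
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write BED intervals (0-based, half-open)
#'
#' Tracks with fewer than 3 columns, non-integer coordinates or end < start
#' are rejected with the offending line number. Strand, when present, is
#' column 6.
#'
#' @param path File path.
#' @return Data frame with `contig`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- read_lines_normalised(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
  bad <- is.na(start) | is.na(end) | end < start
  if (any(bad)) stop("malformed BED line ", which(bad)[1L], ": bad coordinates")
  out <- data.frame(contig = vapply(parts, `[`, character(1), 1L),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- vapply(parts, `[`, character(1), 4L)
  if (all(nf >= 5L)) out$score <- vapply(parts, `[`, character(1), 5L)
  if (all(nf >= 6L)) out$strand <- vapply(parts, `[`, character(1), 6L)
  out
}

#' @rdname read_bed
#' @param intervals Data frame with `contig`, `start`, `end`, optionally
#'   `name`, `score`, `strand`.
#' @param header Optional comment lines written at the top.
#' @export
write_bed <- function(intervals, path, header = NULL) {
  cols <- c("contig", "start", "end")
  extra <- intersect(c("name", "score", "strand"), names(intervals))
  # strand requires the name and score placeholders
  if ("strand" %in% extra) {
    if (!"name" %in% extra) intervals$name <- "."
    if (!"score" %in% extra) intervals$score <- 0L
    extra <- c("name", "score", "strand")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(intervals) > 0L) {
    utils::write.table(intervals[, c(cols, extra), drop = FALSE], con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

PILEUP_COLUMNS <- c("gene", "pos0", "strand", "ref", "alt", "depth",
                    "alt_count", "quals", "read_pos")

#' Read/write pileup-style mismatch tables
#'
#' Tab-separated with header; columns `gene`, `pos0` (0-based), `strand`,
#' `ref`, `alt`, `depth`, `alt_count`, `quals` (comma-joined Phred),
#' `read_pos` (comma-joined within-read offsets). Extra columns are kept.
#'
#' @param path File path.
#' @return Data frame of mismatch observations.
#' @export
read_pileup_tsv <- function(path) {
  lines <- read_lines_normalised(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 1L) stop("empty pileup table")
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = NA,
                           quote = "")
  missing <- setdiff(PILEUP_COLUMNS, names(tab))
  if (length(missing) > 0L) {
    stop("pileup table lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(tab$alt_count > tab$depth | tab$depth < 0)
  if (length(bad) > 0L) {
    stop("malformed pileup line ", bad[1L] + 1L, ": alt_count > depth")
  }
  tab$quals <- as.character(tab$quals)
  tab$read_pos <- as.character(tab$read_pos)
  tab
}

#' @rdname read_pileup_tsv
#' @param observations Data frame of mismatch observations.
#' @param header Optional comment lines (e.g. seed provenance).
#' @export
write_pileup_tsv <- function(observations, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  cols <- intersect(c(PILEUP_COLUMNS, setdiff(names(observations), PILEUP_COLUMNS)),
                    names(observations))
  utils::write.table(observations[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a VCF-like site table
#'
#' 1-based positions (POS = pos0 + 1), REF/ALT in DNA alphabet, INFO with
#' depth, alt count, level, LLR, context and rejection reasons.
#'
#' @param sites Data frame as returned by [filter_sites()], optionally with
#'   a `context` column.
#' @param path Output path.
#' @param header Extra header lines.
#' @return The path, invisibly.
#' @export
write_sites_vcf <- function(sites, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(header)) writeLines(paste0("##", header), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(sites) > 0L) {
    to_dna <- function(x) chartr("U", "T", toupper(x))
    info <- sprintf("DP=%d;ALT=%d;LEVEL=%.4g;LLR=%.4g%s%s",
                    sites$depth, sites$alt_count,
                    ifelse(sites$depth > 0, sites$alt_count / sites$depth, 0),
                    sites$llr,
                    if (!is.null(sites$context)) paste0(";CTX=", sites$context) else "",
                    ifelse(nzchar(sites$fails), paste0(";FAILS=", sites$fails), ""))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s",
                       sites$gene, sites$pos0 + 1L,
                       paste0(sites$gene, ":", sites$pos0 + 1L),
                       to_dna(sites$ref), to_dna(sites$alt),
                       ifelse(sites$retained, "PASS", sites$first_fail),
                       info), con)
  }
  invisible(path)
}

#' Read/write expression matrices (genes x samples TSV)
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE, comment.char = "#")
  as.matrix(tab)
}

#' @rdname read_expression_tsv
#' @param mat Numeric matrix, genes in rows.
#' @param header Optional comment lines.
#' @export
write_expression_tsv <- function(mat, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write structures in Vienna dot-bracket format
#'
#' @param folds Named list of [fold_result()]s.
#' @param path Output path.
#' @export
write_dotbracket <- function(folds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(folds)) {
    f <- folds[[nm]]
    writeLines(c(paste0(">", nm), f$sequence,
                 sprintf("%s (%.2f)", f$structure, f$mfe)), con)
  }
  invisible(path)
}

#' Read a dot-bracket file
#'
#' @param path File path.
#' @return Named list of [fold_result()]s (without accessibilities).
#' @export
read_dotbracket <- function(path) {
  lines <- read_lines_normalised(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no records in dot-bracket file")
  out <- lapply(hdr, function(i) {
    if (i + 2L > length(lines)) stop("truncated record at line ", i)
    m <- regexec("^([().]+)(?: +\\( *(-?[0-9.]+)\\))?", lines[i + 2L])[[1L]]
    parts <- regmatches(lines[i + 2L], list(m))[[1L]]
    if (length(parts) < 2L) stop("malformed structure at line ", i + 2L)
    fold_result(lines[i + 1L], parts[2L],
                mfe = if (length(parts) >= 3L && nzchar(parts[3L]))
                  as.numeric(parts[3L]) else NA_real_)
  })
  names(out) <- sub("^>", "", lines[hdr])
  out
}

#' Read/write a run configuration (YAML)
#'
#' @param path File path.
#' @return `read_run_config`: a run-config list (see [default_run_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @param config Run-config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}
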