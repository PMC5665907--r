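# Interface to the ViennaRNA command-line folding engine.
#
# Two primitives are used throughout: minimum free energy (MFE) structures
# from RNAfold, and windowed unpaired probabilities from RNAplfold
# (probability that an l-mer is entirely single-stranded in the ensemble).
# A base-pair-maximisation fallback (`fold_maxpair`) exists for pair-table
# unit tests only; it never substitutes for partition-function accessibility.

vienna_available <- function() {
  nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAplfold"))
}

check_vienna <- function() {
  if (!vienna_available()) {
    stop("ViennaRNA executables (RNAfold, RNAplfold) not found on the PATH")
  }
}

#' Parse a dot-bracket string into a pair table
#'
#' @param db Dot-bracket string in Vienna notation (only `(`, `)`, `.`).
#' @return Integer vector, one element per position (1-based); the partner
#'   position, or `NA` for unpaired positions. Involutive by construction.
#' @export
pair_table <- function(db) {
  ch <- split_bases(db)
  if (any(!ch %in% c("(", ")", "."))) {
    stop("dot-bracket string contains characters other than '(', ')', '.'")
  }
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string: unmatched '('")
  pt
}

#' Minimum free energy structure via RNAfold
#'
#' @param sequences Named character vector of RNA sequences.
#' @return Data frame with columns `name`, `sequence`, `structure`
#'   (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold_mfe <- function(sequences) {
  check_vienna()
  sequences <- as_rna(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  input <- paste0(">", names(sequences), "\n", sequences, collapse = "\n")
  out <- system2("RNAfold", c("--noPS"), input = input, stdout = TRUE, stderr = FALSE)
  if (!is.null(attr(out, "status"))) stop("RNAfold failed with status ", attr(out, "status"))
  hdr <- grep("^>", out)
  struct_lines <- out[hdr + 2L]
  m <- regmatches(struct_lines, regexec("^([().]+) +\\( *(-?[0-9.]+)\\)", struct_lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("could not parse RNAfold output for: ",
                     paste(sub("^>", "", out[hdr][bad]), collapse = ", "))
  data.frame(
    name = sub("^>", "", out[hdr]),
    sequence = unname(sequences),
    structure = vapply(m, `[`, character(1), 2L),
    mfe = as.numeric(vapply(m, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

#' Windowed unpaired probabilities via RNAplfold
#'
#' Runs RNAplfold with window parameters `W` (folding window), `L` (maximum
#' base-pair span) and `u` (length of the single-stranded stretch scored).
#'
#' @param sequences Named character vector of RNA sequences.
#' @param u Length of the unpaired stretch (default 7).
#' @param L Maximum base-pair span (default 300).
#' @param W Folding window size (default 400).
#' @return Named list; per sequence a numeric matrix with one row per
#'   position `i` and columns `l = 1..u` holding the probability that the
#'   l-mer ending at `i` is entirely unpaired (`NA` where no full l-mer fits).
#' @export
plfold_unpaired <- function(sequences, u = 7L, L = 300L, W = 400L) {
  check_vienna()
  sequences <- as_rna(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (any(grepl("[^A-Za-z0-9_.-]", names(sequences)))) {
    stop("sequence names must be alphanumeric for RNAplfold output files")
  }
  dir <- tempfile("plfold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fa <- file.path(dir, "input.fa")
  writeLines(paste0(">", names(sequences), "\n", sequences), fa)
  owd <- setwd(dir)
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  status <- system2("RNAplfold", c("-u", u, "-L", L, "-W", W),
                    stdin = fa, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("RNAplfold failed with status ", status)
  res <- lapply(names(sequences), function(nm) {
    f <- paste0(nm, "_lunp")
    if (!file.exists(f)) stop("RNAplfold produced no output for sequence '", nm, "'")
    m <- utils::read.table(f, skip = 2L, row.names = 1L)
    m <- as.matrix(m)
    colnames(m) <- as.character(seq_len(ncol(m)))
    m
  })
  names(res) <- names(sequences)
  res
}

# accessibility of the u-mer centred at 1-based position p:
# the u-mer spans p - floor(u/2) .. p + floor(u/2) and ends at p + floor(u/2)
centered_accessibility <- function(lunp, u = 7L) {
  n <- nrow(lunp)
  half <- u %/% 2L
  acc <- rep(NA_real_, n)
  idx <- seq_len(n)
  ends <- idx + half
  ok <- ends <= n & idx - half >= 1L
  acc[ok] <- lunp[ends[ok], as.character(u)]
  acc
}

#' Fold result container
#'
#' Bundles the sequence, MFE dot-bracket structure, pair table, and
#' per-position centred 7-mer accessibilities for one folded window.
#'
#' @param sequence RNA sequence.
#' @param structure Dot-bracket string.
#' @param accessibility Numeric vector of centred u-mer unpaired
#'   probabilities (NA where no full u-mer fits).
#' @param mfe Minimum free energy in kcal/mol.
#' @param window 1-based `[start, end]` of this window on the source
#'   sequence, if windowed.
#' @return Object of class `fold_result`.
#' @export
fold_result <- function(sequence, structure, accessibility = NULL, mfe = NA_real_,
                        window = NULL) {
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence and structure lengths differ")
  }
  pt <- pair_table(structure)
  if (!is.null(accessibility) && length(accessibility) != nchar(sequence)) {
    stop("accessibility vector length does not match the sequence")
  }
  structure(
    list(sequence = sequence, structure = structure, pairs = pt,
         accessibility = accessibility, mfe = mfe, window = window),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> ", nchar(x$sequence), " nt, MFE ", x$mfe, " kcal/mol\n", sep = "")
  cat(" paired positions: ", sum(!is.na(x$pairs)), "\n", sep = "")
  invisible(x)
}

#' Base-pair maximisation fold (test fallback)
#'
#' A Nussinov-style dynamic program maximising Watson-Crick/wobble pairs with
#' a minimum hairpin loop of 3 nt. Used only to exercise pair-table code in
#' unit tests; thermodynamic analyses always go through the ViennaRNA engine.
#'
#' @param sequence RNA sequence.
#' @return Dot-bracket string of one maximal-pairing structure.
#' @export
fold_maxpair <- function(sequence) {
  s <- split_bases(as_rna(sequence))
  n <- length(s)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  if (n < 5L) return(paste(rep(".", n), collapse = ""))
  dp <- matrix(0L, n, n)
  for (span in 4:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i, j - 1L]
      for (k in i:(j - 4L)) {
        if (can_pair(s[k], s[j])) {
          left <- if (k > i) dp[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) dp[k + 1L, j - 1L] else 0L
          best <- max(best, left + inner + 1L)
        }
      }
      dp[i, j] <- best
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    while (i < j) {
      if (dp[i, j] == (if (j - 1L >= i) dp[i, j - 1L] else 0L)) {
        j <- j - 1L
        next
      }
      done <- FALSE
      for (k in i:(j - 4L)) {
        if (can_pair(s[k], s[j])) {
          left <- if (k > i) dp[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) dp[k + 1L, j - 1L] else 0L
          if (dp[i, j] == left + inner + 1L) {
            db[k] <- "("
            db[j] <- ")"
            if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
            i <- k + 1L
            j <- j - 1L
            done <- TRUE
            break
          }
        }
      }
      if (!done) break
    }
  }
  paste(db, collapse = "")
}
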