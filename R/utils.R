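# Small shared helpers: RNA alphabet handling, seeded sampling, argument checks.

RNA_BASES <- c("A", "C", "G", "U")

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of RNA sequences (A/C/G/U).
#' @return Character vector of reverse complements.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGUacgu", "UGCAugca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Normalise a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and converts T to U; rejects characters outside A/C/G/U/N.
#'
#' @param x Character vector of sequences.
#' @param allow_n Allow the ambiguity code N.
#' @return Character vector in the RNA alphabet.
#' @export
as_rna <- function(x, allow_n = FALSE) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  pat <- if (allow_n) "^[ACGUN]*$" else "^[ACGU]*$"
  bad <- !grepl(pat, out)
  if (any(bad)) {
    stop("sequence contains characters outside the RNA alphabet: ",
         paste(utils::head(unique(x[bad]), 3), collapse = ", "))
  }
  out
}

split_bases <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# stopifnot-style scalar checks with readable messages
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("'", name, "' must be a single number")
  }
  if (x < lower || x > upper) {
    stop("'", name, "' must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop("'", name, "' must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

# derive a reproducible child seed; kept below 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

# homopolymer runs in a sequence; returns 0-based half-open intervals
homopolymer_runs <- function(sequence, min_len = 2L) {
  b <- split_bases(sequence)
  if (length(b) == 0L) {
    return(data.frame(start = integer(), end = integer(), base = character(),
                      stringsAsFactors = FALSE))
  }
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep], base = r$values[keep],
             stringsAsFactors = FALSE)
}
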