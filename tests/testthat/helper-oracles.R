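# Independent brute-force oracles used to cross-check the implementation.
# These are written from first principles and never call the package code
# they verify.

# two-sided rank-sum p by exhaustive enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(r) + 1) / 2
  combos <- utils::combn(length(r), n1)
  stats <- apply(combos, 2L, function(ix) sum(r[ix]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# upper-tail hypergeometric P(X >= ov) by summing point masses
oracle_hyper_upper <- function(ov, nA, nB, N) {
  ks <- max(0L, nA + nB - N):min(nA, nB)
  pm <- choose(nA, ks) * choose(N - nA, nB - ks) / choose(N, nB)
  sum(pm[ks >= ov])
}

# two-sided Fisher exact p for a 2x2 table by enumerating the support and
# summing point masses not exceeding the observed one
oracle_fisher_p <- function(a, b, c, d) {
  rowtot <- a + b
  coltot <- a + c
  N <- a + b + c + d
  ks <- max(0L, rowtot + coltot - N):min(rowtot, coltot)
  lpm <- lchoose(coltot, ks) + lchoose(N - coltot, rowtot - ks) -
    lchoose(N, rowtot)
  pm <- exp(lpm)
  p_obs <- exp(lchoose(coltot, a) + lchoose(N - coltot, rowtot - a) -
                 lchoose(N, rowtot))
  sum(pm[pm <= p_obs * (1 + 1e-7)])
}

# scan every substring of the UTR against the seed definitions
oracle_seed_scan <- function(utr, mirna) {
  rc <- function(s) chartr("ACGU", "UGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  m8 <- rc(substr(mirna, 2, 8))
  a1 <- paste0(rc(substr(mirna, 2, 7)), "A")
  mer8 <- paste0(m8, "A")
  n <- nchar(utr)
  hits <- list()
  for (i in seq_len(n)) {
    if (i + 7 <= n && substr(utr, i, i + 7) == mer8) {
      hits[[length(hits) + 1]] <- data.frame(start = i - 1L, end = i + 7L,
                                             site_type = "8mer")
    }
  }
  starts8 <- vapply(hits, function(h) h$start, integer(1))
  for (i in seq_len(n)) {
    if (i + 6 <= n && substr(utr, i, i + 6) == m8 && !((i - 1L) %in% starts8)) {
      hits[[length(hits) + 1]] <- data.frame(start = i - 1L, end = i + 6L,
                                             site_type = "7mer-m8")
    }
    if (i + 6 <= n && substr(utr, i, i + 6) == a1 && !((i - 2L) %in% starts8)) {
      hits[[length(hits) + 1]] <- data.frame(start = i - 1L, end = i + 6L,
                                             site_type = "7mer-A1")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$site_type), , drop = FALSE]
}

# per-record re-check of all eight filter predicates, written independently
oracle_site_pass <- function(rec, ann, llr) {
  level <- if (rec$depth > 0) rec$alt_count / rec$depth else 0
  at_snp <- any(ann$snps$contig == rec$gene & ann$snps$pos0 == rec$pos0)
  in_rep <- any(ann$repeats$contig == rec$gene &
                  ann$repeats$start <= rec$pos0 & rec$pos0 < ann$repeats$end)
  hp <- ann$homopolymers
  in_hp <- any(hp$contig == rec$gene & (hp$end - hp$start) > 4 &
                 hp$start <= rec$pos0 & rec$pos0 < hp$end)
  reg <- ann$regions
  in_intron <- any(reg$contig == rec$gene & reg$type == "intron" &
                     reg$start <= rec$pos0 & rec$pos0 < reg$end)
  near_sj <- any(ann$splice$contig == rec$gene &
                   abs(ann$splice$pos0 - rec$pos0) <= 4)
  llr >= 2 && rec$depth >= 10 && rec$alt_count >= 2 && level >= 0.1 &&
    !at_snp && !in_rep && !in_hp && !(in_intron && near_sj)
}

# grid-search evaluation of the two likelihood models underlying the LLR
oracle_llr <- function(quals, depth) {
  p_err <- 10^(-quals / 10)
  n_ref <- depth - length(quals)
  f_grid <- seq(0, 1 - 1e-9, length.out = 20001)
  ll <- vapply(f_grid, function(f) {
    sum(log(f + (1 - f) * p_err)) + n_ref * log1p(-f)
  }, numeric(1))
  (max(ll) - ll[1]) / log(10)
}

# opposite-base rule evaluated directly from a dot-bracket string
oracle_opposite <- function(seq, db, site0) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  st <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") st <- c(st, i)
    if (ch[i] == ")") { pt[i] <- st[length(st)]; pt[st[length(st)]] <- i; st <- st[-length(st)] }
  }
  s <- strsplit(seq, "")[[1]]
  i <- site0 + 1L
  base_at <- function(j) if (!is.na(j) && j >= 1 && j <= n) s[j] else "N"
  if (!is.na(pt[i])) return(base_at(pt[i]))
  if (i > 1 && !is.na(pt[i - 1])) return(base_at(pt[i - 1] - 1L))
  if (i < n && !is.na(pt[i + 1])) return(base_at(pt[i + 1] + 1L))
  "N"
}

# random mismatch records spanning all the rule boundaries
random_filter_records <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(
      gene = sample(c("gA", "gB"), n, TRUE),
      pos0 = sample(0:199, n, TRUE),
      strand = "+",
      ref = "A", alt = "G",
      depth = sample(c(0, 5, 9, 10, 11, 15, 30, 100), n, TRUE),
      alt_count = 0L,
      other_count = 0L,
      quals = "",
      read_pos = "",
      untestable = FALSE,
      stringsAsFactors = FALSE
    ) -> rec
    rec$alt_count <- vapply(rec$depth, function(d) {
      if (d == 0) 0L else sample(0:min(d, 12), 1L)
    }, integer(1))
    rec$quals <- vapply(rec$alt_count, function(a) {
      if (a == 0) "" else paste(sample(c(3, 10, 20, 30, 40), a, TRUE), collapse = ",")
    }, character(1))
    rec
  }) -> rec
  rec
}

# annotation set exercising every exclusion rule on two 200-nt contigs
filter_test_annotations <- function() {
  annotation_set(
    regions = data.frame(
      contig = c("gA", "gA", "gB", "gB"),
      start = c(0L, 120L, 0L, 100L),
      end = c(120L, 200L, 100L, 200L),
      type = c("UTR3", "intron", "UTR3", "intron"),
      strand = "+", stringsAsFactors = FALSE),
    snps = data.frame(contig = c("gA", "gB"), pos0 = c(17L, 55L),
                      stringsAsFactors = FALSE),
    repeats = data.frame(contig = "gA", start = 40L, end = 56L,
                         stringsAsFactors = FALSE),
    homopolymers = data.frame(contig = c("gA", "gB", "gB"),
                              start = c(70L, 10L, 150L),
                              end = c(75L, 14L, 157L),
                              base = c("A", "C", "U"),
                              stringsAsFactors = FALSE),
    splice = data.frame(contig = c("gA", "gB"), pos0 = c(120L, 100L),
                        stringsAsFactors = FALSE)
  )
}
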