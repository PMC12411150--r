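# Shared fixtures: toy genomes and independent oracles. Oracles are kept
# deliberately naive (explicit loops, base-R statistics) so they stay
# independent of the package's own code paths.

toy_genome <- function(n_chrom = 2, len = 3e7, cent = len / 2) {
  genome_definition(paste0("chr", seq_len(n_chrom)),
                    rep(len, n_chrom), rep(cent, n_chrom))
}

toy_grid <- function(n_chrom = 2, len = 3e7, bin = 2e5, cent = len / 2) {
  make_bins(toy_genome(n_chrom, len, cent), bin)
}

# Exhaustive O(n^2) arc search computing each two-sample t directly with
# mean()/var() on explicit index sets.
oracle_best_arc <- function(x, minseg = 3L) {
  n <- length(x)
  best <- list(i = NA, j = NA, t = -1)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k < minseg || (n - k) < minseg) next
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      ssw <- sum((arc - mean(arc))^2) + sum((rest - mean(rest))^2)
      d <- mean(arc) - mean(rest)
      sst <- sum((x - mean(x))^2)
      t <- if (n - 2 <= 0 || ssw <= 1e-9 * (sst + 1e-100)) {
        if (abs(d) > 1e-9 * (max(abs(x - mean(x))) + 1e-100)) Inf else 0
      } else {
        abs(d) / sqrt((ssw / (n - 2)) * (1 / k + 1 / (n - k)))
      }
      if (t > best$t) best <- list(i = i, j = j, t = t)
    }
  }
  best
}

# Naive ungapped mismatch scan, forward and reverse complement.
oracle_read_matches <- function(read, ref, max_mm) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  scan1 <- function(rd, rf) {
    m <- nchar(rd); n <- nchar(rf)
    if (m > n) return(FALSE)
    rdv <- strsplit(rd, "")[[1]]
    rfv <- strsplit(rf, "")[[1]]
    ok_base <- rdv %in% c("A", "C", "G", "T")
    for (s in 0:(n - m)) {
      mm <- sum(!(ok_base & rdv == rfv[(s + 1):(s + m)]))
      if (mm <= max_mm) return(TRUE)
    }
    FALSE
  }
  scan1(read, ref) || scan1(rc(read), ref)
}

# Textbook chi-square: expected from margins, sum((O-E)^2/E).
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
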