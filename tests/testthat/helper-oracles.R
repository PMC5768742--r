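# Shared fixture builders and independent brute-force oracles.

# Uniform-fragment map: n fragments of `width` bp on one or more chromosomes.
uniform_fragments <- function(n, width = 100, chroms = "c1") {
  per <- ceiling(n / length(chroms))
  df <- do.call(rbind, lapply(chroms, function(cc) {
    k <- min(per, n - (match(cc, chroms) - 1) * per)
    data.frame(chrom = cc, start = (seq_len(k) - 1) * width,
               end = seq_len(k) * width)
  }))
  fragment_map(df$chrom, df$start, df$end)
}

# Contact matrix from a dense symmetric matrix over a uniform fragment map.
dense_cm <- function(M, width = 100, chroms = "c1") {
  fr <- uniform_fragments(nrow(M), width, chroms)
  ax <- fragment_axis(fr)
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_matrix(idx[, 1], idx[, 2], M[idx], ax)
}

# Random dense symmetric non-negative matrix.
random_sym <- function(n, lambda = 5) {
  M <- matrix(rpois(n * n, lambda), n)
  M <- M + t(M)
  diag(M) <- rpois(n, lambda)
  M
}

# O(n^4) brute-force quality table: q[k, d] for interval [k, k+d]
# (off-diagonal pairs only, matching the interval-density definition).
brute_quality <- function(M, gamma) {
  n <- nrow(M)
  q <- matrix(NA_real_, n, n - 1)
  for (k in seq_len(n - 1)) for (l in (k + 1):n) {
    s <- 0
    for (a in k:(l - 1)) for (b in (a + 1):l) s <- s + M[a, b]
    q[k, l - k] <- s / (l - k)^gamma
  }
  q
}

# Exhaustive enumeration of all valid segmentations (domains of at least
# `minb` bins, gaps allowed); returns the maximal objective for a score
# matrix sc[k, d] where intervals with sc <= 0 are never chosen.
brute_best_segmentation <- function(sc, minb) {
  n <- nrow(sc)
  rec <- function(pos) {
    if (pos > n) return(0)
    best <- rec(pos + 1)                       # leave pos unassigned
    ends <- seq.int(pos + minb - 1, n)
    ends <- ends[ends <= n & ends > pos]
    for (e in ends) {
      v <- sc[pos, e - pos]
      if (!is.na(v) && v > 0) best <- max(best, v + rec(e + 1))
    }
    best
  }
  rec(1)
}

# Score matrix that call_domains_dp optimises for a given config.
dp_score_matrix <- function(cm, config) {
  qt <- domain_quality(cm, config$gamma, max_span = config$max_span_bins)
  if (config$centering == "mean") qt$qprime else qt$q
}

# Small synthetic design for fast tests.
small_design <- function(genome_mb = 1.5, depth = 3e6, seed = 1, ...) {
  synthetic_design(genome = genome_layout("chrT", genome_mb * 1e6),
                   depth = depth, seed = seed, ...)
}

# Boundary recovery of called cuts against planted cuts, in fragments.
cut_recovery <- function(called_domains, planted_domains, tol_frag = 1) {
  called <- sort(unique(c(called_domains$start_bin,
                          called_domains$end_bin + 1L)))
  planted <- sort(unique(c(planted_domains$start_bin,
                           planted_domains$end_bin + 1L)))
  mean(vapply(planted, function(b) any(abs(called - b) <= tol_frag),
              logical(1)))
}
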