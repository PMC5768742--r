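#' Expected contact count by genomic distance
#'
#' For each chromosome, the mean (balanced) contact count over all unmasked
#' fragment pairs whose midpoint separation falls in a fixed-width distance
#' bin. Pairs with zero observed contacts contribute zeros to the mean.
#' Bins without any pair are flagged (NA mean).
#'
#' @param mat a [contact_matrix()] (balanced counts are used when a bias is
#'   present).
#' @param binwidth distance bin width in bp (default 200).
#' @param max_distance largest separation considered, in bp (default 500
#'   kb); pairs beyond it are ignored.
#' @return An `expected_by_distance` object: list of per-chromosome data
#'   frames with `dist_lo`, `dist_hi`, `mean`, `n_pairs`.
#' @export
expected_by_distance <- function(mat, binwidth = 200, max_distance = 5e5) {
  tab <- mat$axis$table
  M <- scoring_counts(mat)
  tr <- methods::as(M, "TsparseMatrix")
  ti <- tr@i + 1L; tj <- tr@j + 1L; tx <- tr@x
  unmasked <- !mat$mask
  out <- list()
  nbin <- ceiling(max_distance / binwidth)
  for (cc in unique(tab$chrom)) {
    rows <- which(tab$chrom == cc)
    mid <- tab$mid[rows]
    ok <- unmasked[rows]
    n <- length(rows)
    # pair counts per distance bin over all unmasked pairs, by row offset
    cnt <- numeric(nbin)
    for (d in seq_len(n - 1)) {
      dist <- mid[(1 + d):n] - mid[1:(n - d)]
      both <- ok[(1 + d):n] & ok[1:(n - d)]
      dist <- dist[both & dist < max_distance]
      if (!length(dist)) {
        if (min(mid[(1 + d):n] - mid[1:(n - d)]) >= max_distance) break
        next
      }
      b <- floor(dist / binwidth) + 1L
      tb <- tabulate(b, nbins = nbin)
      cnt <- cnt + tb
    }
    # summed counts per bin from stored entries (chromosome rows are a
    # contiguous block of the axis)
    lo <- rows[1]; hi <- rows[length(rows)]
    sel <- ti >= lo & tj <= hi & ti != tj
    ii <- ti[sel]; jj <- tj[sel]; xx <- tx[sel]
    keep <- unmasked[ii] & unmasked[jj]
    ii <- ii[keep]; jj <- jj[keep]; xx <- xx[keep]
    dist <- abs(tab$mid[jj] - tab$mid[ii])
    inb <- dist < max_distance
    sums <- numeric(nbin)
    if (any(inb)) {
      b <- floor(dist[inb] / binwidth) + 1L
      agg <- rowsum(xx[inb], b)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    out[[cc]] <- data.frame(
      dist_lo = binwidth * (seq_len(nbin) - 1),
      dist_hi = binwidth * seq_len(nbin),
      mean = ifelse(cnt > 0, sums / cnt, NA_real_),
      n_pairs = cnt)
  }
  structure(out, class = "expected_by_distance", binwidth = binwidth,
            max_distance = max_distance)
}

# Expected value at given (chrom, distance) pairs; NA outside defined bins.
expected_at <- function(expected, chrom, dist) {
  bw <- attr(expected, "binwidth")
  out <- rep(NA_real_, length(dist))
  for (cc in unique(chrom)) {
    e <- expected[[cc]]
    if (is.null(e)) next
    sel <- chrom == cc
    b <- floor(dist[sel] / bw) + 1
    v <- rep(NA_real_, sum(sel))
    inb <- b >= 1 & b <= nrow(e)
    v[inb] <- e$mean[b[inb]]
    out[sel] <- v
  }
  out
}

#' Intra-TAD condensation
#'
#' Mean (balanced) contact frequency over all intra-TAD fragment pairs
#' (i < j), per TAD. Fragments with no ligation products (masked rows) are
#' excluded from the pairs. TADs whose size falls in `size_range` are
#' flagged as members of the size-matched comparison set.
#'
#' @param mat a fragment-axis [contact_matrix()].
#' @param domains a fragment-axis `domain_set`.
#' @param size_range inclusive size window in bp for the comparison set
#'   (default 5--20 kb).
#' @return A `condensation_table` data frame: per TAD `condensation`,
#'   `n_pairs`, `n_fragments_used`, `size_bp`, `included`.
#' @export
condensation <- function(mat, domains, size_range = c(5000, 20000)) {
  tr <- methods::as(scoring_counts(mat), "TsparseMatrix")
  ti <- tr@i + 1L; tj <- tr@j + 1L; tx <- tr@x
  unmasked <- !mat$mask
  n <- nrow(domains)
  # TAD membership per axis row (domains are non-overlapping)
  tad_of <- rep(NA_integer_, nrow(mat$axis$table))
  for (k in seq_len(n))
    tad_of[seq.int(domains$start_bin[k], domains$end_bin[k])] <- k
  nfrag <- vapply(seq_len(n), function(k)
    sum(unmasked[seq.int(domains$start_bin[k], domains$end_bin[k])]),
    numeric(1))
  npair <- nfrag * (nfrag - 1) / 2
  sel <- ti != tj & !is.na(tad_of[ti]) & !is.na(tad_of[tj]) &
    tad_of[ti] == tad_of[tj] & unmasked[ti] & unmasked[tj]
  sel[is.na(sel)] <- FALSE
  sums <- numeric(n)
  if (any(sel)) {
    agg <- rowsum(tx[sel], tad_of[ti[sel]])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  cond <- ifelse(npair > 0, sums / npair, NA_real_)
  size <- domains$end_bp - domains$start_bp
  out <- data.frame(tad = seq_len(n), chrom = domains$chrom,
                    size_bp = size, condensation = cond, n_pairs = npair,
                    n_fragments_used = nfrag,
                    included = size >= size_range[1] & size <= size_range[2])
  class(out) <- c("condensation_table", "data.frame")
  out
}

#' Distance-normalised enrichment between two domains
#'
#' Mean over all fragment pairs (a in A, b in B) of observed / expected
#' contacts at the pair's separation. Pairs whose expectation is undefined
#' (empty distance bin) are skipped and counted.
#'
#' @param mat a fragment-axis [contact_matrix()].
#' @param domainA,domainB single rows of a `domain_set` (disjoint, same
#'   chromosome).
#' @param expected an [expected_by_distance()] result for `mat`.
#' @return List with `ratio`, `n_pairs_used`, `n_pairs_skipped`.
#' @export
pair_enrichment <- function(mat, domainA, domainB, expected) {
  pair_enrichment_core(scoring_counts(mat), !mat$mask, mat$axis$table$mid,
                       domainA, domainB, expected)
}

pair_enrichment_core <- function(M, unmasked, mid, domainA, domainB,
                                 expected) {
  if (domainA$chrom != domainB$chrom)
    stop("domains must be on the same chromosome")
  ra <- seq.int(domainA$start_bin, domainA$end_bin)
  rb <- seq.int(domainB$start_bin, domainB$end_bin)
  if (length(intersect(ra, rb))) stop("domains must be disjoint")
  ra <- ra[unmasked[ra]]; rb <- rb[unmasked[rb]]
  if (!length(ra) || !length(rb))
    return(list(ratio = NA_real_, n_pairs_used = 0L,
                n_pairs_skipped = 0L))
  obs <- as.matrix(M[ra, rb, drop = FALSE])
  dist <- abs(outer(mid[ra], mid[rb], `-`))
  exp <- expected_at(expected, rep(domainA$chrom, length(dist)),
                     as.vector(dist))
  ok <- !is.na(exp) & exp > 0
  list(ratio = mean(as.vector(obs)[ok] / exp[ok]),
       n_pairs_used = sum(ok), n_pairs_skipped = sum(!ok))
}

#' Enrichment of adjacent TAD pairs
#'
#' [pair_enrichment()] applied to every pair of adjacent domains on each
#' chromosome.
#'
#' @param mat a fragment-axis [contact_matrix()].
#' @param domains a fragment-axis `domain_set`.
#' @param expected an [expected_by_distance()] result.
#' @return Data frame with `tad_a`, `tad_b` (row indices into `domains`),
#'   `chrom`, `ratio`, `n_pairs_used`, `n_pairs_skipped`.
#' @export
adjacent_pair_enrichment <- function(mat, domains, expected) {
  # general storage makes the many small column subsets cheap
  M <- methods::as(scoring_counts(mat), "generalMatrix")
  unmasked <- !mat$mask
  mid <- mat$axis$table$mid
  out <- list()
  for (cc in unique(domains$chrom)) {
    ids <- which(domains$chrom == cc)
    if (length(ids) < 2) next
    for (k in seq_len(length(ids) - 1)) {
      a <- ids[k]; b <- ids[k + 1]
      pe <- pair_enrichment_core(M, unmasked, mid, domains[a, ],
                                 domains[b, ], expected)
      out[[length(out) + 1]] <- data.frame(
        tad_a = a, tad_b = b, chrom = cc, ratio = pe$ratio,
        n_pairs_used = pe$n_pairs_used,
        n_pairs_skipped = pe$n_pairs_skipped)
    }
  }
  if (!length(out))
    return(data.frame(tad_a = integer(0), tad_b = integer(0),
                      chrom = character(0), ratio = numeric(0),
                      n_pairs_used = integer(0),
                      n_pairs_skipped = integer(0)))
  do.call(rbind, out)
}

#' Mean enrichment per chromatin-type pair
#'
#' Groups adjacent-TAD enrichment ratios by the unordered pair of major
#' chromatin types and reports the group means with seeded bootstrap
#' intervals. Type pairs without any TAD pair are absent from the table.
#'
#' @param enrichments result of [adjacent_pair_enrichment()].
#' @param classes a `domain_class_table` aligned to the domain set.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed for the bootstrap.
#' @return Data frame with `type_pair`, `mean_ratio`, `n_pairs`, `ci_lo`,
#'   `ci_hi` (2.5/97.5% bootstrap percentiles).
#' @export
neighbor_type_summary <- function(enrichments, classes, n_boot = 200,
                                  seed = 1) {
  short <- c(active = "A", inactive = "I", polycomb = "P",
             undetermined = "U")
  ta <- short[classes$major_type[enrichments$tad_a]]
  tb <- short[classes$major_type[enrichments$tad_b]]
  pair <- paste0(pmin(ta, tb), "-", pmax(ta, tb))
  ok <- !is.na(enrichments$ratio)
  with_seed(seed, {
    groups <- split(enrichments$ratio[ok], pair[ok])
    rows <- lapply(names(groups), function(g) {
      v <- groups[[g]]
      bm <- vapply(seq_len(n_boot),
                   function(i) mean(sample(v, replace = TRUE)), numeric(1))
      data.frame(type_pair = g, mean_ratio = mean(v), n_pairs = length(v),
                 ci_lo = stats::quantile(bm, 0.025, names = FALSE),
                 ci_hi = stats::quantile(bm, 0.975, names = FALSE))
    })
    do.call(rbind, rows)
  })
}

#' Contrast of TAD-pair contacts within vs across super-TADs
#'
#' Mean enrichment ratio of adjacent TAD pairs lying inside the same
#' super-TAD versus pairs that span an inter-super-TAD region (members
#' localised to different regions or to an inter-super-TAD).
#'
#' @param enrichments result of [adjacent_pair_enrichment()].
#' @param nesting result of [nest_domains()].
#' @return List with `mean_within_super`, `mean_spanning`, `contrast`
#'   (their ratio), and group sizes; values are NA (flagged) when a group is
#'   empty.
#' @export
supertad_contact_contrast <- function(enrichments, nesting) {
  loc <- nesting$assignment$localization
  reg <- nesting$assignment$region_id
  a <- enrichments$tad_a; b <- enrichments$tad_b
  within <- loc[a] == "super-TAD" & loc[b] == "super-TAD" &
    !is.na(reg[a]) & reg[a] == reg[b]
  spanning <- !within
  ok <- !is.na(enrichments$ratio)
  mw <- if (any(within & ok)) mean(enrichments$ratio[within & ok]) else NA_real_
  ms <- if (any(spanning & ok)) mean(enrichments$ratio[spanning & ok]) else NA_real_
  list(mean_within_super = mw, mean_spanning = ms,
       contrast = if (!is.na(mw) && !is.na(ms) && ms > 0) mw / ms else NA_real_,
       n_within = sum(within & ok), n_spanning = sum(spanning & ok))
}

#' Permutation test of condensation parity between chromatin types
#'
#' Compares mean condensation between two chromatin types over the
#' size-matched TAD set by a two-sided permutation test on the type labels.
#'
#' @param cond a [condensation()] table.
#' @param classes a `domain_class_table` aligned to the domain set.
#' @param types the two major types to compare (default active vs
#'   inactive).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return List with `observed_diff`, `p.value`, group means and sizes.
#' @export
condensation_parity_test <- function(cond, classes,
                                     types = c("active", "inactive"),
                                     n_perm = 1000, seed = 1) {
  sel <- cond$included & classes$major_type %in% types &
    !is.na(cond$condensation)
  v <- cond$condensation[sel]
  g <- classes$major_type[sel]
  if (length(unique(g)) < 2)
    return(list(observed_diff = NA_real_, p.value = NA_real_,
                n = table(g)))
  obs <- mean(v[g == types[1]]) - mean(v[g == types[2]])
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      gp <- sample(g)
      mean(v[gp == types[1]]) - mean(v[gp == types[2]])
    }, numeric(1))
    list(observed_diff = obs,
         p.value = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
         group_means = tapply(v, g, mean), n = table(g))
  })
}
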