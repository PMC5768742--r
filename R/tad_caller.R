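#' Caller configuration
#'
#' Parameters of the dynamic-programming domain caller.
#'
#' @param gamma scaling exponent of the interval density (dimensionless,
#'   non-negative). Larger values favour smaller domains. Default 0.9, the value
#'   used for fragment-resolution annotation.
#' @param gamma_fallback exponent used when re-annotating chromosomes whose
#'   domain borders abut read deserts (default 0.6).
#' @param gamma_max,step range and step of the optional consensus sweep.
#' @param min_domain_bins smallest admissible domain, in axis bins
#'   (default 2).
#' @param max_span_bins largest interval span scored by the DP, in bins
#'   (default 600, i.e. ~120 kb at restriction-fragment resolution);
#'   `NULL` means unrestricted, whose quadratic memory cost is only
#'   advisable for small or coarsely binned matrices.
#' @param desert_min minimum run of masked bins that counts as a read desert
#'   (default 3).
#' @param centering score used by the segmentation DP: `"none"` (default)
#'   maximises the raw scaled density `q`, which always favours covering
#'   the chromosome and lets gamma alone set the domain scale; `"mean"`
#'   maximises the mean-centred score `q - mu(span)`. The centred score is
#'   the classical quality normalisation and is always reported, but as a
#'   segmentation objective it rewards cherry-picking above-average
#'   intervals, which fragments the annotation on noisy data (see the
#'   methods vignette).
#' @return A `caller_config` list.
#' @export
caller_config <- function(gamma = 0.9, gamma_fallback = 0.6, gamma_max = 2.0,
                          step = 0.1, min_domain_bins = 2L,
                          max_span_bins = 600L, desert_min = 3L,
                          centering = c("none", "mean")) {
  stopifnot(gamma >= 0, step > 0, min_domain_bins >= 2)
  structure(list(gamma = gamma, gamma_fallback = gamma_fallback,
                 gamma_max = gamma_max, step = step,
                 min_domain_bins = as.integer(min_domain_bins),
                 max_span_bins = max_span_bins,
                 desert_min = as.integer(desert_min),
                 centering = match.arg(centering)),
            class = "caller_config")
}

# Matrix used for domain scoring: balanced when a bias is present, raw
# counts otherwise.
scoring_counts <- function(mat) {
  if (is.null(mat$bias)) mat$counts else balanced_counts(mat)
}

#' Scaled interval-density quality table
#'
#' For every interval `[k, k+d]` of a single-chromosome block (spans
#' `d = 1..max_span`), the quality is the sum of (balanced) contacts with
#' both ends inside the interval, divided by `d^gamma`. Diagonal entries
#' (self-ligation counts) are excluded: they carry no information about
#' cross-locus contact structure and would otherwise reward arbitrarily
#' fine segmentations. `mu[d]` is the exact mean quality over all intervals
#' of span `d`; the mean-centred score is `q - mu`.
#'
#' @param mat a [contact_matrix()] (balanced if a bias is present).
#' @param gamma scaling exponent.
#' @param chrom chromosome to score; may be omitted for a single-chromosome
#'   matrix.
#' @param max_span largest span (bins) to score; default `n - 1`.
#' @return List with `q` (n x max_span matrix, `q[k, d]` = quality of
#'   `[k, k+d]`, `NA` beyond the chromosome), `mu` (length max_span), and
#'   `qprime = q - mu`.
#' @export
domain_quality <- function(mat, gamma, chrom = NULL, max_span = NULL) {
  rows <- if (is.null(chrom)) {
    chroms <- unique(mat$axis$table$chrom)
    if (length(chroms) > 1)
      stop("matrix spans several chromosomes; pass `chrom`")
    seq_len(nrow(mat$counts))
  } else cm_chrom_rows(mat, chrom)
  B <- scoring_counts(mat)[rows, rows, drop = FALSE]
  qt <- quality_core(B, gamma, max_span)
  qt$qprime <- sweep(qt$q, 2, qt$mu, `-`)
  qt
}

# Column-streaming computation of interval sums; B is a sparse symmetric
# matrix (upper triangle stored) restricted to one chromosome.
quality_core <- function(B, gamma, max_span = NULL) {
  B <- methods::as(methods::as(B, "CsparseMatrix"), "symmetricMatrix")
  if (B@uplo != "U") B <- Matrix::t(B)
  n <- nrow(B)
  W <- if (is.null(max_span)) n - 1L else as.integer(min(max_span, n - 1L))
  if (n < 2 || W < 1)
    return(list(q = matrix(NA_real_, n, max(W, 1)), mu = rep(NA_real_, max(W, 1)),
                n = n, max_span = max(W, 1), gamma = gamma))
  p <- B@p; ri <- B@i + 1L; xv <- B@x
  q <- matrix(NA_real_, n, W)
  S <- numeric(n)
  spans <- seq_len(W)
  span_pow <- spans^gamma
  for (l in seq_len(n)) {
    kmin <- max(1L, l - W)
    wlen <- l - kmin + 1L
    a <- numeric(wlen)
    lo <- p[l] + 1L; hi <- p[l + 1L]
    if (hi >= lo) {
      r <- ri[lo:hi]; v <- xv[lo:hi]
      sel <- r >= kmin & r < l      # diagonal excluded
      if (any(sel)) {
        t <- numeric(wlen)
        idx <- r[sel] - kmin + 1L
        t[idx] <- t[idx] + v[sel]
        a <- rev(cumsum(rev(t)))
      }
    }
    S[kmin:l] <- S[kmin:l] + a
    dmax <- min(W, l - 1L)
    if (dmax >= 1L) {
      ds <- seq_len(dmax)
      q[cbind(l - ds, ds)] <- S[l - ds] / span_pow[ds]
    }
  }
  mu <- colMeans(q, na.rm = TRUE)
  list(q = q, mu = mu, n = n, max_span = W, gamma = gamma)
}

new_domain_set <- function(df, level, axis, config = NULL) {
  rownames(df) <- NULL
  class(df) <- c("domain_set", "data.frame")
  attr(df, "level") <- level
  attr(df, "genome") <- axis$genome
  attr(df, "axis_kind") <- axis$kind
  attr(df, "config") <- config
  df
}

#' @exportS3Method base::print
print.domain_set <- function(x, ...) {
  cat("domain_set (", attr(x, "level"), "): ", nrow(x), " domains",
      if (nrow(x)) paste0(", median size ",
                          stats::median(x$end_bp - x$start_bp), " bp"),
      "\n", sep = "")
  invisible(x)
}

#' Annotate domains by dynamic programming
#'
#' Computes, per chromosome, the segmentation maximising the sum of
#' normalised interval scores `max(q - mu, 0)` over chosen non-overlapping
#' intervals, with unassigned bins allowed between domains. Intervals with
#' non-positive normalised score are never emitted. Ties are broken towards
#' fewer domains, then leftmost starts. Multiplying the matrix by a constant
#' leaves the result unchanged.
#'
#' @param mat a balanced [contact_matrix()].
#' @param config a [caller_config()].
#' @param level label stored on the result (`"TAD"` or `"super-TAD"`).
#' @return A `domain_set`: data frame with columns `chrom`, `start_bin`,
#'   `end_bin` (inclusive, genome-wide axis row indices, 1-based), `start_bp`,
#'   `end_bp`, `score`, `gamma_used`, sorted and non-overlapping.
#' @export
call_domains_dp <- function(mat, config = caller_config(), level = "TAD") {
  tab <- mat$axis$table
  out <- list()
  for (cc in unique(tab$chrom)) {
    rows <- which(tab$chrom == cc)
    if (length(rows) < config$min_domain_bins) next
    B <- scoring_counts(mat)[rows, rows, drop = FALSE]
    qt <- quality_core(B, config$gamma, config$max_span_bins)
    dom <- dp_segment(qt, config$min_domain_bins, config$centering)
    if (!nrow(dom)) next
    out[[cc]] <- data.frame(
      chrom = cc,
      start_bin = rows[dom$start], end_bin = rows[dom$end],
      start_bp = tab$start[rows[dom$start]], end_bp = tab$end[rows[dom$end]],
      score = dom$score, gamma_used = config$gamma,
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start_bin = integer(0),
               end_bin = integer(0), start_bp = numeric(0),
               end_bp = numeric(0), score = numeric(0),
               gamma_used = numeric(0))
  new_domain_set(df, level, mat$axis, config)
}

# Single-chromosome DP over a quality table. Returns start/end (local
# 1-based bins) and scores, plus the optimal objective as an attribute.
dp_segment <- function(qt, min_domain_bins, centering = "none") {
  n <- qt$n; W <- qt$max_span
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0))
  if (n < min_domain_bins) return(structure(empty, objective = 0))
  qp <- if (centering == "mean") sweep(qt$q, 2, qt$mu, `-`) else qt$q
  scale <- max(abs(qp), 1e-300, na.rm = TRUE)
  eps <- 1e-9 * scale
  dmin <- min_domain_bins - 1L
  opt <- numeric(n + 1L)       # opt[m+1] = best objective on bins 1..m
  choice <- integer(n)         # span of domain ending at l, 0 = unassigned
  for (l in seq_len(n)) {
    best <- opt[l]; bd <- 0L
    dhi <- min(W, l - 1L)
    if (dhi >= dmin) {
      ds <- seq.int(dhi, dmin)           # descending: leftmost start on ties
      sc <- qp[cbind(l - ds, ds)]
      ok <- which(sc > 0)
      if (length(ok)) {
        vals <- opt[l - ds[ok]] + sc[ok]
        w <- which.max(vals)
        if (vals[w] > best + eps) { best <- vals[w]; bd <- ds[ok][w] }
      }
    }
    opt[l + 1L] <- best; choice[l] <- bd
  }
  starts <- integer(0); ends <- integer(0); scores <- numeric(0)
  l <- n
  while (l >= 1L) {
    if (choice[l] == 0L) { l <- l - 1L } else {
      k <- l - choice[l]
      starts <- c(k, starts); ends <- c(l, ends)
      scores <- c(qp[k, choice[l]], scores)
      l <- k - 1L
    }
  }
  structure(data.frame(start = starts, end = ends, score = scores),
            objective = opt[n + 1L])
}

#' Call super-TADs on a binned matrix
#'
#' Runs the segmentation DP on the ICE-balanced binned matrix (20 kb by
#' default), then labels each resulting tile by its internal
#' distance-normalised contact enrichment: tiles whose off-diagonal bin
#' pairs are on average more frequent than expected at their separation
#' (enrichment >= `min_enrichment`) are super-TAD material, and runs of
#' adjacent super tiles are merged into super-TADs. The regions between
#' super-TADs are the inter-super-TAD regions (see [nest_domains()]).
#'
#' @param mat a fragment-resolution [contact_matrix()] (raw counts are
#'   fine; the binned matrix is balanced internally).
#' @param config a [caller_config()]; the DP uses its gamma.
#' @param binsize bin size in bp (default 20 kb).
#' @param min_enrichment minimum mean internal observed/expected ratio for
#'   a tile to count as super-TAD material; `NULL` (default) splits the
#'   bimodal tile-enrichment distribution adaptively by 1-d 2-means on the
#'   log enrichment and takes the upper mode.
#' @param ice_tol,ice_max_iter balancing parameters for the binned matrix.
#' @return A `domain_set` (level "super-TAD") on the bin axis, with
#'   attribute `tiles` (the underlying tiling with its enrichment values).
#' @export
call_supertads <- function(mat, config = caller_config(), binsize = 20000,
                           min_enrichment = NULL, ice_tol = 1e-5,
                           ice_max_iter = 200L) {
  binned <- bin_matrix(mat, binsize)
  binned <- suppressWarnings(ice_normalize(binned, ice_tol, ice_max_iter))
  tiles <- call_domains_dp(binned, config, level = "tile")
  if (!nrow(tiles)) return(new_domain_set(as.data.frame(tiles), "super-TAD",
                                          binned$axis, config))
  expected <- expected_by_distance(binned, binwidth = binsize,
                                   max_distance = binsize *
                                     (max(tiles$end_bin - tiles$start_bin) + 2))
  M <- methods::as(scoring_counts(binned), "generalMatrix")
  mid <- binned$axis$table$mid
  enr <- vapply(seq_len(nrow(tiles)), function(k) {
    rows <- seq.int(tiles$start_bin[k], tiles$end_bin[k])
    if (length(rows) < 2) return(NA_real_)
    obs <- as.matrix(M[rows, rows, drop = FALSE])
    ut <- upper.tri(obs)
    dist <- abs(outer(mid[rows], mid[rows], `-`))
    exp <- expected_at(expected, rep(tiles$chrom[k], sum(ut)), dist[ut])
    ok <- !is.na(exp) & exp > 0
    if (!any(ok)) return(NA_real_)
    mean(obs[ut][ok] / exp[ok])
  }, numeric(1))
  tiles$enrichment <- enr
  if (is.null(min_enrichment)) {
    v <- log(enr[!is.na(enr) & enr > 0])
    min_enrichment <- if (length(unique(v)) > 2) {
      km <- stats::kmeans(v, centers = stats::quantile(v, c(0.25, 0.75)))
      exp(mean(km$centers))          # midpoint of the two modes
    } else 1
  }
  is_super <- !is.na(enr) & enr >= min_enrichment
  out <- list()
  for (cc in unique(tiles$chrom)) {
    idx <- which(tiles$chrom == cc & is_super)
    if (!length(idx)) next
    # merge runs of adjacent super tiles
    grp <- cumsum(c(1, diff(idx) > 1 |
                      tiles$start_bin[idx[-1]] -
                        tiles$end_bin[idx[-length(idx)]] > 1))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      out[[length(out) + 1]] <- data.frame(
        chrom = cc,
        start_bin = tiles$start_bin[members[1]],
        end_bin = tiles$end_bin[members[length(members)]],
        start_bp = tiles$start_bp[members[1]],
        end_bp = tiles$end_bp[members[length(members)]],
        score = mean(tiles$enrichment[members]),
        gamma_used = config$gamma, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    as.data.frame(tiles)[integer(0), ]
  res <- new_domain_set(df, "super-TAD", binned$axis, config)
  attr(res, "tiles") <- tiles
  attr(res, "binsize") <- binsize
  res
}

#' Re-annotate chromosomes whose borders abut read deserts
#'
#' A read desert is a run of at least `desert_min` consecutive masked
#' (zero-coverage) bins. When any domain boundary lies within one bin of
#' such a run, the whole chromosome is re-annotated with `gamma_fallback`
#' and its annotation replaced; other chromosomes are kept untouched.
#'
#' @param mat the balanced [contact_matrix()] used for calling.
#' @param domains the [call_domains_dp()] result.
#' @param config a [caller_config()].
#' @return A `domain_set` with attributes `fallback_chroms` (chromosomes
#'   re-annotated) and `deserts` (data frame of masked runs).
#' @export
readdesert_fallback <- function(mat, domains, config = caller_config()) {
  tab <- mat$axis$table
  deserts <- list()
  trigger <- character(0)
  for (cc in unique(tab$chrom)) {
    rows <- which(tab$chrom == cc)
    r <- rle(mat$mask[rows])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= config$desert_min)
    if (!length(runs)) next
    dd <- data.frame(chrom = cc, first_bin = rows[starts[runs]],
                     last_bin = rows[ends[runs]], stringsAsFactors = FALSE)
    deserts[[cc]] <- dd
    dom <- domains[domains$chrom == cc, ]
    if (!nrow(dom)) next
    bnd <- c(dom$start_bin, dom$end_bin)
    near <- vapply(seq_len(nrow(dd)), function(k)
      any(bnd >= dd$first_bin[k] - 1L & bnd <= dd$last_bin[k] + 1L),
      logical(1))
    if (any(near)) trigger <- c(trigger, cc)
  }
  deserts <- if (length(deserts)) do.call(rbind, deserts) else
    data.frame(chrom = character(0), first_bin = integer(0),
               last_bin = integer(0))
  out <- domains
  if (length(trigger)) {
    cfg2 <- config
    cfg2$gamma <- config$gamma_fallback
    redone <- call_domains_dp(mat, cfg2, level = attr(domains, "level"))
    keep <- domains[!(domains$chrom %in% trigger), ]
    repl <- redone[redone$chrom %in% trigger, ]
    df <- rbind(as.data.frame(keep), as.data.frame(repl))
    df <- df[order(match(df$chrom, unique(tab$chrom)), df$start_bin), ]
    out <- new_domain_set(df, attr(domains, "level"),
                          list(genome = attr(domains, "genome"),
                               kind = attr(domains, "axis_kind")),
                          config)
  }
  attr(out, "fallback_chroms") <- trigger
  attr(out, "deserts") <- deserts
  out
}

#' Boundary centers of a domain set
#'
#' One center per junction of adjacent domains on a chromosome: the midpoint
#' between the end of the upstream domain and the start of the downstream
#' domain, rounded down.
#'
#' @param domains a `domain_set`.
#' @return A `boundary_set`: data frame with columns `chrom`, `pos` (bp).
#' @export
boundary_centers <- function(domains) {
  out <- list()
  for (cc in unique(domains$chrom)) {
    dom <- domains[domains$chrom == cc, ]
    if (nrow(dom) < 2) next
    up_end <- dom$end_bp[-nrow(dom)]
    down_start <- dom$start_bp[-1]
    out[[cc]] <- data.frame(chrom = cc,
                            pos = floor((up_end + down_start) / 2),
                            stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = numeric(0))
  rownames(df) <- NULL
  class(df) <- c("boundary_set", "data.frame")
  attr(df, "genome") <- attr(domains, "genome")
  df
}

#' Fraction of same-fragment junctions between adjacent domains
#'
#' A junction between adjacent fragment-resolution domains is
#' "same-fragment" when the last fragment of the upstream domain and the
#' first fragment of the downstream domain are identical or adjacent, i.e.
#' no fragment lies between them.
#'
#' @param domains a fragment-axis `domain_set`.
#' @return List with `fraction` and a per-junction `table` (chrom, upstream
#'   last fragment, downstream first fragment, gap in fragments,
#'   `same_fragment` flag).
#' @export
contiguity_fraction <- function(domains) {
  if (!identical(attr(domains, "axis_kind"), "fragment"))
    stop("contiguity is defined on fragment-axis domains")
  rowsl <- list()
  for (cc in unique(domains$chrom)) {
    dom <- domains[domains$chrom == cc, ]
    if (nrow(dom) < 2) next
    up_last <- dom$end_bin[-nrow(dom)]
    down_first <- dom$start_bin[-1]
    gap <- down_first - up_last - 1L
    rowsl[[cc]] <- data.frame(chrom = cc, up_last_frag = up_last - 1L,
                              down_first_frag = down_first - 1L,
                              gap_fragments = gap,
                              same_fragment = gap <= 0L,
                              stringsAsFactors = FALSE)
  }
  tabl <- if (length(rowsl)) do.call(rbind, rowsl) else
    data.frame(chrom = character(0), up_last_frag = integer(0),
               down_first_frag = integer(0), gap_fragments = integer(0),
               same_fragment = logical(0))
  rownames(tabl) <- NULL
  list(fraction = if (nrow(tabl)) mean(tabl$same_fragment) else NA_real_,
       table = tabl)
}

#' Nest fragment-resolution TADs into super-TADs
#'
#' A TAD is assigned to a super-TAD, or to the inter-super-TAD region
#' between two super-TADs (including chromosome flanks), when at least
#' `inclusion` of its length overlaps that region; otherwise it is
#' unassigned.
#'
#' @param tads,supertads `domain_set` objects on the same genome.
#' @param inclusion minimum overlap fraction of the TAD length
#'   (default 0.75).
#' @return List with `assignment` (per TAD: `localization` in
#'   super-TAD/inter-super-TAD/unassigned, plus region id) and `counts`
#'   (TADs per region, the histogram of TADs per super-TAD and
#'   inter-super-TAD).
#' @export
nest_domains <- function(tads, supertads, inclusion = 0.75) {
  genome <- attr(tads, "genome")
  regions <- list()
  for (cc in genome$chrom) {
    len <- genome$length[genome$chrom == cc]
    sup <- supertads[supertads$chrom == cc, ]
    sup <- sup[order(sup$start_bp), ]
    bounds <- rbind(
      if (nrow(sup)) data.frame(start = sup$start_bp, end = sup$end_bp,
                                kind = "super-TAD"),
      {
        gs <- c(0, sup$end_bp); ge <- c(sup$start_bp, len)
        keep <- ge > gs
        if (any(keep)) data.frame(start = gs[keep], end = ge[keep],
                                  kind = "inter-super-TAD")
      })
    if (is.null(bounds) || !nrow(bounds)) next
    bounds <- bounds[order(bounds$start), ]
    bounds$chrom <- cc
    regions[[cc]] <- bounds
  }
  regions <- do.call(rbind, regions)
  regions$region_id <- paste0(substr(regions$kind, 1, 5), "_", regions$chrom,
                              "_", seq_len(nrow(regions)))
  loc <- rep("unassigned", nrow(tads))
  rid <- rep(NA_character_, nrow(tads))
  for (k in seq_len(nrow(tads))) {
    reg <- regions[regions$chrom == tads$chrom[k], ]
    ov <- pmax(0, pmin(reg$end, tads$end_bp[k]) -
                  pmax(reg$start, tads$start_bp[k]))
    frac <- ov / (tads$end_bp[k] - tads$start_bp[k])
    hit <- which(frac >= inclusion)
    if (length(hit)) {
      loc[k] <- reg$kind[hit[1]]
      rid[k] <- reg$region_id[hit[1]]
    }
  }
  assignment <- data.frame(tad = seq_len(nrow(tads)), chrom = tads$chrom,
                           start_bp = tads$start_bp, end_bp = tads$end_bp,
                           localization = loc, region_id = rid,
                           stringsAsFactors = FALSE)
  assigned <- assignment[!is.na(assignment$region_id), ]
  counts <- if (nrow(assigned)) {
    agg <- stats::aggregate(list(n_tads = assigned$tad),
                            by = list(region_id = assigned$region_id),
                            FUN = length)
    agg$kind <- regions$kind[match(agg$region_id, regions$region_id)]
    agg
  } else data.frame(region_id = character(0), n_tads = integer(0),
                    kind = character(0))
  list(assignment = assignment, counts = counts, regions = regions)
}

#' Domain size statistics and genome coverage
#'
#' @param domains a `domain_set`.
#' @return List with `median_bp`, `quantiles_bp` (0, 25, 50, 75, 100%),
#'   `coverage` (covered bp / genome bp) and `n_domains`.
#' @export
domain_size_stats <- function(domains) {
  sizes <- domains$end_bp - domains$start_bp
  genome <- attr(domains, "genome")
  list(n_domains = nrow(domains),
       median_bp = if (length(sizes)) stats::median(sizes) else NA_real_,
       quantiles_bp = stats::quantile(sizes),
       coverage = sum(sizes) / genome_total_length(genome))
}

#' Read / write domain sets as BED
#'
#' Columns: chrom, start, end, name (`level:index`), score, strand (`.`),
#' gamma_used.
#' @param domains a `domain_set`.
#' @param path file path.
#' @param level level tag for reading.
#' @return `read_domains` returns a `domain_set` (without axis bin indices);
#'   `write_domains` returns `path` invisibly.
#' @export
write_domains <- function(domains, path) {
  df <- data.frame(domains$chrom,
                   format(domains$start_bp, scientific = FALSE, trim = TRUE),
                   format(domains$end_bp, scientific = FALSE, trim = TRUE),
                   paste0(attr(domains, "level"), ":", seq_len(nrow(domains))),
                   signif(domains$score, 6), ".", domains$gamma_used)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_domains
#' @export
read_domains <- function(path, level = "TAD") {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]), start_bin = NA_integer_,
                    end_bin = NA_integer_, start_bp = df[[2]],
                    end_bp = df[[3]], score = df[[5]], gamma_used = df[[7]],
                    stringsAsFactors = FALSE)
  lens <- vapply(split(out$end_bp, out$chrom), max, numeric(1))
  genome <- genome_layout(names(lens), lens)
  new_domain_set(out, level, list(genome = genome, kind = "bp"))
}
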