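#' Boundary-centered occupancy profile
#'
#' Mean track occupancy in fixed-width windows spanning a symmetric flank
#' around each boundary center (by default 100 windows of 80 bp covering
#' +/- 4 kb). Regions without track coverage count as zero occupancy.
#' Centers whose flank extends past a chromosome end are clipped to the
#' chromosome (the out-of-genome part counts as zero) and flagged.
#'
#' @param track a [signal_track()].
#' @param centers a `boundary_set` (or data frame with `chrom`, `pos`).
#' @param flank half-width of the profiled region in bp (default 4000).
#' @param window window width in bp (default 80); `2 * flank / window`
#'   windows are produced.
#' @param genome optional [genome_layout()] used for clipping; taken from
#'   the centers attribute when present.
#' @return Data frame with `offset` (window center relative to the boundary
#'   center, bp) and `occupancy` (mean over centers); attribute `clipped`
#'   lists centers whose flank was clipped.
#' @export
occupancy_profile <- function(track, centers, flank = 4000, window = 80,
                              genome = NULL) {
  stopifnot(flank > 0, window > 0, (2 * flank) %% window == 0)
  if (is.null(genome)) genome <- attr(centers, "genome")
  nwin <- as.integer(2 * flank / window)
  offsets <- -flank + window / 2 + window * (seq_len(nwin) - 1)
  if (!nrow(centers))
    return(structure(data.frame(offset = offsets,
                                occupancy = rep(NA_real_, nwin)),
                     clipped = integer(0)))
  Fint <- track_integrator(track)
  nc <- nrow(centers)
  ws <- rep(centers$pos, each = nwin) - flank +
    window * (seq_len(nwin) - 1)        # window starts, recycled per center
  we <- ws + window
  cc <- rep(centers$chrom, each = nwin)
  clipped <- integer(0)
  if (!is.null(genome)) {
    lens <- stats::setNames(genome$length, genome$chrom)[cc]
    bad <- ws < 0 | we > lens
    if (any(bad)) clipped <- unique(ceiling(which(bad) / nwin))
    ws <- pmin(pmax(ws, 0), lens)
    we <- pmin(pmax(we, 0), lens)
  }
  occ <- (Fint(cc, we) - Fint(cc, ws)) / window
  prof <- rowMeans(matrix(occ, nrow = nwin))
  structure(data.frame(offset = offsets, occupancy = prof),
            clipped = clipped)
}

#' Shuffled-background occupancy profile
#'
#' Draws boundary centers uniformly at random over each chromosome
#' (preserving the per-chromosome center counts), computes the occupancy
#' profile, and averages over shuffles. Deterministic under a fixed seed.
#'
#' @param track a [signal_track()].
#' @param n_centers named integer vector of centers per chromosome, or a
#'   `boundary_set` whose per-chromosome counts are copied.
#' @param genome a [genome_layout()].
#' @param n_shuffles number of random center sets (default 100).
#' @param seed integer seed (required).
#' @param flank,window as in [occupancy_profile()].
#' @return Data frame with `offset` and `occupancy` (mean over windows,
#'   centers and shuffles).
#' @export
shuffled_background <- function(track, n_centers, genome, n_shuffles = 100,
                                seed, flank = 4000, window = 80) {
  if (inherits(n_centers, "data.frame"))
    n_centers <- table(factor(n_centers$chrom, levels = genome$chrom))
  n_centers <- stats::setNames(as.integer(n_centers), names(n_centers))
  if (sum(n_centers) == 0) stop("n_centers must be positive")
  with_seed(seed, {
    profs <- vapply(seq_len(n_shuffles), function(s) {
      pos <- unlist(lapply(names(n_centers), function(cc) {
        len <- genome$length[genome$chrom == cc]
        floor(stats::runif(n_centers[[cc]], 0, len))
      }))
      chrom <- rep(names(n_centers), n_centers)
      occupancy_profile(track,
                        data.frame(chrom = chrom, pos = pos,
                                   stringsAsFactors = FALSE),
                        flank, window, genome)$occupancy
    }, numeric(2 * flank / window))
    offsets <- -flank + window / 2 + window * (seq_len(2 * flank / window) - 1)
    data.frame(offset = offsets, occupancy = rowMeans(profs))
  })
}

#' Observed / shuffled enrichment profile
#'
#' Elementwise ratio of an observed boundary-centered occupancy profile to a
#' shuffled background on the same window grid. Windows with zero background
#' are flagged and carry an undefined (NA) ratio rather than an infinity.
#'
#' @param observed,background data frames from [occupancy_profile()] and
#'   [shuffled_background()].
#' @param n_shuffles,seed bookkeeping fields stored on the result.
#' @return An `enrichment_profile` data frame with `offset`, `observed`,
#'   `background`, `ratio`, `flagged`.
#' @export
enrichment_ratio <- function(observed, background, n_shuffles = NA,
                             seed = NA) {
  if (!isTRUE(all.equal(observed$offset, background$offset)))
    stop("observed and background profiles use different window grids")
  zero <- background$occupancy <= 0
  ratio <- ifelse(zero, NA_real_, observed$occupancy / background$occupancy)
  out <- data.frame(offset = observed$offset, observed = observed$occupancy,
                    background = background$occupancy, ratio = ratio,
                    flagged = zero)
  class(out) <- c("enrichment_profile", "data.frame")
  attr(out, "n_shuffles") <- n_shuffles
  attr(out, "seed") <- seed
  out
}

#' Pair sites of two insulator proteins
#'
#' Anchor peaks whose interval lies within `max_gap` bp of some partner peak
#' interval; the site position is the anchor peak summit. This encodes
#' co-occurrence of a DNA-binding protein (e.g. BEAF-32) with a bridging
#' partner (e.g. CP190 or Chromator).
#'
#' @param anchor,partner [peak_set()] objects on the same genome.
#' @param max_gap maximum gap between the two peak intervals in bp
#'   (default 200; 0 requires overlap or touching).
#' @return A `pair_site_set` data frame with `chrom`, `pos` and attribute
#'   `pair` (anchor/partner labels).
#' @export
pair_sites <- function(anchor, partner, max_gap = 200) {
  ga <- GenomicRanges::GRanges(anchor$chrom,
                               IRanges::IRanges(anchor$start + 1, anchor$end))
  gp <- GenomicRanges::GRanges(partner$chrom,
                               IRanges::IRanges(partner$start + 1,
                                                partner$end))
  hits <- GenomicRanges::findOverlaps(ga, gp, maxgap = max_gap)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- data.frame(chrom = anchor$chrom[keep], pos = anchor$summit[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_site_set", "data.frame")
  attr(out, "pair") <- c(anchor = attr(anchor, "protein"),
                         partner = attr(partner, "protein"))
  out
}

#' Co-localization of sites with TAD borders
#'
#' A border is hit when any site lies within `tol` bp of its center; a site
#' is at-border when it lies within `tol` of any center. A border with
#' several qualifying sites counts once. When an expected hit rate (from
#' shuffled centers) is supplied, a Fisher exact test of the hit/miss
#' contrast is included.
#'
#' @param sites a [peak_set()] (summits are used) or a `pair_site_set` /
#'   data frame with `chrom`, `pos`.
#' @param centers a `boundary_set`.
#' @param tol distance tolerance in bp (default 2000).
#' @param expected_hit_rate optional border hit proportion under the
#'   shuffled null, for [border_enrichment_test()].
#' @return A `colocalization` list: `n_borders`, `n_sites`, `borders_hit`,
#'   `borders_hit_prop`, `sites_at_borders`, `sites_at_borders_prop`, and
#'   `fisher_p` when an expected rate was given.
#' @export
colocalize <- function(sites, centers, tol = 2000,
                       expected_hit_rate = NULL) {
  pos <- if (!is.null(sites$pos)) sites$pos else sites$summit
  schrom <- sites$chrom
  bhit <- logical(nrow(centers))
  shit <- logical(length(pos))
  for (cc in unique(centers$chrom)) {
    cp <- centers$pos[centers$chrom == cc]
    sp <- pos[schrom == cc]
    if (length(sp)) {
      bhit[centers$chrom == cc] <-
        vapply(cp, function(p) any(abs(sp - p) <= tol), logical(1))
      shit[schrom == cc] <-
        vapply(sp, function(p) any(abs(cp - p) <= tol), logical(1))
    }
  }
  out <- list(n_borders = nrow(centers), n_sites = length(pos),
              borders_hit = sum(bhit),
              borders_hit_prop = mean(bhit),
              sites_at_borders = sum(shit),
              sites_at_borders_prop = if (length(pos)) mean(shit) else NA_real_,
              border_hit = bhit, site_hit = shit)
  if (!is.null(expected_hit_rate))
    out$fisher_p <- border_enrichment_test(sum(bhit), nrow(centers),
                                           expected_hit_rate)$p.value
  class(out) <- "colocalization"
  out
}

#' @exportS3Method base::print
print.colocalization <- function(x, ...) {
  cat("colocalization:", x$borders_hit, "/", x$n_borders, "borders hit (",
      round(100 * x$borders_hit_prop, 1), "%); ", x$sites_at_borders, "/",
      x$n_sites, "sites at borders (",
      round(100 * x$sites_at_borders_prop, 1), "%)\n")
  invisible(x)
}

#' Fisher exact test of border enrichment
#'
#' Two-sided exact test on the 2x2 table (hit/miss x observed/shuffled),
#' where the shuffled column carries the expected hit count
#' `round(expected_hit_rate * n_borders)`.
#'
#' @param borders_hit observed hit count.
#' @param n_borders number of borders.
#' @param expected_hit_rate expected hit proportion under the shuffled null.
#' @return The [stats::fisher.test()] result (two-sided).
#' @export
border_enrichment_test <- function(borders_hit, n_borders,
                                   expected_hit_rate) {
  exp_hit <- round(expected_hit_rate * n_borders)
  tab <- matrix(c(borders_hit, n_borders - borders_hit,
                  exp_hit, n_borders - exp_hit), nrow = 2)
  stats::fisher.test(tab)
}

#' Venn partition of border hits across proteins
#'
#' Classifies each border by the combination of proteins (or pair-site
#' sets) with a site within `tol` of its center.
#'
#' @param site_sets named list of [peak_set()] / `pair_site_set` objects.
#' @param centers a `boundary_set`.
#' @param tol distance tolerance in bp (default 2000).
#' @return Named integer vector of border counts per protein combination
#'   (`"none"` for borders hit by no protein); sums to `nrow(centers)`.
#' @export
border_venn <- function(site_sets, centers, tol = 2000) {
  hits <- vapply(site_sets,
                 function(s) colocalize(s, centers, tol)$border_hit,
                 logical(nrow(centers)))
  combo <- apply(hits, 1, function(h)
    if (!any(h)) "none" else paste(names(site_sets)[h], collapse = "&"))
  table(combo)
}
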