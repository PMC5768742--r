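#' Per-TAD epigenetic mark enrichment matrix
#'
#' Each track is Z-scored genome-wide (weighted by interval width, so the
#' score is per-bp), then averaged over each domain interval. Domains with
#' no track coverage get 0 and are flagged.
#'
#' @param tracks named list of [signal_track()] objects, one per mark.
#' @param domains a `domain_set` (rows of the result follow its order).
#' @return Numeric matrix (TADs x marks) with attribute `uncovered`
#'   (logical matrix of TAD/mark combinations without coverage).
#' @export
tad_mark_enrichment <- function(tracks, domains) {
  n <- nrow(domains)
  width <- domains$end_bp - domains$start_bp
  out <- matrix(0, n, length(tracks),
                dimnames = list(NULL, names(tracks)))
  uncov <- matrix(FALSE, n, length(tracks),
                  dimnames = list(NULL, names(tracks)))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    w <- tr$end - tr$start
    m <- sum(tr$value * w) / sum(w)
    s <- sqrt(sum(w * (tr$value - m)^2) / sum(w))
    if (s == 0) { uncov[, k] <- TRUE; next }
    ztr <- tr
    ztr$value <- (tr$value - m) / s
    Fint <- track_integrator(ztr)
    cov <- track_integrator(signal_track(tr$chrom, tr$start, tr$end, 1))
    covered <- cov(domains$chrom, domains$end_bp) -
      cov(domains$chrom, domains$start_bp)
    val <- (Fint(domains$chrom, domains$end_bp) -
              Fint(domains$chrom, domains$start_bp)) / width
    zero <- covered == 0
    val[zero] <- 0
    uncov[zero, k] <- TRUE
    out[, k] <- val
  }
  attr(out, "uncovered") <- uncov
  out
}

#' Seeded k-means typing of domains
#'
#' Lloyd's algorithm with k-means++ initialisation, run `n_restarts` times
#' under a fixed seed; the solution with the smallest within-cluster sum of
#' squares is returned. The objective is recorded after every Lloyd
#' iteration and is non-increasing by construction.
#'
#' @param x numeric matrix (rows = domains, e.g. from
#'   [tad_mark_enrichment()]).
#' @param k number of clusters (default 8).
#' @param seed integer seed.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return List with `cluster` (1..k per row), `centers` (k x ncol matrix),
#'   `tot_withinss`, and `wss_trace` (objective after each iteration of the
#'   winning restart).
#' @export
kmeans_types <- function(x, k = 8, seed = 1, n_restarts = 10,
                         max_iter = 100) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of rows")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(x, k, max_iter)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
    best
  })
}

# One k-means++ initialisation followed by Lloyd iterations.
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x),
                    dimnames = list(NULL, colnames(x)))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  cluster <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dists <- vapply(seq_len(k),
                    function(j) rowSums(sweep(x, 2, centers[j, ])^2),
                    numeric(n))
    newc <- max.col(-dists, ties.method = "first")
    for (j in seq_len(k)) {
      rows <- newc == j
      if (any(rows)) centers[j, ] <- colMeans(x[rows, , drop = FALSE])
    }
    wss <- sum(dists[cbind(seq_len(n), newc)])
    trace <- c(trace, wss)
    if (identical(newc, cluster)) break
    cluster <- newc
  }
  dists <- vapply(seq_len(k),
                  function(j) rowSums(sweep(x, 2, centers[j, ])^2),
                  numeric(n))
  list(cluster = cluster,
       centers = centers,
       tot_withinss = sum(dists[cbind(seq_len(n), cluster)]),
       wss_trace = trace)
}

#' Default mark grouping
#'
#' A conventional grouping of a 15-mark panel into active, inactive and
#' polycomb-associated marks; users override with their own mapping.
#'
#' @return Named list of character vectors.
#' @export
default_mark_groups <- function() {
  list(active = c("H3K4me3", "H3K4me1", "H3K27ac", "H3K36me3", "PolII"),
       inactive = c("H3K9me2", "H3K9me3", "H1", "Lamin", "SUUR"),
       polycomb = c("H3K27me3", "Pc", "Ez", "Psc", "dRING"))
}

#' Assign clusters to major chromatin types
#'
#' Each cluster's major type is the mark group (active / inactive /
#' polycomb) with the highest mean centroid Z-score among its marks,
#' provided that mean exceeds `tau`; otherwise (or on a tie) the cluster is
#' "undetermined".
#'
#' @param clusters cluster id per domain (from [kmeans_types()]).
#' @param centroids k x marks centroid matrix with mark column names.
#' @param mark_groups named list mapping groups to mark names; unlisted
#'   marks are ignored.
#' @param tau minimum centroid group mean in Z units (default 0.5).
#' @return A `domain_class_table` data frame with columns `cluster` and
#'   `major_type` per domain; attribute `cluster_types` gives the per-cluster
#'   call and group means.
#' @export
assign_major_types <- function(clusters, centroids,
                               mark_groups = default_mark_groups(),
                               tau = 0.5) {
  if (is.null(colnames(centroids)))
    stop("centroids must carry mark column names")
  gm <- vapply(mark_groups, function(marks) {
    marks <- intersect(marks, colnames(centroids))
    if (!length(marks)) return(rep(NA_real_, nrow(centroids)))
    rowMeans(centroids[, marks, drop = FALSE])
  }, numeric(nrow(centroids)))
  ctype <- apply(gm, 1, function(v) {
    if (all(is.na(v))) return("undetermined")
    mx <- max(v, na.rm = TRUE)
    if (mx <= tau) return("undetermined")
    top <- names(v)[!is.na(v) & v == mx]
    if (length(top) != 1) return("undetermined")   # tie rule
    top
  })
  out <- data.frame(cluster = clusters,
                    major_type = ctype[clusters],
                    stringsAsFactors = FALSE)
  class(out) <- c("domain_class_table", "data.frame")
  attr(out, "cluster_types") <- data.frame(cluster = seq_len(nrow(centroids)),
                                           major_type = ctype, gm)
  out
}

#' Chromatin-type vs super-TAD localization test
#'
#' Tests whether active and inactive TADs segregate between super-TADs and
#' inter-super-TADs: a 2x2 contingency table (active/inactive x
#' super-TAD/inter-super-TAD) with a two-sided Fisher exact test.
#'
#' @param classes a `domain_class_table` aligned to the TAD set.
#' @param nesting result of [nest_domains()] for the same TAD set.
#' @return List with `table`, `p.value`, and the marginal localization
#'   proportions `inactive_in_super`, `active_in_inter`; `NULL` (with a
#'   warning) when a class is empty.
#' @export
type_localization_test <- function(classes, nesting) {
  loc <- nesting$assignment$localization
  keep <- classes$major_type %in% c("active", "inactive") &
    loc %in% c("super-TAD", "inter-super-TAD")
  if (!any(keep)) { warning("no classified TADs to test"); return(NULL) }
  tp <- factor(classes$major_type[keep], levels = c("active", "inactive"))
  lc <- factor(loc[keep], levels = c("super-TAD", "inter-super-TAD"))
  tab <- table(tp, lc)
  if (any(rowSums(tab) == 0)) {
    warning("empty chromatin class; localization test skipped")
    return(NULL)
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, p.value = ft$p.value,
       inactive_in_super = tab["inactive", "super-TAD"] /
         sum(tab["inactive", ]),
       active_in_inter = tab["active", "inter-super-TAD"] /
         sum(tab["active", ]))
}
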