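#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()]. Either a
#' [synthetic_design()] (the synthetic study) or a set of input paths
#' (`contacts`, `fragments`, plus optional peak/track paths) must be given.
#'
#' @param design a [synthetic_design()], or `NULL` when reading files.
#' @param contacts,fragments input paths (pairs/COO text and fragment BED)
#'   when no design is given.
#' @param caller a [caller_config()]. The gamma that annotates domains at
#'   a given size scale depends on the distance-decay shape of the data:
#'   the default here (gamma = 0.15) sits in the TAD-scale window of the
#'   synthetic design's pure power-law decay, whereas restriction-fragment
#'   fly maps, with their much shallower short-range decay, are annotated
#'   at TAD scale near gamma = 0.9 (the [caller_config()] default).
#' @param supertad_binsize bin size for super-TAD annotation (default
#'   20 kb).
#' @param supertad_gamma gamma used to tile the binned matrix before
#'   super-TAD classification (default 0.9; the fine 20 kb tiling is then
#'   classified and merged, see [call_supertads()]).
#' @param flank,window,tol boundary profile and co-localization parameters
#'   (bp).
#' @param pair_max_gap maximum gap for [pair_sites()] (bp).
#' @param n_shuffles shuffled-background replicates.
#' @param ice_tol,ice_max_iter balancing parameters.
#' @param tau major-type threshold (Z units).
#' @param size_range condensation comparison window (bp).
#' @param seed master seed; every stochastic stage derives its own sub-seed
#'   from it.
#' @param outdir output directory, or `NULL` to skip persisting artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(design = synthetic_design(), contacts = NULL,
                       fragments = NULL,
                       caller = caller_config(gamma = 0.15,
                                              max_span_bins = 600),
                       supertad_binsize = 20000, supertad_gamma = 0.9,
                       flank = 4000, window = 80,
                       tol = 2000, pair_max_gap = 200, n_shuffles = 100,
                       ice_tol = 1e-5, ice_max_iter = 200L, tau = 0.5,
                       size_range = c(5000, 20000), seed = 1,
                       outdir = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$design) && (is.null(contacts) || is.null(fragments)))
    stop("either a design or contacts + fragments paths are required")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates matrix construction, ICE balancing, TAD and super-TAD
#' annotation with the read-desert fallback, boundary statistics, insulator
#' enrichment and co-localization, border prediction, chromatin typing,
#' and TAD-interaction metrics, and returns a machine-readable report.
#' Re-running with an identical configuration (and seed) reproduces the
#' report exactly.
#'
#' @param config a [run_config()].
#' @return A `run_report` list; artifacts and `report.json` are written to
#'   `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config_seed = config$seed)
  synthetic <- !is.null(config$design)

  # --- stage: inputs -------------------------------------------------------
  if (synthetic) {
    design <- config$design
    design$seed <- config$seed
    fragments <- make_fragment_map(design)
    truth <- plant_domains(design, fragments)
    mat <- simulate_contact_matrix(design, fragments, truth)
    peaksim <- simulate_peak_track(design, truth)
    marks <- simulate_mark_signals(design, truth)
    peaks <- peaksim$peaks
    tracks <- peaksim$tracks
  } else {
    fragments <- read_fragment_map(config$fragments)
    mat <- load_contacts(config$contacts, fragments)
    truth <- NULL; peaks <- NULL; tracks <- NULL; marks <- NULL
  }
  report$n_fragments <- nrow(fragments)
  report$total_contacts <- cm_total(mat)

  # --- stage: balance ------------------------------------------------------
  mat <- ice_normalize(mat, tol = config$ice_tol,
                       max_iter = config$ice_max_iter)
  report$ice_converged <- attr(mat, "converged")

  # --- stage: call ---------------------------------------------------------
  tads <- call_domains_dp(mat, config$caller, level = "TAD")
  tads <- readdesert_fallback(mat, tads, config$caller)
  centers <- boundary_centers(tads)
  stats_tad <- domain_size_stats(tads)
  contig <- contiguity_fraction(tads)
  report$n_tads <- stats_tad$n_domains
  report$tad_median_bp <- stats_tad$median_bp
  report$tad_coverage <- stats_tad$coverage
  report$contiguity_fraction <- contig$fraction
  report$fallback_chroms <- attr(tads, "fallback_chroms")

  sup_cfg <- config$caller
  sup_cfg$max_span_bins <- NULL
  sup_cfg$gamma <- config$supertad_gamma
  supertads <- call_supertads(mat, sup_cfg, config$supertad_binsize,
                              ice_tol = config$ice_tol,
                              ice_max_iter = config$ice_max_iter)
  report$n_supertads <- nrow(supertads)
  nesting <- if (nrow(supertads)) nest_domains(tads, supertads) else NULL

  # --- stage: enrich -------------------------------------------------------
  if (!is.null(peaks)) {
    genome <- fragment_genome(fragments)
    pairsAB <- pair_sites(peaks[["BEAF-32"]], peaks[["CP190"]],
                          config$pair_max_gap)
    pairsAC <- pair_sites(peaks[["BEAF-32"]], peaks[["Chromator"]],
                          config$pair_max_gap)
    allpairs <- rbind(as.data.frame(pairsAB), as.data.frame(pairsAC))
    co_pairs <- colocalize(allpairs, centers, config$tol)
    report$pair_sites_at_borders_prop <- co_pairs$sites_at_borders_prop
    report$borders_with_pair_prop <- co_pairs$borders_hit_prop
    venn <- border_venn(peaks, centers, config$tol)
    report$borders_with_any_protein_prop <-
      1 - as.vector(venn["none"] %||% 0) / nrow(centers)
    profs <- lapply(names(peaks), function(p) {
      obs <- occupancy_profile(tracks[[p]], centers, config$flank,
                               config$window, genome)
      bg <- shuffled_background(tracks[[p]], centers, genome,
                                config$n_shuffles, seed = config$seed + 11,
                                flank = config$flank,
                                window = config$window)
      enrichment_ratio(obs, bg, config$n_shuffles, config$seed + 11)
    })
    names(profs) <- names(peaks)
    report$central_enrichment <- vapply(profs, function(p)
      p$ratio[which.min(abs(p$offset))], numeric(1))

    # --- stage: predict ----------------------------------------------------
    labels <- label_fragments(fragments, centers)
    pairtracks <- list(pairs = peaks_to_coverage(
      peak_set(allpairs$chrom, allpairs$pos - config$tol / 2,
               allpairs$pos + config$tol / 2)))
    feat_pairs <- ztransform(fragment_signal_matrix(pairtracks, fragments))
    fit_pairs <- fit_border_model(feat_pairs, labels,
                                  split_seed = config$seed + 21)
    report$auc_pair_features <- fit_pairs$auc
    if (!is.null(marks)) {
      active <- config$design$mark_groups$active
      feat_marks <- ztransform(
        fragment_signal_matrix(marks[active], fragments))
      fit_marks <- fit_border_model(feat_marks, labels,
                                    split_seed = config$seed + 21)
      report$auc_mark_features <- fit_marks$auc
    }
  }

  # --- stage: classify -----------------------------------------------------
  classes <- NULL
  if (!is.null(marks) && nrow(tads) >= 8) {
    mm <- tad_mark_enrichment(marks, tads)
    km <- kmeans_types(mm, k = 8, seed = config$seed + 31)
    classes <- assign_major_types(km$cluster, km$centers,
                                  config$design$mark_groups, config$tau)
    report$major_type_counts <- table(classes$major_type)
    if (!is.null(nesting)) {
      tl <- type_localization_test(classes, nesting)
      if (!is.null(tl)) {
        report$inactive_in_super_prop <- tl$inactive_in_super
        report$active_in_inter_prop <- tl$active_in_inter
        report$type_localization_p <- tl$p.value
      }
    }
  }

  # --- stage: interactions -------------------------------------------------
  expected <- expected_by_distance(mat)
  cond <- condensation(mat, tads, config$size_range)
  report$median_condensation <-
    stats::median(cond$condensation[cond$included], na.rm = TRUE)
  enr <- adjacent_pair_enrichment(mat, tads, expected)
  if (!is.null(classes)) {
    nts <- neighbor_type_summary(enr, classes, seed = config$seed + 41)
    report$neighbor_type_means <-
      stats::setNames(nts$mean_ratio, nts$type_pair)
  }
  if (!is.null(nesting)) {
    ctr <- supertad_contact_contrast(enr, nesting)
    report$supertad_contrast <- ctr$contrast
  }

  # --- persist -------------------------------------------------------------
  out <- list(report = report, fragments = fragments, matrix = mat,
              tads = tads, supertads = supertads, centers = centers,
              nesting = nesting, classes = classes, condensation = cond,
              adjacent_enrichment = enr, truth = truth)
  class(out) <- "run_report"
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_fragment_map(fragments, file.path(config$outdir, "fragments.bed"))
    write_domains(tads, file.path(config$outdir, "tads.bed"))
    if (nrow(supertads))
      write_domains(supertads, file.path(config$outdir, "supertads.bed"))
    utils::write.table(centers, file.path(config$outdir, "boundaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  r <- x$report
  cat("run_report:", r$n_tads, "TADs (median",
      round(r$tad_median_bp / 1000, 1), "kb, coverage",
      round(100 * r$tad_coverage, 1), "%);", r$n_supertads, "super-TADs\n")
  if (!is.null(r$contiguity_fraction))
    cat("  same-fragment junctions:",
        round(100 * r$contiguity_fraction, 1), "%\n")
  if (!is.null(r$borders_with_pair_prop))
    cat("  borders with a pair site:",
        round(100 * r$borders_with_pair_prop, 1), "%\n")
  invisible(x)
}
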