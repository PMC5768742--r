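#' Synthetic Hi-C study design
#'
#' Parameters of the seeded generators that emulate a fragment-resolution
#' Hi-C study of a compact genome: a restriction-fragment map with a target
#' median fragment length, a genome tiled by alternating super-TAD blocks
#' and inter-super-TAD strings of slightly smaller TADs,
#' power-law distance decay with multiplicative within-TAD, within-super-TAD
#' and neighbour-type contact boosts, Poisson-sampled counts, insulator peak
#' tracks enriched at planted borders, and per-TAD chromatin mark signals.
#'
#' @param genome a [genome_layout()]; default two chromosomes totalling
#'   10 Mb.
#' @param median_fragment target median restriction-fragment length (bp),
#'   default 194.
#' @param n_super cap on the number of super-TAD blocks planted, or `NULL`
#'   (default) to alternate super-TAD and inter-super-TAD blocks across the
#'   whole genome.
#' @param tads_per_super,tads_per_inter admissible TAD counts per super-TAD
#'   block and per inter-super-TAD string; the defaults (5-10 and 2-5, with
#'   the default TAD size medians) reproduce the published size medians of
#'   ~140 kb super-TADs, ~40 kb inter-super-TADs and ~13 kb TADs overall.
#' @param tad_size_median_super,tad_size_median_inter,tad_size_sdlog
#'   log-normal TAD size parameters (bp) inside the two block kinds.
#' @param alpha power-law distance-decay exponent (default 1).
#' @param within_boost within-TAD contact fold (default 4).
#' @param super_boost within-super-TAD (cross-TAD) contact fold
#'   (default 2).
#' @param neighbor_boost named folds for adjacent-TAD contacts by type pair
#'   (names like `"A-A"`, `"I-I"`; unlisted pairs are 1).
#' @param type_probs_super,type_probs_inter chromatin-type frequencies
#'   (A/I/P/U) for TADs inside super-TADs and inside inter-super-TADs.
#' @param depth expected total contact count (default 2e7).
#' @param max_range distance cap of the simulation in bp (default 300 kb);
#'   longer-range pairs carry negligible intensity under the decay and are
#'   not sampled.
#' @param border_element_prob probability that a planted border carries a
#'   border element: a BEAF-32 peak plus a CP190 or Chromator partner peak
#'   (default 0.77, the published pair co-localization rate).
#' @param border_single_prob probability that a border additionally carries
#'   a lone peak of one protein, chosen uniformly (default 0.65; together
#'   with the element probability this reproduces the published >91%
#'   any-protein border coverage without creating extra protein pairs).
#' @param background_peak_density background peaks per Mb per protein
#'   (default 100).
#' @param peak_jitter_sd Gaussian jitter of border peak positions (bp).
#' @param peak_width peak interval width (bp).
#' @param track_smooth_halfwidth half-width (bp) of the boxcar kernel
#'   turning peak calls into the smoothed occupancy signal track
#'   (default 3000).
#' @param mark_effect mean mark signal (Z units) inside TADs of the mark's
#'   type (default 3).
#' @param mark_bin mark track bin width (bp).
#' @param mark_groups mark panel, as in [default_mark_groups()].
#' @param fragment_bias add per-fragment multiplicative biases drawn
#'   log-uniform between 0.5 and 2 (exercises ICE; default FALSE).
#' @param seed base seed; each generator derives its own sub-seed from it.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(genome = genome_layout(c("chrS1", "chrS2"),
                                                    c(6e6, 4e6)),
                             median_fragment = 194,
                             n_super = NULL,
                             tads_per_super = 5:10,
                             tads_per_inter = 2:5,
                             tad_size_median_super = 16000,
                             tad_size_median_inter = 9000,
                             tad_size_sdlog = 0.35,
                             alpha = 1.0,
                             within_boost = 4,
                             super_boost = 2,
                             neighbor_boost = c("A-A" = 0.67, "I-I" = 1.5,
                                                "P-P" = 1.5),
                             type_probs_super = c(A = 0.1, I = 0.6,
                                                  P = 0.2, U = 0.1),
                             type_probs_inter = c(A = 0.7, I = 0.1,
                                                  P = 0.05, U = 0.15),
                             depth = 2e7,
                             max_range = 3e5,
                             border_element_prob = 0.77,
                             border_single_prob = 0.65,
                             background_peak_density = 100,
                             peak_jitter_sd = 100,
                             peak_width = 300,
                             track_smooth_halfwidth = 3000,
                             mark_effect = 3,
                             mark_bin = 500,
                             mark_groups = default_mark_groups(),
                             fragment_bias = FALSE,
                             seed = 1) {
  design <- as.list(environment())
  stopifnot(design$within_boost > 0, design$super_boost > 0,
            all(design$neighbor_boost > 0),
            design$border_element_prob >= 0, design$border_element_prob <= 1,
            design$depth >= 0)
  class(design) <- "synthetic_design"
  design
}

#' Generate a synthetic fragment map
#'
#' Fragment lengths are drawn i.i.d. from a geometric distribution with the
#' design's target median, then truncated so the fragments tile each
#' chromosome exactly.
#'
#' @param design a [synthetic_design()].
#' @param seed seed; defaults to a sub-seed of the design seed.
#' @return A [fragment_map()].
#' @export
make_fragment_map <- function(design, seed = design$seed + 1) {
  m <- design$median_fragment
  stopifnot(m > 0)
  p <- 1 - 0.5^(1 / m)
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(design$genome)), function(k) {
      len <- design$genome$length[k]
      if (m >= len)
        return(data.frame(chrom = design$genome$chrom[k], start = 0,
                          end = len))
      bounds <- numeric(0)
      at <- 0
      while (at < len) {
        draw <- stats::rgeom(ceiling((len - at) / m) + 100, p) + 1
        bounds <- c(bounds, at + cumsum(draw))
        at <- bounds[length(bounds)]
      }
      bounds <- bounds[bounds < len]
      data.frame(chrom = design$genome$chrom[k],
                 start = c(0, bounds), end = c(bounds, len))
    })
    df <- do.call(rbind, pieces)
    fragment_map(df$chrom, df$start, df$end, design$genome)
  })
}

#' Plant the domain structure of a synthetic genome
#'
#' Tiles each chromosome with alternating super-TAD blocks and
#' inter-super-TAD strings of contiguous TADs, snapping every domain edge
#' to a restriction-fragment boundary, and assigns chromatin types.
#'
#' @param design a [synthetic_design()].
#' @param fragments the [make_fragment_map()] result.
#' @param seed seed; defaults to a sub-seed of the design seed.
#' @return A ground-truth list: `tads` and `supertads` (fragment-axis
#'   `domain_set`s), `boundaries` (`boundary_set` of TAD junctions),
#'   `tad_type` (A/I/P/U per TAD), `tad_boost` (within-TAD fold per TAD),
#'   `tad_in_super` (logical per TAD), `frag_tad`, `frag_super`,
#'   `frag_type` (per-fragment assignments, NA outside).
#' @export
plant_domains <- function(design, fragments, seed = design$seed + 2) {
  axis <- fragment_axis(fragments)
  genome <- design$genome
  with_seed(seed, {
    tad <- list(); sup <- list()
    n_super_left <- if (is.null(design$n_super)) Inf else design$n_super
    for (k in seq_len(nrow(genome))) {
      cc <- genome$chrom[k]; len <- genome$length[k]
      fr <- fragments[fragments$chrom == cc, ]
      starts <- fr$start
      at <- 0; in_super <- TRUE
      while (at < len - 2 * design$median_fragment) {
        if (in_super) {
          ntad <- sample(design$tads_per_super, 1)
          med <- design$tad_size_median_super
          probs <- design$type_probs_super
        } else {
          ntad <- sample(design$tads_per_inter, 1)
          med <- design$tad_size_median_inter
          probs <- design$type_probs_inter
        }
        sizes <- stats::rlnorm(ntad, log(med), design$tad_size_sdlog)
        edges <- at + cumsum(sizes)
        # snap edges to fragment starts (or chromosome end)
        snap <- vapply(edges, function(e) {
          i <- findInterval(e, starts)
          cand <- c(starts[i], if (i < length(starts)) starts[i + 1] else len)
          cand[which.min(abs(cand - e))]
        }, numeric(1))
        snap <- pmin(snap, len)
        bounds <- sort(unique(c(at, snap)))
        bounds <- bounds[bounds <= len]
        if (length(bounds) < 2) break
        block_start <- at
        for (t in seq_len(length(bounds) - 1)) {
          if (bounds[t + 1] - bounds[t] < 3 * design$median_fragment) next
          tad[[length(tad) + 1]] <- data.frame(
            chrom = cc, start_bp = bounds[t], end_bp = bounds[t + 1],
            type = sample(names(probs), 1, prob = probs),
            in_super = in_super, stringsAsFactors = FALSE)
        }
        at <- bounds[length(bounds)]
        if (in_super) {
          sup[[length(sup) + 1]] <- data.frame(
            chrom = cc, start_bp = block_start, end_bp = at,
            stringsAsFactors = FALSE)
          n_super_left <- n_super_left - 1
        }
        in_super <- !in_super && n_super_left > 0
      }
    }
    tad <- do.call(rbind, tad)
    sup <- do.call(rbind, sup)
    # fragment-axis bin indices from the snapped bp edges
    frag_of <- function(chrom, pos, last = FALSE) {
      locate_fragments(fragments, chrom, pos - as.numeric(last)) + 1L
    }
    tads <- new_domain_set(
      data.frame(chrom = tad$chrom,
                 start_bin = frag_of(tad$chrom, tad$start_bp),
                 end_bin = frag_of(tad$chrom, tad$end_bp, last = TRUE),
                 start_bp = tad$start_bp, end_bp = tad$end_bp,
                 score = NA_real_, gamma_used = NA_real_,
                 stringsAsFactors = FALSE),
      "TAD", axis)
    supertads <- new_domain_set(
      data.frame(chrom = sup$chrom,
                 start_bin = frag_of(sup$chrom, sup$start_bp),
                 end_bin = frag_of(sup$chrom, sup$end_bp, last = TRUE),
                 start_bp = sup$start_bp, end_bp = sup$end_bp,
                 score = NA_real_, gamma_used = NA_real_,
                 stringsAsFactors = FALSE),
      "super-TAD", axis)
    frag_tad <- rep(NA_integer_, nrow(fragments))
    for (t in seq_len(nrow(tads)))
      frag_tad[seq.int(tads$start_bin[t], tads$end_bin[t])] <- t
    frag_super <- rep(NA_integer_, nrow(fragments))
    for (s in seq_len(nrow(supertads)))
      frag_super[seq.int(supertads$start_bin[s],
                         supertads$end_bin[s])] <- s
    list(tads = tads, supertads = supertads,
         boundaries = boundary_centers(tads),
         tad_type = tad$type,
         tad_boost = rep(design$within_boost, nrow(tads)),
         tad_in_super = tad$in_super,
         frag_tad = frag_tad, frag_super = frag_super,
         frag_type = ifelse(is.na(frag_tad), NA_character_,
                            tad$type[frag_tad]))
  })
}

#' Simulate a fragment-resolution contact matrix with planted structure
#'
#' Contact intensity for a same-chromosome fragment pair at midpoint
#' separation `d` is proportional to `d^-alpha`, multiplied by the
#' within-TAD boost when both ends share a TAD, the super-TAD boost when
#' they share a super-TAD (but not a TAD), and the type-pair neighbour
#' boost when they sit in adjacent TADs. Counts are independent Poisson
#' draws scaled so the expected total equals the design depth.
#'
#' @param design a [synthetic_design()].
#' @param fragments the fragment map.
#' @param truth a [plant_domains()] result (generated if missing).
#' @param seed seed; defaults to a sub-seed of the design seed.
#' @return A [contact_matrix()] on the fragment axis with attribute `truth`
#'   (the ground-truth list, including any planted fragment biases in
#'   `frag_bias`).
#' @export
simulate_contact_matrix <- function(design, fragments, truth = NULL,
                                    seed = design$seed + 3) {
  if (is.null(truth)) truth <- plant_domains(design, fragments)
  axis <- fragment_axis(fragments)
  n <- nrow(fragments)
  mid <- axis$table$mid
  chromcode <- match(fragments$chrom, design$genome$chrom)
  tadid <- truth$frag_tad
  supid <- truth$frag_super
  tadtype <- truth$tad_type
  nb <- design$neighbor_boost
  max_off <- min(n - 1, ceiling(design$max_range /
                                  max(design$median_fragment / 2, 1)))
  with_seed(seed, {
    frag_bias <- if (isTRUE(design$fragment_bias))
      exp(stats::runif(n, log(0.5), log(2))) else rep(1, n)
    lambda_for <- function(d) {
      i <- seq_len(n - d); j <- i + d
      ok <- chromcode[i] == chromcode[j]
      i <- i[ok]; j <- j[ok]
      dist <- mid[j] - mid[i]
      keep <- dist > 0 & dist <= design$max_range
      i <- i[keep]; j <- j[keep]; dist <- dist[keep]
      if (!length(i)) return(NULL)
      w <- dist^(-design$alpha)
      ti <- tadid[i]; tj <- tadid[j]
      same_tad <- !is.na(ti) & !is.na(tj) & ti == tj
      w[same_tad] <- w[same_tad] * truth$tad_boost[ti[same_tad]]
      same_sup <- !same_tad & !is.na(supid[i]) & !is.na(supid[j]) &
        supid[i] == supid[j]
      w[same_sup] <- w[same_sup] * design$super_boost
      adj <- !is.na(ti) & !is.na(tj) & tj == ti + 1L
      if (any(adj) && length(nb)) {
        key <- paste0(pmin(tadtype[ti[adj]], tadtype[tj[adj]]), "-",
                      pmax(tadtype[ti[adj]], tadtype[tj[adj]]))
        f <- nb[key]
        f[is.na(f)] <- 1
        w[adj] <- w[adj] * f
      }
      w <- w * frag_bias[i] * frag_bias[j]
      list(i = i, j = j, w = w)
    }
    total <- 0
    for (d in seq_len(max_off)) {
      lam <- lambda_for(d)
      if (is.null(lam)) break    # every pair at this offset is out of range
      total <- total + sum(lam$w)
    }
    K <- if (total > 0) design$depth / total else 0
    ii <- vector("list", max_off); jj <- ii; xx <- ii
    for (d in seq_len(max_off)) {
      lam <- lambda_for(d)
      if (is.null(lam)) break
      x <- stats::rpois(length(lam$w), K * lam$w)
      nz <- x > 0
      if (any(nz)) {
        ii[[d]] <- lam$i[nz]; jj[[d]] <- lam$j[nz]; xx[[d]] <- x[nz]
      }
    }
    mat <- contact_matrix(unlist(ii), unlist(jj), unlist(xx), axis)
    truth$frag_bias <- frag_bias
    attr(mat, "truth") <- truth
    attr(mat, "n_pairs") <- cm_total(mat)
    mat
  })
}

#' Simulate insulator peak calls and occupancy tracks
#'
#' Plants border elements (a BEAF-32 peak plus a CP190 or Chromator partner
#' peak) at each TAD boundary with the design's element probability, adds
#' independent per-protein border peaks and uniform background peaks, and
#' derives a coverage signal track per protein.
#'
#' @param design a [synthetic_design()].
#' @param truth a [plant_domains()] result.
#' @param seed seed; defaults to a sub-seed of the design seed.
#' @return List with `peaks` (named list of [peak_set()]), `tracks` (named
#'   list of [signal_track()]), `element_border` (logical per boundary:
#'   carries a planted pair), and `pair_positions` (bp of planted pair
#'   sites).
#' @export
simulate_peak_track <- function(design, truth, seed = design$seed + 4) {
  proteins <- c("BEAF-32", "CP190", "Chromator")
  ctr <- truth$boundaries
  genome <- design$genome
  with_seed(seed, {
    nb <- nrow(ctr)
    element <- stats::runif(nb) < design$border_element_prob
    partner <- sample(c("CP190", "Chromator"), nb, replace = TRUE)
    single <- stats::runif(nb) < design$border_single_prob
    single_protein <- sample(proteins, nb, replace = TRUE)
    half <- design$peak_width / 2
    add_peaks <- function(chrom, pos) {
      lens <- stats::setNames(genome$length, genome$chrom)[chrom]
      pos <- pmin(pmax(pos, half), lens - half)
      data.frame(chrom = chrom, start = pos - half, end = pos + half,
                 summit = pos, stringsAsFactors = FALSE)
    }
    out <- list()
    for (p in proteins) {
      at_border <- if (p == "BEAF-32") element else element & partner == p
      sel <- at_border | (single & single_protein == p)
      bp <- if (any(sel))
        add_peaks(ctr$chrom[sel],
                  round(ctr$pos[sel] +
                          stats::rnorm(sum(sel), 0, design$peak_jitter_sd)))
      else NULL
      bg <- do.call(rbind, lapply(seq_len(nrow(genome)), function(k) {
        nbg <- stats::rpois(1, design$background_peak_density *
                              genome$length[k] / 1e6)
        if (nbg == 0) return(NULL)
        add_peaks(rep(genome$chrom[k], nbg),
                  floor(stats::runif(nbg, half, genome$length[k] - half)))
      }))
      all <- rbind(bp, bg)
      out[[p]] <- peak_set(all$chrom, all$start, all$end, all$summit,
                           signal = 1, protein = p)
    }
    tracks <- lapply(out, peaks_to_coverage,
                     halfwidth = design$track_smooth_halfwidth)
    list(peaks = out, tracks = tracks, element_border = element,
         element_partner = partner,
         pair_positions = ctr[element, , drop = FALSE])
  })
}

#' Coverage signal track of a peak set
#'
#' The number of peaks covering each base pair, as a piecewise-constant
#' [signal_track()]. With `halfwidth` set, each peak instead contributes a
#' boxcar of that half-width around its summit, i.e. a smoothed peak
#' density.
#'
#' @param peaks a [peak_set()].
#' @param halfwidth half-width (bp) of the per-peak boxcar around the
#'   summit, or `NULL` (default) to use the raw peak intervals.
#' @return A [signal_track()].
#' @export
peaks_to_coverage <- function(peaks, halfwidth = NULL) {
  if (!is.null(halfwidth)) {
    peaks <- data.frame(chrom = peaks$chrom,
                        start = pmax(peaks$summit - halfwidth, 0),
                        end = peaks$summit + halfwidth)
  }
  parts <- lapply(unique(peaks$chrom), function(cc) {
    p <- peaks[peaks$chrom == cc, ]
    pos <- sort(unique(c(p$start, p$end)))
    delta <- numeric(length(pos))
    ev <- rowsum(c(rep(1, nrow(p)), rep(-1, nrow(p))),
                 c(match(p$start, pos), match(p$end, pos)))
    delta[as.integer(rownames(ev))] <- ev[, 1]
    depth <- cumsum(delta)[-length(pos)]
    keep <- depth > 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = cc, start = pos[-length(pos)][keep],
               end = pos[-1][keep], value = depth[keep])
  })
  df <- do.call(rbind, parts)
  signal_track(df$chrom, df$start, df$end, df$value)
}

#' Simulate chromatin mark signal tracks
#'
#' Bins the genome at the design's mark bin width; within a TAD of type T,
#' marks belonging to T's group get mean `mark_effect` (Z units), all other
#' marks mean 0, with unit Gaussian noise everywhere.
#'
#' @param design a [synthetic_design()].
#' @param truth a [plant_domains()] result.
#' @param seed seed; defaults to a sub-seed of the design seed.
#' @return Named list of [signal_track()] objects, one per mark.
#' @export
simulate_mark_signals <- function(design, truth, seed = design$seed + 5) {
  genome <- design$genome
  groups <- design$mark_groups
  marks <- unlist(groups, use.names = FALSE)
  group_of <- rep(names(groups), lengths(groups))
  type_group <- c(A = "active", I = "inactive", P = "polycomb", U = "none")
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(k) {
    len <- genome$length[k]
    nb <- ceiling(len / design$mark_bin)
    starts <- (seq_len(nb) - 1) * design$mark_bin
    data.frame(chrom = genome$chrom[k], start = starts,
               end = pmin(starts + design$mark_bin, len),
               stringsAsFactors = FALSE)
  }))
  binmid <- (bins$start + bins$end) / 2
  bin_type <- rep(NA_character_, nrow(bins))
  for (cc in unique(bins$chrom)) {
    td <- truth$tads[truth$tads$chrom == cc, ]
    tt <- truth$tad_type[truth$tads$chrom == cc]
    sel <- bins$chrom == cc
    if (!nrow(td)) next
    idx <- findInterval(binmid[sel], td$start_bp)
    v <- rep(NA_character_, sum(sel))
    ok <- idx > 0
    ok[ok] <- binmid[sel][ok] < td$end_bp[idx[ok]]
    v[ok] <- tt[idx[ok]]
    bin_type[sel] <- v
  }
  with_seed(seed, {
    out <- lapply(seq_along(marks), function(m) {
      mu <- ifelse(!is.na(bin_type) &
                     type_group[bin_type] == group_of[m],
                   design$mark_effect, 0)
      signal_track(bins$chrom, bins$start, bins$end,
                   stats::rnorm(nrow(bins), mu, 1))
    })
    names(out) <- marks
    out
  })
}
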