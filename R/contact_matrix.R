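#' Sparse Hi-C contact matrix
#'
#' A symmetric, non-negative contact-count matrix over an axis of restriction
#' fragments or fixed-size bins. Counts are stored as a sparse symmetric
#' matrix (upper triangle); rows with zero total coverage are masked.
#' Balancing weights (see [ice_normalize()]) are carried in `bias`, with
#' `balanced[i,j] = counts[i,j] / (bias[i] * bias[j])`.
#'
#' @param i,j 1-based axis indices of the non-zero entries (any order;
#'   symmetrised internally).
#' @param x contact counts, non-negative.
#' @param axis an axis as returned by [fragment_axis()] or [bin_axis()].
#' @return A `contact_matrix` object: list with elements `counts`
#'   (`dsCMatrix`), `axis`, `bias` (or `NULL`), `mask` (logical).
#' @export
contact_matrix <- function(i, j, x, axis) {
  n <- nrow(axis$table)
  if (length(x) && any(x < 0)) stop("contact counts must be non-negative")
  ii <- pmin(i, j); jj <- pmax(i, j)
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(x),
                                 dims = c(n, n), symmetric = TRUE)
  new_contact_matrix(counts, axis)
}

new_contact_matrix <- function(counts, axis, bias = NULL) {
  counts <- methods::as(counts, "symmetricMatrix")
  mask <- Matrix::rowSums(counts) == 0
  out <- list(counts = counts, axis = axis, bias = bias, mask = mask)
  class(out) <- "contact_matrix"
  out
}

#' Axis constructors for contact matrices
#'
#' `fragment_axis` wraps a [fragment_map()]; `bin_axis` tiles every
#' chromosome of a genome layout with fixed-size bins (the final bin of a
#' chromosome may be shorter).
#'
#' @param fragments a [fragment_map()].
#' @param genome a [genome_layout()].
#' @param binsize bin size in bp.
#' @return An axis object: list with `kind` ("fragment" or "bin"), `table`
#'   (data frame chrom/start/end/mid, one row per matrix row), `genome`, and
#'   `binsize` for bin axes.
#' @export
fragment_axis <- function(fragments) {
  stopifnot(inherits(fragments, "fragment_map"))
  tab <- data.frame(chrom = fragments$chrom, start = fragments$start,
                    end = fragments$end,
                    mid = fragment_midpoints(fragments),
                    stringsAsFactors = FALSE)
  list(kind = "fragment", table = tab, genome = fragment_genome(fragments),
       fragments = fragments, binsize = NULL)
}

#' @rdname fragment_axis
#' @export
bin_axis <- function(genome, binsize) {
  stopifnot(binsize > 0)
  tabs <- lapply(seq_len(nrow(genome)), function(k) {
    len <- genome$length[k]
    nb <- ceiling(len / binsize)
    starts <- (seq_len(nb) - 1) * binsize
    data.frame(chrom = genome$chrom[k], start = starts,
               end = pmin(starts + binsize, len), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$mid <- (tab$start + tab$end) / 2
  list(kind = "bin", table = tab, genome = genome, fragments = NULL,
       binsize = binsize)
}

#' @exportS3Method base::print
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$counts), "x", ncol(x$counts), x$axis$kind,
      "axis;", length(cm_triplets(x)$x), "stored entries; total",
      format(cm_total(x), big.mark = ","),
      if (!is.null(x$bias)) "; balanced" else "", "\n", sep = " ")
  invisible(x)
}

# Upper-triangle triplets (i <= j, 1-based) of the stored counts.
cm_triplets <- function(mat) {
  tm <- methods::as(mat$counts, "TsparseMatrix")
  list(i = tm@i + 1L, j = tm@j + 1L, x = tm@x)
}

#' Total contact count of a matrix
#'
#' Sum of all pair counts (upper triangle plus diagonal, i.e. each contact
#' counted once).
#' @param mat a [contact_matrix()].
#' @return numeric scalar.
#' @export
cm_total <- function(mat) sum(cm_triplets(mat)$x)

# Per-row totals with each contact counted at both ends (diagonal once).
cm_marginals <- function(mat, balanced = FALSE) {
  m <- if (balanced) balanced_counts(mat) else mat$counts
  as.vector(Matrix::rowSums(m))
}

#' Balanced counts of a contact matrix
#'
#' @param mat a [contact_matrix()] carrying a bias vector (after
#'   [ice_normalize()]).
#' @return A sparse symmetric matrix of balanced counts.
#' @export
balanced_counts <- function(mat) {
  if (is.null(mat$bias)) stop("matrix has no balancing weights; run ice_normalize()")
  b <- mat$bias
  b[is.na(b)] <- 1  # masked rows have no entries anyway
  out <- mat$counts
  tr <- cm_triplets(mat)
  out@x <- tr$x / (b[tr$i] * b[tr$j])
  out
}

# Row indices of a chromosome block on the axis.
cm_chrom_rows <- function(mat, chrom) which(mat$axis$table$chrom == chrom)

#' Load fragment-level contacts
#'
#' Reads either a pairs-like text file with columns `chrom1 pos1 chrom2 pos2`
#' (header lines starting with `#` ignored) or a 3-column COO file
#' `i j count` of 0-based fragment indices, and accumulates counts on the
#' fragment axis. Rows with zero total coverage are masked.
#'
#' @param path input file.
#' @param fragments the [fragment_map()] defining the axis.
#' @return A [contact_matrix()] on the fragment axis, with attribute
#'   `n_pairs` (total input pair count).
#' @export
load_contacts <- function(path, fragments) {
  axis <- fragment_axis(fragments)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) {
    mat <- contact_matrix(integer(0), integer(0), numeric(0), axis)
    attr(mat, "n_pairs") <- 0
    return(mat)
  }
  fields <- strsplit(trimws(lines[lineno]), "[ \t]+")
  nf <- lengths(fields)
  if (all(nf == 3)) {
    m <- matrix(as.numeric(unlist(fields)), ncol = 3, byrow = TRUE)
    n <- nrow(axis$table)
    if (any(m[, 1] < 0 | m[, 1] >= n | m[, 2] < 0 | m[, 2] >= n)) {
      bad <- which(m[, 1] < 0 | m[, 1] >= n | m[, 2] < 0 | m[, 2] >= n)[1]
      stop("fragment index out of range at line ", lineno[bad])
    }
    mat <- contact_matrix(m[, 1] + 1, m[, 2] + 1, m[, 3], axis)
    attr(mat, "n_pairs") <- sum(m[, 3])
    return(mat)
  }
  if (!all(nf >= 4)) stop("unrecognized contact file format: ", path)
  c1 <- vapply(fields, `[`, character(1), 1)
  p1 <- as.numeric(vapply(fields, `[`, character(1), 2))
  c2 <- vapply(fields, `[`, character(1), 3)
  p2 <- as.numeric(vapply(fields, `[`, character(1), 4))
  what <- paste0("line ", lineno)
  fi <- locate_fragments(fragments, c1, p1, what)
  fj <- locate_fragments(fragments, c2, p2, what)
  mat <- contact_matrix(fi + 1, fj + 1, rep(1, length(fi)), axis)
  attr(mat, "n_pairs") <- length(fi)
  mat
}

#' Bin a fragment-resolution matrix to fixed-size bins
#'
#' Each fragment is assigned to the bin containing its midpoint; counts are
#' aggregated, conserving the grand total exactly.
#'
#' @param mat a [contact_matrix()].
#' @param binsize target bin size in bp.
#' @return A [contact_matrix()] on a [bin_axis()].
#' @export
bin_matrix <- function(mat, binsize) {
  axis <- bin_axis(mat$axis$genome, binsize)
  rowmap <- axis_bin_of(mat$axis$table, axis)
  tr <- cm_triplets(mat)
  out <- contact_matrix(rowmap[tr$i], rowmap[tr$j], tr$x, axis)
  attr(out, "n_pairs") <- attr(mat, "n_pairs")
  out
}

# Map axis rows (by midpoint) to rows of a bin axis over the same genome.
axis_bin_of <- function(table, binaxis) {
  genome <- binaxis$genome
  nbins <- vapply(genome$length, function(l) ceiling(l / binaxis$binsize),
                  numeric(1))
  offs <- c(0, cumsum(nbins))[seq_len(nrow(genome))]
  names(offs) <- genome$chrom
  as.integer(offs[table$chrom] + floor(table$mid / binaxis$binsize) + 1)
}

#' ICE matrix balancing
#'
#' Iterative correction: multiplicative per-row biases are estimated so that
#' all unmasked rows of the balanced matrix have equal sums. Each iteration
#' divides by the outer product of the current row-sum vector (normalised to
#' mean 1 over unmasked rows); convergence is declared when the maximum
#' relative deviation of the balanced row sums falls below `tol`.
#'
#' @param mat a [contact_matrix()]; rows with zero coverage are masked and
#'   excluded.
#' @param tol relative row-sum deviation threshold (default `1e-5`).
#' @param max_iter maximum number of iterations; non-convergence is flagged
#'   (attribute `converged`) with a warning, never silent.
#' @return The matrix with `bias` filled in (NA for masked rows), plus
#'   attributes `converged` and `iterations`.
#' @export
ice_normalize <- function(mat, tol = 1e-5, max_iter = 200L) {
  A <- mat$counts
  n <- nrow(A)
  unm <- !mat$mask
  if (!any(unm)) {
    mat$bias <- rep(NA_real_, n)
    attr(mat, "converged") <- TRUE
    attr(mat, "iterations") <- 0L
    return(mat)
  }
  b <- rep(1, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- as.vector(A %*% (1 / b)) / b     # balanced row sums
    srel <- s / mean(s[unm])
    dev <- max(abs(srel[unm] - 1))
    b[unm] <- b[unm] * srel[unm]
    if (dev < tol) { converged <- TRUE; break }
  }
  b[!unm] <- NA_real_
  mat$bias <- b
  attr(mat, "converged") <- converged
  attr(mat, "iterations") <- it
  if (!converged)
    warning("ICE did not converge after ", max_iter, " iterations (max dev ",
            signif(max(abs(srel[unm] - 1)), 3), ")")
  mat
}

#' Estimate map resolution (Rao convention)
#'
#' The map resolution is the smallest candidate bin size at which at least
#' `fraction` of the assayable bins (bins containing at least one axis row)
#' accumulate at least `min_contacts` total contacts.
#'
#' @param mat a [contact_matrix()].
#' @param candidate_binsizes ascending candidate bin sizes in bp.
#' @param min_contacts minimum per-bin contact total (default 1000).
#' @param fraction required fraction of qualifying bins (default 0.8).
#' @return The selected bin size (bp), with attributes `fractions` (per
#'   candidate) and `flagged` (`TRUE` when no candidate qualified and the
#'   largest was returned).
#' @export
estimate_map_resolution <- function(mat, candidate_binsizes,
                                    min_contacts = 1000, fraction = 0.8) {
  stopifnot(!is.unsorted(candidate_binsizes))
  marg <- cm_marginals(mat)
  fracs <- vapply(candidate_binsizes, function(bs) {
    baxis <- bin_axis(mat$axis$genome, bs)
    rowmap <- axis_bin_of(mat$axis$table, baxis)
    tot <- numeric(nrow(baxis$table))
    agg <- rowsum(marg, rowmap)
    tot[as.integer(rownames(agg))] <- agg[, 1]
    eligible <- seq_len(nrow(baxis$table)) %in% rowmap
    mean(tot[eligible] >= min_contacts)
  }, numeric(1))
  ok <- which(fracs >= fraction)
  if (length(ok)) {
    res <- candidate_binsizes[ok[1]]
    flagged <- FALSE
  } else {
    res <- candidate_binsizes[length(candidate_binsizes)]
    flagged <- TRUE
  }
  attr(res, "fractions") <- stats::setNames(fracs, candidate_binsizes)
  attr(res, "flagged") <- flagged
  res
}

#' Pearson correlation between two replicate matrices
#'
#' Both matrices are binned to `binsize`; the correlation is computed over
#' the union of non-zero upper-triangle entries of the two binned matrices.
#'
#' @param matA,matB [contact_matrix()] objects on the same axis.
#' @param binsize bin size for the comparison (default 20 kb).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
replicate_correlation <- function(matA, matB, binsize = 20000) {
  stopifnot(identical(matA$axis$table$chrom, matB$axis$table$chrom))
  a <- bin_matrix(matA, binsize)
  b <- bin_matrix(matB, binsize)
  ta <- cm_triplets(a); tb <- cm_triplets(b)
  n <- nrow(a$counts)
  ka <- (ta$i - 1) * n + ta$j
  kb <- (tb$i - 1) * n + tb$j
  keys <- union(ka, kb)
  if (length(keys) < 3) {
    warning("fewer than 3 non-zero binned entries; correlation undefined")
    return(NA_real_)
  }
  va <- numeric(length(keys)); va[match(ka, keys)] <- ta$x
  vb <- numeric(length(keys)); vb[match(kb, keys)] <- tb$x
  stats::cor(va, vb)
}

#' QC summary of a contact map
#'
#' @param mat a [contact_matrix()].
#' @param replicate optional second matrix for replicate correlation.
#' @param candidate_binsizes candidates for [estimate_map_resolution()].
#' @param cor_binsize bin size for [replicate_correlation()].
#' @return List with `map_resolution`, `replicate_correlation` (or `NA`),
#'   `total_valid_pairs`.
#' @export
qc_report <- function(mat, replicate = NULL,
                      candidate_binsizes = c(200, 500, 1000, 2000, 5000,
                                             10000, 20000),
                      cor_binsize = 20000) {
  res <- estimate_map_resolution(mat, candidate_binsizes)
  rc <- if (is.null(replicate)) NA_real_ else
    replicate_correlation(mat, replicate, cor_binsize)
  list(map_resolution = as.numeric(res),
       map_resolution_flagged = attr(res, "flagged"),
       replicate_correlation = rc,
       total_valid_pairs = cm_total(mat))
}

#' Persist / load a contact matrix as COO text plus a JSON sidecar
#'
#' `write_contact_matrix` writes `<prefix>.coo` (0-based `i j count`) and
#' `<prefix>.json` (axis kind, bin size, genome, mask, bias).
#'
#' @param mat a [contact_matrix()].
#' @param prefix path prefix for the two files.
#' @param fragments the [fragment_map()] to rebuild a fragment axis
#'   (required when the stored axis kind is "fragment").
#' @return `write_contact_matrix` returns `prefix` invisibly;
#'   `read_contact_matrix` returns a [contact_matrix()].
#' @export
write_contact_matrix <- function(mat, prefix) {
  tr <- cm_triplets(mat)
  utils::write.table(data.frame(tr$i - 1L, tr$j - 1L, tr$x),
                     paste0(prefix, ".coo"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- list(kind = mat$axis$kind, binsize = mat$axis$binsize,
               genome = list(chrom = mat$axis$genome$chrom,
                             length = mat$axis$genome$length),
               n = nrow(mat$counts), bias = mat$bias,
               mask = which(mat$mask) - 1L)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(prefix, fragments = NULL) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  genome <- genome_layout(side$genome$chrom, side$genome$length)
  axis <- if (identical(side$kind, "fragment")) {
    if (is.null(fragments)) stop("fragment-axis matrix requires `fragments`")
    fragment_axis(fragments)
  } else {
    bin_axis(genome, side$binsize)
  }
  coo <- utils::read.table(paste0(prefix, ".coo"), sep = "\t")
  mat <- contact_matrix(coo[[1]] + 1, coo[[2]] + 1, coo[[3]], axis)
  if (!is.null(side$bias) && length(side$bias)) {
    bias <- as.numeric(side$bias)
    bias[bias == -1] <- NA  # JSON null round-trip guard
    mat$bias <- bias
  }
  mat
}
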