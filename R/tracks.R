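#' Binned continuous signal track
#'
#' A piecewise-constant occupancy signal (bedGraph-like): non-overlapping
#' 0-based half-open intervals with a numeric value. Regions not covered by
#' any interval have value zero.
#'
#' @param chrom,start,end,value interval vectors.
#' @return A `signal_track` data frame, sorted by chromosome then start.
#' @export
signal_track <- function(chrom, start, end, value) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("track intervals must have positive width")
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), ]
  for (cc in unique(df$chrom)) {
    sub <- df[df$chrom == cc, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping track intervals on ", cc)
  }
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Read / write bedGraph signal tracks
#' @param path file path.
#' @param track a [signal_track()].
#' @return `read_bedgraph` returns a [signal_track()].
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  df <- utils::read.table(text = lines[keep], sep = "\t")
  signal_track(df[[1]], df[[2]], df[[3]], df[[4]])
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(
    data.frame(track$chrom,
               format(track$start, scientific = FALSE, trim = TRUE),
               format(track$end, scientific = FALSE, trim = TRUE),
               track$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Per-chromosome integrator of a signal track. Returns a function
# F(chrom, pos) = integral of the track value over [0, pos), vectorised.
# Uncovered regions integrate as zero.
track_integrator <- function(track) {
  parts <- split(track[, c("start", "end", "value")], track$chrom)
  parts <- lapply(parts, function(p) {
    p <- p[order(p$start), ]
    list(s = p$start, e = p$end, v = p$value,
         cumend = cumsum(p$value * (p$end - p$start)))
  })
  function(chrom, pos) {
    out <- numeric(length(pos))
    for (cc in unique(chrom)) {
      pp <- parts[[cc]]
      sel <- chrom == cc
      if (is.null(pp)) next
      p <- pos[sel]
      idx <- findInterval(p, pp$s)
      val <- numeric(length(p))
      pos_in <- idx > 0
      if (any(pos_in)) {
        i <- idx[pos_in]
        val[pos_in] <- pp$cumend[i] - pp$v[i] * pmax(0, pp$e[i] - p[pos_in])
      }
      out[sel] <- val
    }
    out
  }
}

#' Insulator peak set
#'
#' Peak intervals with summits, as from narrowPeak calls.
#'
#' @param chrom,start,end interval vectors (0-based half-open).
#' @param summit summit positions (bp); defaults to interval midpoints.
#' @param signal per-peak signal values (arbitrary units).
#' @param protein label of the profiled protein.
#' @return A `peak_set` data frame with attribute `protein`.
#' @export
peak_set <- function(chrom, start, end, summit = NULL, signal = 1,
                     protein = "peak") {
  if (is.null(summit)) summit <- floor((start + end) / 2)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), summit = as.numeric(summit),
                   signal = as.numeric(signal), stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("peaks must have positive width")
  if (any(df$summit < df$start | df$summit > df$end))
    stop("summit outside peak interval")
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), ]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  attr(df, "protein") <- protein
  df
}

#' Read peaks from BED6+ / narrowPeak
#'
#' For 10-column narrowPeak input the summit is `start + column 10` (unless
#' that offset is -1); otherwise the interval midpoint.
#'
#' @param path file path.
#' @param protein protein label.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, protein = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#")
  summit <- if (ncol(df) >= 10) {
    off <- df[[10]]
    ifelse(off >= 0, df[[2]] + off, floor((df[[2]] + df[[3]]) / 2))
  } else floor((df[[2]] + df[[3]]) / 2)
  sig <- if (ncol(df) >= 7) df[[7]] else if (ncol(df) >= 5) df[[5]] else 1
  peak_set(df[[1]], df[[2]], df[[3]], summit, sig, protein)
}

#' @rdname read_peaks
#' @param peaks a [peak_set()].
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom,
                   format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   attr(peaks, "protein"), peaks$signal, ".", peaks$signal,
                   -1, -1,
                   format(peaks$summit - peaks$start, scientific = FALSE,
                          trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Save and restore the RNG state around seeded operations so that seeded
# helpers do not disturb the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}
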