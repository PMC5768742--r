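#' Genome layout
#'
#' An ordered set of chromosomes with their lengths. This is the coordinate
#' system underlying fragment maps, contact matrices, signal tracks and peak
#' sets. All coordinates in the package are 0-based, half-open, as in the BED
#' family of formats.
#'
#' @param chrom character vector of unique chromosome names, in genome order.
#' @param length integer vector of chromosome lengths in base pairs.
#' @return A `genome_layout` object (data frame with columns `chrom`,
#'   `length`).
#' @examples
#' genome_layout(c("chr2L", "chr2R"), c(23011544, 21146708))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in size")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' @exportS3Method base::print
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp\n")
  print.data.frame(x, ...)
  invisible(x)
}

genome_total_length <- function(genome) sum(genome$length)

#' Restriction-fragment map
#'
#' Construct a fragment map: an ordered partition of each chromosome into
#' restriction fragments. Fragments must tile each chromosome without gaps or
#' overlaps (0-based, half-open intervals). Genome-wide 0-based fragment
#' indices are assigned in genome order.
#'
#' @param chrom,start,end vectors describing the fragments, sorted by
#'   chromosome then start.
#' @param genome optional [genome_layout()]; inferred from the last fragment
#'   end per chromosome when missing.
#' @return A `fragment_map` object: data frame with columns `chrom`, `start`,
#'   `end`, `frag` (0-based genome-wide index) and a `genome` attribute.
#' @export
fragment_map <- function(chrom, start, end, genome = NULL) {
  chrom <- rep(as.character(chrom), length.out = length(start))
  start <- as.numeric(start)
  end <- as.numeric(end)
  ord_levels <- unique(chrom)
  if (!is.null(genome)) {
    if (!all(ord_levels %in% genome$chrom))
      stop("fragment chromosomes missing from genome layout")
    ord_levels <- genome$chrom[genome$chrom %in% ord_levels]
  }
  o <- order(match(chrom, ord_levels), start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop("fragment ", bad, " (", chrom[bad], ":", start[bad], "-", end[bad],
         ") has non-positive length")
  }
  for (cc in ord_levels) {
    idx <- which(chrom == cc)
    s <- start[idx]; e <- end[idx]
    if (s[1] != 0)
      stop("fragments on ", cc, " do not start at 0 (row ", idx[1], ")")
    if (length(idx) > 1) {
      gap <- s[-1] - e[-length(e)]
      if (any(gap > 0)) {
        bad <- which(gap > 0)[1]
        stop("gap between fragments on ", cc, " at row ", idx[bad + 1])
      }
      if (any(gap < 0)) {
        bad <- which(gap < 0)[1]
        stop("overlapping fragments on ", cc, " at row ", idx[bad + 1])
      }
    }
    if (!is.null(genome)) {
      len <- genome$length[genome$chrom == cc]
      if (abs(e[length(e)] - len) > 0)
        stop("fragments on ", cc, " do not end at chromosome length")
    }
  }
  if (is.null(genome)) {
    lens <- vapply(ord_levels, function(cc) max(end[chrom == cc]), numeric(1))
    genome <- genome_layout(ord_levels, lens)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    frag = seq_along(chrom) - 1L, stringsAsFactors = FALSE)
  class(out) <- c("fragment_map", "data.frame")
  attr(out, "genome") <- genome
  out
}

#' @exportS3Method base::print
print.fragment_map <- function(x, ...) {
  g <- attr(x, "genome")
  cat("fragment_map:", nrow(x), "fragments on", nrow(g), "chromosome(s);",
      "median length", stats::median(x$end - x$start), "bp\n")
  invisible(x)
}

fragment_genome <- function(fragments) attr(fragments, "genome")

fragment_midpoints <- function(fragments) (fragments$start + fragments$end) / 2

#' Digest a genome in silico
#'
#' Cut each chromosome sequence at every occurrence of a restriction motif.
#' The cut convention is that cleavage occurs 5' of the recognition site on
#' the forward strand (as for DpnII at GATC), i.e. at the motif start, so
#' every fragment except the first on each chromosome begins with the motif.
#' A chromosome without any motif occurrence yields a single fragment
#' spanning it.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet], one
#'   sequence per chromosome.
#' @param motif recognition-site text, e.g. `"GATC"` for DpnII.
#' @return A [fragment_map()] with attribute `median_length`, the genome-wide
#'   median fragment length in bp.
#' @examples
#' fm <- digest_genome(c(chrA = "AAGATCAAGATCAA"), "GATC")
#' attr(fm, "median_length")
#' @export
digest_genome <- function(sequences, motif = "GATC") {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else {
    seqs <- vapply(sequences, as.character, character(1))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by chromosome")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) stop("empty sequence")
  motif <- toupper(motif)
  pieces <- lapply(names(seqs), function(cc) {
    s <- Biostrings::DNAString(seqs[[cc]])
    hits <- Biostrings::matchPattern(motif, s)
    cuts <- Biostrings::start(hits) - 1L  # 0-based cleavage positions
    cuts <- cuts[cuts > 0]                # motif at position 0 cuts nothing off
    bounds <- c(0, cuts, length(s))
    data.frame(chrom = cc, start = bounds[-length(bounds)],
               end = bounds[-1], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  genome <- genome_layout(names(seqs), nchar(seqs))
  fm <- fragment_map(df$chrom, df$start, df$end, genome)
  attr(fm, "median_length") <- stats::median(fm$end - fm$start)
  fm
}

#' Read / write a fragment map as 4-column BED
#'
#' The BED columns are chrom, start, end, fragment_index (0-based,
#' genome-wide). Reading validates the tiling invariants and rejects
#' overlapping or gapped fragments, naming the offending row.
#'
#' @param path file path.
#' @param fragments a [fragment_map()].
#' @return `read_fragment_map` returns a [fragment_map()];
#'   `write_fragment_map` returns `path` invisibly.
#' @export
read_fragment_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "frag"),
                          colClasses = c("character", "numeric", "numeric",
                                         "integer"))
  fm <- fragment_map(df$chrom, df$start, df$end)
  if (!identical(fm$frag, sort(df$frag)))
    stop("fragment indices in ", path, " are not 0..n-1 in genome order")
  fm
}

#' @rdname read_fragment_map
#' @export
write_fragment_map <- function(fragments, path) {
  stopifnot(inherits(fragments, "fragment_map"))
  utils::write.table(
    data.frame(fragments$chrom, format(fragments$start, scientific = FALSE,
                                       trim = TRUE),
               format(fragments$end, scientific = FALSE, trim = TRUE),
               fragments$frag),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Map (chrom, pos) pairs to 0-based fragment indices; errors report the
# offending element using `what` (e.g. an input line number).
locate_fragments <- function(fragments, chrom, pos, what = NULL) {
  genome <- fragment_genome(fragments)
  idx <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    gl <- genome$length[genome$chrom == cc]
    if (length(gl) == 0) {
      bad <- which(sel)[1]
      stop("unknown chromosome '", cc, "'",
           if (!is.null(what)) paste0(" at ", what[bad]) else "")
    }
    p <- pos[sel]
    if (any(p < 0 | p >= gl)) {
      bad <- which(sel)[which(p < 0 | p >= gl)[1]]
      stop("position ", pos[bad], " outside ", cc,
           if (!is.null(what)) paste0(" at ", what[bad]) else "")
    }
    sub <- fragments[fragments$chrom == cc, ]
    idx[sel] <- sub$frag[findInterval(p, sub$start)]
  }
  idx
}
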