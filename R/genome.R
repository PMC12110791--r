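#' Define a genome coordinate space
#'
#' A genome layout names the chromosomes of the working assembly and fixes
#' their lengths. Every interval the pipeline handles is validated against a
#' layout; chromosome matching is exact string match (no "chr" prefix
#' normalisation), because silent renaming corrupts overlap counts.
#'
#' All coordinates in this package are 0-based, half-open (`[start, end)`),
#' BED-style. Formats with other conventions (GFF3) are converted at the I/O
#' boundary.
#'
#' @param chrom_names Character vector of unique chromosome identifiers, in
#'   the order they should be reported.
#' @param chrom_lengths Integer-like vector of chromosome lengths in bp
#'   (all `>= 1`), parallel to `chrom_names`.
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `chrom_names` and `chrom_lengths` (a named numeric vector).
#' @examples
#' gl <- genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_size(gl)
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have the same length")
  }
  if (length(chrom_names) == 0L) stop("a genome layout needs at least one chromosome")
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (any(is.na(chrom_lengths)) || any(chrom_lengths < 1)) {
    stop("chromosome lengths must be >= 1")
  }
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = stats::setNames(chrom_lengths, chrom_names)
    ),
    class = "genome_layout"
  )
}

#' Total genome length
#'
#' @param layout A [genome_layout()].
#' @return Total length in bp (sum of chromosome lengths).
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$chrom_lengths)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosomes,",
      format(genome_size(x), big.mark = ","), "bp total\n")
  invisible(x)
}

# Internal: order a chromosome factor by layout order (or alphabetically when
# no layout is supplied).
chrom_order <- function(chroms, layout = NULL) {
  lev <- if (is.null(layout)) sort(unique(chroms)) else layout$chrom_names
  factor(chroms, levels = lev)
}

# Internal: convert a data.frame with chrom/start/end (0-based half-open)
# into a GRanges (1-based closed) for overlap queries.
df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
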