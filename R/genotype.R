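# Read-depth copy-number genotyping. For a diploid genome the copy number
# of a region is estimated as 2 * (regional mean depth / genome-wide mean
# depth); the estimate is scale-invariant in the sample's sequencing depth.

#' Genotype CNVRs from windowed depth tracks
#'
#' For each sample, a global reference depth `m` is taken over all of that
#' sample's windows; for each CNVR, the regional depth `r` is the
#' overlap-weighted mean of the counts of windows intersecting the region
#' (a window contributes in proportion to the bp it shares with the
#' region). The copy-number estimate is `2 * r / m`.
#'
#' The default reference statistic is the median window count: because CNV
#' regions cover only a small minority of windows, the median is the depth
#' of the diploid background and is not inflated or deflated by the very
#' regions being genotyped, which makes the estimator exact on noiseless
#' tracks. The plain mean (slightly biased by the CNV windows it includes)
#' is available via `stat = "mean"` for sensitivity checks.
#'
#' A CNVR with no overlapping window coverage is imputed CN = 2 and flagged
#' in the returned `mask` attribute. No GC correction is applied; a
#' per-window correction can be performed upstream on the tracks themselves.
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param tracks List of [depth_track()] objects, one per sample (named by
#'   sample, or carrying `sample_id` fields).
#' @param stat Global reference depth statistic, `"median"` (default) or
#'   `"mean"`.
#' @return Numeric matrix (rows = CNVR ids, columns = sample ids) with a
#'   logical `mask` attribute marking imputed cells. A sample whose global
#'   reference depth is zero is an error.
#' @export
genotype_cnvrs <- function(cnvrs, tracks, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- vapply(tracks, `[[`, character(1), "sample_id")
  }
  samples <- names(tracks)
  mat <- matrix(NA_real_, nrow = nrow(cnvrs), ncol = length(samples),
                dimnames = list(cnvrs$cnvr_id, samples))
  mask <- matrix(FALSE, nrow(cnvrs), length(samples),
                 dimnames = dimnames(mat))
  for (s in samples) {
    tr <- tracks[[s]]
    stopifnot(inherits(tr, "depth_track"))
    missing_chrom <- setdiff(unique(cnvrs$chrom), names(tr$counts))
    if (length(missing_chrom)) {
      stop("track for sample ", s, " does not cover chromosome(s): ",
           paste(missing_chrom, collapse = ", "))
    }
    allc <- unlist(tr$counts, use.names = FALSE)
    m <- if (stat == "median") stats::median(allc) else mean(allc)
    if (!is.finite(m) || m == 0) {
      stop("degenerate depth track for sample ", s,
           ": global reference depth is 0")
    }
    W <- tr$window_size
    for (i in seq_len(nrow(cnvrs))) {
      counts <- tr$counts[[cnvrs$chrom[i]]]
      s0 <- cnvrs$start[i]; e0 <- cnvrs$end[i]
      w_lo <- floor(s0 / W) + 1L                   # 1-based window indices
      w_hi <- min(ceiling(e0 / W), length(counts))
      if (w_lo > length(counts)) { mat[i, s] <- 2; mask[i, s] <- TRUE; next }
      idx <- w_lo:w_hi
      win_start <- (idx - 1) * W
      ov <- pmin(e0, win_start + W) - pmax(s0, win_start)
      ov <- pmax(ov, 0)
      if (sum(ov) == 0) { mat[i, s] <- 2; mask[i, s] <- TRUE; next }
      r <- sum(counts[idx] * ov) / sum(ov)
      mat[i, s] <- 2 * r / m
    }
  }
  attr(mat, "mask") <- mask
  mat
}
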