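# Vst: the copy-number analogue of Fst. For one CNVR and one population
# pair, Vst = (Vt - Vs) / Vt, where Vt is the copy-number variance over the
# pooled samples of the pair and Vs is the mean of the within-population
# variances weighted by population size. Variances use the population
# divisor (n, not n-1), the classical convention for this statistic; the
# divisor is exposed for sensitivity checks.

var_pop <- function(x, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (divisor == "n") mean((x - mean(x))^2) else stats::var(x)
}

#' Pairwise Vst per CNVR
#'
#' Computes, for every CNVR row of the copy-number matrix, the divergence
#' `Vst = (Vt - Vs)/Vt` between two populations: `Vt` is the variance of CN
#' over the pooled samples of both populations and
#' `Vs = (n1*V1 + n2*V2)/(n1 + n2)` the size-weighted mean within-population
#' variance. When `Vt = 0` (an invariant locus) Vst is defined as 0, which
#' keeps the ranking total. Vst is at most 1 and may be negative; it is
#' invariant under relabelling the two populations, under adding a constant
#' to all CN values, and under scaling them by a positive constant.
#'
#' Masked (imputed) matrix cells are included at their imputed value; a
#' message reports how many were used.
#'
#' @param mat Copy-number matrix from [genotype_cnvrs()] (rows = CNVRs,
#'   columns = samples).
#' @param popmap Population map data.frame (see [read_population_map()]).
#' @param pair Character vector of two population labels, both with at
#'   least 2 samples in the matrix.
#' @param divisor `"n"` (population variance, default) or `"n-1"`.
#' @return data.frame with `cnvr_id`, `pop_a`, `pop_b` (lexicographic),
#'   `vt`, `vs`, `vst`, `percentile_rank` (mid-rank percentile of `vst`
#'   among all CNVRs of this pair, in `[0, 100]`).
#' @export
vst_pairwise <- function(mat, popmap, pair, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  stopifnot(length(pair) == 2L, pair[1L] != pair[2L])
  s1 <- popmap$sample_id[popmap$population == pair[1L]]
  s2 <- popmap$sample_id[popmap$population == pair[2L]]
  s1 <- intersect(s1, colnames(mat)); s2 <- intersect(s2, colnames(mat))
  if (length(s1) < 2L || length(s2) < 2L) {
    stop("both populations need >= 2 samples present in the matrix (",
         pair[1L], ": ", length(s1), ", ", pair[2L], ": ", length(s2), ")")
  }
  mask <- attr(mat, "mask")
  if (!is.null(mask)) {
    used <- sum(mask[, c(s1, s2), drop = FALSE])
    if (used > 0) message(used, " masked (imputed) CN cells included in Vst")
  }
  n1 <- length(s1); n2 <- length(s2)
  m1 <- mat[, s1, drop = FALSE]; m2 <- mat[, s2, drop = FALSE]
  vt <- unname(apply(cbind(m1, m2), 1L, var_pop, divisor = divisor))
  v1 <- unname(apply(m1, 1L, var_pop, divisor = divisor))
  v2 <- unname(apply(m2, 1L, var_pop, divisor = divisor))
  vs <- (n1 * v1 + n2 * v2) / (n1 + n2)
  vst <- ifelse(vt > 0, (vt - vs) / vt, 0)
  ord <- sort(pair)
  res <- data.frame(
    cnvr_id = rownames(mat), pop_a = ord[1L], pop_b = ord[2L],
    vt = vt, vs = vs, vst = vst,
    percentile_rank = 100 * rank(vst, ties.method = "average") / length(vst),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Mean Vst over all CNVRs of one population pair
#'
#' Plain arithmetic mean including negative values.
#'
#' @param records Vst data.frame from [vst_pairwise()] (non-empty).
#' @return The mean Vst.
#' @export
mean_vst <- function(records) {
  if (nrow(records) == 0L) stop("no Vst records")
  mean(records$vst)
}

#' Outlier-calling policy for the Vst distribution
#'
#' @param mode `"top_fraction"`: take the highest `ceil(top_fraction * N)`
#'   CNVRs; or `"percentile_threshold"`: take CNVRs strictly above the given
#'   percentile of the Vst distribution.
#' @param top_fraction Fraction in (0,1) for `top_fraction` mode
#'   (default 0.05, the upper 5%).
#' @param percentile Percentile in (0,100) for threshold mode (default 98).
#' @return An `outlier_policy` object.
#' @export
outlier_policy <- function(mode = c("top_fraction", "percentile_threshold"),
                           top_fraction = 0.05, percentile = 98) {
  mode <- match.arg(mode)
  stopifnot(top_fraction > 0, top_fraction < 1,
            percentile > 0, percentile < 100)
  structure(list(mode = mode, top_fraction = top_fraction,
                 percentile = percentile), class = "outlier_policy")
}

#' Call upper-tail Vst outliers
#'
#' In `top_fraction` mode the records are sorted by decreasing Vst and the
#' top `ceil(fraction * N)` are taken; the threshold reported is the
#' smallest included Vst. In `percentile_threshold` mode the threshold is
#' the stated percentile of the Vst values (linear interpolation between
#' order statistics, `stats::quantile` type 7) and outliers are the records
#' strictly above it — if all values are equal, none exceed.
#'
#' @param records Vst data.frame for one population pair (non-empty).
#' @param policy An [outlier_policy()].
#' @return List with `outliers` (character vector of CNVR ids) and
#'   `threshold` (the Vst cutoff used).
#' @export
call_outliers <- function(records, policy = outlier_policy()) {
  stopifnot(inherits(policy, "outlier_policy"))
  N <- nrow(records)
  if (N == 0L) stop("no Vst records to call outliers from")
  if (policy$mode == "top_fraction") {
    k <- ceiling(policy$top_fraction * N)
    ord <- order(records$vst, decreasing = TRUE)
    take <- ord[seq_len(k)]
    list(outliers = records$cnvr_id[take],
         threshold = min(records$vst[take]))
  } else {
    thr <- unname(stats::quantile(records$vst, policy$percentile / 100,
                                  type = 7))
    list(outliers = records$cnvr_id[records$vst > thr], threshold = thr)
  }
}

#' Genes near outlier CNVRs
#'
#' The deduplicated, sorted union of `genes_within_1kb` over the outlier
#' CNVRs of one pair.
#'
#' @param outlier_ids Character vector of CNVR ids.
#' @param context_calls Output of [classify_context()].
#' @return Sorted character vector of gene ids.
#' @export
outlier_genes <- function(outlier_ids, context_calls) {
  hit <- context_calls$cnvr_id %in% outlier_ids
  sort(unique(unlist(context_calls$genes_within_1kb[hit], use.names = FALSE)))
}

#' Attach plotting coordinates to Vst records
#'
#' Adds `chrom` and `midpoint` columns (CNVR midpoint in bp) so the table
#' can be drawn as a Manhattan plot per population pair.
#'
#' @param records Vst data.frame.
#' @param cnvrs CNVR data.frame with matching `cnvr_id`s.
#' @return The records with `chrom` and `midpoint` columns prepended after
#'   `cnvr_id`.
#' @export
vst_manhattan_table <- function(records, cnvrs) {
  i <- match(records$cnvr_id, cnvrs$cnvr_id)
  if (anyNA(i)) stop("Vst record for unknown CNVR id")
  cbind(records[, "cnvr_id", drop = FALSE],
        data.frame(chrom = cnvrs$chrom[i],
                   midpoint = floor((cnvrs$start[i] + cnvrs$end[i]) / 2)),
        records[, setdiff(names(records), "cnvr_id"), drop = FALSE])
}
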