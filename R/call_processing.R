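# Per-call retention filters and cross-caller consensus for one sample.
# Filtering happens before consensus: the read-depth caller's quality fields
# (pval, q0) are call-level quantities, so calls are vetted individually and
# only survivors compete for cross-caller support.

#' Call-retention filter thresholds
#'
#' Defaults follow standard stringent read-depth CNV practice: keep a call
#' only if its significance p-value is below 0.001, the fraction of
#' zero-mapping-quality reads (q0) is below 0.5, and the call spans strictly
#' more than 1 kb. Calls lacking a quality field pass that condition
#' vacuously (callers that never report it are not penalised).
#'
#' @param max_pval Retain calls with `pval < max_pval` (strict).
#' @param max_q0 Retain calls with `q0 < max_q0` (strict).
#' @param min_len Retain calls with `end - start > min_len` (strict:
#'   a call of exactly `min_len` bp is removed).
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(max_pval = 0.001, max_q0 = 0.5, min_len = 1000) {
  stopifnot(max_pval > 0, max_q0 > 0, min_len >= 1)
  structure(list(max_pval = max_pval, max_q0 = max_q0, min_len = min_len),
            class = "filter_policy")
}

#' Apply retention filters to CNV calls
#'
#' Pure filter: keeps calls with (`pval` missing or `< max_pval`) and (`q0`
#' missing or `< max_q0`) and (`end - start > min_len`); input order is
#' preserved. Idempotent, and output is always a subset of input.
#'
#' @param calls Call data.frame (see [read_calls()]).
#' @param policy A [filter_policy()].
#' @return The retained calls.
#' @export
filter_calls <- function(calls, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(calls) == 0L) return(calls)
  keep <- (is.na(calls$pval) | calls$pval < policy$max_pval) &
    (is.na(calls$q0) | calls$q0 < policy$max_q0) &
    (calls$end - calls$start > policy$min_len)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus-merge policy across caller roles
#'
#' @param min_callers Minimum number of distinct callers supporting a
#'   consensus call (default 2).
#' @param min_reciprocal_overlap Two calls support each other when their
#'   overlap is at least this fraction of *both* call lengths (default 0.5).
#' @param require_same_type Only merge calls of the same SV type
#'   (default `TRUE`).
#' @param anchor_caller Optional caller role that must be present in every
#'   emitted consensus group (default `"POPRD"`, the population-aware
#'   read-depth caller used as the base set); `NULL` disables the anchor.
#' @return A `consensus_policy` object.
#' @export
consensus_policy <- function(min_callers = 2L, min_reciprocal_overlap = 0.5,
                             require_same_type = TRUE,
                             anchor_caller = "POPRD") {
  stopifnot(min_callers >= 1, min_callers <= length(CALLERS),
            min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  if (!is.null(anchor_caller)) anchor_caller <- match.arg(anchor_caller, CALLERS)
  structure(list(min_callers = as.integer(min_callers),
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 require_same_type = isTRUE(require_same_type),
                 anchor_caller = anchor_caller),
            class = "consensus_policy")
}

# union-find with path compression; small n, plain vectors
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build per-sample consensus calls across callers
#'
#' Graph merge: calls are nodes; an edge connects two calls from *different*
#' callers, on the same chromosome, of the same SV type (when
#' `require_same_type`), whose reciprocal overlap meets the policy
#' threshold. Each connected component supported by at least `min_callers`
#' distinct callers (and containing the anchor caller, if one is set) emits
#' one consensus call spanning the component's median start to median end
#' (medians of an even count are rounded down). The consensus inherits the
#' minimum `pval`, maximum `q0`, and mean `est_cn` of its members.
#'
#' @param calls Call data.frame for a single sample (column `caller`
#'   distinguishes the sources).
#' @param policy A [consensus_policy()].
#' @return Consensus calls sorted by chromosome then start, with
#'   `caller = "CONSENSUS"` and an `n_callers` support column.
#' @export
consensus_merge <- function(calls, policy = consensus_policy()) {
  stopifnot(inherits(policy, "consensus_policy"))
  out <- empty_calls()
  out$n_callers <- integer(0)
  if (nrow(calls) == 0L) return(out)
  if (length(unique(calls$sample_id)) > 1L) {
    stop("consensus_merge operates on one sample at a time")
  }
  n <- nrow(calls)
  parent <- seq_len(n)
  f <- policy$min_reciprocal_overlap
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (calls$caller[i] == calls$caller[j]) next
      if (calls$chrom[i] != calls$chrom[j]) next
      if (policy$require_same_type && calls$svtype[i] != calls$svtype[j]) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      if (ov <= 0) next
      if (ov / (calls$end[i] - calls$start[i]) >= f &&
          ov / (calls$end[j] - calls$start[j]) >= f) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  med_floor <- function(x) floor(stats::median(x))
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(idx) {
    members <- calls[idx, , drop = FALSE]
    support <- unique(members$caller)
    if (length(support) < policy$min_callers) return(NULL)
    if (!is.null(policy$anchor_caller) &&
        !policy$anchor_caller %in% support) return(NULL)
    svtype <- names(sort(table(members$svtype), decreasing = TRUE))[1L]
    data.frame(
      sample_id = members$sample_id[1L], caller = "CONSENSUS",
      chrom = members$chrom[1L],
      start = med_floor(members$start), end = med_floor(members$end),
      svtype = svtype,
      pval = if (all(is.na(members$pval))) NA_real_ else min(members$pval, na.rm = TRUE),
      q0 = if (all(is.na(members$q0))) NA_real_ else max(members$q0, na.rm = TRUE),
      est_cn = if (all(is.na(members$est_cn))) NA_real_ else mean(members$est_cn, na.rm = TRUE),
      n_callers = length(support),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(out)
  res <- do.call(rbind, rows)
  res <- res[order(chrom_order(res$chrom), res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
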