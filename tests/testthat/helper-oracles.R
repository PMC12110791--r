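# Independent brute-force oracles used to cross-check the interval and
# variance machinery. These are deliberately naive (per-base marking,
# all-pairs scans, explicit loops) and share no code with the package paths
# they validate.

toy_layout <- function(len = 1e5, n = 1L) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

make_calls <- function(start, end, svtype = "DUP", sample_id = "s1",
                       caller = "RD", chrom = "chr1", pval = NA_real_,
                       q0 = NA_real_, est_cn = NA_real_) {
  data.frame(sample_id = sample_id, caller = caller, chrom = chrom,
             start = start, end = end, svtype = svtype,
             pval = pval, q0 = q0, est_cn = est_cn,
             stringsAsFactors = FALSE)
}

# two-pass population variance, written out longhand
oracle_var_n <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}

oracle_vst <- function(x1, x2) {
  vt <- oracle_var_n(c(x1, x2))
  if (vt == 0) return(0)
  vs <- (length(x1) * oracle_var_n(x1) + length(x2) * oracle_var_n(x2)) /
    (length(x1) + length(x2))
  (vt - vs) / vt
}

# per-base union of call intervals on one small chromosome; returns regions
# with min-start/max-end and the class implied by the member calls
oracle_regions <- function(calls, chrom_len) {
  covered <- logical(chrom_len)
  for (i in seq_len(nrow(calls))) {
    covered[(calls$start[i] + 1):calls$end[i]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- list()
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    member <- calls$start < e & calls$end > s
    types <- sort(unique(calls$svtype[member]))
    cls <- if (identical(types, "DUP")) "gain"
           else if (identical(types, "DEL")) "loss" else "both"
    out[[length(out) + 1L]] <- data.frame(start = s, end = e,
                                          cnvr_class = cls,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# all-pairs consensus components via boolean transitive closure
oracle_consensus_components <- function(calls, policy) {
  n <- nrow(calls)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (calls$caller[i] == calls$caller[j]) next
      if (calls$chrom[i] != calls$chrom[j]) next
      if (policy$require_same_type && calls$svtype[i] != calls$svtype[j]) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      if (ov > 0 &&
          ov / (calls$end[i] - calls$start[i]) >= policy$min_reciprocal_overlap &&
          ov / (calls$end[j] - calls$start[j]) >= policy$min_reciprocal_overlap) {
        adj[i, j] <- TRUE
      }
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  comp
}

# exact hypergeometric upper tail by summing the pmf from binomial
# coefficients (no distribution functions)
oracle_hyper_upper <- function(k, K, N, n) {
  tot <- 0
  for (j in k:min(K, n)) {
    tot <- tot + choose(K, j) * choose(N - K, n - j)
  }
  tot / choose(N, n)
}

# small cohort config used by pipeline-level tests (same noise model as the
# defaults, fewer loci on a smaller genome so the suite stays fast)
small_sim <- function(seed = 11L, ...) {
  sim_config(seed = seed,
             genome = genome_layout(paste0("chr", 1:2), rep(2e6, 2)),
             n_shared_loci = 12L, n_divergent_loci = 6L,
             n_background_genes = 8L, ...)
}
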