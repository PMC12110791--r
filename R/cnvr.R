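# Cohort-level CNVR construction: overlapping calls from any samples are
# unioned into copy number variation regions, each region is classified by
# the SV types observed in it (gain / loss / both), and regions longer than
# their class's cap are discarded.

#' Type-specific CNVR length caps
#'
#' Regions longer than the cap for their class are discarded (not
#' truncated). Defaults: deletion-only and mixed regions must not exceed
#' 50 kb, duplication-only regions must not exceed 500 kb.
#'
#' @param max_len_loss Cap in bp for loss (deletion-only) CNVRs.
#' @param max_len_both Cap in bp for mixed CNVRs.
#' @param max_len_gain Cap in bp for gain (duplication-only) CNVRs.
#' @return A `length_policy` object.
#' @export
length_policy <- function(max_len_loss = 50000, max_len_both = 50000,
                          max_len_gain = 500000) {
  stopifnot(max_len_loss > 0, max_len_both > 0, max_len_gain > 0)
  structure(list(max_len_loss = max_len_loss, max_len_both = max_len_both,
                 max_len_gain = max_len_gain),
            class = "length_policy")
}

#' Merge calls across samples into CNVRs
#'
#' Per chromosome, calls are sorted by start and maximal sets of
#' transitively overlapping intervals (at least 1 bp shared, any SV type,
#' any sample) collapse into one region spanning the minimum start to the
#' maximum end. Coordinates are half-open, so abutting calls (e.g.
#' `[100,200)` and `[200,300)`) share no base and stay separate. Each region
#' is classified `gain` (only DUP calls), `loss` (only DEL), or `both`, then
#' regions exceeding their class's length cap are dropped and the survivors
#' get `cnvr_<k>` identifiers in genomic order. The result is
#' order-invariant in the input calls.
#'
#' @param calls Call data.frame pooled over all samples (typically the
#'   per-sample consensus calls).
#' @param policy A [length_policy()].
#' @param layout Optional [genome_layout()] fixing chromosome order.
#' @return data.frame with columns `cnvr_id`, `chrom`, `start`, `end`,
#'   `cnvr_class`, `n_carriers`, `n_calls` and a list-column `carriers`
#'   (per-sample sets of observed SV types). Attribute `n_discarded` counts
#'   regions removed by the length policy.
#' @export
build_cnvrs <- function(calls, policy = length_policy(), layout = NULL) {
  stopifnot(inherits(policy, "length_policy"))
  if (nrow(calls) == 0L) {
    out <- data.frame(cnvr_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      cnvr_class = character(0), n_carriers = integer(0),
                      n_calls = integer(0), stringsAsFactors = FALSE)
    out$carriers <- list()
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  calls <- calls[order(chrom_order(calls$chrom, layout), calls$start, calls$end), ,
                 drop = FALSE]
  regions <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    cur_start <- cc$start[1L]; cur_end <- cc$end[1L]; members <- 1L
    flush <- function(s, e, idx) {
      m <- cc[idx, , drop = FALSE]
      types <- sort(unique(m$svtype))
      cls <- if (identical(types, "DUP")) "gain"
             else if (identical(types, "DEL")) "loss" else "both"
      carriers <- lapply(split(m$svtype, m$sample_id), function(x) sort(unique(x)))
      list(chrom = ch, start = s, end = e, cnvr_class = cls,
           carriers = carriers, n_calls = nrow(m))
    }
    if (nrow(cc) > 1L) {
      for (i in 2:nrow(cc)) {
        if (cc$start[i] < cur_end) {  # >= 1 bp overlap under half-open coords
          cur_end <- max(cur_end, cc$end[i])
          members <- c(members, i)
        } else {
          regions[[length(regions) + 1L]] <- flush(cur_start, cur_end, members)
          cur_start <- cc$start[i]; cur_end <- cc$end[i]; members <- i
        }
      }
    }
    regions[[length(regions) + 1L]] <- flush(cur_start, cur_end, members)
  }
  cls <- vapply(regions, `[[`, character(1), "cnvr_class")
  len <- vapply(regions, function(r) r$end - r$start, numeric(1))
  cap <- c(gain = policy$max_len_gain, loss = policy$max_len_loss,
           both = policy$max_len_both)[cls]
  keep <- len <= cap
  kept <- regions[keep]
  out <- data.frame(
    cnvr_id = sprintf("cnvr_%d", seq_along(kept)),
    chrom = vapply(kept, `[[`, character(1), "chrom"),
    start = vapply(kept, `[[`, numeric(1), "start"),
    end = vapply(kept, `[[`, numeric(1), "end"),
    cnvr_class = vapply(kept, `[[`, character(1), "cnvr_class"),
    n_carriers = vapply(kept, function(r) length(r$carriers), integer(1)),
    n_calls = vapply(kept, `[[`, integer(1), "n_calls"),
    stringsAsFactors = FALSE
  )
  out$carriers <- lapply(kept, `[[`, "carriers")
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Summarize the CNVR landscape
#'
#' Counts per class, total and mean region length, the fraction of the
#' genome covered, and a length histogram over the half-open bins
#' `[0,2kb)`, `[2,5kb)`, `[5,10kb)`, `[10kb,Inf)`.
#'
#' `mean_len` is the floor of total length over count (integer bp, matching
#' how such averages are conventionally printed); the exact ratio is kept in
#' `mean_len_exact`. An empty CNVR set yields an all-zero summary with
#' `empty = TRUE`.
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param genome A [genome_layout()] supplying the denominator for
#'   `genome_fraction`.
#' @return A `landscape_summary` object (list).
#' @export
summarize_landscape <- function(cnvrs, genome) {
  stopifnot(inherits(genome, "genome_layout"))
  n_total <- nrow(cnvrs)
  bins <- c("[0,2kb)", "[2,5kb)", "[5,10kb)", "[10kb,Inf)")
  if (n_total == 0L) {
    return(structure(list(
      n_total = 0L, n_gain = 0L, n_loss = 0L, n_both = 0L,
      total_len = 0, mean_len = 0, mean_len_exact = 0,
      genome_fraction = 0,
      size_class_counts = stats::setNames(rep(0L, 4), bins),
      empty = TRUE), class = "landscape_summary"))
  }
  len <- cnvrs$end - cnvrs$start
  total_len <- sum(len)
  size_cut <- cut(len, breaks = c(0, 2000, 5000, 10000, Inf),
                  right = FALSE, labels = bins)
  structure(list(
    n_total = n_total,
    n_gain = sum(cnvrs$cnvr_class == "gain"),
    n_loss = sum(cnvrs$cnvr_class == "loss"),
    n_both = sum(cnvrs$cnvr_class == "both"),
    total_len = total_len,
    mean_len = floor(total_len / n_total),
    mean_len_exact = total_len / n_total,
    genome_fraction = total_len / genome_size(genome),
    size_class_counts = stats::setNames(as.integer(table(size_cut)), bins),
    empty = FALSE
  ), class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf("CNVR landscape: %d regions (%d gain / %d loss / %d both)\n",
              x$n_total, x$n_gain, x$n_loss, x$n_both))
  cat(sprintf("  total %s bp, mean %s bp, %.2f%% of genome\n",
              format(x$total_len, big.mark = ","),
              format(x$mean_len, big.mark = ","), 100 * x$genome_fraction))
  cat("  size classes:",
      paste(names(x$size_class_counts), x$size_class_counts,
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# Internal: summary as a one-row data.frame for TSV export.
landscape_as_df <- function(x) {
  data.frame(
    n_total = x$n_total, n_gain = x$n_gain, n_loss = x$n_loss,
    n_both = x$n_both, total_len = x$total_len, mean_len = x$mean_len,
    genome_fraction = x$genome_fraction,
    n_0_2kb = x$size_class_counts[[1L]], n_2_5kb = x$size_class_counts[[2L]],
    n_5_10kb = x$size_class_counts[[3L]], n_10kb_up = x$size_class_counts[[4L]],
    stringsAsFactors = FALSE
  )
}
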