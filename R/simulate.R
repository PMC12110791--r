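# Synthetic multi-population CNV cohort with known ground truth.
#
# The generator emulates the downstream products of a resequencing CNV
# study: per-sample true integer copy numbers at planted loci, noisy
# per-caller call sets (boundary jitter, false negatives, decoy false
# positives), windowed depth tracks consistent with each sample's true copy
# numbers, a gene annotation with genes deliberately placed within 1 kb of
# loci, and QTL intervals overlapping a known subset of loci. Everything is
# driven by one integer seed.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the package is validated under:
#' three populations of 7/10/10 samples on a miniature 3 x 10 Mb genome,
#' with 60 shared CNV loci and 12 population-divergent loci.
#'
#' True loci are placed on the depth-window grid (starts and lengths are
#' multiples of `window_size`) so that read-depth genotyping is exactly
#' calibrated in the noiseless limit; observed calls are de-aligned from the
#' grid by boundary jitter. Loci are kept at least 10 kb apart so that
#' jittered calls from neighbouring loci cannot merge.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param genome A [genome_layout()] (default 3 chromosomes x 10 Mb).
#' @param populations Named integer vector of samples per population
#'   (default `c(NY = 7, PN = 10, XN = 10)`).
#' @param n_shared_loci Loci with the same carrier frequency in every
#'   population (default 60).
#' @param n_divergent_loci Loci with population-contrasted copy numbers
#'   (default 12); each is assigned a target population pair in rotation,
#'   with one pair member fixed at CN 2, the other fixed at the locus's
#'   carrier CN, and the remaining population segregating at
#'   `divergent_third_freq`.
#' @param locus_length_range Log-uniform range in bp for locus lengths
#'   (default 2--20 kb; all lengths at least 2 windows so truth survives the
#'   1 kb call-length filter even after jitter).
#' @param carrier_freq_range Uniform range for shared-locus carrier
#'   frequency (default 0.3--0.9).
#' @param divergent_third_freq Carrier frequency of the non-target
#'   population at divergent loci (default 0.5).
#' @param jitter_sd SD in bp of the rounded zero-mean normal jitter applied
#'   to emitted call endpoints (default 50).
#' @param fn_rate Per-caller probability of missing a true carrier call
#'   (default 0.05).
#' @param fp_rate Decoy-call intensity: each sample/caller emits
#'   `Poisson(fp_rate * n_loci)` false calls at random positions
#'   (default 0.02).
#' @param depth_mean Expected reads per window at CN 2 (default 30).
#' @param window_size Depth window size in bp (default 1000).
#' @param depth_noise If `TRUE` (default) window counts are Poisson draws
#'   around their expectation `depth_mean * CN/2`; if `FALSE` the tracks
#'   carry the expectations themselves (the noiseless limit).
#' @param n_background_genes Genes placed away from any locus
#'   (default 30); additional genes are tied to loci (one within 1 kb of
#'   every divergent locus, and genes overlapping the first shared loci to
#'   exercise exonic/intronic contexts).
#' @param n_random_qtls,n_wide_qtls Extra QTLs placed at random (narrow) and
#'   deliberately wider than the 5 Mb span filter (defaults 4 and 2); 8
#'   QTLs are always placed over known loci.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(seed = 1L,
                       genome = genome_layout(paste0("chr", 1:3), rep(1e7, 3)),
                       populations = c(NY = 7L, PN = 10L, XN = 10L),
                       n_shared_loci = 60L,
                       n_divergent_loci = 12L,
                       locus_length_range = c(2000, 20000),
                       carrier_freq_range = c(0.3, 0.9),
                       divergent_third_freq = 0.5,
                       jitter_sd = 50,
                       fn_rate = 0.05,
                       fp_rate = 0.02,
                       depth_mean = 30,
                       window_size = 1000,
                       depth_noise = TRUE,
                       n_background_genes = 30L,
                       n_random_qtls = 4L,
                       n_wide_qtls = 2L) {
  stopifnot(inherits(genome, "genome_layout"),
            length(populations) >= 2L, all(populations >= 2L),
            !is.null(names(populations)),
            n_shared_loci >= 0, n_divergent_loci >= 0,
            locus_length_range[1L] >= 1000,
            locus_length_range[2L] >= locus_length_range[1L],
            all(carrier_freq_range >= 0), all(carrier_freq_range <= 1),
            divergent_third_freq >= 0, divergent_third_freq <= 1,
            jitter_sd >= 0, fn_rate >= 0, fn_rate <= 1, fp_rate >= 0,
            depth_mean > 0, window_size >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# vst for one vector of copy numbers, from first principles (divisor n)
locus_vst <- function(cn, groups, pair) {
  x1 <- cn[groups == pair[1L]]; x2 <- cn[groups == pair[2L]]
  vt <- var_pop(c(x1, x2))
  if (vt == 0) return(0)
  vs <- (length(x1) * var_pop(x1) + length(x2) * var_pop(x2)) /
    (length(x1) + length(x2))
  (vt - vs) / vt
}

# sorted population pairs as a list of length-2 character vectors
pop_pairs <- function(labels) {
  labels <- sort(unique(labels))
  out <- list()
  for (i in seq_len(length(labels) - 1L)) {
    for (j in (i + 1L):length(labels)) {
      out[[length(out) + 1L]] <- c(labels[i], labels[j])
    }
  }
  out
}

#' Simulate a multi-population CNV cohort with ground truth
#'
#' See [sim_config()] for the generative model. Deterministic given the
#' config seed. The per-locus `expected_vst_*` columns in the truth table
#' are computed from the assigned true copy numbers by the Vst formula
#' itself, so downstream recovery can be checked exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `cnv_cohort` with elements `truth` (data.frame),
#'   `calls` (data.frame over all samples and callers), `depth` (named list
#'   of [depth_track()]s), `genes` ([gene_models()]), `qtls` (data.frame),
#'   `popmap` (data.frame), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- config$genome
  W <- config$window_size
  min_gap <- 10000

  pops <- config$populations
  sample_ids <- unlist(lapply(names(pops), function(p)
    sprintf("%s_%02d", p, seq_len(pops[[p]]))), use.names = FALSE)
  popmap <- data.frame(
    sample_id = sample_ids,
    population = rep(names(pops), times = pops),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(popmap)

  ## ---- locus placement (window-aligned, >= min_gap apart) ----
  n_loci <- config$n_shared_loci + config$n_divergent_loci
  draw_len <- function() {
    l <- exp(stats::runif(1, log(config$locus_length_range[1L]),
                          log(config$locus_length_range[2L])))
    max(2L, round(l / W)) * W
  }
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  place_interval <- function(len, aligned = TRUE, clearance = min_gap) {
    for (try in 1:500) {
      ch <- sample(layout$chrom_names, 1L,
                   prob = layout$chrom_lengths / sum(layout$chrom_lengths))
      chlen <- layout$chrom_lengths[[ch]]
      if (chlen < len + 2 * clearance) next
      if (aligned) {
        nslots <- floor((chlen - len - clearance) / W)
        s <- sample.int(nslots, 1L) * W
      } else {
        s <- floor(stats::runif(1, clearance, chlen - len - clearance))
      }
      e <- s + len
      same <- placed[placed$chrom == ch, , drop = FALSE]
      if (nrow(same) == 0L ||
          all(s - clearance >= same$end | e + clearance <= same$start)) {
        return(list(chrom = ch, start = s, end = e))
      }
    }
    stop("could not place a locus of ", len,
         " bp; use a larger genome or fewer/shorter loci")
  }
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    loci[[i]] <- place_interval(draw_len())
    placed <- rbind(placed, as.data.frame(loci[[i]], stringsAsFactors = FALSE))
  }
  truth <- data.frame(
    locus_id = sprintf("locus_%03d", seq_len(n_loci)),
    chrom = vapply(loci, `[[`, character(1), "chrom"),
    start = vapply(loci, `[[`, numeric(1), "start"),
    end = vapply(loci, `[[`, numeric(1), "end"),
    svtype = rep(c("DUP", "DEL"), length.out = n_loci),
    divergent = rep(c(FALSE, TRUE),
                    times = c(config$n_shared_loci, config$n_divergent_loci)),
    target_pair = NA_character_,
    stringsAsFactors = FALSE
  )

  ## ---- true copy numbers ----
  draw_cn <- function(svtype) {
    if (svtype == "DUP") sample(3:6, 1L, prob = c(0.4, 0.3, 0.2, 0.1))
    else sample(0:1, 1L, prob = c(0.2, 0.8))
  }
  pairs <- pop_pairs(names(pops))
  cn <- matrix(2, nrow = n_loci, ncol = n_samp,
               dimnames = list(truth$locus_id, popmap$sample_id))
  for (i in seq_len(n_loci)) {
    level <- draw_cn(truth$svtype[i])
    if (!truth$divergent[i]) {
      f <- stats::runif(1, config$carrier_freq_range[1L],
                        config$carrier_freq_range[2L])
      carrier <- stats::runif(n_samp) < f
      if (!any(carrier)) carrier[sample.int(n_samp, 1L)] <- TRUE
      cn[i, carrier] <- level
    } else {
      pr <- pairs[[((i - config$n_shared_loci - 1L) %% length(pairs)) + 1L]]
      truth$target_pair[i] <- paste(pr, collapse = "-")
      third <- setdiff(names(pops), pr)
      cn[i, popmap$population == pr[2L]] <- level
      th <- popmap$population %in% third
      carrier <- th & stats::runif(n_samp) < config$divergent_third_freq
      cn[i, carrier] <- level
    }
  }
  for (pr in pairs) {
    truth[[paste0("expected_vst_", pr[1L], "_", pr[2L])]] <-
      apply(cn, 1L, locus_vst, groups = popmap$population, pair = pr)
  }
  cn_df <- as.data.frame(cn)
  names(cn_df) <- paste0("cn_", colnames(cn))
  truth <- cbind(truth, cn_df)
  rownames(truth) <- NULL

  ## ---- per-caller noisy call sets ----
  jit <- function(x) {
    if (config$jitter_sd == 0) x else x + round(stats::rnorm(1, 0, config$jitter_sd))
  }
  call_rows <- list()
  for (caller in CALLERS) {
    for (s in seq_len(n_samp)) {
      sid <- popmap$sample_id[s]
      for (i in seq_len(n_loci)) {
        if (cn[i, s] == 2) next
        if (config$fn_rate > 0 && stats::runif(1) < config$fn_rate) next
        chlen <- layout$chrom_lengths[[truth$chrom[i]]]
        st <- max(0, jit(truth$start[i]))
        en <- min(chlen, jit(truth$end[i]))
        if (en <= st) en <- st + 1
        noise_cn <- if (config$depth_noise)
          max(0, cn[i, s] + stats::rnorm(1, 0, 0.1)) else cn[i, s]
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          sample_id = sid, caller = caller, chrom = truth$chrom[i],
          start = st, end = en, svtype = truth$svtype[i],
          pval = if (caller == "RD") 10^-stats::runif(1, 4, 8) else NA_real_,
          q0 = if (caller == "RD") stats::runif(1, 0, 0.4) else NA_real_,
          est_cn = if (caller == "PAIRED") NA_real_ else noise_cn,
          stringsAsFactors = FALSE
        )
      }
      n_fp <- stats::rpois(1, config$fp_rate * n_loci)
      for (k in seq_len(n_fp)) {
        len <- floor(exp(stats::runif(1, log(config$locus_length_range[1L]),
                                      log(config$locus_length_range[2L]))))
        ch <- sample(layout$chrom_names, 1L)
        chlen <- layout$chrom_lengths[[ch]]
        st <- floor(stats::runif(1, 0, chlen - len))
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          sample_id = sid, caller = caller, chrom = ch,
          start = st, end = st + len,
          svtype = sample(SVTYPES, 1L),
          pval = if (caller == "RD") 10^-stats::runif(1, 2, 5) else NA_real_,
          q0 = if (caller == "RD") stats::runif(1, 0, 0.8) else NA_real_,
          est_cn = if (caller == "PAIRED") NA_real_
                   else stats::runif(1, 0.5, 4),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else empty_calls()
  calls <- calls[order(calls$sample_id, calls$caller,
                       chrom_order(calls$chrom, layout), calls$start), ,
                 drop = FALSE]
  rownames(calls) <- NULL

  ## ---- depth tracks ----
  depth <- stats::setNames(vector("list", n_samp), popmap$sample_id)
  for (s in seq_len(n_samp)) {
    counts <- list()
    for (ch in layout$chrom_names) {
      chlen <- layout$chrom_lengths[[ch]]
      nwin <- ceiling(chlen / W)
      lam <- rep(config$depth_mean, nwin)
      on_ch <- which(truth$chrom == ch & cn[, s] != 2)
      for (i in on_ch) {
        idx <- (floor(truth$start[i] / W) + 1L):min(ceiling(truth$end[i] / W), nwin)
        ws <- (idx - 1) * W
        wlen <- pmin(ws + W, chlen) - ws
        ov <- pmax(pmin(truth$end[i], ws + W) - pmax(truth$start[i], ws), 0)
        lam[idx] <- config$depth_mean *
          (ov * cn[i, s] / 2 + (wlen - ov)) / wlen
      }
      counts[[ch]] <- if (config$depth_noise) stats::rpois(nwin, lam) else lam
    }
    depth[[popmap$sample_id[s]]] <-
      depth_track(popmap$sample_id[s], W, counts, layout$chrom_lengths)
  }

  ## ---- gene annotation ----
  gene_rows <- list(); exon_rows <- list()
  add_gene <- function(chrom, start, end, strand, exons) {
    gid <- sprintf("gene_%03d", length(gene_rows) + 1L)
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      gene_id = gid, gene_name = sprintf("GENE%d", length(gene_rows) + 1L),
      chrom = chrom, start = start, end = end, strand = strand,
      biotype = "protein_coding", stringsAsFactors = FALSE)
    for (e in exons) {
      exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
        gene_id = gid, start = e[1L], end = e[2L], stringsAsFactors = FALSE)
    }
    gid
  }
  div_idx <- which(truth$divergent)
  strands <- c("+", "-")
  for (k in seq_along(div_idx)) {
    i <- div_idx[k]
    gs <- truth$end[i] + 500; ge <- gs + 3000
    add_gene(truth$chrom[i], gs, ge, strands[(k %% 2L) + 1L],
             list(c(gs, gs + 400), c(gs + 2000, gs + 2600)))
  }
  overlap_idx <- utils::head(which(!truth$divergent), 20L)
  for (k in seq_along(overlap_idx)) {
    i <- overlap_idx[k]
    gs <- max(0, truth$start[i] - 800); ge <- truth$end[i] + 800
    exons <- if (k %% 2L == 0L) {
      list(c(truth$start[i] + 100, truth$start[i] + 500))      # exonic hit
    } else {
      list(c(gs, gs + 300), c(ge - 300, ge))                    # intronic only
    }
    add_gene(truth$chrom[i], gs, ge, strands[(k %% 2L) + 1L], exons)
  }
  gene_iv <- function() {
    if (!length(gene_rows)) return(placed[0, , drop = FALSE])
    do.call(rbind, lapply(gene_rows, function(g)
      data.frame(chrom = g$chrom, start = g$start, end = g$end)))
  }
  for (k in seq_len(config$n_background_genes)) {
    len <- floor(stats::runif(1, 2000, 8000))
    occupied <- rbind(placed, gene_iv())
    for (try in 1:500) {
      ch <- sample(layout$chrom_names, 1L)
      chlen <- layout$chrom_lengths[[ch]]
      s0 <- floor(stats::runif(1, 0, chlen - len))
      same <- occupied[occupied$chrom == ch, , drop = FALSE]
      if (nrow(same) == 0L ||
          all(s0 - 2000 >= same$end | s0 + len + 2000 <= same$start)) {
        mid <- s0 + floor(len / 2)
        add_gene(ch, s0, s0 + len, sample(strands, 1L),
                 list(c(s0 + 100, mid), c(mid + 200, s0 + len - 100)))
        break
      }
    }
  }
  genes <- gene_models(do.call(rbind, gene_rows), do.call(rbind, exon_rows))

  ## ---- QTLs ----
  traits <- c("Subcutaneous fat thickness", "Longissimus muscle area",
              "Multiple birth", "Tenderness score", "Antral follicle number",
              "Body weight", "Marbling score", "Meat color")
  qtl_rows <- list()
  add_qtl <- function(chrom, start, end, trait) {
    qtl_rows[[length(qtl_rows) + 1L]] <<- data.frame(
      qtl_id = sprintf("qtl_%02d", length(qtl_rows) + 1L),
      trait_name = trait, chrom = chrom, start = start, end = end,
      stringsAsFactors = FALSE)
  }
  # spans are capped by chromosome length so the generator works on small
  # genomes too; at the default 10 Mb chromosomes the "wide" QTLs exceed the
  # 5 Mb span filter and the rest stay well under it
  qtl_loci <- truth[seq(1L, n_loci, length.out = min(8L, n_loci)), , drop = FALSE]
  for (i in seq_len(nrow(qtl_loci))) {
    chlen <- layout$chrom_lengths[[qtl_loci$chrom[i]]]
    span <- floor(stats::runif(1, min(5e5, 0.1 * chlen), min(3e6, 0.4 * chlen)))
    s0 <- max(0, qtl_loci$start[i] - floor(stats::runif(1, 0, span / 2)))
    e0 <- min(chlen, s0 + span)
    add_qtl(qtl_loci$chrom[i], s0, e0, traits[((i - 1L) %% length(traits)) + 1L])
  }
  for (k in seq_len(config$n_random_qtls)) {
    ch <- sample(layout$chrom_names, 1L)
    chlen <- layout$chrom_lengths[[ch]]
    span <- floor(stats::runif(1, min(1e6, 0.2 * chlen), min(4e6, 0.45 * chlen)))
    s0 <- floor(stats::runif(1, 0, chlen - span))
    add_qtl(ch, s0, s0 + span, sample(traits, 1L))
  }
  for (k in seq_len(config$n_wide_qtls)) {
    ch <- sample(layout$chrom_names, 1L)
    chlen <- layout$chrom_lengths[[ch]]
    span <- floor(stats::runif(1, min(6e6, 0.7 * chlen), min(8e6, 0.9 * chlen)))
    s0 <- floor(stats::runif(1, 0, chlen - span))
    add_qtl(ch, s0, s0 + span, sample(traits, 1L))
  }
  qtls <- do.call(rbind, qtl_rows)

  structure(list(truth = truth, calls = calls, depth = depth, genes = genes,
                 qtls = qtls, popmap = popmap, config = config),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf(
    "cnv_cohort: %d samples in %d populations; %d true loci (%d divergent); %d calls\n",
    nrow(x$popmap), length(unique(x$popmap$population)), nrow(x$truth),
    sum(x$truth$divergent), nrow(x$calls)))
  invisible(x)
}

#' Write / read the ground-truth locus table
#'
#' One row per planted locus: coordinates, SV type, divergence flag and
#' target pair, per-sample true copy number (`cn_<sample>` columns), and the
#' expected Vst per population pair (`expected_vst_<A>_<B>` columns,
#' recomputable from the CN columns).
#'
#' @param truth Truth data.frame from [simulate_cohort()].
#' @param path Output path.
#' @param comment Optional comment line.
#' @return `path`, invisibly.
#' @export
truth_report <- function(truth, path, comment = NULL) {
  write_tsv(truth, path, comment)
}

#' @rdname truth_report
#' @export
read_truth_report <- function(path) {
  read_tsv(path, colClasses = c(locus_id = "character"))
}

#' Match planted loci to recovered CNVRs
#'
#' For every truth locus, finds the CNVR with the largest overlap (ties
#' broken by genomic order), or `NA` when no CNVR overlaps it.
#'
#' @param truth Truth data.frame.
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @return Character vector of CNVR ids parallel to `truth` rows.
#' @export
match_truth_cnvrs <- function(truth, cnvrs) {
  out <- rep(NA_character_, nrow(truth))
  if (nrow(cnvrs) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(df_to_gr(truth), df_to_gr(cnvrs))
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(truth$end[qi], cnvrs$end[si]) - pmax(truth$start[qi], cnvrs$start[si])
  for (q in unique(qi)) {
    cand <- which(qi == q)
    out[q] <- cnvrs$cnvr_id[si[cand[which.max(ov[cand])]]]
  }
  out
}

#' Write a simulated cohort to a directory of pipeline input files
#'
#' Emits one call TSV per sample/caller (`calls_<sample>_<caller>.tsv`), one
#' depth TSV per sample (`depth_<sample>.tsv`), `genes.gff3`, `qtls.tsv`,
#' `popmap.tsv`, and `truth.tsv`.
#'
#' @param cohort A `cnv_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in cohort$popmap$sample_id) {
    for (caller in CALLERS) {
      sel <- cohort$calls$sample_id == sid & cohort$calls$caller == caller
      write_calls(cohort$calls[sel, , drop = FALSE],
                  file.path(dir, sprintf("calls_%s_%s.tsv", sid, caller)))
    }
    write_depth_track(cohort$depth[[sid]],
                      file.path(dir, sprintf("depth_%s.tsv", sid)))
  }
  write_gff3(cohort$genes, file.path(dir, "genes.gff3"))
  write_qtl_table(cohort$qtls, file.path(dir, "qtls.tsv"))
  write_population_map(cohort$popmap, file.path(dir, "popmap.tsv"))
  truth_report(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
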