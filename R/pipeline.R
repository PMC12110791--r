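# End-to-end orchestration: simulate (or ingest) -> filter/consensus ->
# CNVR -> genotype -> annotate/QTL -> Vst, as one configured, logged,
# resumable run over plain files. A stage is skipped on rerun when the md5
# of its inputs and parameters matches the manifest and its outputs exist;
# no workflow engine, just a TSV manifest.

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory for all stage products.
#' @param sim A [sim_config()] describing the synthetic cohort; its `seed`
#'   drives the run. Stage inputs are generated into `out_dir/inputs`. To
#'   run on pre-existing files, point `input_dir` at a directory laid out
#'   like [write_cohort()]'s output (then `sim` supplies only the genome
#'   layout and population names).
#' @param input_dir Optional directory of existing input files.
#' @param filter A [filter_policy()].
#' @param consensus A [consensus_policy()].
#' @param lengths A [length_policy()].
#' @param flank Gene-assignment flank in bp (default 1000).
#' @param max_qtl_span QTL span filter in bp (default 5 Mb).
#' @param outlier An [outlier_policy()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            input_dir = NULL,
                            filter = filter_policy(),
                            consensus = consensus_policy(),
                            lengths = length_policy(),
                            flank = 1000,
                            max_qtl_span = 5e6,
                            outlier = outlier_policy()) {
  stopifnot(inherits(sim, "sim_config"), inherits(filter, "filter_policy"),
            inherits(consensus, "consensus_policy"),
            inherits(lengths, "length_policy"),
            inherits(outlier, "outlier_policy"))
  structure(list(out_dir = out_dir, sim = sim, input_dir = input_dir,
                 filter = filter, consensus = consensus, lengths = lengths,
                 flank = flank, max_qtl_span = max_qtl_span,
                 outlier = outlier),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys `out_dir`, `input_dir`, `flank`, `max_qtl_span` map
#' directly; nested mappings `sim`, `filter`, `consensus`, `lengths`,
#' `outlier` override the corresponding policy defaults field by field.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, over) do.call(fun, if (is.null(over)) list() else over)
  pipeline_config(
    out_dir = y$out_dir %||% stop("config needs out_dir"),
    sim = build(sim_config, y$sim),
    input_dir = y$input_dir,
    filter = build(filter_policy, y$filter),
    consensus = build(consensus_policy, y$consensus),
    lengths = build(length_policy, y$lengths),
    flank = y$flank %||% 1000,
    max_qtl_span = y$max_qtl_span %||% 5e6,
    outlier = build(outlier_policy, y$outlier)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of arbitrary strings (serialised through a temp file)
md5_strings <- function(...) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(unlist(list(...)), tf)
  unname(tools::md5sum(tf))
}

# hash of the scientific configuration only: filesystem locations are
# run-specific and must not perturb the recorded parameter fingerprint
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$input_dir <- NULL
  md5_strings(deparse(unclass_recursive(cfg)))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Run the full CNVR/Vst pipeline
#'
#' Executes the stages in dependency order, writing each stage's products
#' plus a manifest row (stage name, input/parameter hash, outputs, row
#' count). Rerunning with unchanged inputs and configuration skips completed
#' stages; changing an upstream file or parameter invalidates that stage and
#' everything downstream of it. Every TSV product carries the configuration
#' hash in a `#` header line. Progress and row counts are logged to
#' `run.log` in the output directory (and to the console when
#' `verbose = TRUE`).
#'
#' @param config A [pipeline_config()].
#' @param verbose Echo log lines to the console (default `TRUE`).
#' @return Invisibly, the run manifest data.frame.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(config)
  hdr <- paste("config", chash)
  logf <- file.path(out, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    if (verbose) message(line)
  }
  manifest_path <- file.path(out, "manifest.tsv")
  manifest <- if (file.exists(manifest_path)) {
    read_tsv(manifest_path)
  } else {
    data.frame(stage = character(0), hash = character(0),
               outputs = character(0), n_rows = integer(0),
               stringsAsFactors = FALSE)
  }
  save_manifest <- function() write_tsv(manifest, manifest_path)
  # run one stage with skip-if-unchanged semantics
  stage <- function(name, input_files, params, outputs, n_fun, run_fun) {
    h <- md5_strings(unname(tools::md5sum(input_files)), deparse(params), chash)
    prev <- manifest[manifest$stage == name, , drop = FALSE]
    paths <- file.path(out, outputs)
    if (nrow(prev) == 1L && prev$hash == h && all(file.exists(paths))) {
      logmsg("stage ", name, ": up to date, skipped")
      return(invisible(FALSE))
    }
    marker <- paste0(paths[1L], ".partial")
    dir.create(dirname(marker), recursive = TRUE, showWarnings = FALSE)
    file.create(marker)
    ok <- FALSE
    tryCatch({
      run_fun(paths)
      ok <- TRUE
    }, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    }, finally = if (ok) unlink(marker))
    n <- n_fun()
    manifest <<- rbind(manifest[manifest$stage != name, , drop = FALSE],
                       data.frame(stage = name, hash = h,
                                  outputs = paste(outputs, collapse = ","),
                                  n_rows = n, stringsAsFactors = FALSE))
    save_manifest()
    logmsg("stage ", name, ": wrote ", paste(outputs, collapse = ", "),
           " (", n, " rows)")
    invisible(TRUE)
  }

  layout <- config$sim$genome
  ## stage 1: inputs
  in_dir <- config$input_dir
  if (is.null(in_dir)) {
    in_dir <- file.path(out, "inputs")
    stage("simulate", character(0), unclass_recursive(config$sim),
          "inputs/truth.tsv",
          n_fun = function() nrow(read_truth_report(file.path(in_dir, "truth.tsv"))),
          run_fun = function(paths) {
            cohort <- simulate_cohort(config$sim)
            write_cohort(cohort, in_dir)
          })
  }
  for (f in c("popmap.tsv", "qtls.tsv", "genes.gff3")) {
    if (!file.exists(file.path(in_dir, f))) {
      stop("input file missing at stage start: ", file.path(in_dir, f))
    }
  }
  popmap <- read_population_map(file.path(in_dir, "popmap.tsv"))
  samples <- popmap$sample_id
  call_files <- as.vector(outer(samples, CALLERS, function(s, c)
    file.path(in_dir, sprintf("calls_%s_%s.tsv", s, c))))
  depth_files <- file.path(in_dir, sprintf("depth_%s.tsv", samples))

  ## stage 2: filter + consensus
  stage("consensus", call_files,
        list(unclass_recursive(config$filter), unclass_recursive(config$consensus)),
        "consensus_calls.tsv",
        n_fun = function() nrow(read_tsv(file.path(out, "consensus_calls.tsv"))),
        run_fun = function(paths) {
          per_sample <- lapply(samples, function(sid) {
            raw <- do.call(rbind, lapply(CALLERS, function(cl)
              read_calls(file.path(in_dir, sprintf("calls_%s_%s.tsv", sid, cl)),
                         sid, cl, layout)))
            kept <- filter_calls(raw, config$filter)
            cons <- consensus_merge(kept, config$consensus)
            logmsg("  ", sid, ": ", nrow(raw), " raw -> ", nrow(kept),
                   " filtered -> ", nrow(cons), " consensus")
            cons
          })
          all_cons <- do.call(rbind, per_sample)
          df <- all_cons[, c("sample_id", "chrom", "start", "end", "svtype",
                             "pval", "q0", "est_cn", "n_callers")]
          write_tsv(df, paths[1L], hdr)
        })

  ## stage 3: CNVRs
  stage("cnvr", file.path(out, "consensus_calls.tsv"),
        unclass_recursive(config$lengths),
        c("cnvr.tsv", "cnvr.bed", "summary.tsv"),
        n_fun = function() nrow(read_cnvr_table(file.path(out, "cnvr.tsv"))),
        run_fun = function(paths) {
          cons <- read_tsv(file.path(out, "consensus_calls.tsv"))
          cnvrs <- build_cnvrs(cons, config$lengths, layout)
          logmsg("  ", nrow(cnvrs), " CNVRs kept, ",
                 attr(cnvrs, "n_discarded"), " discarded by length policy")
          write_cnvr_table(cnvrs, paths[1L], hdr)
          write_cnvr_bed(cnvrs, paths[2L], hdr)
          write_tsv(landscape_as_df(summarize_landscape(cnvrs, layout)),
                    paths[3L], hdr)
        })

  ## stage 4: genotype
  stage("genotype", c(file.path(out, "cnvr.tsv"), depth_files), list(),
        "cn_matrix.tsv",
        n_fun = function() nrow(read_cn_matrix(file.path(out, "cn_matrix.tsv"))),
        run_fun = function(paths) {
          cnvrs <- read_cnvr_table(file.path(out, "cnvr.tsv"))
          tracks <- lapply(stats::setNames(samples, samples), function(sid)
            read_depth_track(file.path(in_dir, sprintf("depth_%s.tsv", sid)), sid))
          write_cn_matrix(genotype_cnvrs(cnvrs, tracks), paths[1L], hdr)
        })

  ## stage 5: annotation + QTL
  stage("annotate",
        c(file.path(out, "cnvr.tsv"), file.path(in_dir, "genes.gff3"),
          file.path(in_dir, "qtls.tsv")),
        list(flank = config$flank, max_qtl_span = config$max_qtl_span),
        c("context.tsv", "qtl_overlap.tsv"),
        n_fun = function() nrow(read_tsv(file.path(out, "context.tsv"))),
        run_fun = function(paths) {
          cnvrs <- read_cnvr_table(file.path(out, "cnvr.tsv"))
          genes <- read_gff3(file.path(in_dir, "genes.gff3"))
          ctx <- classify_context(cnvrs, genes, config$flank)
          df <- data.frame(cnvr_id = ctx$cnvr_id,
                           context = as.character(ctx$context),
                           genes_within_1kb = vapply(ctx$genes_within_1kb,
                                                     paste, character(1),
                                                     collapse = ","),
                           stringsAsFactors = FALSE)
          write_tsv(df, paths[1L], hdr)
          qtls <- read_qtl_table(file.path(in_dir, "qtls.tsv"), layout)
          qo <- intersect_qtl(cnvrs, qtls, config$max_qtl_span)
          logmsg("  ", qo$summary$n_cnvrs_overlapping, " CNVRs overlap ",
                 qo$summary$n_qtls_overlapped, " QTLs")
          write_tsv(qo$pairs, paths[2L], hdr)
        })

  ## stage 6: Vst + outliers
  stage("vst",
        c(file.path(out, "cn_matrix.tsv"), file.path(out, "cnvr.tsv"),
          file.path(in_dir, "popmap.tsv")),
        unclass_recursive(config$outlier),
        c("vst.tsv", "outliers.tsv"),
        n_fun = function() nrow(read_vst_table(file.path(out, "vst.tsv"))),
        run_fun = function(paths) {
          mat <- read_cn_matrix(file.path(out, "cn_matrix.tsv"))
          cnvrs <- read_cnvr_table(file.path(out, "cnvr.tsv"))
          all_rec <- list(); all_out <- list()
          for (pr in pop_pairs(popmap$population)) {
            rec <- suppressMessages(vst_pairwise(mat, popmap, pr))
            logmsg("  ", pr[1L], "-", pr[2L], ": mean Vst ",
                   sprintf("%.4f", mean_vst(rec)))
            all_rec[[length(all_rec) + 1L]] <- vst_manhattan_table(rec, cnvrs)
            oc <- call_outliers(rec, config$outlier)
            all_out[[length(all_out) + 1L]] <- data.frame(
              pop_a = rec$pop_a[1L], pop_b = rec$pop_b[1L],
              cnvr_id = oc$outliers, threshold = oc$threshold,
              stringsAsFactors = FALSE)
          }
          write_vst_table(do.call(rbind, all_rec), paths[1L], hdr)
          write_tsv(do.call(rbind, all_out), paths[2L], hdr)
        })

  invisible(manifest)
}
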