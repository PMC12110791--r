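# Readers/writers for every external file the pipeline touches. One
# convention throughout: internal coordinates are 0-based half-open; GFF3
# (1-based inclusive) is converted at this boundary and nowhere else. Lines
# starting with '#' are comments in every TSV dialect here, so that pipeline
# outputs can carry a config-hash header.

CALLERS <- c("RD", "PAIRED", "POPRD")
SVTYPES <- c("DEL", "DUP")

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}

# A zero-row call table with the canonical column set.
empty_calls <- function() {
  data.frame(
    sample_id = character(0), caller = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), svtype = character(0),
    pval = numeric(0), q0 = numeric(0), est_cn = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Read one caller's CNV calls for one sample
#'
#' Parses a tab-separated call file with header columns `chrom`, `start`,
#' `end`, `svtype` and optional quality columns `pval`, `q0`, `est_cn`.
#' Coordinates are taken as 0-based half-open. `pval` is the caller's
#' significance for the call, `q0` the fraction of supporting reads with zero
#' mapping quality, `est_cn` the caller's own copy-number estimate; absent
#' columns (or `NA` cells) yield missing fields that downstream filters treat
#' as vacuously passing.
#'
#' @param path Path to a TSV call file.
#' @param sample_id Sample identifier to stamp on every call.
#' @param caller Caller role, one of `"RD"` (single-sample read depth),
#'   `"PAIRED"` (discordant/split read pairs), `"POPRD"` (population-aware
#'   read depth).
#' @param layout Optional [genome_layout()]; when given, calls on unknown
#'   chromosomes are rejected.
#'
#' @return A data.frame of validated calls in file order, with columns
#'   `sample_id`, `caller`, `chrom`, `start`, `end`, `svtype`, `pval`, `q0`,
#'   `est_cn`.
#' @export
read_calls <- function(path, sample_id, caller, layout = NULL) {
  caller <- match.arg(caller, CALLERS)
  lines <- readLines(path)
  content <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(content) == 0L) stop("no header line found in ", path)
  header <- strsplit(lines[content[1L]], "\t", fixed = TRUE)[[1L]]
  required <- c("chrom", "start", "end", "svtype")
  if (!all(required %in% header)) {
    stop("call file ", path, " must have header columns: ",
         paste(required, collapse = ", "))
  }
  data_lines <- content[-1L]
  if (length(data_lines) == 0L) {
    out <- empty_calls()
    return(out)
  }
  fields <- strsplit(lines[data_lines], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop("line ", data_lines[bad[1L]], " of ", path, ": expected ",
         length(header), " fields, found ", nf[bad[1L]])
  }
  m <- do.call(rbind, fields)
  colnames(m) <- header
  getnum <- function(col) {
    if (!col %in% header) return(rep(NA_real_, nrow(m)))
    v <- m[, col]
    v[v %in% c("", "NA", ".")] <- NA
    suppressWarnings(as.numeric(v))
  }
  start <- getnum("start"); end <- getnum("end")
  chk <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop("line ", data_lines[i[1L]], " of ", path, ": ", msg)
  }
  chk(is.na(start) | is.na(end) | start < 0 | start != floor(start) |
        end != floor(end), "malformed coordinates")
  chk(end <= start, "end must be greater than start")
  svtype <- m[, "svtype"]
  chk(!svtype %in% SVTYPES, paste0("unknown svtype (expected ",
                                   paste(SVTYPES, collapse = "/"), ")"))
  chrom <- m[, "chrom"]
  if (!is.null(layout)) {
    chk(!chrom %in% layout$chrom_names, "chromosome not in genome layout")
    chk(end > layout$chrom_lengths[chrom], "call extends past chromosome end")
  }
  pval <- getnum("pval"); q0 <- getnum("q0"); est_cn <- getnum("est_cn")
  chk(!is.na(pval) & (pval < 0 | pval > 1), "pval outside [0,1]")
  chk(!is.na(q0) & (q0 < 0 | q0 > 1), "q0 outside [0,1]")
  chk(!is.na(est_cn) & est_cn < 0, "est_cn must be >= 0")
  data.frame(
    sample_id = sample_id, caller = caller, chrom = chrom,
    start = start, end = end, svtype = svtype,
    pval = pval, q0 = q0, est_cn = est_cn,
    stringsAsFactors = FALSE
  )
}

#' Write CNV calls for one sample/caller to a TSV file
#'
#' Inverse of [read_calls()]: writes the `chrom`, `start`, `end`, `svtype`,
#' `pval`, `q0`, `est_cn` columns; `read_calls(write_calls(x))` restores the
#' call fields exactly.
#'
#' @param calls Call data.frame (at least the coordinate/type columns).
#' @param path Output path.
#' @param comment Optional comment line written at the top.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, comment = NULL) {
  cols <- intersect(c("chrom", "start", "end", "svtype", "pval", "q0", "est_cn"),
                    names(calls))
  write_tsv(calls[, cols, drop = FALSE], path, comment)
}

#' Bundle gene bodies and their exons into a gene-model set
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`), `biotype`.
#' @param exons data.frame with columns `gene_id`, `start`, `end`; every
#'   exon must lie within its gene's span and exons of a gene must not
#'   overlap one another.
#' @return An object of class `gene_models` (list with `genes` and `exons`).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene IDs")
  if (!all(exons$gene_id %in% genes$gene_id)) stop("exon with unknown parent gene")
  if (nrow(exons)) {
    gi <- match(exons$gene_id, genes$gene_id)
    if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi])) {
      stop("exon outside its gene span")
    }
    ord <- order(exons$gene_id, exons$start)
    ex <- exons[ord, ]
    same <- ex$gene_id[-1L] == ex$gene_id[-nrow(ex)]
    if (nrow(ex) > 1L && any(same & ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("overlapping exons within one gene")
    }
    exons <- ex
  }
  rownames(genes) <- NULL; rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` and `exon` features, attaching exons to parent genes via
#' the `Parent` attribute (directly, or through an intermediate transcript
#' feature). GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. Exons whose parent cannot be resolved to a
#' gene are skipped with a warning; duplicate gene IDs are an error.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_gene <- type == "gene"
  if (!any(is_gene)) {
    warning("no gene features found in ", path)
    return(gene_models(
      genes = data.frame(gene_id = character(0), gene_name = character(0),
                         chrom = character(0), start = numeric(0),
                         end = numeric(0), strand = character(0),
                         biotype = character(0), stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
    ))
  }
  gid <- as.character(gr$ID)
  g <- gr[is_gene]
  gene_ids <- as.character(g$ID)
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs in ", path)
  pick <- function(x, fallback) {
    if (is.null(x)) return(fallback)
    x <- as.character(x)
    ifelse(is.na(x), fallback, x)
  }
  genes <- data.frame(
    gene_id = gene_ids,
    gene_name = pick(g$Name, gene_ids),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1,
    end = as.numeric(GenomicRanges::end(g)),
    strand = ifelse(as.character(GenomicRanges::strand(g)) == "-", "-", "+"),
    biotype = pick(g$biotype, "protein_coding"),
    stringsAsFactors = FALSE
  )
  # map any feature ID (gene or transcript) up to its gene
  parent_of <- function(ids) {
    out <- rep(NA_character_, length(ids))
    hit <- match(ids, gid)
    for (step in 1:3) {  # climb at most gene <- mRNA <- exon-parent chains
      unresolved <- !is.na(hit) & is.na(out)
      if (!any(unresolved)) break
      at_gene <- unresolved & type[hit] == "gene"
      out[at_gene] <- gid[hit[at_gene]]
      up <- unresolved & !at_gene
      if (any(up)) {
        par <- vapply(gr$Parent[hit[up]], function(p)
          if (length(p)) as.character(p[1L]) else NA_character_, character(1))
        hit[up] <- match(par, gid)
      }
    }
    out
  }
  ex <- gr[type == "exon"]
  exons <- data.frame(gene_id = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (length(ex)) {
    par1 <- vapply(ex$Parent, function(p)
      if (length(p)) as.character(p[1L]) else NA_character_, character(1))
    gene_of <- ifelse(par1 %in% gene_ids, par1, parent_of(par1))
    orphan <- is.na(gene_of) | !gene_of %in% gene_ids
    if (any(orphan)) {
      warning(sum(orphan), " exon(s) without resolvable gene parent skipped")
    }
    ex <- ex[!orphan]
    exons <- data.frame(
      gene_id = gene_of[!orphan],
      start = GenomicRanges::start(ex) - 1,
      end = as.numeric(GenomicRanges::end(ex)),
      stringsAsFactors = FALSE
    )
  }
  gene_models(genes, exons)
}

#' Write gene models as GFF3
#'
#' Emits one `gene` line per gene and one `exon` line per exon (`Parent` set
#' to the gene), converting the internal 0-based half-open coordinates back
#' to GFF3's 1-based inclusive convention. `read_gff3(write_gff3(x))`
#' restores the models.
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes; e <- models$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf(
      "%s\tcnvpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
      g$chrom[i], as.integer(g$start[i] + 1), as.integer(g$end[i]),
      g$strand[i], g$gene_id[i], g$gene_name[i], g$biotype[i]), con)
    ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ei))) {
      writeLines(sprintf(
        "%s\tcnvpop\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        g$chrom[i], as.integer(ei$start[j] + 1), as.integer(ei$end[j]),
        g$strand[i], g$gene_id[i], j, g$gene_id[i]), con)
    }
  }
  invisible(path)
}

#' Read a sample-to-population assignment table
#'
#' @param path TSV with header columns `sample_id` and `population`.
#' @return data.frame with one row per sample. A sample listed twice is an
#'   error.
#' @export
read_population_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample_id", "population") %in% names(df))) {
    stop("population map must have columns sample_id, population")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample '", df$sample_id[duplicated(df$sample_id)][1L],
         "' appears more than once in the population map")
  }
  df[, c("sample_id", "population")]
}

#' @rdname read_population_map
#' @param popmap Population-map data.frame.
#' @param comment Optional comment line.
#' @export
write_population_map <- function(popmap, path, comment = NULL) {
  write_tsv(popmap[, c("sample_id", "population")], path, comment)
}

#' Read a QTL interval table
#'
#' @param path TSV with header columns `qtl_id`, `trait_name`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param layout Optional [genome_layout()] for chromosome validation.
#' @return data.frame of QTL records; `end <= start` is an error.
#' @export
read_qtl_table <- function(path, layout = NULL) {
  df <- read_tsv(path, colClasses = c(qtl_id = "character"))
  need <- c("qtl_id", "trait_name", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("QTL table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$end <= df$start)) stop("QTL with end <= start in ", path)
  if (!is.null(layout) && !all(df$chrom %in% layout$chrom_names)) {
    stop("QTL on chromosome not in genome layout")
  }
  df[, need]
}

#' @rdname read_qtl_table
#' @param qtls QTL data.frame.
#' @param comment Optional comment line.
#' @export
write_qtl_table <- function(qtls, path, comment = NULL) {
  write_tsv(qtls[, c("qtl_id", "trait_name", "chrom", "start", "end")],
            path, comment)
}

#' Export CNVRs as BED6
#'
#' One line per CNVR: chrom, start, end, name = CNVR id, score = carrier
#' count, strand = ".".
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param path Output path.
#' @param comment Optional comment line.
#' @return `path`, invisibly.
#' @export
write_cnvr_bed <- function(cnvrs, path, comment = NULL) {
  bed <- data.frame(
    chrom = cnvrs$chrom, start = cnvrs$start, end = cnvrs$end,
    name = cnvrs$cnvr_id, score = cnvrs$n_carriers, strand = ".",
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cnvr_bed
#' @export
read_cnvr_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "cnvr_id", "n_carriers", "strand")
  df[, c("cnvr_id", "chrom", "start", "end", "n_carriers")]
}

#' Read/write the full CNVR table (coordinates, class, counts)
#'
#' The TSV sibling of the BED export, keeping the CNVR class and call count;
#' `read_cnvr_table(write_cnvr_table(x))` restores these columns exactly.
#'
#' @param cnvrs CNVR data.frame.
#' @param path File path.
#' @param comment Optional comment line.
#' @export
write_cnvr_table <- function(cnvrs, path, comment = NULL) {
  cols <- c("cnvr_id", "chrom", "start", "end", "cnvr_class",
            "n_carriers", "n_calls")
  write_tsv(cnvrs[, cols], path, comment)
}

#' @rdname write_cnvr_table
#' @export
read_cnvr_table <- function(path) {
  read_tsv(path, colClasses = c(cnvr_id = "character"))
}

#' Write/read a CNVR-by-sample copy-number matrix
#'
#' TSV with a `cnvr_id` key column and one column per sample. Cells that were
#' genotyped from zero depth coverage (imputed CN = 2) are recorded in
#' `# mask` comment lines and restored into the matrix's `mask` attribute on
#' read. Round trip preserves values, labels, and mask.
#'
#' @param mat Numeric matrix (rows = CNVRs, columns = samples), optionally
#'   carrying a logical `mask` attribute of the same shape.
#' @param path File path.
#' @param comment Optional comment line.
#' @export
write_cn_matrix <- function(mat, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  mask <- attr(mat, "mask")
  if (!is.null(mask) && any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    writeLines(sprintf("# mask\t%s\t%s",
                       rownames(mat)[idx[, 1L]], colnames(mat)[idx[, 2L]]), con)
  }
  df <- data.frame(cnvr_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_cn_matrix
#' @export
read_cn_matrix <- function(path) {
  lines <- readLines(path)
  cmt <- grepl("^#", lines)
  body <- lines[!cmt]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  dat <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (length(dat) == 0L) {
    mat <- matrix(numeric(0), nrow = 0, ncol = length(header) - 1L,
                  dimnames = list(character(0), header[-1L]))
    attr(mat, "mask") <- matrix(FALSE, 0, ncol(mat),
                                dimnames = dimnames(mat))
    return(mat)
  }
  m0 <- do.call(rbind, dat)
  ids <- m0[, 1L]
  mat <- matrix(as.numeric(m0[, -1L, drop = FALSE]), nrow = nrow(m0),
                dimnames = list(ids, header[-1L]))
  mask <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  mlines <- lines[cmt][grepl("^# mask\t", lines[cmt])]
  for (ml in mlines) {
    f <- strsplit(ml, "\t", fixed = TRUE)[[1L]]
    mask[f[2L], f[3L]] <- TRUE
  }
  attr(mat, "mask") <- mask
  mat
}

#' Write/read a per-sample windowed depth track
#'
#' BedGraph-like TSV with columns `chrom`, `start`, `end`, `count`: one row
#' per fixed-size window (the final window of a chromosome may be shorter).
#'
#' @param track A `depth_track` object (see [genotype_cnvrs()]).
#' @param path File path.
#' @param comment Optional comment line.
#' @export
write_depth_track <- function(track, path, comment = NULL) {
  stopifnot(inherits(track, "depth_track"))
  rows <- lapply(names(track$counts), function(ch) {
    n <- length(track$counts[[ch]])
    s <- (seq_len(n) - 1) * track$window_size
    data.frame(chrom = ch, start = s,
               end = pmin(s + track$window_size, track$chrom_lengths[[ch]]),
               count = track$counts[[ch]], stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path, comment)
}

#' @rdname write_depth_track
#' @param sample_id Sample identifier for the restored track.
#' @export
read_depth_track <- function(path, sample_id) {
  df <- read_tsv(path)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(df)))
  ws <- max(df$end - df$start)
  counts <- split(df$count, factor(df$chrom, levels = unique(df$chrom)))
  lens <- vapply(split(df$end, factor(df$chrom, levels = unique(df$chrom))),
                 max, numeric(1))
  depth_track(sample_id, ws, counts, lens)
}

#' Construct a depth track
#'
#' @param sample_id Sample identifier.
#' @param window_size Window size in bp.
#' @param counts Named list (by chromosome) of per-window read counts.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return A `depth_track` object.
#' @export
depth_track <- function(sample_id, window_size, counts, chrom_lengths) {
  stopifnot(window_size >= 1, all(names(counts) %in% names(chrom_lengths)))
  for (ch in names(counts)) {
    expected <- ceiling(chrom_lengths[[ch]] / window_size)
    if (length(counts[[ch]]) != expected) {
      stop("chromosome ", ch, ": expected ", expected, " windows, got ",
           length(counts[[ch]]))
    }
    if (any(counts[[ch]] < 0)) stop("negative window count on ", ch)
  }
  structure(list(sample_id = sample_id, window_size = window_size,
                 counts = counts,
                 chrom_lengths = as.list(chrom_lengths[names(counts)])),
            class = "depth_track")
}

#' Write/read a Vst result table
#'
#' @param records Vst data.frame from [vst_pairwise()] (optionally with
#'   `chrom`/`midpoint` columns for plotting).
#' @param path File path.
#' @param comment Optional comment line.
#' @export
write_vst_table <- function(records, path, comment = NULL) {
  write_tsv(records, path, comment)
}

#' @rdname write_vst_table
#' @export
read_vst_table <- function(path) {
  read_tsv(path, colClasses = c(cnvr_id = "character"))
}
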