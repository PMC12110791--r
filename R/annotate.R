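# Genomic-context classification, gene assignment, QTL colocalization and
# hypergeometric term enrichment for CNVRs. Overlap queries go through
# GenomicRanges; all coordinates stay 0-based half-open and are shifted to
# 1-based closed only inside the GRanges conversion helper.

#' Classify CNVRs by genomic context and assign nearby genes
#'
#' Each CNVR receives exactly one context by precedence: it is `exonic` if
#' it overlaps any exon of any gene; otherwise `intronic` if it overlaps a
#' gene body; otherwise `upstream` if it lies within `flank` bp 5' of a gene
#' start (strand-aware); otherwise `downstream` if within `flank` bp 3';
#' otherwise `intergenic`. Independently of the context label, every gene
#' whose span inflated by `flank` bp on both sides intersects the CNVR is
#' assigned to it (strand-ignorant), giving the "genes within 1 kb" set used
#' for enrichment and outlier-gene reporting.
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param genes A [gene_models()] object.
#' @param flank Flanking distance in bp (default 1000).
#' @return data.frame with `cnvr_id`, `context` (factor with the five
#'   levels) and list-column `genes_within_1kb`.
#' @export
classify_context <- function(cnvrs, genes, flank = 1000) {
  stopifnot(inherits(genes, "gene_models"), flank >= 0)
  levels5 <- c("exonic", "intronic", "upstream", "downstream", "intergenic")
  n <- nrow(cnvrs)
  if (n == 0L) {
    out <- data.frame(cnvr_id = character(0),
                      context = factor(character(0), levels = levels5))
    out$genes_within_1kb <- list()
    return(out)
  }
  gr_c <- df_to_gr(cnvrs)
  g <- genes$genes
  context <- rep("intergenic", n)
  genes_near <- rep(list(character(0)), n)
  if (nrow(g) > 0L) {
    gr_gene <- df_to_gr(g)
    plus <- g$strand == "+"
    up <- data.frame(chrom = g$chrom,
                     start = ifelse(plus, pmax(g$start - flank, 0), g$end),
                     end = ifelse(plus, g$start, g$end + flank))
    dn <- data.frame(chrom = g$chrom,
                     start = ifelse(plus, g$end, pmax(g$start - flank, 0)),
                     end = ifelse(plus, g$end + flank, g$start))
    hits_any <- function(df) {
      ok <- df$end > df$start
      v <- logical(n)
      if (any(ok)) {
        v[unique(S4Vectors::queryHits(
          GenomicRanges::findOverlaps(gr_c, df_to_gr(df[ok, , drop = FALSE]))))] <- TRUE
      }
      v
    }
    in_gene <- countOverlapsL(gr_c, gr_gene)
    in_exon <- if (nrow(genes$exons) > 0L) {
      ex <- genes$exons
      ex$chrom <- g$chrom[match(ex$gene_id, g$gene_id)]
      countOverlapsL(gr_c, df_to_gr(ex))
    } else logical(n)
    in_up <- hits_any(up)
    in_dn <- hits_any(dn)
    context[in_dn] <- "downstream"
    context[in_up] <- "upstream"
    context[in_gene] <- "intronic"
    context[in_exon] <- "exonic"
    infl <- data.frame(chrom = g$chrom, start = pmax(g$start - flank, 0),
                       end = g$end + flank)
    ho <- GenomicRanges::findOverlaps(gr_c, df_to_gr(infl))
    if (length(ho)) {
      by_cnvr <- split(g$gene_id[S4Vectors::subjectHits(ho)],
                       S4Vectors::queryHits(ho))
      for (k in names(by_cnvr)) {
        genes_near[[as.integer(k)]] <- sort(unique(by_cnvr[[k]]))
      }
    }
  }
  out <- data.frame(cnvr_id = cnvrs$cnvr_id,
                    context = factor(context, levels = levels5),
                    stringsAsFactors = FALSE)
  out$genes_within_1kb <- genes_near
  out
}

# logical "has at least one overlap"
countOverlapsL <- function(query, subject) {
  GenomicRanges::countOverlaps(query, subject) > 0
}

#' Intersect CNVRs with QTL intervals
#'
#' QTLs whose genomic span is `>= max_qtl_span` are removed first (the span
#' stands in for the mapping confidence interval; wide, poorly localised
#' QTLs are uninformative). Every remaining (CNVR, QTL) pair sharing at
#' least 1 bp is reported with its overlap length, together with summary
#' counts of distinct CNVRs, distinct QTLs, and distinct CNVRs per trait.
#'
#' @param cnvrs CNVR data.frame.
#' @param qtls QTL data.frame (see [read_qtl_table()]).
#' @param max_qtl_span QTLs at or above this span in bp are excluded
#'   (default 5 Mb, i.e. keep spans strictly narrower than 5 Mb).
#' @return List with `pairs` (data.frame `cnvr_id`, `qtl_id`, `trait_name`,
#'   `overlap_bp`) and `summary` (list `n_cnvrs_overlapping`,
#'   `n_qtls_overlapped`, `per_trait` named count vector).
#' @export
intersect_qtl <- function(cnvrs, qtls, max_qtl_span = 5e6) {
  stopifnot(max_qtl_span > 0)
  qtls <- qtls[(qtls$end - qtls$start) < max_qtl_span, , drop = FALSE]
  pairs <- data.frame(cnvr_id = character(0), qtl_id = character(0),
                      trait_name = character(0), overlap_bp = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(cnvrs) > 0L && nrow(qtls) > 0L) {
    hits <- GenomicRanges::findOverlaps(df_to_gr(cnvrs), df_to_gr(qtls))
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- pmin(cnvrs$end[qi], qtls$end[si]) - pmax(cnvrs$start[qi], qtls$start[si])
      pairs <- data.frame(cnvr_id = cnvrs$cnvr_id[qi],
                          qtl_id = as.character(qtls$qtl_id[si]),
                          trait_name = qtls$trait_name[si],
                          overlap_bp = ov, stringsAsFactors = FALSE)
    }
  }
  per_trait <- if (nrow(pairs)) {
    tab <- tapply(pairs$cnvr_id, pairs$trait_name,
                  function(x) length(unique(x)))
    sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
  } else integer(0)
  list(pairs = pairs,
       summary = list(
         n_cnvrs_overlapping = length(unique(pairs$cnvr_id)),
         n_qtls_overlapped = length(unique(pairs$qtl_id)),
         per_trait = per_trait))
}

#' Hypergeometric term enrichment for a gene set
#'
#' One-sided (upper-tail) hypergeometric test per term: with `N` background
#' genes of which `K` carry the term, and a query set of `n` genes of which
#' `k` carry it, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Benjamini-Hochberg adjusted q-values are
#' computed across all tested terms; terms with `k = 0` are skipped. The
#' `significant` flag applies `alpha` to the raw p-value (both columns are
#' always reported, so an adjusted cutoff can be applied instead).
#'
#' @param gene_set Character vector of query gene IDs (must be a subset of
#'   `background`).
#' @param term_map data.frame with columns `term_id`, `term_name`,
#'   `gene_id`; gene memberships outside the background are ignored.
#' @param background Character vector of background gene IDs (non-empty).
#' @param alpha Raw-p significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame sorted by p: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `significant`.
#' @export
enrich_terms <- function(gene_set, term_map, background, alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("background gene set is empty")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background)) {
    stop("gene_set contains genes not in the background")
  }
  stopifnot(all(c("term_id", "term_name", "gene_id") %in% names(term_map)))
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background); n <- length(gene_set)
  terms <- unique(term_map[, c("term_id", "term_name")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- unique(term_map$gene_id[term_map$term_id == terms$term_id[i]])
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    if (k == 0L) return(NULL)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, K = K, n = n, N = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
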