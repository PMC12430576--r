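#' Extract candidate genes from regions by variant-effect class
#'
#' Intersects candidate regions (1-based inclusive) with a per-SNP effect
#' table and keeps sites of the requested functional classes (by default the
#' protein-altering ones: exonic nonsynonymous, stop gain, stop loss), grouped
#' by gene. Invariant to region order and to splitting a region into abutting
#' halves.
#'
#' @param regions tibble with `chrom`, `start`, `end` (and optionally
#'   `region_id`).
#' @param effects effect table: `chrom`, `pos`, `gene_id`, `class` with class
#'   from `exonic_nonsynonymous`, `exonic_synonymous`, `stopgain`, `stoploss`,
#'   `intronic`, `intergenic`, `other`.
#' @param classes character set of classes to keep.
#' @return list with `sites` (tibble: region_id, chrom, pos, gene_id, class),
#'   `genes` (sorted unique gene ids) and `class_counts` (named integer
#'   tallies over the kept sites).
#' @export
genes_in_regions <- function(regions, effects,
                             classes = c("exonic_nonsynonymous", "stopgain",
                                         "stoploss")) {
  bad <- setdiff(classes, effect_classes)
  if (length(bad)) stop("unknown effect classes: ", paste(bad, collapse = ", "))
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("region_%02d", seq_len(nrow(regions)))
  }
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    sel <- effects$chrom == regions$chrom[i] &
      effects$pos >= regions$start[i] & effects$pos <= regions$end[i] &
      effects$class %in% classes
    if (any(sel)) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        region_id = regions$region_id[i],
        chrom = effects$chrom[sel], pos = effects$pos[sel],
        gene_id = effects$gene_id[sel], class = effects$class[sel])
    }
  }
  sites <- if (length(hits)) do.call(rbind, hits) else
    tibble::tibble(region_id = character(0), chrom = character(0),
                   pos = integer(0), gene_id = character(0), class = character(0))
  sites <- unique(sites[order(sites$chrom, sites$pos), ])
  counts <- table(factor(sites$class, levels = effect_classes))
  list(sites = sites,
       genes = sort(unique(stats::na.omit(sites$gene_id))),
       class_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Hypergeometric term enrichment over a gene-to-term map
#'
#' Database-agnostic over-representation test: for every term annotated to at
#' least one selected gene, the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing `k` term-carrying genes among `K` selected from a
#' background of `M` genes of which `m` carry the term, with
#' Benjamini-Hochberg adjustment across the tested terms.
#'
#' @param selected character vector of selected gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param gene2term tibble `gene_id`, `term_id`.
#' @param term_meta optional tibble `term_id`, `namespace`, `description`
#'   joined onto the result.
#' @return tibble sorted by p: `term_id`, `k`, `K`, `m`, `M`, `p`, `q`
#'   (+ namespace/description when supplied).
#' @export
term_enrichment <- function(selected, background, gene2term, term_meta = NULL) {
  selected <- unique(selected); background <- unique(background)
  extra <- setdiff(selected, background)
  if (length(extra)) {
    stop("selected genes not in background: ", paste(extra, collapse = ", "))
  }
  if (length(background) == 0L) stop("background must be non-empty")
  g2t <- gene2term[gene2term$gene_id %in% background, ]
  M <- length(background); K <- length(selected)
  sel_terms <- unique(g2t$term_id[g2t$gene_id %in% selected])
  rows <- lapply(sel_terms, function(tm) {
    carriers <- unique(g2t$gene_id[g2t$term_id == tm])
    m <- length(carriers)
    k <- length(intersect(carriers, selected))
    tibble::tibble(term_id = tm, k = k, K = K, m = m, M = M,
                   p = stats::phyper(k - 1, m, M - m, K, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(tibble::tibble(term_id = character(0), k = integer(0), K = integer(0),
                          m = integer(0), M = integer(0), p = numeric(0),
                          q = numeric(0)))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), ]
  if (!is.null(term_meta)) {
    i <- match(out$term_id, term_meta$term_id)
    out$namespace <- term_meta$namespace[i]
    out$description <- term_meta$description[i]
  }
  out
}

#' Per-namespace term classification of a gene set
#'
#' The descriptive counterpart of [term_enrichment()]: tallies, per namespace
#' (BP/MF/CC/pathway), how many of the given genes carry each term -- the
#' bar-chart classification used to characterize small candidate sets, where
#' formal testing is underpowered.
#'
#' @inheritParams term_enrichment
#' @return tibble `namespace`, `term_id`, `description`, `n_genes`, sorted by
#'   namespace then decreasing count.
#' @export
classify_terms <- function(selected, gene2term, term_meta) {
  g2t <- unique(gene2term[gene2term$gene_id %in% selected, ])
  if (nrow(g2t) == 0L) {
    return(tibble::tibble(namespace = character(0), term_id = character(0),
                          description = character(0), n_genes = integer(0)))
  }
  cnt <- as.data.frame(table(g2t$term_id), stringsAsFactors = FALSE)
  names(cnt) <- c("term_id", "n_genes")
  i <- match(cnt$term_id, term_meta$term_id)
  out <- tibble::tibble(namespace = term_meta$namespace[i],
                        term_id = cnt$term_id,
                        description = term_meta$description[i],
                        n_genes = as.integer(cnt$n_genes))
  out[order(out$namespace, -out$n_genes, out$term_id), ]
}
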