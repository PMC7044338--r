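## Duplication-mode classification, GO over-retention enrichment, and
## ortholog filtering by alignment-hit thresholds.

#' Classify gene duplication modes
#'
#' Priority WGT > tandem > dispersed: a gene with a syntenic ortholog in any
#' reference species is WGT-derived; otherwise a gene with a same-chromosome
#' homolog separated by at most `tandem_max_intervening` genes is a tandem
#' duplicate; any other homolog-bearing gene is a dispersed duplicate; genes
#' without homologs are singletons.
#'
#' @param genome `phex_genome`.
#' @param synteny_flags character vector of gene ids with a syntenic
#'   ortholog in at least one reference species.
#' @param homology_pairs data.frame(gene_a, gene_b): within-genome homolog
#'   pairs (undirected).
#' @param tandem_max_intervening max intervening genes for tandem (default 5).
#' @return data.table(gene_id, class) with class in
#'   WGT/tandem/dispersed/singleton; classes partition the gene set.
#' @export
classify_duplications <- function(genome, synteny_flags, homology_pairs,
                                  tandem_max_intervening = 5L) {
  g <- genome$genes
  hp <- as.data.table(homology_pairs)
  hp <- rbind(hp[, .(gene = gene_a, mate = gene_b)],
              hp[, .(gene = gene_b, mate = gene_a)])
  hp <- hp[gene != mate]
  pos <- g[, .(gene_id, chrom, rank)]
  hp <- merge(hp, pos, by.x = "gene", by.y = "gene_id")
  hp <- merge(hp, pos, by.x = "mate", by.y = "gene_id",
              suffixes = c("", "_mate"))
  tandem_genes <- unique(hp[chrom == chrom_mate &
                              abs(rank - rank_mate) - 1L <= tandem_max_intervening]$gene)
  homolog_genes <- unique(hp$gene)
  cls <- data.table(gene_id = g$gene_id)
  cls[, class := fifelse(gene_id %in% synteny_flags, "WGT",
                         fifelse(gene_id %in% tandem_genes, "tandem",
                                 fifelse(gene_id %in% homolog_genes,
                                         "dispersed", "singleton")))]
  cls[]
}

#' One-sided Fisher (hypergeometric) GO enrichment
#'
#' For each GO term with at least one study-set member, tests
#' over-representation of the term in the study set against the universe
#' (one-sided, greater). Benjamini-Hochberg correction across tested terms.
#'
#' @param go data.frame(gene_id, go_id).
#' @param study_set character vector, subset of `universe`.
#' @param universe character vector of all genes considered.
#' @return data.table(go_id, a, b, c, d, odds_ratio, p_value, q_value)
#'   sorted by q then p; `a` = study genes with the term, `b` = study genes
#'   without it, `c`/`d` likewise outside the study set.
#' @export
fisher_enrichment <- function(go, study_set, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(study_set %in% universe)) stop("study set not contained in universe")
  g <- as.data.table(go)[gene_id %in% universe]
  study_set <- unique(study_set)
  n_u <- length(unique(universe))
  n_s <- length(study_set)
  terms <- g[gene_id %in% study_set, unique(go_id)]
  if (!length(terms))
    return(data.table(go_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric()))
  res <- rbindlist(lapply(terms, function(tm) {
    with_term <- unique(g[go_id == tm]$gene_id)
    a <- sum(study_set %in% with_term)
    b <- n_s - a
    cc <- length(with_term) - a
    d <- (n_u - n_s) - cc
    p <- phyper(a - 1L, a + cc, b + d, a + b, lower.tail = FALSE)
    orr <- (a * d) / (b * cc)
    data.table(go_id = tm, a = a, b = b, c = cc, d = d,
               odds_ratio = orr, p_value = p)
  }))
  res[, q_value := p.adjust(p_value, method = "BH")]
  setorder(res, q_value, p_value, go_id)
  res[]
}

#' Ortholog-filter parameters for alignment hits
#'
#' @param max_e E-value ceiling (default 1e-20, inclusive).
#' @param min_coverage coverage floor in percent (exclusive, default 50).
#' @param min_identity identity floor in percent (exclusive, default 35).
#' @return list of class `phex_ortholog_filter`.
#' @export
ortholog_filter_config <- function(max_e = 1e-20, min_coverage = 50,
                                   min_identity = 35) {
  structure(list(max_e = max_e, min_coverage = min_coverage,
                 min_identity = min_identity),
            class = "phex_ortholog_filter")
}

#' Filter alignment hits to putative ortholog set
#'
#' Keeps hits with e_value <= max_e, coverage > min_coverage and
#' identity > min_identity; returns the distinct query genes surviving.
#'
#' @param hits data.frame with e_value, identity_pct, coverage_pct,
#'   query_id.
#' @param f `ortholog_filter_config()`.
#' @return character vector of query gene ids.
#' @export
ortholog_filter <- function(hits, f = ortholog_filter_config()) {
  h <- as.data.table(hits)
  need <- c("query_id", "e_value", "identity_pct", "coverage_pct")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  keep <- h[e_value <= f$max_e & coverage_pct > f$min_coverage &
              identity_pct > f$min_identity]
  sort(unique(keep$query_id))
}

#' Copy-number histogram of reference genes
#'
#' @param synteny_map data.frame(r_id, q_id): retained query copies per
#'   reference gene (absent reference genes may be listed with NA q_id or
#'   supplied via `all_ref_ids`).
#' @param all_ref_ids optionally, the complete reference gene set so genes
#'   with zero retained copies are counted.
#' @return named integer vector: counts of reference genes with 0, 1, 2, 3
#'   retained copies. Multiplicity above 3 is an error.
#' @export
copy_number_table <- function(synteny_map, all_ref_ids = NULL) {
  sm <- as.data.table(synteny_map)
  sm <- sm[!is.na(q_id)]
  mult <- sm[, .(multiplicity = data.table::uniqueN(q_id)), by = r_id]
  if (nrow(mult) && any(mult$multiplicity > 3L))
    stop("reference gene with more than 3 retained copies: ",
         mult[multiplicity > 3L]$r_id[1L])
  zeros <- 0L
  if (!is.null(all_ref_ids))
    zeros <- length(setdiff(unique(all_ref_ids), mult$r_id))
  out <- vapply(1:3, function(k) sum(mult$multiplicity == k), integer(1))
  setNames(c(zeros, out), as.character(0:3))
}
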