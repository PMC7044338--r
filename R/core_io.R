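## Domain containers and readers/writers.
##
## Coordinate contract: every interval held in memory is 0-based half-open
## [start, end).  GFF3 (1-based closed) is converted at the I/O boundary and
## nowhere else; BED enters unchanged.  Gene `rank` is the 0-based ordinal of
## the gene among genes of the same chromosome ordered by start (ties broken
## by gene_id), so rank arithmetic equals "number of intervening genes + 1".

#' Construct a genome object
#'
#' A genome is a gene table plus chromosome lengths. Ranks are (re)computed
#' here; callers never supply them.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` ("+"/"-"). Coordinates are 0-based half-open.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   Missing chromosomes default to the maximum gene end.
#' @param name genome label.
#' @return An object of class `phex_genome`: list with `name`, `genes`
#'   (data.table with added `rank`), `chrom_lengths`.
#' @export
new_genome <- function(genes, chrom_lengths = NULL, name = "genome") {
  g <- as.data.table(genes)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("genes table missing columns: ", paste(miss, collapse = ", "))
  g <- g[, .(gene_id = as.character(gene_id), chrom = as.character(chrom),
             start = as.numeric(start), end = as.numeric(end),
             strand = as.character(strand))]
  if (nrow(g)) {
    if (anyDuplicated(g$gene_id)) {
      dup <- g$gene_id[duplicated(g$gene_id)][1L]
      stop("duplicate gene ID: ", dup)
    }
    bad <- g[start >= end]
    if (nrow(bad)) stop("gene with end <= start: ", bad$gene_id[1L])
    if (any(g$start < 0)) stop("negative gene coordinate")
    if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  setorder(g, chrom, start, gene_id)
  g[, rank := seq_len(.N) - 1L, by = chrom]
  cl <- if (nrow(g)) g[, .(len = max(end)), by = chrom] else
    data.table(chrom = character(), len = numeric())
  lens <- setNames(cl$len, cl$chrom)
  if (!is.null(chrom_lengths)) {
    lens[names(chrom_lengths)] <- as.numeric(chrom_lengths)
    extra <- setdiff(names(chrom_lengths), names(lens))
    if (length(extra)) lens <- c(lens, setNames(as.numeric(chrom_lengths[extra]), extra))
  }
  if (nrow(g)) {
    over <- g[lens[chrom] < end]
    if (nrow(over)) stop("gene extends past chromosome length: ", over$gene_id[1L])
  }
  structure(list(name = name, genes = g, chrom_lengths = lens),
            class = "phex_genome")
}

#' @export
print.phex_genome <- function(x, ...) {
  cat(sprintf("<phex_genome '%s': %d genes on %d chromosomes>\n",
              x$name, nrow(x$genes), length(x$chrom_lengths)))
  invisible(x)
}

#' Number of genes per chromosome of a genome
#' @param genome a `phex_genome`.
#' @return named integer vector.
#' @export
chrom_gene_counts <- function(genome) {
  cnt <- genome$genes[, .N, by = chrom]
  setNames(cnt$N, cnt$chrom)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` rows; if a file carries no gene rows, spans are derived from
#' mRNA rows (grouped by ID) and failing that from CDS rows grouped by Parent.
#' Input order is irrelevant (sorted internally); duplicate gene IDs are a
#' hard error.
#'
#' @param path GFF3 file.
#' @param name genome label.
#' @return `phex_genome` with 0-based half-open coordinates and ranks.
#' @export
read_gff3 <- function(path, name = basename(path)) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path, "': ",
                                          conditionMessage(e)))
  df <- as.data.table(as.data.frame(gr))
  if (!nrow(df)) {
    return(new_genome(data.table(gene_id = character(), chrom = character(),
                                 start = numeric(), end = numeric(),
                                 strand = character()), name = name))
  }
  df[, type := as.character(type)]
  if (any(df$type == "gene")) {
    gg <- df[type == "gene"]
    ids <- as.character(gg$ID)
  } else if (any(df$type == "mRNA")) {
    gg <- df[type == "mRNA"]
    ids <- as.character(gg$ID)
  } else if (any(df$type == "CDS")) {
    cds <- df[type == "CDS"]
    par <- vapply(cds$Parent, function(p) as.character(p)[1L], character(1))
    gg <- cds[, .(seqnames = seqnames[1L], start = min(start), end = max(end),
                  strand = strand[1L]), by = .(ID = par)]
    ids <- gg$ID
  } else stop("GFF3 contains no gene, mRNA or CDS features: ", path)
  if (anyNA(ids)) stop("GFF3 gene feature without ID attribute in ", path)
  genes <- data.table(gene_id = ids,
                      chrom = as.character(gg$seqnames),
                      start = as.numeric(gg$start) - 1,  # to 0-based half-open
                      end = as.numeric(gg$end),
                      strand = ifelse(as.character(gg$strand) == "-", "-", "+"))
  lens <- NULL
  si <- GenomeInfoDb_lengths(gr)
  if (length(si)) lens <- si
  new_genome(genes, chrom_lengths = lens, name = name)
}

# seqlengths if the GFF3 declared ##sequence-region pragmas
GenomeInfoDb_lengths <- function(gr) {
  sl <- tryCatch(GenomeInfoDb::seqlengths(gr), error = function(e) NULL)
  if (is.null(sl) || all(is.na(sl))) return(numeric())
  sl <- sl[!is.na(sl)]
  setNames(as.numeric(sl), names(sl))
}

#' Write a genome's gene models to GFF3
#' @param genome `phex_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(genome$chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       as.integer(genome$chrom_lengths[[ch]])), con)
  if (nrow(g)) {
    lines <- sprintf("%s\tpaleohex\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, as.integer(g$start) + 1L, as.integer(g$end),
                     g$strand, g$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read transposable-element features
#'
#' @param path BED3+ or GFF3 file.
#' @param dialect `"bed"` (0-based half-open, used as-is) or `"gff3"`
#'   (1-based closed, converted). Mandatory: the two dialects are
#'   indistinguishable from content alone.
#' @return data.table(chrom, start, end, family), 0-based half-open.
#'   Overlapping features are retained as-is; merge on demand.
#' @export
read_te_bed <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    te <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
    if (!nrow(te)) return(data.table(chrom = character(), start = numeric(),
                                     end = numeric(), family = character()))
    out <- data.table(chrom = as.character(te[[1L]]),
                      start = as.numeric(te[[2L]]),
                      end = as.numeric(te[[3L]]),
                      family = if (ncol(te) >= 4L) as.character(te[[4L]]) else "TE")
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    fam <- if (!is.null(df$ID)) as.character(df$ID) else as.character(df$type)
    out <- data.table(chrom = as.character(df$seqnames),
                      start = as.numeric(df$start) - 1,
                      end = as.numeric(df$end),
                      family = fam)
  }
  if (nrow(out) && any(out$start < 0)) stop("negative TE coordinate in ", path)
  if (nrow(out) && any(out$start >= out$end)) stop("TE with end <= start in ", path)
  out[]
}

#' Write TE features as BED3+1
#' @param tes data.table(chrom, start, end, family).
#' @param path output file.
#' @export
write_te_bed <- function(tes, path) {
  data.table::fwrite(tes[, .(chrom, start = as.integer(start),
                             end = as.integer(end), family)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Construct an expression table
#'
#' @param values non-negative gene x sample matrix with dimnames.
#' @param unit `"raw_count"` or `"TPM"`.
#' @param gene_length named vector of effective lengths (bp), required for
#'   raw counts. Effective length is exonic length where known, else gene span.
#' @return `phex_expression` object.
#' @export
expression_table <- function(values, unit = c("raw_count", "TPM"),
                             gene_length = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (any(values < 0)) stop("negative expression value")
  if (unit == "raw_count") {
    if (is.null(gene_length)) stop("gene_length required for raw counts")
    miss <- setdiff(rownames(values), names(gene_length))
    if (length(miss)) stop("gene_length missing for: ", miss[1L])
    if (any(gene_length[rownames(values)] <= 0)) stop("non-positive gene length")
  }
  structure(list(values = values, unit = unit, gene_length = gene_length),
            class = "phex_expression")
}

#' Convert raw counts to TPM
#'
#' TPM_g = 1e6 * (c_g / L_g) / sum_h (c_h / L_h), per sample. Already-TPM
#' input is returned unchanged (idempotent).
#'
#' @param table `phex_expression`.
#' @return `phex_expression` with unit `"TPM"`; each column sums to 1e6.
#' @export
to_tpm <- function(table) {
  stopifnot(inherits(table, "phex_expression"))
  if (table$unit == "TPM") return(table)
  L <- table$gene_length[rownames(table$values)]
  rate <- table$values / L
  tot <- colSums(rate)
  if (any(tot == 0)) stop("all-zero sample column: TPM undefined for sample '",
                          colnames(table$values)[which(tot == 0)[1L]], "'")
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  expression_table(tpm, unit = "TPM")
}

#' Read a homology hit table
#'
#' TSV with header: query_id, subject_id, e_value, identity_pct,
#' coverage_pct, bitscore.
#' @param path TSV file.
#' @return data.table of hits.
#' @export
read_homology_tsv <- function(path) {
  h <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("query_id", "subject_id", "e_value", "identity_pct",
            "coverage_pct", "bitscore")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  validate_hits(h)
  h[]
}

validate_hits <- function(h) {
  if (!nrow(h)) return(invisible(h))
  if (any(h$e_value < 0)) stop("negative e_value in hit table")
  if (any(h$identity_pct < 0 | h$identity_pct > 100)) stop("identity_pct outside [0,100]")
  if (any(h$coverage_pct < 0 | h$coverage_pct > 100)) stop("coverage_pct outside [0,100]")
  invisible(h)
}

#' Read an expression TSV (gene x sample, first column gene_id)
#' @param path TSV file.
#' @param unit `"raw_count"` or `"TPM"`.
#' @param gene_length named lengths, for raw counts.
#' @return `phex_expression`.
#' @export
read_expression_tsv <- function(path, unit = c("raw_count", "TPM"),
                                gene_length = NULL) {
  unit <- match.arg(unit)
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(d[, -1L, with = FALSE])
  rownames(m) <- as.character(d[[1L]])
  expression_table(m, unit = unit, gene_length = gene_length)
}

#' Read a GO annotation table
#'
#' TSV with header columns `gene_id` and `go_id` (one row per
#' gene-term link). Term ids must match `GO:` + 7 digits.
#' @param path TSV file.
#' @return data.table(gene_id, go_id).
#' @export
read_go_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("gene_id", "go_id") %in% names(d)))
    stop("GO table needs columns gene_id, go_id")
  bad <- d[!grepl("^GO:[0-9]{7}$", go_id)]
  if (nrow(bad)) stop("malformed GO term id: ", bad$go_id[1L])
  unique(d[, .(gene_id = as.character(gene_id), go_id = as.character(go_id))])[]
}
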