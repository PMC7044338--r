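## End-to-end driver: homology hits -> syntenic pairs -> fragments ->
## breakpoints/blocks -> ancestral karyotype -> sub-genome paintings and
## LF/MF1/MF2 labels; plus validation against simulator truth.

#' Run the comparative pipeline on a polyploid/reference pair
#'
#' @param query,ref `phex_genome` objects.
#' @param hits homology hit table (query -> reference).
#' @param syn_cfg `synteny_config()`.
#' @param tolerance breakpoint clustering tolerance (gene ranks).
#' @param window retention-profile window (loci).
#' @return list of class `phex_pipeline`: pairs, fragments, breakpoints,
#'   blocks, annotations, associations, karyotype, units (ancestral gene
#'   order as recovered), items, assignment, gene_labels, counts.
#' @export
run_pipeline <- function(query, ref, hits, syn_cfg = synteny_config(),
                         tolerance = 10L, window = 1001L) {
  pairs <- find_syntenic_pairs(query, ref, hits, syn_cfg)
  frags_all <- assemble_fragments(pairs, syn_cfg)
  ## junction evidence uses every fragment (a short block tail still
  ## witnesses where two boundaries meet); breakpoint detection and block
  ## painting use only fragments passing the span filter, whose ends are
  ## reliable
  evid <- assign_fragment_lanes(frags_all)
  frags <- filter_fragments(frags_all, syn_cfg)
  frags <- assign_fragment_lanes(frags)
  pair_tab <- attr(frags_all, "pairs")[fragment_id %in% frags$fragment_id]
  bps <- detect_breakpoints(frags, ref, tolerance = tolerance)
  blocks <- segment_blocks(ref, bps)
  ann <- project_blocks(blocks, frags)
  assoc <- find_gb_associations(evid, blocks, tolerance = tolerance,
                                pairs = attr(frags_all, "pairs"))
  kary <- assemble_ancestral_karyotype(blocks, assoc, bps)

  ## recovered ancestral coordinate system: per karyotype chromosome, the
  ## reference genes of its blocks in path order
  ref_genes <- ref$genes[, .(r_id = gene_id, chrom, r_rank = rank)]
  unit_rows <- list()
  for (u in seq_along(kary$chromosomes)) {
    kch <- kary$chromosomes[[u]]
    for (i in seq_len(nrow(kch))) {
      bl <- blocks[label == kch$label[i]]
      rk <- bl$start_rank:bl$end_rank
      if (kch$orientation[i] == "inverted") rk <- rev(rk)
      unit_rows[[length(unit_rows) + 1L]] <-
        data.table(chrom = bl$chrom, r_rank = rk, unit = u,
                   label = kch$label[i])
    }
  }
  units <- rbindlist(unit_rows)
  units[, a_rank := seq_len(.N) - 1L, by = unit]
  units <- ref_genes[units, on = .(chrom, r_rank)]

  ## fragment -> unit and ancestral interval
  fr_unit <- units[, .(r_chrom = chrom, r_rank, unit, a_rank, r_id)][
    pair_tab[, .(fragment_id, r_chrom, r_rank)],
    on = .(r_chrom, r_rank)]
  items <- fr_unit[!is.na(unit),
                   {
                     tab <- table(unit)
                     u <- as.integer(names(tab)[which.max(tab)])
                     .(unit = u, a_start = min(a_rank[unit == u]),
                       a_end = max(a_rank[unit == u]),
                       loci = list(r_id[unit == u]))
                   },
                   by = fragment_id]
  items <- merge(items, frags[, .(fragment_id, q_chrom)], by = "fragment_id")
  items[, item_id := fragment_id]
  painted <- reconstruct_subgenome_chromosomes(items)

  ## retention profiles per unit and painting; LF/MF1/MF2 assignment
  pair_frame <- merge(pair_tab[, .(q_id, r_id, fragment_id)],
                      painted[, .(fragment_id, unit, painting)],
                      by = "fragment_id")
  ## density is measured over the region each painting actually covers, so
  ## a regional deletion (or a dropped fragment) does not zero-dilute the
  ## copy's retention rate
  ao_hat <- units[!is.na(r_id), .(locus = r_id, a_chrom = unit, a_rank)]
  prof_list <- list()
  for (u in unique(painted$unit)) {
    ao_u <- ao_hat[a_chrom == u]
    pf <- pair_frame[unit == u]
    its <- painted[unit == u]
    for (p in sort(unique(its$painting))) {
      cov <- unique(unlist(lapply(which(its$painting == p), function(i)
        its$a_start[i]:its$a_end[i])))
      ao_p <- ao_u[a_rank %in% cov][order(a_rank)]
      if (!nrow(ao_p)) next
      ret_p <- data.table(locus = ao_p$locus, copy = p,
                          retained = ao_p$locus %in% pf[painting == p]$r_id)
      pr <- retention_profile(ao_p, ret_p, window = window)
      pr[, unit := u]
      prof_list[[length(prof_list) + 1L]] <- pr
    }
  }
  profiles <- rbindlist(prof_list)
  assignment <- assign_subgenomes(profiles)
  gene_labels <- merge(pair_frame,
                       assignment[, .(unit, painting = copy, label)],
                       by = c("unit", "painting"))
  gene_labels <- gene_labels[, .(gene_id = q_id, r_id, unit, painting, label)]
  mult <- pair_frame[, .(multiplicity = data.table::uniqueN(q_id)), by = r_id]
  counts <- retention_counts(gene_labels, mult)

  structure(list(pairs = pairs, fragments = frags, pair_tab = pair_tab,
                 breakpoints = bps, blocks = blocks, annotations = ann,
                 associations = assoc, karyotype = kary, units = units,
                 items = painted, assignment = assignment,
                 gene_labels = gene_labels, counts = counts),
            class = "phex_pipeline")
}

#' @export
print.phex_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<phex_pipeline: %d pairs, %d fragments, %d breakpoints, ",
                     "%d blocks, %d ancestral chromosomes>\n"),
              nrow(x$pairs), nrow(x$fragments), nrow(x$breakpoints),
              nrow(x$blocks), x$karyotype$n_chromosomes))
  invisible(x)
}

#' Homoeolog doublets between sub-genomes
#'
#' Pairs of genes from the same reference locus assigned to two different
#' sub-genomes; `gene_a` always takes the earlier label in LF < MF1 < MF2
#' order.
#'
#' @param gene_labels data.frame(gene_id, r_id, label) as produced by
#'   [run_pipeline()] (any table mapping genes to loci and labels works).
#' @return data.table(gene_a, gene_b, pair) with pair like "LF-MF1".
#' @export
paralog_doublets <- function(gene_labels) {
  gl <- as.data.table(gene_labels)
  lv <- c("LF", "MF1", "MF2")
  m <- merge(gl[, .(gene_a = gene_id, r_id, label_a = label)],
             gl[, .(gene_b = gene_id, r_id, label_b = label)],
             by = "r_id", allow.cartesian = TRUE)
  m <- m[label_a != label_b & match(label_a, lv) < match(label_b, lv)]
  m[, .(gene_a, gene_b, pair = paste(label_a, label_b, sep = "-"))]
}

#' Validate pipeline output against simulator truth
#'
#' @param pipeline `phex_pipeline` from [run_pipeline()].
#' @param sim `phex_sim` from [simulate_paleohexaploid()].
#' @param tolerance breakpoint matching tolerance (gene ranks).
#' @return list of class `phex_validation`: n_chromosomes /
#'   n_chromosomes_truth, breakpoint precision/recall, association
#'   recall / false positives, unit-level and gene-level sub-genome label
#'   accuracy.
#' @export
validate_against_truth <- function(pipeline, sim, tolerance = 10L) {
  truth <- sim$truth
  ## breakpoints
  det <- pipeline$breakpoints
  pl <- truth$planted_breakpoints
  match_bp <- function(a, b) {
    if (!nrow(a)) return(0L)
    hit <- vapply(seq_len(nrow(a)), function(i)
      nrow(b[chrom == a$chrom[i] & abs(gap - a$gap[i]) <= tolerance]) > 0,
      logical(1))
    sum(hit)
  }
  bp_recall <- if (nrow(pl)) match_bp(pl, det) / nrow(pl) else NA_real_
  bp_precision <- if (nrow(det)) match_bp(det, pl) / nrow(det) else NA_real_

  ## associations: map detected blocks to truth segments by best overlap
  blocks <- pipeline$blocks
  segs <- truth$segments
  block2seg <- vapply(seq_len(nrow(blocks)), function(i) {
    cand <- segs[r_chrom == blocks$chrom[i]]
    ov <- pmin(cand$r_end_rank, blocks$end_rank[i]) -
      pmax(cand$r_start_rank, blocks$start_rank[i]) + 1L
    if (!length(ov) || max(ov) <= 0) return(NA_character_)
    cand$seg_id[which.max(ov)]
  }, character(1))
  names(block2seg) <- blocks$label
  remap <- function(sig) {
    ends <- strsplit(sig, "|", fixed = TRUE)[[1L]]
    lab <- sub("\\..$", "", ends)
    side <- sub("^.*\\.", "", ends)
    sg <- block2seg[lab]
    if (anyNA(sg)) return(NA_character_)
    e <- paste0(sg, ".", side)
    e <- sort(e)
    paste0(e[1L], "|", e[2L])
  }
  cand_sigs <- pipeline$associations[candidate == TRUE]$signature
  mapped <- vapply(cand_sigs, remap, character(1))
  assoc_recall <- if (length(truth$ancestor_junctions))
    mean(truth$ancestor_junctions %in% mapped) else NA_real_
  assoc_fp <- sum(!mapped %in% truth$ancestor_junctions)

  ## sub-genome labels: per (unit, painting), majority truth label of genes
  gl <- merge(pipeline$gene_labels,
              truth$genes[, .(gene_id = q_id, copy_label)], by = "gene_id")
  unit_truth <- gl[, .(truth_label = names(which.max(table(copy_label))),
                       n = .N), by = .(unit, painting)]
  unit_cmp <- merge(unit_truth,
                    pipeline$assignment[, .(unit, painting = copy, label)],
                    by = c("unit", "painting"))
  unit_accuracy <- mean(unit_cmp$label == unit_cmp$truth_label)
  gene_accuracy <- mean(gl$label == gl$copy_label)

  structure(list(
    n_chromosomes = pipeline$karyotype$n_chromosomes,
    n_chromosomes_truth = truth$config$n_ancestor_chromosomes,
    breakpoint_recall = bp_recall, breakpoint_precision = bp_precision,
    association_recall = assoc_recall, association_false_positives = assoc_fp,
    unit_label_accuracy = unit_accuracy, gene_label_accuracy = gene_accuracy,
    n_units = nrow(unit_cmp)),
    class = "phex_validation")
}

#' @export
print.phex_validation <- function(x, ...) {
  cat(sprintf(paste0("<phex_validation: chroms %d/%d, bp recall %.2f prec %.2f, ",
                     "assoc recall %.2f fp %d, unit acc %.2f gene acc %.2f>\n"),
              x$n_chromosomes, x$n_chromosomes_truth, x$breakpoint_recall,
              x$breakpoint_precision, x$association_recall,
              x$association_false_positives, x$unit_label_accuracy,
              x$gene_label_accuracy))
  invisible(x)
}

#' Write a simulation to pipeline-ready files
#'
#' Emits the polyploid and reference GFF3, TE BED, homology/expression/GO
#' TSVs, CDS FASTAs (when present), and a `truth/` directory of TSVs.
#'
#' @param sim `phex_sim`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gff3(sim$query, file.path(dir, "polyploid.gff3"))
  write_gff3(sim$ref, file.path(dir, "reference.gff3"))
  write_te_bed(sim$tes, file.path(dir, "te.bed"))
  data.table::fwrite(sim$hits, file.path(dir, "hits.tsv"), sep = "\t")
  expd <- data.table(gene_id = rownames(sim$expression$values),
                     sim$expression$values)
  data.table::fwrite(expd, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(sim$go, file.path(dir, "go.tsv"), sep = "\t")
  if (!is.null(sim$cds_ref)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds_ref),
                                file.path(dir, "reference_cds.fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds_query),
                                file.path(dir, "polyploid_cds.fasta"))
  }
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  data.table::fwrite(sim$truth$segments, file.path(tdir, "segments.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$planted_breakpoints,
                     file.path(tdir, "breakpoints.tsv"), sep = "\t")
  writeLines(sim$truth$ancestor_junctions, file.path(tdir, "junctions.txt"))
  data.table::fwrite(sim$truth$genes, file.path(tdir, "genes.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$retained, file.path(tdir, "retained.tsv"), sep = "\t")
  invisible(dir)
}
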