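## Synthetic paleohexaploid genomes with known truth.
##
## Construction is ancestor-first: a diploid ancestor (default 9 chromosomes
## x 300 gene loci) is cut into segments and re-arranged into the diploid
## reference (default 11 chromosomes), so every internal reference junction
## is a detectable shared breakpoint and every ancestor-internal cut is a
## recoverable ancestral block association.  The polyploid descends from
## three full copies of the ancestor with biased fractionation
## (LF/MF1/MF2 retention), copy-private rearrangement noise, TE insertion
## rates anti-correlated with retention, and expression coupled causally to
## promoter TE load.

#' Simulation parameters
#'
#' Defaults are the study conditions used throughout the test-suite:
#' retention 0.8/0.6/0.5, 9 ancestral chromosomes of 300 loci, reference
#' with 11 chromosomes, 20 copy-private rearrangements (yielding ~25
#' descendant chromosomes), Ks peaks at 0.51 (reference split) and 0.28
#' (triplication).
#'
#' @param seed RNG seed: identical configs give identical output.
#' @param ref_seed separate seed for the reference-derivation step (cuts and
#'   segment arrangement). Two configs differing only in `ref_seed` share
#'   the identical ancestor and polyploid but see it through two
#'   independently rearranged references - the reference-choice robustness
#'   check. `NULL` derives it from `seed`.
#' @param n_ancestor_chromosomes,genes_per_chromosome ancestor shape.
#' @param retention_rates named (LF, MF1, MF2) survival probabilities.
#' @param n_rearrangements copy-private fissions+fusions+inversions.
#' @param n_ref_chromosomes reference chromosome count.
#' @param n_ancestor_cuts ancestor-internal cuts when deriving the
#'   reference; planted reference breakpoints =
#'   `n_ancestor_cuts + n_ancestor_chromosomes - n_ref_chromosomes`.
#' @param min_segment_loci minimum segment length (gene loci).
#' @param te_rate_per_kb named per-sub-genome TE insertion rates (LF lowest).
#' @param te_mean_length mean TE length bp (geometric).
#' @param expr_log_mu,expr_log_sd baseline log-expression (natural log).
#' @param beta_te dominance coupling: expression multiplier
#'   exp(-beta_te * promoter TE fraction).
#' @param ks_peaks named (ref_split, wgt) pairwise Ks targets.
#' @param n_codons CDS length in codons.
#' @param gene_len,gene_spacing gene length and start-to-start spacing, bp.
#' @param hit_noise fraction of spurious homology hits added.
#' @param frac_tandem,frac_dispersed fractions of extra tandem / dispersed
#'   duplicate genes.
#' @param n_go_terms GO vocabulary size.
#' @param with_cds generate CDS sequences (disable for speed when only the
#'   structural pipeline is exercised).
#' @return list of class `phex_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ref_seed = NULL,
                       n_ancestor_chromosomes = 9L,
                       genes_per_chromosome = 300L,
                       retention_rates = c(LF = 0.8, MF1 = 0.6, MF2 = 0.5),
                       n_rearrangements = 20L,
                       n_ref_chromosomes = 11L,
                       n_ancestor_cuts = 16L,
                       min_segment_loci = 70L,
                       te_rate_per_kb = c(LF = 0.10, MF1 = 0.25, MF2 = 0.30),
                       te_mean_length = 500,
                       expr_log_mu = 2, expr_log_sd = 1,
                       beta_te = 2,
                       ks_peaks = c(ref_split = 0.51, wgt = 0.28),
                       n_codons = 200L,
                       gene_len = 3000, gene_spacing = 8000,
                       hit_noise = 0.01,
                       frac_tandem = 0.03, frac_dispersed = 0.02,
                       n_go_terms = 50L,
                       with_cds = TRUE) {
  cfg <- as.list(environment())
  if (any(retention_rates <= 0 | retention_rates > 1))
    stop("retention rates must lie in (0, 1]")
  if (n_ancestor_cuts + n_ancestor_chromosomes < n_ref_chromosomes)
    stop("too few ancestor cuts to build that many reference chromosomes")
  if (genes_per_chromosome < 3L * min_segment_loci)
    stop("chromosomes too short for the configured minimum segment length")
  class(cfg) <- "phex_sim_config"
  cfg
}

# sample `n_cuts` interior cut gaps across chromosomes (sizes = named vector
# of gene counts), all >= min_space from ends and from each other
sample_cuts <- function(sizes, n_cuts, min_space) {
  cuts <- data.table(chrom = character(), gap = integer())
  tries <- 0L
  while (nrow(cuts) < n_cuts) {
    tries <- tries + 1L
    if (tries > 5000L) stop("could not place segment cuts; relax min spacing")
    ch <- sample(names(sizes), 1L, prob = sizes)
    n <- sizes[[ch]]
    if (n < 2L * min_space + 2L) next
    g <- sample(seq(min_space, n - min_space), 1L)
    if (nrow(cuts[chrom == ch & abs(gap - g) < min_space])) next
    cuts <- rbind(cuts, data.table(chrom = ch, gap = as.integer(g)))
  }
  setorder(cuts, chrom, gap)
  cuts
}

# distribute segments over `n_chrom` target chromosomes: random order and
# orientation, every chromosome non-empty, and no two segments from the same
# source chromosome adjacent (so every junction is a clean break)
arrange_segments <- function(segs, n_chrom) {
  n <- nrow(segs)
  if (n < n_chrom) stop("fewer segments than target chromosomes")
  for (try in 1:5000) {
    ord <- sample(n)
    src <- segs$src_chrom[ord]
    bounds <- if (n_chrom > 1L) sort(sample(seq_len(n - 1L), n_chrom - 1L)) else integer()
    grp <- findInterval(seq_len(n) - 1L, bounds) + 1L
    ok <- TRUE
    for (i in seq_len(n - 1L))
      if (grp[i] == grp[i + 1L] && src[i] == src[i + 1L]) { ok <- FALSE; break }
    if (!ok) next
    return(data.table(seg_id = segs$seg_id[ord],
                      tgt_chrom = grp,
                      tgt_pos = seq_len(n),
                      orientation = sample(c("forward", "inverted"), n,
                                           replace = TRUE)))
  }
  stop("could not arrange segments without same-source adjacencies")
}

# lay out an ordered gene list as a chromosome: bp coordinates
layout_chrom <- function(n, cfg) {
  start <- (seq_len(n) - 1L) * cfg$gene_spacing + 1000
  data.table(start = start, end = start + cfg$gene_len)
}

#' Simulate a paleohexaploid genome with known truth
#'
#' @param cfg `sim_config()`.
#' @return list of class `phex_sim`: `query` and `ref` (`phex_genome`),
#'   `hits`, `tes`, `expression` (`phex_expression`, TPM), `go`,
#'   `homology_pairs`, `cds_ref` / `cds_query` (named character, when
#'   `with_cds`), and `truth` (segments, planted breakpoints, ancestor
#'   junction signatures, ancestor gene order, per-locus retention, per-gene
#'   copy labels and duplication classes, promoter TE fractions).
#' @export
simulate_paleohexaploid <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "phex_sim_config"))
  n_ac <- cfg$n_ancestor_chromosomes
  gpc <- cfg$genes_per_chromosome
  a_chroms <- sprintf("A%02d", seq_len(n_ac))
  loci <- data.table(locus = sprintf("L%05d", seq_len(n_ac * gpc)),
                     a_chrom = rep(a_chroms, each = gpc),
                     a_rank = rep(seq_len(gpc) - 1L, times = n_ac))

  ## ===== phase A: ancestor and polyploid (seeded by `seed`) ===============
  ## the descendant genome is generated before and independently of the
  ## reference, so different `ref_seed`s view one fixed polyploid
  set.seed(cfg$seed)
  rates <- cfg$retention_rates
  copy_labels <- names(rates)
  retained <- data.table(locus = rep(loci$locus, times = 3L),
                         copy = rep(1:3, each = nrow(loci)),
                         retained = unlist(lapply(1:3, function(cix)
                           runif(nrow(loci)) < rates[[cix]])))
  copies <- lapply(1:3, function(cix) {
    keep <- retained[copy == cix & retained == TRUE]$locus
    lapply(a_chroms, function(ch) {
      idx <- loci$a_chrom == ch & loci$locus %in% keep
      data.table(locus = loci$locus[idx], strand = "+")
    })
  })
  n_ops <- cfg$n_rearrangements
  if (n_ops > 0L) for (op in seq_len(n_ops)) {
    cix <- sample(1:3, 1L)
    type <- sample(c("fission", "fusion", "inversion"), 1L,
                   prob = c(0.05, 0.15, 0.80))
    chrs <- copies[[cix]]
    nch <- length(chrs)
    if (type == "fusion" && nch >= 2L) {
      ij <- sample(nch, 2L)
      a <- chrs[[ij[1L]]]
      b <- chrs[[ij[2L]]]
      if (runif(1) < 0.5) {
        b <- b[rev(seq_len(nrow(b)))]
        b[, strand := fifelse(strand == "+", "-", "+")]
      }
      chrs[[ij[1L]]] <- rbind(a, b)
      chrs[[ij[2L]]] <- NULL
    } else if (type == "fission") {
      big <- which(vapply(chrs, nrow, integer(1)) >= 90L)
      if (length(big)) {
        i <- big[sample(length(big), 1L)]
        n <- nrow(chrs[[i]])
        cut <- sample(seq(45L, n - 45L), 1L)
        chrs[[length(chrs) + 1L]] <- chrs[[i]][(cut + 1L):n]
        chrs[[i]] <- chrs[[i]][1:cut]
      }
    } else {
      i <- sample(nch, 1L)
      g <- chrs[[i]]
      if (nrow(g) >= 10L) {
        len <- min(nrow(g), sample(5:15, 1L))
        lo <- sample(nrow(g) - len + 1L, 1L)
        win <- lo:(lo + len - 1L)
        newloc <- rev(g$locus[win])
        newstr <- rev(fifelse(g$strand[win] == "+", "-", "+"))
        g[win, `:=`(locus = newloc, strand = newstr)]
        chrs[[i]] <- g
      }
    }
    copies[[cix]] <- chrs
  }

  ## polyploid layout
  chrom_list <- list()
  for (cix in 1:3) for (k in seq_along(copies[[cix]])) {
    g <- copies[[cix]][[k]]
    if (!nrow(g)) next
    g <- copy(g)
    g[, copy := cix]
    chrom_list[[length(chrom_list) + 1L]] <- g
  }
  chrom_list <- chrom_list[sample(length(chrom_list))]
  q_chroms <- sprintf("La%02d", seq_along(chrom_list))
  qrows <- rbindlist(lapply(seq_along(chrom_list), function(i) {
    g <- chrom_list[[i]]
    data.table(q_chrom = q_chroms[i], pos = seq_len(nrow(g)),
               locus = g$locus, strand = g$strand, copy = g$copy,
               class = "WGT", src_gene = NA_character_)
  }))
  ## extra tandem / dispersed duplicates
  n_base <- nrow(qrows)
  n_tan <- round(cfg$frac_tandem * n_base)
  n_dis <- round(cfg$frac_dispersed * n_base)
  if (n_tan > 0L) {
    src <- qrows[sample(.N, n_tan)]
    ins <- copy(src)[, `:=`(class = "tandem", src_gene = src$locus,
                            pos = pos + 0.5, locus = NA_character_)]
    qrows <- rbind(qrows, ins)
  }
  if (n_dis > 0L) {
    src <- qrows[!is.na(locus)][sample(.N, n_dis)]
    ins <- copy(src)
    ins[, `:=`(class = "dispersed", src_gene = src$locus, locus = NA_character_,
               q_chrom = sample(q_chroms, n_dis, replace = TRUE),
               pos = runif(n_dis, 0.25, max(qrows$pos)))]
    qrows <- rbind(qrows, ins)
  }
  setorder(qrows, q_chrom, pos)
  qrows[, q_rank := seq_len(.N) - 1L, by = q_chrom]
  qrows[, q_id := sprintf("%sg%05d", q_chrom, (q_rank + 1L) * 10L)]
  qcoords <- qrows[, layout_chrom(.N, cfg), by = q_chrom]
  qrows[, `:=`(start = qcoords$start, end = qcoords$end)]
  q_lens <- qrows[, .(len = max(end) + 2000), by = q_chrom]
  query <- new_genome(qrows[, .(gene_id = q_id, chrom = q_chrom,
                                start = start, end = end, strand = strand)],
                      chrom_lengths = setNames(q_lens$len, q_lens$q_chrom),
                      name = "polyploid")

  ## TEs (per-sub-genome insertion rates, LF lowest)
  chrom_copy <- qrows[, .(copy = as.integer(names(which.max(table(copy))))),
                      by = q_chrom]
  te_list <- list()
  for (i in seq_len(nrow(chrom_copy))) {
    ch <- chrom_copy$q_chrom[i]
    rate <- cfg$te_rate_per_kb[[chrom_copy$copy[i]]]
    len <- q_lens[q_chrom == ch]$len
    n_te <- rpois(1L, rate * len / 1000)
    if (n_te == 0L) next
    st <- sort(round(runif(n_te, 0, len - 100)))
    ln <- 50 + rgeom(n_te, 1 / (cfg$te_mean_length - 50))
    te_list[[ch]] <- data.table(chrom = ch, start = st,
                                end = pmin(st + ln, len),
                                family = sprintf("TE%03d", sample(20L, n_te,
                                                                  replace = TRUE)))
  }
  tes <- if (length(te_list)) rbindlist(te_list) else
    data.table(chrom = character(), start = numeric(), end = numeric(),
               family = character())

  ## expression: causally coupled to promoter TE load
  prom <- promoter_te_density(query, tes, upstream = 2000)
  prom[is.na(prom)] <- 0
  tissues <- c("root", "stem", "leaf")
  base <- exp(rnorm(nrow(qrows), cfg$expr_log_mu, cfg$expr_log_sd))
  names(base) <- qrows$q_id
  mult <- exp(-cfg$beta_te * prom[qrows$q_id])
  vals <- vapply(tissues, function(tt)
    base * mult * exp(rnorm(nrow(qrows), 0, 0.3)), numeric(nrow(qrows)))
  rownames(vals) <- qrows$q_id
  vals <- sweep(vals, 2L, colSums(vals), "/") * 1e6
  expression <- expression_table(vals, unit = "TPM")

  ## CDS with planted synonymous divergence (keyed by locus and query gene)
  core <- qrows[!is.na(locus)]
  extra <- qrows[!is.na(src_gene)]
  cds_locus <- cds_query <- NULL
  if (cfg$with_cds) {
    anc <- random_fourfold_cds(nrow(loci), cfg$n_codons)
    names(anc) <- loci$locus
    k_stem <- cfg$ks_peaks[["ref_split"]] - cfg$ks_peaks[["wgt"]] / 2
    k_copy <- cfg$ks_peaks[["wgt"]] / 2
    lupin_base <- mutate_fourfold(anc, k_stem)
    copy_cds <- lapply(1:3, function(cix) mutate_fourfold(lupin_base, k_copy))
    cds_locus <- anc
    core_cds <- vapply(seq_len(nrow(core)), function(i)
      copy_cds[[core$copy[i]]][[core$locus[i]]], character(1))
    names(core_cds) <- core$q_id
    extra_cds <- character()
    if (nrow(extra))
      extra_cds <- mutate_fourfold(setNames(lupin_base[extra$src_gene],
                                            extra$q_id), 0.05)
    cds_query <- c(core_cds, extra_cds)
  }
  ## GO annotation, keyed by locus (renamed to reference ids below)
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  n_per <- pmin(1L + rpois(nrow(loci), 1), 4L)
  go_locus <- unique(data.table(locus = rep(loci$locus, times = n_per),
                                go_id = unlist(lapply(n_per, sample, x = terms))))

  ## ===== phase B: the diploid reference (seeded by `ref_seed`) ============
  set.seed(if (is.null(cfg$ref_seed)) cfg$seed + 1000L else cfg$ref_seed)
  sizes <- setNames(rep(gpc, n_ac), a_chroms)
  cuts <- sample_cuts(sizes, cfg$n_ancestor_cuts, cfg$min_segment_loci)
  segs <- list()
  for (ch in a_chroms) {
    g <- c(0L, cuts[chrom == ch]$gap, gpc)
    for (i in seq_len(length(g) - 1L))
      segs[[length(segs) + 1L]] <- data.table(src_chrom = ch,
                                              a_start = g[i],
                                              a_end = g[i + 1L] - 1L)
  }
  segs <- rbindlist(segs)
  setorder(segs, src_chrom, a_start)
  segs[, seg_id := sprintf("S%02d", .I)]
  arr <- arrange_segments(segs, cfg$n_ref_chromosomes)
  segs <- merge(segs, arr, by = "seg_id")
  setorder(segs, tgt_chrom, tgt_pos)

  r_chroms <- sprintf("Pv%02d", seq_len(cfg$n_ref_chromosomes))
  ref_rows <- list()
  seg_ref <- list()
  for (tc in seq_len(cfg$n_ref_chromosomes)) {
    ss <- segs[tgt_chrom == tc]
    rank0 <- 0L
    for (i in seq_len(nrow(ss))) {
      idx <- which(loci$a_chrom == ss$src_chrom[i] &
                     loci$a_rank >= ss$a_start[i] & loci$a_rank <= ss$a_end[i])
      if (ss$orientation[i] == "inverted") idx <- rev(idx)
      k <- length(idx)
      ref_rows[[length(ref_rows) + 1L]] <-
        data.table(locus = loci$locus[idx], r_chrom = r_chroms[tc],
                   r_rank = rank0 + seq_len(k) - 1L,
                   strand = if (ss$orientation[i] == "inverted") "-" else "+")
      seg_ref[[length(seg_ref) + 1L]] <-
        data.table(seg_id = ss$seg_id[i], r_chrom = r_chroms[tc],
                   r_start_rank = rank0, r_end_rank = rank0 + k - 1L,
                   r_orient = ss$orientation[i])
      rank0 <- rank0 + k
    }
  }
  ref_map <- rbindlist(ref_rows)
  seg_ref <- rbindlist(seg_ref)
  ref_map[, r_id := sprintf("%sg%04d", r_chrom, r_rank + 1L)]
  ref_genes <- ref_map[order(r_chrom, r_rank)]
  coords <- ref_genes[, layout_chrom(.N, cfg), by = r_chrom]
  ref_genes[, `:=`(start = coords$start, end = coords$end)]
  ref_lens <- ref_genes[, .(len = max(end) + 2000), by = r_chrom]
  ref <- new_genome(ref_genes[, .(gene_id = r_id, chrom = r_chrom,
                                  start = start, end = end, strand = strand)],
                    chrom_lengths = setNames(ref_lens$len, ref_lens$r_chrom),
                    name = "reference")

  ## truth: planted reference breakpoints & ancestor junction signatures
  planted_bp <- seg_ref[r_start_rank > 0L,
                        .(chrom = r_chrom, gap = r_start_rank)]
  segs_a <- copy(segs); setorder(segs_a, src_chrom, a_start)
  anc_junctions <- segs_a[, if (.N > 1L) .(p = seg_id[-.N], q = seg_id[-1L]),
                          by = src_chrom]
  seg_orient <- setNames(seg_ref$r_orient, seg_ref$seg_id)
  anc_end <- function(seg, side) {
    # side "left"/"right" in ancestor reading direction -> block end in ref
    fw <- seg_orient[seg] == "forward"
    pick <- ifelse(fw == (side == "left"), "h", "t")
    paste0(seg, ".", pick)
  }
  truth_junc <- if (nrow(anc_junctions)) {
    e1 <- anc_end(anc_junctions$p, "right")
    e2 <- anc_end(anc_junctions$q, "left")
    sort(ifelse(e1 < e2, paste0(e1, "|", e2), paste0(e2, "|", e1)))
  } else character()
  locus_seg <- seg_assign_loci(segs_a, loci)

  ## ===== phase C: observables tied to reference ids =======================
  set.seed(cfg$seed + 777L)
  ref_of <- setNames(ref_map$r_id, ref_map$locus)
  hits <- data.table(query_id = core$q_id, subject_id = ref_of[core$locus],
                     e_value = 10^-runif(nrow(core), 50, 180),
                     identity_pct = runif(nrow(core), 75, 95),
                     coverage_pct = runif(nrow(core), 85, 100))
  hits[, bitscore := round(identity_pct * 5)]
  n_noise <- round(cfg$hit_noise * nrow(core))
  if (n_noise > 0L) {
    noise <- data.table(query_id = sample(qrows$q_id, n_noise, replace = TRUE),
                        subject_id = sample(ref_map$r_id, n_noise, replace = TRUE),
                        e_value = 10^-runif(n_noise, 5, 30),
                        identity_pct = runif(n_noise, 40, 60),
                        coverage_pct = runif(n_noise, 30, 80))
    noise[, bitscore := round(identity_pct * 2)]
    hits <- rbind(hits, noise)
    hits <- unique(hits, by = c("query_id", "subject_id"))
  }
  ## within-genome homology pairs (for duplication classification)
  wgt_pairs <- merge(core[, .(q_id, locus, copy)],
                     core[, .(mate = q_id, locus, mate_copy = copy)],
                     by = "locus", allow.cartesian = TRUE)[q_id < mate]
  extra_pairs <- merge(extra[, .(q_id, src_gene)],
                       core[, .(mate = q_id, src_gene = locus)],
                       by = "src_gene", allow.cartesian = TRUE)
  homology_pairs <- rbind(wgt_pairs[, .(gene_a = q_id, gene_b = mate)],
                          extra_pairs[, .(gene_a = q_id, gene_b = mate)])
  go <- go_locus[, .(gene_id = ref_of[locus], go_id)]
  cds_ref <- if (!is.null(cds_locus))
    setNames(cds_locus[ref_map$locus], ref_map$r_id) else NULL

  ## truth tables
  label_of <- setNames(copy_labels, as.character(1:3))
  truth <- list(
    config = cfg,
    segments = merge(seg_ref, segs_a[, .(seg_id, a_chrom = src_chrom, a_start,
                                         a_end)], by = "seg_id"),
    planted_breakpoints = planted_bp[order(chrom, gap)],
    ancestor_junctions = truth_junc,
    ancestor_order = loci[, .(locus, a_chrom, a_rank)],
    retained = retained,
    locus_segment = data.table(locus = names(locus_seg), seg_id = locus_seg),
    genes = qrows[, .(q_id, q_chrom, q_rank, locus, copy,
                      copy_label = label_of[as.character(copy)], class,
                      src_gene)],
    promoter_te = prom,
    ref_of_locus = ref_of
  )
  structure(list(query = query, ref = ref, hits = hits[], tes = tes,
                 expression = expression, go = go,
                 homology_pairs = homology_pairs,
                 cds_ref = cds_ref, cds_query = cds_query, truth = truth),
            class = "phex_sim")
}

# locus -> containing ancestor segment id
seg_assign_loci <- function(segs_a, loci) {
  out <- character(nrow(loci))
  for (i in seq_len(nrow(segs_a))) {
    idx <- which(loci$a_chrom == segs_a$src_chrom[i] &
                   loci$a_rank >= segs_a$a_start[i] &
                   loci$a_rank <= segs_a$a_end[i])
    out[idx] <- segs_a$seg_id[i]
  }
  setNames(out, loci$locus)
}

# random CDS over the six fourfold codon families without positional
# degeneracy elsewhere (GGx GCx GTx CCx ACx TCx): every third position is
# exactly one synonymous site and the CDS is stop-free
FOURFOLD_PREFIX6 <- c("GG", "GC", "GT", "CC", "AC", "TC")
random_fourfold_cds <- function(n_seq, n_codons) {
  pf <- sample(FOURFOLD_PREFIX6, n_seq * n_codons, replace = TRUE)
  third <- sample(BASES, n_seq * n_codons, replace = TRUE)
  codons <- paste0(pf, third)
  m <- matrix(codons, nrow = n_seq)
  apply(m, 1L, paste, collapse = "")
}

# Poisson(k) substitution events per third position, each a jump to one of
# the three other bases (Jukes-Cantor on synonymous sites)
mutate_fourfold <- function(cds, k) {
  nm <- names(cds)
  n_seq <- length(cds)
  n_codons <- nchar(cds[[1L]]) %/% 3L
  m <- matrix(unlist(strsplit(cds, "")), nrow = n_seq, byrow = TRUE)
  third_cols <- seq(3L, 3L * n_codons, by = 3L)
  thirds <- m[, third_cols, drop = FALSE]
  events <- matrix(rpois(length(thirds), k), nrow = n_seq)
  while (any(events > 0)) {
    idx <- which(events > 0)
    off <- sample.int(3L, length(idx), replace = TRUE)
    thirds[idx] <- BASES[((match(thirds[idx], BASES) - 1L + off) %% 4L) + 1L]
    events[idx] <- events[idx] - 1L
  }
  m[, third_cols] <- thirds
  setNames(apply(m, 1L, paste, collapse = ""), nm)
}
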