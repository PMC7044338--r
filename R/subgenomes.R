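## Partitioning the triplicated genome into LF / MF1 / MF2.
##
## Retention density is measured per ancestral gene locus in a centered
## window of 1001 loci (500 each side, truncated at chromosome ends);
## copies of each ancestral chromosome are ranked by mean density:
## least fractionated (LF), more fractionated 1 and 2 (MF1, MF2).

#' Sliding-window retention profile per sub-genome copy
#'
#' @param ancestor_order data.frame(locus, a_chrom, a_rank): the ancestral
#'   gene order (one row per locus; `a_rank` 0-based within chromosome).
#' @param retained data.frame(locus, copy, retained): per copy, whether each
#'   locus has a surviving homolog (logical). Copies are arbitrary ids.
#' @param window centered window size in loci (odd; default 1001).
#' @return data.table(locus, a_chrom, a_rank, copy, density) with density in
#'   percent, windows truncated at chromosome ends and never crossing
#'   chromosomes.
#' @export
retention_profile <- function(ancestor_order, retained, window = 1001L) {
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3 loci")
  half <- window %/% 2L
  ao <- as.data.table(ancestor_order)
  rt <- as.data.table(retained)
  out <- list()
  for (cp in unique(rt$copy)) {
    flags <- rt[copy == cp]
    m <- merge(ao, flags[, .(locus, retained)], by = "locus", all.x = TRUE)
    m[is.na(retained), retained := FALSE]
    setorder(m, a_chrom, a_rank)
    m[, density := {
      x <- as.numeric(retained)
      n <- .N
      cs <- cumsum(x)
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      wsum <- cs[hi] - c(0, cs)[lo]
      100 * wsum / (hi - lo + 1L)
    }, by = a_chrom]
    out[[as.character(cp)]] <- m[, .(locus, a_chrom, a_rank, copy = cp, density)]
  }
  rbindlist(out)[]
}

#' Rank sub-genome copies into LF / MF1 / MF2
#'
#' Per assignment unit (by default the ancestral chromosome), the up-to-three
#' copies are ordered by mean retention density; the densest is LF, then
#' MF1, then MF2. Ties are broken by total retained gene count, then copy
#' id. More than three copies in a unit violates the triplication model and
#' errors.
#'
#' @param profile output of [retention_profile()]; its `a_chrom` is used as
#'   the unit unless a `unit` column is present.
#' @return data.table(unit, copy, label, mean_density, n_retained).
#' @export
assign_subgenomes <- function(profile) {
  pr <- as.data.table(profile)
  if (!"unit" %in% names(pr)) pr[, unit := a_chrom]
  agg <- pr[, .(mean_density = mean(density),
                n_retained = sum(density > 0)), by = .(unit, copy)]
  bad <- agg[, .N, by = unit][N > 3L]
  if (nrow(bad))
    stop("more than 3 copies in unit ", bad$unit[1L],
         ": violates the triplication model")
  setorder(agg, unit, -mean_density, -n_retained, copy)
  agg[, label := c("LF", "MF1", "MF2")[seq_len(.N)], by = unit]
  agg[]
}

# feasible 3-painting assignments of items within one conflict component:
# no painting may contain two items overlapping in ancestral rank space
paintings_feasible <- function(olap, assign_vec) {
  if (!nrow(olap)) return(TRUE)
  !any(assign_vec[olap$i] == assign_vec[olap$j])
}

#' Distribute fragments into three sub-genome paintings
#'
#' Rule 1: a painting never holds two fragments overlapping the same
#' ancestral interval. Rule 2: among feasible distributions the one with the
#' fewest genomic rearrangements is chosen, counted as adjacency breaks:
#' within a painting, consecutive fragments (in ancestral order) lying on
#' different polyploid chromosomes. Components larger than `component_cap`
#' fall back to a greedy first-fit with a warning. Ties are resolved by the
#' first minimal assignment in lexicographic order.
#'
#' @param items data.frame(item_id, q_chrom, unit, a_start, a_end): one row
#'   per fragment (or per-chromosome fragment run) with its ancestral-rank
#'   interval within its unit. An optional list-column `loci` (ancestral
#'   locus ids covered by the item) refines the conflict test: two items
#'   conflict only when they share more than one locus (redundant
#'   coverage), which is robust both to interval inflation by straggler
#'   pairs and to a single spurious shared pair from homology noise.
#' @param component_cap exhaustive-search cap on component size.
#' @return the items table with a `painting` column (1..3).
#' @export
reconstruct_subgenome_chromosomes <- function(items, component_cap = 12L) {
  it <- copy(as.data.table(items))
  it[, painting := NA_integer_]
  has_loci <- "loci" %in% names(it)
  for (u in unique(it$unit)) {
    idx <- which(it$unit == u)
    sub <- it[idx]
    n <- nrow(sub)
    ov <- data.table(i = integer(), j = integer())
    if (n > 1L) {
      cmb <- utils::combn(n, 2L)
      keep <- sub$a_start[cmb[1L, ]] <= sub$a_end[cmb[2L, ]] &
        sub$a_start[cmb[2L, ]] <= sub$a_end[cmb[1L, ]]
      if (has_loci && any(keep)) {
        for (kk in which(keep))
          keep[kk] <- length(intersect(sub$loci[[cmb[1L, kk]]],
                                       sub$loci[[cmb[2L, kk]]])) > 1L
      }
      ov <- data.table(i = cmb[1L, keep], j = cmb[2L, keep])
    }
    # connected components of the overlap graph
    comp <- seq_len(n)
    if (nrow(ov)) for (k in seq_len(nrow(ov))) {
      a <- comp[ov$i[k]]; b <- comp[ov$j[k]]
      if (a != b) comp[comp == b] <- a
    }
    dens <- if (has_loci)
      vapply(seq_len(n), function(i)
        length(sub$loci[[i]]) / (sub$a_end[i] - sub$a_start[i] + 1),
        numeric(1)) else rep(0, n)
    ## components are solved in chromosome order, each scored against the
    ## items already painted, so rule 2 (fewest rearrangements) acts across
    ## the whole ancestral chromosome, not within isolated depth groups
    comp_order <- unique(comp[order(vapply(seq_len(n), function(i)
      min(sub$a_start[comp == comp[i]]), numeric(1)))])
    assign_vec <- rep(NA_integer_, n)
    for (cp in comp_order) {
      mem <- which(comp == cp)
      k <- length(mem)
      olap <- ov[i %in% mem & j %in% mem]
      olap[, i := match(i, mem)]; olap[, j := match(j, mem)]
      done <- which(!is.na(assign_vec))
      score_of <- function(av) {
        ids <- c(done, mem)
        full <- assign_vec; full[mem] <- av
        breaks <- painting_breaks(sub[ids], full[ids])
        spread <- sum(vapply(1:3, function(p) {
          d <- dens[ids][full[ids] == p]
          if (length(d) > 1L) max(d) - min(d) else 0
        }, numeric(1)))
        c(breaks, spread)
      }
      if (k > component_cap) {
        warning("conflict component of ", k, " fragments in unit ", u,
                "; falling back to greedy painting")
        assign_vec[mem] <- greedy_painting(sub[mem], olap)
      } else {
        grid <- as.matrix(expand.grid(rep(list(1:3), k)))
        best <- NULL; best_score <- c(Inf, Inf)
        for (gi in seq_len(nrow(grid))) {
          av <- grid[gi, ]
          if (!paintings_feasible(olap, av)) next
          sc <- score_of(av)
          if (sc[1L] < best_score[1L] ||
              (sc[1L] == best_score[1L] && sc[2L] < best_score[2L] - 1e-12)) {
            best_score <- sc; best <- av
          }
        }
        if (is.null(best))
          stop("infeasible conflict component in unit ", u,
               " (more than 3-fold depth): loci ",
               paste(sub$item_id[mem], collapse = ", "))
        assign_vec[mem] <- best
      }
    }
    it[idx, painting := assign_vec]
  }
  it[]
}

# adjacency breaks: within each painting, consecutive items (by ancestral
# start) on different polyploid chromosomes
painting_breaks <- function(sub, av) {
  breaks <- 0L
  for (p in unique(av)) {
    mem <- which(av == p)
    if (length(mem) < 2L) next
    mem <- mem[order(sub$a_start[mem])]
    breaks <- breaks + sum(sub$q_chrom[mem][-1L] != sub$q_chrom[mem][-length(mem)])
  }
  breaks
}

greedy_painting <- function(sub, olap) {
  n <- nrow(sub)
  av <- rep(NA_integer_, n)
  for (cur in order(sub$a_start)) {
    used <- unique(av[c(olap[j == cur]$i, olap[i == cur]$j)])
    used <- used[!is.na(used)]
    free <- setdiff(1:3, used)
    if (!length(free))
      stop("infeasible conflict component (more than 3-fold depth) at item ",
           sub$item_id[cur])
    # prefer the painting whose latest item shares this item's chromosome
    pick <- free[1L]
    for (f in free) {
      prev <- which(av == f)
      if (length(prev) &&
          sub$q_chrom[prev[which.max(sub$a_end[prev])]] == sub$q_chrom[cur]) {
        pick <- f; break
      }
    }
    av[cur] <- pick
  }
  av
}

#' Retention counts per sub-genome and uniformity chi-square
#'
#' @param gene_labels data.frame(gene_id, label) with label in LF/MF1/MF2:
#'   polyploid genes having a syntenic reference ortholog, with their
#'   sub-genome.
#' @param ref_multiplicity optional data.frame(r_id, multiplicity): per
#'   reference gene, how many retained copies (0..3); multiplicities above 3
#'   are an error.
#' @return list of class `phex_retention`: counts (named LF/MF1/MF2),
#'   multiplicity histogram, chisq statistic, df, p_value.
#' @export
retention_counts <- function(gene_labels, ref_multiplicity = NULL) {
  gl <- as.data.table(gene_labels)
  counts <- c(LF = nrow(gl[label == "LF"]),
              MF1 = nrow(gl[label == "MF1"]),
              MF2 = nrow(gl[label == "MF2"]))
  ht <- NULL
  if (!is.null(ref_multiplicity)) {
    rm_ <- as.data.table(ref_multiplicity)
    if (any(rm_$multiplicity > 3L))
      stop("reference gene with more than 3 retained copies: ",
           rm_[multiplicity > 3L]$r_id[1L])
    ht <- vapply(0:3, function(k) sum(rm_$multiplicity == k), integer(1))
    names(ht) <- as.character(0:3)
  }
  tot <- sum(counts)
  if (tot > 0) {
    expd <- rep(tot / 3, 3)
    stat <- sum((counts - expd)^2 / expd)
    p <- pchisq(stat, df = 2, lower.tail = FALSE)
  } else { stat <- NA_real_; p <- NA_real_ }
  structure(list(counts = counts, multiplicity = ht,
                 chisq = stat, df = 2L, p_value = p),
            class = "phex_retention")
}

#' @export
print.phex_retention <- function(x, ...) {
  cat(sprintf("<phex_retention: LF=%d MF1=%d MF2=%d, chisq=%.3f, p=%.3g>\n",
              x$counts[["LF"]], x$counts[["MF1"]], x$counts[["MF2"]],
              x$chisq, x$p_value))
  invisible(x)
}
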