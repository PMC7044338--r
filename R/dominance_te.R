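## Homoeolog expression dominance and transposable-element density profiles.

#' Flag the bottom 1% of genes of a tissue as not expressed
#'
#' Genes are sorted by expression (high to low) within the tissue; the
#' lowest floor(0.01 n) genes are flagged, with ties at the cut value all
#' flagged.
#'
#' @param expr_values named numeric vector of TPM for one tissue.
#' @param fraction flagged fraction (default 0.01).
#' @return logical vector (same names): TRUE = treated as not expressed.
#' @export
bottom_fraction_flags <- function(expr_values, fraction = 0.01) {
  n <- length(expr_values)
  k <- floor(fraction * n)
  if (k < 1L) return(setNames(rep(FALSE, n), names(expr_values)))
  cut <- sort(expr_values, partial = k)[k]
  setNames(expr_values <= cut, names(expr_values))
}

#' Call expression dominance within paralog doublets
#'
#' Bottom-1% genes contribute expression 0. A doublet is evaluable when the
#' larger of the two (zeroed) values exceeds 5 TPM. `gene_a` is called
#' dominant when expr_a >= f * expr_b (and not vice versa); symmetric for
#' `gene_b`; both or neither direction yields `neutral`.
#'
#' @param doublets data.frame(gene_a, gene_b, pair) where `pair` names the
#'   sub-genome pair (e.g. "LF-MF1").
#' @param expr `phex_expression` in TPM.
#' @param tissue sample column to use.
#' @param f fold threshold (1, 1.5, 2, 3, 4, 6, 10, ...).
#' @param min_expr evaluability threshold (default 5, exclusive).
#' @param bottom_fraction not-expressed fraction (default 0.01).
#' @return data.table(gene_a, gene_b, pair, tissue, f, expr_a, expr_b, call)
#'   with call in a_dominant / b_dominant / neutral / not_evaluable.
#' @export
call_dominance <- function(doublets, expr, tissue, f = 2,
                           min_expr = 5, bottom_fraction = 0.01) {
  stopifnot(inherits(expr, "phex_expression"))
  if (expr$unit != "TPM") stop("expression must be TPM; run to_tpm() first")
  if (!tissue %in% colnames(expr$values)) stop("unknown tissue: ", tissue)
  v <- expr$values[, tissue]
  flags <- bottom_fraction_flags(v, bottom_fraction)
  v[flags] <- 0
  d <- as.data.table(doublets)
  miss <- setdiff(c(d$gene_a, d$gene_b), names(v))
  if (length(miss)) stop("doublet gene missing from expression table: ", miss[1L])
  ea <- v[d$gene_a]; eb <- v[d$gene_b]
  evaluable <- pmax(ea, eb) > min_expr
  a_dom <- ea >= f * eb
  b_dom <- eb >= f * ea
  call <- fifelse(!evaluable, "not_evaluable",
                  fifelse(a_dom & !b_dom, "a_dominant",
                          fifelse(b_dom & !a_dom, "b_dominant", "neutral")))
  d[, `:=`(tissue = tissue, f = f, expr_a = ea, expr_b = eb, call = call)]
  d[]
}

#' Exact two-sided binomial test for dominance direction bias
#'
#' Tests n_a successes in n_a + n_b trials at p = 1/2. The primary p-value
#' sums the probabilities of all outcomes no more likely than the observed
#' one; the doubled smaller tail (capped at 1) is reported alongside (the
#' two agree for p = 1/2 up to probability ties).
#'
#' @param n_a,n_b direction counts (non-negative, not both zero).
#' @return list of class `phex_binom`: p_value (minlike), p_two_tail,
#'   n_a, n_b.
#' @export
dominance_binomial_test <- function(n_a, n_b) {
  if (n_a < 0 || n_b < 0) stop("negative count")
  n <- n_a + n_b
  if (n < 1) stop("n_a + n_b must be at least 1")
  probs <- dbinom(0:n, n, 0.5)
  obs <- probs[n_a + 1L]
  p_minlike <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  lo <- sum(probs[0:min(n_a, n_b) + 1L])
  p_two_tail <- min(1, 2 * lo)
  structure(list(p_value = p_minlike, p_two_tail = p_two_tail,
                 n_a = n_a, n_b = n_b),
            class = "phex_binom")
}

#' @export
print.phex_binom <- function(x, ...) {
  cat(sprintf("<phex_binom: %d vs %d, p = %.3g>\n", x$n_a, x$n_b, x$p_value))
  invisible(x)
}

# merge overlapping TE intervals per chromosome -> data.table(chrom,start,end)
merge_te <- function(tes) {
  te <- as.data.table(tes)
  if (!nrow(te)) return(te[, .(chrom, start, end)])
  out <- te[, {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
    .(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }, by = chrom]
  out[]
}

# TE bp overlapping each window; windows and TEs 0-based half-open
window_te_coverage <- function(win, merged) {
  w <- copy(win)
  w[, wid := .I]
  j <- merged[w, on = .(chrom, end > start, start < end), allow.cartesian = TRUE,
              .(wid = i.wid, ov = pmin(x.end, i.end) - pmax(x.start, i.start))]
  cov <- j[!is.na(ov) & ov > 0, .(te_bp = sum(ov)), by = wid]
  out <- rep(0, nrow(w))
  if (nrow(cov)) out[cov$wid] <- cov$te_bp
  out
}

#' TE density profile in gene flanking regions
#'
#' Sliding windows (default 100 bp, step 10 bp) across the 5' and 3' flanks
#' of each gene, orientation following the gene strand; in each window the
#' TE nucleotide fraction is computed against the merged TE set, and the
#' profile is the per-window mean over genes. Windows extending beyond a
#' chromosome end are excluded from that window's mean.
#'
#' @param genome `phex_genome`.
#' @param tes TE table (chrom, start, end), 0-based half-open.
#' @param gene_ids subset of genes to profile (default: all).
#' @param flank_bp flank length per side (default 3000).
#' @param window window size bp.
#' @param step step size bp.
#' @return data.table(side, offset, mean_density, n_genes): `offset` is the
#'   distance of the window start from the gene boundary (0-based, moving
#'   away from the gene); side is "5p" or "3p".
#' @export
te_profile <- function(genome, tes, gene_ids = NULL, flank_bp = 3000,
                       window = 100, step = 10) {
  g <- genome$genes
  if (!is.null(gene_ids)) g <- g[gene_id %in% gene_ids]
  if (!nrow(g)) stop("no genes to profile")
  merged <- merge_te(tes)
  offs <- seq(0, flank_bp - window, by = step)
  lens <- genome$chrom_lengths
  mk <- function(side) {
    # upstream of the 5' end / downstream of the 3' end, strand-aware
    up <- (side == "5p") == (g$strand == "+")
    anchor <- ifelse(up, g$start, g$end)
    wl <- data.table(gene_id = rep(g$gene_id, each = length(offs)),
                     chrom = rep(g$chrom, each = length(offs)),
                     anchor = rep(anchor, each = length(offs)),
                     up = rep(up, each = length(offs)),
                     offset = rep(offs, times = nrow(g)))
    wl[, start := ifelse(up, anchor - offset - window, anchor + offset)]
    wl[, end := start + window]
    wl[, ok := start >= 0 & end <= lens[chrom]]
    wl <- wl[ok == TRUE]
    if (!nrow(wl)) return(data.table(side = character(), offset = numeric(),
                                     mean_density = numeric(), n_genes = integer()))
    wl[, te_bp := window_te_coverage(.SD[, .(chrom, start, end)], merged)]
    prof <- wl[, .(mean_density = mean(te_bp / window), n_genes = .N),
               by = offset]
    data.table(side = side, prof)
  }
  out <- rbind(mk("5p"), mk("3p"))
  setorder(out, side, offset)
  out[]
}

#' Promoter TE density for each gene
#'
#' Promoter = `upstream` bp upstream of the transcription start site
#' (strand-aware: left of start for "+", right of end for "-"), truncated at
#' the chromosome boundary; density = merged-TE covered bp / promoter
#' length.
#'
#' @param genome `phex_genome`.
#' @param tes TE table.
#' @param upstream promoter length bp (default 2000).
#' @return named numeric vector of fractions in `[0,1]` (NA when the
#'   truncated promoter has zero length).
#' @export
promoter_te_density <- function(genome, tes, upstream = 2000) {
  g <- genome$genes
  merged <- merge_te(tes)
  lens <- genome$chrom_lengths
  pstart <- ifelse(g$strand == "+", g$start - upstream, g$end)
  pend <- ifelse(g$strand == "+", g$start, g$end + upstream)
  pstart <- pmax(pstart, 0)
  pend <- pmin(pend, lens[g$chrom])
  win <- data.table(chrom = g$chrom, start = pstart, end = pend)
  plen <- pend - pstart
  dens <- rep(NA_real_, nrow(g))
  pos <- plen > 0
  if (any(pos)) {
    cov <- window_te_coverage(win[pos], merged)
    dens[pos] <- cov / plen[pos]
  }
  setNames(dens, g$gene_id)
}

#' Compare promoter TE density between dominant and suppressed homoeologs
#'
#' For doublets with a directional call at one fold threshold, contrasts the
#' promoter TE density of the dominant member against the suppressed one
#' (two-sided Wilcoxon rank-sum).
#'
#' @param calls output of [call_dominance()] at a single `f`.
#' @param densities named vector from [promoter_te_density()].
#' @return list of class `phex_te_dominance`: mean_dominant,
#'   mean_suppressed, n, p_value.
#' @export
compare_te_by_dominance <- function(calls, densities) {
  cl <- as.data.table(calls)
  if (length(unique(cl$f)) > 1L) stop("calls mix fold thresholds")
  cl <- cl[call %in% c("a_dominant", "b_dominant")]
  if (nrow(cl) < 2L) stop("fewer than 2 evaluable directional doublets")
  dom <- fifelse(cl$call == "a_dominant", cl$gene_a, cl$gene_b)
  sup <- fifelse(cl$call == "a_dominant", cl$gene_b, cl$gene_a)
  dd <- densities[dom]; ds <- densities[sup]
  keep <- !is.na(dd) & !is.na(ds)
  dd <- dd[keep]; ds <- ds[keep]
  if (length(dd) < 2L) stop("fewer than 2 doublets with promoter densities")
  p <- if (all(dd == ds)) 1 else
    suppressWarnings(wilcox.test(dd, ds, alternative = "two.sided")$p.value)
  structure(list(mean_dominant = mean(dd), mean_suppressed = mean(ds),
                 n = length(dd), p_value = p),
            class = "phex_te_dominance")
}

#' @export
print.phex_te_dominance <- function(x, ...) {
  cat(sprintf(
    "<phex_te_dominance: dominant %.4f vs suppressed %.4f (n=%d, p=%.3g)>\n",
    x$mean_dominant, x$mean_suppressed, x$n, x$p_value))
  invisible(x)
}
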