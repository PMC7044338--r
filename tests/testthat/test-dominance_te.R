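library(data.table)

make_expr <- function(values, tissue = "leaf") {
  m <- matrix(values, ncol = 1, dimnames = list(names(values), tissue))
  expression_table(m, unit = "TPM")
}

test_that("dominance calls follow the fold and evaluability rules", {
  v <- c(a = 10, b = 4, c = 40, d = 40, e = 4, f = 1, t1 = 0.01, t2 = 0.02,
         setNames(rep(100, 192), sprintf("x%03d", 1:192)))
  expr <- make_expr(v)
  dbl <- data.table(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                    pair = "LF-MF1")
  calls <- call_dominance(dbl, expr, "leaf", f = 2)
  # (10,4): two-fold dominant; (40,40): neither direction; (4,1): below the
  # >5 evaluability floor
  expect_equal(calls$call, c("a_dominant", "neutral", "not_evaluable"))
  expect_error(call_dominance(dbl, expr, "root", f = 2), "unknown tissue")
})

test_that("bottom-1% genes count as not expressed", {
  n <- 300
  v <- setNames(seq(10, 3000, length.out = n), sprintf("g%03d", 1:n))
  flags <- bottom_fraction_flags(v)
  expect_equal(sum(flags), 3L)  # floor(0.01 * 300)
  expect_true(all(names(which(flags)) == names(sort(v)[1:3])))
  # a flagged partner contributes 0, so the pair is dominant at any fold
  expr <- make_expr(v)
  dbl <- data.table(gene_a = "g299", gene_b = "g001", pair = "LF-MF1")
  expect_equal(call_dominance(dbl, expr, "leaf", f = 10)$call, "a_dominant")
})

test_that("dominance calls equal a literal rule re-implementation", {
  set.seed(13)
  n <- 400
  v <- setNames(c(rexp(n - 4, 1 / 50), 0, 0, 0, 0), sprintf("g%03d", 1:n))
  expr <- make_expr(v)
  dbl <- data.table(gene_a = sample(names(v), 150),
                    gene_b = sample(names(v), 150), pair = "LF-MF1")
  dbl <- dbl[gene_a != gene_b]
  f <- 2
  calls <- call_dominance(dbl, expr, "leaf", f = f)
  cut <- sort(v)[floor(0.01 * n)]
  vv <- ifelse(v <= cut, 0, v)
  expected <- vapply(seq_len(nrow(dbl)), function(i) {
    ea <- vv[dbl$gene_a[i]]; eb <- vv[dbl$gene_b[i]]
    if (max(ea, eb) <= 5) return("not_evaluable")
    ad <- ea >= f * eb; bd <- eb >= f * ea
    if (ad && !bd) "a_dominant" else if (bd && !ad) "b_dominant" else "neutral"
  }, character(1))
  expect_equal(calls$call, expected)
  # order invariance
  calls2 <- call_dominance(dbl[rev(seq_len(.N))], expr, "leaf", f = f)
  expect_equal(calls2$call, rev(calls$call))
})

test_that("exact binomial test matches enumeration and symmetry", {
  expect_equal(dominance_binomial_test(5, 5)$p_value, 1)
  expect_equal(dominance_binomial_test(7, 1)$p_value, 18 / 256)
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    if (a + b == 0) a <- 1
    pab <- dominance_binomial_test(a, b)
    pba <- dominance_binomial_test(b, a)
    expect_equal(pab$p_value, pba$p_value)
    expect_true(pab$p_value > 0 && pab$p_value <= 1)
    # stats::binom.test uses the same minimum-likelihood convention
    expect_equal(pab$p_value, binom.test(a, a + b, 0.5)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(dominance_binomial_test(0, 0), "at least 1")
})

test_that("TE profile equals interval arithmetic on a planted TE", {
  g <- new_genome(data.frame(gene_id = "g1", chrom = "c1",
                             start = 5000, end = 8000, strand = "+"),
                  chrom_lengths = c(c1 = 20000))
  # TE covering 4000..4500: 500 bp immediately 5' of the gene minus 500
  tes <- data.table(chrom = "c1", start = 4000, end = 4500, family = "t")
  pr <- te_profile(g, tes, flank_bp = 1000, window = 100, step = 10)
  p5 <- pr[side == "5p"]
  # window at offset 0 covers [4900,5000): no TE; offset 600 covers
  # [4400,4500): fully inside the TE
  expect_equal(p5[offset == 0]$mean_density, 0)
  expect_equal(p5[offset == 600]$mean_density, 1)    # [4300,4400) inside TE
  expect_equal(p5[offset == 450]$mean_density, 0.5)  # [4450,4550): half
  expect_true(all(pr$mean_density >= 0 & pr$mean_density <= 1))
  # no TEs at all
  pr0 <- te_profile(g, tes[0], flank_bp = 1000)
  expect_true(all(pr0$mean_density == 0))
})

test_that("promoter density is strand-aware and matches a bitmap oracle", {
  g <- new_genome(data.frame(gene_id = c("p", "m"), chrom = "c1",
                             start = c(10000, 30000), end = c(12000, 32000),
                             strand = c("+", "-")),
                  chrom_lengths = c(c1 = 50000))
  tes <- data.table(chrom = "c1",
                    start = c(9500, 32000), end = c(10000, 32500),
                    family = "t")
  d <- promoter_te_density(g, tes, upstream = 2000)
  expect_equal(unname(d["p"]), 0.25)  # 500 of 2000 bp upstream of start
  expect_equal(unname(d["m"]), 0.25)  # minus strand: promoter right of end
  # random fixture vs per-base bitmap
  set.seed(8)
  starts <- round(seq(5000, 95000, length.out = 20))
  genes <- new_genome(data.frame(gene_id = sprintf("g%d", 1:20), chrom = "c1",
                                 start = starts, end = starts + 2000,
                                 strand = sample(c("+", "-"), 20, TRUE)),
                      chrom_lengths = c(c1 = 120000))
  rt <- data.table(chrom = "c1", start = sort(sample(0:110000, 40)))
  rt[, end := start + sample(100:2000, 40, TRUE)]
  rt[, family := "t"]
  dd <- promoter_te_density(genes, rt, upstream = 2000)
  gg <- genes$genes
  for (i in seq_len(nrow(gg))) {
    lo <- if (gg$strand[i] == "+") max(0, gg$start[i] - 2000) else gg$end[i]
    hi <- if (gg$strand[i] == "+") gg$start[i] else min(120000, gg$end[i] + 2000)
    expect_equal(unname(dd[gg$gene_id[i]]), orc_bitmap_cover(rt, "c1", lo, hi),
                 tolerance = 1e-12)
  }
})

test_that("dominant homoeologs carry less promoter TE than suppressed ones", {
  sim <- cached_sim(1, noise = 20L)
  tg <- sim$truth$genes[class == "WGT"]
  gl <- data.table(gene_id = tg$q_id, r_id = sim$truth$ref_of_locus[tg$locus],
                   label = tg$copy_label)
  dbl <- paralog_doublets(gl)
  calls <- call_dominance(dbl[pair == "LF-MF1"], sim$expression, "leaf", f = 2)
  dens <- promoter_te_density(sim$query, sim$tes)
  cmp <- compare_te_by_dominance(calls, dens)
  expect_lt(cmp$mean_dominant, cmp$mean_suppressed)
  expect_lt(cmp$p_value, 0.01)
  # degenerate input: identical densities -> p = 1
  flat <- setNames(rep(0.1, length(dens)), names(dens))
  expect_equal(compare_te_by_dominance(calls, flat)$p_value, 1)
  expect_error(compare_te_by_dominance(calls[1], dens), "fewer than 2")
})
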