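library(data.table)

# reference with two chromosomes of 120 genes each
make_ref <- function(n = 120, chroms = c("rc1", "rc2")) {
  new_genome(do.call(rbind, lapply(chroms, function(ch)
    data.frame(gene_id = sprintf("%s_g%03d", ch, 1:n), chrom = ch,
               start = (0:(n - 1)) * 5000, end = (0:(n - 1)) * 5000 + 2000,
               strand = "+"))), name = "ref")
}

# minimal fragment rows for breakpoint tests
frag_row <- function(q_chrom, r_chrom, lo, hi, copy, orientation = "forward") {
  data.table(fragment_id = paste0("f", q_chrom, lo),
             q_chrom = q_chrom, q_start = lo * 5000, q_end = hi * 5000 + 2000,
             r_chrom = r_chrom, r_start_rank = as.integer(lo),
             r_end_rank = as.integer(hi), orientation = orientation,
             copy_id = copy)
}

test_that("shared fragment ends become breakpoints, lone ends do not", {
  ref <- make_ref()
  fr <- rbind(frag_row("a1", "rc1", 0, 59, "c1"), frag_row("a2", "rc1", 60, 119, "c1"),
              frag_row("b1", "rc1", 0, 59, "c2"), frag_row("b2", "rc1", 60, 119, "c2"),
              frag_row("c1", "rc1", 0, 59, "c3"), frag_row("c2", "rc1", 60, 119, "c3"),
              frag_row("d1", "rc2", 0, 119, "c1"),
              frag_row("d2", "rc2", 0, 44, "c2"), frag_row("d3", "rc2", 45, 119, "c2"))
  bp <- detect_breakpoints(fr, ref, tolerance = 10L)
  expect_equal(nrow(bp), 1L)  # the rc2 cut is single-copy
  expect_equal(bp$chrom, "rc1")
  expect_equal(bp$gap, 60L)
  expect_equal(bp$support, 3L)
})

test_that("planted cuts with retention jitter are recovered exactly", {
  ref <- make_ref(n = 300, chroms = "rc1")
  set.seed(3)
  cuts <- c(70, 150, 230)
  rows <- list()
  for (cp in c("c1", "c2", "c3")) {
    bounds <- c(0, cuts, 300)
    for (i in seq_len(length(bounds) - 1)) {
      lo <- bounds[i] + sample(0:2, 1)      # terminal fractionation jitter
      hi <- bounds[i + 1] - 1 - sample(0:2, 1)
      rows[[length(rows) + 1]] <- frag_row(paste0(cp, i), "rc1", lo, hi, cp)
    }
  }
  bp <- detect_breakpoints(rbindlist(rows), ref, tolerance = 10L)
  expect_equal(nrow(bp), length(cuts))
  expect_true(all(abs(bp$gap - cuts) <= 2))
  expect_true(all(bp$support >= 2))
})

test_that("blocks tile each chromosome and are labelled in order", {
  ref <- make_ref()
  bp <- data.table(chrom = "rc1", gap = c(40L, 80L), support = 2L)
  blocks <- segment_blocks(ref, bp)
  expect_equal(nrow(blocks), 4L)  # 3 on rc1 + 1 whole rc2
  expect_equal(blocks$label, c("A", "B", "C", "D"))
  b1 <- blocks[chrom == "rc1"]
  expect_equal(b1$start_rank, c(0L, 40L, 80L))
  expect_equal(b1$end_rank, c(39L, 79L, 119L))
  expect_equal(sum(blocks$n_genes), 240L)  # exhaustive, disjoint
  none <- segment_blocks(ref, bp[0])
  expect_equal(nrow(none), 2L)  # one block per chromosome
})

test_that("label alphabet extends beyond 26 blocks", {
  ref <- make_ref(n = 300, chroms = "rc1")
  bp <- data.table(chrom = "rc1", gap = as.integer(seq(10, 280, by = 10)))
  blocks <- segment_blocks(ref, bp)
  expect_equal(nrow(blocks), 29L)  # 28 cuts on one chromosome
  expect_equal(blocks$label[27:29], c("AA", "AB", "AC"))
})

test_that("projection emits labels at 50% block overlap with orientation", {
  ref <- make_ref()
  bp <- data.table(chrom = "rc1", gap = 60L)
  blocks <- segment_blocks(ref, bp)
  fr <- rbind(frag_row("q1", "rc1", 0, 59, "c1"),
              frag_row("q1", "rc1", 60, 119, "c1", orientation = "inverted"),
              frag_row("q2", "rc1", 50, 75, "c2"))  # 10/60 of A, 16/60 of B
  ann <- project_blocks(blocks, fr)
  expect_equal(ann[q_chrom == "q1"]$label, c("A", "B"))
  expect_equal(ann[q_chrom == "q1"]$orientation, c("forward", "inverted"))
  expect_equal(nrow(ann[q_chrom == "q2"]), 0L)  # sliver below 50%
})

test_that("junctions require both ends at block boundaries and 2 copies", {
  ref <- make_ref()
  bp <- data.table(chrom = c("rc1", "rc2"), gap = c(60L, 60L))
  blocks <- segment_blocks(ref, bp)  # A,B on rc1; C,D on rc2
  # copies c1 and c2 join end of A to head of D on one query chromosome;
  # the A|B reference adjacency also appears, and one lone B|C junction
  qfrag <- function(q_chrom, q_lo, r_chrom, lo, hi, copy) {
    data.table(fragment_id = paste0("f", q_chrom, r_chrom, lo),
               q_chrom = q_chrom, q_start = q_lo, q_end = q_lo + (hi - lo) * 5000,
               r_chrom = r_chrom, r_start_rank = as.integer(lo),
               r_end_rank = as.integer(hi), orientation = "forward",
               copy_id = copy)
  }
  fr <- rbind(qfrag("x1", 0, "rc1", 0, 59, "c1"),
              qfrag("x1", 300000, "rc2", 60, 119, "c1"),
              qfrag("x2", 0, "rc1", 0, 59, "c2"),
              qfrag("x2", 300000, "rc2", 60, 119, "c2"),
              qfrag("y1", 0, "rc1", 60, 119, "c1"),
              qfrag("y1", 300000, "rc2", 0, 59, "c1"))
  assoc <- find_gb_associations(fr, blocks)
  ad <- assoc[signature == "A.t|D.h"]
  expect_equal(ad$support, 2L)
  expect_true(ad$candidate)
  bc <- assoc[signature == "B.t|C.h"]
  expect_equal(bc$support, 1L)
  expect_false(bc$candidate)  # single copy is not ancestral evidence
})

test_that("reference adjacencies are excluded from ancestral candidates", {
  ref <- make_ref()
  bp <- data.table(chrom = "rc1", gap = 60L)
  blocks <- segment_blocks(ref, bp)
  # two copies each span rc1 with two fragments meeting at the boundary in
  # reference orientation
  fr <- rbind(frag_row("x1", "rc1", 0, 59, "c1"), frag_row("x1", "rc1", 60, 119, "c1"),
              frag_row("x2", "rc1", 0, 59, "c2"), frag_row("x2", "rc1", 60, 119, "c2"))
  assoc <- find_gb_associations(fr, blocks)
  ab <- assoc[signature == "A.t|B.h"]
  expect_true(ab$present_in_reference)
  expect_false(ab$candidate)
  expect_equal(ab$support, 2L)  # exhibition still counted
})

test_that("karyotype assembly follows candidates, support ties and cycles", {
  blocks <- data.table(label = c("A", "B", "C"), chrom = c("r1", "r2", "r3"),
                       start_rank = 0L, end_rank = 99L, n_genes = 100L)
  # no candidates, no breakpoints -> reference karyotype (3 chromosomes)
  k0 <- assemble_ancestral_karyotype(blocks)
  expect_equal(k0$n_chromosomes, 3L)
  # two candidates competing for B.h: support 3 beats support 2
  assoc <- data.table(signature = c("A.t|B.h", "B.h|C.t"),
                      xid = c("A", "B"), yid = c("B", "C"),
                      support = c(3L, 2L), support_span = NA_integer_,
                      copies = "", present_in_reference = FALSE,
                      ends_terminal = FALSE, candidate = TRUE)
  k1 <- assemble_ancestral_karyotype(blocks, assoc)
  expect_equal(k1$n_chromosomes, 2L)
  expect_true("A.t|B.h" %in% k1$accepted_junctions)
  expect_false("B.h|C.t" %in% k1$accepted_junctions)
  # a junction set closing a circle is rejected loudly
  circ <- data.table(signature = c("A.t|B.h", "B.t|C.h", "A.h|C.t"),
                     xid = c("A", "B", "A"), yid = c("B", "C", "C"),
                     support = 3L, support_span = NA_integer_, copies = "",
                     present_in_reference = FALSE, ends_terminal = FALSE,
                     candidate = TRUE)
  expect_error(assemble_ancestral_karyotype(blocks, circ), "cycle")
})

test_that("simulated paleohexaploids recover the planted ancestor exactly", {
  for (s in 101:102) {
    sim <- cached_sim(s, noise = 0L)
    pip <- cached_pipeline(s, noise = 0L)
    v <- validate_against_truth(pip, sim)
    expect_equal(v$n_chromosomes, 9L)
    expect_equal(v$breakpoint_recall, 1)
    expect_equal(v$breakpoint_precision, 1)
    expect_equal(v$association_recall, 1)
    expect_equal(v$association_false_positives, 0L)
  }
})

test_that("two different references deduce the same ancestral karyotype", {
  s1 <- simulate_paleohexaploid(sim_config(seed = 103, ref_seed = 7001L,
                                           n_rearrangements = 0L, with_cds = FALSE))
  s2 <- simulate_paleohexaploid(sim_config(seed = 103, ref_seed = 7002L,
                                           n_rearrangements = 0L, with_cds = FALSE))
  expect_identical(s1$query$genes, s2$query$genes)  # same polyploid
  p1 <- run_pipeline(s1$query, s1$ref, s1$hits)
  p2 <- run_pipeline(s2$query, s2$ref, s2$hits)
  expect_equal(p1$karyotype$n_chromosomes, p2$karyotype$n_chromosomes)
  l1 <- p1$units[!is.na(r_id)]
  l1[, locus := names(s1$truth$ref_of_locus)[match(r_id, s1$truth$ref_of_locus)]]
  l2 <- p2$units[!is.na(r_id)]
  l2[, locus := names(s2$truth$ref_of_locus)[match(r_id, s2$truth$ref_of_locus)]]
  m <- merge(l1[, .(locus, u1 = unit)], l2[, .(locus, u2 = unit)], by = "locus")
  agree <- sum(apply(table(m$u1, m$u2), 1, max)) / nrow(m)
  expect_gte(agree, 0.99)
})
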