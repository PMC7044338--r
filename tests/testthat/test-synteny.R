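test_that("perfectly collinear hits are all accepted with flanking support", {
  fx <- make_collinear_fixture(n = 10, n_noise = 0)
  pairs <- find_syntenic_pairs(fx$query, fx$ref, fx$hits)
  expect_equal(nrow(pairs), 10L)
  expect_true(all(pairs$support >= 2))
})

test_that("a lone hit without flanking corroboration is rejected", {
  ref <- new_genome(data.frame(gene_id = sprintf("r%d", 1:5), chrom = "rc1",
                               start = (0:4) * 1000, end = (0:4) * 1000 + 500,
                               strand = "+"))
  qry <- new_genome(data.frame(gene_id = sprintf("q%d", 1:5), chrom = "qc1",
                               start = (0:4) * 1000, end = (0:4) * 1000 + 500,
                               strand = "+"))
  hits <- data.frame(query_id = "q3", subject_id = "r3", e_value = 1e-50,
                     identity_pct = 90, coverage_pct = 90, bitscore = 300)
  expect_equal(nrow(find_syntenic_pairs(qry, ref, hits)), 0L)
  expect_equal(nrow(find_syntenic_pairs(qry, ref, hits[0, ])), 0L)
})

test_that("accepted pair set matches a literal re-application of the rules", {
  fx <- make_collinear_fixture(n = 50, seed = 7, invert = 20:30, n_noise = 15)
  cfg <- synteny_config()
  got <- find_syntenic_pairs(fx$query, fx$ref, fx$hits, cfg)

  # oracle: plain loops over the definition (flanking support, then best
  # pairing per query, then ploidy cap per reference gene)
  qg <- as.data.frame(fx$query$genes)
  rg <- as.data.frame(fx$ref$genes)
  h <- merge(fx$hits, qg[c("gene_id", "rank")],
             by.x = "query_id", by.y = "gene_id")
  names(h)[names(h) == "rank"] <- "q_rank"
  h <- merge(h, rg[c("gene_id", "rank")], by.x = "subject_id", by.y = "gene_id")
  names(h)[names(h) == "rank"] <- "r_rank"
  support <- integer(nrow(h))
  for (i in seq_len(nrow(h))) {
    fl <- character()
    for (j in seq_len(nrow(h))) {
      if (h$query_id[j] == h$query_id[i]) next
      if (abs(h$q_rank[j] - h$q_rank[i]) <= cfg$flank_window &&
          abs(h$r_rank[j] - h$r_rank[i]) <= cfg$flank_window)
        fl <- union(fl, h$query_id[j])
    }
    support[i] <- length(fl)
  }
  acc <- h[support >= cfg$min_support, ]
  acc$support <- support[support >= cfg$min_support]
  acc <- acc[order(acc$query_id, -acc$support, -acc$bitscore, acc$subject_id), ]
  acc <- acc[!duplicated(acc$query_id), ]
  acc <- acc[order(acc$subject_id, -acc$support, -acc$bitscore, acc$query_id), ]
  keep <- unlist(lapply(split(seq_len(nrow(acc)), acc$subject_id),
                        utils::head, cfg$max_pairings_per_ref))
  acc <- acc[sort(keep), ]

  expect_setequal(paste(got$q_id, got$r_id),
                  paste(acc$query_id, acc$subject_id))
})

test_that("pairs chain into fragments under the interruption rule", {
  # adjacent in both genomes -> one fragment
  p <- make_pair_table(q_ranks = c(10, 11), r_ranks = c(20, 21))
  fr <- assemble_fragments(p)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$n_pairs, 2L)
  # separated by 60 genes AND >200 kb in the query -> two fragments
  p2 <- make_pair_table(q_ranks = c(10, 71), r_ranks = c(20, 21))
  expect_equal(nrow(assemble_fragments(p2)), 2L)
  # 60 genes apart but close in bp -> still one fragment (OR rule)
  p3 <- make_pair_table(q_ranks = c(10, 71), r_ranks = c(20, 21))
  p3[2, `:=`(q_start = p3$q_end[1] + 1000, q_end = p3$q_end[1] + 3000)]
  expect_equal(nrow(assemble_fragments(p3)), 1L)
  # single pair -> single fragment
  expect_equal(nrow(assemble_fragments(make_pair_table(5, 5))), 1L)
})

test_that("a direction flip closes the fragment and sets orientation", {
  p <- make_pair_table(q_ranks = 1:9, r_ranks = c(1:5, 40:37))
  p[6:9, `:=`(r_start = c(40, 39, 38, 37) * 5000,
              r_end = c(40, 39, 38, 37) * 5000 + 2000)]
  fr <- assemble_fragments(p)
  expect_equal(nrow(fr), 2L)
  expect_setequal(fr$orientation, c("forward", "inverted"))
})

test_that("fragment assembly partitions pairs and ignores input order", {
  set.seed(11)
  for (rep in 1:4) {
    n <- 30
    q <- sort(sample(0:200, n))
    r <- q + sample(c(-2:2), n, replace = TRUE)
    p <- make_pair_table(q_ranks = q, r_ranks = r)
    fr <- assemble_fragments(p)
    tab <- attr(fr, "pairs")
    expect_equal(nrow(tab), n)                       # partition: no pair lost
    expect_equal(anyDuplicated(tab[, .(q_id, r_id)]), 0L)
    shuf <- p[sample(n)]
    fr2 <- assemble_fragments(shuf)
    canon <- function(part) sort(vapply(part, function(x)
      paste(sort(x), collapse = ";"), character(1), USE.NAMES = FALSE))
    part1 <- split(paste(tab$q_id, tab$r_id), tab$fragment_id)
    tab2 <- attr(fr2, "pairs")
    part2 <- split(paste(tab2$q_id, tab2$r_id), tab2$fragment_id)
    expect_equal(canon(part1), canon(part2))
    # closure oracle agrees
    orc <- orc_fragment_partition(p, synteny_config())
    expect_equal(canon(part1), canon(orc))
  }
})

test_that("span filter keeps only fragments longer than the threshold", {
  p <- rbind(make_pair_table(q_ranks = 1:50, r_ranks = 1:50),
             make_pair_table(q_ranks = 300:302, r_ranks = 300:302))
  fr <- assemble_fragments(p)
  expect_equal(nrow(fr), 2L)
  kept <- filter_fragments(fr)
  expect_equal(nrow(kept), 1L)
  expect_true(all((kept$q_end - kept$q_start) > 200000))
  # direct recount
  expect_equal(nrow(kept), sum((fr$q_end - fr$q_start) > 200000))
})

test_that("dot-plot export is lossless over pairs", {
  p <- make_pair_table(q_ranks = 1:5, r_ranks = 1:5)
  fr <- assemble_fragments(p)
  dp <- dotplot_table(fr)
  expect_equal(nrow(dp), 5L)
  expect_true(all(c("q_pos", "r_pos", "fragment_id", "orientation") %in% names(dp)))
  empty <- assemble_fragments(p[0])
  expect_equal(nrow(dotplot_table(empty)), 0L)
})
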