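# Shared fixtures. Simulations are cached per (seed, noise, cds) so several
# test files can reuse one replicate.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed, noise = 20L, cds = FALSE, ...) {
  key <- paste0("s", seed, "_n", noise, "_c", as.integer(cds))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_paleohexaploid(
      sim_config(seed = seed, n_rearrangements = noise, with_cds = cds, ...))
  .sim_cache[[key]]
}

cached_pipeline <- function(seed, noise = 20L, cds = FALSE, ...) {
  key <- paste0("p", seed, "_n", noise, "_c", as.integer(cds))
  if (is.null(.sim_cache[[key]])) {
    sim <- cached_sim(seed, noise, cds, ...)
    .sim_cache[[key]] <- run_pipeline(sim$query, sim$ref, sim$hits)
  }
  .sim_cache[[key]]
}

# tiny two-genome collinear fixture with optional inversion and noise hits
make_collinear_fixture <- function(n = 50, seed = 1, invert = NULL,
                                   n_noise = 10) {
  set.seed(seed)
  ref <- new_genome(data.frame(
    gene_id = sprintf("r%03d", 1:n), chrom = "rc1",
    start = (0:(n - 1)) * 5000, end = (0:(n - 1)) * 5000 + 2000,
    strand = "+"), name = "ref")
  ord <- 1:n
  if (!is.null(invert)) ord[invert] <- rev(ord[invert])
  qry <- new_genome(data.frame(
    gene_id = sprintf("q%03d", ord), chrom = "qc1",
    start = (0:(n - 1)) * 5000, end = (0:(n - 1)) * 5000 + 2000,
    strand = "+"), name = "qry")
  hits <- data.frame(query_id = sprintf("q%03d", 1:n),
                     subject_id = sprintf("r%03d", 1:n),
                     e_value = 1e-100, identity_pct = 90,
                     coverage_pct = 95, bitscore = 400)
  if (n_noise > 0) {
    noise <- data.frame(query_id = sprintf("q%03d", sample(n, n_noise, TRUE)),
                        subject_id = sprintf("r%03d", sample(n, n_noise, TRUE)),
                        e_value = 1e-10, identity_pct = 45,
                        coverage_pct = 50, bitscore = 80)
    hits <- rbind(hits, noise)
    hits <- hits[!duplicated(hits[c("query_id", "subject_id")]), ]
  }
  list(query = qry, ref = ref, hits = hits)
}

# synthetic pair table for fragment-assembly tests (one lane)
make_pair_table <- function(q_ranks, r_ranks, spacing = 5000,
                            q_chrom = "qc1", r_chrom = "rc1") {
  data.table::data.table(
    q_id = sprintf("q%03d", seq_along(q_ranks)),
    r_id = sprintf("r%03d", seq_along(q_ranks)),
    q_chrom = q_chrom, q_rank = as.integer(q_ranks),
    q_start = q_ranks * spacing, q_end = q_ranks * spacing + 2000,
    r_chrom = r_chrom, r_rank = as.integer(r_ranks),
    r_start = r_ranks * spacing, r_end = r_ranks * spacing + 2000,
    support = 5L)
}
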