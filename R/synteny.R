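## Syntenic gene pairs and syntenic fragments.
##
## A homology hit (q, r) is promoted to a syntenic pair when it is corroborated
## by the neighbourhood: among the genes flanking q, at least `min_support`
## have their own hit landing near r.  Accepted pairs are then chained into
## fragments: two pairs belong to one fragment when, in each genome
## separately, they are interrupted by fewer than `max_intervening` genes OR
## lie closer than `max_gap` bp, and the ref ranks move monotonically
## (forward or inverted) along the fragment.

#' Synteny detection / chaining parameters
#'
#' @param flank_window genes inspected on each side of a query gene when
#'   counting flanking support.
#' @param min_support minimum corroborating flanking gene pairs.
#' @param max_intervening chaining threshold on intervening gene count
#'   (exclusive: `< max_intervening` chains).
#' @param max_gap chaining threshold on bp distance (exclusive).
#' @param min_fragment_span fragments must span strictly more than this many
#'   bp in the query genome to survive filtering.
#' @param max_pairings_per_ref one reference gene may pair with at most this
#'   many query genes (3 for a triplicated genome).
#' @return list of class `phex_synteny_config`.
#' @export
synteny_config <- function(flank_window = 20L, min_support = 2L,
                           max_intervening = 50L, max_gap = 200000,
                           min_fragment_span = 200000,
                           max_pairings_per_ref = 3L) {
  cfg <- list(flank_window = as.integer(flank_window),
              min_support = as.integer(min_support),
              max_intervening = as.integer(max_intervening),
              max_gap = as.numeric(max_gap),
              min_fragment_span = as.numeric(min_fragment_span),
              max_pairings_per_ref = as.integer(max_pairings_per_ref))
  if (any(unlist(cfg) <= 0)) stop("all synteny parameters must be positive")
  class(cfg) <- "phex_synteny_config"
  cfg
}

# annotate hits with rank/chrom/position of both genes; errors on unknown ids
annotate_hits <- function(hits, query, ref) {
  h <- as.data.table(hits)
  qg <- query$genes[, .(q_id = gene_id, q_chrom = chrom, q_rank = rank,
                        q_start = start, q_end = end)]
  rg <- ref$genes[, .(r_id = gene_id, r_chrom = chrom, r_rank = rank,
                      r_start = start, r_end = end)]
  h <- h[, .(q_id = as.character(query_id), r_id = as.character(subject_id),
             bitscore = if ("bitscore" %in% names(h)) bitscore else 0)]
  miss_q <- setdiff(h$q_id, qg$q_id)
  if (length(miss_q)) stop("hit query gene not in query genome: ", miss_q[1L])
  miss_r <- setdiff(h$r_id, rg$r_id)
  if (length(miss_r)) stop("hit subject gene not in reference genome: ", miss_r[1L])
  h <- qg[h, on = "q_id"]
  h <- rg[h, on = "r_id"]
  h[]
}

#' Find syntenic gene pairs between a polyploid query and a diploid reference
#'
#' A hit (q, r) is accepted iff at least `cfg$min_support` distinct query
#' genes within `cfg$flank_window` ranks of q (either side, excluding q)
#' have a homology hit to a reference gene within `cfg$flank_window` ranks
#' of r on r's chromosome. Per reference gene, at most
#' `cfg$max_pairings_per_ref` query partners are retained (best support,
#' then bitscore, then gene id).
#'
#' @param query,ref `phex_genome` objects.
#' @param hits data.table with `query_id`, `subject_id` and optionally
#'   `bitscore`.
#' @param cfg `synteny_config()`.
#' @return data.table(q_id, r_id, q_chrom, q_rank, q_start, q_end, r_chrom,
#'   r_rank, r_start, r_end, support).
#' @export
find_syntenic_pairs <- function(query, ref, hits, cfg = synteny_config()) {
  empty <- data.table(q_id = character(), r_id = character(),
                      q_chrom = character(), q_rank = integer(),
                      q_start = numeric(), q_end = numeric(),
                      r_chrom = character(), r_rank = integer(),
                      r_start = numeric(), r_end = numeric(),
                      support = integer())
  if (!nrow(as.data.table(hits))) return(empty)
  h <- annotate_hits(hits, query, ref)
  h <- unique(h, by = c("q_id", "r_id"))
  h[, xid := .I]
  w <- cfg$flank_window
  probe <- h[, .(xid, q_chrom, r_chrom, qlo = q_rank - w, qhi = q_rank + w,
                 rlo = r_rank - w, rhi = r_rank + w, q_rank0 = q_rank)]
  cand <- h[probe,
            on = .(q_chrom, r_chrom, q_rank >= qlo, q_rank <= qhi,
                   r_rank >= rlo, r_rank <= rhi),
            allow.cartesian = TRUE,
            .(xid = i.xid, q_flank = x.q_id, q_rank_f = x.q_rank,
              q_rank0 = i.q_rank0)]
  cand <- cand[q_rank_f != q_rank0]
  supp <- cand[, .(support = data.table::uniqueN(q_flank)), by = xid]
  h[, support := 0L]
  h[supp$xid, support := supp$support]
  acc <- h[support >= cfg$min_support]
  if (!nrow(acc)) return(empty)
  # the reference is diploid: each query gene keeps its single best
  # reference counterpart (support, then bitscore, then id)
  setorder(acc, q_id, -support, -bitscore, r_id)
  acc <- acc[, head(.SD, 1L), by = q_id]
  # triplication cap per reference gene
  setorder(acc, r_id, -support, -bitscore, q_id)
  acc <- acc[, head(.SD, cfg$max_pairings_per_ref), by = r_id]
  setorder(acc, q_chrom, q_rank, r_chrom, r_rank)
  acc[, .(q_id, r_id, q_chrom, q_rank, q_start, q_end,
          r_chrom, r_rank, r_start, r_end, support)]
}

# chainability of two pairs in one genome: intervening genes < max_intervening
# OR bp distance < max_gap (both exclusive)
chainable_1d <- function(rank_a, rank_b, lo_a, hi_a, lo_b, hi_b, cfg) {
  interv <- abs(rank_a - rank_b) - 1L
  gap <- pmax(0, pmax(lo_a, lo_b) - pmin(hi_a, hi_b))
  interv < cfg$max_intervening | gap < cfg$max_gap
}

#' Chain syntenic pairs into syntenic fragments
#'
#' Pairs are processed per (query chromosome, reference chromosome) lane in
#' query-rank order. Consecutive pairs are chained when each genome
#' separately satisfies the interruption rule (< `max_intervening` genes or
#' < `max_gap` bp) and the reference rank keeps moving in one direction;
#' a direction flip closes the fragment (micro-inversions become separate
#' fragments). The result partitions the input pair set and is invariant to
#' input order.
#'
#' @param pairs output of [find_syntenic_pairs()].
#' @param cfg `synteny_config()`.
#' @return data.table, one row per fragment: fragment_id, q_chrom, q_start,
#'   q_end, r_chrom, r_start, r_end, r_start_rank, r_end_rank, q_start_rank,
#'   q_end_rank, orientation, n_pairs; plus attribute-free pair membership via
#'   [dotplot_table()].
#' @export
assemble_fragments <- function(pairs, cfg = synteny_config()) {
  p <- as.data.table(pairs)
  if (!nrow(p)) {
    out <- data.table(fragment_id = character(), q_chrom = character(),
                      q_start = numeric(), q_end = numeric(),
                      r_chrom = character(), r_start = numeric(),
                      r_end = numeric(), r_start_rank = integer(),
                      r_end_rank = integer(), q_start_rank = integer(),
                      q_end_rank = integer(),
                      orientation = character(), n_pairs = integer())
    data.table::setattr(out, "pairs", copy(p)[, fragment_id := character(0)])
    return(out)
  }
  setorder(p, q_chrom, r_chrom, q_rank, r_rank)
  p[, fragment_id := NA_character_]
  frag_no <- 0L
  out_fid <- character(nrow(p))
  grp <- p[, .(idx = list(.I)), by = .(q_chrom, r_chrom)]
  for (k in seq_len(nrow(grp))) {
    ii <- grp$idx[[k]]
    n <- length(ii)
    dir <- 0L  # 0 unknown, +1 forward, -1 inverted
    frag_no <- frag_no + 1L
    cur <- sprintf("F%05d", frag_no)
    out_fid[ii[1L]] <- cur
    if (n > 1L) for (j in 2L:n) {
      a <- ii[j - 1L]; b <- ii[j]
      ok_q <- chainable_1d(p$q_rank[a], p$q_rank[b], p$q_start[a], p$q_end[a],
                           p$q_start[b], p$q_end[b], cfg)
      ok_r <- chainable_1d(p$r_rank[a], p$r_rank[b], p$r_start[a], p$r_end[a],
                           p$r_start[b], p$r_end[b], cfg)
      step <- sign(p$r_rank[b] - p$r_rank[a])
      ok_dir <- dir == 0L || step == 0L || step == dir
      if (ok_q && ok_r && ok_dir) {
        if (dir == 0L && step != 0L) dir <- step
      } else {
        frag_no <- frag_no + 1L
        cur <- sprintf("F%05d", frag_no)
        dir <- 0L
      }
      out_fid[b] <- cur
    }
  }
  p[, fragment_id := out_fid]
  frags <- p[, .(q_chrom = q_chrom[1L], q_start = min(q_start), q_end = max(q_end),
                 r_chrom = r_chrom[1L], r_start = min(r_start), r_end = max(r_end),
                 r_start_rank = min(r_rank), r_end_rank = max(r_rank),
                 q_start_rank = min(q_rank), q_end_rank = max(q_rank),
                 orientation = {
                   s <- sum(sign(diff(r_rank)))
                   if (s < 0) "inverted" else "forward"
                 },
                 n_pairs = .N), by = fragment_id]
  data.table::setattr(frags, "pairs", p[])
  frags[]
}

#' Drop fragments below the minimum query span
#'
#' Keeps fragments whose query span is strictly greater than
#' `cfg$min_fragment_span` ("longer than").
#'
#' @param fragments output of [assemble_fragments()].
#' @param cfg `synteny_config()`.
#' @return filtered fragment table (pair attribute restricted accordingly).
#' @export
filter_fragments <- function(fragments, cfg = synteny_config()) {
  keep <- fragments[(q_end - q_start) > cfg$min_fragment_span]
  p <- attr(fragments, "pairs")
  if (!is.null(p))
    data.table::setattr(keep, "pairs", p[fragment_id %in% keep$fragment_id])
  keep[]
}

#' Per-pair dot-plot export for a fragment set
#'
#' @param fragments fragment table carrying its pair attribute (as produced
#'   by [assemble_fragments()] / [filter_fragments()]).
#' @return data.table(q_id, r_id, q_chrom, q_pos, r_chrom, r_pos,
#'   fragment_id, orientation) with one row per syntenic pair.
#' @export
dotplot_table <- function(fragments) {
  p <- attr(fragments, "pairs")
  if (is.null(p)) stop("fragment table lacks pair membership; ",
                       "pass the object returned by assemble_fragments()")
  o <- fragments[, .(fragment_id, orientation)]
  tab <- o[p, on = "fragment_id"]
  tab[, .(q_id, r_id, q_chrom, q_pos = (q_start + q_end) / 2,
          r_chrom, r_pos = (r_start + r_end) / 2, fragment_id, orientation)]
}
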