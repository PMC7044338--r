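## Genomic blocks (GBs) on the diploid reference, their projection onto the
## polyploid, block-association mining, and assembly of the diploid ancestral
## karyotype.
##
## Breakpoints live in reference gene-rank space: a cut `gap = g` on a
## chromosome separates rank g-1 from rank g.  Blocks are labelled A..Z, then
## AA, AB, ... in (chromosome, position) order and tile each reference
## chromosome.

#' Assign fragments to syntenic copy lanes per reference chromosome
#'
#' Fragments covering the same reference region necessarily come from
#' different sub-genome copies; fragments that chain head-to-tail along the
#' reference typically come from the same copy. Greedy interval scheduling:
#' per reference chromosome, fragments sorted by ref start are placed in the
#' occupied-latest lane that is already free (so the pieces of one rearranged
#' copy stay in one lane), opening a new lane when none is free.
#'
#' @param fragments fragment table (needs r_chrom, r_start_rank, r_end_rank).
#' @return the fragment table with a `copy_id` column
#'   (`<r_chrom>.c<lane>`).
#' @export
assign_fragment_lanes <- function(fragments) {
  f <- copy(as.data.table(fragments))
  f[, lane := NA_integer_]
  setorder(f, r_chrom, r_start_rank, r_end_rank)
  for (ch in unique(f$r_chrom)) {
    idx <- which(f$r_chrom == ch)
    lane_end <- numeric()  # last occupied end rank per lane
    for (i in idx) {
      free <- which(lane_end <= f$r_start_rank[i])
      if (length(free)) {
        pick <- free[which.max(lane_end[free])]
      } else {
        lane_end <- c(lane_end, -Inf)
        pick <- length(lane_end)
      }
      lane_end[pick] <- f$r_end_rank[i] + 1
      f[i, lane := pick]
    }
  }
  f[, copy_id := paste0(r_chrom, ".c", lane)]
  f[]
}

#' Detect breakpoints shared by more than one sub-genome copy
#'
#' Every fragment end interior to a reference chromosome proposes a cut at
#' its gene-rank boundary. Cuts are deduplicated per copy, clustered by
#' single linkage within `tolerance` ranks, and clusters supported by at
#' least two distinct copies become breakpoints at the cluster's median gap.
#' Chromosome ends never count.
#'
#' @param fragments fragment table carrying a `copy_id` column (see
#'   [assign_fragment_lanes()]) plus r_chrom, r_start_rank, r_end_rank.
#' @param ref `phex_genome` (for chromosome gene counts).
#' @param tolerance clustering tolerance in gene ranks.
#' @return data.table(chrom, gap, support, copies).
#' @export
detect_breakpoints <- function(fragments, ref, tolerance = 10L) {
  f <- as.data.table(fragments)
  if (!"copy_id" %in% names(f))
    stop("fragments need a copy_id column; run assign_fragment_lanes() first")
  ngenes <- chrom_gene_counts(ref)
  cand <- rbind(
    f[, .(chrom = r_chrom, gap = r_start_rank, copy_id)],
    f[, .(chrom = r_chrom, gap = r_end_rank + 1L, copy_id)]
  )
  # chromosome ends never count; a fragment end within the clustering
  # tolerance of an end is indistinguishable from terminal gene loss
  cand <- cand[gap > tolerance & gap < ngenes[chrom] - tolerance]
  cand <- unique(cand)
  if (!nrow(cand)) return(data.table(chrom = character(), gap = integer(),
                                     support = integer(), copies = character()))
  out <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[chrom == ch][order(gap)]
    cl <- cumsum(c(1L, diff(cc$gap) > tolerance))
    cc[, cluster := cl]
    agg <- cc[, .(gap = as.integer(round(median(gap))),
                  support = data.table::uniqueN(copy_id),
                  copies = paste(sort(unique(copy_id)), collapse = ",")),
              by = cluster]
    out[[ch]] <- data.table(chrom = ch, agg[, .(gap, support, copies)])
  }
  bp <- rbindlist(out)
  bp <- bp[support >= 2L]
  setorder(bp, chrom, gap)
  bp[]
}

# A, B, ..., Z, AA, AB, ...
block_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- n - 26L
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, two[seq_len(extra)])
}

#' Segment the reference genome into genomic blocks
#'
#' Each chromosome is cut at its breakpoints; blocks are labelled
#' alphabetically in chromosome order then position order and tile each
#' chromosome (disjoint, contiguous, exhaustive in gene-rank space).
#'
#' @param ref `phex_genome`.
#' @param breakpoints output of [detect_breakpoints()] (needs chrom, gap).
#' @return data.table(label, chrom, start_rank, end_rank, n_genes).
#' @export
segment_blocks <- function(ref, breakpoints) {
  ngenes <- chrom_gene_counts(ref)
  bp <- as.data.table(breakpoints)
  segs <- list()
  for (ch in names(ngenes)) {
    n <- ngenes[[ch]]
    cuts <- sort(unique(bp[chrom == ch & gap > 0L & gap < n]$gap))
    lo <- c(0L, cuts)
    hi <- c(cuts, n) - 1L
    segs[[ch]] <- data.table(chrom = ch, start_rank = as.integer(lo),
                             end_rank = as.integer(hi))
  }
  blocks <- rbindlist(segs)
  setorder(blocks, chrom, start_rank)
  blocks[, label := block_labels(.N)]
  blocks[, n_genes := end_rank - start_rank + 1L]
  blocks[, .(label, chrom, start_rank, end_rank, n_genes)]
}

#' Project genomic blocks onto the polyploid chromosomes
#'
#' Each fragment emits the label of every block it overlaps by at least
#' `min_overlap` of the block's gene span; inverted fragments emit primed
#' (inverted) labels with block order reversed. The per-chromosome
#' annotation is ordered along the query.
#'
#' @param blocks output of [segment_blocks()].
#' @param fragments fragment table with copy_id (see
#'   [assign_fragment_lanes()]).
#' @param min_overlap fraction of the block's genes a fragment must cover.
#' @return data.table(q_chrom, ord, label, orientation, copy_id,
#'   fragment_id, r_chrom, overlap_genes).
#' @export
project_blocks <- function(blocks, fragments, min_overlap = 0.5) {
  f <- as.data.table(fragments)
  if (!"copy_id" %in% names(f)) stop("fragments need copy_id")
  b <- as.data.table(blocks)
  j <- b[f, on = .(chrom = r_chrom, start_rank <= r_end_rank,
                   end_rank >= r_start_rank), allow.cartesian = TRUE,
         .(label = x.label, chrom = x.chrom,
           b_start = x.start_rank, b_end = x.end_rank, n_genes = x.n_genes,
           fragment_id = i.fragment_id, q_chrom = i.q_chrom,
           q_start = i.q_start, q_end = i.q_end,
           r_start_rank = i.r_start_rank, r_end_rank = i.r_end_rank,
           orientation = i.orientation, copy_id = i.copy_id)]
  if (!nrow(j)) return(data.table(q_chrom = character(), ord = integer(),
                                  label = character(), orientation = character(),
                                  copy_id = character(), fragment_id = character(),
                                  r_chrom = character(), overlap_genes = integer()))
  j[, overlap_genes := pmin(b_end, r_end_rank) - pmax(b_start, r_start_rank) + 1L]
  j <- j[overlap_genes >= min_overlap * n_genes]
  # order blocks within a fragment along the query: forward fragments walk the
  # reference upward, inverted fragments downward
  j[, ord_in_frag := ifelse(orientation == "inverted",
                            -(b_start + b_end) / 2, (b_start + b_end) / 2)]
  setorder(j, q_chrom, q_start, ord_in_frag)
  j[, ord := seq_len(.N), by = q_chrom]
  j[, .(q_chrom, ord, label, orientation, copy_id, fragment_id,
        r_chrom = chrom, overlap_genes)]
}

# which block ends meet at the junction between consecutive annotation
# entries a (left) and b (right):
# right-side end of a: tail if forward, head if inverted
# left-side end of b: head if forward, tail if inverted
junction_signature <- function(lab_a, ori_a, lab_b, ori_b) {
  end_a <- paste0(lab_a, ".", ifelse(ori_a == "inverted", "h", "t"))
  end_b <- paste0(lab_b, ".", ifelse(ori_b == "inverted", "t", "h"))
  ifelse(end_a < end_b, paste0(end_a, "|", end_b), paste0(end_b, "|", end_a))
}

# signatures of adjacencies present in the reference (X.t|Y.h for consecutive
# blocks X, Y of one chromosome)
reference_adjacencies <- function(blocks) {
  b <- as.data.table(blocks)
  setorder(b, chrom, start_rank)
  adj <- b[, if (.N > 1L) .(xid = label[-.N], yid = label[-1L]), by = chrom]
  if (!nrow(adj)) return(data.table(chrom = character(), xid = character(),
                                    yid = character(), signature = character()))
  adj[, signature := junction_signature(xid, "forward", yid, "forward")]
  adj[]
}

#' Mine genomic-block associations from fragment adjacency
#'
#' A junction is recorded wherever two fragments physically adjacent on a
#' polyploid chromosome both terminate at a genomic-block boundary (within
#' `tolerance` gene ranks): the facing fragment ends name the block ends
#' that meet, so X-Y and X-Y' junctions are distinct signatures.
#' Rearrangements interior to a block move no block boundary and therefore
#' do not disturb junction evidence. Support counts distinct sub-genome
#' copies. Junctions equal to a reference adjacency are flagged
#' `present_in_reference`; for every reference adjacency an exhibition row
#' is also emitted whose support counts copies retaining the junction
#' (a fragment spanning the boundary, or a ref-like junction). Ancestral
#' candidates have support >= 2 and are absent from the reference.
#'
#' @param fragments fragment table with `copy_id` (see
#'   [assign_fragment_lanes()]).
#' @param blocks output of [segment_blocks()].
#' @param tolerance boundary matching tolerance in gene ranks.
#' @param pairs optional pair table (the `pairs` attribute of
#'   [assemble_fragments()]); when given, a fragment counts as spanning a
#'   reference boundary only if it holds syntenic pairs within `tolerance`
#'   on both sides of the cut, which is robust to range inflation by
#'   straggler pairs.
#' @return data.table(signature, xid, yid, support, copies,
#'   present_in_reference, candidate).
#' @export
find_gb_associations <- function(fragments, blocks, tolerance = 10L,
                                 pairs = NULL) {
  f <- copy(as.data.table(fragments))
  b <- as.data.table(blocks)
  ref_adj <- reference_adjacencies(b)
  empty <- data.table(signature = character(), xid = character(),
                      yid = character(), support = integer(),
                      copies = character(), present_in_reference = logical(),
                      candidate = logical())
  if (!nrow(f)) return(empty)
  # block end met by a fragment end; NA when the end is interior to a block
  block_end_at <- function(chrom_v, rank_v, ori_v, side) {
    vapply(seq_along(rank_v), function(i) {
      bb <- b[chrom == chrom_v[i] & start_rank <= rank_v[i] + tolerance &
                end_rank >= rank_v[i] - tolerance]
      # the end type is fixed by orientation and facing side:
      # a forward fragment stops on a t-boundary at its right side and an
      # h-boundary at its left side; inverted fragments swap the two
      want_t <- (ori_v[i] == "forward") == (side == "right")
      if (want_t) {
        hit <- bb[abs(end_rank - rank_v[i]) <= tolerance]
        if (nrow(hit)) paste0(hit$label[1L], ".t") else NA_character_
      } else {
        hit <- bb[abs(start_rank - rank_v[i]) <= tolerance]
        if (nrow(hit)) paste0(hit$label[1L], ".h") else NA_character_
      }
    }, character(1))
  }
  setorder(f, q_chrom, q_start)
  ## block ends sitting at polyploid chromosome termini, per copy: direct
  ## evidence that this copy does NOT join them to anything
  term <- f[, {
    lf <- 1L; rt <- .N
    rl <- fifelse(orientation[lf] == "forward", r_start_rank[lf], r_end_rank[lf])
    rr <- fifelse(orientation[rt] == "forward", r_end_rank[rt], r_start_rank[rt])
    el <- block_end_at(r_chrom[lf], rl, orientation[lf], "left")
    er <- block_end_at(r_chrom[rt], rr, orientation[rt], "right")
    .(end = c(el, er), copy_id = copy_id[c(lf, rt)])
  }, by = q_chrom]
  term <- term[!is.na(end)]
  jn <- f[, if (.N > 1L) {
    a_idx <- 1:(.N - 1L); b_idx <- 2:.N
    ra <- fifelse(orientation[a_idx] == "forward",
                  r_end_rank[a_idx], r_start_rank[a_idx])
    rb <- fifelse(orientation[b_idx] == "forward",
                  r_start_rank[b_idx], r_end_rank[b_idx])
    ea <- block_end_at(r_chrom[a_idx], ra, orientation[a_idx], "right")
    eb <- block_end_at(r_chrom[b_idx], rb, orientation[b_idx], "left")
    .(ea = ea, eb = eb, copy_id = copy_id[a_idx])
  }, by = q_chrom]
  jn <- jn[!is.na(ea) & !is.na(eb) & ea != eb]
  agg <- if (nrow(jn)) {
    jn[, signature := fifelse(ea < eb, paste0(ea, "|", eb),
                              paste0(eb, "|", ea))]
    jn[, .(support = data.table::uniqueN(copy_id),
           copies = paste(sort(unique(copy_id)), collapse = ",")),
       by = signature]
  } else data.table(signature = character(), support = integer(),
                    copies = character())
  agg[, present_in_reference := signature %in% ref_adj$signature]
  ## reference-adjacency exhibition: copies spanning the boundary plus
  ## copies showing a ref-like junction
  if (nrow(ref_adj)) {
    bnd <- merge(ref_adj, b[, .(xid = label, chrom, cut = end_rank + 1L)],
                 by = c("chrom", "xid"))
    exh <- lapply(seq_len(nrow(bnd)), function(i) {
      span <- f[r_chrom == bnd$chrom[i] & r_start_rank < bnd$cut[i] &
                  r_end_rank >= bnd$cut[i]]
      if (!is.null(pairs) && nrow(span)) {
        cut <- bnd$cut[i]
        pp <- as.data.table(pairs)[fragment_id %in% span$fragment_id &
                                     r_chrom == bnd$chrom[i]]
        lf <- unique(pp[r_rank >= cut - tolerance & r_rank < cut]$fragment_id)
        rt <- unique(pp[r_rank >= cut & r_rank < cut + tolerance]$fragment_id)
        span <- span[fragment_id %in% intersect(lf, rt)]
      }
      met <- agg[signature == bnd$signature[i]]
      cps <- unique(c(span$copy_id,
                      if (nrow(met)) strsplit(met$copies, ",")[[1L]]))
      data.table(signature = bnd$signature[i],
                 support = length(cps),
                 support_span = data.table::uniqueN(span$copy_id),
                 copies = paste(sort(cps), collapse = ","),
                 present_in_reference = TRUE)
    })
    exh <- rbindlist(exh)
    agg <- rbind(agg[present_in_reference == FALSE], exh, fill = TRUE)
  }
  if (!nrow(agg)) return(empty)
  ends <- data.table::tstrsplit(agg$signature, "|", fixed = TRUE)
  agg[, xid := sub("\\..$", "", ends[[1L]])]
  agg[, yid := sub("\\..$", "", ends[[2L]])]
  if (!"support_span" %in% names(agg)) agg[, support_span := NA_integer_]
  ## ends_terminal records whether both of a junction's block ends are also
  ## observed as polyploid chromosome termini somewhere: for a reference
  ## adjacency under a breakpoint this distinguishes true separation (the
  ## copies end their chromosomes there) from collided noise cuts
  agg[, ends_terminal := vapply(signature, function(sg) {
    ends <- strsplit(sg, "|", fixed = TRUE)[[1L]]
    all(ends %in% term$end)
  }, logical(1))]
  agg[, candidate := support >= 2L & !present_in_reference]
  setorder(agg, -support, signature)
  agg[, .(signature, xid, yid, support, support_span, copies,
          present_in_reference, ends_terminal, candidate)]
}

#' Assemble the diploid ancestral karyotype from blocks and associations
#'
#' Graph over block ends (two nodes per block). Edges: candidate
#' associations (weight = support) plus reference adjacencies. A reference
#' adjacency is dropped when a breakpoint (support >= 2) falls at its block
#' boundary and no sub-genome copy still exhibits the adjacency (its
#' exhibition count in `associations` is 0) - every copy breaking a
#' reference junction is the evidence the ancestor did not have it.
#' Conflicts at a block end are resolved by higher support, then reference
#' preference, then lexicographic signature; each end carries at most one
#' edge; a cycle is an error. Maximal paths are the ancestral chromosomes.
#'
#' @param blocks output of [segment_blocks()].
#' @param associations output of [find_gb_associations()] (used both for
#'   candidates and for reference-adjacency exhibition counts).
#' @param breakpoints output of [detect_breakpoints()]; `NULL` means no
#'   boundary is contradicted.
#' @return object of class `phex_karyotype`: list of chromosomes, each a
#'   data.table(label, orientation); plus `n_chromosomes`.
#' @export
assemble_ancestral_karyotype <- function(blocks, associations = NULL,
                                         breakpoints = NULL) {
  b <- as.data.table(blocks)
  assoc <- if (is.null(associations)) data.table() else as.data.table(associations)
  ref_adj <- reference_adjacencies(b)
  # exhibition of a reference adjacency = copies observed carrying it;
  # spanning exhibition (an unbroken fragment through the boundary) is the
  # only evidence strong enough to veto a breakpoint
  if (nrow(ref_adj)) {
    if (nrow(assoc)) {
      m <- assoc[ref_adj, on = "signature"]
      ref_adj[, support := fifelse(is.na(m$support), 0L, m$support)]
      sp <- if ("support_span" %in% names(assoc)) m$support_span else m$support
      ref_adj[, support_span := fifelse(is.na(sp), 0L, sp)]
      et <- if ("ends_terminal" %in% names(assoc)) m$ends_terminal else FALSE
      ref_adj[, ends_terminal := fifelse(is.na(et), FALSE, et)]
    } else ref_adj[, `:=`(support = 0L, support_span = 0L,
                          ends_terminal = FALSE)]
  }
  # drop reference adjacencies contradicted by a breakpoint
  if (!is.null(breakpoints) && nrow(as.data.table(breakpoints)) && nrow(ref_adj)) {
    bp <- as.data.table(breakpoints)
    bnd <- b[, .(label, chrom, start_rank, end_rank)]
    ref_adj <- merge(ref_adj,
                     bnd[, .(xid = label, chrom, cut = end_rank + 1L)],
                     by = c("chrom", "xid"), all.x = TRUE)
    has_bp <- !is.na(bp[ref_adj, on = .(chrom, gap = cut), which = TRUE])
    # a breakpoint removes the reference adjacency unless the spanning
    # evidence overrides it: two spanning copies always do; a single
    # spanning copy does only when no copy ends chromosomes at both block
    # ends (one spanning copy + terminal ends is the signature of a
    # secondary fusion recreating the reference junction, not of descent)
    ref_adj[, contradicted := has_bp &
              !(support_span >= 2L | (support_span == 1L & !ends_terminal))]
    ref_adj <- ref_adj[contradicted == FALSE]
  }
  edges <- list()
  if (nrow(assoc) && "candidate" %in% names(assoc)) {
    cnd <- assoc[candidate == TRUE]
    if (nrow(cnd))
      edges[[1L]] <- cnd[, .(signature, support, is_ref = FALSE)]
  }
  if (nrow(ref_adj))
    edges[[length(edges) + 1L]] <- ref_adj[, .(signature, support, is_ref = TRUE)]
  edges <- if (length(edges)) rbindlist(edges) else
    data.table(signature = character(), support = integer(), is_ref = logical())
  edges <- unique(edges, by = "signature")
  setorder(edges, -support, -is_ref, signature)
  # greedy matching on block ends with union-find cycle detection
  labels <- b$label
  parent <- setNames(labels, labels)
  find_root <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  end_used <- new.env(parent = emptyenv())
  accepted <- character()
  partner <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    sg <- edges$signature[i]
    ends <- strsplit(sg, "|", fixed = TRUE)[[1L]]
    if (!is.null(end_used[[ends[1L]]]) || !is.null(end_used[[ends[2L]]])) next
    la <- sub("\\..$", "", ends[1L]); lb <- sub("\\..$", "", ends[2L])
    ra <- find_root(la); rb <- find_root(lb)
    if (ra == rb)
      stop("cycle formed while assembling karyotype at junction ", sg,
           " (blocks ", la, ", ", lb, ")")
    parent[[ra]] <- rb
    end_used[[ends[1L]]] <- TRUE; end_used[[ends[2L]]] <- TRUE
    partner[[ends[1L]]] <- ends[2L]; partner[[ends[2L]]] <- ends[1L]
    accepted <- c(accepted, sg)
  }
  # walk maximal paths
  visited <- new.env(parent = emptyenv())
  chroms <- list()
  other_end <- function(e) {
    lab <- sub("\\..$", "", e)
    side <- sub("^.*\\.", "", e)
    paste0(lab, ".", if (side == "h") "t" else "h")
  }
  free_ends <- paste0(labels, ".h")[vapply(paste0(labels, ".h"),
                                           function(e) is.null(partner[[e]]),
                                           logical(1))]
  free_t <- paste0(labels, ".t")[vapply(paste0(labels, ".t"),
                                        function(e) is.null(partner[[e]]),
                                        logical(1))]
  starts <- sort(c(free_ends, free_t))
  for (st in starts) {
    lab <- sub("\\..$", "", st)
    if (!is.null(visited[[lab]])) next
    path <- list()
    e <- st
    repeat {
      lab <- sub("\\..$", "", e)
      visited[[lab]] <- TRUE
      side <- sub("^.*\\.", "", e)
      path[[length(path) + 1L]] <-
        data.table(label = lab,
                   orientation = if (side == "h") "forward" else "inverted")
      nxt <- partner[[other_end(e)]]
      if (is.null(nxt)) break
      e <- nxt
    }
    chroms[[length(chroms) + 1L]] <- rbindlist(path)
  }
  structure(list(chromosomes = chroms, n_chromosomes = length(chroms),
                 accepted_junctions = accepted),
            class = "phex_karyotype")
}

#' @export
print.phex_karyotype <- function(x, ...) {
  cat(sprintf("<phex_karyotype: %d chromosomes>\n", x$n_chromosomes))
  for (i in seq_along(x$chromosomes)) {
    ch <- x$chromosomes[[i]]
    cat(sprintf("  chr%02d: %s\n", i,
                paste0(ch$label, ifelse(ch$orientation == "inverted", "'", ""),
                       collapse = " ")))
  }
  invisible(x)
}

#' Karyotype as label strings (one chromosome per line, primes = inversion)
#' @param karyotype `phex_karyotype`.
#' @return character vector.
#' @export
karyotype_strings <- function(karyotype) {
  vapply(karyotype$chromosomes, function(ch)
    paste0(ch$label, ifelse(ch$orientation == "inverted", "'", ""),
           collapse = " "), character(1))
}
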