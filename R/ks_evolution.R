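## Codon-level Ks/Ka (Nei & Gojobori 1986 with Jukes-Cantor correction),
## Ks-distribution peaks, molecular-clock dating, synonymous-site
## supermatrices and neighbor-joining trees.

BASES <- c("A", "C", "G", "T")

# genetic code lookup on codon strings
.codon_env <- new.env(parent = emptyenv())
genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$code <- setNames(as.character(gc), names(gc))
  }
  .codon_env$code
}
aa_of <- function(codon) unname(genetic_code()[codon])
is_stop <- function(codon) aa_of(codon) == "*"

# fraction of the 3 possible single-nucleotide changes at each position that
# are synonymous; changes creating stop codons count as nonsynonymous.
# Returns numeric(3). Stop codons themselves return NA (caller masks them).
# Memoized over the 64 codons.
codon_syn_fractions <- function(codon) {
  key <- paste0("S_", codon)
  val <- .codon_env[[key]]
  if (!is.null(val)) return(val)
  val <- codon_syn_fractions_impl(codon)
  assign(key, val, envir = .codon_env)
  val
}

codon_syn_fractions_impl <- function(codon) {
  if (is_stop(codon)) return(rep(NA_real_, 3L))
  aa0 <- aa_of(codon)
  nt <- strsplit(codon, "")[[1L]]
  vapply(1:3, function(p) {
    alt <- setdiff(BASES, nt[p])
    syn <- vapply(alt, function(b) {
      mut <- nt; mut[p] <- b
      mc <- paste(mut, collapse = "")
      !is_stop(mc) && aa_of(mc) == aa0
    }, logical(1))
    sum(syn) / 3
  }, numeric(1))
}

# all minimal substitution pathways between two codons; each pathway is an
# ordering of the differing positions.  Pathways passing through a stop codon
# are excluded (if all are excluded, all are used).  Returns c(sd, nd):
# average synonymous / nonsynonymous differences over pathways.
# Memoized over codon pairs.
codon_path_differences <- function(c1, c2) {
  key <- paste0("D_", c1, c2)
  val <- .codon_env[[key]]
  if (!is.null(val)) return(val)
  val <- codon_path_differences_impl(c1, c2)
  assign(key, val, envir = .codon_env)
  val
}

codon_path_differences_impl <- function(c1, c2) {
  nt1 <- strsplit(c1, "")[[1L]]
  nt2 <- strsplit(c2, "")[[1L]]
  dif <- which(nt1 != nt2)
  nd <- length(dif)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(dif)
  res <- lapply(perms, function(ord) {
    cur <- nt1
    syn <- 0; non <- 0; blocked <- FALSE
    for (p in ord) {
      aa_from <- aa_of(paste(cur, collapse = ""))
      cur[p] <- nt2[p]
      nxt <- paste(cur, collapse = "")
      if (is_stop(nxt)) blocked <- TRUE
      if (aa_of(nxt) == aa_from && !is_stop(nxt)) syn <- syn + 1 else non <- non + 1
    }
    list(syn = syn, non = non, blocked = blocked)
  })
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(sd = mean(vapply(res[ok], `[[`, numeric(1), "syn")),
    nd = mean(vapply(res[ok], `[[`, numeric(1), "non")))
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

#' Pairwise Ks/Ka by the Nei-Gojobori (1986) method
#'
#' Synonymous-site fractions are computed per codon position (changes to stop
#' codons count as nonsynonymous), S is averaged over the two sequences,
#' multi-hit codons average synonymous/nonsynonymous differences over all
#' minimal substitution pathways (pathways through stops excluded), and the
#' Jukes-Cantor correction maps the proportions ps, pn to Ks, Ka. Codons
#' containing gaps, ambiguity codes or stops in either sequence are masked.
#'
#' @param seq1,seq2 aligned CDS strings (or DNAString), equal length,
#'   length divisible by 3.
#' @return list of class `phex_ks`: S, N, sd, nd, ps, pn, Ks, Ka,
#'   codons_used, undefined (TRUE when ps or pn >= 3/4 saturates the
#'   correction; the saturated value is NA).
#' @export
nei_gojobori <- function(seq1, seq2) {
  cs1 <- split_codons(seq1)
  cs2 <- split_codons(seq2)
  if (length(cs1) != length(cs2)) stop("aligned sequences differ in length")
  clean <- grepl("^[ACGT]{3}$", cs1) & grepl("^[ACGT]{3}$", cs2)
  keep <- clean & !vapply(cs1, is_stop, logical(1), USE.NAMES = FALSE) &
    !vapply(cs2, is_stop, logical(1), USE.NAMES = FALSE)
  keep[is.na(keep)] <- FALSE
  cs1 <- cs1[keep]; cs2 <- cs2[keep]
  if (!length(cs1)) stop("no complete codon columns to compare")
  s1 <- sum(vapply(cs1, function(cc) sum(codon_syn_fractions(cc)), numeric(1)))
  s2 <- sum(vapply(cs2, function(cc) sum(codon_syn_fractions(cc)), numeric(1)))
  S <- (s1 + s2) / 2
  N <- 3 * length(cs1) - S
  dd <- mapply(codon_path_differences, cs1, cs2)
  sd_ <- sum(dd["sd", ])
  nd_ <- sum(dd["nd", ])
  ps <- if (S > 0) sd_ / S else 0
  pn <- if (N > 0) nd_ / N else 0
  # saturation boundary padded against floating-point wobble
  jc <- function(p) if (p < 0.75 - 1e-9) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(ps); ka <- jc(pn)
  structure(list(S = S, N = N, sd = sd_, nd = nd_, ps = ps, pn = pn,
                 Ks = ks, Ka = ka, codons_used = length(cs1),
                 undefined = is.na(ks) || is.na(ka)),
            class = "phex_ks")
}

#' @export
print.phex_ks <- function(x, ...) {
  cat(sprintf("<phex_ks: Ks=%.4f Ka=%.4f (S=%.2f N=%.2f sd=%.2f nd=%.2f, %d codons)>\n",
              x$Ks, x$Ka, x$S, x$N, x$sd, x$nd, x$codons_used))
  invisible(x)
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Each aligned residue is replaced by the next codon of that gene's CDS;
#' gaps become `---`. Every residue is checked against the standard-code
#' translation of its codon; a mismatch is an error naming gene and position.
#' A trailing stop codon in the CDS is tolerated and dropped.
#'
#' @param protein_aln named character vector (or AAStringSet) of gap-aligned
#'   protein sequences.
#' @param cds_by_gene named character vector (or DNAStringSet) of ungapped
#'   CDS, names matching `protein_aln`.
#' @return named character vector of codon-aligned CDS (equal lengths,
#'   divisible by 3).
#' @export
back_translate <- function(protein_aln, cds_by_gene) {
  prot <- setNames(as.character(protein_aln), names(protein_aln))
  cds <- setNames(toupper(as.character(cds_by_gene)), names(cds_by_gene))
  miss <- setdiff(names(prot), names(cds))
  if (length(miss)) stop("no CDS for aligned sequence: ", miss[1L])
  out <- vapply(names(prot), function(g) {
    aa <- strsplit(prot[[g]], "")[[1L]]
    codons <- split_codons(cds[[g]])
    if (length(codons) && is_stop(codons[length(codons)]))
      codons <- codons[-length(codons)]
    res <- character(length(aa))
    j <- 0L
    for (i in seq_along(aa)) {
      if (aa[i] == "-") { res[i] <- "---"; next }
      j <- j + 1L
      if (j > length(codons))
        stop("CDS of ", g, " shorter than its aligned protein")
      tr <- aa_of(codons[j])
      if (!identical(tr, aa[i]))
        stop("translation mismatch for ", g, " at residue ", i,
             ": codon ", codons[j], " is ", tr, ", alignment has ", aa[i])
      res[i] <- codons[j]
    }
    if (j < length(codons))
      stop("CDS of ", g, " longer than its aligned protein")
    paste(res, collapse = "")
  }, character(1))
  out
}

#' Globally align two protein sequences (Needleman-Wunsch, BLOSUM62)
#'
#' Thin wrapper so codon alignments can be produced without an external
#' aligner; affine gap penalties 10 / 0.5.
#'
#' @param p1,p2 protein sequences (character).
#' @return character vector of the two aligned sequences.
#' @export
align_protein_pair <- function(p1, p2) {
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(p1),
                                      Biostrings::AAString(p2),
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

#' Ks for a table of gene pairs
#'
#' Convenience wrapper: for each (query, subject) pair, translate both CDS,
#' align the proteins (Needleman-Wunsch unless the CDS are already equal
#' length, in which case they are used as aligned), back-translate, and run
#' [nei_gojobori()].
#'
#' @param pairs data.frame with columns `q_id`, `r_id` (gene ids).
#' @param cds_q,cds_r named CDS sets (character or DNAStringSet).
#' @return data.table(q_id, r_id, S, N, sd, nd, ps, pn, Ks, Ka, undefined).
#' @export
ks_for_pairs <- function(pairs, cds_q, cds_r) {
  p <- as.data.table(pairs)
  cq <- setNames(toupper(as.character(cds_q)), names(cds_q))
  cr <- setNames(toupper(as.character(cds_r)), names(cds_r))
  res <- lapply(seq_len(nrow(p)), function(i) {
    a <- cq[[p$q_id[i]]]; b <- cr[[p$r_id[i]]]
    if (is.null(a) || is.null(b)) stop("missing CDS for pair ",
                                       p$q_id[i], " / ", p$r_id[i])
    if (nchar(a) != nchar(b)) {
      pa <- translate_cds(a); pb <- translate_cds(b)
      al <- align_protein_pair(pa, pb)
      bt <- back_translate(setNames(al, c("a", "b")), c(a = a, b = b))
      a <- bt[["a"]]; b <- bt[["b"]]
    }
    k <- nei_gojobori(a, b)
    data.table(q_id = p$q_id[i], r_id = p$r_id[i], S = k$S, N = k$N,
               sd = k$sd, nd = k$nd, ps = k$ps, pn = k$pn,
               Ks = k$Ks, Ka = k$Ka, undefined = k$undefined)
  })
  rbindlist(res)
}

translate_cds <- function(cds) {
  codons <- split_codons(cds)
  aa <- vapply(codons, aa_of, character(1), USE.NAMES = FALSE)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}

#' Modes of a Ks distribution
#'
#' Gaussian kernel density (default bandwidth: Silverman's rule) on Ks values
#' after excluding values above `exclude_above`; peaks are local maxima of
#' the density on a 512-point grid, filtered to at least `min_height_frac`
#' of the tallest mode, returned in ascending Ks order.
#'
#' @param ks numeric vector of Ks values.
#' @param bandwidth kernel bandwidth; `NULL` for Silverman's rule.
#' @param exclude_above saturation cutoff (default 3).
#' @param min_height_frac minor-mode filter, fraction of the global maximum.
#' @return numeric vector of peak Ks locations.
#' @export
ks_peak <- function(ks, bandwidth = NULL, exclude_above = 3,
                    min_height_frac = 0.05) {
  x <- ks[is.finite(ks) & ks >= 0 & ks <= exclude_above]
  if (!length(x)) stop("no usable Ks values")
  if (length(unique(x)) == 1L) return(unique(x))
  bw <- if (is.null(bandwidth)) bw.nrd0(x) else bandwidth
  d <- density(x, bw = bw, n = 512L)
  y <- d$y
  n <- length(y)
  ismax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  keep <- ismax & y >= min_height_frac * max(y)
  peaks <- d$x[keep]
  o <- order(peaks)
  structure(peaks[o], height = y[keep][o])
}

#' Location of the tallest mode of a Ks distribution
#' @inheritParams ks_peak
#' @return single Ks value.
#' @export
ks_main_peak <- function(ks, bandwidth = NULL, exclude_above = 3) {
  p <- ks_peak(ks, bandwidth = bandwidth, exclude_above = exclude_above)
  h <- attr(p, "height")
  if (is.null(h)) p[1L] else as.numeric(p[which.max(h)])
}

#' Molecular-clock dating parameters
#' @param neutral_rate substitutions per site per year (default 6.38e-9).
#' @return list of class `phex_dating_config`.
#' @export
dating_config <- function(neutral_rate = 6.38e-9) {
  if (neutral_rate <= 0) stop("neutral_rate must be positive")
  structure(list(neutral_rate = neutral_rate), class = "phex_dating_config")
}

#' Convert Ks to divergence time
#'
#' t = Ks / (2 mu) years: the synonymous substitutions accumulate along both
#' diverging lineages, so the pairwise Ks is split across the two branches.
#'
#' @param ks Ks value(s), non-negative.
#' @param cfg `dating_config()`.
#' @return time(s) in years.
#' @export
divergence_time <- function(ks, cfg = dating_config()) {
  if (any(ks < 0, na.rm = TRUE)) stop("negative Ks")
  ks / (2 * cfg$neutral_rate)
}

# first two codon nucleotides that make the third position fourfold degenerate
.fourfold_env <- new.env(parent = emptyenv())
fourfold_prefixes <- function() {
  if (is.null(.fourfold_env$pfx)) {
    code <- genetic_code()
    pfx <- character()
    for (a in BASES) for (b in BASES) {
      aa <- code[paste0(a, b, BASES)]
      if (length(unique(aa)) == 1L && !any(aa == "*")) pfx <- c(pfx, paste0(a, b))
    }
    .fourfold_env$pfx <- pfx
  }
  .fourfold_env$pfx
}

#' Extract a synonymous-site supermatrix from multi-species codon alignments
#'
#' A column's third position is taken as a synonymous site iff the column is
#' gap-free and every species' codon there has a fourfold-degenerate third
#' position. Sites are concatenated per species in alignment order then
#' column order.
#'
#' @param alignments list of named character vectors (or DNAStringSets); all
#'   alignments must contain exactly the same species set.
#' @return named character vector: one concatenated synonymous-site sequence
#'   per species.
#' @export
extract_synonymous_supermatrix <- function(alignments) {
  if (!length(alignments)) stop("no alignments given")
  species <- sort(names(alignments[[1L]]))
  seqs <- setNames(rep("", length(species)), species)
  pfx <- fourfold_prefixes()
  for (ai in seq_along(alignments)) {
    aln <- alignments[[ai]]
    if (!setequal(names(aln), species))
      stop("species set mismatch in alignment ", ai)
    mat <- do.call(rbind, lapply(species, function(s) split_codons(aln[[s]])))
    rownames(mat) <- species
    ok <- apply(mat, 2L, function(col) {
      all(grepl("^[ACGT]{3}$", col)) && all(substr(col, 1L, 2L) %in% pfx)
    })
    if (any(ok)) {
      third <- substr(mat[, ok, drop = FALSE], 3L, 3L)
      third <- matrix(third, nrow = length(species))
      seqs <- paste0(seqs, apply(third, 1L, paste, collapse = ""))
      names(seqs) <- species
    }
  }
  seqs
}

#' Jukes-Cantor distance matrix from a supermatrix
#'
#' p-distance per species pair over the concatenated sites, corrected as
#' d = -3/4 ln(1 - 4p/3).
#'
#' @param supermatrix named character vector of equal-length sequences.
#' @return symmetric distance matrix.
#' @export
jc_distance <- function(supermatrix) {
  sp <- names(supermatrix)
  n <- length(sp)
  chars <- lapply(supermatrix, function(s) strsplit(s, "")[[1L]])
  D <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(chars[[i]] != chars[[j]])
    d <- if (p < 0.75 - 1e-9) -0.75 * log(1 - 4 * p / 3) else NA_real_
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei NJ (via ape). Branch lengths are reported as computed
#' (possibly negative).
#'
#' @param D symmetric non-negative matrix with zero diagonal; row/col names
#'   are taxa (or supply `taxa`).
#' @param taxa optional taxon labels.
#' @return `phylo` object; serialize with [ape::write.tree()].
#' @export
nj_tree <- function(D, taxa = NULL) {
  D <- as.matrix(D)
  if (!is.null(taxa)) dimnames(D) <- list(taxa, taxa)
  if (nrow(D) < 3L) stop("NJ needs at least 3 taxa")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("negative distances")
  ape::nj(stats::as.dist(D))
}
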