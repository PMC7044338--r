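# Independent oracle implementations used to cross-check the package: each
# re-derives the quantity from first principles with plain loops and no
# shared code path with the implementation under test.

.orc_code <- as.character(Biostrings::GENETIC_CODE)
names(.orc_code) <- names(Biostrings::GENETIC_CODE)

orc_aa <- function(codon) unname(.orc_code[codon])

# Nei-Gojobori by literal counting: per-position synonymous site fractions
# (changes to stops are nonsynonymous), minimal pathways enumerated
# recursively, stop-passing pathways excluded unless all are.
orc_ng86 <- function(s1, s2) {
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- codons(s1); c2 <- codons(s2)
  keep <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2) &
    orc_aa(c1) != "*" & orc_aa(c2) != "*"
  c1 <- c1[keep]; c2 <- c2[keep]
  site_frac <- function(codon) {
    nt <- strsplit(codon, "")[[1]]
    tot <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), nt[p])) {
      mut <- nt; mut[p] <- b
      mc <- paste(mut, collapse = "")
      if (orc_aa(mc) != "*" && orc_aa(mc) == orc_aa(codon)) tot <- tot + 1 / 3
    }
    tot
  }
  paths <- function(from, to) {
    dif <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(dif)) return(list())
    if (length(dif) == 1L) {
      step <- strsplit(from, "")[[1]]; step[dif] <- strsplit(to, "")[[1]][dif]
      return(list(list(paste(step, collapse = ""))))
    }
    out <- list()
    for (p in dif) {
      step <- strsplit(from, "")[[1]]; step[p] <- strsplit(to, "")[[1]][p]
      mid <- paste(step, collapse = "")
      for (rest in paths(mid, to)) out <- c(out, list(c(mid, rest)))
    }
    out
  }
  S <- N <- sd_ <- nd_ <- 0
  for (i in seq_along(c1)) {
    S <- S + (site_frac(c1[i]) + site_frac(c2[i])) / 2
    if (c1[i] != c2[i]) {
      pl <- paths(c1[i], c2[i])
      ok <- vapply(pl, function(pp) !any(orc_aa(unlist(pp)) == "*"), logical(1))
      if (!any(ok)) ok <- rep(TRUE, length(pl))
      syn <- non <- numeric(0)
      for (pp in pl[ok]) {
        cur <- c1[i]; s <- 0; n <- 0
        for (nxt in unlist(pp)) {
          if (orc_aa(nxt) == orc_aa(cur) && orc_aa(nxt) != "*") s <- s + 1
          else n <- n + 1
          cur <- nxt
        }
        syn <- c(syn, s); non <- c(non, n)
      }
      sd_ <- sd_ + mean(syn); nd_ <- nd_ + mean(non)
    }
  }
  N <- 3 * length(c1) - S
  ps <- if (S > 0) sd_ / S else 0
  pn <- if (N > 0) nd_ / N else 0
  jc <- function(p) if (p < 0.75 - 1e-9) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, sd = sd_, nd = nd_, ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn))
}

# random stop-free codon string of n codons (any sense codon)
orc_random_cds <- function(n_codons) {
  sense <- names(.orc_code)[.orc_code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# two-sided binomial p by explicit enumeration of all 2^n equally likely
# outcome sequences: fraction whose success count is no more likely than
# the observed one
orc_binom_2n <- function(k, n) {
  pc <- integer(2^n)
  for (i in 1:(2^n - 1)) pc[i + 1] <- pc[bitwShiftR(i, 1L) + 1L] + (i %% 2L)
  tab <- tabulate(pc + 1L, nbins = n + 1L)  # outcomes per success count
  prob_k <- tab / 2^n                       # P(count = k)
  obs <- prob_k[k + 1L]
  sum(tab[prob_k <= obs * (1 + 1e-7)]) / 2^n
}

# one-sided (greater) Fisher p by explicit hypergeometric tail sum
orc_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  xs <- a:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# fragment partition oracle: boolean-matrix transitive closure over the
# chainability relation between query-consecutive pairs, then sequential
# monotone splitting inside each closure component
orc_fragment_partition <- function(pairs, cfg) {
  p <- data.table::as.data.table(pairs)
  data.table::setorder(p, q_chrom, r_chrom, q_rank, r_rank)
  lanes <- split(seq_len(nrow(p)), paste(p$q_chrom, p$r_chrom))
  part <- integer(nrow(p))
  fid <- 0L
  ch1 <- function(i, j) {
    gq <- abs(p$q_rank[i] - p$q_rank[j]) - 1L
    bq <- max(0, max(p$q_start[i], p$q_start[j]) - min(p$q_end[i], p$q_end[j]))
    gr <- abs(p$r_rank[i] - p$r_rank[j]) - 1L
    br <- max(0, max(p$r_start[i], p$r_start[j]) - min(p$r_end[i], p$r_end[j]))
    (gq < cfg$max_intervening || bq < cfg$max_gap) &&
      (gr < cfg$max_intervening || br < cfg$max_gap)
  }
  for (idx in lanes) {
    n <- length(idx)
    adj <- diag(TRUE, n)
    if (n > 1) for (k in 1:(n - 1))
      adj[k, k + 1] <- adj[k + 1, k] <- ch1(idx[k], idx[k + 1])
    reach <- adj
    for (m in seq_len(n)) reach <- (reach %*% adj) > 0 | reach
    comp <- integer(n); cc <- 0L
    for (k in seq_len(n)) if (comp[k] == 0L) {
      cc <- cc + 1L
      comp[which(reach[k, ])] <- cc
    }
    for (ccc in unique(comp)) {
      mem <- which(comp == ccc)
      dir <- 0L
      fid <- fid + 1L
      part[idx[mem[1]]] <- fid
      if (length(mem) > 1) for (k in 2:length(mem)) {
        a <- idx[mem[k - 1]]; b <- idx[mem[k]]
        st <- sign(p$r_rank[b] - p$r_rank[a])
        if (ch1(a, b) && (dir == 0L || st == 0L || st == dir)) {
          if (dir == 0L && st != 0L) dir <- st
        } else { fid <- fid + 1L; dir <- 0L }
        part[idx[mem[k]]] <- fid
      }
    }
  }
  # return partition as canonical list of member sets keyed by pair identity
  split(paste(p$q_id, p$r_id), part[seq_len(nrow(p))])
}

# per-base bitmap TE coverage of an interval
orc_bitmap_cover <- function(tes, chrom, lo, hi) {
  if (hi <= lo) return(NA_real_)
  bits <- logical(hi - lo)
  tt <- tes[tes$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tt))) {
    a <- max(tt$start[i], lo); b <- min(tt$end[i], hi)
    if (b > a) bits[(a - lo + 1):(b - lo)] <- TRUE
  }
  mean(bits)
}
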