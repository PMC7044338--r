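test_that("Nei-Gojobori reproduces hand-derived cases", {
  k0 <- nei_gojobori("ATGAAA", "ATGAAA")
  expect_equal(k0$Ks, 0)
  expect_equal(k0$Ka, 0)
  # one synonymous change at a fourfold third position over two glycine codons
  k1 <- nei_gojobori("GGTGGA", "GGCGGA")
  expect_equal(k1$sd, 1)
  expect_equal(k1$S, 2)
  expect_equal(k1$ps, 0.5)
  expect_equal(k1$Ks, -0.75 * log(1 / 3))
  expect_equal(k1$Ka, 0)
  # one nonsynonymous change, S averaged over the two codons
  k2 <- nei_gojobori("ATG", "ATA")
  expect_equal(k2$S, 1 / 3)
  expect_equal(k2$N, 8 / 3)
  expect_equal(k2$nd, 1)
  expect_equal(k2$Ka, -0.75 * log(0.5))
  expect_equal(k2$Ks, 0)
})

test_that("Nei-Gojobori is symmetric and masks incomplete codons", {
  set.seed(5)
  for (rep in 1:10) {
    a <- orc_random_cds(6)
    b <- orc_random_cds(6)
    ka <- nei_gojobori(a, b)
    kb <- nei_gojobori(b, a)
    expect_equal(ka$S, kb$S)
    expect_equal(ka$sd, kb$sd)
    expect_equal(ka$Ks, kb$Ks)
  }
  # gapped codon is excluded from both sequences
  kg <- nei_gojobori("GGT---GGA", "GGCAAAGGA")
  expect_equal(kg$codons_used, 2L)
})

test_that("Nei-Gojobori agrees with the exhaustive pathway oracle", {
  set.seed(17)
  for (rep in 1:50) {
    a <- orc_random_cds(sample(1:3, 1))
    b <- orc_random_cds(nchar(a) / 3)
    got <- nei_gojobori(a, b)
    orc <- orc_ng86(a, b)
    expect_equal(got$S, orc$S, tolerance = 1e-10)
    expect_equal(got$N, orc$N, tolerance = 1e-10)
    expect_equal(got$sd, orc$sd, tolerance = 1e-10)
    expect_equal(got$nd, orc$nd, tolerance = 1e-10)
  }
})

test_that("back-translation maps aligned residues onto codons", {
  bt <- back_translate(c(x = "M-K"), c(x = "ATGAAA"))
  expect_equal(unname(bt["x"]), "ATG---AAA")
  expect_error(back_translate(c(x = "MK"), c(x = "ATGCCC")),
               "translation mismatch for x at residue 2")
  # round trip on random proteins
  set.seed(23)
  for (rep in 1:5) {
    cds <- orc_random_cds(20)
    prot <- strsplit(orc_aa(substring(cds, seq(1, 58, 3), seq(3, 60, 3))), "")
    prot <- paste(unlist(prot), collapse = "")
    gapped <- paste0(substr(prot, 1, 7), "--", substr(prot, 8, 20))
    bt <- back_translate(setNames(gapped, "g"), setNames(cds, "g"))
    recovered <- gsub("---", "--", bt, fixed = TRUE)
    # translating back (skipping gaps) returns the original protein
    cod <- substring(bt, seq(1, nchar(bt) - 2, 3), seq(3, nchar(bt), 3))
    aa <- ifelse(cod == "---", "-", orc_aa(cod))
    expect_equal(paste(aa, collapse = ""), gapped)
  }
})

test_that("ks_peak finds simulated modes and handles degenerate input", {
  set.seed(31)
  x <- abs(rnorm(1000, 0.28, 0.05))
  p <- ks_peak(x)
  expect_true(any(abs(p - 0.28) < 0.02))
  expect_lt(abs(ks_main_peak(x) - 0.28), 0.02)
  y <- c(rnorm(1000, 0.12, 0.03), rnorm(1000, 0.51, 0.06))
  py <- ks_peak(y[y > 0])
  expect_true(any(abs(py - 0.12) < 0.03))
  expect_true(any(abs(py - 0.51) < 0.03))
  expect_equal(as.numeric(ks_peak(rep(0.2, 50))), 0.2)
  expect_error(ks_peak(numeric()), "no usable")
  # saturation filter
  expect_true(all(ks_peak(c(x, rep(5, 100))) <= 3))
})

test_that("divergence time is Ks/(2 mu) and linear in Ks", {
  cfg <- dating_config()
  expect_equal(divergence_time(0, cfg), 0)
  expect_equal(divergence_time(0.2, cfg), 2 * divergence_time(0.1, cfg))
  expect_equal(divergence_time(0.12, dating_config(1e-8)), 6e6)
  expect_error(divergence_time(-0.1), "negative")
  expect_error(dating_config(0), "positive")
})

test_that("synonymous supermatrix keeps fourfold gap-free third positions", {
  aln <- list(g1 = c(sp1 = "GGTATG", sp2 = "GGCATG", sp3 = "GGGATG"))
  sm <- extract_synonymous_supermatrix(aln)
  expect_equal(sm, c(sp1 = "T", sp2 = "C", sp3 = "G"))
  # gap in one species excludes the column
  aln2 <- list(g1 = c(sp1 = "GGT", sp2 = "---", sp3 = "GGG"))
  expect_equal(unname(nchar(extract_synonymous_supermatrix(aln2))), rep(0L, 3))
  expect_error(extract_synonymous_supermatrix(
    list(g1 = c(sp1 = "GGT", sp2 = "GGC"), g2 = c(sp1 = "GGT", sp3 = "GGC"))),
    "species set mismatch")
})

test_that("supermatrix site count equals a per-column degeneracy scan", {
  set.seed(41)
  sp <- c("s1", "s2", "s3", "s4")
  alns <- lapply(1:5, function(i) {
    base <- orc_random_cds(15)
    setNames(lapply(sp, function(s) {
      m <- strsplit(base, "")[[1]]
      idx <- sample(length(m), 5)
      m[idx] <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
      paste(m, collapse = "")
    }), sp)
  })
  alns <- lapply(alns, unlist)
  sm <- extract_synonymous_supermatrix(alns)
  # oracle: a column is synonymous iff every species' codon translates
  # identically under all four third bases
  count <- 0L
  for (aln in alns) {
    cods <- lapply(aln, function(s)
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))
    for (j in seq_along(cods[[1]])) {
      ok <- all(vapply(sp, function(s) {
        cd <- cods[[s]][j]
        if (!grepl("^[ACGT]{3}$", cd)) return(FALSE)
        aas <- orc_aa(paste0(substr(cd, 1, 2), c("A", "C", "G", "T")))
        length(unique(aas)) == 1 && !any(aas == "*")
      }, logical(1)))
      if (ok) count <- count + 1L
    }
  }
  expect_equal(unname(nchar(sm[1])), count)
})

test_that("NJ recovers three-taxon branch lengths and additive trees", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # zero-length cherry from two identical taxa
  D2 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr2 <- nj_tree(D2)
  expect_equal(min(tr2$edge.length), 0)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  D3 <- D; D3[1, 2] <- 5
  expect_error(nj_tree(D3), "symmetric")
})

test_that("JC distances from a supermatrix feed NJ", {
  sm <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "CCCCCCCCCA")
  D <- jc_distance(sm)
  expect_equal(D["a", "b"], -0.75 * log(1 - 4 * 0.1 / 3))
  expect_true(isSymmetric(D))
})
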