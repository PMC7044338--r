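---
title: "Reconstructing sub-genomes and dating polyploidy with paleohex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing sub-genomes and dating polyploidy with paleohex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleohex)
```

# The problem

Many plant genomes are ancient polyploids. White lupin (*Lupinus albus*) is a
paleohexaploid: a whole-genome triplication (WGT) left three homoeologous
copies of every ancestral chromosome, which then diverged by biased gene loss
(fractionation), chromosome rearrangement, transposable-element (TE)
accumulation and expression divergence. Given only a modern triplicated
genome and a diploid relative used as a reference, `paleohex` reconstructs:

* **syntenic gene pairs and fragments** between polyploid and reference,
* **genomic blocks (GBs)**: reference segments delimited by rearrangement
  breakpoints shared across sub-genome copies,
* the **diploid ancestral karyotype**, as an ordered, oriented arrangement
  of blocks,
* the three **sub-genomes** LF / MF1 / MF2 (least- to most-fractionated),
* **Ks-based dating** of speciation and polyploidy events,
* **homoeolog expression dominance** and its association with promoter TE
  load,
* **duplication-mode classes** and GO over-retention enrichment.

Because the real genomes are large and external, the package ships a
synthetic paleohexaploid generator with complete ground truth; every stage of
the pipeline is exercised and validated end-to-end on simulated genomes.

# Synteny: pairs and fragments

A homology hit $(q, r)$ is promoted to a *syntenic pair* when the
neighbourhood corroborates it: among the `flank_window` (default 20) genes on
each side of $q$, at least `min_support` (default 2) distinct genes must have
their own hit within `flank_window` ranks of $r$. Collinearity is measured in
*gene-rank space* (the ordinal position of a gene on its chromosome), which
is robust to TE-driven length differences between genomes.

Two caps keep the pairing consistent with ploidy: each reference gene may
pair with at most `max_pairings_per_ref` (3) query genes, and each query gene
keeps only its best reference partner (support, then bitscore) — the
reference is diploid, so a query gene has exactly one orthologous reference
locus. Without the query-side cap, a spurious near-diagonal hit can give one
gene two accepted partners and corrupt fragment monotonicity downstream.

Accepted pairs are chained into *syntenic fragments*: walking pairs in query
order within one (query chromosome, reference chromosome) lane, two
consecutive pairs chain when **in each genome separately** they are
interrupted by fewer than `max_intervening` (50, exclusive) genes **or** lie
closer than `max_gap` (200 kb, exclusive). We read the interruption rule as a
per-genome disjunction applied in both genomes, since both clauses are
proximity tests. Reference ranks must move monotonically within a fragment;
a direction flip closes it, so micro-inversions become separate fragments and
every fragment has a well-defined orientation. Fragments spanning more than
`min_fragment_span` (200 kb, strict) in the query survive the size filter
used for counting and painting.

# Breakpoints, blocks and the ancestral karyotype

Every fragment end interior to a reference chromosome proposes a cut in
reference gene-rank space. Cuts are deduplicated per sub-genome copy,
clustered by single linkage within `tolerance` (10 ranks), and clusters
supported by **more than one copy** become breakpoints: a cut seen in a
single copy is a private rearrangement, while independent copies ending at
the same reference position indicate the ancestor was assembled differently
there. Candidate cuts within `tolerance` of a chromosome end are discarded —
terminal gene loss is indistinguishable from rearrangement that close to an
end. Breakpoints split the reference into blocks labelled `A`, `B`, ...
(`AA`, `AB`, ... past 26), which tile each chromosome.

Block *associations* are mined directly from fragment adjacency: wherever
two fragments physically adjacent on a polyploid chromosome both terminate
at block boundaries (within `tolerance`), the facing block ends name a
junction, with `X.h`/`X.t` ends distinguishing `X`–`Y` from `X`–`Y'`
junctions. Mining junctions from fragment ends, rather than from whole-block
painting labels, makes the evidence insensitive to rearrangements interior
to a block: an inversion in the middle of a block moves no block boundary.
For the same reason, junction and breakpoint-spanning evidence may use
fragments below the 200 kb filter — a short surviving block tail still
witnesses where two boundaries meet. Junctions present in the reference are
recorded as *exhibitions* of that reference adjacency; junctions absent from
the reference and supported by **at least two** copies are ancestral
candidates.

The karyotype assembler builds a graph on block ends. Edges are the
candidate junctions plus the reference adjacencies, except that a reference
adjacency sitting on a breakpoint is removed unless the spanning evidence
overrides it: kept when two or more copies span the boundary with
pair-verified coverage on both sides, or when exactly one copy spans it and
no copy exhibits both block ends as chromosome termini. The asymmetric rule
separates two look-alike situations: coincidentally collided copy-private
cuts (a false breakpoint — the remaining copies genuinely run through, so
the adjacency is restored and the spuriously split block is healed) versus a
secondary fusion that recreated the reference junction in one copy (the
other copies end their chromosomes at the boundary, which is positive
evidence of true separation). Spanning is verified at the syntenic-pair
level — a fragment only counts as spanning when it holds pairs within
`tolerance` on *both* sides of the cut — so a stray out-of-order pair cannot
fake continuity. Conflicts at a block end are resolved by higher support,
then reference preference, then lexicographic label; each end carries at
most one edge, and a cycle is reported as an error (circular chromosomes are
outside the model). Maximal paths are the ancestral chromosomes.

With three copies the evidence has one genuinely ambiguous configuration: a
fission exactly at a true ancestral junction in one copy produces the same
observable pattern (two copies joined, one copy split) as two convergent
fusions creating an identical novel junction. The package resolves it in
favour of the junction (parsimony: one event rather than two independent
identical ones); the simulator section explains why convergent identical
fusions are vanishingly rare in realistic data.

# Sub-genome reconstruction and retention

Fragments are distributed into three *paintings* per ancestral chromosome
under two rules: (1) a painting never contains two fragments covering the
same ancestral locus, and (2) among feasible distributions the one implying
the fewest rearrangements wins, counted as adjacency breaks — consecutive
fragments of a painting lying on different polyploid chromosomes. Redundant
coverage is established on shared loci (more than one shared locus; a single
shared locus is within homology-noise), not on interval overlap, which a
stray pair could inflate. Conflict components are solved exhaustively (up to
`component_cap` = 12 items, greedy beyond with a warning) but *sequentially
along the chromosome*, each component scored against the items already
painted; otherwise non-overlapping depth groups would be solved in isolation
and the painting permutation would be arbitrary from block to block. Ties
prefer paintings homogeneous in retention density, since same-copy pieces
share a fractionation rate.

Retention density is profiled in a centered window of 1001 ancestral loci
(500 per side, truncated at chromosome ends, never crossing chromosomes).
For ranking, each painting's mean density is computed over the region it
actually covers, so a regional deletion or a filtered fragment does not
zero-dilute the copy's rate — real paleopolyploids show exactly such
terminal regional deletions. Per ancestral chromosome, the densest painting
is LF, then MF1, then MF2; ties break by retained-gene count, then copy id.
Retention counts per sub-genome are tested against uniform retention with a
3-category chi-square goodness-of-fit (df = 2).

A note on calibration: if genes are retained *independently* per copy with
equal rates, the three counts are independent binomials and the Pearson
statistic is conservative relative to its nominal chi-square null (the
multinomial sampling model conditions on the total). The calibration test in
the suite therefore simulates the test's own null — total retained genes
fixed, sub-genome assignment uniform — under which the p-value is uniform.

# Ks, dating, and trees

Pairwise Ks/Ka uses the Nei–Gojobori (1986) method: per-codon synonymous
site fractions (changes producing stop codons count as nonsynonymous),
S averaged over the two sequences, observed differences averaged over all
minimal substitution pathways with stop-passing pathways excluded, and the
Jukes–Cantor correction $K = -\tfrac34\ln(1 - \tfrac43 p)$. Codons with
gaps, ambiguity codes or stops in either sequence are masked pairwise;
proportions at or beyond the $p = 3/4$ saturation boundary (with a small
numeric guard) are flagged undefined. Protein alignments for unequal-length
CDS use Needleman–Wunsch (BLOSUM62, affine 10/0.5), then codons are
back-translated onto the alignment with a per-residue translation check.

Ks distributions are summarised by the modes of a Gaussian kernel density
(Silverman bandwidth, 512-point grid, values above Ks = 3 excluded; modes
below 5% of the main mode suppressed); a kernel estimate is deterministic
with respect to binning where a histogram is not. Divergence times use
$t = K_s / (2\mu)$ with $\mu = 6.38\times10^{-9}$ synonymous substitutions
per site per year: the substitutions split across the two diverging
lineages. Synonymous supermatrices take third positions of codons that are
fourfold-degenerate in every species at gap-free columns; distances are
JC-corrected p-distances and trees are classic neighbor-joining (via `ape`),
whose exactness on additive matrices the suite verifies.

# Expression dominance and TE profiles

Expression tables are converted to TPM ($10^6 c_g/L_g / \sum_h c_h/L_h$).
Within a tissue, the bottom 1% of genes by expression (ties at the cut
included) are treated as not expressed and contribute zero. A homoeolog
doublet is evaluable when the larger member exceeds 5 TPM; at fold threshold
$f$, a member is dominant when its expression is at least $f$ times its
partner's and the reverse does not hold. Direction bias across doublets is
tested with an exact two-sided binomial test at $p = 1/2$, summing the
probabilities of all outcomes no more likely than the observed count (the
doubled-smaller-tail variant is reported alongside).

TE density around genes uses 100-bp windows stepped by 10 bp across both
flanks (default 3 kb per side; the flank length is configurable since
published figures show unspecified "vicinity regions"), orientation
following gene strand, overlapping TEs merged before counting, and windows
crossing chromosome ends dropped. Promoters are the 2 kb upstream of the
TSS, strand-aware and truncated at chromosome boundaries. Dominant and
suppressed doublet members are compared on promoter TE density with a
two-sided Wilcoxon rank-sum test (the choice of test is ours; the source
analyses report the contrast without naming one).

# Duplication modes, GO enrichment, ortholog filtering

Duplication classes follow the priority WGT > tandem > dispersed: syntenic
genes are WGT-derived; non-syntenic genes with a same-chromosome homolog
within 5 intervening genes (configurable; "neighboring" is not quantified in
the source) are tandem; other homolog-bearing genes are dispersed; the rest
are singletons. GO over-retention enrichment uses one-sided (greater)
hypergeometric tests per term with Benjamini–Hochberg correction reported
alongside raw p-values. The ortholog filter keeps hits with
E-value $\le 10^{-20}$, coverage > 50% and identity > 35%; the E-value
inequality is read as a ceiling, since an E-value *floor* would accept
arbitrarily poor alignments and contradict the filter's purpose.

# The synthetic paleohexaploid generator

`simulate_paleohexaploid()` builds, in three independently seeded phases:

1. **Ancestor and polyploid** (`seed`): a diploid ancestor of 9 chromosomes
   by 300 gene loci; three copies with independent Bernoulli retention at
   rates 0.8 / 0.6 / 0.5 (LF / MF1 / MF2); 20 copy-private rearrangements
   (fission / fusion / inversion at 0.05 / 0.15 / 0.80, inversion windows
   5–15 genes), yielding about 25 descendant chromosomes; 3% tandem and 2%
   dispersed extra duplicates; TE insertion rates anti-correlated with
   retention (0.10 / 0.25 / 0.30 per kb, geometric lengths, mean 500 bp);
   expression log-normal ($\mu = 2$, $\sigma = 1$ on the log scale) with the
   causal dominance coupling $\exp(-\beta \cdot \text{promoter TE
   fraction})$, $\beta = 2$, then TPM-normalised per tissue.
2. **Reference** (`ref_seed`): the ancestor is cut at 16 interior positions
   (segments at least 70 loci) and the 25 segments are re-arranged, with
   random orientations, into 11 reference chromosomes such that no two
   same-ancestor-chromosome segments are adjacent. Every internal reference
   junction is then a recoverable shared breakpoint (14 by default) and
   every ancestor-internal cut a recoverable ancestral association (16).
   Because the polyploid is generated before and independently of the
   reference, two configs differing only in `ref_seed` view one fixed
   polyploid through two different references — the reference-choice
   robustness check.
3. **Observables** (`seed`-derived): homology hits with identity/coverage
   noise and 1% spurious hits; CDS of 200 codons drawn from the six
   fourfold-degenerate codon families without first/second-position
   degeneracy (GGN, GCN, GTN, CCN, ACN, TCN), so every third position is
   exactly one synonymous site and the coding alphabet is stop-free by
   construction; synonymous divergence planted as Poisson/JC substitutions
   at third positions targeting pairwise Ks 0.28 between copies and 0.51 to
   the reference, which NG86 recovers directly; GO terms assigned at random.

Geometry matters: genes are spaced 8 kb apart so that even the
most-fractionated copy of the smallest (70-locus) segment spans more than
the 200-kb fragment filter; at tighter spacing, fractionation compresses
real fragments below the filter and silently deletes junction evidence.

The rearrangement-type mix is deliberately inversion-heavy. End-to-end
fusions in a genome with only ~20 chromosome ends collide: with several
fusions per copy, two copies create the *same* novel end-to-end junction
with birthday-problem probability of several percent per genome, which
mimics shared ancestry and is an artifact of discretising fusion points to
gene-resolution chromosome ends — in real genomes, two sub-genomes
independently forming base-identical junctions is essentially impossible.
Keeping fusions rare restores the realistic prior while preserving the
configured descendant chromosome count.

**What passing tests do and do not show.** The generator emulates the
statistical structure of a fractionating paleohexaploid — collinearity
broken by planted rearrangements, biased gene loss, TE load anti-correlated
with retention, expression dominance causally coupled to promoter TE — but
not sequence-level reality: no TE sequence models, no read-level expression
noise, no assembly errors or missing genes beyond fractionation, hit noise
far simpler than BLAST against a real proteome, and CDS restricted to a
synonymous-only alphabet (Ka is zero by construction). Recovery rates
measured on these simulations bound the method's behaviour under its own
model assumptions, not its accuracy on any real genome.

# Numerical and degenerate-input choices

* Gene rank ties (identical starts) break lexicographically by gene id.
* TPM effective length is exonic length where known, else gene span.
* `ks_peak` on constant data returns that constant; empty input errors.
* The LF/MF1/MF2 labels are undefined under exactly equal retention; the
  assignment is still deterministic (tie-breaks), and simulations with equal
  rates recover labels at chance level, as expected.
* Retention profile windows are truncated at chromosome ends and the
  divisor follows the truncated window.
* All interval arithmetic is 0-based half-open internally; GFF3's 1-based
  closed convention is converted at I/O boundaries only.

# Problem sizes used by the test-suite

The suite validates structural recovery on 50 clean and 50 noisy replicates
at the default genome size (2700 ancestral loci, ~5700 polyploid genes),
oracle equivalence on 500 random short codon pairs, complete binomial
enumerations up to n = 20, hypergeometric tables up to n = 30, and
calibration over 200 null replicates — sizes at which each check is exact or
statistically decisive while the whole suite stays fast.

# Known limitations

* Breakpoint and association evidence comes from exactly three sub-genome
  copies; evidence patterns that need a fourth observer (the
  fission-at-junction vs convergent-fusion ambiguity above) are resolved by
  prior, not by data. Comparative designs with a second polyploid species
  would disambiguate.
* "Fewest rearrangements" is a breakpoint-count heuristic with exhaustive
  search over small conflict components, not a genome-rearrangement distance
  (no DCJ / sorting by reversals).
* GO terms are flat labels; no DAG propagation.
* The NG86 estimator is the classic counting method; no maximum-likelihood
  codon models are provided.
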