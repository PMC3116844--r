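---
title: "Fold recognition with fold-specific PSSM libraries: methods and design"
author: "FoldScanR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold recognition with fold-specific PSSM libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FoldScanR)
```

# The problem

Protein structure is conserved far beyond the point where sequence identity
remains detectable: two proteins sharing a fold can sit below 25% pairwise
identity, the "twilight zone" where ordinary alignment statistics no longer
separate homologs from chance. FoldScanR implements a fold-recognition
method built for this regime. Rather than comparing a query against single
sequences, it measures the query against *libraries of fold-specific PSSMs*
(position-specific scoring matrices), turns the measurements into a compact
vector representation of the protein, and relates proteins through the
correlation of those vectors.

# The method

## Fold-specific PSSM libraries

For every fold of interest, a library of PSSMs is constructed from a set of
fold-labelled sequences:

1. Each library seed comes with a set of collected homologs (in the
   original protocol these come from an iterated database search; here they
   are an explicit input, so any source -- files, a user's own PSI-BLAST
   run, or the built-in simulator -- can supply them).
2. Homologs nearly identical to the seed (global identity >= 0.90) are
   removed, then the set is made non-redundant with a greedy keep-first
   sweep at >= 0.40 identity (`filterNearIdentical()`, `filterRedundant()`).
   Both identities come from Needleman-Wunsch global alignment with
   BLOSUM62, gap opening 10 and gap extension 0.5 -- the same settings used
   for every identity quoted by the package.
3. One PSSM is built per seed (`buildPSSM()`): homologs are placed on seed
   columns by global alignment, observed counts are weighted with Henikoff
   position-based weights, matrix-derived (Tatusov-style) pseudocounts with
   weight `beta = 10` are mixed in relative to the per-column effective
   observation count (distinct residues minus one), and each column is
   scored as log2 odds against the background, rounded to 2 decimals.

A `LibraryCollection` fixes an ordered set of fold libraries; the order of
the manifest file is the single source of axis-order truth for every
profile computed against the collection.

## Scanning and the fold-specific score

A query is compared to every PSSM of a library by local (Smith-Waterman)
profile alignment with affine gaps; one best alignment per PSSM is kept.
Alignments are filtered by an E-value threshold and by *coverage*, the
fraction of the PSSM spanned by the alignment. Two presets mirror the
method's standard settings:

* `"strict"`: E <= 0.01, no coverage requirement (the default);
* `"permissive"`: E <= 1e10, coverage >= 0.80.

For every aligned pair that is identical or conserved -- operationally,
whose BLOSUM62 score is positive -- that score is added to the query
position's *positional score* P_i. The fold-specific score of the query for
the library is

    score = sum_i max(P_i, 0) / n

with `n` the query length. Repeating this over all fold libraries yields
the query's *structural sequence profile*, a vector with one entry per
fold axis. Two proteins are then related by the Pearson correlation of
their profiles (the *structural similarity score*, in [-1, 1]); pairs
scoring above 0.1 are conventionally treated as structurally related, and
`predictFold()` annotates a query with the axis of its highest
fold-specific score.

## Template selection

For template-based modelling, candidate template domains and the target are
represented over one fold's PSSMs as (identity x coverage) feature vectors:
per PSSM, the best surviving alignment's identity over aligned pairs times
its coverage, 0 when nothing survives. The entities are clustered
hierarchically with distance 1 - Pearson (average linkage), and the top-k
candidates by Pearson similarity to the target are returned
(`selectTemplates()`, default k = 3, the usual maximum number of templates
passed downstream). The original procedure selects templates as a visually
chosen group in the dendrogram; since no cut criterion is stated, we
operationalise the choice as top-k similarity to the target and emit the
dendrogram for inspection. The output is a ranked template list plus a
FASTA bundle ready for external multiple alignment and model building,
which are out of scope here.

# Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| NW gap opening / extension | 10 / 0.5 | global alignments behind all identity computations; a gap of length k costs open + k*extend |
| near-identical filter | 0.90 (inclusive) | homologs at or above this identity to a seed are dropped |
| redundancy filter | 0.40 (inclusive) | survivors are pairwise below this identity |
| pseudocount weight beta | 10 | weight of matrix-derived pseudocounts relative to the per-column effective count |
| profile SW gap opening / extension | 5.5 / 0.5 bits | BLAST's protein defaults (11/1 half-bits) re-expressed on the PSSM's bit scale |
| KA lambda, K | 0.534, 0.041 | BLAST gapped BLOSUM62 constants; lambda is per score unit, and the published 0.267 per half-bit becomes 0.534 per bit |
| E-value / coverage presets | (0.01, 0) and (1e10, 0.80) | strict and permissive scan filters |
| similarity calling threshold | 0.1 | structural similarity above which a pair is called related |
| templates k | 3 | templates returned per target |

Because the package serialises PSSM scores as real-valued log2 odds (2
decimals) rather than rounded integer half-bits, every constant expressed
"per score unit" is given on the bit scale; keeping the E-value constants on
the half-bit scale would overstate E by orders of magnitude.
`calibrateParams()` fits lambda and K for a specific PSSM by a
maximum-likelihood Gumbel fit to the score maxima of random
background-composition queries, and recovers the published ungapped
BLOSUM62 lambda within a few percent when run on a matrix-row PSSM.

# Numerical choices

* **Background frequencies.** PSSM log-odds are scored against the
  background implied by BLOSUM62 itself: pair frequencies
  Q ∝ p0_a p0_b 2^(s/2) are seeded with the Robinson-Robinson amino-acid
  frequencies, normalised, and the marginals of Q are used as background,
  with cond(r|a) = Q_ar / p_a as the pseudocount source. Because Q is
  symmetric with marginals equal to the background, a column whose observed
  frequencies equal the background scores exactly zero -- the model is
  self-consistent, which an external frequency table cannot guarantee
  against a rounded matrix.
* **Zero-variance profiles.** Pearson correlation is undefined for a
  constant vector; `structuralSimilarity()` returns 0 ("no evidence"),
  keeping all-against-all tables total without NaN propagation.
* **Ties.** `predictFold()` resolves ties to the earliest axis; rankings
  in `topkConfusion()` and `selectTemplates()` break score ties by id;
  co-optimal alignments resolve to the first optimum in row-major scan
  order with a fixed traceback preference. All outputs are deterministic.
* **Ambiguity codes.** `X` is accepted on input; matrix rows for `X` come
  from the matrix file when present (score -1 against everything
  otherwise); PSSM columns whose seed residue is not a standard letter
  score 0 everywhere, and query `X` residues score 0 against every PSSM
  column. Positional scores only ever add positive substitution scores, so
  tracks stay non-negative.
* **Thresholds are inclusive** on their stated side: E <= threshold,
  coverage >= threshold, identity >= threshold for removal.
* **Coordinates** are 1-based and inclusive, in files and in memory.

# The synthetic benchmark generator

`makeBenchmark()` builds a self-contained benchmark world so the entire
pipeline is testable without external databases. Per fold, one ancestor is
drawn from the background; a conserved core (fraction equal to the lower
edge of the identity band) is fixed; seeds, homologs and held-out queries
are independent mutants dialled by `mutateToIdentity()` -- an indel process
followed by batched point substitutions, measured with the package's own
Needleman-Wunsch identity -- to a target drawn uniformly from the band.
Because a single substitution can restructure the optimal alignment of a
short sequence and jump identity past the band, steps that overshoot are
rolled back and retried with smaller batches; targets that remain
unreachable (e.g. a frozen core above the requested identity) raise an
error after a bounded number of batches.
Substitutions mix matrix-derived (conservative) exchange probabilities with
a uniform draw in equal parts: fully conservative replacement makes
independent mutants coincide too often (inflating pairwise identity above
the band), while fully uniform replacement destroys the positively scoring
substitution structure that gives fold libraries their signal; the even mix
keeps family-member pairwise identities inside the band while preserving
that structure. Sharing one mutable-site set within a family is what makes
*pairwise* identities (not just identities to the ancestor) land in the
band, the controlled variable of the twilight-zone regime.

The generator's default study conditions are 8 folds, 2 seeds per fold, 15
homologs per seed, 5 held-out queries per fold, an identity band of
0.20-0.30, indel rate 0.02, and lengths drawn from a truncated normal of
135 +/- 90 (minimum 40), mimicking the composition of a twilight-zone
benchmark set. The mutation model is a biased substitution process, not an
explicit phylogeny: the method under test is alignment-based, and the
identity band -- not tree shape -- is the variable that matters.

What passing tests on this world do and do not show: synthetic families
share a literal conserved core and have no domain architecture, secondary
structure, repeats or compositional bias, so recognition here demonstrates
the pipeline's statistical machinery (library specificity, profile
separation, ranking behaviour) under controlled twilight-zone identity --
not performance on real structural databases.

# Evaluation machinery

All-against-all structural similarities with same-fold / different-fold
truth labels feed `rocCurve()` (global threshold sweep; pairs scoring at or
above the threshold are called positive; trapezoidal AUC),
`topkConfusion()` (per query, same-fold partners inside the top k are TP,
different-fold inside are FP, same-fold outside are FN; sets keyed by
unordered pairs for Venn-style comparison via `compareMethods()`) and
`cumulativeDistribution()` (ECDF plus fraction above a threshold such as
0.1). Pairs are pooled globally across queries, matching the all-against-all
ranking protocol; per-query averaging is not the default.

# Problem sizes

The test suite validates both alignment kernels against exhaustive
brute-force enumeration (all matched-pair sets) on 100 random instances
each at lengths <= 8, checks Pearson correctness on 1,000 random vector
pairs at 1e-12, and runs the full pipeline end to end on the default
8-fold benchmark world (40 queries, 780 labelled pairs), where it requires
top-1 fold accuracy >= 0.7 (chance 0.125) and same/different-fold AUC
>= 0.9. `scripts/acceptance.R` reruns that world from scratch and reports
the measured statistics.

# Known limitations

* Library construction replaces the original iterated-database expansion
  with explicit homolog inputs, and homolog placement uses one global
  alignment to the seed rather than master-slave HSPs; with very divergent
  homologs the column mapping is correspondingly cruder.
* One best local alignment per (query, PSSM): sub-optimal HSPs do not
  contribute to positional scores.
* E-values use a single analytical formula with fixed constants unless
  calibrated per PSSM; effective-length corrections of database search
  engines are not reproduced (`m` and `n` are explicit parameters instead).
* The aligned partner of a query residue is the PSSM's *reference* residue
  at the aligned column (a PSSM column has no single residue, so the
  reference is the natural representative); the alternative reading -- the
  column's top-scoring residue -- is available via
  `positionalScores(partner = "column-max")` but is not the default.
* Fold libraries beyond ~10^2 folds are out of tested territory, as are
  nucleotide sequences and alignment interchange formats.
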