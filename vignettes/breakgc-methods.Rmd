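---
title: "Methods: linking double-strand-break repair to prokaryotic GC content"
author: "breakgc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking double-strand-break repair to prokaryotic GC content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakgc)
```

## The scientific question

Prokaryotic genomic GC content spans roughly 0.2 to 0.75, and mutation alone
cannot explain the high end: mutation is universally AT-biased, so something
must push G/C alleles to fixation. One candidate selective agent is exposure
to DNA double-strand breaks (DSBs). Organisms that carry Ku — the conserved
DNA-end-binding protein required for non-homologous end joining (NHEJ) — are
by implication organisms for which DSB repair matters, and GC pairs (three
hydrogen bonds, stronger stacking) plausibly aid end-joining at breaks.
`breakgc` implements the four quantitative analyses that together test this
association:

1. **Polymorphism fate** (`polarize` functions, `run_polymorphism()`):
   estimate each genome's mutational bias and the equilibrium GC content it
   implies, and compare with observed GC. A genome sitting above its
   mutational equilibrium is experiencing GC-favouring fixation (selection
   or biased gene conversion).
2. **Recombination detection** (`phi_*` functions, `run_recombination()`):
   the pairwise homoplasy index with a permutation test, used to contrast GC
   of recombining vs non-recombining genes — the footprint expected under
   GC-biased gene conversion.
3. **Restriction-site flanks** (`flank_*` functions, `run_flanks()`): GC
   enrichment in the bases flanking AT-rich restriction-enzyme recognition
   sites (sites of potential self-inflicted DSBs), against a
   permuted-motif null.
4. **Phylogenetic regression** (`fit_pgls()`, `run_regression()`): logit GC
   content regressed on Ku presence, log10 genome length and their
   interaction under Brownian-motion (BM) or Ornstein-Uhlenbeck (OU)
   covariance with a measurement-error term.

The package consumes standard formats (FASTA alignments via Biostrings,
Newick trees via ape, TSV tables) and emits tibbles throughout.

## Polymorphism polarization and equilibrium GC

Within a cluster of closely related genomes sharing ortholog alignments,
every genome serves once as the *focal* genome; its *nearest* neighbour
(maximal identity over the concatenated core alignment) supplies the
polymorphism contrast and the most diverged cluster member *polarizes* it:
where focal and nearest disagree and the outgroup matches the nearest, the
focal allele is derived. Counting derived AT→GC changes (`n_at_to_gc`) over
surveyed ancestral-AT columns and GC→AT changes over ancestral-GC columns
gives per-site rates `v` and `u`, the bias ratio `m = u/v`, and the
equilibrium GC content `v/(u+v) = 1/(1+m)` expected under mutation alone.

Filters follow the printed analysis settings: focal genomes whose best
match is more than 1% diverged are dropped (`identity >= 0.99`, boundary
inclusive), as are focal rows with fewer than 5 informative changes
(`n_informative >= 5` kept). Columns with a gap or ambiguity in any triplet
member are excluded from numerators and denominators alike, keeping the
two in the same universe.

**Denominator choice.** Per-site rates need a denominator. The default
counts only *outgroup-consistent* columns (outgroup equals nearest — the
columns where a focal event is detectable), split by ancestral class. A
`denominator = "all"` toggle instead counts every surveyed column, classed
by the outgroup base. The consistent version makes the estimator exactly
unbiased under the package's own generator and is the default.

A fourfold-degenerate variant (`fourfold_restrict()`) surveys only third
codon positions of fourfold codon families, read off the outgroup sequence
in frame, yielding a composition measure shielded from amino-acid-level
selection; it typically retains about a third of the informative changes.

**Known direction of bias on real data.** Polymorphisms in alignable coding
sequence have often already felt selection, which drags expected GC toward
the genomic background — a false-negative direction for detecting
GC-favouring fixation, not a false-positive one.

## The PHI recombination test

For each gene alignment the parsimony-informative columns are retained and
every pair of nearby columns is scored by *refined incompatibility*: the
cycle rank $E - V + C$ of the bipartite graph whose vertices are the
observed states of the two columns and whose edges the observed state
combinations. The score is the minimum number of extra changes the pair
forces on any single tree (zero iff compatible; for binary states this is
the four-gamete test), which the test suite verifies against an exhaustive
parsimony search over all tree topologies on small cases.

The PHI statistic is the mean incompatibility over pairs of informative
sites at most `window` sites apart (default 100, in informative-site
units). Recombination makes *nearby* sites more mutually compatible than
distant ones, so low observed PHI relative to a random re-ordering of the
sites signals recombination: the permutation test draws `n_perm` uniform
orderings and reports the one-sided add-one estimate
$p = (1 + \#\{\phi_{perm} \le \phi_{obs}\})/(n_{perm}+1)$, with floor
$1/(n_{perm}+1)$. Genes with fewer than two informative sites (or no
eligible pair) are excluded and logged. Because sites are exchangeable
under the no-recombination null, the test is exact; the acceptance suite
confirms nominal type-I error over 1,000 tree-simulated genes.

Calls across all cluster–gene pairs are corrected jointly by
Benjamini–Hochberg at FDR 0.05 (both defaults configurable; published
analyses of this kind use 10,000 permutations — the package defaults to
1,000 and the t-statistics of the downstream contrast are insensitive to
this). The GC contrast then compares, per cluster, mean GC of recombining
vs non-recombining genes (paired t-test across clusters) and contrasts the
per-cluster difference between Ku-encoding clusters (any member with Ku)
and Ku-lacking clusters (Welch t-test).

## Restriction-site flank analysis

Recognition sequences are expanded over the IUPAC alphabet and mapped to
both strands (palindromes counted once per position); AT-rich motifs are
those with expected AT fraction ≥ 0.75 (boundary inclusive; ambiguity codes
contribute their expected fraction). For each distance 1–200 bp the mean
G/C indicator over all sites and both flanks is computed; circular genomes
wrap, linear contigs truncate, and flanks overlapping another site are kept
(a DSB at a site is strand- and neighbour-agnostic). The null profile uses
a uniformly drawn permutation of the motif's letters, redrawn until it
differs from the original, preserving base composition exactly. The
per-genome observed-minus-null difference (each genome weighted equally) is
bootstrapped across genomes (default 1,000 resamples, percentile 95% CI)
per distance. One permuted motif per genome mirrors the original analysis;
`n_null` can be raised to shrink null variance.

## Phylogenetic regression

GC content is logit transformed, $GC_l = \log(\%GC/(1-\%GC))$, making a
bounded trait usable with Gaussian trait models, and modelled as

$$ y = X\beta + \varepsilon,\qquad
   \varepsilon \sim N(0,\; \sigma_p^2 V + \sigma_e^2 I), $$

with design columns intercept, Ku (binary), log10 genome length and the
Ku×length interaction. $V$ is the BM covariance (shared root-to-MRCA path
lengths) or the stationary OU kernel
$e^{-\alpha d_{ij}}/(2\alpha)$ on tip-to-tip distances.

Fitting is by maximum likelihood — ML rather than REML because AICs are
compared across covariance models — with the mixture reparameterized as
$\Sigma = s\,[wV + (1-w)I]$, $w \in [0,1]$: for fixed $w$ the GLS estimate
of $\beta$ and the profile scale $\hat s$ are closed-form, so the ML fit is
a one-dimensional optimization (plus a log-grid-then-refine search over
$\alpha$ for OU, which avoids ridge pathologies). Both variance components
are bounded below at zero; the $\sigma_e^2$ term acts like a Pagel's-λ
attenuation, and the test suite checks agreement with an independent
Pagel-λ GLS fit. Coefficient p-values use t statistics on $n - p$ degrees
of freedom (software commonly reports asymptotic z values; at thousands of
taxa the difference is negligible). AIC is $2k - 2\ell$ with $k$ counting
$\beta$, both variance components, and $\alpha$ when estimated.

The GC4 response is offered both untransformed (`response = "gc4"`) and
logit transformed (`"gc4_logit"`); coefficient scales differ markedly
between the two, so reports state which was used. The uniform-Ku filter
(genera with ≥ 2 genomes, all sharing one Ku state) guards against frequent
horizontal transfer of the NHEJ operon confounding the regression, and
`ku_gc_correlation()` provides the simple point-biserial Ku–GC correlation.

## Synthetic data: what it emulates and what it does not

All generators are seeded, return a truth ledger sufficient to recompute
every expected estimate, and are deterministic given the seed.

**Triplet clusters** (`gen_triplet_cluster()`). An i.i.d. ancestor at GC
`gc0` evolves into focal/nearest/outgroup lineages under a two-class
substitution process whose per-site GC→AT : AT→GC rate ratio is `m`; 5% of
each branch's divergence is planted as within-class (A↔T, G↔C) changes to
exercise the non-informative code path. Events follow an infinite-sites
design: at most one change per column across the triplet, with each
branch's event probability defined per column untouched by the other
branches (outgroup → nearest → focal cascade). This makes the ledger
predict every polarized count exactly and the bias estimator's target
exactly identifiable, so parameter-recovery experiments measure estimator
behaviour, not homoplasy. Real triplets at 5% outgroup divergence *do*
contain homoplasy — parallel changes on the nearest and outgroup branches
masquerade as focal events and, with strong AT-biased mutation, can
deflate $\hat m$ appreciably — so passing recovery tests here demonstrates
correctness of the estimator, not absence of that biological bias.
Divergences default to 0.5% (focal–nearest) and 5% (outgroup), the regime
the cluster resources provide.

**Trees and traits** (`gen_tree_traits()`). Pure-birth trees scaled to unit
height; Ku as a two-state Markov chain with stationary frequency
`ku_prevalence` (transition rates $q_{01} = r\,\pi$, $q_{10} = r(1-\pi)$ —
a symmetric chain cannot hold a 0.3 prevalence at stationarity); log10
genome length by BM around 6.5 (≈ 3 Mb); the response drawn exactly from
the regression model above. Default scales were fixed by a power analysis carried out while designing the 20-replicate × 500-tip recovery experiment: the Ku
and interaction columns are nearly collinear at log10 length ≈ 6.5, so
recovering a Ku coefficient of ~1.3 to within 10% requires
`sigma_length = 0.35` (genome lengths ~0.5–16 Mb at 2σ), a labile Ku
(`ku_rate = 20` switches per unit height — consistent with NHEJ moving
horizontally), and residual variances `sigma_p2 = 0.04`, `sigma_e2 = 0.01`
(phylogenetic heritability 0.8, residual logit-GC SD ≈ 0.22). Genus labels
for the uniform-Ku filter come from average-linkage clustering of patristic
distances.

**Gene alignments** (`gen_gene_alignments()`). Non-recombinant genes evolve
all sites on one tree; recombinant genes are left/right mosaics of two
independently drawn (hence discordant) topologies over the same taxa, with
an optional additive GC shift for recombinant genes. The F81-style site
simulator draws replacement bases from the stationary frequencies.

**Motif genomes** (`gen_genome_with_motifs()`). I.i.d. background at a set
GC, guaranteed free of spurious motif matches by redrawing offending
windows (a deliberate deviation from nature that makes site counts exact);
non-overlapping motif instances planted at well-separated positions with
flanking bases written per a supplied per-distance GC profile out to 200 bp.

None of the generators model operon structure, strand skew, repeats,
indels, rate heterogeneity beyond the two-class scheme, or
restriction-enzyme methylation sensitivity; conclusions about those
features cannot be drawn from the simulations passing.

## Numerical and design choices

- Coordinates are 0-based half-open internally; conversion happens only at
  I/O boundaries (FASTA/BED-style output).
- GC counts exclude ambiguity codes from numerator and denominator, so
  N-runs in draft genomes cannot tilt composition.
- The standard genetic code is the default for fourfold-site detection;
  the code table is configurable for taxa with variant codes.
- Ties in nearest/outgroup identity break lexicographically by genome id,
  for determinism.
- The permutation p-value uses the add-one estimator (never exactly zero).
- `optimize()` on $w \in [0,1]$ is supplemented by explicit boundary
  evaluation, since interior searches can miss $\hat w \in \{0, 1\}$
  (pure-error and pure-phylogenetic fits).
- Degenerate inputs are flagged rather than silently dropped: zero
  AT→GC events give `expected_gc = 0` with `bias_flag = "no_at_to_gc"`;
  a single-genome flank bootstrap degenerates to its point estimate with a
  message; singular regression designs raise an error naming the constant
  column.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the Monte-Carlo error of each experiment is
comfortably below the tolerance it is judged against: 20 clusters × 20 kb
for bias recovery (pooled counts across retained focal rows; a mean of
per-replicate ratios would be upward-biased at these event counts), 500
CDSs for composition recovery, 20 replicates × 500 tips for regression
recovery, 1,000 genes × 1,000 permutations for the PHI type-I check, and
8-genome cohorts for the flank bootstrap calibration. The headline analyses
of the motivating study (10^5 genomes, 4 × 10^5 cluster–gene pairs) require
bulk public-database downloads and are out of scope here.
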