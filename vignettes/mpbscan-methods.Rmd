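---
title: "Methods: the mPBS selection scan and its coalescent null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mPBS selection scan and its coalescent null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

mpbscan targets a recurring situation in conservation and population
genomics: a handful of populations (here, tiger subspecies are the
motivating case) that diverged *recently* from a large shared
metapopulation, each through its own founder events and bottlenecks, with
weak continued immigration. Under that history, genetic drift alone
produces strong, heterogeneous differentiation, so a credible scan for
selection must ask not "which windows are extreme?" but "which windows are
more extreme than this demography already predicts?". The package
implements the whole chain needed to pose that question on a multi-sample
VCF: genotype filtering, windowed differentiation, a four-population
branch statistic, a structured-coalescent simulator for the neutral null,
SFS-based demographic fitting, runs-of-homozygosity accounting, and
candidate-gene enrichment.

# The statistic

For two populations, Hudson's FST estimator is computed per site as a
numerator/denominator pair,

$$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad \hat D = p_1(1-p_2) + p_2(1-p_1),$$

and a window's estimate is the **ratio of sums** $\sum \hat N / \sum \hat
D$ over its usable sites, never a mean of per-site ratios (the two differ,
and the ratio-of-sums form is the stable one; a test asserts the
difference on a two-site example). Sites monomorphic across the pair
contribute 0/0 and are skipped; negative window estimates are legal.

Each pairwise FST becomes a branch time via $T = -\log(1 - F_{ST})$,
interpretable as divergence in drift units. Negative estimates are clamped
to zero first — otherwise $T < 0$ and the branch-length reading fails —
and $F_{ST} = 1$ propagates as missing rather than infinite.

With four populations $a, b, c, d$ the **metapopulation branch statistic**
for focal $a$ is

$$\mathrm{mPBS}_a = \frac{2(T_{ab}+T_{ac}+T_{ad}) - (T_{bc}+T_{bd}+T_{cd})}{6},$$

which is exactly the mean of the three classic three-population PBS values
over the three choices of non-focal pair. We implement this symmetric form
deliberately: a literal reading of the usual rendered expression
($2T_{ab}+T_{ac}+T_{ad}-\ldots$) is asymmetric in $b$ versus $c,d$, which
contradicts the statistic's meaning as the focal terminal branch length
and fails the additivity check (on a star tree with terminal branches
$b_i$ and $T_{ij} = b_i + b_j$, the symmetric form returns $b_a$ exactly;
a brute-force test verifies equality with the PBS-triplet mean to 1e-12).
The literal variant stays available behind `mpbs(..., literal = TRUE)` for
comparison. mPBS assumes each population diverged independently from the
metapopulation with negligible subsequent migration; under selection in
one lineage the focal terminal branch lengthens and the statistic grows.

Windows are 50 kb sliding by 10 kb by default (0-based half-open
internally; VCF I/O converts at the boundary). A terminal partial window
is emitted only when it covers bases no full window reaches, which keeps
every base covered and reproduces the natural window counts (a 1-Mb
scaffold gives 96 full windows). Windows with fewer than `min_sites = 10`
usable sites per pair are reported missing, not zero. Outliers are the top
`top_fraction = 0.001` of non-missing windows per focal population, ties
at the threshold included.

# The simulator and its null

The null distribution comes from a structured-coalescent simulator written
for exactly the demography the scan assumes: islands with effective
diploid sizes $N_i$, backward migration into a parent metapopulation at
rate $m_i$ per lineage per generation, wholesale merger at the divergence
time, bottlenecks as epochs of constant reduced size (so an epoch's
intensity is the usual $t/2N$), and nested metapopulation levels for
two-stage models. Between demographic events, lineages coalesce within a
deme at rate $k(k-1)/2 \cdot 1/(2N)$; waiting times are exponential;
mutations fall on branches as a Poisson process with rate $\mu \times
\text{branch length} \times L$ under infinite sites on an integer grid
(collisions redrawn). Everything is deterministic given a seed, and
per-window seeds derive from a master seed by a counter scheme, so window
$i$ of a batch never depends on the batch size.

Two calibration identities anchor the implementation: $E[T_2] = 2N$
generations for a pair of lineages in one deme, and Watterson's $E[S] =
4N\mu L \sum_{i<n} 1/i$. Both are asserted at 2,000 replicates (±5% and
±10%).

**Independent oracle.** Because the simulator is the package's scientific
core, it is validated against a genuinely independent process: a forward,
discrete-generation Wright–Fisher simulation of the same demography
(burn-in of the root deme to mutation–drift equilibrium, explicit
generation-by-generation parent choice, forward mutation events). The two
implementations share no sampling machinery, and their means of
segregating sites and of two-deme Hudson FST agree within two standard
errors at 500 replicates. The oracle refuses deme sizes above 500 or event
times beyond 5,000 generations — forward simulation at larger scale is not
its job. A small systematic gap of order $k^2/N$ between the discrete and
continuous-time models is visible at $N = 100$ (about 3% on segregating
sites) and sits well inside the test bands.

**Recombination.** The coalescent itself draws one genealogy per window
(`n_recomb_blocks = 1`), the conservative choice that the closed-form
checks require. Where a window should behave like real data — whose 50-kb
windows are far from single genealogies (population-scaled recombination
$\rho = 4Nr L \approx 40$ at $N = 2\times 10^4$, $r = 10^{-8}$/bp) — an
independent-blocks approximation is available: the window is the
concatenation of `n_recomb_blocks` independently simulated equal-length
blocks. This ignores linkage *between* blocks and enforces free
recombination at block boundaries; it is an approximation to an ancestral
recombination graph, not a replacement, and it is used only where stated.

# The bundled demographic model

`default_tiger_model()` encodes the stage-1 continent–island topology:
four subspecies (SUM, BEN, MAL, AMU; 3/3/4/3 diploids sampled, the
high-coverage demographic subset) diverging from a 20,000-diploid Asian
metapopulation 1,500–1,840 generations ago (the published 7,500–9,200-year
range at 5 years per generation), founder-effect epochs at divergence for
SUM and BEN only, strong recent contractions for SUM and AMU only, an
ancient metapopulation bottleneck around 46,800 generations (~234 kya),
mutation rate 0.35e-8 per site per generation, and immigration of
4e-5 per lineage per generation (below one migrant per generation for
every deme). Divergence times, the event structure, and the rate/time
conventions follow the published point estimates; the sizes and migration
rate are *illustrative desk-scale values chosen once* so that windowed
Hudson FST spans roughly 0.10 (BEN–MAL, the least differentiated pair) to
0.30 (AMU–SUM, the most), bracketing the published genome-wide range, with
AMU and SUM the most drifted lineages. The full published parameter vector
lives in a supplement that this package does not reproduce; nothing
downstream depends on these particular sizes beyond that regime.

# The synthetic-data generator

`generate_fixture()` builds a complete dataset — VCF, scaffold table,
population map, gene annotation (BED), GO-style term map, and a
ground-truth manifest — by simulating consecutive 50-kb loci under the
model and concatenating them into scaffolds. Its defaults are the study
conditions the package's end-to-end checks run under, and each was chosen
once, for a stated reason:

* **Genome size 4 × 50 Mb.** About 20,000 sliding windows, so the
  top-0.1% outlier set (k = 20) has room for the injected loci *and* the
  sliding windows that partially overlap them. Sliding windows are
  correlated: a strong locus elevates up to nine overlapping windows, and
  with only ten slots the neighbors of strong loci can crowd out a weaker
  locus's peak even when every injected peak exceeds every neutral window.
* **`n_recomb_blocks = 40`** (1.25-kb blocks), the realistic linkage scale
  for 50-kb windows given $\rho \approx 40$; fully linked windows make
  windowed FST so noisy that the neutral tail swallows any plausible
  injected signal.
* **`injection_factor = 0.02`.** Selection is emulated demographically:
  inside injected windows the focal population's diploid size is
  multiplied by this factor, giving a post-divergence drift intensity
  $t/2N \approx 12$ — essentially certain local fixation, the footprint of
  a completed hard sweep (zero within-population diversity at the swept
  locus). Injected windows remain valid coalescent samples; no allele
  frequencies are forced.
* **Annotation** places ~5 genes/Mb uniformly and guarantees one gene
  centred in every injected window, so enrichment ground truth is always
  scoreable; the designated term `GO:SIM0001` tags the injected-window
  genes plus ~1% of the background.

What the generator does *not* emulate: genotyping error and depth
variation (DP/GQ fields are absent from simulated VCFs; the filter code
paths are exercised on constructed fixtures instead), linked selection,
mutation-type composition and biased gene conversion, and linkage between
blocks. Passing end-to-end tests therefore demonstrate that the pipeline
recovers demographically injected drift excess under its own model
assumptions — not that it is robust to artifacts real resequencing data
carry.

`score_recovery()` scores an outlier set against the manifest by interval
overlap: an injected locus counts as recovered when any outlier window
overlaps it. With sliding windows this is the meaningful recall (the exact
50-kb tile and its 10-kb-shifted neighbors carry the same signal).

# SFS fitting

The folded joint SFS identifies cell $(d_1,\dots,d_k)$ with its complement
$(n_1-d_1,\dots,n_k-d_k)$, keeping the representative with the smaller
total (ties broken lexicographically); folding is exactly invariant under
allele relabeling, asserted by test. Expected cell probabilities are
Monte-Carlo estimates from simulated windows; empty cells are floored at
$\varepsilon = 1/(10\,n_{\text{replicates}})$ and the vector renormalized
— the standard stabilization for simulation-based composite likelihoods.
The composite log-likelihood is the multinomial $\sum_i m_i \log p_i$ over
polymorphic cells, treating sites as independent.

`fit_parameters()` maximizes this objective with common random numbers
(the same simulation seed at every evaluation, making the surface
deterministic and the fit reproducible): golden-section search for one
free parameter, Nelder–Mead with five seeded restarts and bound penalties
for several. Estimates at a search bound are flagged. The two-stage
protocol — fit a stage-1 model, freeze it, fit the additional parameters of
a model with a nested regional metapopulation — is supported through the
parameter-address mechanism (`"populations.BEN.divergence_time"` and the
like). Monte-Carlo precision is the practical constraint: contrasts of a
few composite-likelihood units need enough replicates per evaluation
(2,000 at the scales used in the tests) to sit above the simulation noise;
the desk-scale recovery experiment (150 observed 20-kb windows, ~2,500
SNPs, 1,000 replicates per evaluation, bounds [100, 1500] on a true
divergence time of 500) recovers the parameter with ~14% median relative
error over ten seeds. Singleton masking is available as a flag on the
observed side by dropping singleton cells before fitting. Publication-scale
optimizers and datasets of hundreds of thousands of SNPs are out of
scope; this is a transparent desk-scale stand-in with its own documented
protocol.

# Runs of homozygosity

The detector is a transparent sliding-window rule, not a hidden Markov
model: an interval of consecutive called sites qualifies when every
`window_sites = 50`-site sub-window contains at most `max_het_per_window
= 1` heterozygous calls; maximal qualifying intervals (merged where they
overlap, so segments are disjoint and detection is monotone in the het
limit) become segments spanning first to last supporting site, kept if at
least `min_length = 10` kb and `min_sites_per_run = 25` homozygous sites.
A brute-force enumeration over random toy genomes asserts exact agreement.
Absolute ROH calls are method-dependent — an HMM with allele-frequency
priors will call different segments — so cross-method comparisons should
stay within one caller.

Length-class proportions follow the subtraction-denominator convention:
the $\ge 1$ Mb proportion divides by the full autosome length $A$; the
100 kb–1 Mb proportion by $A$ minus the $\ge 1$ Mb total; the 10–100 kb
proportion by $A$ minus the $\ge 100$ kb total. Reporting additionally
splits $\ge 2$ Mb from 1–2 Mb and gives the $\ge 100$ kb total. The worked
example (A = 100 Mb; runs of 3 Mb, 500 kb, 50 kb) gives 0.03,
500k/97M ≈ 0.0051546 and 50k/96.5M ≈ 0.0005181, asserted exactly.

# Enrichment

Homolog deduplication groups overlapping same-strand records into
transitive clusters and keeps the first by coordinate order ("first" is
ambiguous between file order and coordinate order in the usual phrasing;
coordinate order is the deterministic choice). Genes become candidates
when their ±50-kb-flanked interval (clipped at scaffold bounds) intersects
any outlier window, half-open on both sides. Per term, a one-sided
Fisher's exact test (over-representation) on the 2×2 table is computed
against the post-filter gene list as background, with Benjamini–Hochberg
adjustment across tested terms; raw p-values are reported alongside. No
GO-hierarchy propagation is performed — the term map is taken as given —
which understates enrichment of parent terms; a documented limitation.

# Numerical and degenerate-input choices

* MAF is computed on non-missing alleles only; the filter order is fixed
  (genotype-level DP/GQ masking → site-level MAF, then missingness, then
  completeness → scaffold length) and filtering is idempotent.
* FST windows with zero summed denominator, or fewer than `min_sites`
  usable sites, are missing, and missingness propagates through T and mPBS
  rather than being replaced by zero.
* PCA (plink-style variance standardization by $\sqrt{2p(1-p)}$) refuses
  missing data unless mean imputation is explicitly requested, and errors
  on monomorphic-only input.
* The simulator rejects non-coalescing configurations (more than one root
  deme) at validation time and guards against runaway simulations with a
  generous absolute time cap.
* Infinite-sites collisions are redrawn; a window demanding more mutations
  than integer positions errors rather than silently violating the model.

# Problem sizes

The shipped tests and the acceptance script run everything at desk scale,
chosen as the package's own verification sizes: 2,000 replicates for
coalescent calibration; 500 + 500 replicates for oracle agreement; 250
observed versus 1,000 null windows for the KS self-consistency check; ten
seeds for the recovery experiment; and one 200-Mb fixture (4,000 simulated
loci) for the end-to-end scan. The null-distribution machinery supports
the full published scale (one million windows) — it is a seed-derived loop
— but defaults to $10^4$.

# Known limitations

* The independent-blocks recombination model has no linkage between
  blocks; statistics sensitive to long-range LD should not be computed on
  fixtures.
* The bundled model's sizes and migration rates are illustrative; the
  package fits parameters, it does not ship published estimates.
* mPBS inherits the no-post-divergence-migration assumption; with
  substantial gene flow the branch-time reading of $-\log(1-F_{ST})$
  degrades.
* Base-quality filtering happens at variant calling and cannot be
  re-applied from a VCF; `min_base_quality` is recorded for provenance
  only.
* The ROH detector's defaults are declared, not inferred from any external
  caller's supplement; compare proportions, not absolute calls, across
  methods.
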