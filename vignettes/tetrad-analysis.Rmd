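---
title: "Tetrad analysis of crossing over, interference, and the crossover threshold for viability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad analysis of crossing over, interference, and the crossover threshold for viability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

## The biological setting

Budding yeast meiosis produces four haploid spores held together as a
tetrad. Dissecting tetrads and genotyping each spore clone at a panel of
markers gives the most information-rich readout of meiotic recombination
available from classical genetics: for every pair of linked markers, each
tetrad falls into one of three classes — parental ditype (PD), tetratype
(TT), nonparental ditype (NPD) — whose frequencies encode both the
crossover rate and crossover interference. Aneuploidy leaves its own
fingerprints: a homolog pair that receives no crossover (a failure of the
*obligate crossover*) risks Meiosis I nondisjunction, which kills two or
four spores and, for chromosome III, produces viable disomic spores that
carry both mating types and therefore cannot mate ("non-maters").

`tetramap` implements the full analysis chain used to characterise
Msh4-Msh5 hypomorphs — mutants that titrate crossover numbers down toward
the viability threshold — together with a meiosis simulator that generates
dissection data with controllable interference, conversion, and
nondisjunction, so every estimator can be checked against ground truth.

## Estimators

### Perkins map distance and its standard error

For an interval with $n = PD + TT + NPD$ scorable tetrads,

$$\hat d = 100\,\frac{TT/2 + 3\,NPD}{n}\ \text{cM}.$$

The $3\,NPD$ term corrects for double crossovers: an NPD requires a
four-strand double exchange, and under no chromatid interference each NPD
implies two sibling double-crossover tetrads that were scored as PD or TT.
The estimator applies no mapping function; published yeast interval
distances are raw Perkins values, and the golden-fixture tests confirm that
every printed interval distance in the bundled tables is exactly the
rounded Perkins value of its PD/TT/NPD counts.

Treating $(TT, NPD)$ as multinomial and propagating through the estimator
(delta method) with $t = TT/n$, $v = NPD/n$:

$$SE(\hat d) = 100\sqrt{\frac{t(1-t)/4 + 9v(1-v) - 3tv}{n}}.$$

This is a *reconstruction* of the standard errors printed by the historical
web tools, whose generating algorithm was not published: the golden suite
verifies the named check rows exactly at one printed decimal and every
fixture row within 0.1 cM.

### Single-spore route

Counting each viable spore independently, $\hat d = 100\,\mathrm{rec}/\mathrm{total}$,
with a Wilson score interval (no continuity correction) on the recombinant
proportion. Wilson was chosen over Wald and Clopper-Pearson because it
reproduces the published confidence bounds; all 128 printed bounds agree
within 0.1 cM, and the named check rows round exactly. Fractional published
tallies (half-spores from ambiguous scoring) are accepted by the estimators
but never produced by the classifier, whose calls are integral by
construction.

### Aberrant-tetrad exclusion

A tetrad that segregates non-2:2 at *any* marker of a chromosome is
excluded from *all* intervals of that chromosome (not just the flanking
ones). The published per-chromosome interval totals are equal within every
strain (e.g. 556 for all three chromosome III intervals of the wild-type
data, 572 complete tetrads minus 16 aberrants), which per-interval
exclusion would not guarantee; the per-chromosome rule reproduces every
total exactly.

### Interference: coefficient of coincidence

For adjacent intervals with $R_i = TT_i + NPD_i$ crossover-containing
tetrads, the chance expectation of double-crossover (DCO) tetrads is
$R_1R_2/n$; a tetrad counts once as a DCO if it carries a detected exchange
in both intervals, whatever the mix of TT and NPD. COC = observed/expected;
the two-tailed p-value uses the normal approximation to
$\mathrm{Binomial}(n, \mathrm{exp}/n)$ *with* continuity correction —
verified against the published p-values (0.004 and 0.667 reproduce only
with the correction). Interference is called when $p < 0.05$ and COC < 1.

A calibration subtlety, measured by the acceptance suite: against its null
expectation the binomial test holds its nominal size (simulated type-I
error inside [0.03, 0.07] at $\alpha = 0.05$), but the full plug-in
procedure — expectation estimated from the same tetrads — is conservative
(type-I error well below nominal) because the observed DCO count and the
estimated expectation are positively correlated. This conservatism is a property of
the published method itself, not of this implementation; COC deficits
called significant are, if anything, understated.

### Interference: NPD ratio

Under a Poisson number $x$ of exchanges per bivalent in the interval and
uniform chromatid choice,

$$p_{TT} = \tfrac23\left(1 - e^{-3x/2}\right), \qquad
  p_{PD} - p_{NPD} = e^{-x},$$

with $p_{PD}+p_{TT}+p_{NPD}=1$; as $x \to \infty$ the classes approach
$1{:}4{:}1$ proportions ($\tfrac16,\tfrac23,\tfrac16$). These closed forms
are tested against a brute-force Monte-Carlo of one million simulated
meioses. Two routes give the expected NPD count under no interference:

* **Papazian** (moment fit): solve $p_{TT}(x) = TT/n$, giving
  $E[NPD] = \tfrac n2\left[(1-T) - (1-3T/2)^{2/3}\right]$; requires
  $T < 2/3$, the model's tetratype ceiling.
* **MLE**: maximise the multinomial log-likelihood of $(PD, TT, NPD)$ over
  $x$ by bounded scalar search on $[10^{-6}, 20]$ (relative tolerance
  $10^{-8}$, deterministic), then $E[NPD] = n\,p_{NPD}(\hat x)$.

Both report a 1-df chi-square goodness of fit of the three classes against
the fitted expectations. The algorithm behind the published expected-NPD
values was never described; the MLE route lands within a few percent of
every published value (e.g. 34.8 vs 33.4 for the wild-type TRP5-CYH2
interval), which is why those printed values are treated as corroboration,
not as golden numbers. The test suite instead validates both routes by
simulation: null ($m=0$) data give ratios near 1 and non-small p-values,
interfering data ($m=3$) are flagged in at least 90% of replicates.

### Exact tests

`fisher_exact_2x2()` sums hypergeometric point probabilities no larger than
the observed table's (relative tie tolerance $10^{-7}$), returning $p = 1$
for degenerate margins. It is verified against an independent
binomial-coefficient enumeration for every 2×2 table with all margins ≤ 30
(about 164,000 tables) and against `stats::fisher.test` spot checks.

## The simulator

`sim_params()` + `simulate_dataset()` emulate an SK1-style dissection
experiment: a handful of chromosomes, 4–11 markers, a few hundred tetrads.

* **Crossover placement.** Each bivalent receives crossovers at 2 per
  Morgan of genetic length (a crossover involves two of four chromatids, so
  interval length in cM equals percent recombinant spores). Interference
  follows the stationary counting (chi-square) model: precursor events are
  Poisson at $2(m+1)(1-f)$ per Morgan, every $(m+1)$-th matures into a
  crossover, and the phase is randomised so the process is stationary.
  $m=0$ reduces exactly to the Poisson null of the NPD-ratio model, giving
  a closed-form cross-check. A fraction $f$ of crossover activity runs
  through an interference-free Poisson pathway (the Mms4-Mus81-like
  component; roughly 20% on large chromosomes in published estimates, the
  default).
* **Chromatid choice.** Each crossover exchanges the distal segments of one
  chromatid of each *local parental identity*, chosen uniformly and
  independently (no chromatid interference). The centromere-group
  alternative — one chromatid from each centromere pair — has identical
  single-interval class probabilities but makes an exchange between two
  locally-identical chromatids genetically silent for the distal interval,
  which manifests as spurious negative coincidence (COC well below 1 in
  null data); the local-identity model is the classical one under which
  disjoint intervals are independent, and the Monte-Carlo oracle in the
  test suite deliberately retains the other mechanism as an independent
  route to the same single-interval law.
* **Gene conversion** overwrites one uniformly chosen chromatid's allele at
  a marker with probability `conversion_prob` per marker per meiosis
  (default 0.02, matching the ~0–5% per-marker aberrant segregation of
  wild-type-like strains), yielding 3:1/1:3 tetrads. Co-conversion tracts
  and post-meiotic segregation are not modelled — none were scorable in the
  source data.
* **Nondisjunction and death.** A bivalent with zero crossovers nondisjoins
  at Meiosis I with probability `ndj_prob_e0` (default 0.5: achiasmate
  homologs segregate essentially at random; the source study reports no
  direct rate, so this is an order-of-magnitude choice). Both homologs go
  to one pole: two sister spores become disomic, the other two nullisomic.
  Nullisomy is always lethal; disomy is lethal except where flagged viable
  (chromosome III by default — its disome is the non-mater). Dead spores
  carry `NONE` at every marker; viable disomes carry `BOTH` on the disomic
  chromosome, which is what makes the non-mater signature scorable.
* **Defaults.** The default marker map mirrors the classical panel on
  chromosomes III, VII, and VIII with interval sizes equal to the wild-type
  tetrad distances (13.8/6.1/14.9, 36.0/9.3/21.1, 21.5/24.7 cM) placed
  inside full chromosome lengths of 115/350/180 cM, so crossovers also form
  outside the marked region as in real meioses. Interference order defaults
  to $m = 3$, a mid-range value for budding yeast counting-model fits.
  `seed` drives a single generator; identical seeds give byte-identical
  output files.

### What the generator does and does not emulate

It reproduces: 2:2 segregation with low conversion rates, counting-model
interference (underdispersed crossover counts; zero-crossover bivalents
rarer than Poisson at equal length — the obligate-crossover protection),
PD:TT:NPD = 1:2:1 among two-exchange bivalents, chromosome-size-dependent
map structure, the excess of 0- and 2-spore-viable tetrads under strong
nondisjunction, and the non-mater sister-spore signature of chromosome III
nondisjunction. It does not emulate: DSB-level mechanics, crossover
homeostasis as an explicit feedback, locus-specific hot/cold spots,
spore death from causes other than aneuploidy, co-conversion, or ectopic
events. Passing tests therefore certify the estimators against this
idealised meiosis, not against every failure mode of real dissection data
(scoring errors, contaminated clones, disome mosaics).

## Numerical choices and degenerate inputs

* Report tables round half away from zero at one decimal only at
  serialisation; all internal values are full precision.
* `interval_tally()` accepts non-negative reals so published fractional
  tallies flow through the estimators; `n = 0` tallies raise errors rather
  than returning NaN.
* `coc_test()` clamps the two-tailed p to $[0, 1]$ (the continuity
  correction can push the naive value above 1 near obs = exp) and treats
  zero-expected with zero-observed as $p = 1$, COC undefined.
* `papazian_expected_npd()` refuses $T \ge 2/3$ (model infeasible); the MLE
  route has no such restriction because the likelihood remains well-defined.
* The MLE search interval $[10^{-6}, 20]$ spans map distances from
  essentially 0 to far beyond any real yeast interval (at $x = 20$ the
  class probabilities are at their asymptote to machine precision).

## Test problem sizes

The suite exercises the estimators at the scale of the real study: golden
checks on all 64 published interval rows; parameter recovery at $n = 2000$
tetrads for 5/10/20 cM intervals; SE calibration over 500 replicates of 300
tetrads; COC calibration over 2000 null replicates of 500 tetrads (two
10-cM intervals, ~16 expected DCOs each) and 200 interfering replicates of
700 tetrads; a $10^6$-meiosis Monte-Carlo per checked $x$; and the
exhaustive ≤30-margin Fisher sweep. These sizes were chosen to keep every
Monte-Carlo band at least three standard errors wide while matching the
sample sizes of real dissection experiments.

## Known limitations

* The NPD-ratio expectations for very short intervals (few expected NPDs)
  are unstable in both routes; the published analysis applied the test only
  where at least ~8 NPDs were expected, and that practice is recommended
  here (the report driver simply skips infeasible intervals).
* The plug-in COC test is conservative (see above); a randomisation test
  conditioning on the margins would calibrate it exactly but would no
  longer be the published procedure.
* Sister-spore inference relies on identity at centromere-linked markers
  and will misclassify a pair separated by a crossover between the
  centromere and the marker; with tightly linked centromere markers this
  error is small.
* The simulator's nondisjunction acts only on zero-crossover bivalents at
  Meiosis I; precocious sister separation and Meiosis II errors are out of
  scope.
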