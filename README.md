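# tetramap

Tetrad analysis of meiotic crossing over, crossover interference, and spore
viability in budding yeast, built around the question of how far crossing
over can fall before Meiosis I chromosome segregation fails. In
*Saccharomyces cerevisiae*, every homolog pair needs at least one crossover
(the *obligate crossover*) to disjoin at Meiosis I; hypomorphic alleles of
the pro-crossover complex Msh4-Msh5 titrate crossover levels down toward
that threshold, and dissection data (four genotyped spores per meiosis)
carry the full readout: map distances, interference, gene conversion,
nondisjunction, and spore death.

The package provides, as an integrated and tested chain:

* **Dissection-data model and I/O** — tab-separated tables with one row per
  spore clone, allele calls `P1`/`P2`/`BOTH`/`NONE` (`BOTH` encodes disomes,
  e.g. the chromosome-III disome that carries both mating types), per-marker
  segregation classification (2:2 vs 3:1/1:3/4:0/0:4 gene conversions), and
  aberrant-segregation rates.
* **Linkage estimation** — interval classification into parental ditype,
  tetratype and nonparental ditype (PD/TT/NPD), the Perkins map distance

  cM = 100 · (TT/2 + 3·NPD) / n,

  its multinomial delta-method standard error

  SE = 100 · sqrt[(t(1−t)/4 + 9v(1−v) − 3tv) / n],  t = TT/n, v = NPD/n,

  single-spore recombination frequencies (cM = 100 · rec/total) with Wilson
  score confidence intervals, and per-chromosome map sums. Tetrads aberrant
  at any marker of a chromosome are excluded from all intervals of that
  chromosome, which keeps per-chromosome interval totals equal.
* **Interference statistics** — the coefficient of coincidence
  COC = DCO_obs / DCO_exp with DCO_exp = R₁R₂/n (Rᵢ = TTᵢ + NPDᵢ) and a
  continuity-corrected two-tailed binomial test; and the NPD-ratio test
  (observed/expected NPDs) with the expectation computed either by
  Papazian's tetratype-moment formula or by maximum likelihood over the
  no-interference tetrad-class model
  p_TT = ⅔(1 − e^(−3x/2)), p_PD − p_NPD = e^(−x).
* **Strain statistics** — spore-viability profiles (tetrads by number of
  viable spores), the chromosome-III nondisjunction signature (non-mater,
  sister-spore two-spore tetrads), an exact Fisher 2×2 test, and the
  viability-versus-crossover threshold table.
* **A meiosis simulator** — counting-model (chi-square) crossover
  interference with order *m* plus an interference-free Poisson pathway,
  uniform chromatid choice (no chromatid interference), per-marker gene
  conversion, and Meiosis-I nondisjunction of zero-crossover bivalents with
  aneuploid spore death; it emits dissection tables in the same format the
  analysis side consumes, plus a ground-truth sidecar.

The printed count tables of the Msh4-Msh5 mutagenesis study (eight strains
of per-interval spore/tetrad tallies; the 57-allele viability/map survey;
observed double-crossover counts; published NPD-ratio rows) ship as plain
TSV fixtures (`load_fixture()`), so every published headline number can be
regenerated from raw counts.

## Worked example

```r
library(tetramap)

fx <- load_fixture("table2_nhy")

# wild-type HIS4-LEU2: PD=413, TT=141, NPD=2 complete tetrads
tal <- fx$tallies[["wild-type"]][["HIS4-LEU2"]]
perkins_distance(tal)   # 13.75899  -> printed as 13.8 cM
perkins_se(tal)         # 1.175609  -> printed as 1.2 cM

# the same interval from 2711 single spores (351 recombinant)
spore_rf(2360, 351)     # 12.94725  -> 12.9 cM
wilson_ci(351, 2711)    # 11.73573 14.26363 -> 11.7-14.3 cM

# crossover interference on chromosome VIII (CEN8-THR1 x THR1-CUP1):
dexp <- expected_dco(fx$tallies[["wild-type"]][["CEN8-THR1"]],
                     fx$tallies[["wild-type"]][["THR1-CUP1"]])  # 107.2138
coc_test(67, dexp, 538)
# <coc_result> obs=67 exp=107.2 COC=0.625 p=1.803e-05 (interference)

# simulate a wild-type-like dissection experiment and analyse it
d <- simulate_dataset(sim_params(n_tetrads = 700, seed = 101))
rep <- run_analysis(analysis_config(d))
sum(rep$map_table$cM_tetrad)  # ~143 cM over the 8 intervals (true: 147.4)
```

Interpretation: the Perkins estimator corrects two-strand double crossovers
through the NPD class, so its 13.8 cM agrees with the 12.9 cM single-spore
frequency on this short interval; a COC of 0.625 with p < 0.0001 means the
chromosome VIII interval pair shows strong positive crossover interference.

## Analysis workflow

The `analysis/` scripts are thin drivers over the package that regenerate
the study's result tables under `results/`:

1. `01_map_distances.R` — per-interval map table (both routes) and the
   chromosome-size-dependent crossover loss in the hypomorphs.
2. `02_interference.R` — COC and NPD-ratio interference tests for
   wild-type versus the `msh4-R676W` threshold allele.
3. `03_viability_threshold.R` — the 57-allele viability-vs-crossover
   threshold surface and the Msh4/Msh5 subunit-asymmetry Fisher tests.
4. `04_simulation_calibration.R` — simulator runs pushed through the same
   pipeline: map recovery, interference signal, and the nondisjunction
   spore-death phenotype.

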