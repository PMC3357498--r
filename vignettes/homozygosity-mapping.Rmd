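---
title: "Homozygosity mapping from population haplotype frequencies"
author: "rohmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping from population haplotype frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmap)
```

## The problem

A recessive mutation inherited twice from a recent common ancestor
(5–50 generations back) sits inside a run of homozygosity (ROH): a
stretch of SNPs at which the patient carries two copies of the same
haplotype. Long ROH, however, are common even in outbred genomes,
because common haplotypes meet by chance. Physical length alone
separates the two origins poorly. The quantity that does separate them
is the *population frequency of the entire homozygous haplotype* (HF):
a chance ROH is built from a haplotype that many people carry, while a
founder haplotype that has survived tens of generations of
recombination is rare. `rohmap` estimates HF from unrelated population
controls and turns it into genome-wide empirical significance, for
single patients, sharing patients, and affected sib pairs.

## Model

### Pairwise haplotype frequencies by EM

For each pair of adjacent SNPs, the four two-locus haplotype
frequencies are estimated from unphased control genotypes by an EM
algorithm ([emPairwiseHF()], [pairwiseHFTable()]). All genotype classes
except the double heterozygote contribute unambiguous haplotype counts;
the E step splits double heterozygotes between the cis and trans
configurations in proportion to the current frequency products. The EM
is initialized at linkage equilibrium, iterates to a tolerance of
`1e-8` on the largest absolute frequency change with a cap of 1000
iterations, and is deterministic — the two-locus likelihood is
well-behaved, so no random restarts are used. The per-pair sample size
`v` counts individuals non-missing at *both* markers (pairwise
complete).

### The rare-haplotype surrogate K

A haplotype transition observed in a patient but estimated at frequency
zero in controls cannot be scored by a frequency of 0. It is assigned
the surrogate `K` defined by a 95% probability of escaping observation
in the control sample: `(1 − K)^(2v) = 0.95`. Two conventions were
possible for the sample size — `v` haplotypes or `v` diploid
individuals (`2v` haplotypes). The package reads `v` as diploid
individuals, hence the exponent `2v`; the alternative is available via
the `nHaplotypes` argument of [rareHaplotypeK()]. After substituting
`K` for the zero cell, the remaining three frequencies of that pair are
rescaled by `(1 − K)` so the four frequencies still sum to one — the
substitution rule alone does not say this, but without renormalization
the pair is no longer a probability distribution. Both the substitution
and the rescaling are folded per cell into precomputed log lookup
tables, so a queried zero cell evaluates to
`K / (K + (1 − K) · rowRest)` and non-zero cells are untouched.

### The region chain

The frequency of the whole homozygous haplotype `g1 … gn` is the
first-order Markov chain

$$HF = P(g_1)\prod_{i=2}^{n} \frac{P(g_{i-1},g_i)}{P(g_{i-1})},$$

with `P(g_{i-1})` taken as the row marginal of the same pair table, so
each factor is at most 1 and extending a region can only decrease HF.
All products are log sums; the linear-scale HF of a long region
underflows to zero routinely and harmlessly — every comparison runs on
the −log10 scale. Heterozygous exceptions and missing genotypes inside
a region (allowed by the run-calling budgets) carry no homozygous
allele; the chain bridges them by marginalizing over the unobserved
allele (a product of the raw conditional matrices across the gap),
which can only increase HF relative to observing the alleles — a
conservative treatment. `HBC_s = HF²` is the chance that a single
patient carries the region homozygous.

### Sharing and sib pairs

When `N` of `T` patients are homozygous for the same allele sequence
over a consensus interval, the package evaluates the binomial upper
tail `HBC_m = P(X ≥ N)`, `X ~ Binomial(T, p)` with `p` a representative
per-patient `HF²`. This form is anchored by its reduction to
`HBC_m = HBC_s` at `N = T = 1` and reproduces the qualitative behaviour
that matters: sensitivity grows quickly with `N` and barely depends on
`T`. The representative `p` is the *maximum* carrier `HF²` over the
consensus interval (the conservative choice; a geometric-mean rule is
available), and the consensus interval itself is re-scored — not the
carriers' full runs. For affected sib pairs, each family contributes
the smaller `HF²` of its two siblings, and the final P-value is
multiplied by `(1/4)^N` because a sib pair shares both alleles IBD with
probability 1/4.

### Empirical significance

Analytic interpretation of `HBC` values across the genome is unsafe:
marker density and allele-frequency coverage vary, so equal `HBC`
values in different regions are not equally surprising. The package
therefore measures every region against a Monte-Carlo null built from
the controls themselves: for the single-patient mode, the best
(smallest `HF²`) region of each control genome; for the sharing modes,
per round, `T` random controls are drawn and the best `HBC_m` over
regions shared by `N` or fewer of them is recorded. The empirical
P-value uses an add-one pseudocount, `P = (1 + #{null ≥ stat})/(M+1)`,
so a finite null can never report `P = 0`.

Two rules deserve explanation:

* **Leave-one-out.** A patient's rare haplotype is absent from the EM
  training data; a control scored against a table trained *on itself*
  can never hit the `K` rule for its own haplotypes. That asymmetry
  makes control statistics systematically milder than case statistics
  and the empirical P anti-conservative. By default each control's
  best region is therefore scored against a leave-one-out table (its
  own genotypes removed, EM warm-started from the full fit), and a
  case individual that also appears in the control panel is removed
  from both the table and the null before being scored. Disable with
  `leaveOneOut = FALSE`.
* **Exclusion between rounds.** In the multi-patient null, the
  interval recorded in a round is masked in subsequent rounds
  (`exclusion = TRUE`). The alternative reading — no masking — is
  available via `--no-exclusion` / `exclusion = FALSE`; masking gives
  the more conservative null because a single extreme control region
  cannot dominate every round. The sib-pair null pairs random controls
  into pseudo-families; the `(1/4)^N` factor applies only to the real
  sib pairs (the pseudo-pairs are unrelated), i.e. to the case
  P-value, after ranking.

Seed handling: every Monte-Carlo routine takes a single integer seed
driving R's generator; null distributions record their seed and
bit-reproduce under it.

## Run calling

The contribution of the method is the statistic, not the run caller, so
the ROH scan is deliberately plain: a greedy left-to-right scan per
chromosome that extends a run until one more marker would exceed the
heterozygote or missing budget; boundaries are always homozygous
markers, runs never overlap. Defaults: `minSnps = 25` (the chain needs
at least two markers; 25 filters trivially short runs), `maxHet = 0`
(genotyping error is not modelled, so a heterozygote genuinely breaks
homozygosity), `maxMissing = 2`. All are configurable; relaxing a
budget can only extend coverage.

## The synthetic study population

All validation runs on synthetic data with known truth; nothing is
downloaded. Two generating processes are provided:

* **markov** — haplotypes drawn from a first-order Markov chain over
  the markers. This is the same model class as the statistic, so true
  pairwise and whole-region frequencies have closed forms; it is the
  oracle mode for unit tests.
* **pool** (default) — haplotypes are copying mosaics over a finite
  founder pool: donors are drawn from pool frequencies and switch as a
  Poisson process on the genetic map. This creates what the statistic
  actually has to cope with: genuinely rare long haplotypes (for the
  `K` rule), background ROH where two mosaics copy the same donor, and
  LD that is *not* first-order Markov — so passing tests in this mode
  is evidence beyond the model class.

The frozen study conditions, chosen once as a desk-scale analogue of a
dense SNP-array study: 5,000 markers, two chromosomes, 20 kb spacing at
a uniform 1 cM/Mb (50 SNPs/cM — of the order of, though sparser than,
a 600K genome-wide array), allele frequencies uniform on (0.05, 0.95),
adjacent-marker haplotype correlation 0.7, a founder pool of 200
haplotypes with Dirichlet(1) frequencies, donor-switch scale 5 cM, 100
controls. Founder tracts are planted by transmitting a pool haplotype
through `g` meioses per inheritance path (Poisson crossovers, each
generation conditioned on transmitting the focal allele — otherwise no
affected exists) and intersecting two independent paths; if the
intersection covers fewer than 25 markers the transmission is redrawn,
mirroring the conditioning on an affected who actually inherited a
homozygous region.

What this population does *not* emulate: genotyping error and strand
issues, demographic history (bottlenecks, admixture), variable
recombination and marker density along the genome, and case/control
ancestry mismatch. Passing the validation suite therefore shows the
statistic behaves correctly *under its own assumptions plus
out-of-model LD*, not that it is robust to array artefacts or
population stratification — on real data those enter through the
controls and the marker panel.

## Validation experiments (sizes used by the test suite)

* **Oracle equivalence** — the EM matches an iterative-refinement grid
  maximization of the two-locus likelihood on 50 random panels to
  1e-6; the region chain matches hand evaluation from counted phased
  tables, and collapses to the allele-frequency product on no-LD
  panels (1e-9).
* **Sharing tail** — `HBC_m` equals exhaustive enumeration over all
  `2^T` carrier patterns for every `T ≤ 12`, `N ≤ T`,
  `p ∈ {0.01, 0.1, 0.5}`, to 1e-12.
* **Null calibration** — 500 patients drawn from the same population
  as the 100 controls (no planted tract): empirical P-values are
  stochastically ≥ uniform (one-sided Kolmogorov–Smirnov at α = 0.01).
* **Planted-tract recovery** — 200 replicates per founder age
  `g ∈ {10, 30, 50}`: the planted region ranks first in the patient's
  genome in ≥ 90% of replicates at `g = 10`, with recovery declining
  monotonically in `g` (older founder alleles leave shorter tracts that
  background homozygosity increasingly matches).
* **Sharing sensitivity** — 100 replicates each of 2-of-10, 4-of-10
  and 4-of-50 carriers at `g = 30`: recovery grows with the number of
  carriers and is nearly unchanged by the total patient count.
* **Cousin IBD sharing** — 20,000 replicate pedigrees per
  configuration (see below).

## The cousin-sharing simulation and its closed-form check

For case–control applications one wants the chance that two apparently
unrelated patients share a segment IBD merely through a distant common
ancestral couple. [cousinSharingProbability()] simulates this directly:
each relative's lineage haplotype is a mosaic labelled by its
founder-haplotype origin, built from per-meiosis crossover telegraphs
(Poisson on genetic distance, no interference) over the 22 autosomes
with a bundled sex-averaged map (~35.5 Morgans); sharing means an
overlapping interval with the *same* founder-haplotype label in all
relatives.

The simulation is cross-checked against a closed form: relatives
separated by `m` meioses through `a = 2` common ancestors share on
average about `a (rm + c) / 2^(m-1)` segments (`r` the map length in
Morgans, `c = 22` chromosomes), so the sharing probability is
approximately `1 − exp(−E)`. For two 10th cousins (`m = 22`) this gives
about 7.6 × 10⁻⁴; the test suite verifies simulation and closed form
agree for 7th cousins, where Monte-Carlo error is small at test-scale
replicate counts. Sensitivity note: the probability scales nearly
linearly with the assumed total map length, so any comparison with
figures obtained under a different map or meiosis-counting convention
must state both.

## Numerical and degenerate-input policy

* All chain arithmetic in natural-log space; statistics compared on
  −log10(HBC); ties in ranking broken by the raw statistic.
* EM pairs with zero informative controls are an error (the table
  cannot cover the pair); non-convergence at the iteration cap returns
  the last iterate with a warning flag kept in the table.
* `findSharedRegions` treats missing genotypes and heterozygous
  exceptions inside a run as wildcards compatible with either allele;
  a wildcard individual can therefore appear in two overlapping
  carrier sets.
* Representative `p` values are clamped to the open interval (0, 1)
  before the binomial tail.
* PLINK text carries no allele order, so reading normalizes allele A
  to the first allele observed per marker; writing emits heterozygotes
  alleleA-first, making write→read the identity for any panel already
  in that coding (everything the simulators emit) and a per-marker
  dosage complement otherwise. Case/control panels are harmonized by
  marker id and position; swapped allele labels are flipped, apparent
  strand flips are excluded with a warning (never auto-resolved), and
  any other allele mismatch is an error.

## Limitations

The first-order chain underestimates the frequency of haplotypes with
long-range LD (it multiplies conditionals that cannot see beyond one
marker), which makes `HBC` conservative-leaning for regions in strong
extended LD but can overstate rarity where LD is long-ranged and the
control sample is small. `K` handles unseen transitions but not unseen
*combinations* of seen transitions. The empirical null inherits the
resolution of the control count (the smallest single-patient P with
`M` controls is `1/(M+1)`). Only sib pairs are supported among
relatives; general pedigrees are out of scope.
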