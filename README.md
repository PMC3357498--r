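# rohmap

Homozygosity mapping without pedigrees: **rohmap** decides whether a run
of homozygosity (ROH) in a patient's SNP genotypes is plausibly
*homozygosity by descent* (HBD) from a recent common founder — the
signature of a recessive disease mutation — or merely *homozygosity by
chance* (HBC) assembled from haplotypes that are common in the
population. It needs no family data: only genotypes of unaffected
controls from the same population. It is aimed at medical geneticists
mapping recessive Mendelian disease in singleton patients, small groups
of (possibly distantly related) patients, case–control panels, and
affected sib pairs.

## The statistic

For a homozygous region spanning SNPs `G1 … Gn` with homozygous alleles
`g1 … gn`, the population frequency of the entire haplotype is
evaluated with a first-order Markov chain over two-locus haplotype
frequencies estimated from controls:

```
HF = P(g1) * prod_{i=2..n} P(g_{i-1}, g_i) / P(g_{i-1})
```

* The pairwise frequencies `P(g_{i-1}, g_i)` are maximum-likelihood
  estimates from unphased control genotypes via an EM algorithm (only
  double heterozygotes carry phase ambiguity).
* A haplotype transition observed in the patient but never in the `v`
  controls is assigned the surrogate frequency `K` solving
  `(1 − K)^(2v) = 0.95` — the frequency at which it would escape
  observation with 95% probability.
* The chance of one patient being homozygous for the whole region is
  `HBC_s = HF²`; the chance that `N` of `T` patients share it is the
  binomial upper tail `HBC_m = P(X ≥ N)`, `X ~ Binomial(T, HF²)`.
* Genome-wide significance is empirical: the best (smallest-`HF²`)
  region in every control genome forms a Monte-Carlo null, and a
  region's P-value is its rank against that null (add-one
  pseudocount). Sib-pair analyses use the smaller sibling `HF²` per
  family and multiply the final P-value by `(1/4)^N`.

The package also contains the two simulators used for validation: a
founder-allele transmitter (Poisson crossovers, no interference; the
surviving founder segment around the focal locus after `g` meioses) and
an LD-structured synthetic population generator (first-order Markov
haplotypes, or copying mosaics over a finite founder pool) with known
truth.

## Worked example

Simulate a population (2,000 SNPs on two chromosomes, 1 cM/Mb), plant a
10-generation-old founder tract homozygous in one patient, and analyse
that patient against 60 controls:

```r
library(rohmap)
model <- populationModel(nMarkers = 2000, nChrom = 2, seed = 7)
study <- simulateStudy(model, nControls = 60, nCases = 1, nCarriers = 1,
                       g = 10, seed = 23)
res <- runAnalysis(list(mode = "single", cases = study$cases,
                        controls = study$controls, seed = 1))
as.data.frame(res$regions)[, c("seqnames", "start", "end", "nSnps",
                               "hf", "hbcS", "score", "empiricalP")]
#>   seqnames   start      end nSnps       hf      hbcS score empiricalP
#> 1        1 4820000 11740000   347 4.51e-54 2.04e-107   107     0.0164
```

The patient's one qualifying ROH (4.82–11.74 Mb on chromosome 1)
recovers the planted tract (4.86–11.74 Mb). Its haplotype frequency is
astronomically small (`HF ≈ 5e-54`, so `HBC_s ≈ 2e-107`): no common
haplotype explains a homozygous stretch of 347 SNPs, marking it as HBD
from a recent founder. The empirical P-value 0.0164 = 1/(60+1) says it
is more extreme than the best homozygous region of every one of the 60
control genomes — the resolution limit of a 60-control null.

A command-line front end with the same modes
(`single`/`multi`/`casecontrol`/`sibpair`/`simulate`) is installed at
`system.file("scripts", "rohmap.R", package = "rohmap")`.

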