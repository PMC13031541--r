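# KaryoCline

Detection, karyotyping and downstream analysis of polymorphic chromosomal
inversions from hard-called genotype data.

## The scientific problem

A polymorphic inversion suppresses recombination in heterokaryotypes, so its
two arrangements (here called **S** and **N**, for "south" and "north")
diverge and segregate like two alleles of a single locus. Three signatures
follow, and this package turns each into a tested, reusable computation:

1. **Local PCA trimodality.** A PCA restricted to the inverted interval
   splits individuals into three clusters along PC1 — the two homokaryotypes
   (SS, NN) flanking the heterokaryotypes (SN) — while PCA of the rest of
   the chromosome reflects ordinary population structure. Sliding 50-kb
   window PCA therefore localises the inversion; the SN cluster is also the
   most heterozygous, which anchors the cluster-to-karyotype mapping.
2. **Deep arrangement divergence.** Hudson's FST (ratio of averages,
   numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
   `p1(1-p2) + p2(1-p1)`) contrasts SS vs NN inside the interval against
   background differentiation; near-fixed coding SNPs that create or destroy
   a restriction site yield a cheap diagnostic **PCR-RFLP** assay, validated
   by in-silico digestion and marker-vs-PCA concordance. Haplotype
   relationships at the marker region are summarised by an ε = 0 minimum
   spanning network (the union of all minimum spanning trees).
3. **Clines and fitness.** Arrangement frequency `p = (2·SS + SN)/(2n)` is
   modelled along latitude or temperature by aggregated binomial regression
   `logit(p) = β0 + β1·x`, with a likelihood-ratio χ² (df = 1) and deviance
   R² = 1 − D_res/D_null; karyotype proportions are tested against
   Hardy–Weinberg by a plain χ² (df = 1). Egg-to-adult viability is fitted
   by a quadratic thermal performance curve `v(T) = aT² + bT + c`, from
   which rmax, Topt, CTmin/CTmax, tolerance and breadth follow in closed
   form, and analysed by binomial GLM with type-II likelihood-ratio tests.

A synthetic-data module generates genotype matrices, cline count tables,
marker regions and viability experiments with known truth, so the whole
chain is testable end to end without any external download.

## Worked example

```r
library(KaryoCline)

## simulate a two-continent dataset carrying a 400-kb inversion
cfg <- simulationConfig(seed = 7, dInv = 0.5)
sim <- simulateInversionDataset(cfg)
wp  <- windowPca(sim$genotypes)                      # 50-kb windows
rc  <- detectInversionRegion(wp, sim$genotypes)
rc
#> RegionCall: chr4:300001-700000
#>   qualifying windows: 8 of 20

kc <- assignKaryotypes(sim$genotypes, calledRegion(rc))
kc
#> KaryotypeCalls for 240 samples
#>  SS  SN  NN
#>  52 121  67
#>   cluster PC1 means: NN=-18.815, SN=1.251, SS=21.332
#>   confidence: ok

## differentiation between arrangements inside the inversion
kt  <- sim$truth$karyotype
fst <- windowedFst(sim$genotypes, names(kt)[kt == "SS"],
                   names(kt)[kt == "NN"], region = calledRegion(rc))
fst
#> FstResult A vs B: global FST = 0.7938 (667 sites, 16 windows)

## cline of arrangement frequency on the packaged European table
tab <- readLocationTable(system.file("extdata", "european_locations.tsv",
                                     package = "KaryoCline"))
fitBinomialCline(tab, "latitude")
#> ClineFit (logit link) on latitude:
#>   slope -0.1064 (SE 0.0113), LRT chisq 100.44 (df 1, p 1.22e-23), deviance R2 0.60
```

The called interval matches the simulated truth exactly, every karyotype
label is recovered, the between-arrangement FST (0.79) sits at the
configuration's analytic target (`targetArrangementFst(cfg)` = 0.79), and
the S-arrangement frequency falls by about 0.11 logits per degree of
latitude northwards — a strongly supported cline (χ² = 100.44, df = 1).

See the methods vignette (`vignettes/inversion-karyotyping.Rmd`) for the
models, defaults and design decisions.

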