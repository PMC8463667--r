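# mitomix

Quantification of mitochondrial augmentation: how much of a sample's
mitochondrial DNA — and of a cell's mitochondrial content — is exogenous
(donor-derived), plus digital-PCR copy number and deletion heteroplasmy.
Written for researchers analyzing mitochondrial transfer/augmentation
experiments in hematopoietic or other cell populations, and for anyone who
needs a validated, simulation-backed reference implementation of these
measurements.

## What it computes

**Percent exogenous mtDNA.** Donor and recipient mtDNA haplotypes differ at
informative SNPs. From aligned reads over the circular mtDNA reference
(rCRS-like, 16,569 bp), the package piles up each informative site and
averages the donor-allele frequencies:

    f̂ = (100 / K) Σₖ cₖ / nₖ   (%),    SEM = 100 · s / √K

with `cₖ/nₖ` the donor-allele frequency at SNP k (base quality ≥ 20,
mapping quality ≥ 20, depth ≥ 100; sites in deletions, homopolymers or
excluded regions are flagged and skipped).

**Digital PCR.** Poisson occupancy from positive partitions,
`λ = −ln(1 − n_pos/n_valid)`, gives copies/chip `λ·n_valid` and copies/ng;
deletion heteroplasmy from paired assays is
`h = 100·(1 − copies_FL / copies_total)`, where the full-length assay
targets a site inside the deletion and the total assay a site outside it.

**Exogenous mitochondrial content.** From per-cell two-channel fluorescence
(Dendra2 label on exogenous mitochondria, MitoTracker for total), the
channel gain is calibrated on fully-labeled control cells and the estimate
is 100 × the median per-cell ratio, with a bootstrap CI.

Each estimator has a matched simulator (`simulate_reads()`,
`simulate_dpcr()`, `simulate_dpcr_heteroplasmy()`,
`simulate_fluorescence()`) with known ground truth; the test suite
validates every estimator by parameter recovery. See the methods vignette
(`vignettes/mitomix-methods.Rmd`) for models, defaults and limitations.

## Worked example

Simulate augmentation of a deletion-carrying recipient (the hardest case:
a 4,978 bp deletion at 83.5% heteroplasmy) at a true exogenous fraction of
5.4%, then estimate it back:

```r
library(mitomix)

ref  <- make_reference(16569, seed = 1)
del  <- deletion_spec(8470, 13447, heteroplasmy = 0.835)
pair <- derive_haplotypes(ref, n_snps = 30, deletion = del, seed = 2)

cfg <- read_sim_config(coverage = 2500, mixture_fraction = 0.054, seed = 3)
sim <- simulate_reads(pair, cfg)
fit <- fit_mixture(sim, pair)
summary(fit)
#> Informative-SNP mixture estimate
#> Percent exogenous mtDNA: 5.537 +/- 0.08771 (SEM over 29 SNPs)
#> Mean depth at informative sites: 2505x
#> 95% CI (normal, across SNPs): [5.365, 5.709]
#> Excluded sites: 1 (flagged_site:1)
```

The estimate (5.54 ± 0.09%) brackets the simulated truth of 5.4%; one of
the 30 informative SNPs fell in a homopolymer run and was excluded. The
deletion does not bias the estimate because fragments are sampled in
proportion to molecule mass and deletion-interval sites are excluded.

Digital PCR on the same sample's deletion load:

```r
chips <- simulate_dpcr_heteroplasmy(1527, 0.835, ng_loaded = 6.55, seed = 4)
fl <- copies_per_ng(chips$full_length)
tt <- copies_per_ng(chips$total)
tt
#> <copy_number> total: lambda 0.5029, 1.006e+04 copies/chip, 1536 copies/ng (95% CI 1502-1570)
deletion_heteroplasmy(fl, tt)
#> Deletion heteroplasmy: 84.01% (full_length vs total)
```

And the fluorescence readout of exogenous mitochondrial content:

```r
panel <- simulate_fluorescence(n_cells = 500, exo_fraction = 0.084,
                               noise_cv = 0.3, seed = 5)
exo_mito_fraction(panel, seed = 6)
#> Exogenous mitochondrial content: 8.50% of total (95% CI 7.37-9.67)
#>   500 recipient cells, 50 calibration cells, gain 0.785
```

A thin command-line wrapper is provided at `exec/mitomix`
(`mitomix simulate|estimate|dpcr|recover ...`); `run_recovery_experiment()`
orchestrates multi-dose recovery studies and `write_report()` emits
JSON/TSV reports.

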