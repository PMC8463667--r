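---
title: "Measuring mitochondrial augmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mitochondrial augmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Mitochondrial augmentation loads cells ex vivo with exogenous, donor-derived
mitochondria. Because donor and recipient mtDNA haplotypes differ at a
handful of positions, the fraction of a sample's mtDNA that is exogenous is
measurable from sequencing data; absolute mtDNA copy number and
large-deletion load are measurable by digital PCR; and the exogenous share
of a cell's mitochondrial *content* (organelles, not genomes) is measurable
from two-channel fluorescence. `mitomix` implements these three estimators
and, because real augmentation experiments have no ground truth, a matched
set of simulators whose known truth lets every estimator be validated by
parameter recovery. This vignette describes the models, the defaults and why
they were chosen, and what the simulators do and do not capture.

## Percent exogenous mtDNA from informative SNPs

Let the donor and recipient haplotypes differ at K positions (informative
SNPs). At SNP k, a pileup over aligned reads gives a depth $n_k$ and a count
$c_k$ of bases matching the donor allele. The estimator is the unweighted
mean of per-site donor-allele frequencies,

$$\hat{f} = \frac{100}{K}\sum_{k=1}^{K} \frac{c_k}{n_k} \quad (\%),
\qquad \mathrm{SEM} = \frac{100\, s}{\sqrt{K}},$$

with $s$ the standard deviation of the per-site frequencies. Each variant
contributes equally regardless of its depth; a depth-weighted mean is
available behind `weight_by_depth = TRUE` but is not the default, because
with amplification-induced depth imbalance an unweighted mean keeps every
site's evidence on the same footing (and the per-site binomial noise at
2500x is negligible next to site-to-site scatter).

Site filters, all explicit and logged in the per-SNP table:

* **Base quality ≥ 20, mapping quality ≥ 20** (`min_baseq`, `min_mapq`).
  Upstream pipelines rarely publish these thresholds; 20 is the
  conventional 1%-error cutoff. The simulator emits Q30/MAPQ60 reads, so on
  synthetic data these filters are inert unless deliberately raised.
* **Depth ≥ 100** (`min_depth`): below ~100x the per-site binomial noise
  approaches the percentage points being measured.
* **Flagged sites** are discovered but excluded from the mean:
  sites inside a declared recipient deletion (template dosage differs
  between haplotypes there), sites inside homopolymer runs ≥ 5 bases on
  either haplotype (locally elevated sequencing error), and sites in
  user-supplied excluded intervals (a hypervariable control-region preset
  ships with the package but is off by default, since chimerism pipelines
  typically use every discriminating variant). `use_flagged = TRUE`
  restores flagged sites for sensitivity analyses.

**Error floor.** With a per-base substitution error rate $e$, a site with
true donor fraction $f$ is observed at $f(1-e) + (1-f)e/3$: errors from the
recipient base land on the donor base a third of the time. At the default
$e = 0.001$ this is an upward shift of at most 0.033 percentage points at
$f = 0$ and a downward shift of $100e = 0.1$ points at $f = 1$. The
estimator reports raw averages and documents the floor rather than
subtracting it — the shift is far below the biological effect sizes of
interest, and background subtraction would add an estimated, not measured,
quantity.

## The read simulator

`simulate_reads()` emits 2 x 150 bp pairs with truth-correct alignments —
no external aligner is involved, so the pileup can be checked against exact
per-read tallies. The design choices that matter:

* **Mass-proportional molecule sampling.** `mixture_fraction` and deletion
  heteroplasmy are *molecule-level* fractions. Fragments are drawn from the
  three molecule species (donor, full-length recipient, deletion-carrying
  recipient) with probability proportional to molecule fraction x molecule
  length, exactly as shotgun sequencing of a DNA mass does. This makes
  per-molecule per-site depth equal across species, so the donor-allele
  frequency at sites outside the deletion equals `mixture_fraction`. The
  alternative — drawing each fragment's species directly with probability
  equal to its molecule fraction — would concentrate the deleted molecules'
  reads on a shorter circle and inflate their per-site depth by
  L/(L−d) (~1.43 for the 4,978 bp deletion), biasing the estimate
  low by a fifth at high heteroplasmy. Measured allele frequencies in
  real data follow the mass model, so that is what the simulator does.
* **Read-pair count.** Pairs = coverage x effective length / (2 x read
  length), with effective length the mass-weighted mean molecule length
  (equal to the genome length when no deletion is present). Realized mean
  depth at retained sites then matches the coverage target.
* **Circularity.** Fragments may span the origin; such reads are split into
  two alignment records (the second flagged supplementary, hard-clipped),
  and reads crossing a deletion junction carry a `D` CIGAR operation.
  The pileup counts each fragment once per position, resolving
  mate or segment overlaps by base quality.
* **Errors.** Substitutions only, i.i.d. at `error_rate`, uniform over the
  other three bases; base qualities fixed at Q30. Indel errors, quality
  decay along the read, and GC bias are deliberately out of scope — they
  are orthogonal to allele-frequency estimation at isolated SNPs.
* **Amplification modes.** `rca_uniform` places fragments uniformly on the
  circle, emulating rolling-circle amplification. `pcr_two_amplicon`
  restricts placement to two configurable intervals (defaults split the
  circle into two overlapping halves; real long-range primer coordinates
  are not modeled) with a configurable per-amplicon depth ratio. Only the
  *structure* of PCR bias — restricted placement and depth imbalance — is
  modeled, which is what the estimator's robustness claim needs; the
  unweighted mean stays unbiased because SNP positions are placed
  independently of amplicon boundaries.
* **Insert geometry.** Fragment length is fixed at 2 x read length + 50
  (a 350 bp insert); insert-size variance adds nothing at isolated SNPs.

## Digital PCR

A chip partitions the template into ~20,000 chambers; with Poisson loading,
the occupancy implied by a positive fraction $p = n_{pos}/n_{valid}$ is
$\lambda = -\ln(1-p)$, giving copies/chip $= \lambda\, n_{valid}$ and
copies/ng after dividing by the loaded mass. A saturated chip
($p = 1$) has undefined $\lambda$ and errors out. The 95% CI is a Wilson
binomial interval on $p$ pushed through the same transform — the interval
the instrument software reports is not documented, so the method is named
in the output. Partition volume is not modeled: concentrations are
reported per chip and per ng only.

Deletion heteroplasmy uses paired assays: a *total* assay targeting a site
outside the deletion detects every molecule; a *full-length* assay
targeting a site inside it detects only non-deleted molecules. Then

$$h = 100\left(1 - \frac{\text{copies}_{FL}}{\text{copies}_{total}}\right)\ \%,$$

clamped to [0, 100] with a flag and warning when sampling noise puts the
full-length assay above the total (expected near $h = 0$); clamping is
preferred to erroring because the event is a routine noise outcome, and to
silent truncation because the flag preserves the evidence. The ratio makes
per-chip and per-ng normalization equivalent when both chips load equal
mass. Dual-probe (two-dye) chips are handled with an independent-target
approximation: double-positive partitions count in both channels.

The chip simulator draws the molecule count M ~ Poisson(concentration x
mass), scatters molecules uniformly over partitions, and records M as
ground truth. Finer partitioning converges on the *realized* M; the
residual gap to the nominal concentration is irreducible Poisson loading
noise (~1.8% relative at 3,000 molecules), which is why recovery checks
compare against M, and concentration recovery is asserted on means over
replicate chips.

## Exogenous mitochondrial content from fluorescence

Per recipient cell, a total-mitochondria stain (MitoTracker) and a label
carried only by exogenous mitochondria (Dendra2) are read as intensities.
The unknown relative channel gain g is calibrated as the median
Dendra2/MitoTracker ratio over fully-labeled control cells; each recipient
cell's exogenous fraction is then $(d_i/g)/m_i$ and the estimate is 100 x
the median across cells, with a percentile bootstrap CI (default 200
resamples). Medians are used throughout because both channels carry
multiplicative lognormal noise whose ratio has median exactly 1, making the
estimator median-consistent at any noise level — a mean-based estimator
would need a noise-dependent correction. At least 10 calibration and 10
recipient cells are required.

The panel simulator draws per-cell total signal lognormal (sdlog 0.6
around 1000 a.u., the order-of-magnitude spread typical of flow
intensities), channel gain 0.8, and independent lognormal channel noise
with configurable CV (mean 1). It does not model autofluorescence,
spectral bleed-through, label decay over time (the labeled fraction is
therefore a lower bound in real data), or segmentation error.

## Seeds and determinism

Every stochastic stage takes an explicit integer seed. Pipeline runs derive
per-stage, per-replicate seeds as a 32-bit FNV-1a hash of
`global_seed/stage/replicate` reduced into R's integer range
(`derive_seed()`), so stages have independent reproducible streams with no
hidden global state; the RNG state is saved and restored around every
simulator call. Reports serialize percentages at 4 significant digits for
stable diffs and echo the full configuration and its content hash.

## Validation scale and what passing shows

The test suite validates by parameter recovery at the study's own scale
where the claim depends on it — a 16,569 bp reference, 30 informative SNPs,
2500x coverage, 20 replicate seeds for mixture recovery (truth 0.625%,
5.4%, 14.5%); 20,000-partition chips for copy number (59.72 copies/ng) and
heteroplasmy (83.5%); 500-cell panels for fluorescence (8.4%) — and at
reduced scale (1–5 kb genomes, 40–800x) for structural properties:
pileup-vs-brute-force equality, boundary exactness at mixture fractions 0
and 1, binomial scatter, dose monotonicity, amplification-mode concordance,
and byte-level determinism. Passing these shows the estimators are correct
*under the generative models above*; real data add alignment artifacts,
NUMT contamination, indels, site-specific error, and instrument QC rules
that the simulators intentionally omit (externally aligned BAMs are
accepted, so those effects can be studied upstream).

## Known limitations

* Haplotype pairs differing by indels are rejected (`alignment required`);
  only substitution markers are supported.
* Variant calling is sidestepped: informative SNPs come from diffing known
  consensus haplotypes, not from calling on reads.
* The sequencing-error floor is documented, not subtracted; estimates at
  true fractions below ~0.1% are dominated by it.
* dPCR "valid partition" instrument QC is taken as input, not modeled.
* The fluorescence calibration assumes control cells are fully labeled;
  label dilution makes real estimates lower bounds.
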