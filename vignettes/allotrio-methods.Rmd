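---
title: "Methods: doubled-haploid genotype filtering, trio-based allotetraploid detection, and organelle rate comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doubled-haploid genotype filtering, trio-based allotetraploid detection, and organelle rate comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allotrio)
```

## The biological setting

Nori aquaculture lines of *Pyropia* are maintained as *cultures* grown from
a single blade; for genomics, a *doubled-haploid* culture is prepared from a
single monospore (one haploid cell), so its diploid conchocelis phase should
be **homozygous at every locus**. This package analyses multi-sample variant
calls (a merged VCF with `GT` and `GQ` fields) from panels of such cultures,
together with one sample of a closely related sister species and one
interspecific F1 hybrid. Three signals are of interest:

1. whether the hybrid is an **allotetraploid** (carries both full parental
   chromosome sets, and is therefore seen as heterozygous wherever its
   parents are fixed for different alleles);
2. **population structure** among the doubled haploids (clusters of nearly
   identical aquaculture lines, subgroups within one strain, and a
   phenotype-associated subgroup);
3. the relative **rates of evolution** of the chloroplast and mitochondrial
   genomes.

## Genotype model and filters

Genotypes are stored as allele dose (0 = hom-ref, 1 = het, 2 = hom-alt,
`NA` = missing), restricted to biallelic SNVs. Multiallelic records are
dropped rather than split: all downstream statistics assume two alleles,
per-site accounting stays comparable, and the drop is counted in the
provenance. Filters run in a fixed order whose exchange would change
results:

1. **GQ masking** (`min_gq`, default 20): calls below the threshold become
   missing. 20 is the conventional caller cut-off (1% error at face value).
2. **Site missingness** (`max_missing`, default 0.1): sites whose
   missing-call fraction exceeds the threshold are dropped, as in PLINK's
   `--geno 0.1`. At `max_missing = 1` nothing is dropped.
3. **Heterozygous-locus removal** (separate function): any locus
   heterozygous in a homozygosity-expected sample is discarded. A het call
   in a doubled haploid cannot be a genotype; it flags collapsed repeats or
   contaminating (e.g. bacterial) reads mis-mapped onto the reference.

Every filter returns a report whose counts reconcile exactly with the
matrix dimensions, mirroring the habit of reporting the surviving site
count at each step.

## The trio allotetraploidy test

Let A and B be the (homozygous) parents and H the hybrid. A locus is
**informative** when A is hom-ref and B is hom-alt, both non-missing. Only
this orientation is tabulated by default (the mirrored one is available by
swapping arguments); the one-sided condition also suppresses regions
mis-mapped in either parent, since a contaminated locus rarely passes both
homozygosity conditions at once. At informative loci the hybrid falls into
four classes: two-ref / het / two-alt / unclassified (missing), which
partition the informative set.

The **heterozygous fraction** is computed over classified loci only;
missing hybrid calls carry no evidence about ploidy. The verdict is
`het_fraction >= threshold` with `threshold = 0.8`: a true allotetraploid
sits near 1 (observed ~0.88-0.94 under realistic noise and with an
rRNA-homogenised region included), while recombinant or wrong-parent
scenarios produce large homozygous classes; 0.8 separates these regimes
with margin on both sides. Fewer than `min_classified = 100` loci yield an
`NA` verdict rather than a guess. With `threshold`-boundary ties the call
is positive (`>=` semantics, fixed).

**rRNA homogenisation.** After an interspecific cross the nuclear rRNA
repeat of one parent can be eliminated, so inside those regions the hybrid
is homozygous for the other parent's alleles. The classifier therefore
accepts an exclusion mask; run once with and once without it to see the
homogenised region as a coherent two-alt block (the simulator plants this
block on the 80-90% stretch of chromosome 1 by default).

## Identity-by-state and classical MDS

Per site, IBS similarity is `1 - |dose_i - dose_j| / 2`; the pairwise
distance is one minus its mean over sites non-missing in **both** samples
(pairwise deletion), which tolerates realistic missingness without whole-site
deletion. No LD pruning or sample reweighting is applied.

Ordination is classical (Torgerson) MDS implemented directly: double-centre
the squared distances, eigendecompose, build coordinates from the top-k
eigenpairs. Negative eigenvalues — expected, since IBS distances need not be
Euclidean — are truncated to zero and reported; no additive constant is
used. The implementation is cross-checked in the tests against
`stats::cmdscale` and against exact distance reconstruction at `k = n - 1`
(< 1e-8 for Euclidean inputs). Because coordinates are only defined up to
rotation/reflection, all tests compare reconstructed distances, never raw
axes.

The **hybrid-midpoint statistic** projects H onto the A-B segment:
`t = (H - A)·(B - A) / |B - A|²`, with an off-axis residual scaled by
`|B - A|`. An allotetraploid's dose is the parental mean at every
fixed-difference site, so `t` concentrates near 0.5; across 20 simulated
datasets at the default design it stays within [0.4, 0.6] (observed
~0.54-0.55 — within-species polymorphism shared between the hybrid and its
cluster-A parent shifts it slightly).

## Group-specific variant screen

A locus is a candidate when all non-missing cases share one genotype class,
that class occurs in zero non-missing controls, and the per-group missing
counts are within tolerances (defaults 0). All-missing cases never
nominate a locus. This is deliberately a *specificity* predicate, not an
association test: with a handful of cases, exact class sharing is the
published practice, and the missingness tolerances are exposed because
real data rarely allow zero missing calls. Candidate sets are monotone
non-decreasing in the tolerances (tested). The published screens added a
manual visual-inspection step that cannot be automated faithfully; instead
the result table carries the per-locus evidence (class, non-missing counts)
so a reviewer can apply their own triage. Simulated subgroup-planted
mutations are recovered with recall 1.0 at zero noise.

## Variable-site alignments and the organelle rate ratio

For phylogenetic export, sites with at least two genotype classes among
non-missing calls become alignment columns: ref base for hom-ref, alt base
for hom-alt, `N` for het or missing. Heterozygous calls are exported as `N`
rather than IUPAC codes because the intended sample sets are
homozygous-only and downstream tools treat `N` uniformly. A
parsimony-informative column has ≥ 2 states (ignoring `N`/gaps) each in
≥ 2 sequences.

The chloroplast-vs-mitochondrion comparison uses the **ratio of mean
pairwise distances**, restricted to sample pairs present in both
alignments, so both means cover identical pairs. Distances are mismatch
fractions over co-called columns, optionally Jukes-Cantor corrected
(`d = -3/4 log(1 - 4p/3)`). The correction matters: at a 10× ratio on top
of a chloroplast divergence of ~0.01 substitutions/site the mitochondrial
p-distances are already partially saturated, biasing the uncorrected ratio
downward by ~10%; JC69 restores the input ratio. This estimator is a
declared, reproducible surrogate for comparing tree branch lengths — the
published comparison was between trees, without a stated formula.

## The simulator

`simulate_truth()` generates the truth; `observe_vcf()` degrades it into a
VCF. Defaults are the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 50 kb | enough sites (~2,000 variants) for stable fractions at second-scale runtimes |
| clusters | 3 × 5 samples, FST 0.2 | three closed clusters of closely related aquaculture lines; Balding–Nichols is the standard FST-structured SNP model, ancestral frequencies U(0.1, 0.9) |
| admixed | 2 samples | per-site 50/50 ancestry from clusters 1-2, emulating admixed lines |
| sister species | divergence 0.01/site | gives ~1,000 fixed differences, the trio test's raw material |
| strain structure | cluster 1 split in 2 subgroups; 20 shared + 5 private flips/member | mirrors a strain observed to split into subgroups (7 + 5 samples) with one subgroup phenotype-associated; planted at sites otherwise monomorphic, so recall is well defined |
| rRNA mask | 10% of chr1 | a contiguous homogenised block large enough to be visible in class counts |
| organelles | 10 kb, cp 0.01 subst/site, mt:cp = 10 | the reported ~10× rate contrast; one shared Yule genealogy (unit mean root-to-tip depth) since organelles co-inherit; JC substitution via `phangorn::simSeq` |
| hybrid | parents = first strain sample + sister; organelles from the sister | uniparental organelle inheritance from the second parent, as observed; configurable |
| noise | error 0.002, missing 0.02, GQ U{30..99} / U{2..40} | caller-realistic defaults; an error replaces the call by a uniformly chosen *different* class, so P(het \| error on a homozygote) = 1/2, and erroneous calls draw low GQ so that a GQ < 20 filter removes 18/39 of them. The true error profile of any given caller is unknown; these are surfaced in `noise_model()` |

Determinism: the master seed spawns fixed-offset streams per stage
(genome/polymorphism, divergence, planting, organelles; observation takes
its own seed), so identical configuration + seed reproduce byte-identical
output, and each stage is independently reproducible.

**What the simulator does not emulate** — and hence what green tests do
*not* establish about real data: read-level artifacts and mapping bias,
indels and structural variants, bacterial contamination, linkage
disequilibrium (sites are drawn independently), organelle heteroplasmy, and
callers whose error profile differs from the uniform-replacement model.
Conclusions about a real call set still require the filters' reports and
the per-locus evidence tables to be inspected.

## Numerical choices and degenerate inputs

* Positions are 1-based inclusive everywhere a VCF position is meant; BED
  masks are 0-based half-open and converted on read.
* Half-calls (`./1`) and anything containing `.` in GT are missing; phased
  separators are accepted and treated as unphased.
* A pair with zero co-nonmissing sites is an error naming the pair (not a
  silent NA); zero variable sites yield a valid empty alignment with a
  warning; a zero chloroplast mean distance with positive mitochondrial
  distance reports an infinite ratio with a warning.
* `p >= 0.75` makes the JC69 transform infinite; it warns and propagates.
* Site order is preserved by every filter; exclude/restrict masking
  partitions the site set exactly.

## Problem sizes used in the tests

Simulation-backed checks run at the default design (19 samples, ~2,000
variant sites), with 20 seeds for distributional claims (hybrid midpoint,
divergence counts) and 200 random small matrices for oracle equality of the
trio classifier; organelle recovery uses 10 samples × 10 kb. These sizes
give stable statistics at a test-suite runtime of well under a minute per
module.

## Known limitations

* The trio test assumes both parents (or close relatives) are in the panel;
  a surrogate parent inflates the homozygous classes — which is itself
  informative (observed as ~10-12% two-ref in practice) but confounds exact
  interpretation.
* The specificity screen is not a statistical test and reports no error
  rates; with few cases, chance-specific loci occur and must be triaged on
  the exported evidence.
* The rate-ratio estimator equals branch-length-based estimates only under
  clock-like evolution on a shared genealogy; it is reported with its
  correction method for that reason.
* MDS on IBS distances is descriptive; no uncertainty is attached to
  coordinates or to the midpoint statistic.
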