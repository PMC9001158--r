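---
title: "Genomic composition and allele-depth dosage: how raddose infers water frog genomotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic composition and allele-depth dosage: how raddose infers water frog genomotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raddose)
library(dplyr)
```

## The biological setting

*Pelophylax* kl. *esculentus*, the edible frog, is a hybridogenetic
hybrid of the pool frog (*P. lessonae*, genome L) and the marsh frog
complex (*P. ridibundus* and relatives, genome R). In the germline of the
hybrid one parental genome is discarded and the other transmitted
clonally, which produces diploid LR and triploid LLR/LRR animals and
three recognisable population breeding systems: the L-E system (LR
persists by backcrossing with LL), the modified L-E system (LLR triploids
stacked on top of the L-E system) and all-hybrid E-E populations.
Monitoring therefore needs, per individual, not just a species label but
a *genomotype* — the count of L and R genome copies.

`raddose` infers genomotypes from ddRAD SNP matrices that carry
per-allele read depths, and classifies ponds from the genomotypes found
in them. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The inference model

### Diagnostic loci

A locus is *diagnostic* when one allele is fixed in the L genome and the
other in the R genome. Given reference panels from the two largest
clusters of an ordination — one panel expected to be the parental species
(homozygous everywhere diagnostic), one the diploid hybrid (heterozygous
everywhere diagnostic) — `identify_diagnostic_loci()` keeps loci where
every called reference of the first panel is homozygous *for the same
allele*, every called reference of the second is heterozygous, and each
panel has at most `max_missing_per_cluster = 3` missing calls. Which
cluster is the parental species is not known a priori;
`find_diagnostic_loci()` tries both orientations and keeps the one that
yields at least `min_diagnostic = 10` loci. Under the null (two panels of
the same species), a locus passing in either orientation requires ten
simultaneous genotype coincidences, so the two orientations are sharply
asymmetric in practice; both succeeding raises an error rather than a
silent guess.

### Genomic composition

For an individual, over its called diagnostic loci,
`composition_profile()` reports the fractions homozygous-L
(`p_homL`), homozygous-R (`p_homR`) and heterozygous (`p_het`), which sum
to one, plus the per-locus relative L-allele coverage
`rel_L = depth_L / (depth_L + depth_R)` at heterozygous loci with total
depth at least `min_depth = 8` (the same depth floor used in SNP
filtering — below it the dosage signal is mostly binomial noise).

### Allele-depth dosage

The dosage model is the heart of the ploidy call: at a heterozygous
diagnostic locus of total depth $n_i$, the L-allele read count is

$$X_i \sim \mathrm{Binomial}(n_i,\ p), \qquad
  p \in \{1/2,\ 2/3,\ 1/3\}$$

for LR, LLR and LRR respectively — the expected allele fraction equals
the allele's genome-copy fraction. `classify_genotype()` pools the
per-locus binomial log-likelihoods (per-locus depths, not pooled counts,
so deep loci carry more weight but no locus dominates) and applies a
decision cascade:

1. `p_homL >= homo_min` (default 0.95) → **LL**; `p_homR >= homo_min` →
   **RR**;
2. `p_het >= het_min` (default 0.90) → a hybrid; its ploidy is the
   maximum-likelihood dosage model, accepted only when at least
   `min_het_loci = 10` loci inform the likelihood *and* the winner beats
   the runner-up by `margin_llr = 2` log-units; otherwise
   **E_UNKNOWN_PLOIDY** (a hybrid whose ploidy the data cannot support);
3. anything else is **UNDETERMINED**; when both `p_homL` and `p_het`
   exceed 0.25 the profile looks like a mixture of a parental and a
   hybrid sample and is flagged `CONTAMINATION_SUSPECT`.

The thresholds operationalise what is, in practice, read off
density plots of `rel_L` by eye. They are all surfaced in
`classify_config()`. Defaults were chosen as follows: 0.95/0.90 leave
room for a ~1% genotyping error rate times ~10% misorientation without
crossing categories; 2 log-units corresponds to a likelihood ratio of
about 7.4 in favour of the winning ploidy; and 10 informative loci is the
point where the per-locus KL divergence between the 1/2 and 2/3 models at
depth 30 (~1.8 nats/locus) makes the margin essentially always decisive
for true diploids/triploids while letting genuinely ambiguous profiles
fall through to `E_UNKNOWN_PLOIDY`. At infinite depth the cascade is
exact: profiles with `rel_L` fixed at 1/2, 2/3 or 1/3 are classified
deterministically, and swapping the L/R orientation of the diagnostic set
maps LL↔RR and LLR↔LRR while leaving LR fixed (both properties are
tested).

### Breeding systems

`classify_pond()` turns a pond's genomotype calls into a system label by
ordered rules: triploids with LR but without LL → `E_E_CANDIDATE`
("candidate" because the absence of LL from a finite sample may be a
sampling artifact); LLR alongside LL → `MODIFIED_L_E`; LL with LR →
`L_E`; a single observed genomotype → `UNDETERMINED`. Hybrids of unknown
ploidy count as hybrid presence for the L-E rule only — they cannot
testify to triploidy. RR presence is flagged in the notes whatever the
system, since RR animals (invasive marsh frogs or rare viable
hybrid×hybrid offspring) matter for management regardless.

## Upstream steps

**Deduplication.** ddRAD libraries are PCR-amplified, so identical
inserts can be either PCR copies or genuinely independent molecules. The
degenerate base region (DBR) in the adapter disambiguates:
`remove_pcr_duplicates()` groups pairs by (R1 prefix, R2 prefix, DBR) and
keeps the highest-mean-quality pair per group, ties broken by input
order. A 30-base prefix key (rather than full reads) is used because 3'
ends decay in quality; the key length is a parameter.

**Filtering.** `filter_snps()` applies, in a fixed order, per-cell depth
masking (< 8 reads → missing), minor allele frequency (< 0.05 removed,
computed allele-wise over called genotypes only), per-SNP missingness
(mds) and per-individual missingness (mdi). The order matters and is
deliberate: MAF is computed on depth-masked calls, and individual-level
missingness is meaningful only over the final locus set. Technical
replicates are resolved before filtering — the best replicate is kept
when it has more than 300,000 reads, otherwise replicates are combined by
summing depths cell-wise with a consensus genotype (conflicts become
missing); samples need more than 50,000 reads to enter the final dataset.

**Replicate sweep.** `snp_error_rate()` estimates the SNP-calling error
as the fraction of discordant calls over cells where both replicates are
called; discordance is counted at the genotype level (any allele
differs), the more conservative of the two conventions. `run_sweep()`
evaluates each upstream assembly setting across the mds × mdi grid
{0.3, 0.4, 0.5}², and `select_setting()` replaces the traditional
judgement call ("maximise loci and individuals at low error") with a
deterministic lexicographic rule: discard records above the 25th
percentile of observed error rates, then maximise individuals, then SNPs,
ties to the lowest error and then input order. The percentile gate is
configurable; 25% encodes a strong preference for clean calls over
dataset size.

**Ordination and references.** `pca_genotypes()` encodes calls as A2
dosage (0/1/2), mean-imputes missing cells per locus and
eigendecomposes the covariance. Mean imputation is the standard neutral
choice: imputed cells sit at the locus centroid and add no between-group
signal. "Centrally located" reference individuals are quantified as
smallest Euclidean distance to the cluster centroid in the first two
components, with a missingness cap (default 0.2) and ties broken by
missingness then id — the ordination itself provides no natural metric
beyond this. Cluster membership comes from an external ancestry matrix
via the strict `q > 0.8` rule (`assign_from_q()`); fitting the admixture
model itself is out of scope, the matrix is an input.

**Markers.** The 33-bp MND1 fragment differs between the L and R alleles
at exactly two positions; direct sequencing of a heterozygote shows the
two-base IUPAC code at both. `call_mnd1()` reads the two positions and
returns LESSONAE / ESCULENTUS / RR_GENOTYPE, or UNIDENTIFIED on any
discordant or unreadable combination — the marker's known failure mode
(an RR individual heterozygous by descent at MND1 is called ESCULENTUS)
is preserved, not patched, because it is a property of the marker, not of
the software. ND1 haplogroups are assigned by nearest Hamming distance to
reference haplotypes; ties are unresolvable and flagged.
`marker_concordance()` counts agreement only over individuals identified
by *both* methods: a method that abstains is not wrong, so UNIDENTIFIED
calls are excluded from the rate's denominator.

## The synthetic-data generator

`simulate_pond()` emits exactly the structure the inference assumes:

* diagnostic loci fixed oppositely in the L and R genomes; heterozygous
  cells draw their L-read count from the dosage binomial;
* non-diagnostic loci with allele frequencies uniform on [0.05, 0.95]
  per genome, shared between the genomes with probability 0.5, sampled
  within individuals by Hardy–Weinberg — *except* that triploids carry a
  clonally transmitted parental-genome pair (one shared LL diplotype for
  all LLR, one RR diplotype for all LRR). This emulates hemiclonal
  reproduction, in which the triploid's doubled genome passes to progeny
  as a unit; without it, LLR is nearly indistinguishable from LR in
  genotype space, whereas with it triploids form their own ordination
  cluster, as real surveys observe;
* per-cell depth is negative-binomial with mean `mean_depth` (default
  30×) and dispersion 5 — RAD coverage is strongly overdispersed
  relative to Poisson — truncated at 1 read for called cells and 2 for
  heterozygotes so a called heterozygote always shows both alleles (the
  conditioning shifts the dosage mean by well under 1% at default depth);
* genotyping errors flip a call to a uniformly chosen different state
  (default rate 0.008 per cell, which yields replicate discordance in
  the 1.5% range typical of RAD data); missingness is i.i.d. per cell
  (default 0.1);
* all randomness flows from a single integer seed; identical seeds give
  identical tables.

`simulate_country()` shares one locus panel across ponds and adds a
synthetic ancestry matrix (Dirichlet-concentrated on each individual's
own genomotype cluster) standing in for the external admixture input.
`simulate_dbr_reads()`, `simulate_replicates()` and
`simulate_marker_sequences()` generate the dedup, error-calibration and
marker inputs with planted truth. The MND1 templates and ND1 references
shipped by `mnd1_templates()` / `nd1_references()` are *synthetic*
stand-ins with the documented structure (two diagnostic substitutions;
~7% between-haplogroup divergence); real templates and GenBank reference
sequences can be passed wherever they are accepted.

What passing the synthetic tests does **not** show: the generator has no
linkage, no read-level sequencing error, no allele-specific amplification
bias (which would shift `rel_L` off the copy fraction), no batch or
library effects, and its two-population allele-frequency model is not a
coalescent — cluster geometry in real PCAs will be messier, and real
dosage densities are wider than binomial. The depth distribution is
plausible rather than fitted to any empirical dataset. Conclusions about
the *code* transfer to real data; conclusions about *power* at a given
depth do so only approximately.

## Validation sizes and determinism

The test suite validates the dosage chain on cohorts of 15 LLR / 15 LR
individuals at depth 30 with ≥ 50 informative heterozygous loci each, and
genomotype recovery (≥ 98% required) on 500 individuals spanning all five
classes at depth 30, 30% missingness and 1% genotyping error. Filtering,
reference ranking and deduplication are checked against independent
brute-force reimplementations on randomized instances (20 × 200 cells,
≤ 500 read pairs). Error calibration covers planted rates
{0, 0.01, 0.02, 0.05} with a 3-standard-error band. The end-to-end run
simulates a 33-pond survey (≈ 270 frogs, 300 loci) and requires every
pond's planted breeding system back. These sizes keep the full suite
under half a minute while leaving the binomial bands comfortably
narrower than the effects being tested.

Degenerate inputs are handled explicitly rather than by accident: empty
read sets return a zeroed report; a filter pass that removes everything
warns instead of erroring; an individual with no called diagnostic locus
is unclassifiable and skipped with a warning; zero comparable replicate
cells, overlapping reference panels, ambiguous cluster orientation and
tied haplogroup distances are all errors that name the problem.

## Known limitations

* Ploidy beyond three genomes (LLLR etc.) and the LLL genotype are not
  modelled; an LLL animal is indistinguishable from LL at diagnostic
  loci, exactly as in the underlying method.
* The `q > 0.8` rule is threshold-sharp by design; individuals near the
  boundary become UNASSIGNED and simply drop out of reference selection.
* `select_setting()`'s percentile gate is a modelling choice, not an
  estimate; two analysts preferring different error/size trade-offs
  should set it differently.
* Combining technical replicates re-derives nothing at read level: it
  sums depths and takes call consensus, which is correct only downstream
  of locus assembly.
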