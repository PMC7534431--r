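---
title: "Mapping heteroduplex DNA in nuclease-induced mitotic recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping heteroduplex DNA in nuclease-induced mitotic recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetdnamap)
```

## The biological system

When a site-specific double-strand break (DSB) is induced in a yeast
chromosome and repaired by homologous recombination off a
sequence-diverged ectopic donor, the repaired duplex records the repair
mechanism in its sequence. In a mismatch-repair-deficient (*mlh1*)
background, strand-transfer intermediates survive as heteroduplex DNA
(hetDNA): at every engineered SNP inside the transferred region, the two
strands of the product carry different parental alleles. Sequencing both
strands of each recombinant colony therefore reveals, SNP by SNP,
whether a position is recipient on both strands (`RR`), heterozygous
(`HET`, hetDNA), or donor on both strands (`DD`, a gene-conversion
patch).

The geometry of hetDNA discriminates pathways:

* **SDSA** (synthesis-dependent strand annealing) leaves a single hetDNA
  tract on one side of the break — upstream (promoter-proximal,
  negative coordinates) or downstream (positive coordinates).
* **dHJ dissolution** leaves hetDNA on both sides (bidirectional).
* **Crossovers** (dHJ cleavage) are scored phenotypically via a
  papillation assay (more than three 5FOA-resistant papillae) and are
  not sequenced.

A separate signal is superimposed on the tract pattern: DNA polymerase
delta proofreads a mismatch close to an invading or annealing 3' end
before extending it. When the break-proximal SNP sits 8 nt from the 3'
end this excision is frequent and converts the terminal SNP to `DD`;
at 22 nt it is rare.

## The generative model

`repair_params()` fixes the study conditions. Each simulated event
draws, in order:

1. crossover vs noncrossover (`p_crossover`, default 0.09);
2. for noncrossovers, bidirectional vs unidirectional
   (`p_bidirectional_given_NCO`, default 0.13);
3. for unidirectional events, downstream vs upstream
   (`p_downstream_given_unidirectional`, default 0.73);
4. a tract extent per engaged side, i.i.d. lognormal with median 900 bp
   (`meanlog = log(900)`, `sdlog = 0.6`), measured in bp from the break;
5. one proofreading flag per side of the break, with probabilities
   selected by the distance of that side's first SNP from the break:
   `{8 nt: (up 0.83, down 0.35), 22 nt: (up 0.08, down 0.07)}`.

The defaults are the observed I-SceI event fractions and terminal-SNP
loss rates; `sdlog` is a modelling choice (the assay's pooled tract
lengths span roughly 22 bp to 2 kb with a median near 900 bp, which a
lognormal with `sdlog` 0.6 reproduces; no dispersion is published).
Several points were genuinely open and are resolved as follows:

* **Dissolution is the only bidirectional NCO source.** NCOs from dHJ
  cleavage are rare in this assay and are omitted from the model.
* **Proofreading acts per side, independent of tract side.** The
  conversion patch is carried by the resynthesized terminal segment, so
  a side can show `DD` at its first SNP even when its transient hetDNA
  was dismantled (SDSA's invading side). This is required for the
  observed ~83% upstream terminal loss across *all* NCOs.
* **Invading vs annealing asymmetry is not asserted.** The published
  fractions are per physical side (upstream/downstream); whether the
  upstream rate belongs to the invading or the annealing end is not
  decidable from sequence data, so the lookup is keyed by side.
* **Tract extents are clamped at `homology_span / 2`.** A tract that
  would run past the end of the shared homology is bounded by it;
  clamping (rather than redrawing) keeps the configured median
  unbiased and is the physically sensible reading.

`realize_product()` converts an event into two strand vectors over the
marker map: SNPs with `|position| <= extent` on an engaged side are
heterozygous, and a set proofreading flag overwrites the break-proximal
SNP of its side to donor on both strands.

## Substrate geometry and coordinates

`build_marker_map()` places SNPs at 50-bp spacing starting 22 nt (or
8 nt) from the break on each side; the default 42 + 42 SNPs span the
4.2-kb homology of the assay substrates. Coordinates are signed nt
offsets with no position 0; they are measured from the edges of the
4-bp tetramer that is duplicated in the donor (the region between the
two nuclease nicks). The published "8 nt / 22 nt from the 3' end" is
mapped onto this frame as the first-SNP offset; sub-overhang differences
in the exact terminus are carried by `enzyme_spec()` (I-SceI: 4-nt 3'
overhangs, no gap; ZFN: 4-nt 5' overhangs, 8-bp gap after processing)
and are not modelled per strand, because every downstream analysis
operates on SNP coordinates. The cleavage-site insertion is padded to
2 mod 3 nt so that copying the donor's 4 extra bp restores the reading
frame — bookkeeping only, no ORF is modelled.

## Read emission

Each noncrossover is amplified under a unique 16-nt forward/reverse
barcode pair; reads are `forward barcode + amplicon +
reverse-complement(reverse barcode)`. Each read samples the minor
strand with probability `minor_fraction` (binomial per read, mimicking
molecule sampling from a colony lysate; default 0.5, two strands of one
duplex). Substitution errors are i.i.d. per base (default 0.002,
CCS-like); an indel rate exists but defaults to 0 so that genotyping
stays position-based. What the generator does *not* emulate: chimeric
PCR molecules, barcode synthesis errors, coverage skew between
colonies, and real CCS quality structure. Passing tests therefore show
correctness of the analysis logic under the stated error model, not
robustness to every artefact of real libraries.

## The analysis pipeline

* **Demultiplexing** matches both barcodes exactly (a Hamming tolerance
  exists, default 0). Every read lands in one group or the unassigned
  bin.
* **Genotyping** calls a read `R`/`D` at a SNP only when its 11-nt
  window (SNP plus 5-nt flank on each side) matches the corresponding
  allele's context exactly, else `N`. A single substitution anywhere in
  the window produces `N`, deliberately conservative.
* **Species calling** clusters reads by genotype vector with `N` as a
  wildcard: unique patterns are processed in order of decreasing count
  (ties broken lexicographically) and join the first cluster whose
  founding pattern they are compatible with. Clusters holding at least
  10% of the group's reads are the detected species; reads in smaller
  clusters (presumed sequencing errors) are absorbed into the nearest
  species by Hamming distance over jointly confident positions, ties to
  the larger cluster. Haplotypes are per-position weighted majorities;
  position ties give `N`.
* **Filters**: at least 20 reads, exactly two distinct species (one or
  more confidently differing SNPs), minor species at least 10% of reads
  (compared on counts, so 3/30 passes exactly). Groups with more than
  two species at threshold are excluded as `multi_species` — a
  conservative choice for a case the published criteria do not
  address.
* **Tract mapping**: per-SNP states from the two haplotypes; terminal
  removal = `DD` at the break-proximal SNP of a side (`NA` when
  ambiguous); tract length per side = distance from the break to the
  most distal `HET` SNP (no interpolation beyond the last SNP — a
  conservative, reproducible convention); discontinuous `HET` runs
  count as one tract. Profiles with more than 20% ambiguous SNPs are
  dropped from summaries.

With error-free reads and balanced species the pipeline is exact: every
included product's profile equals the simulated truth, which is the
package's oracle-equivalence test.

## Statistics

Comparisons between cohorts use 2x2 chi-square tests with the Yates
continuity correction on by default — recomputing the published
P-values from their printed counts reproduces them under the corrected
statistic only. Tract lengths are compared by a Mann-Whitney U test:
exact enumeration of the conditional rank distribution (a counting
recursion over the tied rank multiset) when both samples have at most
8 observations, otherwise the normal approximation with tie
correction; the two-sided p is the null probability of a deviation of
U from its mean at least as large as observed. Proportion intervals
are Wilson score intervals (the method behind the published
"non-overlapping 95% CIs" is unstated; Wilson behaves well at the
observed extremes such as 0/10). Southern-blot arithmetic normalizes
recipient to donor intensity per timepoint and to the t = 0 ratio;
`cut_fraction` is `1 - min(r_t)` and `repaired_fraction(t1, t2)` is the
recovered share of broken molecules `(r_t2 - r_t1)/(1 - r_t1)`, the
reading that reconciles with the published "16% of breaks repaired";
the raw ratio difference is available as an option.

## Problem sizes and numerical behavior

The package's own validation uses: a 550-product cohort (about 500
sequenced noncrossovers) at full 4.2-kb scale for the exact-recovery
check; 10,000 events for parameter recovery (3 binomial standard
errors); and about 1,000 noncrossovers through the full read-level
pipeline for median-length recovery. Because tract lengths are read off
a 50-bp SNP grid, the measured cohort median sits on grid values
(822/872/922 bp around the configured 900 bp); recovery within 10%
absorbs both this discretization and sampling noise. All simulations
are reproducible from a single seed; cohort artifacts are
byte-identical across reruns.

## Known limitations

The model assumes mismatches are never repaired (complete MMR loss) and
does not model tract-internal repair, resection kinetics, NHEJ, or
chimeric amplicons. Crossover hetDNA is not emitted (the assay
sequences noncrossovers only), so CO-side conclusions rest on the
papillation counts alone. The species-clustering rules are one
deterministic resolution of criteria whose published description names
only the species count and minor fraction; other reasonable rules could
classify borderline error-laden groups differently.
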