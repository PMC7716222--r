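---
title: "Forensic mitogenome haplotyping: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic mitogenome haplotyping: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohap)
```

## The problem

Forensic mitochondrial DNA comparison works on *haplotypes*: a sample's
sequence expressed as a list of named differences from the 16,569 bp
revised Cambridge Reference Sequence (rCRS), interpreted over a stated
range. Population databases of such haplotypes underpin the match
statistics reported in casework. Producing database-grade ("platinum
quality") haplotypes from high-coverage short-read sequencing requires
more than a generic variant caller: heteroplasmy (within-individual
mixtures of mitochondrial molecules) must be detected, confirmed and
encoded by convention; homopolymer regions must be summarized by their
dominant length molecule rather than by unstable indel calls; nuclear
copies of mitochondrial segments (NUMTs) and accidental two-donor
mixtures must be screened out; and the resulting sample sets must be
summarized with lineage-marker statistics (random match probabilities,
haplotype diversity, pairwise Φst, PCoA).

`mitohap` implements that pipeline end to end on two input surfaces —
aligned reads (SAM or the in-memory read stack) and a per-position,
per-strand pileup table — together with a seeded synthetic-data module
that generates populations, truth sets, reads and pileups with the
statistical structure the pipeline assumes, so that every stage is
testable without access to any specimen data.

## Variant calling model

Calling is per pileup column with hard thresholds, mirroring
low-frequency variant detection as practised in forensic mtDNA work:

* **Trimming.** 20 nt are removed from the 5' end of every read, 20 nt
  from the 3' end of paired reads, and reads shorter than 40 bp are
  discarded (`trim_reads`).
* **Base-quality neighborhood filter.** A base is excluded when its own
  Phred quality is below 30 or any base within ±5 positions is below 30
  (`quality_mask`). The upstream tool's exact neighborhood semantics are
  unpublished; per-base masking with these parameters is our
  interpretation and is recorded as such.
* **Depth.** No call of any kind at columns with filtered depth < 100×;
  such positions are excluded from the reported interpretation range and
  listed in the metrics.
* **Variant frequency.** Alleles at ≥ 5% of filtered depth are retained;
  a single retained non-reference allele is a fixed substitution (or
  deletion — the deletion allele competes as a base class), two retained
  bases are a point heteroplasmy (PHP) encoded with the two-base IUPAC
  code and the recorded major-base frequency. More than two retained
  alleles never produces a call; it sets a mixture-suspect flag consumed
  by QC.
* **Strand balance.** Each retained allele needs at least 1% of its own
  supporting reads on each strand. We apply the rule per allele (not per
  column); this choice is noted as the plausible reading of a
  forward/reverse balance filter and is the stricter one for one-strand
  artifacts.
* **Ties.** Two non-reference bases at exactly equal counts are both
  retained (PHP) with the major designated by base order A<C<G<T — a
  deterministic, logged tie-break.
* **NUMT screen.** The same machinery evaluated at a 2% threshold
  reports alleles passing all filters at 2% but failing 5%
  (`numt_screen`), annotated with membership in the nps 6,636–11,428
  amplicon where nuclear co-amplification presents.

Detection near the threshold is necessarily statistical: at 1000× a true
6% minor allele exceeds the 5% cutoff with probability ≈ 0.92, and ≥ 99%
detection holds pooled across minor fractions 6–45%, which is how the
test suite frames it.

## Length heteroplasmy

Indels called inside the nine catalogued homopolymer/repeat regions
(nps 303–315, 452–463, 513–524, 565–573, 956–966, 5891–5899, 8270–8289,
12,418–12,425, 16,180–16,193) are withheld from the profile and the
regions are re-analyzed from spanning reads: a read contributes when it
covers the region plus one aligned anchor base on each side, reads are
grouped by the motif between the anchors, motifs under five reads are
omitted from the listing, and the most-read motif — the major length
molecule — is diffed against the reference segment to yield the
reported variants, 3'-justified per forensic convention
(`spanning_motifs`, `major_molecule`, `apply_length_calls`).
Same-length motif disagreements at ≥ 5% of spanning reads are emitted as
PHPs inside the region (`php_in_region`). One-base anchoring is our
choice to make motif boundaries well defined; the count floor is
absolute, not proportional; ties between equal-count motifs prefer the
length closer to the reference, then lexicographic order.

## QC ladder

* `confirm_php`: PHPs with minor frequency < 10% must recur (same
  position, same base pair) in an independently amplified replicate;
  otherwise the call reverts to the major base. Confirmation requires
  presence, not frequency agreement. Positions the replicate does not
  cover are *unresolvable* — removed and logged, never silently kept.
* `flag_mixture`: reduced overall major-base frequency (< 0.98 excluding
  heteroplasmy) together with ≥ 3 PHPs, any PHP on a supplied
  haplogroup-diagnostic site, or any >2-allele column. The 0.98/3
  defaults are ours; the source definition is qualitative. Note that at
  realistic divergence (tens of differing sites) a 10% minor donor moves
  a whole-genome average major-base frequency by well under 0.1%, so the
  discriminative trigger in practice is the diagnostic-site rule — the
  frequency trigger catches only gross contamination.
* `find_shared_haplotypes` groups samples whose keys match with PHPs
  excluded and common-position insertions ignored — the candidate list
  for kinship (STR) testing, with an exclusion list for known
  duplicates/relatives. Kinship computation itself is out of scope.
* `compare_analyst_profiles` and `sanger_concordance` report symmetric
  differences, the latter suppressing PHP-versus-major-base differences
  that Sanger chemistry is expected to miss.
* Every profile edit anywhere in the pipeline lands in an audit trail;
  `replay_audit` reapplies a trail to the pre-edit profile and must
  reproduce the final variant set (tested).

## Population statistics

Haplotype keys drop variants outside the comparison range, drop
insertions at the ten ignored length-heteroplasmy positions (16,193,
309, 315, 455, 463, 573, 960, 5899, 8276, 8285), and either keep PHPs
literally or drop them (`php_mode`). Dropping — so a heteroplasmic
sample merges with the matching non-heteroplasmic haplotype — is the
default "excluding PHP" semantics; it reproduces the published
distinct/unique haplotype counts on forced compositions. From the class
sizes $k_i$ ($n = \sum k_i$, $p_i = k_i/n$):

* observed RMP $= \sum p_i^2$ (draw two with replacement),
* empirical RMP $= \sum k_i(k_i-1)/(n(n-1))$ (matching ordered pairs),
* haplotype diversity $= \frac{n}{n-1}(1 - \sum p_i^2)$.

The source never prints these formulas; the definitions were fixed by
exact agreement with every composition-forced row of the published
summary table before implementation, and the three are linked by exact
identities (tested in integer arithmetic). Display follows the table's
conventions: percentages half-up to two decimals, diversity to four.
`resolve_partition` recovers a row's composition by exhaustive
enumeration of partitions consistent with all printed statistics; for
the two rows not forced by counts alone the search returns exactly one
partition.

Genetic distance uses the Kimura 2-parameter form
$d = -\tfrac12\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ with transition and
transversion fractions over compared sites; indel sites, PHP sites in
either haplotype and the reference N placeholder (position 3107) are
excluded (pairwise deletion). Pairwise Φst is the among-population
fraction of an AMOVA on squared K2P distances, with significance from
label permutations (sizes preserved, +1 smoothing); 1000 permutations at
α = 0.05 are the defaults, which the source does not state. Note a
finite-sample property verified in the tests: comparing a population
with an exact copy of itself gives Φst $= -1/(n-1)$, not 0 — every
individual has a zero-distance partner in the other group — so the
"identical populations" anchor is asserted one-sidedly. PCoA is Gower
double-centering of $-D^2/2$ with coordinates scaled by the square roots
of the positive eigenvalues; explained fractions are over positive
eigenvalues only.

PHP characterization classifies each PHP as purine/pyrimidine transition
or transversion, assigns it to control region (nps 16,024–16,569 and
1–576) or coding region, and folds the non-reference-base frequency onto
[0, 0.5]. Continental ancestry is tabulated from user-supplied
haplogroup labels by longest-prefix matching (so B2 → Native American
while B4 → Asian); haplogroup inference itself is out of scope and
unmapped labels are reported as unassigned.

## Synthetic data: what it emulates and what it does not

The real specimens behind the published datasets are not distributed, so
the package carries a deterministic synthetic 16,569 bp reference
(`synthetic_reference`; random background with the nine
length-heteroplasmy motifs planted verbatim — 303–315 is the 7C-T-5C
tract — and N at 3107) and a seeded generator (`sim_config`,
`simulate_population`, `simulate_pileup`, `simulate_reads`). Generator
defaults are the study conditions: 28% of individuals carry PHPs split
1/2/3 as 80.8/16.4/2.7%; 95% of PHPs are transitions with hotspot
weighting at nps 146, 152, 204, 16,093; the folded PHP frequency
spectrum puts 32% of mass at 5–10% and 47.5% below 15% (interior bins
interpolate — only those anchors are published); with probability 0.25
the non-reference base is the major one; per-region length-heteroplasmy
rates are led by HVII at 86.9%, HVI 19.8%, HVIII 7.9%, the 513–524 AC
repeat 4.1% and np 12,418–12,425 at 4.4%, with unpublished regions set
to 1–2%; mean depth 1000×, base error 0.5% (average major-base frequency
≈ 99.5%, matching the published excluding-heteroplasmy metric), NUMTs at
2–3% confined to nps 6,636–11,428, mixtures as a second donor at a
configurable minor fraction. Haplotypes are independent substitution
sets (star phylogeny) of Poisson mean 30 — sufficient for frequency and
distance statistics, not a coalescent model of real phylogeographic
structure.

What passing tests therefore show: the calling rules, thresholds,
motif analysis, QC logic and statistics behave correctly on data with
the assumed error model (i.i.d. base errors, balanced strands, Poisson
depth). What they do not show: robustness to correlated sequencing
artifacts (quality-by-cycle error, strand-biased chemistry, alignment
artifacts around long indels, PCR stutter beyond declared motif
mixtures), to reference bias, or to real phylogenetic structure.

Reads are generated pre-aligned (no mapper in the loop); `read_sam`
enforces the alignment admission contract (no clipping, ≥ 80% identity)
when importing externally aligned data. `simulate_reads` emits reads in
post-trim coordinates; the trimming contract is exercised on hand-built
reads. Origin-wrapping alignments are supported in memory and in
pileups, but are skipped by the SAM writer since a linear SAM record
cannot express them.

## Numerical and degenerate-input choices

* Coordinates are 1-based with inclusive intervals throughout; circular
  wrap is explicit (`circular_position`).
* Position 3107 is carried as N: no variant is named there, and it is
  excluded from K2P site totals.
* PHP codes are restricted to two-base IUPAC codes; three-base ambiguity
  is rejected (at most two alleles can pass a 5% threshold in practice
  under the >2-allele mixture rule).
* Indels are always re-expressed 3'-most (`normalize_indels`), with an
  error if justification would leave the interpretation range.
* Both deletion spellings (`249DEL`, `249-`) are accepted on input; the
  writer emits one, configurably.
* K2P saturation ((1−2P−Q) ≤ 0 or (1−2Q) ≤ 0) is an error naming the
  offending quantity, and Φst names the failing pair.
* Empty pileups, all-below-depth ranges, empty motif tables and n < 2
  sample sets raise errors rather than returning degenerate numbers.

## Problem sizes used in the checks

The test suite exercises: exact recovery on 100 noiseless whole-genome
simulations at 500×; PHP detection pooled over minor fractions
0.06–0.45 at Poisson(1000) depth (50 columns per fraction); 500
replicates of 60/40 motif-mixture recovery at 200 spanning reads;
carrier-rate recovery over 1000 simulated individuals called at 1000×;
permutation type-I error over 200 null comparisons of 8-vs-8 samples at
1000 permutations; mixture-flag sensitivity over 200 simulated 10%
mixtures and specificity over 200 clean whole-genome samples; and
10,000 random partitions for the match-statistic identities. These sizes
were chosen to give comfortable statistical margins for each asserted
bound on a single CPU.

## Known limitations

* The caller does not realign around indels or model mapping error; its
  read model is the admitted alignment.
* Insertion alleles are taken from the single major motif per anchor;
  competing same-anchor insertion motifs outside the nine catalogued
  regions are resolved by count, not phased.
* `php_in_region` maps motif offsets to reference coordinates through
  the length group's most-read motif; within highly divergent same-length
  groups that mapping is heuristic.
* The Φst permutation test permutes individuals, not molecules; it
  matches the standard two-population AMOVA design and nothing finer.
* Haplogroup labels are inputs; the ancestry map covers the major
  continental prefixes and reports anything else as unassigned.
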