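---
title: "Methods: homozygosity mapping and exonic SINE discovery at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity mapping and exonic SINE discovery at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinescout)
library(dplyr)
```

## The problem and the procedure

Autosomal-recessive progressive retinal atrophy (PRA) in a closed dog breed
is the canine counterpart of human retinitis pigmentosa: affected animals
inherit two copies of a causal allele that is identical by descent.
`sinescout` implements the discovery route such a study follows when the
causal allele turns out to be a mobile-element insertion rather than a
small variant, as happened with the exonic SINE in canine *FAM161A*:

1. **Exclusion screen.** Cases are checked against a panel of published
   inherited-eye-disease variants; a homozygous hit ends the analysis.
2. **Homozygosity mapping.** SNP-array genotypes of cases and controls are
   quality-filtered and scanned for runs of homozygosity (ROH); the
   intersection of case ROHs, minus intervals where any control is also
   fully homozygous, defines a critical region, which heterozygous calls
   at the flanks then narrow.
3. **Recessive variant filtering.** Annotated variant calls inside the
   region are filtered under a fully penetrant recessive model (all cases
   homozygous alternate, no control homozygous alternate, high predicted
   impact) and against an external population panel ("common elsewhere"
   disqualifies).
4. **Insertion calling.** When no small variant explains the phenotype,
   read alignments over the region are scanned for the insertion
   signature: clustered terminal soft-clips at two breakpoints, a short
   interval of elevated depth between them (the duplicated target site),
   poly-A content in the clipped sequence, and mates mapping to other
   chromosomes (multi-copy repeat mapping).
5. **Classification.** The insert consensus is aligned against a
   repeat-consensus library; the percent-identity matrix names the family.
6. **Consequence.** The insertion is spliced into the transcript model and
   translated: frame status, aberrant residues, premature-stop position,
   exon extension, and which isoforms are affected.
7. **Assay genotyping.** An allele-specific fragment-length assay
   genotypes a cohort; a segregation report checks concordance with the
   recessive model and computes the insertion allele frequency.

Every step consumes and produces the field's standard formats (PED/MAP,
VCF 4.2, SAM text, FASTA, BED, JSON), so any stage can be run on its own.

## The synthetic-data module

Real WGS and array data for this design are archive-scale. The package
therefore ships a first-class, seeded generator (`sim_config()`,
`simulate_reference()`, `simulate_genotype_cohort()`, `simulate_reads()`,
`simulate_variant_table()`, bundled by `simulate_all()`) that emits every
input with known ground truth. Its defaults are the study conditions the
pipeline is designed around, chosen once and not revisited:

* **Cohort**: 4 cases and 22 controls for the array cohort (the mapping
  step's cohort); the fragment-assay validation table (6 affected, 6
  heterozygous and 14 clear controls) is used directly in the assay
  module. The first two simulated controls are obligate heterozygous
  carriers; the rest carry one insertion allele with probability 0.2.
* **Genome scale**: each of 3 chromosomes has a nominal length of 10 Mb
  carrying 400 array markers (~1 / 25 kb, array-scale sparsity), and a
  20 kb sequenced focal window whose offset on the chromosome is
  recorded. Reads, the gene and the insertion live on the window; markers
  and the ROH live on the chromosome. This decoupling keeps read
  simulation desk-sized while the ROH arithmetic stays at the published
  megabase scale.
* **The gene**: 7 exons, plus strand, no UTRs (a documented
  simplification -- the CDS is the exon span). Exon 4 is alternatively
  spliced; the long isoform encodes 716 residues, the short one 660, so
  the skipped exon encodes 56. The insertion point sits at a codon
  boundary 10 wild-type residues before the end of exon 4.
* **The element**: 210 bp, drawn from the first of four SINE-like library
  consensuses at 3% substitution divergence, poly-A tail (16 bp)
  restored, and -- for in-frame lengths -- its reading frame engineered so
  translation from the insertion point gives 49 aberrant residues and
  then a stop. Retrotransposition duplicates the 15 bp target site, so
  the donor allele is `ref[..g] + element + TSD + ref[g+1..]`; the
  premature stop lies inside the element, so the duplicated tail never
  reaches translation and the published "ins210" bookkeeping applies
  unchanged.
* **Reads**: 150 bp pairs at 30-fold coverage, insert size 400 +/- 50 bp,
  emitted pre-aligned to the insertion-free reference. Reads crossing a
  breakpoint with at least 20 bp of reference anchor are written
  soft-clipped; reads with less anchor (including element-only reads) are
  placed on a different contig at mapping quality 0, mimicking multi-copy
  repeat mapping; 30% of the remaining breakpoint-crossing pairs are
  re-assigned the same way. Sequencing substitution error is off by
  default (`error_rate = 0`); the alignment signature, not the error
  model, is the object of study. `tiled = TRUE` switches to regular
  fragment placement with a fixed insert size, the fully noiseless
  setting in which the depth signature is exact.

What the generator does **not** emulate: base qualities, indel errors,
alignment ambiguity beyond the one-destination repeat mimicry, LD
structure between markers, pedigree relatedness, and X/Y chromosomes.
Passing tests therefore demonstrate the correctness of the algorithms
under their stated model, not robustness to every artefact of real
sequencing.

## Parameters that matter

### ROH scan (`roh_params()`)

The scan follows the classical sliding-window design: a 50-marker window
slides one marker at a time; a window is homozygous if it has at most 1
heterozygous and 5 missing calls; a marker is ROH-eligible when at least
5% of the windows covering it are homozygous; maximal eligible runs are
reported if they have >= 25 markers, >= 1 Mb, marker gaps <= 1 Mb and at
least one marker per 50 kb. The window constants are the widely used
viewer defaults; `min_markers` is scaled from the genome-array value (100)
to 25 because a ~2 Mb run on a 1/25 kb panel holds ~80 markers. One
consequence of the hit-fraction rule worth knowing: with a 5% threshold a
marker needs >= 3 homozygous covering windows, so detected boundaries sit
about two markers inside the true homozygous interval, while chance
homozygosity in flanking markers can extend them outward by a few more.
The critical-region step does not depend on boundary positions at marker
resolution; the refinement step explicitly re-anchors them at the
markers adjacent to the nearest case heterozygous calls. Missing calls do
not terminate a run during refinement (only het calls do), a deliberate,
flagged choice. Samples of unknown status are treated as controls for the
exclusion step.

### Insertion caller (`mei_params()`)

All thresholds that a human applied by eye in a genome viewer are
explicit: depth elevation factor 1.3 over the regional median with
elevated runs capped at `tsd_max_bp = 50`; soft-clips counted from 20 bp,
clustered within +/- 2 bp, supported by >= 3 reads; poly-A calls need a
terminal window of >= 10 bases at >= 80% adenine (the reverse complement,
a 5' poly-T head, is also checked); genotype cutoffs on the clipped
fraction r at 0.2 and 0.8. Mapping-quality-0 reads are kept for depth and
clip evidence -- repeat-derived reads are exactly the signal -- but are
excluded from genotype denominators. With 150 bp reads no single read
spans a 210 bp element, so the caller reports a full insert length only
when the two clip consensuses overlap-merge (>= 15 bp at >= 90%
identity); otherwise the concatenation is flagged partial and the length
stays unknown. Breakpoint convention: `bp_left` is the first base of the
target-site duplication (where left-extending clips start), `bp_right`
its last base; `tsd_sequence` is always the reference substring between
them, asserted on every call. VCF export anchors at `bp_left - 1` with a
symbolic `<INS:ME:SINE>` allele.

At 30-fold Poisson coverage the 1.3x depth threshold sits less than two
standard deviations above the mean, so random fluctuation produces short
spurious "elevated" runs; the caller therefore treats depth elevation as
corroborating evidence (`depth_ratio`) rather than a gate -- calls are
made from clip clusters plus poly-A. The exact one-interval depth
signature is demonstrated under tiled fragments, where it holds.

### Variant filter

"Common in the population panel" is operationalised as panel allele
frequency > 0.05 or any panel individual homozygous alternate, both
configurable; variants absent from the panel are kept and flagged
private. A missing case genotype disqualifies (recessive proof requires
observed homozygosity); a missing control genotype is ignored. The
four-level impact ladder (MODIFIER < LOW < MODERATE < HIGH) stands in for
upstream annotation scores; the filter consumes per-variant panel
summaries (`PANEL_AF`, `PANEL_NHOM` INFO keys) rather than raw panel
genotype matrices -- the rule is identical and the inputs stay desk-sized.

### Alignment and classification

Global (Needleman-Wunsch) alignment with affine gaps, scored +2 match,
-3 mismatch, -5 gap open, -2 per gap base (a length-k gap costs
5 + 2k); the engine is `Biostrings::pairwiseAlignment()` and an
independent recursive scorer verifies it in the tests. Percent identity
is matched columns over aligned columns with terminal-gap columns
excluded from the denominator, so consensuses of unequal length compare
by their aligned core. Poly-A tails are not trimmed before
classification (no trimming is applied anywhere by default). Best hits
tie-break lexicographically and ties are reported.

### Consequence counting rules

The first altered codon is counted aberrant if it is wholly inserted, or
if it mixes reference and inserted bases and its translation differs from
the wild-type residue. `aberrant_aa_count` runs from there to (excluding)
the first stop; `wildtype_tail_aa` is the wild-type residue count from
the same position to the end of the host exon; `exon_extension_aa` is
their difference. `stop_protein_position = protein_start_position +
aberrant_aa_count` is asserted on every call. Standard genetic code only.
Designations render in the field's informal style
(`ACC c.<pos>_ins<len> p.<start>`), not strict HGVS; an unknown insert
length renders `ins?` with a warning. Published coordinate strings are
treated as opaque labels: where a printed c./p. pair is internally
inconsistent under standard ceiling(c/3) mapping, the package uses the
standard mapping and does not attempt to reconcile.

### Assay module

Fragment length is the 5'-to-5' distance from the forward primer to the
reverse primer plus any non-binding tail; integer arithmetic, asserted
deterministic. A primer with zero binding sites on a template yields no
product from that allele -- that is the allele-discrimination mechanism --
while multiple binding sites raise a design error. The wild-type forward
primer designed by `design_insertion_assay()` spans the entire target
site plus flanks, because an insertion with a TSD reconstructs the
wild-type sequence at both junctions and a shorter junction primer would
amplify both alleles. Capillary sizing error is modelled as uniform
+/- 1 bp; genotype calls use a 1 bp matching tolerance.

## Orchestration

`validate_pipeline_config()` schema-checks a YAML (or list) configuration,
collecting all errors rather than stopping at the first, and fills
documented defaults. `run_pipeline()` executes the stages over
standard-format files in the output directory, writes a manifest (config
hash, per-file MD5 checksums, stage timings, warnings) and a final
candidate report; a stage failure halts with the stage name and offending
input. The pipeline scans the critical region only, as the original
analysis did; a manual `region` plus disabled ROH stage reproduces the
downstream results file-for-file. The assay/segregation stage runs on the
synthetic cohort's ground-truth genotypes; for real data the assay
functions are called directly with an observed genotype table. A thin
command-line wrapper over these functions ships in `inst/cli/sinescout.R`.

## Numerical and degenerate-input choices

* Seeding: every generator draws from a stream derived from
  `(seed, stage-tag)`, so outputs are byte-identical for identical
  configs and independent of call order; the caller's RNG state is
  restored afterwards.
* Consensus ties in clip clusters resolve alphabetically; cluster
  breakpoints are the median clip position rounded to integer.
* Interval arithmetic is 1-based inclusive everywhere; BED export
  converts to 0-based half-open.
* Empty intersections, empty regions and zero-evidence loci return empty
  tibbles, not errors; an all-het sample simply has no runs; QC that
  removes every marker is an error naming both removal counts.
* An interior case het call splits a critical region; the longest piece
  is returned and the alternates are attached as an attribute and
  messaged.

## Problem sizes used in the checks

The shipped verification uses 20 independent seeds of the default
cohort for end-to-end recovery (exactly one candidate insertion,
breakpoints within +/- 1 bp, exact TSD, all planted genotypes, planted
variant as sole filter survivor), 100 random <= 200-marker instances for
scanner-versus-enumerator equivalence, and 50 queries at 3% divergence
for classification recovery. These sizes make the whole suite run in a
few minutes on one CPU while keeping every binomial bound meaningful.

## Known limitations

* Single-insertion model per region; nested or adjacent insertions are
  out of scope.
* The caller's insert length is bounded by what two clip consensuses can
  reconstruct; elements much longer than twice the read length will
  always report partial consensuses.
* No HMM/IBD probabilistic ROH model (the window scan is the published
  method); no kinship correction.
* Splice-site disruption, NMD prediction and protein structure are not
  modelled; the consequence module is exon-coding arithmetic only.
* The fragment assay assumes exact primer matches; thermodynamics
  (melting temperature, dimers) are not modelled.
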