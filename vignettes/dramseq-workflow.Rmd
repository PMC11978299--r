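---
title: "Calling reader-directed deaminase editing as an m5C proxy"
author: "dramseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling reader-directed deaminase editing as an m5C proxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

A reader/deaminase fusion does not edit the methylated cytosine itself: the
m5C reader domain binds near the modification and the tethered deaminase
converts *neighbouring* editable bases on single-stranded RNA — cytosines
(APOBEC1, C-to-U, read as C→T) or adenines (TadA-8e, A-to-I, read as A→G).
The observable is therefore a *cluster* of conversions within a window of
roughly ±20 nt around each m5C site, visible in standard RNA-seq, with the
edit ratio at a position (edited reads / covering reads) reflecting the
per-molecule editing probability. Specificity comes from comparison, not
from the chemistry: the same deaminase without a functional reader
(deaminase-only, or a reader-mutant fusion with residual binding) edits
diffusely, and knocking out the m5C methyltransferases NSUN2/NSUN6 removes
the methylation that directs the fusion.

`dramseq` treats each stage of this logic as a separate, testable module:
simulation of reads with known ground truth, strand-aware pileup and
candidate extraction, the comparative filter cascade, and the downstream
summaries (regions, metagene, distances, motifs, amplicon/trace
quantification).

## What the simulator emulates

`simulate_reads()` draws, per transcript, `coverage_mean × L /
read_length` sense-strand fragments placed uniformly. Within
`window_halfwidth` (default 20 nt) of a planted site every editable base is
converted independently per read with probability `edit_rate ×
rate_multiplier`; background (off-target) edits are applied outside windows
at `background_rate`, weighted `background_region_bias`-fold inside 3'UTRs;
flat-profile sequencing errors come last. Alignments are written as
coordinate-sorted SAM with MD/NM tags; minus-strand genes store
reverse-complemented reads, so a transcript-level C-to-U appears as G→A in
reference coordinates — exactly the case the candidate extractor must
handle.

The default condition set mirrors the study design the workflow is built
for: three fusion (DRAM) replicates, one reader-mutant replicate, two
deaminase-only replicates, three knockout replicates. Chosen constants,
and why:

* **per-site edit rates** default to the 13.6–14.7% band measured at the
  two validated target sites (the CBE and ABE site-level rates); the
  end-to-end recovery runs use 0.3, a realistic upper-range value that
  makes per-position power calculable (expected 30 edited reads at 100×).
* **reader-mutant multiplier 0.02**: mutated readers retain some binding,
  so a small nonzero floor stresses the filters more honestly than zero.
* **knockout multiplier 0.1**: knockouts abolish most but not all directed
  editing (residual methylation and nonspecific binding); 0.1 places the
  DRAM/knockout ratio quotient near 10, comfortably above the 1.5-fold
  filter, while keeping knockout candidates present for the comparison.
* **deaminase-only background 0.005/read/base, 3:1 3'UTR bias**: no
  measured off-target rate exists, so this is a declared free parameter;
  the bias reproduces the qualitative 3'UTR-heavy distribution of
  deaminase-only editing so background subtraction is genuinely exercised.
* **sequencing error 0.001** (≈ Q30), flat profile.
* **transcript lengths 800–2000 nt**: with 100 nt reads and uniform
  placement the interior depth is `coverage_mean × L / (L − RL + 1)`;
  lengths ≥ 800 keep that within 15% of the nominal coverage while
  preserving the read-count convention `n = coverage × L / RL`.

Replicate `r` of a condition uses seed `seed + r`: reproducible but
non-identical replicates. Identical seeds and specifications give
byte-identical output files.

What the simulator deliberately does *not* model: splicing (single-exon
transcripts; intron/intergenic labels are still supported by the annotator
for multi-block models), indels, PCR duplicates, base-quality variation,
fragment-size distributions, and coverage biases. Passing tests therefore
demonstrate correctness of the *computational* pipeline under its stated
statistical model, not robustness to alignment artefacts or library
chemistry on real data.

## The filter cascade and its edge cases

The default tier requires, per replicate: coverage ≥ 10 reads, edit ratio
in [5%, 95%], ratio ≥ 1.5 × the knockout ratio at the same (reference,
position, conversion), and ≥ 2 edited reads; a site must pass in ≥ 2
replicates (singletons are removed) and is reported with the mean ratio
over passing replicates. Sites present in the deaminase-only condition at
*any* ratio are removed. The high-confidence tier re-applies tightened
thresholds — ratio 10–60%, 2-fold over knockout, ≥ 4 edited reads — to the
aggregated site statistics, which makes it provably a subset of the
default tier and the identity when given the default thresholds.

Decisions the definitions leave open, resolved as follows:

* **knockout division by zero**: a knockout position covered with zero
  edited reads gets ratio `pseudocount / (coverage + pseudocount)`
  (default pseudocount 1), so deep knockout coverage is stronger evidence
  of absence; a position with *no* knockout coverage passes the fold test,
  since absence of coverage is not evidence of absence of editing.
* **"editing events at a given site"** is read as edited reads at that
  site — the only per-site countable quantity.
* **the fold test compares the DRAM sample's ratio** to the knockout
  (not the mutant control's), matching the default-tier wording.
* **order of operations**: replicate filtering runs before background
  subtraction; `subtract_background()` is a pure set-difference step, so
  callers can reorder if desired.
* **overlapping genes**: candidates under genes on both strands are
  emitted once per strand and flagged ambiguous rather than silently
  dropped; intergenic positions are evaluated on both strands.

Note a consequence of literal any-ratio background subtraction, visible in
the bundled analysis scripts: with a diffuse deaminase-only background at
100× coverage, a true site has an appreciable chance of one stray
background edit at the same position, so subtraction removes a substantial
fraction of real sites. That is the assay's own specificity/sensitivity
trade-off, reproduced rather than patched.

## Annotation, distances, motifs

Region assignment uses 0-based half-open intervals throughout, with
precedence CDS > 5'UTR > 3'UTR > intron when isoforms disagree, then the
longest transcript — single-annotation behaviour in the style of metagene
tooling. Metagene coordinates rescale a site's offset within its segment
to [0,1) / [1,2) / [2,3); the profile reports bin proportions summing
to 1 (90 bins by default), with an explicit zero-site flag for empty
input.

Distances are computed per *reference* m5C site: the nearest called edit
on the same reference and gene strand within the window (3000 nt for the
broad view, 80 nt for the fine view; histogram bin widths 50 nt and 1 nt —
declared choices, as the published figures do not state their binning).
Signs follow transcript orientation (negative = upstream), and equidistant
ties resolve downstream for determinism. Reference sites with no edit in
the window contribute no record.

Flanks are extracted on the gene strand with the edited base centred, so
the centre column of the position frequency matrix is pure by
construction; contig-end flanks are N-padded and the padded cells excluded
from column denominators. Information content is `2 − H` bits against a
uniform background with no small-sample correction (the common logo
default; configurable analysis would belong downstream). No enrichment
p-value is attached to motif observations — only the descriptive PFM/IC is
computed.

## Site-level quantification

`bisulfite_fraction()` implements amplicon deep-sequencing quantification:
retained C = methylated, converted T = unmethylated, any other base
(sequencing error) excluded from the denominator, and a QC flag requiring
more than 1000 reads. `sanger_edit_rate()` reads the conversion-pair
proportion off a base-proportion trace and is the exact inverse of
`simulate_sanger_trace()` on the full [0,1] grid. Replicate agreement uses
Pearson correlation of per-mRNA mutation counts over the union gene set
with absences as zero, on raw counts (normalisation is left to the
caller).

## Problem sizes and numerical choices

The bundled analyses and the end-to-end tests use 50 transcripts
(800–2000 nt), 100 planted sites, 100× coverage and nine condition
replicates — sizes chosen so a complete run finishes in about a minute on
a laptop core while leaving per-position binomial noise small relative to
every threshold (expected 30 edited reads per in-window cytosine against
a 2-read floor). Acceptance-style recovery checks use 10,000-read
amplicons and 3-binomial-SD tolerances; exact assertions (trace
quantification, filter predicates, set operations) use equality. Floating
point is treated conservatively: PFM columns are normalised to 1 within
1e-9, and bin-boundary-sensitive tests are constructed on exact binary
fractions.

## Known limitations

Real DRAM-seq data would additionally face alignment errors around edit
clusters, transcript-abundance-driven coverage variation, incomplete
knockout of the methyltransferases, SNP contamination at C/T and A/G
polymorphisms, and reader-binding biases that are not uniform within the
±20 nt window. None of these are modelled; the package's claims are about
the correctness and calibration of the calling logic under its stated
generative model.
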