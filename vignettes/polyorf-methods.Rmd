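---
title: "Methods: alternative ORFs, silent-but-altering variants, and frame-specific conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternative ORFs, silent-but-altering variants, and frame-specific conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyorf)
```

# The model

A mature transcript is treated as potentially polycistronic: besides the
annotated canonical CDS it may encode alternative proteins from ORFs in any
of the three reading frames. `polyorf` operationalises this with a strict
working definition — an alternative ORF (altORF) begins at an ATG, runs
in-frame to its first stop codon (the stop is part of the footprint), and
encodes at least `min_aa = 30` amino acids. The 30-codon floor mirrors the
minimal cut-off used by large altORF prediction databases; it is exposed as
a parameter because the field has no consensus (smORF catalogues use
< 100 codons, classical annotation uses ≥ 100). ORFs shorter than
`smorf_max_aa = 100` codons are tagged as smORFs but never filtered on that
basis.

Classification is purely interval-based against the CDS: `uORF` (entirely
5′), `dORF` (entirely 3′), `overlap_nested` (inside the CDS),
`overlap_partial` (crossing one CDS boundary), `lncRNA_orf` (no CDS on the
transcript). The frame offset of an ORF is `(start − cds_start) mod 3`;
CDS-overlapping ORFs with offset 0 are in-frame truncations or extensions
of the canonical protein and are excluded from the altORF set, while
same-frame ORFs that do not overlap the CDS are kept. By default one ORF is
reported per (frame, stop) pair — the 5′-most start, matching the
longest-isoform convention — with `report_all_starts = TRUE` available when
completeness matters.

## Coordinates, strand, and ambiguity

All internal coordinates are 0-based half-open in transcript space (the BED
convention); GFF3 (1-based inclusive) and VCF (1-based) are converted at
the I/O boundary, which confines off-by-one risk to two well-tested
functions. Minus-strand genes are reverse-complemented at load, so all
downstream logic is strand-free; genomic variant alleles are complemented
during projection. Codons containing `N` translate to `X` and never act as
start or stop codons — an ambiguous base therefore cannot create or
terminate an ORF, only blur one residue — and substitutions whose codon
contains `N` are classified `unknown`.

# Silent-but-altering variants

For each SNV the consequence is computed in the canonical frame and in
every overlapping altORF from the (reference codon, alternative codon,
codon index) triple: synonymous, stop_retained, missense, nonsense,
stop_loss, start_loss (a codon-0 change that destroys the start). A variant
is *silent-but-altering* when it is synonymous or stop-retained canonically
and missense/nonsense/stop-loss/start-loss in at least one altORF.
Stop-retained changes count as silent because they leave the protein
sequence untouched. Indels are out of scope: the package classifies
substitutions only, so "frameshift in the altORF" here can only arise from
the frame shift between ORFs, not from length-changing variants.

A geometric fact underlies the phenomenon: because the genetic code's
redundancy concentrates synonymous changes at the wobble (third) position,
and a frame-shifted overlapping ORF maps the canonical third position onto
its own first or second position, canonically-silent variants
preferentially strike the *informative* positions of overlapping altORFs.
The test suite checks this exhaustively (64 codons × 9 substitutions: no
sense codon admits a synonymous position-2 change, with TAA↔TGA the only
stop-retained one) and verifies every classification against an
independent whole-protein-diff oracle.

# The enrichment test

The claim "synonymous SNVs hit altORFs more often than expected by chance"
needs an explicit chance model; none is standard. The null chosen here:

* the sample space for each transcript is its **canonical-synonymous
  substitution space** — every (position, alternative base) pair inside the
  CDS whose canonical consequence is synonymous or stop-retained;
* under the null, each transcript's observed number of SNV occurrences is
  redrawn uniformly **with replacement** from that space (mutational
  recurrence is real in tumour data), preserving per-transcript counts;
* the statistic is the pooled occurrence-weighted fraction of SNVs whose
  position falls inside an altORF footprint (`frac_positional` — the
  "fell within a predicted alternative protein" quantity); the fraction
  altering an altProt is reported alongside with its own p-value;
* `p = (1 + #{permuted ≥ observed}) / (n_perm + 1)`, one-sided,
  +1-corrected so p is never 0; `n_perm = 1000` by default.

Conditioning on gene composition and per-gene mutation counts isolates
*positional* enrichment from gene-level mutation burden. The analytic
expectation (`expected_frac`, the occurrence-weighted mean altORF coverage
of the synonymous spaces) equals the mean of the permutation distribution
and is reported for interpretability. Gene-level descriptives mirror an
overview table: per gene, the synonymous SNV count, positional and altering
counts and percentages, a flag for "at least one altering SNV", the median
length of the distinct altered altProts, and a class breakdown; these are
reported descriptively, not permuted.

The permutation p is exactly uniform under exchangeability up to the
discreteness of a counts-over-counts statistic; ties between permuted and
observed fractions are counted as "≥", making the test conservative. The
calibration test sizes (500 replicates of ~1,000 draws, 199 permutations)
keep that discreteness small relative to the Kolmogorov–Smirnov resolution.

# Frame-specific conservation periodicity

Coding sequence under purifying selection conserves codon positions 1–2
more strongly than position 3. For a per-base conservation track (phyloP
convention: positive = conserved) and each candidate frame `f`, the track
is split into three codon-position subsignals and the statistic

&nbsp;&nbsp;`Δ_f = mean(pos1 ∪ pos2) − mean(pos3)`

is computed **on raw scores**; the p-value comes from `n_perm` random
shuffles of the score order (re-split each time), one-sided, +1-corrected.
`detect_coding_frames()` reports frames passing a Bonferroni-corrected
`α/3`, so a dual-coding region can return two frames. Denoised subsignals
are attached for visualisation only: thresholding before testing would
distort the null distribution unpredictably.

Denoising is an orthonormal Haar transform with symmetric reflection
padding to the next dyadic length, full-depth decomposition by default,
universal soft threshold `λ = σ̂ √(2 ln n)` with
`σ̂ = median(|finest details|)/0.6745`. Thresholding touches only detail
coefficients, so denoising commutes with adding a constant, and with the
threshold rule `"none"` the transform is an identity to ~1e-9 relative
error. No R wavelet package is a dependency; the transform is ~40 lines and
fully property-tested.

When interpreting results on real tracks, two caveats carry over from the
underlying scores themselves: neutral-rate estimation in phyloP-style
scores presumes a single coding frame, which can bias the very signal being
sought in the alternative frame; and recently evolved altORFs may not yet
show purifying selection at all.

# What the synthetic data emulates — and what it does not

`simulate_study()` stands in for the study's external inputs (tumour
variant catalogues intersected with an altORF prediction database), which
are version-dependent and not reproducible at desk scale. Defaults define
the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_transcripts` | 25 | the 25-oncogene scale of the motivating analysis |
| `length_range` | 900–1800 nt | typical mRNA scale while keeping runtimes small |
| `gc` | 0.50 | human mRNA GC; codon sampling is GC-weighted so coding regions do not distort it |
| `cds_fraction` | 0.5 | CDS flanked by usable UTRs on both sides |
| planted ORFs | 1 uORF + 1 dORF + 1 nested | one of each major class per gene |
| `altprot_len_median` | 45 aa | the reported median predicted-altProt length |
| length distribution | log-normal, sdlog 0.25, truncated 30–300 aa | inverse-CDF sampling; the narrow sdlog keeps the truncated median within ~2% of target |
| `n_variants` | 40 per gene | tens of listed SNVs per gene |
| `enrichment_factor` | 1 | the exact null; >1 plants positional enrichment |
| `track_depth`, `track_noise_sd` | 1.0, 0.5 | signal-to-noise where single-frame detection is reliable at ~300 codons |

Transcripts are built constructively: background sequence at the target GC,
a canonical CDS (ATG, GC-weighted sense codons, stop), then each requested
altORF written in place under joint constraints (its own frame open, the
canonical frame kept free of stops, planted footprints disjoint). Incidental
ORFs that arise by chance outside the planted set are then *policed*: the
transcript is re-scanned and any unplanned prediction is edited away by
breaking its ATG or inserting an early in-frame stop, never touching
canonical or planted start/stop codons or creating stops in protected
frames. This guarantees the emitted truth table is complete — every
prediction is either canonical or planted — at O(length) cost. Every gene
gets a two-exon structure on its own contig with a random strand, so splice
projection and allele complementation are exercised by every fixture.

The generator does **not** emulate: realistic tumour mutational signatures
(draws are uniform or flat-factor-weighted over the synonymous space),
splice isoform diversity, transcript-abundance weighting,
phylogenetically simulated conservation (tracks are Gaussian noise plus
deterministic periodic elevation), or non-ATG initiation. Passing tests
therefore demonstrate correctness of the machinery and calibration of the
statistics under these controlled conditions, not performance on real
genomes.

# Numerical and design choices

* **Permutation p-values** are +1-corrected and one-sided throughout; ties
  count toward the null (conservative).
* **Saturated nulls** (altORFs covering the whole synonymous space) give
  p = 1 by construction — observed and permuted fractions coincide.
* **Degenerate inputs**: empty variant sets and lncRNAs in the enrichment
  path raise errors; transcripts with empty synonymous spaces are excluded
  with a warning; annotation violations at load (CDS not a multiple of 3,
  missing ATG or stop) reject the record with a diagnostic and continue.
* **The dual-coding scan region matters**: a short nested altORF's triplet
  signal is diluted over a full-length track, and outside the overlap the
  canonical signal contributes −depth/2 to other frames' statistics. The
  acceptance script therefore scans the overlap footprint itself, which is
  how a dual-coding locus would be examined in practice.
* **Open choices resolved here** (the source material is silent):
  "longer than 30 codons" is read as protein length ≥ 30 aa, stop excluded;
  ORF footprints include the stop codon, so stop-loss SNVs count as within
  the altORF; the chance model conditions on transcript and count (see
  above); wavelet depth, threshold and the frame-detection criterion are as
  stated, all parameterised.
* **Determinism**: every stochastic entry point takes a seed, uses R's own
  RNG, and restores global RNG state; identical configuration means
  byte-identical output, which the end-to-end test checks literally.

# Verification scales

The test suite verifies: exact oracle equivalence of ORF enumeration on
1,000 random transcripts of 300–3,000 nt against a per-position
brute-force scanner; exact agreement of every possible SNV consequence on
50 simulated fixtures (> 50,000 substitution–ORF pairs) with a
whole-protein-diff oracle plus the exhaustive 64×9 code-table check;
the wobble-position geometry on all fixtures; null calibration of the
enrichment p (500 replicates, Kolmogorov–Smirnov at 0.01, type-I error in
[0.03, 0.07] at α = 0.05); ≥ 90% power at enrichment factor 2 with 200
variants over 200 runs; 3·SE recovery of a ~50%-coverage null; Haar
round-trip identity at 1e-9 and strict MSE reduction on a planted step;
single-frame detection power ≥ 95% at depth 1.0 / noise 0.5 / 300 codons,
familywise false detection consistent with α = 0.05 on null tracks
(binomial test over 200 runs), dual-frame recovery ≥ 90% at noise 0.3; and
byte-identical end-to-end reruns at seed 42 that reproduce the emitted
ground truth exactly.

# Limitations

Substitutions only (no indels, no splice-site scoring, no RNA editing,
no stop-codon read-through, no non-AUG starts); the enrichment null is one
defensible choice among several (a genome-wide or signature-aware null
would answer a different question); conservation scanning assumes a
gap-free per-base track on the transcript (gaps must be interpolated
explicitly); and no attempt is made to score translation evidence — ribosome
profiling and proteomics integration are outside this package's scope.
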