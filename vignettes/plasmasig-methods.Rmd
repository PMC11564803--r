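---
title: "Methods: read-based mutational-signature inference from plasma LCWGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-based mutational-signature inference from plasma LCWGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference model

Low-coverage plasma sequencing (0.5–10×) rarely covers any somatic locus more
than a handful of times, so locus-centric variant calling is hopeless.
`plasmasig` instead treats each *read pair* as the unit of evidence: every
position where an aligned read disagrees with the reference is a candidate
somatic event, and the question becomes one of separating three sources of
mismatches — sequencing error, germline variation, and somatic mutation —
well enough that the *spectrum* of what remains is informative, even though
no individual call is trusted. Signature analysis only needs channel counts,
not genotypes, which is what makes this tractable.

The separation uses four orthogonal observations:

* **Sequencing errors are independent between mates.** A true variant on a
  fragment appears identically in both reads where they overlap; an error
  almost never does. Within the mate overlap, agreeing mismatches get the
  sum of the two base qualities (two independent observations of the same
  molecule), and disagreements keep the higher-quality base with its quality
  reduced by half the lower one — or are discarded entirely under strict
  consensus. For a per-base error rate $e$, the chance that both mates carry
  the *same* wrong base at the same position is about $e^2/3$, which is what
  drives the post-filter error rate down to the $10^{-8}$ scale measured by
  the acceptance suite.
* **Germline variants are catalogued.** An allele-specific lookup against a
  population store (gnomAD-scale VCF, or any 4-column TSV) removes the
  dominant non-somatic biological signal. The lookup is keyed on
  `(chrom, pos, ref, alt)` with indels left-aligned first.
* **Tumour-derived cfDNA fragments are short.** ctDNA is enriched in
  sub-nucleosomal fragment lengths, so an optional fragment-size window
  filter enriches the retained mismatch set for tumour signal before
  fitting.
* **Healthy plasma defines the null.** Even after all filters, healthy cfDNA
  yields non-zero signature weights. Per-signature detection thresholds are
  therefore estimated from a panel of healthy controls rather than assumed
  to be zero.

## Filter parameters

All thresholds are inclusive (`>=`); defaults follow the method's standard
operating point.

| parameter | default | units | role |
|---|---|---|---|
| `min_mapq` | 20 | Phred | per-read mapping quality; whole fragment rejected below it |
| `min_bq` | 65 | Phred (summed) | combined base quality per mismatch; inside overlaps this is the sum of both mates' qualities, outside (when non-overlap mismatches are allowed) the raw single-read quality is compared to the same bar |
| `min_avg_bq` | 25 | Phred | minimum mean base quality per read |
| `min_mismatches`, `max_mismatches` | 1, 15 | events/read | a read above the maximum invalidates its whole fragment (likely mismapping); a read below the minimum simply contributes nothing |
| `fragment_windows` | unset | bp | cfDNA size-selection windows; **mandatory config** when the fragmentomics filter is wanted, since the enriched ranges depend on the assay (the simulator's tumour-like default is Normal(145, 22) vs healthy Normal(166, 24)) |
| `only_overlap`, `strict_overlap` | per preset | — | consensus stringency (see below) |
| `min_read_bq` | 0 | Phred | extra per-mate minimum, used to express "both mates ≥ 32" regimes |
| `min_support` | 1 | fragments | optional site-level read-depth filter on the `multi` count |

`filter_preset()` exposes the nested stringency ladder used in the error-rate
benchmark — `A` (no filters, raw mismatches), `B` (overlap-only after
consensus), `C` (strict consensus), `D` (strict consensus plus per-read
BQ ≥ 32) — and `default`, the full stack with strict consensus. The presets
A–D deliberately switch the quality/count filters off so each step isolates
the consensus rules; their retained sets are provably nested, which the test
suite asserts.

Two threshold-semantics decisions are worth recording. First, the combined-BQ
default of 65 is defined on the *summed* overlap quality; the "per-read
BQ ≥ 32" regime is expressed through `min_read_bq` rather than as summed ≥ 64,
because 40 + 25 = 65 sums past 64 while violating the per-read intent.
Second, for non-overlap mismatches (when they are allowed at all) the raw
single-read quality is compared against `min_bq` unmodified: the summed
threshold is only defined for overlaps, and inventing a rescaling would be a
silent second threshold.

## Consensus details and tie-breaks

* Agreement requires identical `(pos, ref, alt, class)`; for indels inside
  the overlap under strict consensus this means identical representation in
  both mates.
* At quality ties in a disagreement, mate 1's base wins and its quality is
  reduced by half the other's — deterministic and symmetric in magnitude.
* Two substitutions adjacent on both the genome and the read merge into one
  doublet (DBS) event carrying the minimum of the two base qualities; runs
  of three or more adjacent substitutions are discarded as likely alignment
  artefacts (the doublet catalogue has no triplet channels).
* Deletion qualities are the minimum of the flanking read bases; insertion
  qualities the minimum over the inserted bases.

## Catalogues and classification

SBS events are classified on the pyrimidine-normalised trinucleotide
context (reverse complement taken when the central reference base is a
purine); doublets are collapsed onto the 78 canonical COSMIC labels; indels
follow the COSMIC v3.2 ID83 rules — type, length class (1/2/3/4/5+), then
homopolymer length, repeat-unit count, or (for deletions of two or more
bases with no repeat support) microhomology length. Microhomology is the
longest exact match between the deleted sequence's prefix and the 3′ flank
or its suffix and the 5′ flank, computed after left-alignment and only when
the deleted sequence is not a whole repeat unit at the site; repeat support
takes precedence over microhomology. Channel labels match COSMIC file
headers byte-for-byte, so downloaded matrices join without translation.

Sites with `N` in the context are tallied as excluded, never silently
dropped. A site contributes once to the catalogue regardless of its
supporting-fragment count by default (`count_by = "site"`); per-fragment
counting is available as a flag, since the behaviour is a genuine free
choice at higher depth.

## Signature refit

Exposures solve the non-negative least-squares program
$\min_{e \ge 0} \lVert c - S e\rVert_2$ on **raw counts** with a
Lawson–Hanson active-set solver written in the package (an independent
active-set implementation is the cross-check oracle in the tests). Weights
are exposures over their sum; artefact-flagged signatures (default: the
COSMIC v3.2 possible-sequencing-artefact set SBS27, SBS43, SBS45–SBS60,
always user-editable) are then removed and the remainder renormalised to
sum to exactly 1. A per-channel Poisson-weighted variant
(`per_channel_weights = "poisson"`) exists behind a flag; it is not the
default because unweighted NNLS is the variant with the fewest free
choices. No GC-bias background correction is applied to the counts — that
adjustment belongs to the fitting package used in the original analyses and
is intentionally out of scope here; with the built-in simulator the
question does not arise because reads are drawn uniformly.

All-zero catalogues produce a defined all-zero, `no_signal`-flagged result
rather than an error, as do samples whose entire fitted weight sits on
artefact signatures.

## Detection thresholds

For each signature the healthy-panel weights are trimmed of exactly one
maximum and one minimum sample (ties by first occurrence; a flag switches to
two from each end, since "the two samples with the highest and lowest
weights" admits both readings), clamped into $[10^{-6}, 1-10^{-6}]$ —
exact zeros are common and the beta moments are undefined at the boundary —
and fitted by closed-form moment matching:
$\alpha = m\,(m(1-m)/v - 1)$, $\beta = (1-m)(m(1-m)/v - 1)$. The beta
moments are analytic, so the closed form replaces iterative optimisation; a
`refine = TRUE` flag runs a maximum-likelihood polish from the moment
estimate for parity experiments. When $v \ge m(1-m)$ or $v = 0$ the fit is
degenerate and the threshold falls back to the trimmed panel maximum plus a
0.01 floor. The detection threshold is the fitted beta's 0.99 quantile, and
detection requires the sample weight to *strictly* exceed it: the threshold
is itself the 99th percentile of healthy, so equality is non-evidence. No
multiple-testing correction is applied across signatures. At least four
panel samples per signature are required (two trimmed, two remaining);
panels this small will produce wide, conservative thresholds.

## What the simulator emulates — and what it does not

`simulate_clean_reads()` draws fragments with truncated-Normal(166, 24)
lengths (bounds: read length and 500 bp), uniform genomic starts, 100 bp
mates, and injects substitution errors per base at rate $10^{-Q/10}$ under a
discrete quality profile (mean error ≈ 6.5×10⁻⁴). Reads are emitted as
already-aligned records with correct CIGAR/MD by construction, which removes
the aligner from the test loop at the cost of not modelling mismapping —
which is why the mapping-quality and whitelist filters are exercised by
construction in unit tests rather than by the simulator. Not modelled, by
design: PCR/optical duplicates (the duplicate filter trusts upstream
marking), indel sequencing errors (the clean-read analysis concerns
substitution error rates), platform-specific cycle effects beyond the
parametric profile, GC-coverage bias, and germline variation. Spike-ins
edit covering fragments directly (both mates when both cover the site) with
per-fragment Bernoulli(AF) decisions, so no realignment or coverage-skew
controls are needed. ID-signature spike-ins are not simulated: indels
concentrate in repeat and microhomology contexts, and random placement
would not produce a faithful ID spectrum.

Healthy donor reads in the admixture experiments carry a low-level *flat*
background spike: healthy plasma genuinely yields non-zero signature
weights (that is why panel thresholds exist), and without any background
signal every admixture would fit weight ≈ 1 on the target signature,
making purity and depth titrations degenerate. Panel weight tables are
simulated directly from a Dirichlet model (marginally beta per signature),
which matches the threshold model's assumptions by construction — a passing
specificity test therefore validates the fitting/quantile machinery, not
the beta's adequacy for real panels.

Consequently, passing simulations demonstrate the *mechanics* — filter
behaviour, spectrum preservation, threshold calibration, monotone response
to purity and depth — on data whose error process is idealised; they do not
certify performance on real plasma, where alignment artefacts, duplicate
structure, and batch effects add noise the simulator does not generate.

## Desk-scale study sizes

The reproductions run on a 1 Mb fixture genome at 0.41 GC. Spike-in burdens
are quoted per megabase, so desk-scale runs use nominally high rates
(r_m = 600/Mb in the titrations) to reach the *absolute* variant counts a
whole genome would provide at modest burden — 600 variants on 1 Mb is the
count a 3 Gb genome yields at 0.2 mutations/Mb. The titration grids
(purities 1/5/10% at 3×, depths 0.5/1/3× at 10% purity, 20 in-silico
replicates each, seeds held fixed across grid levels so read selections are
nested) were sized by a pilot power computation so that the monotone
detection-frequency properties are statistically resolvable with 20
replicates; the error-rate benchmark simulates ≥10⁸ sequenced bases in
50,000-fragment chunks so memory stays flat.

## Numerical choices

* NNLS tolerance: $10^{-10}$ relative to $\lVert S^\top c\rVert_\infty$;
  KKT conditions are spot-checked in the tests.
* Weight renormalisation is exact (division by the sum); the renormalised
  sum is asserted to 10⁻⁹.
* Beta quantiles come from `qbeta` (the inverse regularised incomplete
  beta); an independent root-finder on `pbeta` agrees to 10⁻⁹ in the tests.
* Coordinates: 0-based half-open BED inputs are converted on read; all
  user-facing positions, VCF output and the internal event representation
  are 1-based. Deletions are keyed at the first deleted base, insertions at
  the base 5′ of the insertion; anchored VCF alleles are produced only at
  the output boundary.
* Sub-seeds for chunked and replicated simulations are derived as
  `(seed * 7919 + i * 104729) mod 2147483629` to stay inside 32-bit range.

## Known limitations

* The germline lookup is allele-specific; whether position-only filtering
  would be more faithful in some settings is untested (a position-only mode
  would be a small extension of the store).
* The error model draws base qualities i.i.d. per base; real error rates
  correlate along cycles and with sequence context, so absolute error-rate
  results transfer as bounds, not point estimates.
* The synthetic signature matrix is a labelled stand-in with COSMIC-shaped
  names and channel structure; analyses of real data must load a real
  COSMIC matrix via `read_signature_catalogue()`.
* Fitting confidence intervals, de-novo signature extraction (NMF) and
  transcription-strand-resolved channels are out of scope.
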