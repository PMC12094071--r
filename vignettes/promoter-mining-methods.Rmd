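---
title: "Mining, designing and profiling bacterial 5' UTR promoter libraries"
author: "utrminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, designing and profiling bacterial 5' UTR promoter libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrminer)
```

# The problem

Establishing expression systems in a newly domesticated bacterium requires
promoters that work in that host. A productive shortcut is to harvest them
from the host's own genome: the intergenic region upstream of a gene — its
5' UTR, read broadly as a combined promoter + ribosome-binding-site unit —
already carries whatever regulatory grammar the organism uses. `utrminer`
implements the full *in silico* arc of that strategy:

1. **Mine** candidate 5' UTRs from an annotated genome (GenBank), with an
   auditable filter cascade.
2. **Design** a capped pool of synthesis-ready oligonucleotides compatible
   with Golden Gate cloning.
3. **Profile** the resulting reporter strains from dual-fluorophore
   plate-reader time series and classify each promoter's temporal bias
   across growth phases.
4. **Simulate** every input with known ground truth, so the whole pipeline
   is testable without any external data.

# Mining model and filter cascade

Every gene contributes one candidate: the intergenic region immediately
upstream on its coding strand (for a `+` gene, the region back to the
previous gene's end; for a `-` gene, the region forward to the next gene's
start, reverse-complemented). Filters *flag* candidates rather than delete
them — reproducing attrition counts requires an audit trail, and
`surviving()` is simply the flag-free view. The flags are:

| flag | rule |
|---|---|
| `opposing_orientation` | the upstream flanking gene lies on the opposite strand (divergent or convergent context; both members of a divergent pair are flagged) |
| `overlap` | the intergenic gap is ≤ 0 bp; the candidate is empty |
| `too_short` / `too_long` | length outside **60–170 bp inclusive** (the bounds themselves are retained; exclusion is strict `<60` / `>170`) |
| `no_transcript` | the downstream gene is absent from the supplied RNA-seq count table — this also removes tRNA/rRNA leaders, which never appear in an mRNA count table |
| `restriction_site` | the sequence contains a BsaI (`GGTCTC`), BsmBI (`CGTCTC`) or BbsI (`GAAGAC`) recognition site on either strand; type-IIS enzymes cut regardless of site orientation, so both strands are screened |

Boundary genes on a linear replicon take the region up to the replicon
edge; with `circular = TRUE` the region wraps the origin instead. Whether
the transcriptome merge should additionally require a count strictly above
zero is left to the data: presence in the table is the criterion, and
counts of exactly zero simply carry no order of magnitude during selection
(below).

# Library design

The synthesis order is capped at 500 sequences of at most 150 nt, so
selection is two-tranche:

* **Tranche 1** — the 350 shortest survivors. Because candidates at most
  98 bp fit the insert window without trimming, this tranche contains all
  of them whenever they number ≤ 350. Ties in length break by gene
  identifier, making selection a pure function of the candidate set.
* **Tranche 2** — the remainder is binned by order of magnitude of read
  count (`floor(log10(count))`, with counts in (0,1) binned at −1), and
  the 50 highest-count candidates per decade are added, highest decade
  first, until the cap. Under-filled bins contribute what they have; there
  is no backfilling across bins, which keeps the tranche semantics
  auditable.

Selected candidates longer than 98 bp are trimmed **from the 5' end** — the
retained 3' bases are those nearest the start codon, where the
ribosome-binding site lives. Each insert is then framed by Golden Gate
flanks (a forward BsaI site on the left, its reverse complement on the
right, cut sites pointing into the insert) and padded with seeded random
bases to exactly 150 nt. The pad sits outside the restriction sites
(outermost 5' end by default, configurable to 3'), so it is never cloned.
Pad draws are rejected and redrawn (up to 100 times, after which the
builder errors; at four candidate bases per position the failure
probability is negligible) whenever a draw would create an additional
type-IIS site anywhere in the oligo, junctions included.

Two numerical caveats are deliberate. First, sites formed by the fixed
flank–insert junction itself are tolerated by default, mirroring the
screen's scope during mining (only the genomic sequence is screened); with
random inserts such junction sites arise in roughly 0.6% of designs, and
`strict_junctions = TRUE` turns them into a hard error for users who want
the stricter guarantee. Second, per-candidate pad seeds are derived from
the library seed, so reruns are byte-identical and a manifest (plan +
seed) suffices to reproduce an order sheet exactly.

The shipped flank sequences are documented placeholders with correct BsaI
geometry; real designs substitute the fusion overhangs dictated by their
entry vector.

# Fluorescence model

Reporter strains carry promoter-driven mCherry on a plasmid and a
constitutive genomic GFP whose expression tracks biomass. Three equations
turn raw plate-reader channels into a phase-bias call:

1. **Background correction.** FI = signal − media-only control, per
   channel and timepoint. Negative FI values are *retained* and flagged,
   not clamped: clamping would bias ratios for weak promoters.
2. **Biomass normalization.** RFU = FI(mCherry) / FI(GFP). GFP is a less
   noisy biomass proxy than OD at low densities, and because late-stationary
   fluorophore accumulation is nearly identical for both fluorophores, the
   ratio stays flat where OD-normalization would drift. Timepoints whose
   GFP FI is below a positivity floor (default 1e−9 signal units) are
   masked.
3. **Differential activity.** The ratio of RFU at the mid-exponential
   timepoint to RFU at the stationary timepoint, each averaged over a
   symmetric 3-sample window (window configurable; 1 gives a point
   estimate). Ratios **< 0.7** classify as stationary-biased, **> 1.3** as
   exponential-biased, in between (bounds inclusive) as unbiased. The
   thresholds are configurable; a published variant phrases them as 75% /
   125%, and 0.7/1.3 is taken as normative here.

Phase timepoints come from the OD600 curve after Savitzky–Golay smoothing
(window 11 samples, polynomial order 3 by default — polynomials of degree
≤ 3 pass unchanged, so the logistic inflection is preserved while
high-frequency noise is attenuated). The mid-exponential timepoint is the
time of maximum slope; the stationary timepoint is the earliest time
attaining the maximum smoothed OD (a curve still rising at the last sample
gets the final timepoint, with a warning). Two robustness choices matter
at realistic noise: the slope series is itself re-smoothed before the
argmax, and the argmax is searched only up to the curve's first arrival in
the plateau band (95% of the OD range) — the mid-exponential point
precedes stationary phase by definition, and these two guards keep
residual plateau noise, which is largest at the filter's one-sided edges,
from masquerading as growth.

A strain is **detectable** when its stationary-phase RFU exceeds the
reporter-free background strain's mean RFU by more than k = 3 background
standard deviations (mean and SD over the background strain's full
smoothed series). Only detectable strains enter the class tally.
Flow-cytometry events are additionally assignable to four quadrants by
closed AU intervals on the green (100,000–500,000 high; 25,000–70,000 low)
and red (8,000–90,000 high; 3,500–4,000 low) channels; events in neither
interval of a channel are `ungated`.

# What the simulator emulates — and what it does not

`genome_spec()`/`generate_genome()` realize a linear replicon with
controlled gap lengths, strand topology, planted restriction sites and
planted motifs, and emit both a GenBank file and a ground-truth candidate
table computed from the layout itself (gap strings, strands, a plain
substring site screen) — never by calling the mining code, so round-trip
tests are genuine. `generate_counts()` spreads counts uniformly within
each requested decade. `generate_candidate_set()` shortcuts straight to a
surviving-candidate table for design-stage work.

`curve_spec()`/`generate_strain_series()` model OD as a logistic
K/(1+exp(−r(t−t0))), GFP as biomass-proportional signal plus media
background, and mCherry as a promoter activity profile times the same
biomass signal. The activity profile is piecewise linear: a constant
exponential-phase level until 2 h after the inflection, a 4 h linear
transition, then a constant stationary level — so the windowed RFU at both
phase timepoints sits on a flat segment and, at zero noise, the recovered
ratio equals the specified `true_ratio` to machine precision. After the
growth plateau both fluorophores share a linear accumulation drift that
cancels in the ratio, reproducing the flat late-stationary RFU the
normalization relies on. Noise is Gaussian with SD proportional to each
signal.

The default cohort (`cohort_design()`) emulates the study conditions this
package is built around: 33 strains — 12 stationary-biased, 10 unbiased,
3 exponential-biased, 8 inactive — measured in triplicate over 36 h at
15 min resolution with 2% noise, K = 1 OD, r = 0.5 h⁻¹, t0 = 10 h,
20,000 AU GFP per OD unit. True ratios are drawn uniformly from
class-typical bands (0.35–0.6, 0.85–1.15, 1.5–2.2) that sit clear of the
0.7/1.3 thresholds, matching the several-fold phase differences reported
for strongly biased natural promoters. Stationary RFU levels are
log-spaced over 0.005–0.61, the two-order-of-magnitude dynamic range
observed for active promoter libraries of this kind, with the strongest
level assigned to the stationary-biased class.

What the simulator does **not** emulate: diauxie or death phases,
plasmid-copy-number enrichment in stationary phase (a real *in trans* bias
the ratio cannot remove), well-to-well growth heterogeneity,
autofluorescence spectra, evaporation, or condition-dependent induction.
Passing tests therefore demonstrate that the computation is correct under
the stated model, not that the model captures every behaviour of real
plate-reader data.

```{r cohort, eval = FALSE}
design <- cohort_design(seed = 1)
sim <- generate_plate_timeseries(design, seed = 2)
res <- analyze_plate(sim$plate, sim$well_map)
res$summary
```

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: genomes of
up to 60 genes for mining round-trips, a 722-candidate survivor pool for
the design stage, one 33-strain cohort (145 timepoints, triplicate wells)
and 200 single-strain simulations at 5% noise for the classifier-accuracy
estimate. These sizes exercise every code path while keeping a full run in
the tens of seconds; all scale linearly.

Other numerical decisions, collected: coordinates are 0-based half-open
internally and 1-based inclusive in every user-facing position (motif
spans, restriction hits); ties for the stationary timepoint resolve to the
earliest; the GFP positivity floor, SG parameters, ratio window, class
thresholds and detectability k are all `pipeline_config()` fields;
selection determinism relies on gene-id tiebreaks, never on RNG; every
generator is a pure function of its seed, and library padding derives
per-candidate seeds from the library seed.

# Known limitations

* The GenBank parser covers the common bacterial case (simple and
  `complement()` locations for gene/CDS/tRNA/rRNA features); compound
  `join()` locations are rejected rather than guessed.
* Divergent intergenic regions are flagged for *both* flanking genes;
  assigning such a region to one gene only would require transcription
  evidence the mining stage does not have.
* Trimming records both pre- and post-trim lengths, since published
  candidate lengths are sometimes quoted pre-trim.
* The detectability rule (background mean + 3 SD) is a pragmatic
  operationalization; detection thresholds for real instruments should be
  calibrated against the instrument's own background strain.
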