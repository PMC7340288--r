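---
title: "Methods: variant prioritization for MMR-pathway panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritization for MMR-pathway panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrscreen)
```

## The problem and the pipeline

Complete-gene capture of the 22 mismatch-repair (MMR) pathway genes —
all introns, exons and UTRs, about 1.213 Mb — called on a cohort of
unselected endometrial-cancer patients yields on the order of 10,000
unique germline variants, roughly 97% of them intronic. `mmrscreen`
turns that call set into a short, auditable list of candidate cancer-risk
variants in five stages:

1. parse each variant's HGVS `c.` name and assign a region class,
2. filter region-by-region on population frequency and prior assertions,
3. score splice impact for intronic variants,
4. derive and combine ACMG/AMP evidence into a 5-tier class, and
5. summarize per patient and per gene.

The pipeline assumes the per-variant annotations (gnomAD frequency,
ClinVar status and submission count, conservation scores, in-silico
predictions) arrive as an annotation table — the package consumes the
output of annotation engines, it does not reimplement them.

## Region classification

The region partition is exon / splice-neighbourhood intron / deep intron /
5'UTR / 3'UTR, driven entirely by the parsed `c.` name:

* An intron offset (`c.306+4`, `c.628-7`) dominates the anchor: a
  5'UTR-anchored variant with an offset (`c.-1028+959`) is intronic, not
  UTR. This matches how such variants are counted in panel reports.
* The splice neighbourhood is `|offset| <= 10` nt (configurable,
  `splice_max`), measured on the intronic side. The exonic base adjacent
  to a junction (e.g. the last base of an exon) stays exonic; its splice
  relevance is handled by the splice scorer, not the region class.
* A ranged edit that touches at least one coding-exon base is exonic:
  a duplication such as `c.3802-4_3825dup` spans the acceptor but
  produces a protein-level consequence, so exon is the class that
  determines its downstream handling.

## The filtering cascade

Stages run in order *region split → frequency → ClinVar prefilter
(exonic) → splice category (intronic)*, and every variant gets a decision
trail; `retained + dropped = input` holds at every stage by construction
and is asserted in tests.

Frequency thresholds are strict upper bounds, reflecting the "less than
0.1%" convention: 0.001 for exons and introns, 0.0001 for UTRs (the UTR
stage is deliberately stricter because effect prediction there is weak and
the candidate list must stay manageable). Variants with no population
frequency are retained (`keep_missing_frequency = TRUE`): absence from
gnomAD is evidence of rarity, not of benignity. The ClinVar prefilter
drops benign/likely-benign exonic variants only; it is not applied to
other regions by default because prior assertions outside exons are too
sparse to be trusted as a drop criterion. Deep-intronic variants must
carry a splice-category flag — new donor/acceptor site or strong cryptic
activation — to survive; splice-neighbourhood variants bypass that
requirement because they are reviewed for junction deactivation instead.

## Splice scoring

Donor sites are scored over a 9-nt window (3 exonic + 6 intronic bases),
acceptors over 15 nt (14 intronic + 1 exonic), with per-position
frequency matrices and the percent-score convention
`(S - S_min)/(S_max - S_min)`, where `S` sums the matrix frequencies of
the observed bases. Default matrices are estimated from all annotated
junctions of the loaded panel with pseudocount 1 — no trained model is
shipped — and a JASPAR-format file can override them.

Two numerical choices matter:

* **GT/AG gating.** A window whose invariant dinucleotide is not GT
  (donor) or AG (acceptor) scores 0 regardless of the rest of the window.
  Biologically a site without the invariant dinucleotide is not a splice
  site; numerically this is what makes a single-base hit at the +1/-1
  position register as *complete* site loss, `delta = -1`, rather than a
  small percentage change diluted over the window.
* **The change score** is `delta = (alt - ref)/ref`, floored at -1, with
  a 1e-9 guard against zero reference scores. Events are thresholded:
  deactivation at `delta <= -0.1` on a canonical site (well above the
  noise of a neutral substitution in these windows, and loose enough to
  capture partial-damage scores around -0.3 at exon-terminal positions);
  a new site when a non-canonical window crosses `tau = 0.70` from below;
  cryptic strong activation when a non-canonical window gains >= 15%
  relative score *and* reaches 80% of the nearest canonical site's score.
  All four are configuration values (`splice_config()`); they are
  declared defaults, not values fitted to data.

Scanning is positional and order-independent: every window of the
appropriate length overlapping the variant is evaluated once, canonical
windows are excluded from the new-site scan, and evaluating a reference
sequence against itself always yields `delta = 0` and no events.

## ACMG evidence and combination

Evidence derivation is a set of independent deterministic rules over the
annotation fields; absent fields simply yield no code:

| code | rule (defaults) |
|------|-----------------|
| PVS1 | nonsense/frameshift consequence, or deactivation at a canonical ±1/2 splice position |
| PS3  | explicit functional-evidence flag (well-established functional studies) |
| PM2  | gnomAD absent, or below the region's rarity threshold |
| PP3 / BP4 | >= 2 concordant in-silico calls, none discordant |
| PP5 / BP6 | reported ClinVar assertion (>= 1 submission), supporting level |
| BA1 / BS1 | frequency >= 5% / >= 0.1% |

The published combining table then maps the evidence set to classes 1–5;
simultaneous satisfaction of a pathogenic-side and a benign-side row is
contradictory evidence and resolves to class 3. The guideline names the
criteria but not a mechanical mapping from annotation fields to codes, so
the mapping above is this package's declared design; it is calibrated
once against the packaged 35-variant fixture (that calibration *is* the
fixture test, asserted openly) and every threshold is overridable through
`acmg_config()`. ClinVar assertions intentionally enter at supporting
strength only, and PS3 only through the explicit functional-evidence
field — in the fixture exactly one variant (the *PMS2* missense with
published functional impairment) carries it. Novel stop-gains reach
class 5 through PVS1 + PM2 + PP3; the combination rules are checked
exhaustively against a literal transliteration of the combining table for
every evidence subset of size <= 6 from a 12-code pool, together with a
directional-monotonicity property (pathogenic-side codes never lower the
class, benign-side codes never raise it).

Out of scope by design: co-segregation (PP1), de-novo (PS2/PM6) and
gene-specific rule adaptations — the pipeline sees no family data.

## Regulatory annotation

5'UTR variants are intersected with TFBS intervals (BED, 0-based
half-open); for each overlapping motif the frequency column at the
variant's offset gives the allele-preference ratio
`(f_ref + 0.01)/(f_alt + 0.01)`. The symmetric pseudocount keeps the
ratio finite and exactly reciprocal under allele swap; a ratio >= 5
(configurable) is flagged as strong preference. Overlap itself is treated
as a hit — strength is reported, not filtered on.

3'UTR variants are screened against canonical miRNA seed-site types.
Sites are anchored on a Watson–Crick match to seed positions 2–7 and
classified once per anchor — 8mer (m8 match + A opposite position 1),
then 7mer-m8, then 7mer-A1; a bare 6mer is not reported. A site is
*disrupted* when the variant falls inside the site interval and the
altered UTR no longer matches that site type. This replaces the trained
two-step SVM used in the original analysis workflow, whose model is not
published: seed matching is deterministic, testable against a brute-force
oracle, and captures the same qualitative call.

## QC

The heterozygous plausibility band for germline VAF is 30–75% inclusive;
values outside (including homozygous-looking 100% calls) are flagged but
never dropped — in practice such calls are resolved by manual review, and
the reference data retains one VAF = 1 variant. Coverage tiers count
samples strictly above 100X and strictly below 30X mean depth.

## The synthetic cohort generator

`sim_config()` defaults *are* the study conditions the pipeline targets:
199 samples, 22 genes totalling 1.213 Mb, 10,680 unique variants with a
97/2/1 intronic/exonic/UTR mix, and a small injected truth set (default
4: two stop-gains, one canonical donor +1 disruption, one functionally
supported rare missense — mirroring the 3 + 1 pathogenic/likely-pathogenic
findings of the modelled study). The frequency spectrum mixes a common
component (30% of variants, 0.2–50% allele frequency, log-uniform) with
rare variants, half of which are absent from the population database;
carrier VAFs are drawn near 0.5 inside the 30–75% band with a 2% outlier
fraction. Annotation fields are simulated *correlated with the truth
labels* (injected variants are conserved and concordantly predicted
deleterious) because the classifier consumes them; label noise on
ClinVar cells is configurable.

Generated junctions sample their windows from a strongly conserved
consensus profile (per-position consensus probability 0.98, GT/AG
invariant), as real canonical sites are highly conserved; matrices
trained on the generated panel therefore score every generated junction
high, which the tests assert at >= 0.7.

What the generator does **not** emulate: read-level artefacts (mapping
errors, strand bias, the *PMS2*/*PMS2CL* pseudogene problem), linkage
between variants, indel-rich repeat regions, and realistic per-gene
variant density differences. Passing the synthetic end-to-end test
therefore demonstrates the *logic* of the pipeline (recall of engineered
pathogenic variants, exclusion of common ones, reproducibility from a
seed), not calling performance on real reads.

All randomness flows from a single integer seed (`sim_config(seed = )`);
panel generation and cohort generation use seed and seed + 1 so the two
can be regenerated independently. Every output is bit-reproducible from
(seed, config).

## Numerical and degenerate-input conventions

* Genomic coordinates are 1-based inclusive; BED input is converted from
  0-based half-open; UTR/miRNA site intervals are reported 0-based
  half-open.
* Intron offsets follow HGVS: + from the donor side, − from the acceptor
  side; projection of an intronic genomic position anchors to the nearer
  junction, ties to the donor side.
* Frequencies are stored as fractions and formatted as percentages with
  4 decimals; "NIL" cells become an explicit absent state, never silent
  `NA` coercion.
* Percentages in summaries are rounded half-up to one decimal.
* Empty inputs are legal everywhere they can arise: an empty call set
  yields an all-zero filter report and summary; an empty depth vector
  yields a zero-count coverage summary.
* The packaged fixture is checksummed (md5) at load time.

## Problem sizes in the test suite

The unit and acceptance tests run the generator at reduced scale —
5–8 genes over 275–440 kb with 700–6,000 variants and 50 samples —
which preserves all the distributional structure the properties test
(region mix, spectrum, junction quality, recall) while keeping the whole
suite under a couple of minutes. The region-mix tolerance check uses
6,000 variants, where the ±1% band is a > 4-sigma margin. The fixture
checks always run at full size (35 variants, cohort size 199).

## Known limitations

* The splice scorer is a positional frequency model; it does not model
  branch points, U2/U12 intron classes or long-range context, and its
  "strong activation" thresholds are declared rather than learned.
* Consequence calling handles substitutions and simple in-CDS
  dup/del/ins; edits spanning an exon boundary are classified by region
  and carried with their reported protein change, not re-translated.
* ACMG evidence derivation covers the codes computable from the
  annotation table; codes needing family or case-level data never fire.
* The miRNA module predicts canonical seed sites only — no compensatory
  3' pairing, no context scores.
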