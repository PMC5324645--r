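---
title: "Formula assignment and interactive van Krevelen reports: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formula assignment and interactive van Krevelen reports: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vankrev)
```

## The problem

Ultra-high-resolution mass spectrometry (FTICR MS) of complex mixtures —
dissolved and soil organic matter, petroleum, aerosols, whisky — produces
centroid spectra with thousands of resolved peaks between roughly m/z 200 and
700. At ppm-to-ppb mass accuracy, most peaks can be assigned a unique neutral
molecular formula C~c~H~h~N~n~O~o~S~s~(P~p~). The assigned formulae are then
interrogated through a small set of standard derived quantities and plots:
the van Krevelen diagram (H/C against O/C, one point per formula), double
bond equivalents (DBE) against carbon number, the modified aromaticity index
(AI~mod~) against carbon number, heteroatom class distributions, and an
assignment-coverage overlay separating monoisotopic assignments, ^13^C
isotopologues and unassigned peaks.

This package implements the full chain: candidate formula generation with
heuristic chemical filtering, automated assignment of whole peak lists by
Kendrick mass defect / z* homologous-series analysis, ^13^C~1~ isotopologue
annotation, the three-text-file exchange convention, a standalone interactive
multi-tab HTML report with four linked panels, and a deterministic synthetic
spectrum generator with known ground truth for validation.

## Exact-mass chemistry

All masses derive from a pinned table of most-abundant-isotope masses
(^12^C = 12 exactly, ^1^H = 1.0078250319, ^14^N = 14.0030740052,
^16^O = 15.9949146221, ^32^S = 31.97207069, ^31^P = 30.97376151 Da), so
results are bit-stable across platforms. Ion/neutral conversion for the
supported [M−H]^−^ and [M+H]^+^ ESI species uses the proton mass 1.0072765 Da
— i.e. it accounts for the electron, which matters at the sub-ppm accuracy
the instruments deliver (the electron is 0.55 mDa, about 1.4 ppm at m/z 400).

The derived quantities are

* DBE = 1 + c − h/2 + n/2 + p/2 (oxygen and sulfur do not contribute;
  phosphorus is counted at its trivalent baseline and is disabled by default
  in the search ranges);
* AI~mod~ = (1 + c − 0.5 o − s − 0.5 h) / (c − 0.5 o − s − n − p), the
  conservative aromaticity estimate that treats half the oxygen as
  carboxyl-like. Degenerate inputs (denominator ≤ 0 or negative numerator)
  are clamped to 0 rather than propagated as NaN, so every formula has a
  plottable value;
* Kendrick coordinates on the CH~2~ scale: kendrick mass = m/z × 14/m(CH~2~),
  KMD = nominal − kendrick mass with nominal = round-half-up, and
  z* = (nominal IUPAC mass mod 14) − 14. The sign convention (KMD positive
  for typical CHO compounds) follows dominant petroleomics usage; all series
  logic depends only on the invariance of KMD and z* along a CH~2~ ladder,
  which holds under either sign choice. Round-half-up affects only
  pathological masses ending exactly in .5.

## Candidate generation

`generate_candidates()` enumerates every formula in a per-element count
lattice (defaults C 1–100, H 0–200, N 0–5, O 0–30, S 0–2, P 0–0) whose exact
mass falls within a ppm window of a target neutral mass, then filters by
heuristic plausibility rules in the spirit of the "golden rules" used for
small-molecule formula assignment:

| rule | default | rationale |
|---|---|---|
| valence cap | h ≤ 2c + 2 + n + p | saturated acyclic bound |
| H/C window | 0.3–3.0 | covers condensed aromatics to saturated chains |
| O/C cap | ≤ 1.2 | carbohydrate-like upper bound |
| N/C cap | ≤ 0.5 | generous for NOM |
| S/C cap | ≤ 0.2 | generous for NOM |
| DBE | integer, ≥ 0 | chemical realisability |
| parity | even-electron neutral | implemented as "DBE is a non-negative integer", equivalent to the nitrogen rule for even-electron neutrals |

Every rule is toggleable. Internally the heteroatom counts are iterated and
the admissible hydrogen range is solved analytically from the mass window;
the test suite proves this is output-equivalent (membership *and* order) to
naive full enumeration. Candidates are sorted by |ppm error| with
deterministic tie-breaks (fewer heteroatoms, fewer O, Hill string). A
configurable cap (default 10,000) turns pathological windows into a classed
error instead of an unbounded enumeration.

`min_candidate_spacing()` reports the smallest mass gap between surviving
candidates around a given m/z — the standard diagnostic for choosing an
assignment tolerance: a threshold safely below the local spacing makes
assignment unambiguous at that mass.

## Homologous-series assignment

`assign_formulas()` implements the canonical petroleomics realisation of
KMD/z* series assignment:

1. **Group.** Peaks are stratified by z*; within a stratum, single-linkage
   clustering on KMD (sort, cut at gaps > `kmd_tol`, default 5·10^−4^)
   yields the homologous series. With 0.2 ppm mass error a peak's KMD moves
   by about 10^−4^ at m/z 500, so the default comfortably holds series
   together without bridging neighbours.
2. **Seed.** Within each series, each member's candidate list is generated at
   the stricter `tol_ppm_seed` (default 0.5 ppm). The member with the fewest
   (non-zero) candidates seeds the series — ties go to the most intense
   member, then the lowest m/z — and its best candidate becomes the seed
   formula. Seeding from the least ambiguous member, rather than the most
   intense or lowest-mass one, is the design choice here; it directly
   minimises the chance of seeding a whole series from an ambiguous match.
3. **Propagate.** Every other member receives seed ± k·CH~2~ (k from the
   rounded mass offset), accepted only if the implied counts are in range,
   every enabled rule passes, and the observed m/z matches within
   `tol_ppm_member` (default 1.0 ppm). Members that fail stay unassigned.
4. **Isotopologues.** Among still-unassigned peaks, a ^13^C~1~ satellite is
   sought for each assigned parent at +1.0033548 Da (within
   `tol_ppm_member`) with intensity inside [0.2, 3.0] × the expectation
   c × 1.07% × parent intensity. The wide band is deliberate — centroid
   intensities are noisy — and configurable. Each leftover peak attaches to
   at most one parent (closest in ppm). Secondary isotopologues (two ^13^C,
   one ^18^O) are not searched and legitimately remain unassigned.

The three outputs — monoisotopic assignments, isotopologue annotations,
remaining unassigned peaks — always partition the input peak list, and the
whole procedure is deterministic for a fixed configuration.

`min_rel_intensity` defaults to 0: the dense low-abundance "grass" carries
most of a complex mixture's chemical diversity, so nothing is discarded
unless the user asks.

## The synthetic mixture generator

`make_mixture()` emulates the features of a negative-mode SRFA-type spectrum
that matter to the assignment problem: 50 CH~2~-homologous series (5–15
members) drawn from the rule-passing CHO/CHNO/CHOS lattice with weights
0.7/0.2/0.1, ion m/z confined to 200–700, Gaussian mass error of 0.2 ppm,
one ^13^C~1~ satellite per parent at c × 1.07% × parent intensity with 5%
log-normal ratio noise, log-normal parent intensities (a few dominant peaks
over heavy grass), and 100 noise peaks. These defaults are the package's
study conditions; the acceptance checks run against them unchanged.

Two generator design choices deserve note. Series are placed so that their
(z*, KMD) strata — and the strata their satellites will occupy — are mutually
separated by at least 0.002 in KMD, as distinct homologous series are in real
spectra; without separation, two coincident series would merge into one
cluster and the CH~2~ propagation could not serve both. Noise peaks are
constrained to be genuinely unassignable: at least 3 ppm from every true
peak and with no rule-passing candidate within 2 ppm, which is what "noise"
means to an assignment pipeline (a peak that happens to sit on a lattice mass
is chemistry, not noise).

What the generator does **not** emulate: mass-dependent error correlation
(miscalibration), peak coalescence and shoulders, space-charge shifts,
secondary isotopologues, adducts and multiply charged species, and
detector-limited dynamic range. Passing tests on these fixtures therefore
demonstrate the correctness of the series logic, generator and bookkeeping
under clean conditions — not robustness to instrument artefacts.

## Known limitation: exotic substitutions can mimic the ^13^C shift

With nitrogen and sulfur enabled at their default maxima, the lattice
substitution −6C +3H +5N −4O +2S reproduces the ^13^C−^12^C mass difference
to within 27 µDa (≈ 0.09 ppm at m/z 300). Satellite ladders of large CHO
parents (c ≥ 16, o ≥ 4) can therefore be formally matched by N~5~S~2~-type
formulae within a 1 ppm tolerance, and since the assigner deliberately
assigns monoisotopic series before isotopologues, such satellites are
reported as (chemically implausible) monoisotopic assignments rather than as
isotopologues. This is a genuine ambiguity of exact-mass assignment, not a
bookkeeping error; practitioners avoid it by restricting element ranges to
what the sample can plausibly contain (for pure CHO/CHNO material, set
`element_ranges(S = c(0, 0))` or lower `nc_max`/`sc_max`), or by inspecting
the heteroatom class distribution, where such artefacts stand out as
N~5~S~2~-class towers. The parent formulae themselves are unaffected —
recovery of true monoisotopic formulae is complete on the study conditions —
and the limitation is visible, by design, in the coverage overlay.

## The HTML report

`build_report()` writes one self-contained HTML document (no external
resources; hyperlinks to ChemSpider fire only when clicked). A single JSON
record store — one record per monoisotopic assignment, indexed 0…n−1 — is
embedded once and feeds all views: the van Krevelen panel (colour = m/z,
size = relative abundance, square-root scaled so glyph *area* is linear in
abundance), the centroid spectrum, DBE vs C# and AI~mod~ vs C# (colour =
oxygen number), the coverage overlay, and the data table. Selection is a
shared set of record indices, so brushing in any panel highlights the same
formulae everywhere including the table; this index-based contract is what
makes desynchronisation impossible. Hover shows formula, m/z, intensity,
ppm error, DBE, AI~mod~ and class; clicking a selected glyph opens the
record's ChemSpider formula search. For 10^4^ records the document stays
under ~3 MB (about 250 bytes per record plus a fixed ~20 kB runtime).

Static `batch_static_plots()` figures use the same encodings via base
graphics on cairo devices; vector output is byte-deterministic for a fixed
model.

## Problem sizes and runtimes

The test suite validates the generator against a brute-force enumeration
oracle on 100 random (mass, tolerance) queries over a ~230,000-formula
lattice, and runs the full pipeline on mixtures of 5–50 series
(≈ 80–1100 peaks). The complete study-condition pipeline — generation,
assignment, annotation, report — runs in well under a minute on one core;
the dominant cost is candidate generation during seeding, which is vectorised
over the heteroatom grid.

## Defaults at a glance

| parameter | default | unit | meaning |
|---|---|---|---|
| `tol_ppm_seed` | 0.5 | ppm | candidate window for series seeding |
| `tol_ppm_member` | 1.0 | ppm | acceptance for propagation and isotopologues |
| `kmd_tol` | 0.0005 | — | KMD link threshold within a z* stratum |
| `min_rel_intensity` | 0 | fraction of base peak | keep the grass |
| isotopologue band | [0.2, 3.0] | × expected ratio | tolerant to centroid intensity noise |
| candidate cap | 10,000 | formulae | bound on pathological windows |
| element ranges | C 1–100, H 0–200, N 0–5, O 0–30, S 0–2, P 0 | counts | NOM-appropriate lattice |
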