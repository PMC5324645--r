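# vankrev

Molecular formula assignment and interactive van Krevelen reports for
high-resolution mass spectrometry of complex mixtures.

Ultra-high-resolution (FTICR) mass spectra of natural organic matter,
petroleum, aerosols or aged beverages contain thousands of resolved centroid
peaks, most of which can be assigned a unique neutral formula
C<sub>c</sub>H<sub>h</sub>N<sub>n</sub>O<sub>o</sub>S<sub>s</sub> at ppm-level
mass accuracy. `vankrev` is for the analysts who make and review those
assignments. It provides:

* **Exact-mass chemistry** — monoisotopic masses from a pinned isotope table,
  [M−H]⁻/[M+H]⁺ conversion including the electron, DBE
  (1 + c − h/2 + n/2 + p/2), the modified aromaticity index
  AI<sub>mod</sub> = (1 + c − 0.5o − s − 0.5h)/(c − 0.5o − s − n − p),
  elemental ratios, Kendrick mass, Kendrick mass defect (KMD) and z*.
* **A candidate formula generator** with heuristic plausibility filtering
  (valence cap, H/C, O/C, N/C, S/C windows, integer non-negative DBE,
  even-electron parity), plus the minimum-candidate-spacing diagnostic for
  choosing assignment tolerances.
* **Automated peak-list assignment** by CH₂ homologous series: peaks are
  grouped on shared (z*, KMD), each series is seeded from its least ambiguous
  member, the seed formula is propagated ±kCH₂ along the series, and ¹³C₁
  isotopologues are annotated among the remainder. The result partitions
  every input peak into monoisotopic / isotopologue / unassigned.
* **The three-text-file exchange convention** (assigned, isotopologues,
  unassigned) for interoperability with other assignment software, in either
  direction.
* **A standalone interactive HTML report** — van Krevelen, centroid spectrum,
  DBE vs C#, AI<sub>mod</sub> vs C# as four linked panels fed by one embedded
  record store (brushing in any panel highlights the same formulae in all
  panels and the data table), an assignment-coverage overlay, hover readouts,
  ChemSpider formula-search hyperlinks, and a downloadable data table — plus
  batch publication-quality static figures.
* **A deterministic synthetic-spectrum generator** with complete ground
  truth, emulating an SRFA-like negative-mode spectrum (CH₂ series across
  m/z 200–700, ppm-scale mass error, ¹³C satellites, unassignable noise).

## Worked example

```r
library(vankrev)

# a synthetic SRFA-like spectrum with known ground truth
mix <- make_mixture(mixture_spec(n_series = 20, seed = 11))
mix
#> <synthetic_mixture> 502 peaks (isotopologue: 201, noise: 100, parent: 201)

set <- assign_formulas(mix$peaks)
summary(set)
#> Formula assignment summary
#> <assignment_set>
#>   peaks:         502
#>   monoisotopic:  335
#>   isotopologues: 67
#>   unassigned:    100
#>   m/z range:     201.1860 - 639.2852
#>   |error| ppm:   median 0.160, max 0.999
```

All 201 true parent formulae are among the monoisotopic assignments with
sub-ppm error; the 100 noise peaks all land in `unassigned`. (The extra
monoisotopic rows are ¹³C satellites of large CHO parents formally matched by
exotic N₅S₂-type formulae — a genuine exact-mass ambiguity discussed in the
methods vignette, and the reason element ranges should be narrowed to the
chemistry a sample can actually contain.)

```r
# candidate generation and the spacing diagnostic
generate_candidates(198.0528234, tol_ppm = 1)
#>   formula C  H N O S P calc_mass    error_ppm
#> 1 C9H10O5 9 10 0 5 0 0  198.0528 0.0001489502

sp <- min_candidate_spacing(499, "neg", 20, element_ranges(N = c(0, 0), S = c(0, 0)))
#> min spacing at m/z 499: 5.8732 mDa (11.75 ppm) between C25H8O12 and C18H12O17
```

A 1 ppm tolerance is therefore unambiguous for CHO assignments at m/z 499 —
the nearest candidates sit ~12 ppm apart.

```r
# three-file convention, report, figures
write_assignment_set(set, "srfa")          # srfa_assigned.tsv, srfa_isotopologues.tsv, srfa_unassigned.tsv
model <- build_report_model(set)
build_report(model, "report.html")         # self-contained, three tabs, linked panels
export_data_table(model, "records.tsv")
batch_static_plots(model, "figs", c("svg", "png"))
```

A thin command-line wrapper covers the same pipeline:

```sh
ivk synth --series 50 --sigma-ppm 0.2 --seed 1 --out peaks.csv --truth truth.tsv
ivk assign peaks.csv --seed-ppm 0.5 --ppm 1.0 --out run
ivk classes run_assigned.tsv
ivk plot run --out report.html --static-dir figs
```

File schemas are documented in `docs/formats.md`; the science and every
tunable default are described in `vignettes/formula-assignment.Rmd`.

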