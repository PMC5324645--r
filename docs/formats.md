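# File formats

All files are plain delimited text. `vankrev` writes tabs; readers accept
comma- or tab-delimited input (peak lists additionally whitespace), so files
produced by any software matching these column schemas can be used.

## Centroid peak list (input)

Two columns, header optional, any of comma/tab/whitespace delimiters:

| column | type | unit |
|---|---|---|
| mz | float | Th |
| intensity | float | arbitrary, ≥ 0 |

Rows that fail to parse abort the read with their line numbers. Duplicate
m/z values are collapsed to the maximum intensity with a warning.

## Three-file assignment convention

Written by `write_assignment_set(set, prefix)` as `<prefix>_assigned.tsv`,
`<prefix>_isotopologues.tsv`, `<prefix>_unassigned.tsv`; read back by
`read_assignment_set(prefix)`. Floating m/z values carry 7 decimals
(sub-ppb at m/z 700), ppm errors 3 decimals. A missing isotopologue file is
treated as empty. Extra columns are preserved as opaque annotations.

### `<prefix>_assigned.tsv` — monoisotopic peak assignments

| column | type | meaning |
|---|---|---|
| mz | float, 7 dp | observed m/z, Th |
| intensity | float, 4 dp | observed intensity |
| formula | text | neutral formula, Hill notation (`C9H10O5`) |
| calc_mz | float, 7 dp | calculated ion m/z |
| error_ppm | float, 3 dp | signed (observed − calc)/calc × 10⁶ |
| C H N O S P | integer | element counts of the neutral formula |
| dbe | float, 1 dp | double bond equivalents |
| ai_mod | float, 4 dp | modified aromaticity index |
| hc | float, 4 dp | H/C |
| oc | float, 4 dp | O/C |
| class | text | heteroatom class label (`O5`, `N1O3`, `CH`) |
| provenance | text | `seed` or `propagated` |

### `<prefix>_isotopologues.tsv` — isotopologue annotations

| column | type | meaning |
|---|---|---|
| mz | float, 7 dp | observed satellite m/z |
| intensity | float, 4 dp | observed intensity |
| parent_mz | float, 7 dp | observed m/z of the monoisotopic parent |
| parent_formula | text | parent's neutral formula |
| isotope | text | `13C1` |
| ratio_obs_exp | float, 4 dp | observed / expected intensity ratio |

### `<prefix>_unassigned.tsv` — remaining detected peaks

| column | type |
|---|---|
| mz | float, 7 dp |
| intensity | float, 4 dp |

## Report data table (`export_data_table`)

One row per monoisotopic assignment, identical to the records embedded in
the HTML report, stable column order:

`index, mz, intensity, rel_intensity, formula, C, O, hc, oc, dbe, ai_mod,
error_ppm, class, region, chemspider`

`index` is the 0-based shared key used for linked selection; `region` is the
van Krevelen compound-class region label; `chemspider` is the ChemSpider
formula-search URL.
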