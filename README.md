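# multirose

Layout and rendering for **multidimensional rose charts** — a polar-area
(Nightingale / coxcomb) generalisation for rectangular category ×
attribute tables — plus their **stacked** variant, where each category is
a single petal whose attributes pile up as radial layers. The package
computes a renderer-independent chart model (petal geometry, value-shaded
colours, extreme-value labels, legend, centre text), renders it to
deterministic standalone SVG, exports it as JSON for external front ends,
and ships a command-line interface.

It is aimed at anyone who needs a compact visual comparison of several
numeric attributes across a handful of categories — the bundled case
study compares four COVID-19 rates (death, infection, vaccination,
complete vaccination, all in %) across six countries.

## The method

Given an `n_cat × n_attr` table of non-negative values `v[c, a]`:

**Flat chart.** The circle is split into `n_attr` equal sections of
`360 / n_attr` degrees, one per attribute; each section is split into
`n_cat` petals of `360 / (n_attr · n_cat)` degrees, one per category
(4 attributes × 6 categories → four 90° sections of six 15° petals).
Every petal is an annular sector from `r_inner` to an outer radius that
encodes the (optionally rescaled) value against the global maximum
`v_ref`:

- *area mode* (default): `r = sqrt(r_inner² + (r_max² − r_inner²) · v / v_ref)`,
  so the petal's annular area — `(Δθ/2)(r_out² − r_in²)` — is
  proportional to the value (the classic polar-area convention);
- *linear mode*: `r = r_inner + (r_max − r_inner) · v / v_ref`, so the
  radial extent is proportional instead.

**Stacked chart.** One petal of `360 / n_cat` degrees per category; the
attributes are layers from the centre outward with cumulative radii
`r_k = r(Σ_{j≤k} v[c, j])` against `v_ref = max_c Σ_a v[c, a]`, so each
layer's thickness (linear) or annular area (area mode) encodes its own
value and the tallest petal reaches `r_max`.

**Colour.** Each attribute gets a base hue (default order red, yellow,
blue, green, …); within an attribute, petal lightness falls linearly from
0.85 at the column minimum to 0.35 at the column maximum — the smaller
the value, the lighter the colour. Normalisation is per attribute and
uses unscaled values.

**Labels.** To avoid the label occlusion that plagues dense rose charts,
only each attribute's maximum and minimum are annotated, at the petal
mid-angle just outside the rim; the chart centre (the "stamen") can show
one selected cell in full. Petals can be re-sorted by value, clockwise
(descending) or counterclockwise, without moving the slot boundaries.

## Worked example

```r
library(multirose)
m <- covid_fixture()         # the bundled 6-country x 4-rate table
m
#> <data_matrix: 6 categories x 4 attributes>
#>        Death Rate Infection Rate Vaccination Rate Complete Vaccination Rate
#> USA          1.18           9.37            75.28                     63.54
#> India        1.18           5.67            67.68                     50.95
#> Brazil       2.48          37.86            79.59                     70.06
#> UK           0.91           3.92            76.77                     71.02
#> France       0.69           7.90            79.79                     76.39
#> Russia       2.79           4.63            52.49                     47.85

cfg <- chart_config(kind = "flat", sort = "clockwise",
                    scale_factors = c("Death Rate" = 5, "Infection Rate" = 1.2))
model <- rose_chart(m, cfg)
model
#> <chart_model: flat, 24 petals, 8 labels, v_ref = 79.79>

model$labels[model$labels$attribute == "Death Rate",
             c("category", "kind", "text", "anchor_theta_deg")]
#>   category kind  text anchor_theta_deg
#> 1   Russia  max 2.79%              7.5
#> 2   France  min 0.69%             82.5

write_svg(render_svg(model), "covid_flat.svg")
```

24 petals (6 countries × 4 rates) in four 90° sections; `v_ref = 79.79`
is the largest value in the table (France's vaccination rate), so that
petal reaches `r_max`. The death-rate section is sorted clockwise, so its
maximum (Russia, 2.79%) sits in the first 15° slot and is labelled there;
the ×5 / ×1.2 scale factors enlarge the small death- and infection-rate
petals for legibility while the labels keep the unscaled values. The
stacked variant of the same table is
`rose_chart(m, chart_config(kind = "stacked"))` — 6 petals of 60°, four
layers each.

From a shell:

```sh
Rscript inst/scripts/rose.R --demo --kind flat --sort cw --paper-scaling -o covid_flat.svg
Rscript inst/scripts/rose.R generate --n-cat 6 --n-attr 4 --seed 7 --out synthetic.csv
Rscript inst/scripts/rose.R --input synthetic.csv --kind stacked -o synthetic.svg
```

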