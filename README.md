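# phcprofile

Regional health care profiles for primary health care catchment areas.

## The problem

When a new multi-professional primary health care unit (PHCU) is planned,
its founders must draw up a care strategy that matches the health needs of
the population it will actually serve. That population is not an
administrative unit: it is the *catchment area* — the set of municipalities
within a maximum car-travel time of the chosen location, deliberately not
bound by district borders. `phcprofile` generates the decision-support
document for this task: a multi-page **regional health care profile** for
any freely selectable location municipality, built from a catalogue of 35
indicators in five domains (demography/socio-economics, disease prevention
and risk factors, epidemiology and mortality, health care service supply,
outpatient care utilisation).

The intended users are health-services researchers and regional health
planners. Because the original data sources of such systems are restricted
administrative registers, the package ships a seeded synthetic country
generator at the Austrian scale — 2122 municipalities partitioned into 116
political districts — so the entire pipeline is runnable and testable with
fictive data.

## The method

For a location municipality $\ell$ and cutoff $t^\*$ (report levels 10, 15,
20 minutes), the catchment is the isochrone membership set on the weighted
municipality road network,

$$C(\ell, t^\*) = \{ m : d(\ell, m) \le t^\* \},$$

with $d(\cdot,\cdot)$ exact shortest-path car-travel minutes (Dijkstra).
Each of the 35 indicators is aggregated over $C$ according to its kind:
unweighted mean of municipal values (percentages, prevalences, rates, life
expectancies), sum (population, facility counts), ratio of sums
$\left(\sum_m x_m / \sum_m y_m\right)\cdot s$ for "X per Y" supply and
utilisation indicators, or the nearest-facility travel time from $\ell$.
The catchment value is then set against the distribution of the same
indicator over the 116 districts: values are winsorised at Tukey fences
$[Q_1 - 3\,\mathrm{IQR},\; Q_3 + 3\,\mathrm{IQR}]$ (type-7 quantiles),
summarised as total range, quartiles and median, compared with the national
value, and ranked — rank 1 is the most favourable position under the
indicator's polarity, ties take the best rank. The report is a printable
PDF: map page, a 35-row boxplot panel with overlaid circle (catchment) and
square (comparator district) glyphs and a red national reference line, a
results table (also written as a sidecar CSV with unrounded values), and
two pages of indicator definitions.

## Worked example

```r
library(phcprofile)

cat0 <- load_catalogue("default")
co   <- generate_country(seed = 1)          # Austria-scale fixture
p    <- build_profile(profile_request("M0042", 15, "D007"), cat0, co)
print(p)
r <- summary(p)
head(r[r$indicator_id %in% c("pop_total", "pct_65plus", "life_exp_men",
                             "inhab_per_gp", "time_to_hospital",
                             "n_pharmacies"), ])
```

```
Regional health care profile: location M0042, cutoff 15 min, comparator D007
  catchment: 5 municipalities; 35 indicators; 12 cleaned district values
       indicator_id catchment  national rank
1         pop_total  21468.00 5.376e+06  107
3        pct_65plus     25.48 2.158e+01   11
11     life_exp_men     78.31 7.875e+01   75
23     inhab_per_gp   1431.20 1.664e+03   25
28 time_to_hospital     13.80 1.746e+01   48
29     n_pharmacies      5.00 9.630e+02   80
```

Reading: the 15-minute catchment of municipality `M0042` holds 5
municipalities and about 21 500 inhabitants. Its share of residents aged
65+ (25.5 %) ranks 11th-highest among the 116 districts plus the catchment
— an ageing population arguing for geriatric-oriented services — while male
life expectancy (78.3 years) sits in the lower half (rank 75). One general
practitioner serves about 1430 inhabitants, better than the national 1660.
Twelve district values across all indicators were winsorised at the outlier
fences before summarising.

Rendering the full report:

```r
render_pdf(p, report_style(), "M0042_15min.pdf", co, cat0)
```

writes the 5-page PDF and `M0042_15min_table.csv`. A command-line front end
with `generate-fixture`, `profile`, `batch` and `validate` subcommands is
installed at `inst/cli/phcprofiler.R`.

The batch datapoint table — one row per (municipality, cutoff, indicator),
the precomputation that feeds the interactive generator — comes from
`generate_all_datapoints(cat0, co, c(10, 15, 20))`: 2122 × 3 = 6366 rows
per indicator, 222 810 in total, in a few seconds.

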