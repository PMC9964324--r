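# fpicpi

Gene-set potential indices for two metal-ion-mediated cell-death programs —
ferroptosis and cuproptosis — in bulk and single-cell transcriptomes, with
the full analysis pipeline around them: moderated differential expression,
co-expression module detection, Kaplan–Meier prognosis, and per-cell
subcluster contrasts. The motivating use case is hepatocellular carcinoma
cell lines treated with curcumin, where the two programs respond in a
cell-line-specific way.

## The indices

A potential index is built from a *directional gene-set pair*: positive
components that enable the death program and negative components that
suppress it. Per sample, each set is scored by single-sample gene set
enrichment (ssGSEA): genes are ranked by expression (highest of *N* genes
gets rank *N*), and

```
ES(S) = Σ_{i=1..N} [ P_in(i) − P_out(i) ]
P_in(i)  = Σ_{g∈S, pos(g)≤i} r_g^α / Σ_{g∈S} r_g^α
P_out(i) = #{g∉S, pos(g)≤i} / (N − |S|)
```

the integrated difference between the rank-weighted in-set CDF and the
uniform out-of-set CDF (α = 0.25 by default). The index is then

```
index = normalize( ES(positive) − ES(negative) )
```

z-scored across the samples of one call. The **CPI** (Cuproptosis Potential
Index) ships with built-in components — positive PDX1, LIAS, LIPT1, DLD,
DLAT, PDHA1, PDHB; negative MTF1, GLS, CDKN2A (an FDX1 variant of the
positive set is also bundled) — while the **FPI** (Ferroptosis Potential
Index) loads its driver/suppressor pair from a GMT file: the sets are data,
not code.

## Worked example

Score the CPI on a synthetic cohort that mirrors the assumed design (three
cell lines × control/curcumin × three replicates) with a planted +2 SD
shift on the positive components in treated samples:

```r
library(fpicpi)

defn <- cpi_definition()
cfg <- bulk_sim_config(
  n_genes = 1000,
  index_shift = data.frame(cell_line = c("PLC", "KMCH", "Huh7"),
                           treatment = "curcumin",
                           component = "positive", shift = 2),
  index_genes = defn$pair, seed = 42)
sim <- simulate_bulk(cfg)

res <- compute_index(sim$expr, defn, meta = sim$meta)
head(res, 4)
#>        sample_id raw_difference index_value cell_line treatment
#> 1  PLC_control_1       76.74786  -0.3153341       PLC   control
#> 2  PLC_control_2      -75.28738  -1.4728469       PLC   control
#> 3  PLC_control_3       53.30999  -0.4937772       PLC   control
#> 4 PLC_curcumin_1      229.13535   0.8448604       PLC  curcumin

compare_groups(res, by = "treatment")
#>   group_a  group_b n_a n_b statistic           p significance_code
#> 1 control curcumin   9   9        48 0.001086247                **
```

`raw_difference` is ES(positive) − ES(negative) per sample; `index_value`
is its z-score across the 18 samples. The planted positive-component shift
raises the treated group's CPI, and the two-sided Wilcoxon rank-sum test
across 9 treated vs 9 control samples flags it at p ≈ 0.001 (`**`).

The other stages follow the same pattern: `moderated_t_test()` +
`intersect_degs()` for DEGs gated at |log2FC| > 1 and BH-adjusted p < 0.05;
`pick_soft_threshold()` / `detect_modules()` / `module_trait()` for
co-expression modules (unsigned TOM, power 21, minimum size 30, merge cut
0.25); `km_fit()` / `logrank_test()` / `dichotomize_by_expression()` for
expression-dichotomized prognosis; `score_cells()` /
`compare_subclusters()` for per-cell indices across labelled subclusters;
and `run_pipeline()` to drive everything from one YAML or list config with
a reproducibility manifest.

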