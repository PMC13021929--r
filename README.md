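# cutTagGro

Integrated analysis of transcription-factor chromatin binding
(CUT&Tag) and nascent transcription (GRO-seq) for studies of
GGAA-driven oncogenic transcription factors and the drugs that
modulate them.

## The problem

An ETS-family fusion transcription factor binds GGAA-containing
response elements — long `(GGAA)n` microsatellite enhancers, isolated
single GGAA motifs, and heterotypic "tandem" sites where a GGAA sits
within 200 bp of a cofactor motif (AP-1, RUNX2, E2F, FLI1-core) — and
drives a characteristic transcriptional program. A DNA-binding drug
can disturb this program through two distinct mechanisms that
steady-state RNA measurements cannot distinguish:

* **altered initiation** — polymerases start less (or more) often, so
  nascent signal moves uniformly along the gene; or
* **impaired processivity** — polymerases start but attrit with
  distance, producing a downward slope from TSS to TES that hits long
  genes hardest.

`cutTagGro` quantifies both readouts and joins them per response
element. For a gene with TSS/body/TES windows
`[TSS-300, TSS+30)`, `[TSS+30, TES-30)`, `[TES-30, TES+300)` (sense
strand, 5'-end counting), the core statistic is the elongation index

    EI   = log2((TES_cpm + 1) / (TSS_cpm + 1))
    dEI  = EI_treated - EI_control

which cancels initiation changes and, for an added attrition of
`dkappa` per kb on a gene of `L` kb, converges to
`log2(exp(-dkappa * L))`. Differential binding per peak is a
pseudocounted log2 CPM ratio with a moderated-t p-value and
Benjamini–Hochberg FDR; targets of the factor are classified from a
knockdown DE table at |log2FC| >= 1, adjusted p < 0.01; QC includes
FRiP, Spearman replicate correlation and cumulative-hypergeometric
motif enrichment. A negative-binomial simulator generates genomes
with planted elements, reads and fragments under known
initiation/attrition/occupancy truth so every estimator is validated
by parameter recovery.

## Worked example

```r
library(cutTagGro)

# a complete synthetic experiment: low-concentration-exposure preset
cfg <- simConfig(seed = 1)
res <- runPipeline(pipelineConfig(preset = "lce", seed = 1))

res$report$n_planted_elements
#> [1] 300
signif(res$report$metagene_body_slope, 2)
#> [1] 0.00025
res$tes$tests
#>       class            p
#> 1   induced 1.171880e-09
#> 2 repressed 8.881483e-10
#> 3   neither 8.509228e-04
round(res$report$mean_delta_ei_by_tertile, 3)
#>  small medium  large
#>  0.034  0.045  0.038
head(res$binding[res$binding$significant, c("peak_id", "log2fc", "fdr")], 3)
#>    peak_id    log2fc          fdr
#> 1 elem_001  2.605314 1.024365e-11
#> 2 elem_002  1.529333 9.439956e-07
#> 3 elem_003 -2.239902 1.749611e-10
nrow(res$master)
#> [1] 12195
```

Read it as: the initiation-only preset leaves the metagene body slope
at zero (no processivity impairment) while strongly repressing the
planted induced targets at the TES (rank-sum p ~ 1e-11) and leaving
the tertile delta-EI profile flat; differential binding recovers the
planted occupancy shifts peak by peak. Under the attrition preset
(`preset = "hce"`) the slope turns negative and mean delta-EI orders
large < medium < small.

The element-level join lives in `res$master`: one row per discovered
element with its class, nearest gene, target class, binding
log2FC/FDR, delta-EI, TES log2FC and antisense statistics.

A thin command-line wrapper over the same functions ships in
`inst/scripts/ctg.R` (subcommands `simulate`, `motifs`, `targets`,
`bind`, `gro`, `run`).

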