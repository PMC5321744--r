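# nucdis

Transcription-coupled nucleosome disassembly analysis from ChIP occupancy
data.

## The problem

Elongating RNA polymerase II (RNAPII) must pass through the nucleosomes
positioned over gene bodies. In fission yeast, the chromatin remodeller
Fun30/Fft3 localises to transcribing regions and, together with the histone
chaperone FACT, disassembles nucleosomes ahead of the polymerase; FACT then
reassembles them behind it. Because most transiently disassembled
nucleosomes are immediately reassembled, the *loss* of histone H3 visible in
a remodeller deletion mutant (`fft3Δ`) is only a faint, distorted readout of
the underlying *disassembly* activity — the H3 change barely correlates with
transcription even when the disassembly it reflects is strictly
transcription-coupled.

`nucdis` implements the steady-state decomposition that untangles this. For
every gene, disassembly is written as

    D = L + R

where `D` is the steady-state fraction of gene-body nucleosomes disassembled
by transcription, `L` the fraction lost (not immediately reassembled) and
`R` the fraction immediately reassembled. With two further assumptions —
loss in the remodeller-null mutant is proportional to wild-type loss
(`L_fft3 = x · L_wt`, `x = 1 − x′`), and reassembly is abolished in the
FACT-defective mutant (`R_spt16 ≈ 0`, so `D_spt16 = L_spt16`) — the two
observable H3 occupancy-change vectors determine the reassembly-null
disassembly up to the unknown remodeller contribution `x′`:

    D_spt16(x′) = ΔH3_fft3 / x′ − ΔH3_spt16

Since disassembly must be transcription-coupled, `x′` is estimated by grid
search as the value maximising the Pearson correlation between
`D_spt16(x′)` and RNAPII occupancy. The per-gene values at the optimum are
the remodeller-attributable disassembly levels `x′·D_wt`, on an arbitrary
scale.

Around this core the package provides the standard supporting stages:
gene-level `log2(IP/INPUT)` quantification of coverage tracks over ORFs,
mutant/WT occupancy changes, scale-regions metagene matrices (TSS/TES
anchored), k-means gene classification, threshold gene sets with
hypergeometric overlap tests, Pearson/Tukey statistics, and a seeded
synthetic-cohort generator with latent ground truth so the whole pipeline is
testable without external data.

## Worked example

```r
library(nucdis)

cfg    <- generatorConfig(n_genes = 2000, seed = 42)   # true x' = 0.84
cohort <- generateCohort(cfg, tracks = FALSE)
obs    <- observablesFromTable(cohort@geneTable)
est    <- estimateContribution(obs)
est
#> ContributionEstimate: x-hat = 0.96 (r = 0.797) over 2000 genes
#>   curve flatness 0.211 (identifiable at tol 0.001)

lev <- fun30DisassemblyLevels(est)
pol <- occupancyColumn(cohort@geneTable, "pol_wt")
pearsonR(occupancyColumn(cohort@geneTable, "dH3_fft3"), pol)$r
#> [1] 0.5707202
pearsonR(lev, pol)$r
#> [1] 0.7966727
```

The raw H3 loss correlates weakly with transcription (r = 0.57) while the
reconstructed disassembly correlates strongly (r = 0.80) — the qualitative
signature of transcription-coupled disassembly masked by efficient
reassembly. The point estimate `x-hat = 0.96` overshoots the generating
value 0.84: the r(x′) curve is nearly flat above its optimum at high
contributions, so the argmax carries several grid steps of sampling scatter
(quantified in the methods vignette). The `identifiable` flag guards
against the fully degenerate case — when loss is strictly proportional to
disassembly across genes, the curve is exactly flat and no contribution can
be inferred.

A complete run (tracks, quantification, metagene, classification, model,
report) is one call:

```r
report <- runPipeline(pipelineConfig("out", seed = 1,
                                     generator = list(n_genes = 1500)))
```

or, from a shell, `Rscript inst/scripts/nucdis-pipeline.R --outdir out
--seed 1`. Real data enter either as bedGraph coverage plus a GFF3/BED
annotation, or as a pre-computed gene table (TSV with columns `gene_id`,
`dH3_fft3`, `dH3_spt16`, `pol_wt`).

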