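# cernakit

Competing endogenous RNA (ceRNA) network inference for two-group RNA-seq
experiments, with a first-class synthetic-data generator so every stage can
be validated against planted ground truth.

## The problem

Circular RNAs (circRNAs) can act as molecular sponges: by carrying binding
sites for a miRNA they sequester it and relieve the repression of that
miRNA's mRNA targets. Studies of this regulation — the motivating design is
grazing (G) versus indoor-fed control (C) sheep skeletal muscle, five
biological replicates per group — follow a standard pipeline:

1. **Back-splice junction calling.** Reads that fail contiguous alignment
   are split into terminal 20-mer anchors; anchors aligning uniquely in
   head-to-tail orientation (right anchor upstream of left) indicate a
   circRNA junction, confirmed by reconstructing the read from the doubled
   circular segment. A call needs at least two *distinct* supporting read
   sequences in at least one sample, and is typed against the annotation
   (annot-exon, exon-intron, one-exon, intron, antisense, intergenic).
2. **Normalization and differential expression.** RPM for circRNAs, TPM for
   miRNAs; a negative-binomial Wald test per feature; differential at
   |log2FC| ≥ 1 and p < 0.05.
3. **Dual target prediction.** A seed-match scan (miRNA positions 2–8) and a
   miRanda-style duplex aligner (score ≥ 140, energy ≤ −10 kcal/mol, strict
   5′ seed pairing, gap open −4, gap extend −9), intersected per
   (miRNA, target) pair.
4. **Network assembly.** Sponge legs must correlate negatively
   (Spearman ρ < −0.5), the circRNA–mRNA leg positively (Pearson r > 0.7),
   all at p < 0.05; a (circRNA, miRNA, mRNA) triple needs all three legs
   with a shared miRNA.
5. **Over-representation analysis** of the resulting gene sets
   (hypergeometric upper tail, BH adjustment, 0.05 cutoff).

None of this can be unit-tested on real data without the original reads, so
cernakit ships a simulator that plants known junctions, binding sites, fold
changes and sponge correlations, and the whole pipeline is scored against
that truth. The methods vignette (`vignettes/cerna-methods.Rmd`) documents
the models, defaults and their rationale.

## Worked example

```r
library(cernakit)
res <- run_cerna_pipeline(seed = 1)
res
#> <cerna_pipeline>
#>   planted triples  : 8
#>   reported triples : 8
#>   recall 1.00 / precision 1.00 / circRNA detection recall 1.00
```

All 8 planted triples were recovered with no false triples, and all 12
planted circRNAs were called at exact junction coordinates. The
differential-expression summary for the circRNA panel:

```r
glance(res$de$circ)
#> # A tibble: 1 × 6
#>   n_features  n_up n_down  n_ns lfc_thr p_thr
#> 1         12    10      1     1       1  0.05
```

(8 planted up-regulated circles plus background differential features; one
feature stays non-significant.) The assembled triples carry their three
correlation legs — the two sponge legs strongly negative, the
circRNA–mRNA leg strongly positive, as the sponge model predicts:

```r
dplyr::select(res$triples, circ_id, mirna_id, mrna_id,
              scc_circ_mir, scc_mir_mrna, pcc_circ_mrna)
#> # A tibble: 8 × 6
#>   circ_id mirna_id mrna_id scc_circ_mir scc_mir_mrna pcc_circ_mrna
#> 1 circ001 mir010   gene025       -0.964       -0.988         0.957
#> 2 circ003 mir001   gene018       -0.952       -0.915         0.966
#> 3 circ004 mir012   gene003       -0.855       -0.818         0.740
#> 4 circ006 mir008   gene028       -0.915       -0.927         0.943
#> # ...
```

Result objects follow tidyverse conventions: `tidy()` and `glance()` for
tables and summaries, `autoplot()` for a volcano plot (`cerna_de`), an
enrichment dot plot (`cerna_ora`) and a tripartite network diagram
(`cerna_triples`); `export_network()` writes TSV, GraphML and Sankey JSON.

Every stage is also callable on its own (`simulate_reference()`,
`plant_regulation()`, `simulate_counts()`, `simulate_reads()`,
`detect_circrnas()`, `run_de()`, `predict_targets()`, `build_edges()`,
`assemble_triples()`, `ora()`), on plain tibbles and standard files (FASTA,
GTF, FASTQ, TSV, GMT). A thin command-line front end with `simulate`,
`detect-circ`, `de`, `targets`, `network` and `enrich` subcommands lives at
`inst/scripts/cerna-cli.R`.

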