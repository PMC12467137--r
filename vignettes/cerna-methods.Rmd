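---
title: "Methods: simulation-backed ceRNA network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-backed ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cernakit reconstructs the standard circRNA–miRNA–mRNA competing endogenous
RNA (ceRNA) workflow for a two-group bulk RNA-seq design — control (C) versus
grazing (G) sheep muscle is the motivating setting, with five biological
replicates per group — as a set of composable, tested stages. Because real
ceRNA studies cannot be validated without the original sequencing data, the
package treats a synthetic-data generator as a first-class component: every
stage can be scored against planted ground truth.

```{r}
library(cernakit)
res <- run_cerna_pipeline(seed = 1)
res$metrics
```

## The pipeline and its model

**Back-splice calling.** Circular RNAs are detected from reads that fail
contiguous genome alignment but whose terminal 20-mer anchors align uniquely
in head-to-tail orientation: the read's right anchor maps upstream of its
left anchor. A candidate junction `(acceptor_start, donor_end)` (0-based
half-open) is accepted only if the whole read is reproduced verbatim from the
doubled genomic segment of the circle; support then counts *distinct*
supporting read sequences per sample, and a call is retained when some sample
reaches two (`min_support`, exposed as an argument; a pooled-counting mode is
available via `per_sample = FALSE` because the community is not uniform on
this point). Calls are classified against the annotation into one-exon,
annot-exon, exon-intron, intron, antisense and intergenic types, with
precedence in that order.

Two deliberate simplifications: the aligner is exact-match (the head-to-tail
logic, not alignment heuristics, is the method under study), and the
"circular sequence" of a circle is its genomic span rather than a spliced
isoform — full-length circRNA isoform reconstruction is out of scope, and the
read-confirmation step is defined on the genomic span.

When a junction lies in a repeat the breakpoint is ambiguous (shifting both
coordinates left by one yields the same read set whenever the base before the
acceptor equals the last base of the circle). The caller resolves ties by the
leftmost-acceptor convention; the simulator pins every planted junction (it
edits the single base upstream of the acceptor, outside the circle, iterated
to a fixpoint across overlapping circles) so planted coordinates are exactly
recoverable and recall can honestly be measured at exact-coordinate level.

**Normalization and differential expression.** circRNA junction counts are
normalized to reads per million mapped reads (RPM) and mature miRNA counts to
a per-million scale (TPM without a length term — mature miRNAs are nearly
constant length). Differential expression uses a compact negative-binomial
Wald engine: median-of-ratios size factors (explicit size factors can be
passed instead), a per-feature method-of-moments dispersion with variance
`m + alpha * m^2` floored at `1e-8`, log2 fold change (G over C) from
normalized group means with a 0.5 pseudo-count, and a two-sided Wald p-value
referred to a t distribution with `n1 + n2 - 2` degrees of freedom. The t
reference is a measured calibration choice: with five replicates per group
the per-feature variance estimate is noisy, and under a pure null simulation
(2000 features, dispersion 0.1) the normal reference rejects at 0.08 while
t(8) rejects at 0.045; the acceptance suite re-measures this. Features are
called differential at `|log2FC| >= 1` (inclusive) and raw `p < 0.05`
(strict); a Benjamini–Hochberg column is reported for information but not
used for calling. No shrinkage of fold changes is applied.

One practical caveat the simulations exposed: median-of-ratios normalization
assumes most features are not differential. The simulated panels are tiny
(12 circRNAs of which 8 are planted differential), so `run_cerna_pipeline()`
passes library-size-derived size factors — the simulator records per-sample
mapped totals driven by a log-normal depth factor, as in a real library where
the analysed panel is a negligible share of all reads. On real, large feature
panels the median-of-ratios default is the right choice.

**Target prediction.** Two predictors run independently and are intersected
at the (miRNA, target) pair level. The seed-match scan reports every
(possibly overlapping) occurrence of the reverse complement of the seed
(miRNA positions 2–8 from the 5' end), labelled `8mer` when an A faces
position 1, else `7mer-m8`. The duplex aligner performs a local alignment of
the reversed miRNA against a bounded target window under miRanda-flavoured
constants — Watson–Crick +5, G:U +1, mismatch −3, gap open −4, gap extend −9
per position, with pair scores doubled at seed positions 2–8 — and a
three-level per-pair energy proxy (G:C −3, A:U −2, G:U −1 kcal/mol). A site
passes at score ≥ 140, energy ≤ −10 kcal/mol, and strict seed pairing
(Watson–Crick only, gap-free, across positions 2–8). The score/energy
thresholds and gap penalties are the published miRanda settings; the
match/wobble/mismatch values and the energy proxy are package choices,
monotone in duplex stability and set so that a fully complementary site of a
21–23-nt miRNA clears both thresholds (a perfect duplex scores `5n + 35`,
i.e. 140 at n = 21). They live in one block of constants. Candidate windows
are anchored at seed matches — sites without a perfect seed cannot pass the
strict-seed filter, so anchoring loses nothing. Circular targets are scanned
on the doubled sequence (junction-straddling sites included) with positions
reported modulo the circular length. Pair-level (not site-level)
intersection is used because the two predictors' coordinate conventions
differ; thermodynamic folding energies and conservation scores are out of
scope.

**Network assembly.** On normalized expression across all ten samples pooled
(pooling both groups is what makes group-driven co-expression detectable),
every predicted (miRNA, circRNA) and (miRNA, mRNA) pair is tested by
Spearman correlation (average ranks; two-sided p from the t approximation,
with an exact rank-permutation p available for n ≤ 10 as
`spearman_exact_p()`), and every (circRNA, mRNA) pair sharing a candidate
miRNA by Pearson correlation. Edges survive at SCC < −0.5 (strict),
PCC > 0.7 (strict) and p < 0.05 (strict); by default the p filter applies to
all three edge types, with `p_scope = "pcc"` restricting it to the Pearson
leg (the choice a reader might make where the p clause binds only to the
final filter). A triple is emitted when all three legs exist for a shared
miRNA; output is deduplicated, lexicographically ordered, and re-checked by
an independent validator pass. Export formats: triples/edge TSV, GraphML,
and a Sankey-ready JSON (three node columns circRNA → miRNA → mRNA, link
weights = |correlation|).

**Over-representation.** The GO/KEGG stage is implemented as generic
hypergeometric ORA against a user-supplied term map (GMT): upper-tail
`P(X >= k)`, BH adjustment, significance on adjusted p < 0.05 by default
(`raw_p = TRUE` for the raw-p reading). Real ontology content, DAG
propagation and pathway topology are out of scope; `simulate_term_map()`
provides toy term maps so the stage is testable offline.

## What the simulator emulates — and what it does not

`simulate_reference()` builds random-sequence chromosomes, non-overlapping
multi-exon genes with a ≥ 200-nt 3'UTR, mature miRNAs, and planted circles
drawn from a type mix that, like muscle circRNA catalogues, is dominated by
exonic circles. `plant_regulation()` embeds, per triple, the full reverse
complement of the miRNA into the host 3'UTR and the circle body, and assigns
true log2 fold changes with the sponge sign pattern (circRNA and mRNA up in
G, miRNA down). `simulate_counts()` draws negative-binomial counts
(variance `m + alpha m^2`) with one latent log-normal factor per triple per
sample multiplying the circRNA and mRNA means and dividing the miRNA mean —
the simplest construction that guarantees the correlation sign structure the
network filter selects for. `simulate_reads()` emits error-free
junction-spanning reads (distinct breakpoints, ≥ 20 nt on both sides of the
junction) plus linear background reads; an optional uniform substitution
error rate exists, and because anchor matching is exact, errors reduce
recall by design.

Defaults, chosen once and with units: planted |log2FC| = 3 (strong, as the
recoverability analysis below requires; within the range reported for
strongly regulated muscle circRNAs), background differential fraction 0.25
with |log2FC| in 1.5–3, NB dispersion 0.05 (moderately expressed features),
base means 200–2000 log-uniform, sponge factor sdlog 0.5, sequencing-depth
factor sdlog 0.15 around 2×10⁷ mapped reads, read length 100, four junction
reads per circle per sample, n = 5 per group. The planted effect size is a
designed property of the benchmark, not an empirical claim: at n = 5 the
per-feature detection power is ≈ 0.995 at |log2FC| = 3, so a planted triple
(three features, three correlation legs) is recoverable ≈ 95% of the time,
which is what lets end-to-end recall measure pipeline correctness rather
than statistical power. At |log2FC| = 2.5 the same arithmetic gives
per-triple recovery below 0.9, i.e. the benchmark would conflate the two.

Planted triples are kept independent by construction: triple mRNAs are drawn
from genes whose 3'UTR lies outside every planted circle, circle-body sites
avoid 3'UTRs and other circles, and embedded sites never touch
junction-flanking bases. Without these rules, a planted site can be
genuinely present in a second, unplanted molecule, and precision measured
against the planted list becomes ill-defined.

What passing tests therefore show: the calling, filtering, prediction and
assembly logic is correct on data whose generative model matches the
pipeline's assumptions. What they do not show: robustness to sequencing
error, misalignment, isoform complexity, GC or length bias, batch effects,
or weak effect sizes — real data properties the generator deliberately omits.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; GTF is written 1-based
  closed, BED 0-based half-open; miRNAs are stored in the DNA alphabet
  (U→T) so one alphabet serves all sequence code.
- Reads shorter than 2 × 20 nt are skipped and counted, not fatal; anchors
  with more than one exact hit across both strands are discarded (no
  rescue); reconstruction mismatches are counted and rejected.
- All-zero features test as `p = 1, log2FC = 0, ns`; all-zero samples and
  zero mapped totals are errors naming the sample.
- Constant expression vectors make a correlation undefined: the edge is
  skipped with a warning.
- Correlation p-values use the t approximation with n − 2 df; at n = 10 it
  sits within 0.014 of the exact permutation p (the acceptance suite
  re-measures the bound at 0.02).
- The dispersion floor is 1e-8; the fold-change pseudo-count is 0.5 and is
  also used inside the Wald variance to keep zero-containing features
  finite.
- Tie-break in back-splice placement: leftmost acceptor, stable under the
  simulator's junction pinning.
- Problem sizes used by the test and acceptance runs — 20 pipeline seeds at
  30 genes / 15 miRNAs / 12 circles / 8 triples, a 2000-feature null DE
  simulation, 20 exact-permutation instances at n = 10, 100 random
  seed-scan pairs, duplex toys up to 10 nt — were chosen so the whole suite
  completes in a few minutes on a single core while keeping Monte-Carlo
  error well inside each asserted band.

## Known limitations

- The DE engine is a documented stand-in, deliberately isolated behind
  `de_test()` so a different engine can be swapped in; it does not reproduce
  any specific published tool's numbers (no dispersion shrinkage, no fold
  change moderation).
- The duplex energy model is a per-pair proxy, not nearest-neighbour
  thermodynamics; scores and energies are comparable within this package
  only.
- Exact-match detection means a single sequencing error in an anchor loses
  that read; real callers tolerate mismatches.
- The Spearman exact-permutation reference assumes untied data and n ≤ 10.
- Enrichment ignores term-term structure; adjusted-p significance with BH is
  the default reading of a "0.05 cutoff".
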