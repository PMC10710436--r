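# phasebench

Alignment-based benchmarking of locally phased small variant calls (SNPs and
INDELs under 50 bp) in R.

## Why

A VCF encodes a genome as differences from a reference, and for complex
variants — anything not expressible as a single SNP or INDEL — many
sequence-identical encodings exist, especially in the low-complexity regions
where INDELs concentrate. Benchmarking tools that match VCF records therefore
reward or punish callers for their *representation* choices, and tools that
discard phasing will accept any of the 2^h local phasings of h heterozygous
records, which favors fragmented callsets. phasebench compares callsets at
the sequence level instead:

* **A standard representation.** Variant representation is a global
  affine-gap alignment problem with penalties (m, x, o, e) and gap cost
  g(n) = o + n·e. Each cluster of dependent variants is applied to the
  reference and realigned under the standard penalties, design point
  **C = (0, 5, 6, 2)** (normalized (0, 1, 1.2, 0.4)), so equivalent inputs
  converge to one form before evaluation.
* **Reach-based clustering.** Variants whose optimal alignments can interact
  (paths staying off the main diagonal within the penalty budget of their
  original representation) are merged iteratively; truth and query clusters
  within 50 bp group into independent *superclusters*.
* **Local phasing enforced, global phasing free.** Within a supercluster each
  truth haplotype is aligned against a query graph in which every query
  variant is taken wholly or skipped wholly; the truth-to-query haplotype
  pairing minimizing total edit distance fixes the supercluster's phase
  (X/Y). Switch errors *between* superclusters are counted by a phase-block
  dynamic program but never change variant credit.
* **Partial credit.** Each alignment is cut at sync points; segments where
  the query removes all truth-vs-reference edit distance are true positives,
  segments that leave it unchanged are FP/FN, and in between a call earns
  credit 1 − ED_query/ED_ref. A 3-bp insertion called with one base missing
  (edit distance 3 → 1) counts as 2/3 TP + 1/3 FP.
* **Distance metrics.** Edit distance (ED), distinct edits (DE; jointly
  optimized as 2DE + ED via design point B = (0, 3, 2, 1)) and alignment
  distance depend only on the truth and query sequences, with Phred-style
  Q-scores −10·log10(query/reference); the F1 Q-score is −10·log10(1 − F1).
* **Stability statistics.** Across representations of many submissions,
  `amrc()` (average maximum rank change) and `stability_r2()` quantify how
  much an evaluation depends on representation.

## Worked example

```r
library(phasebench)

ref   <- make_reference(6000, repeat_fraction = 0.3, seed = 7)
truth <- plant_variants(ref, seed = 8)                 # 24 variant records
noisy <- corrupt(truth$callset, ref$seqs,              # plant known errors
                 n_fp = 2, n_fn = 1, n_indel_len = 1, seed = 9)

ev <- run_evaluation(ref$seqs, truth$callset, noisy$callset)
ev
#> phased small variant benchmarking evaluation
#>   superclusters: 17   switch errors: 0
#>   SNP   best F1 0.9744 (Q15.9)
#>   INDEL best F1 0.9762 (Q16.2)
#>   ED 4  DE 4  ALN 23 (at lowest threshold)

dplyr::filter(tidy(ev), category != "TP")
#>   start ref     alt  role category    credit
#> 1   607   C       A truth       FN 0.0000000
#> 2  1037   G       T query       FP 0.0000000
#> 3  3961      CATCCA query       PP 0.8571429
#> 4  3961     CATCCAT truth       PP 0.8571429
#> 5  5392   G       T query       FP 0.0000000
```

The two planted false positives and the dropped call come back as exactly
one FP record each and one FN; the 7-bp insertion called with 6 bases is a
partial positive with credit 1 − 1/7 = 0.857. `glance(ev)` gives the one-row
summary, `autoplot(ev)` the precision-recall curve over quality thresholds,
`autoplot(ev, type = "distance")` the remaining ED/DE curves, and
`write_report(ev, dir)` the TSV/VCF report bundle. Key steps are exposed
individually: `normalize_params()`, `align_affine()`, `iterative_cluster()`,
`standardize_callset()`, `build_superclusters()`, `eval_supercluster()`,
`ed_de()`, `phase_forward_backward()`, `amrc()`.

A thin command-line driver is included:

```sh
Rscript inst/cli/phasebench.R eval --ref ref.fa --truth truth.vcf \
    --query query.vcf --out report/
Rscript inst/cli/phasebench.R synth --length 10000 --seed 1 --fp 3 --out fix/
```

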