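---
title: "Benchmarking phased small variant calls by realignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking phased small variant calls by realignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasebench)
library(dplyr)
```

## The problem

A VCF stores a genome as differences from a reference. For an isolated SNP
that encoding is unique after normalization, but a *complex* variant — any
difference not expressible as a single SNP or INDEL — admits many
sequence-identical encodings, especially in low-complexity sequence where
INDELs concentrate. Two callers can emit the same diploid genome yet receive
different precision/recall from a benchmarking tool that matches VCF records,
and tools that ignore phasing will accept any of the $2^h$ local phasings of
$h$ heterozygous records, which rewards fragmented representations.

phasebench evaluates a locally phased query callset against a locally phased
truth callset at the *sequence* level:

1. **Representation as alignment.** Which records describe a haplotype
   difference is exactly the choice of a minimum-penalty global alignment
   under affine-gap penalties $(m, x, o, e)$, where a gap of length $n$ costs
   $g(n) = o + ne$. Penalty schemes are compared after normalizing to
   $m = 0$, $x = 1$ (`normalize_params()`). When $2(o+e) < x$ a substitution
   is always reported as a 1-bp insertion plus deletion
   (`snp_decomposes()`), the regime of copy-number aligners.
2. **Standardization.** Every cluster of dependent variants is applied to
   the reference and realigned under the standard penalties, design point
   C $=(0, 5, 6, 2)$, the approximate centroid of popular short- and
   long-read aligner defaults. The emitted records are decomposed, trimmed
   and left-shifted, so equivalent inputs converge to one representation.
3. **Clustering.** Two variant clusters must be evaluated jointly when some
   optimal alignment path can stay off the main diagonal between them within
   the penalty budget of their original representation. `reach_extend()`
   computes how far such paths reach; `iterative_cluster()` merges adjacent
   clusters to a fixpoint starting from one cluster per variant. A fast
   positional heuristic (`gap_cluster()`) is available as a fallback.
4. **Superclustering.** Truth and query clusters from all four haplotypes
   whose reaches come within 50 bp are grouped transitively
   (`build_superclusters()`); superclusters are independent evaluation
   units.
5. **Local phasing and credit.** Within a supercluster each truth haplotype
   is aligned to a query *graph* — the reference window where each query
   variant is taken wholly or skipped wholly — so false positives can be
   skipped free (`align_truth_to_query_graph()`). The pairing of truth to
   query haplotypes with minimum total edit distance defines the
   supercluster's phase (X, Y, or uncategorized on ties). The chosen
   alignment is cut at *sync points* (variant-free boundaries the path
   crosses on the main diagonal), and each segment is credited by comparing
   the truth-vs-reference edit distance $ED_{ref}$ with the truth-vs-query
   distance $ED_{query}$: a true positive when $ED_{query} = 0$, a false
   positive/negative when the distance is unchanged, and a *partial
   positive* with credit $1 - ED_{query}/ED_{ref}$ otherwise. A 3-bp
   insertion called with one base missing reduces the distance from 3 to 1
   and counts as 2/3 TP + 1/3 FP.
6. **Metrics.** Counts are accumulated per haplotype (a homozygous false
   positive is two false positives). Precision uses truth-side true
   positives, $TP_{truth} / (TP_{truth} + FP_{query})$, which is stable when
   representations split records differently; recall is
   $TP_{truth} / (TP_{truth} + FN_{truth})$; the F1 Q-score is
   $-10\log_{10}(1 - F1)$. Distance metrics — edit distance (ED), distinct
   edits (DE) and alignment distance — depend only on the truth and query
   sequences. ED and DE come from the alignment at design point B
   $=(0,3,2,1)$, which globally minimizes $2\,DE + ED$ (a gap opening is one
   distinct edit, each edited base one unit of ED, a substitution one of
   each); the reported ED may therefore exceed the Levenshtein minimum.
   Their Q-scores are $-10\log_{10}(\text{query term}/\text{reference
   term})$.
7. **Global phasing.** Supercluster phase categories feed a two-state
   dynamic program (`phase_forward_backward()`) minimizing switch errors
   plus supercluster phasing errors; phase blocks are recovered in the
   backward pass and switch errors are counted at block boundaries.
8. **Stability statistics.** Across representations of the same callsets,
   `amrc()` reports the average rank swing between each submission's best
   and worst representation (ranks are insertion positions into the other
   submissions' sorted median Q-scores), and `stability_r2()` the
   coefficient of determination of per-representation Q-scores around the
   per-submission means.

## A worked example

```{r example}
ref <- make_reference(6000, repeat_fraction = 0.3, seed = 7)
truth <- plant_variants(ref, seed = 8)
noisy <- corrupt(truth$callset, ref$seqs, n_fp = 2, n_fn = 1,
                 n_indel_len = 1, seed = 9)
ev <- run_evaluation(ref$seqs, truth$callset, noisy$callset)
ev
glance(ev)
tidy(ev) %>% filter(category != "TP")
```

The same evaluation is invariant to how the query chose to write its
variants:

```{r invariance}
sapply(c("C", "A", "B", "D"), function(p) {
  q <- render_representation(noisy$callset, ref$seqs, p, role = "query")
  e <- run_evaluation(ref$seqs, truth$callset, q)
  pr <- e$pr_curve
  pr$f1[pr$class == "ALL" & pr$threshold == min(pr$threshold)]
})
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `params` | point C $(0,5,6,2)$ | penalties for clustering budgets and standardization; normalized $(0,1,1.2,0.4)$ |
| `supercluster_gap` | 50 bases | reach distance that groups truth/query clusters |
| `cluster_gap` | 50 bases | positional gap for the fast clustering heuristic |
| `reach_limit` | 64 bases | cap on off-diagonal reach extension; generous relative to budget$/e$ plus the longest low-complexity tracts the generator emits |
| `subset_cap` | 8 | exhaustive query-variant subset enumeration limit per haplotype and supercluster; beyond it a greedy leave-one-out search is used |
| `max_iters` | 100 | clustering merge passes before a non-convergence warning |
| `switch_cost`, `phase_error_cost` | 1, 1 | weights of the global phasing DP; the relative weighting is genuinely open, and equal unit costs make the reported optimum an unweighted error count |

Design points A $=(0,8,1,1)$ and D $=(0,2,4,1)$ are package choices within
their published regimes (A decomposes substitutions; D penalizes gaps more
than C); `"fragmented"` is the unit-cost point $(0,1,0,1)$, which produces
maximally fragmented, edit-distance-minimal records.

## Numerical and policy choices

* Coordinates are 0-based half-open internally; conversion happens only at
  VCF read/write. Missing QUAL is read as 0 so such records appear only at
  the lowest quality threshold. FILTER is ignored unless `pass_only = TRUE`.
  Homozygous records contribute one variant per haplotype, which is what
  makes homozygous errors count twice.
* Alignment tie-breaks: diagonal > deletion > insertion, gap continuation
  over gap opening, and INDELs left-shifted against the full contig — the
  conventional left-aligned normal form, and deterministic.
* Standardized records merged from several inputs carry the *minimum* member
  QUAL (conservative for precision-recall sweeps). Because different input
  representations group records differently before merging, points at
  intermediate quality thresholds may differ slightly across
  representations; counts at the lowest threshold (all calls) are
  representation-invariant, and that is what the invariance tests assert.
* The quality sweep uses the distinct query QUAL values as thresholds;
  truth variants are always retained.
* Q-scores are capped at 100 when the error term is zero and undefined
  (`NA`) when the reference term is zero. `segment_credit()` clamps
  $ED_{query} > ED_{ref}$ (a call that worsens the sequence) to zero credit.
* The phasing DP prefers fewer switches at equal cost, so an isolated
  discordant supercluster is reported as one phasing error inside a block
  rather than two switches; the end-of-contig tie adopts the last
  categorized supercluster's state, which keeps the result covariant under a
  global relabeling of X and Y.
* Degenerate inputs: empty callsets evaluate to empty (NA metrics); an
  unphased heterozygous genotype is an error naming the record; haploid or
  ungenotyped records error by default with `skip_invalid = TRUE` to skip.

## What the synthetic generator does and does not emulate

`make_reference()` interleaves random sequence with homopolymer and short
tandem repeat tracts (default 30% of bases, the regime where INDEL
representation is genuinely ambiguous); `plant_variants()` places SNPs
(2/kb), INDELs (0.5/kb, 1–12 bp, biased into tracts where insertions
duplicate local sequence), and complex variants (0.1/kb) with a
heterozygous:homozygous mix of 2:1 — densities chosen to resemble a diploid
human sample while keeping desk-scale runs fast. `render_representation()`
re-expresses callsets at any design point, guaranteeing sequence-identical
haplotypes; `corrupt()` plants false positives, dropped calls, INDEL length
errors, flips and switches, and records them in a ledger so tests can close
the loop exactly.

The generator does not simulate reads, sequencing error profiles, genotyping
uncertainty, structural variants, or the reference biases of real pipelines;
QUAL values are draws, not calibrated probabilities. Passing tests therefore
demonstrate correctness of the evaluation machinery and its representation
invariance, not variant-caller performance on real data.

## Problem sizes used by the test suite

The packaged checks run at desk scale as a deliberate design point:
oracle-equivalence suites sample 1000 sequence pairs of up to 8 bp and 60
phasing instances of up to 12 superclusters; representation invariance uses
50 seeded 10-kb genomes (30% repeats) with planted errors evaluated at four
design points plus the fragmented representation; recovery uses 100 seeded
2.5-kb genomes. `scripts/acceptance.R` recomputes the same quantities at
slightly reduced counts.

## Known limitations

* Exact subset enumeration in the query graph is exponential; the cap plus
  greedy fallback can in principle miss the optimal branch choice in
  superclusters with more than eight query variants on one haplotype.
* Reach extension is windowed at `reach_limit`; dependence mediated by a
  repeat run longer than the window would be missed (not reachable under
  point-C budgets at the generator's tract lengths).
* Switch errors are counted between superclusters only; flip errors inside a
  supercluster surface as credit loss, not as a phasing statistic.
* Multi-sample VCFs use the first sample; structural variants (≥ 50 bp),
  symbolic alleles and breakends are out of scope.
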