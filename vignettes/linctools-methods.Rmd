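---
title: "Models, parameters and design choices in linctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in linctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`linctools` identifies long intergenic non-coding RNAs (lincRNAs) in an
assembled transcriptome and characterises them by expression, putative
function and miRNA interactions. This vignette explains each model, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open.

## The discovery cascade

The cascade is a sequence of set-reducing predicates applied in a fixed
order; each stage records its inputs, removals (with reasons) and retentions
in a ledger whose conservation invariants are validated on every run.

1. **Intergenic extraction.** Transcripts whose assembly-comparison class
   code is `u` (entirely intergenic relative to the reference annotation).
   The class code is read from a `class_code` GTF attribute or from a
   separate two-column lookup table, since assembler output dialects vary.
2. **Length.** Retain spliced length strictly greater than 200 nt. "Long"
   non-coding RNA conventionally means *more than* 200 nt; a transcript of
   exactly 200 nt is removed. The boundary is configurable (`min_len`).
3. **Longest ORF.** Retain transcripts whose longest open reading frame is
   at most 300 nt. An ORF is ATG-to-stop with the stop codon *counted in the
   length*; a 303-nt ORF is ATG plus 99 codons plus a stop. Transcripts with
   known strand are scanned in the three sense frames (their sequences are
   sense-oriented); unstranded transcripts — the common case for single-exon
   intergenic assemblies — are scanned over all six frames so antisense
   coding capacity cannot leak through. Codons containing `N` never match
   ATG or a stop. ATG stretches that run off the transcript end without an
   in-frame stop are not counted as ORFs by default (`include_open_ended`
   reverses this); counting only complete ORFs is conservative and
   deterministic. Ties between equally long ORFs resolve to the 5'-most
   start on the forward strand, then forward over reverse.
4. **Homology evidence.** Transcripts with a protein (BLASTX-style) hit at
   e-value <= 1e-3 are removed first; among the remainder, those with a
   protein-domain (hmmscan-style) hit at the same cutoff. The two removal
   sets are therefore disjoint, which is the only reading under which
   published per-stage tallies of this design add up. Evidence is consumed
   from plain tables rather than by invoking search services, keeping the
   cascade deterministic and testable.
5. **Coding potential.** Scores strictly above 0 are removed; a score of
   exactly 0 is retained. Every transcript reaching this stage must have a
   score — a missing score is an error, not a silent pass.
6. **Gene flanking.** A transcript is removed when the minimum genomic gap
   between its span and any coding-gene span on the same chromosome is at
   most 500 nt, with overlap counting as gap zero. The rule is
   strand-agnostic: it guards against unannotated transcription-start
   extensions on either strand.

Survivors are assigned identifiers `Ca_linc_0001 ...` ordered by
(chromosome, start, transcript id). Coordinate order is reproducible and
stable under re-runs, which matters because the identifiers are referenced
by every downstream table.

The CPC and flanking stages are independent predicates on the surviving
set, so swapping them changes per-stage removal counts but never the final
set; the test suite asserts this invariance.

All internal coordinates are 0-based half-open; GTF/GFF3 (1-based
inclusive) and BED (0-based half-open) use their native conventions at the
file boundary only.

## Tissue specificity and expression classes

The tau index over an expression vector $x$ across $N$ tissues,

$$\mathrm{TSI} = \frac{\sum_{i=1}^{N} (1 - x_i/x_{\max})}{N - 1},$$

is 0 for uniform expression and 1 for single-tissue expression, is
scale-invariant, and never increases when a non-maximal tissue's expression
rises. All-zero rows have no defined index; they are flagged rather than
assigned a value, and are never called specific. Transcripts with
TSI >= 0.9 are called specific to their maximal tissue (first tissue in
column order on exact ties).

Expression classes bin a transcript's maximal FPKM at
very low [0,2), low [2,5), moderate [5,10), high [10,20], very high (20,∞).
Only the outer boundaries (< 2, > 20) are canonical; the interior breaks
are this package's convention and are configurable. "Expressed in a
tissue" uses a default threshold of 1 FPKM (`min_expr_fpkm`), made explicit
because per-tissue expressed counts are meaningless without it.

Stage-specific calls require >= 3 FPKM in at least one target tissue and
<= 0.1 FPKM in every non-target tissue. Heatmap display z-scores each row
over tissues (mean 0, sd 1; constant rows map to 0).

Co-expression uses the average-rank Spearman correlation with tie
correction (as implemented by `stats::cor`). Rows with zero variance have
no defined rank correlation; their pairs are reported with `rho = 0` and a
flag rather than being silently dropped, for auditability.

## Bicolor-network GO propagation

The candidate pair universe for co-expression edges contains lincRNA-mRNA
and mRNA-mRNA pairs (lincRNA-lincRNA pairs are excluded by default; a flag
includes them). The edge threshold is the (100 − p)-th percentile of
absolute correlations with p = 0.5 by default, i.e. the top 0.5% of pairs;
edge weight is |rho|. Protein-interaction edges are allowed among mRNA
nodes only, min-max normalized to [0,1]; where both evidence types cover a
pair the weights combine by `max` (keeping weights in [0,1]; `mean` is
available). The network is symmetric with zero diagonal.

Propagation uses the symmetric degree normalization
$W' = D^{-1/2} W D^{-1/2}$ (isolated nodes get zero rows) and iterates

$$F \leftarrow \alpha\, W' F + (1 - \alpha)\, Y$$

from $F = Y$ until the per-term L1 change falls below `tol` (default 1e-6,
cap 1000 iterations; non-convergence is flagged, never silent). With this
normalization the spectral radius of $\alpha W'$ is below 1 for
$\alpha < 1$, so the iteration converges to
$F = (1-\alpha)(I - \alpha W')^{-1} Y$; the test suite verifies equality
with the direct solve on networks up to 200 nodes and checks the
fixed-point residual. The propagation parameter is **not pinned down by the
method's provenance**; $\alpha = 0.8$ is the conventional value for this
family of diffusion methods and is configurable. Likewise the matrix
normalization and the evidence-combination rule are stated here as this
package's choices.

Per term, lincRNAs are ranked by score (ties by node id) and the top 100
with *strictly positive* score receive the term. The positive-score guard
is a deliberate choice: a rank cap alone would annotate disconnected
lincRNAs with arbitrary terms in small networks. First-degree-neighbour
annotation (the union of directly connected mRNAs' terms) is recorded
separately from the propagation output.

Enrichment is the upper-tail hypergeometric probability
$P(X \ge k)$ for $k$ study hits of a term with $K$ carriers in a population
of $N$, with Benjamini-Hochberg adjustment reported alongside; the
significance threshold "e−10" is read as 1e-10 and is configurable.

## miRNA target expectation score

The miRNA (5'→3') is aligned antiparallel against each candidate window so
position $i$ pairs with the $i$-th base of the reversed window. Penalties:
Watson-Crick 0, G:U wobble 0.5, mismatch 1, bulge 2; all doubled at miRNA
positions 2-13 (the seed, counted from the 5' end). At most one bulge per
duplex, on either strand (so admissible window lengths are the miRNA length
±1); this bounded search keeps the scan linear per window with fully
vectorised prefix/suffix penalty sums, and matches the biological
expectation that functional plant duplexes are nearly contiguous. The
expectation is the penalty total; sites with expectation <= 3 are reported,
and when a precomputed target-site accessibility (UPE) table is supplied,
hits above 25 kcal/mol are additionally removed — accessibility is consumed,
not computed, because it requires RNA folding that is out of scope here.
Only the cutoffs (3 and 25) are fixed by the workflow this package
operationalises; the penalty constants follow the standard plant
target-prediction convention and every one is a function argument.

Overlapping hits of a miRNA-lincRNA pair collapse greedily to the best
score (ties: fewer bulges, then 5'-most target position); the interaction
network counts distinct (lincRNA, miRNA) pairs — multiple sites on one
transcript do not multiply edges — and classifies each connected
component's pattern from the lincRNA perspective (one_to_one, one_to_many,
many_to_one, many_to_many).

## The synthetic study: what it emulates, and what it does not

The generators produce, under a single seed, a deterministic study with
planted ground truth:

- **Discovery fixture** (~104 transcripts over 2 chromosomes, ~90 coding
  genes): one planted cohort per filter category — genic transcripts with
  non-`u` codes, `u` transcripts of <= 200 nt, constructed ORFs > 300 nt
  (the first of exactly 303 nt; ORF flanks and interiors use
  pyrimidine-only codons so no start or stop can arise in any other frame
  on either strand), protein/domain-evidence hits, positive
  coding-potential scores, placements within 500 nt of genes, and clean
  true lincRNAs (AU-rich, GC ≈ 0.33 versus ≈ 0.45 for mRNA-like
  sequences, rejection-sampled to contain no six-frame ORF above 300 nt).
  The gene grid guarantees every planted transcript is removed at exactly
  its designed stage, so discovery achieves exact recovery by construction.
- **Expression fixture** (11 tissues: GS, YL, SAM, FB1-4, FL1-4): planted
  tissue-specific rows (12-20 FPKM in one tissue, 0.02 elsewhere),
  housekeeping rows (constant mean, mostly below 2 FPKM so the class
  histogram is dominated by the very-low class), and co-regulated blocks
  sharing a geometric tissue gradient (ratio 1.5 between adjacent ranks:
  steep enough that 20% lognormal noise rarely permutes ranks, shallow
  enough that block members stay below the tau = 0.9 specificity
  threshold). Block gradients use mutually uncorrelated tissue
  permutations — disjoint modules should be expression-orthogonal, and over
  only 11 tissues random permutations are not reliably so.
- **Network fixture**: mRNA modules matching the expression blocks, dense
  intra-module PPI edges (scores 0.7-1.0) versus sparse inter-module edges
  (0.05-0.25), one GO term per module.
- **miRNA fixture**: random 21-nt miRNAs (position 20 forced to G so a
  non-seed wobble is always constructible) and sites built by exact penalty
  arithmetic at designed expectations 0, 0.5, 2, 3 and 3.5 — the last
  deliberately beyond the reporting cutoff. Exact construction makes
  recovery tests sharp rather than statistical.

Lognormal multiplicative noise (CV 20% by default) is a reasonable first
approximation to RNA-seq dispersion but the fixtures do **not** emulate
read-level artifacts, assembly fragmentation, chimeric transcripts,
mappability gaps, correlated library effects, or annotation errors in the
reference gene set. Passing the planted-truth tests therefore demonstrates
that the *algorithms* implement their definitions correctly and recover
clean signal; it does not certify performance on real libraries, where the
filter inputs (assemblies, homology tables, coding-potential scores) carry
their own error modes.

## Fixture-scale calibrations

Two thresholds are defined relative to catalog scale and must be rescaled
for desk-size fixtures, a point this vignette states explicitly because it
affects how the recovery metrics are measured:

- The top-0.5% co-expression percentile presumes a pair universe many
  orders of magnitude larger than the planted structure. In the reference
  fixture (~2,800 pairs, ~280 planted coherent pairs) the tests and the
  acceptance script use the top 15% so the edge threshold falls between the
  background and planted correlation distributions. The small-block
  fixture used to validate the 0.5% rule itself keeps planted pairs below
  0.5% of the universe.
- The per-term annotation rank cap of 100 (≈ 4-5% of a multi-thousand
  catalog) is rescaled to the planted per-module lincRNA count (4) when
  measuring module recovery; a cap of `0.05 × fixture lincRNA count` would
  be smaller than a single module and could not measure recovery at all.

## Problem sizes and numerical conventions

Test-suite problem sizes (chosen as representative desk scale): 100 random
600-nt sequences for the ORF oracle; random networks of 30-200 nodes for
the propagation oracle (tolerance 1e-5 against the direct solve); 1000
seeded draws for the enrichment null-uniformity check (discrete
hypergeometric p-values are randomized with the standard
$P(X>k) + V\,P(X=k)$ construction before the Kolmogorov-Smirnov test);
80 random duplexes for the gapless scoring oracle; 100 dinucleotide-shuffle
replicates for the negative control. Quantile computation uses R's default
type-7 interpolation; min-max normalization maps constant vectors to zero;
percentage reporting exposes both nearest-integer and floor conventions
because published summaries mix them ("at least 79%" floors, "29%"
rounds).
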