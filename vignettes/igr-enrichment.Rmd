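---
title: "Enriching bacterial intergenic regions for structured RNA discovery"
author: "igrsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enriching bacterial intergenic regions for structured RNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

Structured noncoding RNAs — riboswitches above all — concentrate in
bacterial intergenic regions (IGRs) that are atypically long and GC-rich
relative to the bulk of intergenic sequence in the same genome. `igrsieve`
operationalizes that observation as a per-genome enrichment device:

1. every IGR between protein-coding genes is extracted and described by
   exactly two features, %GC content and nucleotide length;
2. IGRs containing a known structured-RNA annotation form the positive
   class, all remaining IGRs the negative class;
3. a support-vector classifier with a radial basis-function (RBF) kernel
   is trained de novo on these labels, and every *unannotated* IGR whose
   decision value is positive is carried forward as a candidate.

The classifier is deliberately not a predictive model. With tens of
positives against hundreds-to-thousands of negatives, two features, and no
held-out evaluation, it cannot certify that a candidate is an RNA. Its job
is to reduce the search space handed to the expensive downstream homology
and covariation analysis, in a way that is systematic, reproducible, and
visually auditable: `plotGenome()` overlays the level-0 contour of the
decision function on the GC-versus-length scatter, and the user is
expected to look at it. A genome in which the known-RNA cluster does not
stand clear of the bulk is a poor substrate for this entire approach, and
`trainClassifier()` makes the minimal version of that judgement a hard
error (fewer than `minPositives = 5` labeled IGRs).

### Decision function and scaling

Features are standardized to zero mean and unit variance over all training
IGRs of the genome (means and SDs are stored in the model). The decision
function is the usual SVM dual form,
$d(x) = \sum_i \alpha_i e^{-\gamma\|z(x)-s_i\|^2} - \rho$, evaluated
in-package from the stored support vectors; positive values indicate
similarity to known-RNA IGRs. With `gammaMode = "auto"`, γ is half the
reciprocal of the mean per-feature variance of the scaled features, which
is 0.5 by construction after unit-variance scaling; the formula is
evaluated rather than hard-coded so a `logLength` transform or future
feature changes remain correct.

Class imbalance is absorbed by weights: the positive class is weighted
`w * n_negative / n_positive`, the negative class 1. At `w = 1` this is
plain inverse-frequency balancing; `w` is the single advertised knob for
growing (`w > 1`) or shrinking (`w < 1`) the selected region. The
selection threshold itself is fixed at the canonical margin `d(x) > 0` —
a tuned probability cutoff would add a second, redundant knob.

### Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `C` | 1.0 | — | SVM cost; larger hugs the training labels tighter |
| `gammaMode` / `gamma` | auto (0.5) | scaled space | RBF width |
| `w` | 1.0 | — | positive-weight multiplier; region size |
| `minPositives` | 5 | IGRs | minimal training support per class |
| `minOverlapFraction` | 0.5 | fraction of RNA annotation | labeling rule |
| `evalueMax` | 1e-5 | — | BLASTX hit stringency |
| `minLength` (refilter) | 50 | nt | hard floor on surviving fragments |
| `pad` | 0 | nt | expansion of hits before subtraction |

Conventional values throughout: 1e-5 is the customary homology-screen
stringency, 50 nt is near the lower bound of useful structured-RNA
queries, and zero padding is the least destructive default.

## Design choices that were genuinely open

**Coordinates.** Internally everything is 1-based closed in
`GRanges`/`IRanges`, the native Bioconductor convention; BED (0-based
half-open) and BLAST tabular (1-based closed, minus-frame hits reported
with swapped query coordinates) are converted at the I/O boundary. Sticking
to the container's own convention eliminates a whole class of off-by-one
bugs at the price of converting twice in well-tested readers.

**What delimits an IGR.** Only `CDS` features delimit IGRs. Annotated RNA
genes (tRNA, rRNA, ncRNA) remain *inside* IGRs — necessarily so, since
known RNAs inside IGRs are precisely the positive training labels.
CDS intervals are merged across strands before complementing: an IGR is
treated as a double-stranded genomic interval, because downstream homology
searches examine both strands anyway. Flanking-gene identities and strands
are recorded per IGR for later genetic-context interpretation.

**Contig edges and circular origins.** IGRs touching a linear contig edge
are flagged `terminal` and kept by default (`dropTerminal = FALSE`):
draft assemblies truncate genes at contig edges and silently discarding
those IGRs would bias against fragmented genomes. On circular contigs the
two origin-flanking gaps are joined into one IGR whose sequence wraps;
it is stored with unwrapped coordinates (`end` beyond the contig length)
so that interval arithmetic stays monotone.

**Labeling rule.** An IGR gains a family when at least
`minOverlapFraction = 0.5` of the *annotation's* length lies inside the
IGR (strand-blind, `>=` at the boundary). Measuring the fraction over the
annotation rather than the IGR makes the rule robust to annotations that
slightly overhang a flanking gene. Labeling is monotone in the threshold,
and one IGR may carry several families.

**Selection semantics.** IGRs already carrying a known family are scored
but never selected — they are knowns, not candidates. After hit
subtraction, *all* fragments that pass the recheck survive (the best-only
alternative would discard second structured elements in long IGRs); an
IGR none of whose fragments pass is discarded in its entirety. The recheck
is literally the trained classifier plus the length floor: the SVM *is*
the genome's length-and-GC selection criterion, so re-applying anything
else would be inconsistent.

**Deduplication.** Exact, case-insensitive sequence duplicates collapse to
the lexicographically smallest ID — an arbitrary rule fixed for
determinism. Reverse-complement duplicates are kept by default
(`revcomp = TRUE` collapses them), since distinct orientations can carry
distinct genetic context.

## Numerical and determinism notes

* Training rows are sorted by (contig, start) before fitting, and libsvm's
  SMO is deterministic given fixed input order, so identical inputs yield
  identical models. The underlying library orients its decision values by
  the class of the first training row; `trainClassifier()` detects the
  orientation and normalizes the stored coefficients so `d > 0` always
  means RNA-like.
* The model serializes to JSON (scaling, hyperparameters, support vectors,
  dual coefficients, intercept). Decimal serialization reproduces decision
  values to ~1e-15 relative precision — byte-identical across reruns of
  the same pipeline, but not bit-identical to the in-memory model; tests
  compare reloaded models at 1e-12.
* `gcPercent` counts only literal G/C (case-insensitive); IUPAC ambiguity
  codes and N count in the denominator only, so ambiguous bases can only
  lower %GC, never inflate it. The empty sequence is an error by
  construction (a zero-length IGR cannot exist).
* Degenerate inputs fail loudly: zero feature variance, too few positives,
  annotation contigs missing from the FASTA, features overrunning their
  contig. Hits on unknown IGR IDs are skipped with a warning (hit tables
  go stale), malformed lines error with their line number.
* Bundles are byte-stable: member order is sorted, file mtimes are pinned,
  and the archive is rebuilt identically from identical inputs — reruns
  of the whole pipeline at a fixed seed produce byte-identical tables,
  model JSON, FASTA and archives.

## The synthetic-genome generator

`simulateGenome()` emulates the empirical structure the method relies on:
contigs tiled as alternating gene/IGR blocks; genes at 50 ± 3 %GC with
lengths uniform in 300–900 nt; background IGRs AT-rich and short
(32 ± 5 %GC, 120 ± 50 nt, floored at 30 nt); and planted RNA-like IGRs —
a GC-rich, long segment (55 ± 4 %GC, 220 ± 40 nt) between two 10–30 nt
background-composition flanks. Defaults plant 60 such IGRs among 300
background IGRs across three contigs, with half the planted set emitted
as known families (`SYN_k` in the BED file) and half left unannotated as
discoverable truth. Sequences are drawn per base (Bernoulli GC), so
realized composition varies naturally around its target;
`separationMetric()` reports the implied background-versus-planted
Mahalanobis separation (4.5 pooled SDs under the defaults, accounting for
flank dilution and per-base sampling noise) — comfortably inside the
"strong separation" regime the method presumes.

What the simulator does **not** model bounds what passing tests prove:
no RNA secondary structure (irrelevant here — the classifier sees only GC
and length), no codon structure or operons, no annotation errors, and
Gaussian clusters rather than the skewed, overlapping feature clouds of
real genomes. The end-to-end recovery results (sensitivity ≥ 0.9 on
unlabeled planted RNAs, ≤ 15% background selected, across 20 seeds at the
95% level) therefore certify the machinery — extraction, labeling,
training, selection, filtering are wired correctly and reproducibly — not
the biological yield on any particular genome, which depends on that
genome's actual separation.

## Test problem sizes

The property suites run 1,000 randomized gene arrangements (mixed linear
and circular) against a per-base complement oracle, 10,000 random IUPAC
strings against naive GC counting, 1,000 random hit configurations
(including minus-frame and padded cases) against a per-base subtraction
oracle, and 20 simulator seeds through the full enrichment chain. Random
cases are batched into shared containers (one contig or one IGR per case)
so the suites stay fast without shrinking n.

## Limitations

* Two features only; a genome whose structured RNAs are not GC/length
  outliers gains nothing from the enrichment, and the tool's advice in
  that situation is the diagnostic plot, not a number.
* BLASTX, Infernal, CMfinder and friends are not executed; the package
  prepares their inputs (hit-table screening, deterministic bundles) and
  consumes their tabular outputs.
* Hit tables are trusted as given — no reading-frame or ORF verification.
* No hyperparameter search: `C`, `gamma`, `w` are exposed, documented,
  and left to inspection rather than optimized against labels that are
  themselves incomplete.
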