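---
title: "Methods: dropout-screen analysis from raw reads to hit genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dropout-screen analysis from raw reads to hit genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
```

## The screen this package analyses

A pooled CRISPR/Cas9 loss-of-function screen asks which gene knockouts
change a cell population's fitness under a selective pressure. A lentiviral
library delivers one single-guide RNA (sgRNA) per cell; cells carrying a
knockout that sensitises them to the pressure die, and their guides
*drop out* of the pool. Deep sequencing of the integrated sgRNA cassettes
before and after selection, plus counting, turns the biology into a
composition-of-frequencies problem.

The design `dropscreen` targets is a two-arm time course over five
sequenced samples:

* **T0** — after viral transduction and knockout establishment, before any
  T-cell pressure. Comparing T0 against a library reference captures pure
  *viability* effects of the knockouts.
* **T1, T2** — after the first and second round of treatment with
  engager-coupled cytotoxic T cells (the treatment arm).
* **C1, C2** — matched rounds of T-cell exposure *without* the engager
  (the control arm), which flags genes whose loss matters for
  treatment-unspecific reasons.

Essential ("viability") and non-essential control genes ride along in the
library: the former must deplete, the latter must not, or the screen cannot
be trusted.

## Read assignment by anchored approximate matching

In the sequenced amplicon each protospacer sits between two fixed vector
sequences, so the query pattern for guide $i$ is the cassette

$$p_i = \mathrm{flank5} + \mathrm{protospacer}_i + \mathrm{flank3},$$

by default `GACGAAACACCG` and `GTTTAAGAGCTA` (12 nt each, so a 20-nt
protospacer gives a 44-nt cassette). For a read $r$ the matcher evaluates
the Hamming distance between every cassette and every length-matched window
of $r$ — substitutions only, no gaps — and keeps pairs with distance
$d \le d_{\max}$ (default 2). The decision rule is:

* no qualifying pair → **unassigned**;
* all minimal-distance pairs involve one sgRNA → **assigned**, at the
  leftmost minimal offset;
* two or more distinct sgRNAs tie at the minimum → **ambiguous**, and the
  read is discarded from counting.

Design points worth making explicit:

* **N policy.** Any symbol outside A/C/G/T mismatches everything,
  *including itself*; an uncalled base always consumes mismatch budget.
* **Offsets are scanned, not anchored**, because amplicon prefixes vary in
  length; offsets are 0-based.
* **Same-guide offset ties stay assigned** (the tie rule is about distinct
  guides); the leftmost offset is reported for determinism.
* **Strand.** Amplicon orientation is fixed by the PCR primers, so only the
  forward strand is scanned by default; `revcomp = TRUE` additionally scans
  the reverse complement.
* Quality scores are ignored throughout.

The scan is implemented in C++ with early termination once a window exceeds
the current best distance; its correctness is not argued but *tested*,
against a deliberately naive exhaustive scorer written independently in R
(500 random libraries/reads per run, including N-containing and patternless
reads).

## From counts to fold changes

Counts $c_{is}$ (guide $i$, sample $s$) are normalised to
reads-per-million with a symmetric pseudocount:

$$f_{is} = \frac{c_{is} + c_0}{\sum_j (c_{js} + c_0)} \times 10^6,
  \qquad c_0 = 0.5 .$$

The pseudocount guarantees finite log fold changes for zero counts —
exactly the guides a dropout screen cares about. Per-sgRNA fold changes are
$\log_2(f_{i,\mathrm{num}}/f_{i,\mathrm{den}})$ for each contrast; gene
scores are plain unweighted means over the gene's guides (no read-depth
weighting, no variance model — the hit calls downstream are threshold-based,
not test-based, so a heavier model would suggest rigour the procedure does
not use).

The five default contrasts are T1, T2, C1, C2 each against T0, plus the
viability contrast `T0vsRef`. The baseline of the viability contrast is
genuinely underdetermined in screens of this design: if a plasmid-pool
sample was sequenced it is the natural denominator, otherwise the expected
uniform frequency $10^6/n$ is the only option. Both are supported
(`contrast_spec(..., denominator = "library_uniform")`); the uniform
expectation is the default. Likewise T2 is compared against T0, not T1, so
that the two treatment thresholds read as cumulative depletion; both
choices are configurable per contrast.

## Control QC and viability exclusion

`control_qc()` scores the two control sets in the viability contrast:

* an essential control counts as **depleted** when its gene mean is
  $\le -2$ (at-least-fourfold depletion; the bound is *inclusive* because
  "at least fourfold" includes fourfold exactly);
* a non-essential control counts as **stable** when its mean is $> -1$
  (*strict*, following the direction of the inequality symbol).

`viability_depleted_genes()` applies the same inclusive fourfold rule to
target genes and returns the exclusion list for hit calling: genes that
kill cells on their own cannot be interpreted as treatment-specific.
Control genes are kept out of that list by default so they never silently
vanish from QC reporting.

## Hit calling

An sgRNA **scores** when it is depleted in both consecutive treatment
rounds — $\mathrm{T1} < -1$ *and* $\mathrm{T2} < -2$, strict inequalities —
and is *not* depleted in the control arm ($\mathrm{C1} < -1$ and
$\mathrm{C2} < -2$). A gene is a **hit** when at least two distinct sgRNAs
score and it is not viability-excluded.

Two rules were genuinely open and are resolved as package defaults:

* whether the control-arm exclusion requires depletion at *both* control
  timepoints or *either*: the default is **both**, mirroring the structure
  of the treatment criterion; `combine = "either"` gives the stricter
  exclusion, and the choice is recorded in the run metadata;
* "independent sgRNAs" is read as distinct sgRNA identifiers; no
  sequence-similarity de-duplication is attempted.

Hit tables are sorted by descending eligible-guide count then gene symbol,
so reruns are byte-identical.

## The synthetic screen generator

Real screen data cannot ship with a package, so every stage is exercised
against `sim_config()` / `make_library()` / `simulate_truth()` /
`simulate_counts()` / `simulate_fastq()`, a generative model of the screen
with planted, recoverable truth:

* **Library**: random unique 20-nt protospacers, 3–12 guides per gene
  (uniform), 45 essential-control and 47 non-essential-control genes next
  to the configured target genes. `well_separated = TRUE` enforces a
  minimum pairwise Hamming distance of 5 ($2 d_{\max} + 1$ at the default
  budget), which makes error-free read assignment provably unambiguous.
* **Effects** (log2 scale): essential-class genes draw a viability effect
  from $\mathcal N(-3, 0.5)$, applied in *every* sample from T0 on; hit
  genes draw a per-round treatment effect from $\mathcal N(-1.5, 0.3)$,
  applied once at T1 and twice at T2, in the treatment arm only. Per-guide
  offsets $\mathcal N(0, 0.25)$ around the gene effect are drawn once and
  reused across timepoints. The defaults are chosen so planted effects
  straddle the calling thresholds rather than trivially clearing them:
  a $-1.5$/round hit must pass $\mathrm{T1} < -1$ through noise.
* **Abundance and sampling**: lognormal baseline (sdlog 1.0) times the
  effect multipliers; per-sample counts are multinomial at fixed depth
  (default $10^6$), optionally with gamma perturbation of abundances first
  (unit mean, variance 0.05), i.e. negative-binomial-like overdispersion
  that still respects fixed sequencing depth. Dispersion 0 gives the pure
  multinomial.
* **Reads**: each read is random prefix + cassette + random suffix at 75 nt
  with per-base substitution errors (default 0.1%), shuffled, constant
  quality, byte-identical under a fixed seed.

What the generator deliberately does *not* model: transduction MOI and
multiple integrations, FACS bottlenecks, PCR jackpotting, real T-cell
biology, indels in reads. Passing tests therefore demonstrate that the
*procedure* recovers planted truth under honest sampling noise — not that
any particular biological screen was analysed correctly.

One property of the model is worth knowing when interpreting results:
fold-change estimates are compositional. When planted hits hold a large
share of the pool, their depletion inflates everyone else's frequencies,
and estimates converge on the planted effects only in the sparse-hit
regime. The package's recovery tests use sparse hits (5% of 200 genes) for
exactly this reason; a screen in which a third of the pool drops out would
need a different normalisation baseline.

## Numerical and testing choices

* Problem sizes: matcher cross-validation uses 500 random instances of up
  to 50 patterns against 60-nt reads; FASTQ round-trips use $10^5$ reads
  over ~150-guide well-separated libraries; recovery and null-calibration
  runs use 200 target genes plus the full 92 control genes (~2,200 guides)
  at depth $10^6$, five and ten seeds respectively; the full-shape
  demonstration (analysis stage 6) uses 1,572 genes / ~11,000 guides at
  depth $2 \times 10^6$, count-level only.
* All simulation seeds derive deterministically from a single user seed,
  with distinct sub-streams per operation, so stages can be rerun
  independently and reproduce byte-identical artifacts.
* Degenerate inputs have defined behaviour: empty FASTQ → zero counts and
  zero stats; all-zero count column → uniform frequencies plus a warning;
  a control category with no genes → `NA` fraction plus a warning, never a
  silent 0/0.
* Thresholds at boundaries are tested explicitly: a guide at exactly
  $-1.0$ in T1 does **not** pass treatment (strict), a gene mean at exactly
  $-2.0$ **is** viability-depleted (inclusive).

## Known limitations

* Substitution-only matching: a read with an indel inside the cassette is
  counted against the mismatch budget positionally and usually lost.
* No statistical ranking of hits (no p-values, no FDR): the procedure is a
  faithful implementation of a threshold rule, and inherits its
  sensitivity to threshold placement.
* Single pass per arm: without replicates, guide-level variance cannot be
  estimated from the data, which is precisely why the control genes carry
  the QC burden.
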