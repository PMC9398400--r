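---
title: "Designing genome-orthogonal TALE binding elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing genome-orthogonal TALE binding elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotale)
```

## The problem

A designer TALE (dTALE) used as a synthetic transcription activator will
bind, with reduced affinity, genomic sequences a few mismatches away
from its intended effector-binding element (EBE). In a plant genome of
several hundred megabases, a random 19-mer typically has hundreds of
windows within 4 mismatches, and a well-placed near-match upstream of a
TATA box can activate an endogenous gene strongly. `orthotale`
implements a design procedure for EBEs that minimizes this risk, and an
audit procedure that quantifies what risk remains for a given element.

## The model

An EBE is a 19-mer over {A,C,G,T} starting with the invariant T₀
thymine. Positions are numbered 1-based with **T₀ = position 1**
throughout. This is a deliberate coordinate choice: the literature often
calls the leading thymine "position 0", but the position weight
1/√p must be finite at the first position, and published off-target
tables flag first-base mismatches, so the scoring coordinate system
must include T₀ as a real position. Bases 2..19 are read by 18 canonical
repeats via the RVD code (HD → C, NN → G, NI → A, NG → T); T₀ itself is
coordinated by degenerate N-terminal repeats and has no repeat in the
array, which is why `ebe_to_rvds()` returns 18 RVDs for a 19-mer.

For a genomic site with mismatches at positions $P$:

$$S_{OFF} = \sum_{p \in P} \frac{1}{\sqrt{p}} \; \bigl(\text{pref}(RVD_p, b_p) - 0.5\bigr)(-2)$$

where $\text{pref}$ is the RVD-base preference in $[0,1]$ of the
*designed* RVD at position $p$ for the *genomic* base $b_p$. S_M maps
preference affinely onto $[-1, 1]$: a fully disfavored pairing scores
$+1$ (the mismatch disrupts binding — good for orthogonality), a cognate
pairing $-1$, a neutral one $0$. The factor $1/\sqrt{p}$ encodes that
T₀-proximal mismatches are less tolerated than T₀-distal ones, so
proximal mismatches contribute more to the score. A perfect match is the
empty sum, $S_{OFF} = 0$.

Per candidate, the 200 closest off-targets with at least 3 mismatches
are scored. Their mean is the neverword score $S_N$ (higher = the
genome's nearest neighbors are more disrupted = safer), and the ratio of
the mean of the 100 lowest scores to the mean of the remaining 100
summarizes the shape of the distribution: a ratio near 1 means evenly
spread risk, a ratio well below 1 flags a dangerous low-score tail.

### Scoring a T₀ mismatch

No RVD exists at position 1, so the model cannot look a T₀ mismatch up
in the preference matrix. How such a mismatch should be scored is
genuinely open; we chose a fixed, configurable preference
(`t0_preference`, default 0). The default asserts that a non-T at T₀ is
maximally disfavored — consistent with T₀ being essential for binding —
and yields the largest possible contribution ($S_M = 1$ at $F_P = 1$).
Users who consider T₀-mismatched windows to be non-sites at all can
instead filter them out before scoring.

### The preference matrix

The built-in matrix is derived from the canonical code alone: cognate
bases get 1.0, NN's documented weaker preference for A gets 0.6, all
other pairings 0.0. Quantitative preference tables measured from binding
or activation data can be substituted as a TSV
(`load_preference_matrix()`; header `RVD A C G T`, values in $[0,1]$,
cognate base must be the row maximum) without code changes. The matrix
is position-independent by design: all position dependence in the model
is carried by $F_P$, keeping the two factors interpretable and
separately replaceable.

## The design pipeline

`run_design()` chains five stages, all deterministic under one seed:

1. **generate** — random 19-mers, T₀ fixed, bases 2..19 i.i.d. with
   weights A:C:G:T = 4:5:5:5 (close to rice genome composition;
   configurable). Rejection sampling enforces distinctness and a
   pairwise Hamming distance ≥ 2, with a bounded attempt budget so
   infeasible requests fail rather than loop.
2. **filter** — drop candidates with any genomic window (either strand)
   closer than 3 mismatches. The metric is ungapped Hamming distance
   over all same-length windows: TALE repeats read contiguous bases, and
   gapped alignments of a 19-mer to a genome are not a binding model.
3. **scan** — all windows within the scoring ceiling (default 6
   mismatches) of each surviving candidate.
4. **select** — the `n_closest` (default 200) closest sites with ≥ 3
   mismatches; "closest" sorts by mismatch count, then by the total
   position weight $\sum_{p \in P} 1/\sqrt{p}$ descending (the more
   T₀-proximal configuration is the nearer threat), then by coordinate,
   so the selection is deterministic.
5. **rank** — highest $S_N$ first; $S_N$ ties within an absolute
   tolerance (default 1e-9) are broken by $|ratio - 1|$ ascending, then
   by sequence lexicographic order. The multi-objective phrasing
   "highest S_N and ratio closest to 1" is thus resolved
   lexicographically — $S_N$ is the orthogonality measure, the ratio a
   distribution check — rather than by inventing composite weights. An
   alternative `method = "topk"` (filter to the k = 10 best $S_N$, pick
   min $|ratio - 1|$) is available for sensitivity checks.

When a genome yields fewer than 200 eligible sites, all are scored, the
halves split ⌊n/2⌋ / ⌈n/2⌉, and the report row is flagged `short_set`.
With fewer than two scores the ratio is undefined and returned as `NA`
with a classed warning; the same applies when the upper-half mean is
exactly zero. Candidates with *no* scorable site within the ceiling are
reported but excluded from ranking: their risk estimate is an empty set,
not a score of zero.

## The genome scan

`scan_genome()` is exact: the EBE is split into `max_mismatch + 1`
near-equal contiguous blocks; by the pigeonhole principle any window
within the budget must contain at least one block verbatim. Block
occurrences are located with `Biostrings::matchPattern`, and every
candidate window is then verified position-by-position. Windows
containing any non-ACGT character are excluded (soft-masked lowercase is
uppercased first; Ns disqualify). Both strands are searched by default —
a functional EBE can occur on either strand — and minus-strand hits are
reported reverse-complemented into binding orientation with mismatch
positions in EBE coordinates. Coordinates are 0-based half-open
internally and in BED output, 1-based in GFF3-facing code. Overlapping
hits on opposite strands are distinct sites, keyed (chrom, start,
strand).

`brute_force_scan()` implements the same contract as a sliding
per-position comparison with no seeding. It exists so that the fast path
can be proven, not assumed, equivalent: the suite compares complete hit
sets on dozens of random genomes across budgets 0–5 and all strand
modes.

## Gene-context annotation

Gene models are built from GFF3 with the longest mRNA as each gene's
representative (a deterministic single-model-per-gene rule that matches
per-gene counting downstream); introns are exon gaps, UTRs come from
explicit features or exon-minus-CDS split by strand. Each off-target
site is annotated against every gene whose span ± 5 kbp touches it, with
genic precedence CDS > 5'UTR > 3'UTR > intron.

The boundary between "upstream/downstream" and "intergenic" for
non-genic associations is not standardized — both lie within the 5 kbp
window. We label a site upstream/downstream only of its *nearest* gene
(strand-aware side of the span, distance measured from the site
midpoint to the span boundary); associations with farther genes within
the window are intergenic. This is an interpretation, flagged here
deliberately: it is deterministic, keeps a populous residual intergenic
class, and matches how published site tables label specific near-gene
hits, but per-category counts from other tools may bin flank
associations differently. `summarize_categories()` likewise exposes two
counting modes, because published per-category gene totals do not state
whether a gene hit by several sites was counted once or per category:
`"first"` (default) counts each gene once under its highest-precedence
category, `"all"` counts it wherever it occurs.

## Synthetic fixtures

`make_synthetic_genome()` emulates exactly what the scanning machinery
needs: i.i.d. background at a configurable GC (default 0.435, rice-like)
with variants of an EBE planted at known loci, strands, and mismatch
positions. After planting, the generator re-scans with the brute-force
oracle and redraws (bounded retries) if the background happens to
contain an unintended window at or below the largest planted mismatch
count — so the truth table is the *complete* hit inventory at that
budget, and closed-loop tests can assert exact equality.
`make_synthetic_annotation()` adds non-overlapping 1–4-exon gene models
with UTRs as valid GFF3.

What the fixtures do not emulate: repeat structure, segmental
duplication, isochore GC variation, soft-masking, and chromosome-scale
contiguity. Passing tests therefore demonstrate correctness of the
search, scoring, and annotation logic — hit sets, mismatch counts,
category assignment — not that a 19-mer's real-genome census will
resemble a random-background census; real genomes are far more
self-similar. Census counts against real assemblies may also depend on
strand and dedup conventions of other tools (`strands` is a flag for
this reason).

## Problem sizes and numerical choices

The shipped tests and acceptance script run at deliberately modest
sizes chosen to exercise every code path with exact oracles: 5–12 kb
fixture genomes for scan/oracle equivalence (50 genomes × budgets 0–5 ×
3 strand modes), a 60–120 kb random genome and 4–8 candidates for
end-to-end design, and 10,000 draws for the composition
goodness-of-fit (χ², α = 0.01). On a random genome of this size a
19-mer's nearest neighbors sit at 5–6 mismatches, so design runs score
short sets (flagged as such); the machinery is identical at census
scale — scanning a ~380 Mb assembly at budget 4 is minutes of work with
the pigeonhole filter but is not part of the default suite, and needs
the assembly locally (see `inst/extdata/README.md`).

Other numerical details, fixed once: the $S_N$ ranking tie tolerance is
absolute 1e-9 (scores are sums of at most 19 terms of magnitude ≤ 1, so
relative and absolute tolerance are interchangeable at this scale);
final ties break lexicographically so output is reproducible across
platforms; `closest_offtargets()` uses the position-weight tie-break
described above; division-by-zero in the ratio is surfaced as `NA` plus
a warning, never as `Inf`.

## Bundled reference data

The package ships the published off-target site tables of two designer
TALEs characterized in rice, as plain TSVs. The dTALE1 element itself is
not bundled as a string but *reconstructed* (`dtale1_ebe()`): each
reported off-target 19-mer equals the EBE at every unflagged position,
so a per-position consensus of unflagged bases recovers it. The
reconstruction is exact, with one caveat the code surfaces rather than
hides: one table row carries an unflagged mismatch at position 6 (four
of five rows agree on G there; `reconstruct_ebe()` reports it in
`$conflicts` and uses the majority base). For the second element the
published rows flag positions 6 and 8 in every row, so those two
positions are under-determined (`$undetermined`); the tests check its
properties over all consistent completions instead of asserting a single
sequence.

## Limitations

- The additive S_OFF model ignores epistasis between mismatches,
  repeat-composition effects (multiple strong RVDs can compensate for
  mismatches in long arrays), and aberrant repeat lengths; it is a
  ranking heuristic, not a binding-affinity model.
- The built-in preference matrix is a coarse stand-in for measured
  preference tables; with it, most S_M terms are 1 and S_OFF is nearly
  a weighted mismatch count. Rankings sharpen considerably with a
  quantitative matrix supplied by the user.
- Orthogonality is assessed against sequence only: chromatin
  accessibility, promoter context (e.g. distance to a TATA box), and
  expression of the neighboring gene are outside the model, which is
  why the audit output includes gene-context categories for downstream
  judgment rather than a single risk number.
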