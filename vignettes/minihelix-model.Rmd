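---
title: "The three-minihelix model of cloverleaf tRNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-minihelix model of cloverleaf tRNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minihelix)
```

## The model

Cloverleaf tRNA is taken to descend from three ligated 31-nt proto-tRNA
minihelices. Each minihelix is a 17-nt microhelix — a 5-nt stem, 7-nt
loop (anticodon at loop positions 3–5), 5-nt stem — flanked by a 2 × 7-nt
acceptor stem. Ligating three minihelices gives a 93-nt precursor; a
symmetrical 9-nt deletion inside each of the two 14-nt acceptor-stem
junctions (14 − 9 = 5) leaves two 5-nt acceptor-stem relics and the
75-nt conserved core:

| segment | positions | origin |
|---|---|---|
| AS5 | 1–7 | acceptor stem of minihelix 1 |
| DMH | 8–24 | D-loop microhelix (refolded in the cloverleaf) |
| DREM | 25–29 | acceptor-stem relic (pairs with the V loop in the minihelix world) |
| ACMH | 30–46 | anticodon microhelix |
| VLOOP | 47–51 | acceptor-stem relic (the simple 5-nt variable loop) |
| TMH | 52–68 | T-loop microhelix |
| AS3 | 69–75 | acceptor stem of minihelix 3 |

Everything in the package is expressed on this 1-based 75-nt coordinate
system. The 3'-CCA is enzymatically added in archaea and eukaryotes and
is outside the model; segmentation strips it.

The evidence the package quantifies: the anticodon and T stem-loops are
similar in sequence (`seq_identity()` on the reconstructed ancestors
gives 12 matches over the 14 comparable positions) and superposable in
3D (`overlay_ac_vs_t()`); the D relic and V loop retain antiparallel
complementarity (`antiparallel_pair_count("GACCG", "TGGTC")`: 4/5
strict Watson–Crick, 5/5 once the G:T wobble pair between positions 29
and 47 is allowed); and the D-loop ancestor `TAGTCTAGCCTGGACTA` still
folds as a perfect 5-7-5 microhelix whose GCC anticodon decodes glycine.

## Segmentation without a structure

Deposited tRNA sequences rarely come with a trusted secondary
structure, so `segment_trna()` locates arms greedily:

1. The outermost 7 nt on each side are the acceptor stem halves.
2. The T microhelix is the 17 nt immediately 5' of AS3 — in the model
   the T arm is never separated from the acceptor stem by indels.
3. The anticodon microhelix is the best-scoring 17-nt window between
   the D region and the T arm, scored as a 5-7-5 stem-loop
   (Watson–Crick pair = 1, wobble G:T = 0.5, maximum 5). A raw stem
   score cannot discriminate on its own: in an intact core the D
   microhelix also folds 5/5. Candidate windows are therefore ranked by
   `stem score − 0.1 × |v − 5|`, where `v` is the implied V-region
   length; the mild penalty encodes the model's expectation that the
   simple V loop is 5 nt while leaving room for genuinely inserted V
   loops (a 4-nt insertion costs only 0.4). Remaining ties resolve to
   the smaller start. Windows must score at least `min_stem_score`
   (default 3, i.e. at least three good pairs of five) or segmentation
   fails with a diagnostic rather than guessing.
4. The D region is everything between AS5 and the anticodon arm; its
   3'-most 5 nt are the DREM relic (the model fixes the relic adjacent
   to the anticodon stem), the rest is DMH, and any shortfall from the
   full 22 nt is a D deletion. A D region above 22 nt violates the
   model and is an error, never a silent truncation.

When a dot-bracket line is supplied, hairpins whose outermost pair
encloses exactly 15 nt replace the exhaustive window scan as
candidates; scoring and tie-breaking are unchanged.

CCA stripping is conditional: a terminal CCA (or partial CA/A) is
removed only if the outermost 7+7 positions pair at least as well
afterwards. This keeps stripping idempotent for sequences that already
end in a genuine acceptor stem ending in C/A — relevant because the
simulator's random acceptor stems occasionally end in CCA.

Type II tRNAs (long variable arms) are segmented with `v_status =
"inserted"`; the package does not subdivide the long V arm, which the
model does not cover.

### Normalization

Database sequences carry one-letter codes for modified nucleosides. The
map used is: `U→T`, `5` (5-methyl-cytosine) `→C`, `P` (pseudouridine)
`→T`, `1` and `Y` (adenosine derivatives) `→A`. `O` denotes a uracil
*or* guanosine derivative; being genuinely ambiguous it becomes `N`,
which the default strict mode rejects with the offending position, and
which lenient mode carries through (such positions count with the gaps
in profiles, never as observations). The internal alphabet is DNA-style
because the reconstructed ancestral sequences are printed with T;
`write_fasta(..., alphabet = "rna")` converts on output.

## The generative simulator

`ligate_and_delete()` fixes the order of events as ligate → delete (the
true order is unknowable; this one is the simplest that reproduces the
arithmetic). Which 9 of the 14 junction nucleotides are removed is
constrained only by the model's alignments — the D relic at 25–29 aligns
with acceptor positions 3–7, the V loop at 47–51 with 69–73 — so the
default `ligation_plan()` retains junction positions 10–14 (downstream
stem 3–7) at junction 1 and 1–5 (upstream stem 1–5) at junction 2.
Alternative contiguous windows are accepted as configuration for
exploration.

`snapback_replicate()` models minihelix replication as 3'-ligation of a
complementary primer followed by templated extension: each round
appends the exact reverse complement of the previous 31-nt unit.
Copying is deterministic by default; an optional per-base substitution
rate with a seeded PRNG supports drift experiments.

## Synthetic data: what it emulates and what it does not

`generate_trna_set()` draws i.i.d. records from the 75-nt ancestral
core with:

* per-position substitution rate 0.05 — chosen to keep stems
  recognizable while producing visible logo degradation, of the order
  of the variability seen across deep archaeal alignments;
* D-loop deletion probability 0.8, matching the archaeal survey
  proportion of ~20% intact D loops, with deletion lengths uniform on
  1–9 (most real D deletions are a few nucleotides; the support allows
  up to 14) confined to DMH;
* V-loop insertion probability 0.2, lengths uniform on 1–4;
* anticodon positions 37–39 protected from substitution by default,
  because each anticodon is its own lineage and mutating it would
  confound lineage identity.

The generator is Mersenne–Twister seeded and byte-reproducible. It does
**not** emulate phylogenetic correlation (records are i.i.d., not a
coalescent), anticodon diversity, position-specific conservation
differences, or modified-base codes. Passing tests on synthetic sets
therefore demonstrates that the pipeline's bookkeeping and estimators
are correct under the model's own assumptions — not that real archaeal
tRNAs follow the model.

Truth-label recovery: segmentation recovers the configured deletion and
insertion lengths exactly while the anticodon stem remains recognizable.
At substitution rate 0.05 roughly 1% of records accumulate enough stem
damage that arm location fails or mislocates; these are reported (the
`failures` attribute of `segment_set()`, and a warning), never silent.

## Profiles

Frequencies are computed over non-gap observations, with the gap
fraction reported separately; a deleted stretch inside DMH is rendered
as gaps left-aligned against the 5' end of the D region (the actual
deletion site within the loop cannot be reconstructed from sequence),
and V-loop insertions are excluded from core columns so that every
column always sums to the number of sequences. Information content is
`2 − H` bits per column, in [0, 2]; the optional small-sample
correction `3/(2 ln 2 · n)` is off by default, matching common logo
practice. Consensus calling requires a majority frequency above a
threshold in (0.25, 1] and writes `N` below it, `-` for all-gap
columns; `segment_similarity()` excludes `N`/`X` positions from both
numerator and denominator and reports the denominator used.

## Superposition

`kabsch_superpose()` computes the least-squares optimal rigid
superposition via SVD of the 3×3 cross-covariance of the centred point
sets, with the usual determinant-sign correction so the rotation is
always proper; degenerate inputs (fewer than 3 points, collinear sets)
error or warn. The default backbone atom set is P, O5', C5', C4', C3',
O3' (6 atoms per residue, 102 points per 17-residue arm); `"p"` and
`"heavy"` are available. Residues with missing atoms are dropped
pairwise from both selections in `overlay_ac_vs_t()`. The test suite
checks the SVD result against an independent Euler-angle grid search
with local refinement (agreement within 0.01 Å) and against an
established reference implementation. The published ~1.9 Å anticodon/T
arm RMSD refers to a deposited yeast tRNA-Phe structure that the
package does not ship; `overlay_ac_vs_t()` accepts any user-supplied
PDB file and explicit 17-residue ranges (deposited structures with
D-loop deletions need ranges adjusted relative to the 75-nt scheme).

## Problem sizes and numerical choices

The shipped tests run the survey pipeline at n = 500 (classification)
and n = 100–200 (profiles, truth recovery), sizes at which binomial 3σ
bands are tight enough to be informative while the whole suite stays
interactive. Stem scoring uses 0.5 per wobble pair so that a wobble is
worth more than a mismatch but never outweighs a Watson–Crick pair;
`min_stem_score = 3` tolerates two damaged pairs out of five.
Consensus ties between equally frequent letters resolve in A, C, G, T
order deterministically.

## Known limitations

* No thermodynamic folding or general RNA secondary-structure
  prediction; arms are located by the greedy stem score only.
* No Sprinzl-number conversion; coordinates are model coordinates.
* Intron-containing or length-outlying genes (outside 55–100 nt after
  CCA stripping) are rejected, not repaired.
* The anticodon of the middle ancestral minihelix is unknowable; the
  TGT placeholder in `ancestral_sequences()` is a fixture, not a claim.
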