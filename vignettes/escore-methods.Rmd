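---
title: "Embedding-based alignment scoring and alignment distances: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-based alignment scoring and alignment distances: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escore)
```

# The scoring model

A substitution matrix assigns one score per amino-acid pair, independent of
where the residues sit.  The E-score replaces the lookup with a function of
*positions*: given per-residue embedding matrices $E(P)$ ($m \times n$) and
$E(Q)$ ($m' \times n$), the score of aligning position $i$ of $P$ with
position $j$ of $Q$ is the cosine similarity of the corresponding rows,

$$\mathrm{Escore}(i,j) \;=\;
  \frac{E(P)_i \cdot E(Q)_j}{\lVert E(P)_i\rVert\,\lVert E(Q)_j\rVert}
  \;\in\; [-1, 1].$$

The assumptions this rests on:

* **one embedding row per residue** — adapters for real protein language
  models must strip any special/boundary tokens before the matrix reaches
  the package (`register_embedding_model()` documents this contract and
  `model_embed()` validates the row count);
* **no zero rows** — the cosine of a zero vector is undefined; a zero row
  indicates a broken provider, and the package treats it as a hard error
  rather than scoring it 0, since silent zeros would bias alignments;
* **contextuality is the provider's job** — the aligner only ever sees a
  positional score matrix, so a context-free provider reduces the whole
  machinery exactly to fixed-matrix alignment (this reduction is tested).

Both scorer families expose the same interface: a positional score matrix
plus affine gap parameters.  A gap run of length $k$ costs
$\mathrm{open} + k \cdot \mathrm{extend}$, the NCBI BLAST convention, with
defaults $(-11, -1)$ for BLOSUM matrices and $(-0.25, -0.01)$ for E-scores.
The E-score gap penalties are on the cosine scale (scores in $[-1,1]$ rather
than BLOSUM's roughly $[-4, 11]$), which is why they are two orders of
magnitude smaller; they are exposed as arguments and flags because only
their scale, not their exact values, is principled.

# The aligner

`align_pair()` implements the Gotoh three-state recurrence
($M$/$I_x$/$I_y$) in C++, in global and semi-global modes.  Semi-global —
free leading and trailing gap runs in either row — is the default mode of
the evaluation pipeline: homologous domain sequences are expected to align
end to end, and charging end gaps would distort the alignment of sequences
of unequal length.

Numerical and determinism choices:

* Scores are doubles throughout (E-scores are non-integer); there is no
  integer fast path.
* Traceback tie-breaking: diagonal over gap-in-Q over gap-in-P, and gap
  *extension* over gap *opening* at equal score.  Among equal-scoring
  semi-global end cells, the one with the fewest trailing free gaps wins,
  with the bottom-right corner preferred.  Any tie encountered is surfaced
  in the `ties` flag so downstream analyses can detect ambiguous optima.
* The semi-global end-cell scan includes the degenerate corners where one
  sequence lies entirely in leading gaps and the other entirely in trailing
  gaps (score 0); with strongly negative scoring this *is* occasionally the
  optimum, and omitting it makes the dynamic program disagree with the
  definition of the score.
* Cosine values are clamped to $[-1, 1]$ after the division to stop
  floating-point overshoot from leaking out of range.

Correctness is established against `brute_force_align()`, an exhaustive
enumeration of every monotone gap placement (feasible to $|P|+|Q| \le 12$)
scored by the affine cost definition alone — it shares no code with the
recurrence.  The test suite checks 200+ random instances in both modes with
both scorer families, plus a round-trip property: re-scoring any returned
alignment with `score_alignment()` reproduces the reported score exactly.

# The five alignment distances

All five compare two alignments $A_1, A_2$ of the same sequences $P$
(length $n$) and $Q$ (length $m$), lie in $[0,1]$, vanish iff the inputs
describe the same residue pairing structure, and are symmetric.

**Homology-set distances.**  For each residue, its homology set is the
symbol opposite it in the alignment, under three gap treatments: `ssp`
drops gaps (empty set), `seq` labels every gap in sequence $k$ as one
symbol $g^k$, `pos` labels it $g^k_c$ where $c$ counts the residue letters
preceding the gap in that row.  `d_ssp` is one minus the ratio of summed
intersections to summed unions (Jaccard style); `d_seq`/`d_pos` average the
per-position normalized symmetric difference
$|H_1 \triangle H_2| / (|H_1| + |H_2|)$.  Two conventions required a
decision:

* *Aggregation*: the symmetric-difference form is defined per position; the
  scalar distance here is the mean over the $n + m$ residue positions of
  both sequences.  The per-position sets are also exposed
  (`homology_sets()`) for anyone needing a different aggregation.
* *$0/0$*: a position where both sets are empty (possible in the `ssp`
  variant) contributes 0, and an all-empty comparison yields distance 0.
* *Gap subscripts* in the `pos` variant count letters *strictly before* the
  gap.  Any fixed per-row offset in this label changes no distance value
  (labels are only ever compared for equality within a row), so the choice
  is observationally equivalent to counting from 1; the
  strictly-before form is used because it matches the worked positional
  example reproduced in the tests.

**Relative displacement** (`relative_displacement_distance`): with $p_i$
the alignment column of $P[i]$ and $q_j$ of $Q[j]$, the displacement
$d_A(i,j) = p_i - q_j$ describes where the alignment puts the two residues
relative to each other; the distance averages
$|d_{A_1}(i,j) - d_{A_2}(i,j)|$ over all $nm$ residue pairs, divided by
$m+n$, the provable bound on each term (the bound itself is asserted over
randomized sweeps in the tests).

**Closest context** (`closest_context_distance`): combines position and
context.  For each residue and each alignment $\ell$: if the residue faces
a *letter*, the contribution is the fewest letters separating the residue's
position in the *other* alignment from the nearest occurrence of that same
letter in the other alignment's opposite row (gaps do not count; ranges
run half-open, and a reversed range $w[i..j]$ with $i > j$ denotes
positions $j$ through $i-1$); if it faces a *gap*, the contribution is the
absolute difference of letters preceding its position in the two opposite
rows.  Contributions are bounded by $m$ (for $P$'s residues) and $n$ (for
$Q$'s), giving the $4mn$ normalization.  In the letter case the target
letter always occurs in the other row (both alignments contain the same
$Q$), so "no occurrence" is asserted impossible rather than handled.
`closest_context_contributions()` exposes the per-residue terms.

# The synthetic embedder

`synthetic_embedder()` exists so every pipeline component is exercisable
offline and deterministically.  Each amino acid (including the ambiguity
codes B, Z, X, U, O, so the shape contract is total) gets a base vector
drawn once from a seeded standard normal; a residue's embedding is its base
vector plus neighbours' base vectors within `context_window`, weighted
$r^{|\mathrm{offset}|}$ with $r = 0.5$ — a simple, monotone context
influence.  Defaults: dimension 32, window 2.  In moderate dimension the
base vectors are near-orthogonal, so identical residues in identical
contexts score 1, identical residues in different contexts score below 1,
and unrelated residues score near 0.  With `context_window = 0` the
embedding is context-free and the induced behaviour is exactly a fixed
$25 \times 25$ cosine matrix (`context_free_matrix()`).

What it does *not* emulate: biochemical structure in the similarity (no
hydrophobicity clusters), long-range context, or the anisotropic geometry
of real transformer embeddings.  Tests passing with it demonstrate the
correctness of the machinery around an embedding, not the biological
quality of any particular embedding.

# The evaluation pipeline and the synthetic benchmark

`evaluate_msa()` mirrors the standard reference-MSA comparison design:
sample up to `max_pairs` (default 1000) unordered sequence pairs uniformly
without replacement (all pairs when fewer exist), align each pair under
every scorer, compute distances to the MSA-induced reference
(`induced_pairwise()`: the two rows minus columns gapped in both), and
aggregate means, better/equal/worse tallies (exact comparison at $10^{-12}$
— distinct scorers do produce byte-identical alignments, so exact ties are
real), and paired two-sided Wilcoxon signed-rank p-values.  The Wilcoxon
variant is R's `wilcox.test` (exact for small samples without ties, normal
approximation with continuity correction otherwise); an
exact-enumeration oracle in the tests pins its small-sample behaviour.
The design is strictly paired: a pair on which any scorer fails is dropped
from all scorers, with a warning.

`average_score_matrices()` summarizes an embedding on an MSA as two
$20 \times 20$ matrices — mean E-score of residue pairs sampled from the
same column ("aligned") or different columns ("unaligned").  Decisions:
samples for $(a,b)$ and $(b,a)$ are pooled (symmetry by construction);
never-sampled pairs are `NA`, not 0; unaligned draws may hit the same row
(the count is reported); BLOSUM matrices are rescaled for comparison by
max-absolute-entry division (`scale_substitution_matrix()`), the least
structured of the possible affine scalings.  `matrix_correlation()`
correlates the 210 upper-triangle-with-diagonal cells.

**The benchmark generator.**  `simulate_benchmark_msa()` plants a conserved
central motif (12 residues) in a random 80-residue ancestor and derives 8
rows by substituting non-motif positions at rate 0.4 and deleting one block
of up to 6 residues per row (with probability 0.9).  Deletion-only descent
means ancestor positions are MSA columns and the reference alignment is
exact by construction.  The parameter choices model a distantly related
("twilight zone") family: 40% per-row substitution gives roughly 35–40%
pairwise identity, the regime where fixed matrices are known to struggle;
deletions are short and ubiquitous as in curated domain families; the
conserved motif anchors the family the way a functional core does.  Against
a context-free identity/mismatch baseline ($+1/-1$, gaps $-2/-0.5$ — a
unit-scale analogue of matrix-scorer gap conventions, since BLAST's protein
defaults would forbid gaps entirely on a $\pm 1$ matrix), the context-aware
scorer can exploit the fact that a substituted residue keeps its ancestral
neighbourhood.  The acceptance suite runs 20 generator seeds with 10
sampled pairs each and requires the context-aware scorer to achieve lower
mean `d_cc`, `d_d` and `d_pos` with paired Wilcoxon $p < 0.01$ across
seeds.  What passing shows: the full pipeline — embedding, affine-gap DP,
reference projection, distances, paired testing — prefers the scorer whose
assumptions match the generative process.  What it does not show: that any
particular real protein language model beats any particular matrix on real
families; that claim needs real embeddings through the adapter interface.

# Problem sizes

Default test and benchmark sizes were chosen so that exhaustive oracles
remain exact and sweeps remain dense: enumeration-oracle instances at
sequence lengths 1–6 (the full enumeration up to 8989 alignments per
instance), distance-axiom sweeps over 500 random alignment pairs at lengths
up to 5, benchmark families of 8 × 80 residues over 20 seeds, score-matrix
sampling at $10^3$–$10^4$ draws in tests versus the $10^5$ default in the
interface.

# The embedding cache

Embeddings of real models are expensive and reused across many pairwise
alignments, so `embedding_cache()` persists one entry per (model,
sequence-id) key.  The store is a directory of RDS files rather than a
single binary container; each entry records the residue string it was
computed from, and a lookup under a reused id with a different sequence is
an error — stale vectors must never silently flow into alignments.  A
cache hit returns the matrix without recomputation; a miss returns `NULL`
(absence is an ordinary result, not an exception).

# Known limitations

* No local (Smith–Waterman) mode, banding, or linear-memory traceback; the
  DP allocates $O(mn)$ and targets domain-length sequences.
* The `pos`/`seq` scalar distances commit to mean aggregation (above);
  other normalizations of the same per-position quotients exist.
* The synthetic embedder's uniform random substitution model gives
  general-purpose matrices like BLOSUM no advantage over identity scoring;
  comparisons between *matrix* families are outside what the synthetic
  benchmark can resolve.
* `read_msa()` reads aligned FASTA and CLUSTAL only; curated-database
  fetching, Stockholm and PHYLIP are out of scope.
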