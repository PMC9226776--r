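---
title: "Screening metagenomes for lipolytic enzymes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metagenomes for lipolytic enzymes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liposcan)
```

`liposcan` identifies putative lipolytic proteins (esterases and lipases)
in predicted-protein sets from assembled metagenomes and compares their
family and taxon abundance profiles across habitats. This vignette is the
package's own account of the models behind each step, the parameters that
matter, and the design choices taken where the procedure was genuinely
open.

## 1. The profile-HMM engine

Most lipolytic families share the α/β-hydrolase fold with a G-x-S-x-G
pentapeptide around the catalytic serine, and family membership is best
detected by position-specific models rather than pairwise similarity. Each
family is modelled as a Plan7-style profile HMM built from that family's
multiple sequence alignment.

**Architecture.** Alignment columns whose gap fraction is strictly below
`gap_threshold` (default 0.5, the conventional rule) become match states
$M_1..M_L$ in order; residues in the remaining columns are insertions
$I_k$ attached to the preceding match node; gaps at match columns are
deletions $D_k$. There are no $I\!\to\!D$ or $D\!\to\!I$ transitions; the
rare row that would need one (an insertion immediately followed by a
deleted match column) simply contributes no count for that pair.

**Estimation.** Emissions and transitions are (optionally
Henikoff-weighted) counts with a Laplace $+1$ pseudocount:
$e_k(a) = (c_k(a) + 1) / (\sum_b c_k(b) + 20)$, and analogously for the
3-, 2- and 2-way transition distributions out of $M_k$, $I_k$, $D_k$.
This is deliberately simpler than Dirichlet-mixture priors: every
probability is strictly positive, every distribution sums to one within
1e-12, and every value is hand-checkable — the unit tests verify the
emission table of a toy alignment cell by cell.

**Scoring.** Queries are scored in local mode: entry into any match state
with probability $1/L$, free exit from any match state, and log-odds
emissions $\log_2 e_k(a)/p_0(a)$ against the Robinson-Robinson background
$p_0$ (uniform 1/20 selectable). Viterbi (best path) and forward (all
paths) scores are computed in bit space by an Rcpp kernel. Because the
model is small and fully explicit, both recursions are tested against
exhaustive path enumeration on all models with $L \le 3$ and sequences of
length $\le 5$ at tolerance 1e-9, and `forward >= viterbi` is asserted on
larger random models.

**E-values.** HMMER calibrates its scores internally; this engine fits a
Gumbel distribution by maximum likelihood to the Viterbi scores of
`n_decoys` i.i.d. background sequences (defaults: 200 decoys of 350 aa — a
typical α/β-hydrolase length — seed 42). With fitted scale $\lambda$ (per
bit) and location $\tau$,

$$E(s) = N \,\bigl(1 - \exp(-e^{-\lambda (s - \tau)})\bigr),$$

where $N$ is the number of query proteins in the scan (a per-scan
convention, documented rather than assumed). The fit is checked by
self-consistency: among the calibration decoys themselves the proportion
with $P \le 0.1$ must be $0.10 \pm 0.05$. The scan cutoff is the published
$E \le 10^{-10}$; the full-sequence score feeds the cutoff; under a single-hit local model
this is the simpler and stricter of the two common conventions
(full-sequence versus best-domain score).

This engine intentionally does **not** reproduce HMMER bit scores: no
multihit mode, no glocal mode, no Dirichlet priors. The method being
implemented is the *database plus decision procedure*; the engine only has
to rank and threshold homology consistently, which the synthetic
benchmarks verify end to end.

## 2. Similarity search

The confirmation tier searches each candidate against a family-labelled
reference registry. Pairwise comparison is exact Smith-Waterman with
affine gaps (BLOSUM62, gap open 11, extend 1), computed by Biostrings'
dynamic-programming aligner; no heuristic seeding is involved, which is
tractable because registries here are small. E-values use the
Karlin-Altschul form $E = K\,m\,n\,e^{-\lambda S}$ with the published
gapped BLOSUM62/11/1 constants ($\lambda = 0.267$, $K = 0.041$); $n$ is
the total residue count of the registry for database searches and the
partner length for pairwise network edges. Identity is counted over
aligned residue-pair columns only (gap columns excluded from the
denominator) and coverage is the aligned query span over the query length
— the common tabular-report semantics. Scores are validated against
brute-force enumeration of all local alignments on strings of length
$\le 6$.

## 3. The annotation decision engine

A protein passes the 200–800 aa length filter, is scanned against the
main family database, and — if it has a profile hit — searched against the
registry. The rules, in order, with their recorded rule ids:

1. no profile hit → `no_hit`;
2. no similarity hit → `unassigned` (`no_sim_hit`);
3. profile and similarity name the same lipolytic family at ≥ 60 %
   identity and ≥ 70 % coverage → `assigned` (`hmm_sim_agree`);
4. best similarity hit in a miscellaneous α/β-hydrolase family →
   `unassigned` (`miscellaneous_best`);
5. identity or coverage below the gates → `unassigned`
   (`weak_similarity`);
6. strong similarity to a non-lipolytic family → `non_lipolytic`;
7. strong similarity to a *different* lipolytic family → `unassigned`
   (`cross_family`).

Rule 7 is a design decision: the disagreement case (profile says family
F, similarity strongly says lipolytic family G) is not covered verbatim
by the decision procedure's stated clauses. Because assignment requires both
routes to name the *same* family, and the non-lipolytic clause applies
only to non-lipolytic targets, the conservative resolution is
`unassigned`. The rule grid is tested for totality: every combination of
hit presence, target category, identity and coverage fires exactly one
rule.

Note the two different coverage gates: ≥ 80 % when assigning reference
sequences to families during database construction, ≥ 70 % during
annotation. Both are separate fields of `lipo_thresholds()` because they are
genuinely different gates, not one threshold reused.

**Pfam-route families.** Families II (GDSL), VIII (β-lactamase-like) and
patatin-like proteins lack the common fold and take a separate route:
a route-profile hit must be confirmed by a hit in a secondary
confirmation profile set (standing in for curated functional-family
models; which profiles confirm which family is registry configuration),
and family VIII is restricted to 350–450 aa. Route hits without
confirmation, or outside the window, are `non_lipolytic`. When a protein
hits both the main and the route database, the path with the lower best
E-value classifies it — a tie-break that rarely matters in practice
because the two databases target disjoint folds.

**Verification networks.** `build_ssn()` draws an edge between two
sequences when their pairwise E-value is ≤ 1e-10 and the raw alignment
score is ≥ 16 (the stricter clustering mode uses 1e-16). The score
threshold is interpreted in raw alignment-score units and is configurable,
since the webserver convention it mirrors is ambiguous about units.

## 4. LPGM normalization and the comparative layer

The abundance unit is LPGM — Lipolytic hits Per Gigabase (of assembly)
per Million (predicted) genes. The formula is isolated in one function:

$$\mathrm{LPGM} = c \times \frac{10^9}{\text{assembly bp}} \times
  \frac{10^6}{\text{gene count}}$$

The unit name fixes the formula up to convention; tests pin its
homogeneity (linear in counts, inverse in both normalizers). For
clustering and display, LPGM values are transformed as $\log_{10}(x+1)$ —
monotone and zero-preserving, the natural reading of "log-transformed"
for a matrix with structural zeros.

**Distances and clustering.** Bray-Curtis dissimilarities
($\sum_k |x_k - y_k| / \sum_k (x_k + y_k)$, via vegan) with Ward
clustering in the classic `ward.D` convention (Lance-Williams update on
the raw dissimilarities, no pre-squaring), matching the
`vegdist = "bray", "ward.D"` pairing. An all-zero sample pair has
undefined dissimilarity; it is set to 0 with a warning.

**ANOSIM.** $R = (\bar r_B - \bar r_W) / (n(n-1)/4)$ over midranks of all
pairwise dissimilarities, with a seeded label-permutation p-value under
the add-one convention ($p = (1 + \#\{R_\pi \ge R\}) / (1 + B)$,
default $B = 9{,}999$). For small $n$ an exact mode enumerates all $n!$
label permutations; tests require exact agreement with an independent
enumeration oracle for $n \le 7$ and a null rejection rate of
$0.05 \pm 0.02$ over 500 seeded trials.

**Indicator associations.** For each genus, the point-biserial
correlation $r$ against the binary membership vector of every habitat
subset of size 1–3 (never the full set) is computed; the genus reports
its best subset. The subset-size cap is a tractability decision — the
full powerset is hopeless at 15 habitats and single habitats or small
combinations are what the networks display. Significance uses a
permutation test of the *selected maximum*: each permutation shuffles the
abundance vector and recomputes the max-over-subsets $r$, which accounts
for subset selection (999 permutations, add-one convention). Plain $r$ is
the default statistic; the group-equalized variant (`func = "r.g"`, a
weighted correlation giving every habitat equal total weight) is offered
because the standard indicator-analysis tooling supports both and
analyses rarely report which variant they used. The bipartite habitat–genus network keeps
significant positive associations ($P \le 0.05$), drops genera with mean
LPGM < 0.5 across samples, and flags genera as unique / pair / multi by
the size of their habitat subset.

## 5. What the synthetic generators emulate

The generators define the package's benchmark conditions and are
first-class, tested code.

* **Families** (`gen_family_msa`): a consensus of 250–450 aa drawn from
  the background with a G-x-S-x-G motif at a recorded position; members
  are per-site mutants at rate 0.10 (pairwise identity ≈ 0.81, safely
  above the 60 % gate) with rare short indels (rate 0.01, length ≤ 2,
  deletions capped at 3 % of the length) so coverage gates cannot be
  violated by construction. Family VIII consensuses are fixed at 400 aa
  so members stay inside the 350–450 aa window.
* **Protein benchmark** (`gen_protein_set`): ~290 proteins under the
  defaults — 20 positives from each of 6 lipolytic families, 10 from each
  route family, 10 members of each of 2 non-lipolytic families, 80
  unrelated random decoys, and 40 "twilight" decoys built by keeping a
  fraction of a target family's consensus positions and replacing the
  rest. Because the aligner pairs up accidental matches, the
  alignment-measured identity runs above the positional fraction by a
  variable amount, so the kept fraction is calibrated per decoy
  (bisection on fresh draws) until the *global-alignment* identity to the
  consensus lies inside the 20–25 % band. That band mirrors the hardest
  published false-positive class: non-lipolytic proteins with residual
  similarity to lipolytic families, just below the 60 % assignment gate.
* **Communities** (`gen_community`): 4 habitats × 6 samples × 30 genera.
  Every genus has Dirichlet concentration 2; each habitat's 2 planted
  indicator genera get 2 + 12 in that habitat only, and per-sample counts
  are multinomial with 50,000 draws (the per-sample gene count; assembly
  sizes are jittered ±10 % so LPGM normalization does real work). The
  contrast of 12 produces the strong habitat partitioning reported for
  real lipolytic profiles (ANOSIM R ≈ 0.6–0.9); `habitat_effect = 0`
  makes samples exchangeable across habitats by construction, which is
  what the null-calibration tests consume.

What the generators do **not** emulate: real phylogenetic correlation
within families (members are i.i.d. mutants of one consensus),
compositional biases of real proteomes, assembly or gene-calling
artefacts, unequal habitat sample sizes, and genuinely overlapping
families. Passing the synthetic benchmarks therefore demonstrates that
the machinery is correct and the decision semantics behave as documented —
not that recall on real metagenomes would be 100 %.

## 6. Numerical choices and degenerate inputs

* Scores are kept in log2 (bit) space end to end; the forward recursion
  uses a numerically stable log-sum-exp.
* Gumbel fitting profiles the location parameter out and solves the
  one-dimensional scale equation by bracketed root finding; a
  zero-variance decoy score distribution is an explicit calibration
  error.
* Scan ties are broken by higher bit score, then lexicographic family
  name; similarity ties by higher raw score, then target id; Ward merges
  inherit `hclust`'s deterministic ordering. Identical inputs and seeds
  give byte-identical outputs, which the pipeline tests assert on disk.
* Empty protein sets annotate to an empty table with a warning; empty
  alignments, ragged rows, unknown registry families, uncalibrated
  profiles, and malformed profile files are errors (the profile parser
  reports the offending line number).
* All RNG use goes through a private-stream helper that restores the
  caller's RNG state, so library calls never perturb user code.

## 7. Problem sizes

The shipped tests and the acceptance script run the full benchmark at the
default conditions: ~290 proteins against 11 calibrated profiles plus a
~140-sequence registry, 100 seeded community runs for structure recovery,
500 null trials for ANOSIM calibration, and 9,999-permutation ANOSIM for
the headline community. These sizes were chosen so the whole suite
completes in minutes on one core while every statistic still has enough
resolution for its stated tolerance.

## 8. Known limitations

* The engine is single-hit local; proteins with two lipolytic domains
  score as their better domain.
* E-values rest on a 200-decoy Gumbel fit; far-tail E-values (≪ 1e-30)
  are extrapolations and should be read as "very significant" rather
  than literally.
* The Karlin-Altschul constants are the published gapped BLOSUM62/11/1
  values, not re-estimated per scoring scheme; changing the matrix or gap
  costs without updating them shifts the similarity E-value scale.
* Indicator subsets are capped at size 3 by default; a genus whose true
  association is a 4-habitat combination reports its best sub-combination
  instead.
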