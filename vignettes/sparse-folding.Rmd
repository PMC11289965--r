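---
title: "Sparsified MFE folding with dangle contributions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsified MFE folding with dangle contributions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsefold)
```

## The model

An RNA sequence $S = S_1,\dots,S_n$ over $\{A,C,G,U\}$ folds into a
secondary structure $R$: a set of canonical base pairs $i.j$
($\{S_i,S_j\} \in \{\{A,U\},\{C,G\},\{G,U\}\}$) with at most one partner
per base, hairpin loops of at least $m$ unpaired bases ($j - i > m$ for
every pair), and no crossing pairs.  The pairs partition the unpaired bases
into loops — hairpins, interior loops (including stacks and bulges) and
multiloops — and the free energy of a structure is the sum of its loop
energies under the Turner 2004 nearest-neighbor parameters.  `fold_rna()`
returns the structure of minimum free energy (MFE).

The baseline dynamic program is the Zuker–Stiegler recursion in a
partition-friendly form.  With $W(i,j)$ the MFE over general structures of
$S_{i,j}$, $V(i,j)$ over closed structures (pair $i.j$ present), $WM$ over
multiloop fragments with at least one branch, and the decomposition
helpers $W^p$, $WM^p$, $WM^2$:

$$W(i,j) = \min\{\, W^p(i,j),\; V^d(i,j) \,\}$$
$$W^p(i,j) = \min\{\, W(i,j-1),\; \min_{i<k<j} W(i,k-1)+W(k,j) \,\}$$
$$V(i,j) = \min\{\, \mathcal H(i,j);\;
  \min_{\substack{i<p<q<j \\ p-i+j-q-2 \le M}} \mathcal I(i,j;p,q)+V(p,q);\;
  WM^2(i+1,j-1)+a \,\}$$
$$WM(i,j) = \min\{\, WM^p(i,j),\; V^d(i,j)+b \,\},\qquad
  WM^2(i,j) = \min_{i<k<j} WM(i,k-1)+WM(k,j)$$

with $a$, $b$, $c$ the multiloop initiation, branch and unpaired-base
penalties, $\mathcal H$ the hairpin energy and $\mathcal I$ the
interior-loop energy.  All energies are integers in dekacal/mol (0.01
kcal/mol), the native unit of the Vienna parameter-file dialect; division
by 100 happens only at the user-facing boundary, so the whole DP is exact
integer arithmetic — a prerequisite for the bit-encoding strategy below.

**Initialization.** $W(i,i)=0$; $V(i,j)=WM(i,j)=\infty$ for $j-i\le m$;
$WM^2(i,j)=\infty$ for $j-i < 2m+3$.  The last bound is the derived one:
two minimal stems occupy exactly $2(m+2)$ positions, so the first finite
$WM^2$ cell has $j-i = 2m+3$; a stricter bound would contradict the
$WM^2$ split recursion itself, and the package asserts cell-level equality
between its two engines, which forces the derived form.

## Dangle models

Dangling-end terms are stacking interactions between a helix-closing pair
and up to two immediately adjacent unpaired bases.  They occur only at
stem ends in external loops and multiloops, never inside helices.  The
three standard models are selected with `model =`:

* **d0 (no dangle).** $V^d = V$ plus the terminal AU/GU penalty of the
  stem's closing pair.  (The terminal penalty is applied at every helix
  end in external loops, multiloops, hairpins and interior loops per the
  parameter-file semantics; the printed recursions of most treatments omit
  it, but it is required for Turner 2004 fidelity.)
* **d2 (always dangle).** Every stem end adds the both-sides term
  regardless of whether the adjacent bases are paired elsewhere:
  $V^d(i,j) = V(i,j) + \mathrm{dangle}_{53}$, read from the
  `mismatch_exterior` or `mismatch_multi` table depending on the loop the
  stem sits in (single-sided `dangle5`/`dangle3` at the sequence ends,
  zero beyond them).  The multiloop-closing case of $V$ gains the
  corresponding inner-side term.
* **d1 (exclusive dangle).** Each unpaired base may serve at most one
  adjacent stem end.  The recursion takes the minimum of four cases
  per stem span $[i,j]$: no dangle; $V(i+1,j)+\mathrm{dangle}_5(i)$;
  $V(i,j-1)+\mathrm{dangle}_3(j)$; $V(i+1,j-1)+\mathrm{dangle}_{53}(i,j)$.
  Because spans partition the sequence, exclusivity is automatic.  In
  multiloop context each skipped base additionally pays $c$, and the
  multiloop-closing case of $V$ expands to the analogous four cases with
  the closing pair consulted from inside the loop.

**The both-sides table mapping.**  The 53' term of the exclusive model is
read from the same mismatch tables as d2 (exterior vs. multiloop context),
not as a `dangle5 + dangle3` sum.  This was settled empirically: on random
panels the mismatch-table mapping agrees bit-exactly with ViennaRNA's
RNAfold under `-d1` (and `-d0`/`-d2`), while the sum mapping diverges in a
third of instances.  The engines keep the sum mapping as an internal
option (`dangle_terms(..., sum53 = TRUE)` exposes the table arithmetic),
and the parameter schema keeps separate exterior and multiloop both-sides
tables even though Turner 2004 populates them identically.

## Sparsification

The split minimization in $W^p$ (and its multiloop analogues) need not
consider every $k$: if the optimal structure of the suffix $S_{k,j}$ is
itself optimally decomposable, splitting further left can only do as well
(the triangle inequality for $W$).  It therefore suffices to minimize over
*candidates* — spans whose context stem energy strictly beats their best
decomposition:

$$[i,j] \text{ candidate} \iff
  V^d(i,j) < \widehat W^p(i,j)\ \ \text{or}\ \ WM^d(i,j) < \widehat{WM}^p(i,j),$$

where $V^d$ and $WM^d$ are the external-loop and multiloop context stem
energies (terminal penalty, dangle terms, and $b$ included in $WM^d$).
Using context energies rather than the bare $V$ matters for completeness:
under d2 a negative mismatch term can make a stem beat the decomposable
optimum even when $V$ alone does not.  Under d0/d2 both criteria reduce to
the familiar $V$-based forms up to the deterministic context terms; under
d1 both contexts are tested, which is the inequality set that preserves
exact equivalence with the dense recursions (asserted cell-by-cell in the
tests).  Candidates are stored per column $j$; with $Z$ candidates in
total the forward pass runs in $O(n^2 + nZ)$ time.

**Rolling storage.**  The sweep runs rows outward, $i = n \dots 1$ with
$j$ ascending inside each row.  This order is what makes $O(n)$ energy
storage possible: $\widehat W^p(i,j)$ reads $W(i,k-1)$ along the *current
row*, which a column-outer sweep would have to keep quadratically.  Live
state is: one row each of $W$, $WM$, $WM^2$; the two previous $WM^2$ rows
(for the multiloop-closing shifts); and a $(M+2)$-row band of $V$ for the
interior-loop window.  Peak dense-array allocation is
$(M+7)\,(n+2)$ cells — reported per run as `peak_dense_cells` and asserted
flat-per-base in the tests — for an overall space bound of $O(n + Z + T)$.

**Interior loops and trace arrows.**  The interior-loop case of $V$
minimizes over candidate inner pairs (using their stored raw $V$ payload —
never a dangled value, which would silently shift the traced inner pair by
one) and over non-candidates read from the rolling band.  When the optimum
is a non-candidate, the traceback could not recover it later (the band is
long gone), so a *trace arrow* $(i,j) \to (p,q)$ with the target's $V$ is
recorded.  Arrows are reference-counted and garbage-collected: once a row
leaves the interior-loop window it can no longer be targeted, and an arrow
whose source cell is unreachable — not a candidate, not (under d1) a
one-base shift of a candidate stem, and not the target of any live arrow —
is removed, cascading along its own target.  Peak and live arrow counts
and the number removed are reported in `stats`.

**Constraint guard without branches.**  Hard-constraint checks inside the
interior-loop scan use `masked_energy()`: with region flags
$l, r \in \{0,1\}$, the value $e + (((l-1)\,|\,(r-1))\,\&\,\mathrm{INF})$
equals $e$ when both regions are admissible and exceeds every reachable
energy otherwise, without a conditional branch.  The sentinel is
$10^7$ dekacal/mol; any value above half of it is treated as infinite, so
the masked sum never wins a minimization and never overflows 32-bit
arithmetic ($2\cdot\mathrm{INF} \ll 2^{31}$).

## Space-efficient traceback and the three strategies

The traceback keeps no matrices.  Rows of $W$/$WM$/$WM^2$ are recomputed
on demand from the candidate lists alone (same recursions as the forward
pass, $O((j-i)\cdot\bar Z)$ per row), and $V$ cells are entered through
candidates, trace arrows, or hairpin/multiloop case checks.

Under the exclusive model a traced candidate stem must also reveal *which*
dangle case produced its context energy, since the inner pair shifts with
the case and the shifted $V$ values are unavailable (storing the energy
alone is provably insufficient).  Each candidate therefore extends the
classic $(i, V)$ payload with its two context energies, and three
strategies recover the case:

* **trace** — a dedicated *ed-trace-arrow* per ed-candidate stores the
  dangle codes for both contexts.  Such arrows can never be
  garbage-collected (any ed-candidate may sit on the optimal path), so
  their count equals the candidate count exactly.
* **standard** — the context energies are stored bit-encoded,
  $enc = (E \ll 2)\,|\,d$, with the 2-bit code in the low bits
  (00 none, 01 5', 10 3', 11 both).  The codec is defined arithmetically
  ($enc = 4E + d$, $d = enc \bmod 4$ with non-negative remainder) so the
  round trip is exact for negative energies on any conforming platform;
  `encode_energy()`/`decode_energy()` expose it.
* **triplet** — the candidate stores *un-dangled* values: the $V$ of the
  shifted inner pair per context.  At trace time the four dangle terms are
  re-added in printed order and compared with the known context energy.
  A plain first-match rule is not always sufficient: two shift cases can
  re-add to the same total while implying different inner $V$ values (this
  occurred on a random 53-mer in development), so the implementation takes
  the first matching case whose implied inner $V$ cell is itself
  reproducible by some case of the $V$ recursion — a one-level consistency
  check that restores determinism without extra storage.

All three strategies share one forward pass, so their MFEs are identical
by construction; the suite asserts energy equality (structures may differ
only among co-optimal ones).  Reported payload accounting: standard 24
bytes per candidate (the two encoded fields are widened so the full
energy range stays representable after the 2-bit shift), triplet 17
(four 32-bit fields plus one byte of codes used only as forward-pass
working state), trace 16 plus an 8-byte ed-trace-arrow each; d0/d2
candidates are 8-byte $(i, V)$ pairs.

## Hard constraints

Constraints are per-position codes — unconstrained, forced-unpaired
(`x`), or a forced pair (matched brackets) — validated to be canonical,
non-crossing and at least $m+1$ apart.  The engines enforce them
everywhere a base is left unpaired or paired: `pair_allowed()` and
`region_unpaired_ok()` answer in $O(1)$ via a prefix count of
forced-paired positions.  Any added constraint restricts the search space,
so the constrained MFE is never below the unconstrained one, and forced
pairs always appear in the output; both are asserted on random panels.

`random_constraints()` mirrors a simple generator: draw two indices at a
time, keep the pair if canonical, spaced ($j - i > m$, so every forced
pair is feasible), endpoint-disjoint and non-crossing with those already
kept, capped at $\lfloor 0.5 \log_2 n \rfloor$ pairs with a sampling
budget of ten attempts per allowed pair.  It is a pure function of
(sequence, seed).

## Parameters

The bundled set is the published Turner 2004 free-energy table collection
in the Vienna text dialect (stacking; hairpin/bulge/interior initiations
with $\ln$ extrapolation beyond 30 unpaired bases, $\mathrm{lxc} =
107.856$; all mismatch tables; 1×1/2×1/2×2 special interior loops; dangles;
multiloop constants $a = 930$, $b = -90$, $c = 0$; NINIO asymmetry 60
capped at 300; terminal AU/GU 50; tetra-/tri-/hexaloop bonuses).  Enthalpy
sections are omitted — folding is at 37 °C — and the file ships as four
consecutive text chunks that `turner2004_params()` concatenates before
parsing.  Tunable model constants: `m = 3` unpaired bases minimum hairpin
and `M = 30` maximum interior-loop size ($p-i+j-q-2 \le M$), the community
defaults, which are also required to reproduce the worked example below.
Because $c = 0$ in Turner 2004, the multiloop unpaired-penalty paths are
additionally exercised in the tests with a modified parameter set
($c = 40$) to keep them honest.

## What the generators emulate — and what they do not

`random_sequence()` draws i.i.d. bases from a given composition (default
uniform); `dinucleotide_shuffle()` produces a permutation preserving the
exact dinucleotide multiset via the Eulerian-path construction (random
arborescence toward the final base, remaining edges shuffled), which also
fixes the first and last residue.  These match the synthetic inputs used
for correctness testing: they exercise every recursion case, but i.i.d. or
shuffled sequences are compositionally homogeneous and carry no conserved
structure, so passing tests demonstrate algorithmic correctness — exact
agreement with the dense oracle and with RNAfold — not predictive accuracy
on biological RNAs.  Accuracy against reference structures is the province
of `compare_structures()` (sensitivity, PPV, F-measure over exact pair
identity, zero-denominator ratios reported as 0), which users can apply to
their own curated data.

## Numerical choices and tie-breaking

Forward minimizations evaluate cases in the textual order of the
recursions (hairpin, interior by increasing $p$ then $q$, multiloop;
split points ascending; the four exclusive-dangle cases in printed order)
and keep the first strict improvement; the traceback tests cases in the
same order and follows the first achiever, so both engines are
deterministic.  An interior-loop tie between a candidate and a
non-candidate inner pair resolves to the candidate (no arrow is stored).
Degenerate inputs: a pair-free sequence folds to energy 0 with an empty
structure; `n = 1` is a single unpaired base; infeasible constraint sets
(none can arise from `parse_constraints`, which validates) raise an error
rather than returning $\infty$.

## Verification

Worked example, computed here:

```{r}
f <- fold_rna("GGGAAAACCCC", model = "d1")
f
fold_rna("GGGAAAACCCC", model = "d1", constraints = "(.........)")$mfe
```

The test suite asserts, among others: exact MFE equality sparse vs. dense
for 100 seeded random sequences (20–60 nt) across all three dangle models
and all three strategies, with every traced structure re-evaluating
exactly to its reported energy through the independent loop-decomposition
evaluator; cell-level matrix equality between the engines; candidate-set
equality with the dense inequality definition at $n \le 40$; exact MFE
agreement with RNAfold (same parameter values) when ViennaRNA is on the
path; codec round-trips over $[-5000, 5000] \times 4$ codes; and the
branch-free guard against its branching counterpart.  Problem sizes (100
sequences of 20–60 nt, linear-space checks up to $n = 240$) were chosen so
the full suite documents the equivalences at useful scale while remaining
quick to run.

## Known limitations

* Pseudoknots, coaxial stacking, and temperature rescaling from enthalpies
  are out of scope; lonely pairs are permitted (no `--noLP` analogue).
* The structure evaluator shares the engines' interior-loop size bound
  $M$, so hand-built structures containing larger interior loops are
  rejected rather than extrapolated.
* The dense engine is a clarity-first oracle: quadratic space, no
  performance tuning.  For long sequences use the sparse engine; the
  package makes no runtime claims beyond its complexity bounds, and the
  candidate-to-quadratic ratio is reported per run (`stats$z_ratio`)
  without asserting any dataset-dependent factor.
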