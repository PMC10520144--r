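---
title: "Modelling rearrangements of signed circular genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rearrangements of signed circular genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circrearr)
```

## The objects

Bacterial-style genomes — a single circular chromosome carrying `n`
oriented regions (genes or synteny blocks) — are encoded in the *position
paradigm*: a genome instance is a map from region labels `1..n` to signed
positions, a reversed region getting a negative sign.  Extending each map
to the negative labels by the sign rule $\sigma(-i) = -\sigma(i)$ makes it
a bijection on the $2n$ signed labels, an element of the hyperoctahedral
group $H_n$ of order $2^n n!$.  Rearrangement events live in the same
group, as maps from positions to positions, and act by composition.  The
package composes rightmost-first throughout: `compose(a, b)` maps $x$ to
$a(b(x))$.

```{r}
sigma <- make_perm(c(-1, 4, 3, -5, -2))
sigma
```

A circular genome has no distinguished position, so the $2n$ rotations and
reflections of an instance all describe the same physical molecule.  These
symmetries form a dihedral subgroup $D_n \le H_n$, generated by the
one-position rotation and an oriented reflection.  Reflections of oriented
regions flip orientations, so the reflection is *not* the plain sign-rule
extension of an unsigned reflection; we fix the axis through position 1:
$f(1) = -1$, $f(i) = -((n{+}1{-}i) \bmod n + 1)$.  Any other reflection
generates the same subgroup and leads to the same coset-level results;
only the particular representative produced would differ.

A *genome* is therefore a left coset $D_n\sigma$ (realized by
`canonical_genome()`), and a *rearrangement action* — an event considered
up to where on the circle it happens and up to the symmetry of the result
— is a double coset $D_n \alpha D_n$ (`canonical_action()`).  There are
$2^{n-1}(n-1)!$ genomes with $n$ regions.  Canonical representatives are
the lexicographic minimum of the one-row image over the (double) coset,
under the natural integer order $-n < \dots < -1 < 1 < \dots < n$; any
fixed total order would do, this one makes results bit-reproducible.

Applying an action to a genome (`apply_action()`) averages over the $2n$
ways the event can land on the circle, giving a probability distribution
over outcome genomes with exact multiplicities over the denominator $2n$.
Group-algebra formal sums are never materialized: genomes, actions and
outcome distributions are their operational realizations, which suffices
for everything computed here.

## Paradigms

Three further representations of the same genome are conversions of
$\sigma$ with the successor cycle $c = (1\,2\ldots n)(-n\ldots-2\,-1)$
(which maps each position to the next one clockwise and is *not* in $H_n$)
and the all-region orientation flip $r = (1\,{-1})\cdots(n\,{-n})$:

| expression                | meaning                         |
|---------------------------|---------------------------------|
| $\sigma^{-1}$             | position $\to$ region           |
| $\sigma^{-1} c \sigma$    | region $\to$ following region   |
| $\sigma^{-1} c \sigma r$  | head/tail adjacency involution  |

The content representations are invariant across all instances of a genome
because every dihedral element commutes with $c$.  Conversion back from
content cycles (`content_to_position()`) anchors region 1 at position 1
with positive orientation, resolving the $2n$-fold ambiguity
deterministically; the round trip lands in the same dihedral coset.  The
literature also writes the content genome as $\sigma c \sigma^{-1}$; this
package follows the conjugation orientation whose printed worked example
it reproduces, $\sigma^{-1} c \sigma$.

## Cuts and breakpoints

An event physically cuts the circle between some positions and reconnects
the segments.  The cut set falls out of a commutator:
$\mathrm{CutPos}(\alpha) = [n] \setminus \mathrm{Fix}(\alpha^{-1}c^{-1}\alpha c)$,
i.e. the positions $i$ where $c(\alpha(i)) \ne \alpha(c(i))$.  Cut counts
classify events: 2 cuts are inversions, 3 transpositions (with or without
inverting the moved segment), 2–4 block interchanges.  No element of
$H_n$ needs exactly one cut.

```{r}
alpha <- inversion(5, 3, 3)
cut_positions(alpha)
classify_action(canonical_action(alpha))$label
```

One numerical subtlety deserves a note.  Left-multiplying by a symmetry
never changes the cut set, and instances of one action have dihedrally
related cut sets, so the cut *count* and the multiset of circular segment
sizes are invariants of the action.  Stating the exact transformation law
under right multiplication requires naming each cut from both reading
directions: the gap between positions $i$ and $i+1$ is `i` read clockwise
but `-(i+1)` read counterclockwise.  `signed_cut_closure()` returns that
orientation-aware set $\{x : c\alpha(x) \ne \alpha c(x)\}
= \mathrm{CutPos} \cup -c(\mathrm{CutPos})$, for which
$\mathrm{SignedCuts}(d_1\alpha d_2) = d_2^{-1}\cdot\mathrm{SignedCuts}(\alpha)$
holds for every pair of symmetries.  The simpler barred closure
$\mathrm{CutPos} \cup -\mathrm{CutPos}$ (`cut_positions_star()`) is kept
for reporting, and transforms equivariantly under rotations; under
reflections it is the signed closure that carries the law.  Both are
exercised in the test suite.

Breakpoints are the genome-level analogue: adjacencies that disagree with
the reference genome, counted by
$\mathrm{bp}(\sigma) = (2n - |\mathrm{Fix}([\sigma^{-1}, c])|)/2$ with the
fix taken over all $2n$ signed labels — the domain choice is forced by
requiring the reference itself to have zero breakpoints.  The count is a
genome invariant and agrees with the content-paradigm formula
$(2n - |\mathrm{Fix}(r\rho r c)|)/2$, which the suite checks against a
direct adjacency-reading oracle on random genomes.

## Event constructors

`inversion(n, r, len)` implements the closed product-of-2-cycles form for
odd and even lengths, with positions mod $n$ and zeros replaced by $n$;
the even-length anchor means `inversion(n, r, 2)` inverts positions `r`
and `r + 1`.  Lengths must lie in $1..n{-}1$: a length-$n$ "inversion" is
a reflection of the whole circle, i.e. a symmetry requiring zero cuts, and
is rejected rather than silently returned.  Because inverting $n - m$
regions is the same action as inverting $m$, there are exactly
$\lfloor n/2 \rfloor$ distinct inversion actions (`inversion_actions()`).

Transpositions are built compositionally — there is no closed formula —
as chains of single-region moves
`move_one_region(n, r) = Inv(r+1,1) Inv(r,1) Inv(r,2)`, optionally
composing a 1-region inversion at the destination to invert the moved
region.  Correctness is enforced post hoc by the 3-cut contract: every
constructed transposition is checked (in tests) to require exactly three
cuts.  The inverted variant composes the inversion at the *destination*
(equivalently, at the source before moving); composing it at the source
position after the move would invert a bystander region and cost a fourth
cut.

## Exact counting

`count_by_cuts(n, mode)` enumerates all $2^n n!$ elements of $H_n$ as
(permutation, sign-vector) pairs held in an integer matrix, canonicalizes
cosets or double cosets by encoded lexicographic minima, and tallies cut
counts of one representative per class.  The coset counts factor as
$R(n,k) = \binom{n}{k} A(k)$ where $A(k)$ (`a061714()`, computed from its
closed form, no table lookup) counts the reconnections possible for one
fixed cut set — $1, 0, 1, 4, 25, 208, 2121, 25828, \ldots$ — independent
of $n$.  Action counts have closed forms at $k = 2$
($\lfloor n/2 \rfloor$) and $k = 3$
($\lfloor n^2/3 \rfloor - \lfloor n/2 \rfloor$); the latter decomposes
over partitions of $n$ into three segment sizes, with 2, 3 or 4
reconnections according as all, exactly two, or none of the parts are
equal (`three_cut_partitions()`).  The count
$\lfloor (n-1)/2 \rfloor$ for partitions with a repeated part includes the
all-equal partition when $3 \mid n$; direct partition enumeration, which
the package uses, makes the totals come out right either way.  No closed
form is known for four or more cuts; enumeration supplies those values.

Enumeration is capped at $n = 7$ ($|H_7| = 645{,}120$) and refuses larger
`n` with the count it would have produced.  The default test suite runs
brute-force-versus-closed-form checks at $n \le 6$, which complete in
seconds; `transition_matrix()` is capped at $n = 6$ (3840 states).

## Models and Markov chains

A model is a set of distinct actions with positive weights summing to 1.
Weights are parsed to exact rationals (fraction strings like `"2/5"`, or
numerics rationalized exactly), and transition matrices are integer
numerators over a common denominator, so row-stochasticity is exact and
distribution equality needs no tolerance.  Two presets are exposed and
deliberately distinct: `all_inversions_model()` weights the
$\lfloor n/2 \rfloor$ inversion *actions* equally (the inversion-distance
analogue), while `uniform_outcome_inversion_model()` weights them by
outcome-support size so that every genome reachable in one step is equally
likely — for $n = 6$ that is $2/5, 2/5, 1/5$, because the 3-region
inversion has 3 outcomes where the shorter ones have 6.  Outcomes equal to
the source genome stay on the diagonal; nothing is renormalized.

`min_steps_distance()` runs breadth-first search on the support graph
(self-loops ignored), giving the inversion distance under the
all-inversions model; it returns `Inf` for unreachable targets.  A model
may include an identity/symmetry action — it merely adds a self-loop —
but the constructors never produce one.  Mean-first-passage-time and
maximum-likelihood distances are intentionally not implemented; the exact
transition matrix is exported so downstream code can compute them.

```{r}
m <- all_inversions_model(3)
tm <- transition_matrix(m)
length(tm$states)
min_steps_distance(m, reference_genome(3),
                   canonical_genome(make_perm(c(-2, -1, 3))))
```

## Fixtures, file formats, limitations

All test inputs are generated programmatically: printed worked examples
(the 5-region running genome, its ten instances, the 3-region inversion
and its commutator) serve as frozen conformance fixtures, and randomized
property checks draw elements of $H_n$ under fixed seeds.  Nothing is
sampled from real gene orders, so passing tests demonstrate algebraic and
combinatorial correctness — not that any particular weighting is
biologically adequate for a given clade.

Genome files use the GRIMM-style signed gene-order dialect (`>name`
header, whitespace-separated signed integers, `$` terminators tolerated);
only circular signed records are accepted, and linear-genome markers fail
loudly.  Out of scope by design: unsigned or linear genomes,
multi-chromosomal events (fission, fusion, duplication, deletion — these
change the region or chromosome count), DCJ/breakpoint-graph distance
machinery, and estimation of model weights from data.
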