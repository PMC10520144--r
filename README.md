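# circrearr

Exact algebra for rearrangements of signed, uni-chromosomal circular
genomes — the genome architecture of most bacteria.  A genome with `n`
oriented regions (genes or synteny blocks) is a signed permutation: a map
from region labels to signed positions, extended to the hyperoctahedral
group `H_n` by the sign rule `σ(-i) = -σ(i)`.  Rearrangement events
(inversions, transpositions, block interchanges) are elements of the same
group acting by composition.

Because a circle has no distinguished position, the `2n` rotations and
reflections of an instance describe one physical genome.  The package
works at the symmetry-corrected level throughout:

* a **genome** is a left coset `D_n σ` of the dihedral subgroup of
  circular symmetries (`canonical_genome()`); there are `2^(n-1) (n-1)!`
  of them;
* a **rearrangement action** is a double coset `D_n α D_n`
  (`canonical_action()`): the event considered up to where on the circle
  it happens and up to the symmetry of the result;
* applying an action to a genome (`apply_action()`) gives an exact
  probability distribution over outcome genomes.

Events are characterised by their **cut set**
`CutPos(α) = [n] − Fix(α⁻¹c⁻¹αc)` — the positions where the circle must be
severed — with `c` the position-successor cycle.  Two cuts make an
inversion, three a transposition, two to four a block interchange.  The
package counts these classes exactly, both by brute-force coset
enumeration (`count_by_cuts()`, up to n = 7) and by the closed forms
`R(n,k) = C(n,k)·A(k)` with `A(k) = 1, 0, 1, 4, 25, 208, 2121, 25828, …`
reconnections per cut set, `⌊n/2⌋` inversion actions and
`⌊n²/3⌋ − ⌊n/2⌋` transposition actions.  Breakpoint counts
(`bp(σ) = (2n − |Fix([σ⁻¹,c])|)/2`), paradigm conversions (position ↔
content cycles ↔ head/tail adjacencies), GRIMM-style signed gene-order
file I/O, and rearrangement models that induce Markov chains on genome
space round out the toolkit.  All probabilities are exact rationals.

Intended users: researchers in phylogenetics and comparative genomics
building model-based rearrangement distances, and anyone needing exact
signed-permutation arithmetic with circular symmetry handled correctly.

## Worked example

```r
library(circrearr)

sigma <- make_perm(c(-1, 4, 3, -5, -2))   # 5-region genome instance
print(sigma)
#> signed permutation (H_n) on n = 5 regions
#>   one-row: [-1 4 3 -5 -2]
#>   cycles:  (1 -1)(2 4 -5)(5 -2 -4)

breakpoint_count(sigma)                    # adjacencies disagreeing with
#> [1] 4                                   # the reference genome

alpha <- inversion(5, 3, 3)                # invert 3 regions about pos. 3
format_perm(alpha, "cycles")
#> [1] "(2 -4)(3 -3)(4 -2)"
cut_positions(alpha)
#> cut set, n = 5: { 1, 4 }                # severed between 1|2 and 4|5

apply_action(canonical_action(alpha), canonical_genome(sigma))
#> outcome distribution over 5 genomes (denominator 10)
#>            genome multiplicity probability
#>    [-5 -4 2 3 -1]            2         0.2
#>   [-5 -3 -4 2 -1]            2         0.2
#>  [-5 -2 -3 -4 -1]            2         0.2
#>   [-5 -1 -2 -4 3]            2         0.2
#>    [-5 3 -1 -4 2]            2         0.2
```

The event has five equally likely outcomes because the 3-region inversion
can land on any of the five dihedrally inequivalent placements of its two
cuts.  Counting all distinct actions by cut number:

```r
count_by_cuts(5, "double_cosets")
#> n = 5, |H_n| = 3,840, 56 distinct rearrangement actions (double cosets)
#>  0  1  2  3  4  5
#>  1  0  2  6 15 32
```

— 2 inversion actions (`⌊5/2⌋`) and 6 transposition actions
(`⌊25/3⌋ − 2`), as the closed forms predict.  Under the all-inversions
model, the minimal number of events separating this genome from the
reference is its inversion distance:

```r
m <- all_inversions_model(5)
min_steps_distance(m, reference_genome(5), canonical_genome(sigma))
#> [1] 2
```

A command-line dispatcher over the same functions is installed as
`exec/circrearr` (subcommands `convert`, `canonize`, `orbit`, `apply`,
`make`, `cuts`, `breakpoints`, `count`, `matrix`, `dist`).

## Scope

Signed, circular, single-chromosome genomes with a fixed region count
only.  Fissions, fusions, duplications and deletions (which change those
counts), unsigned or linear genomes, DCJ/breakpoint-graph machinery, and
likelihood-based distance estimators are out of scope; the exact
transition matrix is exported so downstream code can build distance
estimators on top.
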