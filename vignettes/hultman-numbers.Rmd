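---
title: "Counting genomes by breakpoint-graph shape: the multichromosomal Hultman numbers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting genomes by breakpoint-graph shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hultman)
```

## The model

A multichromosomal genome on genes $1..n$ is a set of chromosomes, each an
ordered sequence of signed genes, either linear (flanked by telomeres) or
circular.  Every gene $g$ has two extremities, a tail $g^t$ and a head $g^h$;
this package fixes the vertex numbering $g^t \mapsto 2g-1$, $g^h \mapsto 2g$,
which gives a stable total order for canonical output.  Each non-telomeric
adjacency pairs two extremities, so a genome corresponds one-to-one to a
matching on the $2n$ extremity vertices; the matching is perfect exactly when
the genome is purely circular, and a genome with $\ell$ linear chromosomes
leaves $2\ell$ vertices unsaturated.  Because the correspondence is a
bijection, the package identifies genomes with their matchings: genome
equality (`genome_equal()`) is matching equality, which quotients out
chromosome order, circular rotation/reflection and linear reversal.

The breakpoint graph $BG(A,B)$ of two genomes on the same genes is the union
of their matchings on the shared vertex set.  Every vertex has degree 0, 1 or
2, so the graph decomposes uniquely into alternating cycles and paths.  Two
conventions need fixing where degenerate components arise, and `decompose()`
applies them consistently:

* an adjacency present in both genomes contributes two parallel edges,
  which form a 2-edge cycle (required so that $A$ vs $A$ gives $c = n$ and
  the count $H_C(n,n) = 1$ is reproduced);
* a vertex unsaturated in both matchings is a 0-edge path, and counts as an
  *even* path for the DCJ distance.  The recurrences force the first half of
  this convention (their skip-vertex cases create paths from single
  vertices); the even-parity half is a genuine choice, made so that two
  identical linear genomes are at DCJ distance 0.

Two distances are computed from a decomposition with $c$ cycles, $p$ paths
and $e$ even paths: the DCJ distance $d = n - c - e/2$ and the algebraic
rearrangement distance $d_a = n - c - p/2$.  Only $d_a$ is used for the
distributions below, because the counting series do not separate paths by
parity.

## The four counting families

For a fixed identity genome $I$, a Hultman number counts genomes whose
breakpoint graph against $I$ has a prescribed shape:

| family | identity | universe | indices |
|---|---|---|---|
| $H_C(n,c)$ | circular | circular genomes | cycles |
| $H_G(n,c,p)$ | circular | all genomes | cycles, paths |
| $H_L(n,c,p,\ell)$ | $\ell$ linear chromosomes | all genomes | cycles, paths |
| $H_\ell(n,c,p,\ell_i,\ell_a)$ | $\ell_i$ linear chromosomes | genomes with $\ell_a$ linear chromosomes | cycles, paths |

All four are evaluated by recurrences over $e$, the number of still-unvisited
breakpoint-graph vertices.  One genome matching is built edge-by-edge on top
of the identity matching; at each step the smallest unvisited vertex either
closes a cycle (1 way), merges two paths ($e-2-i$ or $e-1-i$ ways, with $i$
the identity-unsaturated vertices still unvisited), connects to an
identity-unsaturated vertex ($i$ ways), or is skipped, creating a telomere.
The parity of $e+i$ decides which operations are available, and in the
$H_\ell$ family the skip-vertex operations — exactly those — decrement the
budget $a = 2\ell_a$ of telomeres the genome being counted may still use.
The printed sources of these recurrences contain two evident typographical
slips (coefficients written with $n$ where the surrounding text counts $e-2$
and $e-1$ edges, and one garbled index tuple); the package implements the
operation counts, and the brute-force certification below arbitrates.

$H_C$ additionally has a closed form through the unsigned Stirling numbers of
the first kind: $H_C(n,c) = 2^{\,n-c}\, {n \brack c}$, which follows by
multiplying the Stirling recurrence ${n \brack c} = {n-1 \brack c-1} +
(n-1){n-1 \brack c}$ by $2^{n-c}$.  `stirling_first_unsigned()` implements
the Stirling recurrence independently, and the identity is asserted for all
$c \le n \le 12$ in the test suite.

## Exact arithmetic

The counts grow superexponentially — $H_C(100,1) = 2^{99}\cdot 99! \approx
10^{187}$ — so no floating-point or 64-bit path is acceptable anywhere in the
counting.  No arbitrary-precision integer dependency is declared; the package
carries its own: little-endian vectors of base-$10^6$ digits stored in
doubles (every intermediate stays far below $2^{53}$, so double arithmetic on
digits is exact), with schoolbook multiplication, long division, and a binary
GCD backing the exact rationals used for probabilities.

The recurrences themselves are evaluated bottom-up in increasing $e$ as
*digit-plane* dynamic programs: a layer is one numeric array holding the
whole $(c, p[, i, a])$ grid with a trailing digit dimension, so a layer step
is a handful of vectorized shift/scale/add operations plus one carry pass,
rather than millions of interpreted scalar updates.  Digit capacity is sized
from the involution bound on the universe (every intermediate count is a
count of matchings on $e \le 2n$ vertices) with headroom, and the carry pass
fails loudly if the top plane ever overflows.  Two structural truncations
keep memory linear in what is actually asked: the $i$ dimension is capped at
the largest $2\ell$ queried, and in the $H_\ell$ family the $a$ dimension is
capped at the largest $2\ell_a$ queried (both indices move in one direction
along the recursion, so truncation is lossless).  On one CPU this makes the
circular and general families comfortable at $n = 100$ and beyond, and the
fixed-linear family practical to $n \approx 30$ with full $a$ range or
$n = 100$ for small $\ell_a$.

## Certification against a dumb oracle

Every recurrence is certified against `oracle_tabulate()`: exhaustive
enumeration (in C++, but with no counting shortcuts) of all matchings on
$2n \le 12$ vertices — perfect, all, or with a fixed number of unsaturated
vertices — each decomposed against the identity matching and tallied by
$(c, p)$.  The test suite and `verify_scenario()` check bit-exact equality of
all four recurrence tables with the enumeration for every $n \le 6$ and every
valid $\ell, \ell_i, \ell_a$ (178 table comparisons).  This is the check that
arbitrates the typo corrections described above: with the printed
coefficients taken literally, the tables disagree already at small $n$.

Two further printed identities are asserted: $\sum_c H_C(n,c) = (2n-1)!!$
(perfect matchings) for $n \le 8$, and $\sum_{c,p} H_G = \sum_{c,p} H_L =$
the involution count on $2n$ vertices for $n \le 6$ and every $\ell$, with
$\sum_{\ell_a} H_\ell = H_L$ for $n \le 5$.  One wording in the sources
deserves a note: the total $\sum_{c,p} H_G(n,c,p)$ is the number of matchings
on $2n$ vertices, i.e. the telephone number evaluated at $2n$ (A000085), not
at $n$; `matching_count()` takes the vertex count as its argument to keep
this unambiguous.

The identity-invariance claim — the tables do not depend on *which* concrete
identity genome with $\ell$ linear chromosomes is used — is tested by
tabulating against several structurally different identities (different
partitions, gene orders and orientations) and comparing to the recurrence,
which is also why the canonical `identity_linear()` (consecutive near-equal
runs, remainder to the first chromosomes) is an arbitrary but harmless
choice.

## Distance distributions and expectations

Since $d_a = n - c - p/2$, the exact distribution of $d_a$ between a uniform
random genome and the identity is a regrouping of the Hultman table:
$D_C(n,d) = H_C(n, n-d)$ in the circular case and
$D(n,d) = \sum_{c + p/2 = n - d} H(n,c,p)$ otherwise.  Distances are stored
as $2d$ integers (odd $p$ makes $d_a$ half-integral), probabilities as exact
reduced rationals, and decimals are rendered by round-half-even on the exact
value (`bigq_decimal()`, default 2 places).

For the circular family the expectation has an analytic form the package
uses as an independent oracle: the recurrence implies the generating
polynomial $\sum_c H_C(n,c)\,x^c = x(x+2)(x+4)\cdots(x+2n-2)$, and
differentiating at $x = 1$ gives

$$E[X_n] = n - \sum_{j=0}^{n-1} \frac{1}{2j+1}.$$

`expected_distance("circular", n)` (table-based) and
`expected_circular_closed_form(n)` (analytic) are asserted equal as exact
rationals for all $n \le 50$ and at $n = 100$.

At $n = 100$ the four universes give noticeably different expectations, all
computed exactly by the acceptance script:

* circular: $96.7157$ (equals the closed form);
* general: $95.2230$;
* identity with one linear chromosome, general universe: $94.7914$;
* one linear chromosome on both sides: $97.0457$ (and $27.6398$ at
  $n = 30$, the size the acceptance script reports for this family).

A reported value of $95.22$ for this expectation at $n = 100$ circulates in
the literature attached to the circular formulation; it is incompatible with
the circular closed form above (the harmonic-type sum diverges, so no
constant-offset limit exists either) but coincides to the printed precision
with the *general*-universe expectation.  The package treats that value as
computed over general genomes and does not adjust anything toward it; the
acceptance script simply reports all four computed expectations.

## Sampling, and what the generators do not emulate

`sample_matchings()` draws uniform perfect matchings by sequential random
pairing (exactly uniform over $(2n-1)!!$), and uniform general matchings by
the standard recursive split on involution counts: the smallest unprocessed
vertex stays unsaturated with probability $T(m-1)/T(m)$.  The split
probabilities are exact rationals converted to doubles, so uniformity is
exact up to double rounding of the thresholds ($<10^{-15}$ relative, far
below anything a $10^4$-draw test can see).  The seed is a required argument
and the caller's RNG state is restored, so there is no hidden global state.
A Monte-Carlo concordance check draws $10^4$ circular genomes at $n = 10$
and requires every bin of the empirical distance histogram to sit within
$3\sigma$ of the exact PMF.

These generators emulate the combinatorial universes exactly — that is their
job, and for counting statements exact enumeration plus uniform sampling is
the whole story.  They do not emulate anything about real genomes: no gene
family sizes, no duplications, indels or unequal content, no chromosome
number or length distributions of real karyotypes.  Passing tests certify
the combinatorics, not biological realism of any genome model.

## Numerical and design choices

* All counting is exact integer; probabilities and expectations exact
  rational; decimals only at the rendering boundary, round-half-even.
* Out-of-range recurrence arguments return 0 (matching the base-case
  conventions); out-of-range $\ell$ parameters are errors, since they
  indicate a malformed query rather than a boundary term.
* The Stirling closed form for $H_C$ is implemented via
  $2^{n-c}{n \brack c}$; a literal partition-sum form of the same identity
  printed in one source is internally inconsistent and is not implemented.
* The enumeration oracle refuses more than 16 vertices by design; the
  equivalence sweep uses $2n \le 12$.  `verify_scenario()` is the one place
  recurrence and oracle meet; neither calls the other anywhere else.
* Test problem sizes — oracle sweep to $n = 6$, sum identities to $n = 8$,
  Stirling identity to $n = 12$, closed-form expectation to $n = 50$ plus
  $n = 100$, $10^4$ Monte-Carlo draws at $n = 10$ — were chosen once as the
  sizes at which every structural branch of the recurrences is exercised
  many times over while the full suite stays interactive (under a minute).

## Limitations

* No rearrangement scenario reconstruction (sorting by DCJ) and no unequal
  gene content, duplicates or indels: genomes are signed permutations of a
  fixed gene set.
* DCJ-distance *distributions* are out of scope: the counting families do
  not separate even from odd paths, so only the algebraic distance is
  derivable from them.  `dcj_distance()` for concrete genome pairs is
  provided.
* No closed forms are implemented for $H_G$, $H_L$, $H_\ell$ (none are
  known); the fixed-linear family's cost grows with the $a$ range, so full
  tables there are practical to $n \approx 30$.
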