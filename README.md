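# hultman

Exact combinatorics of multichromosomal breakpoint graphs, for people
studying genome rearrangements: given a fixed identity genome, how many
genomes on `n` genes have a breakpoint graph with exactly `c` cycles and `p`
paths, and what does that imply for the distribution of the rearrangement
distance between random genomes?

A genome (sets of signed, linear or circular chromosomes over genes `1..n`)
corresponds one-to-one to a matching on the `2n` gene extremities; the
breakpoint graph `BG(A, B)` is the union of two such matchings and
decomposes uniquely into cycles and paths, from which the DCJ distance
`d = n − c − e/2` (`e` = even paths) and the algebraic rearrangement
distance `d_a = n − c − p/2` are read off.  The package computes, with exact
arbitrary-precision arithmetic:

* the four **multichromosomal Hultman numbers** — `H_C(n,c)` (circular
  identity and universe), `H_G(n,c,p)` (circular identity, all genomes),
  `H_L(n,c,p,ℓ)` (identity with `ℓ` linear chromosomes), and
  `H_ℓ(n,c,p,ℓ_i,ℓ_a)` (fixed linear counts on both sides) — by memoized
  bottom-up recurrences, plus the closed form
  `H_C(n,c) = 2^(n−c) [n c]` through independently computed unsigned
  Stirling numbers of the first kind;
* exact **distance distributions**, probability masses and expected values
  of the algebraic distance in all four universes (counts as big integers,
  probabilities as reduced rationals), including the analytic circular
  expectation `E[X_n] = n − Σ_{j<n} 1/(2j+1)`;
* a brute-force **oracle** (exhaustive matching enumeration, ≤ 16 vertices)
  that certifies every recurrence table bit-exactly, and a seeded uniform
  sampler over the genome universes;
* **GRIMM-style I/O** for genome files and a command-line tool.

## Worked example

The two genomes `A = {(1 2 3 4 5 6 7 8 9)}` and
`B = {(6 −1 4 5 −2), (∘ −9 3 8 7 ∘)}`:

```r
library(hultman)
A <- read_grimm(text = c(">A", "1 2 3 4 5 6 7 8 9 @"))$A
B <- read_grimm(text = c(">B", "6 -1 4 5 -2 @", "-9 3 8 7 $"))$B
decompose(A, B)
#> <breakpoint graph decomposition> n = 9: 2 cycle(s), 1 path(s) (0 even)
dcj_distance(A, B)        # 9 - 2 - 0/2
#> [1] 7
algebraic_distance(A, B)  # 9 - 2 - 1/2
#> [1] 6.5
```

The breakpoint graph of `A` and `B` has two cycles and one path; the path
has an odd number of edges, so it contributes nothing to the DCJ distance
and a half unit to the algebraic distance.

Counting all circular genomes on 4 genes by cycles (the column sums to
`7!! = 105`, the number of perfect matchings on 8 vertices):

```r
hultman_table("circular", 4)
#> <hultman_table> scenario = circular, n = 4
#>   c count
#> 1 1    48
#> 2 2    44
#> 3 3    12
#> 4 4     1
#> total: 105
```

The exact distance distribution over *all* genomes on 2 genes (note the
half-integer distances from odd path counts):

```r
distance_distribution("general", 2)
#> <distance_distribution> scenario = general, n = 2
#>     d count probability_exact probability_float
#> 1 0.0     1              1/10               0.1
#> 2 0.5     2               1/5               0.2
#> 3 1.0     3              3/10               0.3
#> 4 1.5     4               2/5               0.4
#> universe: 10
#> expected distance: 1/1 ≈ 1.00
```

Expectations stay exact at any size — at `n = 100` the circular universe
gives a rational with ~90-digit terms, rendered on demand:

```r
bigq_decimal(expected_distance("circular", 100), 4)
#> [1] "96.7157"
```

(The general-genome universe at `n = 100` gives 95.2230 instead; the two are
often conflated, see the vignette.)

Every recurrence is certified against exhaustive enumeration:

```r
verify_scenario("fixed_linear", 3, l_i = 1, l_a = 2)$pass
#> [1] TRUE
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hultman", package = "hultman"))')
Rscript "$CLI" hultman --scenario circular -n 4
Rscript "$CLI" expect --scenario general -n 2        # 1/1 ≈ 1.00
Rscript "$CLI" bg A.grimm B.grimm
Rscript "$CLI" verify --scenario general -n 5        # exit 0 iff oracle agrees
```

Exit codes: 0 success, 1 verification failure, 2 usage error.  `--format
json` serializes counts as decimal strings (they overflow 64-bit integers
from `n ≈ 11` on).

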