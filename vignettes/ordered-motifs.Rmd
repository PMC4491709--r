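---
title: "Ordered 3-node motif spectra: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordered 3-node motif spectra: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordmotif)
```

## The model

An *ordered network* is a directed graph together with a strict total order on
its nodes, supplied by a continuous niche variable such as body mass: smaller
niche value, smaller rank. Between two rank-ordered nodes exactly one of four
*pair states* holds — `none`, `down` (link from the higher-rank node to the
lower), `up` (the reverse), or `bidir` (both). A triple of nodes, read bottom
to top in rank, therefore shows one of $4^3 = 64$ configurations; the 10
containing an isolated node are not substructures, leaving 54 connected
ordered substructures. Ignoring the order, these collapse onto the 13
classical isomorphism classes of connected 3-node digraphs, each class holding
between 1 and 6 ordered members (class size × automorphism-group order of the
class digraph = 3! = 6).

The *ordered motif spectrum* of a network is the count vector
$\eta_{(q,s)}$ over the 54 substructures, obtained by visiting every one of
the $\binom{N}{3}$ node triples and classifying its induced configuration.
Summing over member IDs, $\eta_q = \sum_s \eta_{(q,s)}$, recovers the
unordered census, so the ordered spectrum is a strict refinement.

### Conventions (fixed once, used everywhere)

- **Pair order within a triple:** (bottom,middle), (bottom,top), (middle,top).
- **Edge direction is energy flow:** an edge from A to B means B eats A, so
  upward links run from small prey to large predators. `read_ordered_network()`
  accepts `direction = "eats"` to flip predator→prey files on input.
- **A bidirectional pair contributes 2 directed links**, so the link count
  $l$ of a substructure ranges over $2 \le l \le 6$ and decomposes as
  $l = u + d$ into upward and downward links.
- **Class and member numbering.** There is no canonical published numbering of
  the 54 substructures, so the catalog defines its own deterministic one:
  classes sorted by (link count $l$, lexicographically smallest adjacency
  canonical form over the 6 node permutations), members sorted
  lexicographically by pair-state triple within each class. The three
  substructures that matter most in hierarchy-dominated networks carry stable
  aliases instead of numbers: `fan_in_up` (`none-up-up`), `up_chain`
  (`up-none-up`), `fan_out_up` (`up-up-none`) — the three configurations with
  two upward links and nothing else.
- **Counting is over induced subgraphs** (all three pair states read from the
  full network); there is no non-induced mode.
- **Self-loops** (cannibalism) are stored, reported, and excluded from triple
  counting; they do count toward connectance $C = L/N^2$, the standard
  niche-model accounting.
- **Ties in the niche variable** violate the strict-order assumption; ranks
  then fall back to input order, stably, with a warning, and the ordering
  provenance is attached to every spectrum.

## The directed ordered random model

The ordered generalization of the Erdős–Rényi graph: for every rank-ordered
pair, an upward link appears with probability $p_{up}$ and a downward link
independently with probability $p_{down}$. The four pair states then have
probabilities $(1-p_{up})(1-p_{down})$, $p_{down}(1-p_{up})$,
$p_{up}(1-p_{down})$, $p_{up}p_{down}$, and a substructure's appearance
probability is the product of its three pair factors,

$$P_{(q,s)} = p_{up}^{\,u}(1-p_{up})^{3-u}\; p_{down}^{\,d}(1-p_{down})^{3-d},$$

with $u$ upward and $d$ downward links. Expected counts are
$\eta_{(q,s)} = \binom{N}{3} P_{(q,s)}$.

Two structural consequences, both verified exactly in the test suite:

- **Symmetric case** $p_{up} = p_{down} = p$: $P$ depends only on
  $l = u + d$, giving $p^l(1-p)^{6-l}$ and exactly **5 levels**, constant
  within each isomorphism class.
- **Asymmetric case**: $P$ depends on the pair $(u, d)$; over connected
  substructures $(u,d)$ takes exactly **13 values** — the *statistical
  classes*, which cut across the isomorphism classes. For small asymmetric
  probabilities the three largest-$P$ substructures are exactly the two-up
  configurations (`fan_in_up`, `up_chain`, `fan_out_up`).

**Level grouping tolerance.** Distinct-level counting
(`n_distinct_levels()`) groups values whose relative difference is below
$10^{-12}$: products of identical factor multisets can differ in the last few
ulps depending on evaluation order, while genuinely different levels for any
non-degenerate parameters differ by factors of order $p$ — many orders of
magnitude above the tolerance. Degenerate parameter choices (e.g.
$p_{up} = 1 - p_{up}$ style coincidences) can merge levels; the 13-level
statement is for generic unequal probabilities.

## The niche model

`generate_niche_web(n, c)` implements the standard two-parameter food-web
generator. Each species $i$ gets a niche value $n_i \sim U[0,1]$; its feeding
range is $r_i = x\,n_i$ with $x \sim \mathrm{Beta}(1, \beta)$,
$\beta = 1/(2C) - 1$, so $E[x] = 2C$ and the expected connectance is $C$; the
range centre is $c_i \sim U[r_i/2, n_i]$, which lets diets extend slightly
above a species' own niche value (hence occasional downward links and loops).
Species $i$ eats every $j$ with $n_j \in [c_i - r_i/2,\, c_i + r_i/2]$, stored
as the edge $j \to i$.

Design choices where the procedure is genuinely open:

- **Beta density exponent.** The feeding-range density is implemented as the
  canonical $\mathrm{Beta}(1,\beta)$, $p(x) = \beta(1-x)^{\beta-1}$, the
  Williams–Martinez form with mean $2C$; an exponent of $1-\beta$ sometimes
  seen in secondary descriptions is non-normalizable for $\beta > 1$ and is
  not used.
- **No rejection sampling.** Webs with isolated species, duplicate diets or
  realized-connectance drift are kept; the realized mean connectance still
  matches the target within Monte-Carlo error (tested), because the
  construction is unbiased for $E[L]/N^2$.
- **Connectance accounting** includes self-loops in $L$, while motif counting
  excludes them (distinct triples only).

### What the generators emulate — and what they do not

The niche model reproduces the contiguous-diet, interval-on-a-line structure
of real food webs and the strong upward bias of feeding links, which is why
its spectra are dominated by `fan_in_up`, `up_chain` and `fan_out_up` and why
only a minority of the 54 substructures ever appear at empirical sizes
(N = 56, C = 0.0692: roughly 37 across 1000 realizations, against 54
possible). It does **not** emulate taxonomic aggregation, sampling effort,
body-mass measurement error, or the empirical mismatch between body-mass
order and niche-axis order; passing tests on these ensembles therefore
validate the machinery and the model's own statistics, not any claim about a
particular field data set.

## Null models and Z-scores

`reorder_null()` permutes node ranks uniformly at random while keeping the
topology fixed. Because topology is preserved, the collapsed spectrum of every
replicate equals the original's exactly (asserted per replicate in tests);
only the allocation of counts to ordered members moves. For $N \le 8$,
`exhaustive = TRUE` enumerates all $N!$ orders and returns exact permutation
moments — tests compare the sampled means against this enumeration on 5-node
webs.

`z_profile()` computes $Z_{(q,s)} = (\eta - \bar\eta_{null})/\sigma_{null}$
per entry, with these contracts:

- $\sigma_{null}$ is the **sample** standard deviation ($n-1$ denominator);
  with reasonable ensemble sizes (hundreds of replicates) the choice of
  denominator is immaterial, but it is fixed and documented.
- Substructures absent from the observed network enter with $\eta = 0$ and
  are still scored where $\sigma_{null} > 0$.
- Entries with $\sigma_{null} = 0$ are **flagged degenerate** (`z = NA`),
  never reported as 0 or ±Inf.
- **No multiple-testing correction** is applied: the profile is a descriptive
  fingerprint over 54 correlated entries, not 54 independent hypothesis
  tests; treat individual $|Z|$ magnitudes accordingly.

## Reproducibility and problem sizes

Every stochastic function takes a seed; ensembles draw one sub-seed per
replicate from the master seed, so replicate $k$ is reproducible in
isolation and outputs are byte-identical across runs. RNG use is wrapped in a
local state, leaving the caller's stream untouched.

The package's own verification uses: exhaustive checks over all 64/54
configurations and all 720 triple-labelled permutations for the catalog;
brute-force induced-subgraph oracles on 6–25-node fixtures for counting; 100
realizations at $N = 100$ for model/simulation agreement, with the per-entry
tolerance of three standard errors taking the larger of the sample standard
error and the analytic binomial floor $\sqrt{\binom{N}{3} P (1-P) / reps}$
(entries with expected counts far below one can have a sample standard
deviation of exactly zero); and 1000 niche-model realizations at $N = 56$,
$C = 0.0692$ for the ensemble-level statistics. Spectrum counting iterates
all $\binom{N}{3}$ triples with $O(1)$ adjacency lookups — exact and fast for
food-web sizes ($N$ up to a few hundred); edge-anchored enumeration for large
sparse graphs is deliberately out of scope.

## Known limitations

- Motifs of size ≥ 4 and multi-layer orderings are not implemented.
- The only nulls are the ordered random model, the niche model and rank
  reordering; degree-preserving edge-swap randomization is not provided.
- Weighted or time-resolved counting is out of scope.
- With heavily tied niche variables the "ordered" spectrum reflects the
  arbitrary tie-break as much as the data; the package warns but does not
  refuse.
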