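---
title: "Adaptive-bandwidth density reconstruction of sequencing signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-bandwidth density reconstruction of sequencing signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdeseq)
```

## The model

A mapped single-end sequencing experiment (ChIP-seq of a transcription
factor, a histone mark, an input control) is viewed as a sample from an
unknown probability distribution $f$ over the integer base-pair positions of
a chromosome. After preprocessing, the data are a sorted vector of positions
$X = (x_1, \dots, x_n)$, and the reconstruction is a kernel density
estimate

$$\hat f(x) = \frac{1}{n} \sum_{i=1}^{n} K(x - x_i,\, h_i),$$

where $K(\cdot, h)$ is a kernel of bandwidth $h$ and $h_i$ is either a
single constant $h$ (fixed-bandwidth estimation) or a per-point value
(the sample-point adaptive estimator). Because positions are integers, all
kernels are normalized **discretely**: the weights at integer offsets sum to
exactly one, so $\hat f$ is a proper probability distribution over bases and
held-out "probabilities" really are probabilities. This is a deliberate
choice over continuous-integral normalization, which would only approximate
that property at small bandwidths.

Three kernel shapes are supported, each truncated and scaled so that its
standard deviation is approximately the bandwidth parameter, which makes
tuning curves comparable across shapes:

| shape    | unnormalized weight at offset $j$ | support            |
|----------|-----------------------------------|--------------------|
| gaussian | $\exp(-j^2 / 2h^2)$               | $|j| \le 5h$       |
| square   | $1$                               | $|j| \le 3h$       |
| triangle | $1 - |j|/(6h)$                    | $|j| \le 6h$       |

The support radius is $r = \lfloor m h \rfloor$ for multiplier $m \in
\{5, 3, 6\}$; the floor keeps the support strictly within the nominal
truncation for non-integer $h$. Bandwidths below $0.5$ bp are rejected so
that every shape retains a support radius of at least 1.

## Preprocessing

Reads are restricted to one chromosome; duplicates — identical chromosome,
5′ position and strand, the standard ChIP-seq dedup — are collapsed before
any shifting. Plus- and minus-strand read starts are then shifted toward
each other by half the mean fragment length, $\lfloor L/2 + 1/2 \rfloor$
(ties round up; the fragment length is a user input, not estimated),
clamped to $[1, G]$ and sorted. Reads whose shifted positions coincide are
distinct observations and are retained. Clamping rather than dropping
boundary reads preserves the $n$ that appears in the estimator.

## Bandwidth rules and the zero problem

**KNN1** assigns $h_i$ = distance from $x_i$ to its $k$-th nearest
neighbor among the other points (a multiset: duplicated positions
contribute zero distances; all bandwidths are floored at 1 bp so a kernel
always has positive width). Sparse regions get wide kernels, dense regions
narrow ones.

KNN1 has a practical flaw: between two dense clusters every point's $k$
nearest neighbors can be intra-cluster, no kernel spans the gap, and a
held-out point falling there receives probability zero — collapsing the
joint probability of the entire held-out set ("the zero problem").
**KNN2** repairs this: when all $k$ nearest neighbors of $x_i$ lie on one
side, its bandwidth becomes the distance to the nearest point on the
opposite side, making $\hat f$ strictly positive everywhere between $x_1$
and $x_n$.

Two design points where the rule's letter needed sharpening:

* **Rank-$k$ distance ties** between a left and a right neighbor are
  counted as mixed-side — no override. (Equivalently, a direction is
  "covered" when its nearest point is within the $k$-th neighbor
  distance.)
* **Duplicated positions.** A duplicate of $x_i$ is always among its $k$
  nearest neighbors and lies on *neither* side, so the literal
  "all-on-one-side" condition can never fire for a duplicated cluster-edge
  point — which silently reintroduces the zero problem. The implemented
  rule is therefore stated as directional coverage: *if a direction
  contains at least one point but none of the k nearest neighbors, extend
  the bandwidth to the nearest point in that direction* (both directions
  may extend; points with no opposite-side point at all keep their KNN1
  value, as at the extreme ends of the range). On duplicate-free data this
  is exactly the all-on-one-side override, and it restores the positivity
  guarantee in general. The property suite checks it against a brute-force
  restatement of the rule on random instances with duplicates.

## Uniform blending

The blended estimate $\hat f_\varepsilon(x) = (1-\varepsilon)\hat f(x) +
\varepsilon / G$ assigns baseline mass everywhere on a chromosome of length
$G$; it is the second cure for the zero problem and is controlled by
`epsilon` (default 0.1 — the value the tuning analysis settles on: slightly
less probable held-out data than smaller $\varepsilon$, but it favors
smaller bandwidths, which emphasize true signal regions). Blending is an
increasing affine map of the values, so it changes no local maxima;
maxima are therefore detected on whatever track is supplied.

## Tuning protocol

Positions are partitioned 50/25/25 into training, tuning and test sets by
a seeded uniform permutation (tune and test get `round(0.25 n)` each,
remainder to training). The score of a parameter is the mean natural-log
probability of the tuning points under the training-set estimate; `-Inf`
(possible only at $\varepsilon = 0$) marks an uncovered tuning point. The
test-set summary is the geometric mean probability, `exp` of the same
score.

Grids: bandwidths default to half-integer powers of two, $2^{j/2}$ for
$j = 4..30$ (4 to 32768 bp) — chosen because reported optimal bandwidths
on real data include values like 362, 724 and 1448, which are exactly
half-integer powers of two; $k$ defaults to $1..32$. Ties break toward the
smaller parameter (less smoothing, emphasizing signal regions). The
natural log is used throughout; the base affects plots only, never the
argmax.

## Exact sparse representations

The square-kernel estimate is piecewise constant with at most $2n + 1$
pieces (each point contributes one rise and one fall); it is built by an
event sweep in $O(n \log n)$, independent of $G$, and written as bedGraph.
The triangle-kernel estimate is piecewise linear; its stored breakpoints
are the union of each kernel's apex, support edges and first
outside-support offsets, after pruning knots that linear interpolation of
their neighbors reproduces exactly. Linear interpolation between
breakpoints reproduces dense evaluation at every integer. Gaussian
estimates are not piecewise-simple and are exported densely as fixedStep
WIG.

## Numerical choices

* Kernel normalizers and query evaluation share one C++ routine, so dense
  tracks and `evaluate_at` agree bitwise; kernels are accumulated in
  ascending $x_i$ order in double precision with no compensated summation
  (documented error budget $10^{-6}$ on total mass).
* Support membership is tested with integer arithmetic
  ($|q - x_i| \le r_i$), avoiding float boundary ambiguity.
* Kernels overhanging $[1, G]$ are neither renormalized nor reflected; the
  off-chromosome mass is simply lost from the in-range sum, which matches
  the view that the estimate may vanish "at the extreme ends of the
  range". Mass-conservation checks therefore apply to configurations whose
  supports lie inside the chromosome.
* Dense tracks are stored only over the union of kernel supports, with an
  implicit value (0, or $\varepsilon/G$ after blending) outside.

## The synthetic world

The generator emulates what the estimator sees on real pulldown data:
point-source binding events plus uniform background. A fragment center is
drawn from a source (normal with per-source spread, modeling binding-site
extent plus fragmentation noise — only read *starts* enter the estimator
after shifting, so the fragment-interval geometry itself is not needed) or
uniformly from the chromosome; a fair coin picks the strand, and the read
start is displaced half a fragment length upstream on its strand. Ground
truth is the discretized mixture density, renormalized to $[1, G]$.

The acceptance-scale world is fixed once: $G = 10^6$, $2 \times 10^4$
reads, 50 sources of equal weight (0.7 total) with 50 bp spread evenly
spaced across the chromosome, 30% uniform background, fragment length 150.
Spread 50 bp is a typical point-binding peak half-width; 30% background is
a realistic non-specific pulldown fraction. These values were chosen
before the acceptance measurements and never adjusted toward them.

What a green test does establish: the estimator, bandwidth rules, tuning
protocol and maxima analysis behave as documented on data with known
truth, and the qualitative orderings (adaptive over fixed, gaussian over
triangle over square, tuned over untuned) reproduce at desk scale. What it
does not establish: behavior under sequence-content, mappability or GC
bias, PCR duplication artifacts, paired-end protocols, or real-data scale
($10^8$ bp chromosomes, $10^7$ reads) — none of which the generator
models.

## Known limitations

* Single chromosome at a time; no multi-chromosome merged tracks or
  parallelization.
* Fragment length is an input; no cross-correlation estimation.
* No peak significance testing, enrichment calling, bias correction or
  signal subtraction — the package reconstructs the signal itself.
* bigWig output is out of scope (plain-text bedGraph/WIG only).
* The KNN2 guarantee concerns strict positivity, not accuracy, in gaps; a
  single very distant outlier still receives (and donates) a very wide
  kernel.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(G = 1e5, n_reads = 4000, fragment_length = 150,
                  sources = data.frame(center = c(2e4, 5e4, 8e4),
                                       weight = c(0.25, 0.3, 0.25),
                                       spread = c(30, 50, 80)),
                  background_weight = 0.2, seed = 42)
X <- preprocess(simulate_reads(cfg)$reads, 150, chrom_info(cfg$chrom, cfg$G))
run_compare(X, G = cfg$G, seed = 42)
```

See the README for the numbers this prints and how to read them.
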