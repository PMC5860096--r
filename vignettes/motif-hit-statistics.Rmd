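---
title: "Motif hit statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif hit statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifclump)
```

# The problem

When a DNA sequence is scanned with a transcription factor motif —
a position frequency matrix (PFM) — at a score threshold, some number
X of windows on the two strands will exceed the threshold purely by
chance. Motif hit enrichment analysis asks whether the observed count
in a sequence of interest is surprising relative to that chance
distribution, so its null distribution must be computed accurately.
Two features of real motifs make the naive binomial picture (each of
the 2(N − M + 1) scan positions an independent Bernoulli trial) wrong:

* **self-overlap**: a repetitive or periodic motif that has just
  matched is likely to match again a few positions downstream, so hits
  arrive in *clumps* and the count is overdispersed;
* **strand pairing**: a palindromic motif matches both strands at the
  same position, so hits come in pairs and odd counts are impossible.

`motifclump` models the hit count with a compound Poisson law: clumps
(maximal runs of mutually overlapping hits) arrive as a Poisson process
and carry i.i.d. sizes; the clump-size law is derived from the motif's
self-overlap structure under the background.

# The background model

Unbound DNA is modeled as a homogeneous order-d Markov chain over
{A,C,G,T} with transition probabilities $\pi$ and stationary
distribution $\mu$ (for d = 0, $\mu = \pi$). Because both strands are
scanned, the model must not prefer a strand or a reading direction:
every word of length d + 1 is constrained to have the same stationary
probability as its reverse complement and as its reversal.

`estimate_background()` tallies (d+1)-mer counts, averages them over
the 4-element closure {identity, reverse, complement, reverse
complement} (the maximum-likelihood estimate under the symmetry
constraint), adds a pseudocount (default 1 per (d+1)-mer, which
guarantees the strictly positive probabilities the log-odds score
needs), and derives $\pi$ by row normalization and $\mu$ from the
d-mer marginals.

One numerical subtlety: with ordinary sliding-window counts the prefix
and suffix marginals of the count table differ by sequence-boundary
terms of order d/L, so for d ≥ 2 the marginal-derived $\mu$ would miss
the fixed-point property $\mu\pi = \mu$ by far more than numerical
noise. Counts are therefore tallied *circularly* within each clean
(non-N) segment — each segment contributes d extra wrap-around windows
— which makes the two marginals identical and $\mu$ exactly
stationary. The wrap-around bias is d spurious counts per segment,
negligible against the ML edge effects it replaces. Windows containing
non-ACGT letters are skipped (standard masking convention).

Orders up to d = 2 are the intended regime: order 1–2 captures
dinucleotide structure such as CpG depletion or enrichment, which is
the dominant low-order feature of regulatory DNA; much higher orders
would start to absorb the motifs themselves into the background.

# Scores, thresholds and the grid

The motif score of a window w of length M is the log-likelihood ratio
$s(w) = \log P_M(w) - \log P_B(w)$, where $P_B$ starts the chain in
$\mu$. Its exact distribution under the background is computed by a
dynamic program over motif positions whose state is the Markov context
and the accumulated score, with per-position score increments rounded
to the nearest multiple of a granularity g:

* **g = 0.01** (natural-log units) by default: grids stay below a few
  thousand bins for typical PFMs while the discretization error is
  negligible against hit probabilities of 10^-2–10^-4;
* **nearest-integer rounding** (not floor) keeps the discretization
  unbiased; the brute-force test oracles use the identical rounding so
  DP-vs-enumeration tests can assert exact equality;
* for positions j ≤ d the background factor is the chain factorization
  of $\mu$ into successive conditionals, which telescopes to exactly
  $\mu$, keeping the DP strictly positionwise.

`choose_threshold()` returns the smallest grid score t whose tail
probability is at most the nominal level α, together with the attained
level α′ = P(S ≥ t). **All downstream formulas use α′, not α**: on a
discrete grid the nominal level is generally not attainable, and the
overlap probabilities below divide by the true hit probability.

A consequence of per-position rounding worth knowing: for d ≥ 1 the
grid of a PFM and that of its reverse complement differ by O(g) per
atom, because the stationary factorization sits at opposite ends of
the window on the two strands. The exact (unrounded) scores are
strand-symmetric, and for well-separated motifs the attained hit
probabilities agree exactly; but atom-level grid identity between a
motif and its reverse complement holds only at d = 0. The scanner uses
the identical increment tables as the DP, so "score ≥ t" always means
the same event in the analytic model and in simulation.

# Overlap probabilities

For a shift k between two window starts, the *marginal* overlapping
hit probability is
$\gamma_k = P(S_0 \ge t, S_k \ge t)/\alpha'$, computed exactly from a
two-dimensional score DP (state: context plus both accumulated
scores; zero-probability states pruned). Three strand cases exist:
same strand ($\gamma_k$, k = 1..M−1), forward-then-reverse
($\gamma_{3',k}$, k = 0..M−1; k = 0 is the palindromic pairing) and
reverse-then-forward ($\gamma_{5',k}$, k = 1..M−1). These are marginal
in the sense that whatever happens between the two hits is averaged
over — so they describe overlap redundantly: for the word AAA, an
overlap at shift 2 is forced whenever two consecutive shift-1 overlaps
occur.

The *principal* overlap probabilities $\beta$ remove this redundancy:
$\beta_k$ is the probability of a hit at shift k with **no**
intermediate hit on either strand, under the event order
$Y_1 Y'_1 Y_2 Y'_2 \ldots$ (forward before reverse at equal shift, so
each event is counted once). Exact computation would require
enumerating compatible words (exponential), so $\beta$ is approximated
by a renewal-style chain subtraction: from $\gamma_k$, subtract every
chain "first principal overlap at shift j, then a marginal overlap
from j to k", summing over the strand type of the intermediate hit and
including the palindromic pairing at shift 0:

$$\beta_k = \gamma_k - \beta_{3',0}\gamma_{5',k}
  - \sum_{j=1}^{k-1}\left[\beta_j \gamma_{k-j}
  + \beta_{3',j}\gamma_{5',k-j}\right]$$

$$\beta_{3',k} = \gamma_{3',k} - \sum_{j=1}^{k}\beta_j\gamma_{3',k-j}
  - \sum_{j=0}^{k-1}\beta_{3',j}\gamma_{k-j}, \qquad
  \beta_{3',0} = \gamma_{3',0}$$

$$\beta_{5',k} = \gamma_{5',k}
  - \sum_{j=1}^{k-1}\left[\beta_{5',j}\gamma_{k-j}
  + \beta_j\gamma_{5',k-j}\right]$$

Reverse-to-reverse overlaps equal forward-to-forward ones by the
background symmetry, which is why $\gamma$ and $\beta$ appear in the
reverse chains. Each value is clipped into [0, γ] (an approximation,
not an exact probability, can stray below 0), and the aggregates
B = Σβ, B3 = Σβ3′, B5 = Σβ5′ are clipped so that B + B3 ≤ 1 and
B + B5 ≤ 1, which the clump recursion needs. The shift-0 terms in the
first two recursions matter: without them a palindrome's forced
pairing would be double-counted and every downstream quantity would be
wrong. The approximation is validated against direct Monte-Carlo
frequencies of the defining events on 10 Mb of sampled sequence (3-SE
agreement) in the acceptance suite.

# Clump sizes

On a single strand a clump extends with probability B per hit, so the
clump size is geometric: $\theta_c \propto (1-B)B^{c-1}$.

On two strands the clump is tracked by the strand of its last hit.
A forward-ending clump extends forward-to-forward (rate B) or
forward-to-reverse (B3); a reverse-ending clump extends
reverse-to-reverse (B, by symmetry) or reverse-to-forward (B5). End
factors are 1 − B − B3 (forward end) and 1 − B − B5 (reverse end).
One modeling choice here was genuinely open: the recursion needs a
*start* state. A clump can start with a forward hit, or with a reverse
hit that is not palindromically paired to a forward hit at the same
position (a paired reverse hit can never be first, because the forward
partner precedes it in the event order). The start weights are
therefore proportional to (1, 1 − pair0), where pair0 = β3′,0 is the
shift-0 pairing probability. For a palindrome pair0 = 1: clumps always
start forward, every forward hit is followed by its reverse partner,
and the model puts all mass on even clump sizes — matching simulation,
where observed palindrome clump sizes are always even. With equal
start weights instead, a palindrome would be assigned positive mass on
size 1, which simulation rules out.

Truncation: the recursion decays at the spectral radius of the 2×2
extension matrix (< 1 whenever B + B3 < 1 and B + B5 < 1); it is cut
when the remaining mass falls below `cmax_tol` (default 1e-10, hard
cap 1000) and renormalized.

The *marginal* mode (`overlap_mode = "marginal"`) substitutes the
γ aggregates for B, B3, B5 (and γ3′,0 for pair0) throughout. It serves
as the surrogate for the earlier generation of compound Poisson models
that used marginal overlap probabilities directly; on repeat-like
motifs it overestimates clump sizes — the redundancy the principal
probabilities remove — which is visible as an inflated variance in the
count distribution.

# Hit counts

With E[C] the mean clump size, clumps arrive at rate
$\lambda = 2\alpha'(N - M + 1)/E[C]$ and the count PMF follows the
standard compound-Poisson recursion
$$P(X=0) = e^{-\lambda},\qquad
  P(X=x) = \frac{\lambda}{x}\sum_{x'=0}^{x-1}(x-x')\,
           \theta_{x-x'}\,P(X=x').$$
The $\lambda/x$ prefactor is the only reading consistent with the mean
identity E[X] = λE[C] = 2α′(N − M + 1), which is enforced as a unit
test at 1e-6. The recursion is extended until the cumulative mass
reaches 1 − 1e-10, capped at the hard maximum 2(N − M + 1) hits.
`binomial_counts()` provides the independence reference, and
`enrichment_pvalue()` reports P(X ≥ observed) with the truncated tail
counted toward the p-value (an upper bound, i.e. conservative).

Multiple sequences are handled by treating N as the total scannable
length; per-sequence edge effects (a clump cannot span two sequences)
are ignored, which is accurate when N is much larger than M.

# The simulation harness and what a green test establishes

`sample_sequences()` draws sequences exactly from the fitted
background (first d letters from μ, then π; C++ inner loop, seeded
through R's RNG). `empirical_count_distribution()` scans them on both
strands with the identical score grid and pools per-sequence counts;
batch 25/75% quantiles expose the sampling noise.
`empirical_clump_distribution()` counts clump sizes on one long
sequence, joining consecutive hits (in (start, strand) order, + before
− at equal start) whose starts differ by at most M − 1, i.e. whose
windows overlap; a forward and reverse hit at the same start form one
clump of size 2. Default desk scales are 2000 sequences × 10 kb and
10 Mb for clumps: large enough for 3-SE tests, minutes of runtime.

The generator emulates exactly the world the analytic model assumes —
stationary symmetric order-d background, no masked letters, no real
binding sites. A green comparison therefore establishes internal
consistency (the analytic overlap/clump/count machinery describes what
scanning background-like sequence produces), **not** that real
promoters follow an order-d chain, and not model accuracy in the
non-rare-hit regime: at per-position hit probabilities much above
10^-3 clumps start to interact and the compound Poisson law drifts
toward (mildly conservative) overdispersion.

A caveat on L1 distances at desk scale: the statistic
d = Σ|P_E − Q| has a sampling-noise floor of roughly
$\sqrt{2/(\pi n)}\sum_x\sqrt{Q(x)}$ even when Q is the true law; at
n = 2000 and a dispersed count distribution this floor is near 0.09,
so small measured distances are dominated by simulation noise rather
than model error. Comparisons between models on the *same* simulated
reference remain meaningful.

# Known limitations

* β and θ are renewal-style approximations, not exact probabilities;
  exact clump statistics would require word automata over compatible
  words, which is out of scope.
* Strand-level grid identity fails for d ≥ 1 (rounding asymmetry
  above); the package always anchors both strands to the same
  threshold index.
* The clump-start weighting assumes the shift-0 pairing is the only
  mechanism forcing a reverse hit to be non-initial.
* N-masked windows are skipped by the scanner but the analytic N
  ignores masking; heavily masked sequences should pass an effective
  scannable length.
* The enrichment p-value is a per-motif null tail probability; no
  multiple-testing machinery across motif collections is provided.
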