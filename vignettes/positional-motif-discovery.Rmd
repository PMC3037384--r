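---
title: "Discriminative discovery of positionally distributed motifs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative discovery of positionally distributed motifs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(posmotif)
```

This vignette documents the statistical model implemented by **posmotif**,
the learning procedure, every non-obvious default, and the design decisions
(including deliberate deviations from the naive reading of the published
method) with their rationale. The worked end-to-end example lives in the
package README; this document is the "why", not the "how".

## The model

The package learns one motif from a **labeled promoter pair**: a foreground
(target) set believed to share a regulatory signal, and a background
(control) set. All sequences must have one common length $L$ and a common
anchor (typically the transcription start site, TSS), because the positional
part of the model is defined over absolute start coordinates.

### Foreground: ZOOPS with a positional prior

The foreground class model is a zero-or-one-occurrence-per-sequence (ZOOPS)
mixture. A sequence $x$ of length $L$ either contains no site (probability
$1 - p_{occ}$) and is emitted entirely by an order-0 *flanking* model $F$,
or (probability $p_{occ}$) contains exactly one site of width $w$: a start
$u \in \{1, \dots, L - w + 1\}$ is drawn from a positional law $T$, a strand
from a fixed strand weight (default $1/2$), the site window from a position
weight matrix (PWM) $M$ — reverse-complemented for minus-strand sites — and
the flanks from $F$:

$$P(x \mid \theta) = (1 - p_{occ}) \prod_l F(x_l)
  + p_{occ} \sum_u T(u) \Big[\tfrac12 M(x_{u..u+w-1}) +
  \tfrac12 M(\overline{x_{u..u+w-1}})\Big] \prod_{l \notin u..u+w-1} F(x_l).$$

The positional law $T$ is a mixture of the uniform distribution (weight
$\gamma$) with a **discretized skew normal**: the density
$f(y) = \tfrac{2}{\omega}\,\varphi(z)\,\Phi(\alpha z)$, $z = (y - \xi)/\omega$,
is evaluated at the integer starts $1, \dots, L - w + 1$ and renormalized
over that lattice. Location $\xi$ (bp, internal coordinates), scale $\omega$
(bp) and shape $\alpha$ are learned; $\alpha = 0$ recovers a Gaussian, and
$\gamma = 1$ a flat prior. Reported coordinates are TSS-relative
(`tss_offset` maps position 1 to e.g. $-500$).

### Background class and classification

The background class is a homogeneous Markov model of order $d$ (default 3,
configurable), with ascending-order conditionals for the first $d$
positions. Classification is Bayes' rule over the two class models with
class priors $\pi$; `class_posterior()` gives $P(\text{foreground} \mid x)$.

## Learning: maximum supervised posterior

All parameters — PWM, flanking, background conditionals, $p_{occ}$, class
prior, and the positional parameters — are learned by maximizing the
**supervised posterior**

$$\sum_i \log P(y_i \mid x_i, \theta) + \log q(\theta),$$

the conditional (discriminative) class likelihood plus a prior $q$. The
prior is: symmetric Dirichlet on every probability simplex, with an
equivalent sample size $e$ over $K$ cells giving concentration $1 + e/K$
(defaults: $e = 4$ for motif columns, flanking, background conditionals,
class prior and occurrence); Gaussian on $\xi$ (mean = middle start, sd =
$L/2$) and on the shape (mean 0, sd 4); Gamma on $\omega$ (shape 2, rate
$8/L$, i.e. mean $L/4$); Beta(2, 2) on $\gamma$. The published work keeps
its exact hyperparameters in supplementary text; these defaults are declared
artifact choices, all configurable through `hyperparams()`.

Optimization is quasi-Newton (BFGS) with analytic gradients on an
unconstrained parameterization: log-odds against the first cell for
simplexes, logit for $p_{occ}$, $\pi$, $\gamma$, log for $\omega$. Priors
are evaluated on the natural-parameter scale without transform Jacobians
(a documented convention: the prior regularizes the natural parameters, and
the mode is reported on that scale). Gradients come from mixture
responsibilities, with the count accumulation done in C++; correctness is
established in the test suite by exhaustive-enumeration oracles for the
likelihood (relative error $< 10^{-9}$) and central finite differences for
the gradient.

### Phase shift and motif-length adjustment

The motif width is not known in advance. Each restart starts from width 15
(default) and iterates a heuristic:

1. optimize numerically;
2. find the **insignificant border columns**: border columns whose removal
   keeps the number of predicted promoters at $\geq 80\%$ of its value
   under the full model (the "20% rule", `insignificance_drop = 0.2`);
3. propose a window modification from a codified rule table — only the left
   border uninformative → shift right; only the right → shift left; both →
   truncate; neither → expand by one column on each side (up to
   `max_motif_length`);
4. apply it (overlapping PWM columns copied exactly, new columns uniform,
   the prior location $\xi$ shifted by the left-edge offset) and reoptimize.

A history of visited $(\text{width}, \text{offset})$ window states
suppresses any proposal that would revisit a state, guaranteeing
termination.

### Deviations from the naive reading, and why

These choices were all driven by observed failure modes on synthetic
benchmarks; they are the package's documented interpretation of
under-specified parts of the method.

**Predicted-promoter counting.** The published criterion counts "predicted
promoters". The obvious candidate, $P(c = 1 \mid x) > 1/2$, degenerates to
comparing $p_{occ}$ with $1/2$ whenever the motif is uninformative — early
in the heuristic this collapsed healthy windows to the minimum width. The
heuristic and restart selection therefore count a promoter as predicted iff
at least one position reaches an **empirical p-value below $10^{-3}$
against the control score distribution** — the same definition used for
final site prediction. The posterior variant remains available
(`count_predicted_promoters()` without a control set).

**Joint trimming budget.** Testing each border side independently against
the 20% budget over-trims: single columns each retain 88–95% of
predictions, so both sides pass several columns at once and the motif
collapses. `insignificant_positions()` instead extends the trim greedily
one column at a time on the cheaper side while the *combined* trim stays
within the budget.

**Restart selection.** Supervised posteriors of models with different
widths are not comparable (each PWM column carries its own Dirichlet
normalization, worth $+3$ to $+8.5$ per column depending on the ESS), so
scores are compared after subtracting, per column, the prior density of a
uniform column. Even then the raw training margin can prefer *positional
memorization* — a near-uniform PWM with a spiked positional prior — over a
genuine motif. Across restarts the winner is therefore the heuristic
endpoint predicting the **most promoters** at the control-calibrated
threshold, with the score as tiebreak. Each restart is represented by its
endpoint, not its best intermediate step: the heuristic owns the width
decision.

**Seed search.** Random PWM initializations essentially never find a
planted motif at benchmark scale (the basin is tiny). Each restart instead
scores 50 random length-$w$ foreground subsequences by the objective at the
seeded initialization and starts from the best; subsequences covering true
sites separate well *before* any optimization.

**Reported motif.** The discriminatively fitted PWM only becomes as sharp
as the classification margins require; columns of a clearly recovered motif
can still sit 0.2–0.3 total variation from truth. `predicted_site_pwm()`
reports the motif *as observed in the predictions*: each sequence whose
best site (strand-summed joint posterior) exceeds $1/2$ contributes that
site's letters. This is what a sequence logo of the predictions shows, and
it is the PWM used in the recovery and decoy-discrimination acceptance
checks. The raw parameters are what `write_model()` serializes. Strand
summing matters: a palindromic site splits its posterior evenly between
the two strand components, and per-strand thresholds would drop it.

**Background-model capacity on synthetic data.** With i.i.d. (order-0)
synthetic promoters, a *discriminatively trained* order-3 background model
is free capacity: motif $k$-mers occur only in targets, so down-weighting
them in the control-class model separates the classes with no motif at all.
On a 100+100 implant pair this motif-free solution beat the true motif by
~90 nats of supervised posterior, and optimization seeded *at the truth*
slid away to it; with an order-0 background the motif is recovered cleanly.
The spec default stays order 3 (appropriate for real promoters, whose
higher-order structure is shared between classes); the synthetic
benchmark experiments set `bg_order = 0`, the correctly specified order for
their generator. This is a genuine, reproducible property of discriminative
learning with over-capacity nuisance models, not an implementation detail.

## Prediction

Site calling is calibrated, not thresholded on raw posteriors: the
strand-summed joint posterior $P(c = 1, u \mid x)$ of **every position of
every control sequence** forms an empirical background distribution, and a
candidate's p-value is the fraction of control positions scoring strictly
higher. `call_sites()` returns all positions with $p <$ threshold
(default $10^{-3}$; strict inequality, so threshold 0 returns nothing),
with TSS-relative coordinates and BED export.

## Synthetic benchmarks

`implant_sites()` reproduces the published implantation protocol: given
$n$ site strings and a containment fraction $f$ (default 0.7), it draws
$N = \lfloor n / f \rfloor$ target and $N$ control promoters from a pool
and implants each site — by substitution, preserving length — into one
target promoter, on a uniform strand, at a start drawn uniformly or from a
Gaussian (out-of-range draws resampled). `add_decoy()` plants a decoy site
in *every* target and control promoter (resampling placements that would
overlap an annotated site), creating the class-balanced confounder used to
demonstrate that discriminative learning ignores non-discriminative
signals. `sample_from_model()` draws directly from the ZOOPS generative
process for parameter-recovery experiments.

The acceptance experiments use an 8-bp motif with consensus-letter
probabilities 0.91/0.88 (≈1.4 bits per column, typical of well-conserved
JASPAR motifs). Weaker columns (0.85, ≈1.1 bits) sit at the detection
margin of a 200+200-sequence benchmark and make recovery a coin flip —
the conditions were chosen to test the machinery, not the sample-size
frontier, and were frozen before the acceptance pipeline was finalized.

## Evaluation

Matching the published assessment machinery: nucleotide-level recall and
precision (`nucleotide_pr()`, with precision defined as 1 when nothing is
predicted), threshold-swept PR curves over the pooled ranked predictions,
normalized Euclidean PWM distance (minimum over offsets and reverse
complement of the mean column distance scaled to $[0, 1]$), 0.25-bit
information-content border trimming, IUPAC consensus scanning in
TSS-relative windows, and 2×2 contingency statistics with one-sided
Fisher's exact and pooled two-proportion z-tests. The test suite verifies
the published Table 2 benchmark sizes and all Table 3 sensitivity/FPR/F
values from the printed counts.

## Limitations and problem sizes

* One PWM motif, zero-or-one occurrence per sequence; no multi-occurrence
  or higher-order motif models.
* Equal-length, TSS-anchored sequences only — the positional prior is
  meaningless otherwise.
* Training cost is dominated by `restarts × heuristic steps × BFGS`
  iterations over an $N \times L$ scan; 400 sequences × 250 bp × 10
  restarts ≈ 7 minutes on one CPU. The published default of 50 restarts is
  affordable overnight, not interactively.
* The empirical p-value resolution is $1 / (N_{ctrl} (L - w + 1))$;
  thresholds below that are vacuous.
* On synthetic data, mind the background-order capacity effect above.
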