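---
title: "Embodied number learning with recurrent counting networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embodied number learning with recurrent counting networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`countnet` implements a small neural cognitive architecture in which the
concept of number is grounded in two sensorimotor sequences: counting on
the fingers and reciting the number words. The architecture has four
parts:

1. **A lateralized motor controller/memory** — two recurrent networks,
   one per hand. The right-hand net learns the joint-angle sequence of
   the counting configurations for one..five; the left-hand net learns
   six..ten. Numbers one to five occupy the right hand only; from six on
   the right hand is fully open and left-hand fingers are added, so the
   left net is *switched off* (hidden state clamped to exactly zero)
   whenever a number below six is processed.
2. **An auditory memory** — one recurrent network that learns the
   sequence of the ten number words, each word represented by 13
   mel-frequency cepstral coefficients (MFCCs) taken from an in-package
   table.
3. **A competitive classifier** — a linear map plus softmax over the ten
   number classes, trained on the internal representations the sequence
   memories develop.
4. **A switch/associative layer** — a small state machine that starts,
   stops and resets the counting memories, two learned linear mappings
   `w1` (motor hidden to auditory hidden) and `w2` (the reverse), and the
   orchestration of two-operand addition.

### The sequence memories

Each memory is an output-feedback (Jordan-style) recurrent network with
**linear units and no biases**:

$$h_t = W_{in}\, y_{t-1} + W_{rec}\, h_{t-1}, \qquad y_t = W_{out}\, h_t.$$

During training the feedback $y_{t-1}$ is teacher-forced with the target
sequence; in operation the network feeds its own output back and runs
autonomously. Linearity and the absence of biases give the model its two
signature behaviors: a zero hidden state with zero input stays silent
forever, and counting is started by *incepting* activation — setting all
hidden units to 1. Counting can also resume from the stored state of any
number, which is what makes the hidden vectors usable as number
representations.

The wiring was a genuinely open design point: the architecture diagrams
identify the network's external inputs with its outputs, which is what
the output-feedback recurrence expresses; a purely autonomous variant
(no $W_{in}$) would satisfy the start-state contracts as well but could
not be teacher-forced on proprioceptive input, so the Jordan form was
adopted.

Hidden sizes are 5 per hand for the motor nets (their concatenation is
the 10-value motor representation) and 10 for the auditory net. The
step-0 feedback context is the normalized rest configuration for the
motor nets and the zero vector for the auditory net (there is no "rest
word"). Because the right-hand configurations for five..ten are
identical, the assembled controller trains the right net on one..five
and holds its state from step five on; this makes the "right hand
saturates from five" property exact rather than approximate.

### Training

All networks are trained by a from-scratch **Levenberg–Marquardt**
optimizer on the mean of squared output errors. The damped Gauss–Newton
update is

$$\Delta x = [J^T J + \mu I]^{-1} J^T e,$$

with $\mu$ starting at $10^{-3}$, divided by 10 after every accepted
step and multiplied by 10 after every rejected trial (cap $10^{10}$,
rejections do not consume epochs, so performance decreases strictly
across epochs). Training stops when the infinity norm of the gradient of
the mean squared error falls below $10^{-7}$ or after 1000 accepted
epochs. Derivatives of the recurrent nets are obtained by propagating
sensitivities through the unrolled recurrence (`bptt_jacobian()`), and
are validated against central finite differences in the test suite.

Weights are initialized uniformly on $(-0.5, 0.5)$ under a caller-given
seed; if a counting net fails to reach a teacher-forced mean squared
error of $10^{-6}$ the next seed is tried (up to 10 attempts, all
logged). In practice the nets are over-parameterized relative to their
10-step targets and converge far below the threshold, which is why the
free-running recall of the learned sequences is accurate to well under
$10^{-3}$ per channel.

### Normalization

Every table is scaled to $[-1, 1]$ by dividing each feature (column) by
its maximum absolute value (`normalize_features()`). Per-feature rather
than whole-table scaling was chosen because the first cepstral
coefficient (about $-30$ to $-36$) would otherwise crush the remaining
twelve coefficients to near zero; the whole-table mode is retained as an
option. Scale factors are stored so that novel vectors — a heard word, a
transferred hidden state — can be projected into the same space.

## The five representation datasets

For each number 1..10 the package collects: (1) the concatenated motor
hidden state reached while counting to it (10 values, left half exactly
zero below six); (2) the word's normalized MFCC row, out of sequence
(13 values); (3) the auditory memory's hidden state at that step of the
word sequence (10 values); (4) the concatenation of 1 and 2 (23 values);
(5) the concatenation of 1 and 3 (20 values). The classifier is trained
on one dataset at a time — squared error between the softmax outputs and
the one-hot targets over the ten rows — and the evaluation protocol
retrains it 100 times from different seeded initializations for 10
epochs, reporting per-class medians and standard deviations of the
likelihood assigned to the true class, plus per-epoch learning curves.
This is deliberately a *training-fit* protocol (one exemplar per class,
no held-out data): it measures how quickly and reliably each
representation supports the formation of ten distinct number classes,
not generalization.

## Numerical behavior and a known limitation

Two numerical properties of this system are worth stating plainly,
because they bound what the package reproduces.

**The classifier protocol saturates.** With 10 training rows and
140–240 parameters, damped Gauss–Newton steps with the exact softmax
Jacobian are essentially always accepted; $\mu$ anneals geometrically
and ten epochs suffice to drive the true-class likelihood to ≈ 0.999 on
*all five* datasets. The package therefore reproduces the *direction* of
the classic comparison (all datasets trainable, the fingers-and-words
combination above 90% for every number) but not intermediate likelihood
levels in the 0.25–0.95 range that partially converged optimizers
report: differences between datasets at epoch 10 are in the fourth
decimal place. The repeated-runs machinery, the curves and the paired
tests are all implemented and exercised; their discriminative power on
this saturated regime is limited. The test suite asserts exactly what
this implementation achieves and no more.

**The motor representations are ill-conditioned.** The five right-hand
counting configurations in the joint table span a nearly
four-dimensional subspace (the fifth singular value is ~$10^{-5}$ of the
first). With five hidden units read out through a seven-channel linear
map, the hidden trajectory is pinned to the targets' geometry, so the
10×10 motor representation matrix has condition number around $10^6$.
Consequences: the fingers-to-words associative fit needs the damping to
anneal roughly ten extra decades before its weakest modes converge
(~13–14 accepted iterations to reach a mean squared mapping error of
$10^{-15}$, versus ~3–4 for the better-conditioned words-to-fingers
direction), and occasionally stalls in double precision, which
`train_transfer()` handles by retrying from a fresh seeded
initialization. The mapping error itself ends far below the $10^{-15}$
floor, so cross-modal transfer is accurate to ~$10^{-7}$ per component
and transferred representations classify identically to native ones.

## The switch layer and addition

The switch is a state machine over eight modes (`idle`, `start_all`,
`counting`, `reset_auditory`, `reset_motor`, the two transfer modes, and
`output_to_classifier`) driven by four events (`operand_heard`,
`plus_heard`, `operand_done`, `count_tick`). The published description
of the layer names its capabilities — start by incepting ones, reset one
net, transfer in either direction, emit to the classifier — without a
complete transition table, so the table implemented here (documented in
`?switch_step`) is reconstructed from those capabilities and the
five-step addition narrative; the test suite model-checks it by
exhaustive enumeration of event strings, verifying that nothing can be
emitted to the classifier mid-count.

Addition of $a + b \le 10$ proceeds: both nets count to $a$; the plus
operator resets the auditory net while the motor memory holds $a$; both
count $b$ more ticks, the auditory net reaching $b$ and the motor net
$a+b$; the motor hidden state is transferred through `w1`; and the
result is classified. The classifier used here is the one trained on
dataset 5 (motor ⊕ auditory hidden), so the emitted feature is the
concatenation of the motor hidden state with its `w1` image — the
auditory half *reconstructed through the associative connection* rather
than natively counted, which is precisely the transfer the architecture
exists to support. Operands are recognized from their MFCC rows by a
nearest-neighbour matcher (`recognize_word()`); sums beyond ten are an
error, since no representation exists past ten. Ordered-pair sweeps
over all 45 valid operand pairs across 20 independently trained systems
classify the correct sum in 100% of trials in the shipped tests.

Roles are configurable: by default the motor net is the accumulator and
the auditory net counts operands; `switch_step(..., roles = "swapped")`
exchanges them, using `reset_motor` and `w2` instead.

## Representation geometry

`cluster_representations()` runs complete-linkage agglomerative
clustering on the Euclidean distances between the ten representation
vectors and orders the dendrogram leaves to minimize the summed
consecutive-leaf distance, by exhaustive enumeration of the $2^9$
subtree flips (an exact optimal leaf ordering at this size; the linkage
choice is a documented default, and average linkage gives the same
qualitative picture). The mean absolute numeric difference between
consecutive leaves (`adjacency_score`, 1 = perfect counting order)
quantifies how much a representation mirrors the number line: motor
representations chain along the sequence (their score is reliably below
the word table's), while the raw word coefficients group by acoustic
similarity instead.

## Problem sizes and determinism

All experiments in the package run at the study's native sizes — 11×14
and 10×13 fixture tables, nets with 95–360 weights, five datasets of ten
rows, 100 classifier retrainings of 10 epochs, 100 associative-fit
trials, a 45-pair addition sweep over 20 system seeds — and complete in
seconds to a couple of minutes on one core. Every stochastic step takes
an explicit integer seed and derives component seeds from it by fixed
offsets, so identical seeds give bit-identical weights, datasets, CSVs
and traces.
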