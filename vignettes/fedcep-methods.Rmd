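---
title: "Methods: a desk-scale federated clinical event prediction simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale federated clinical event prediction simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedcep)
```

## What the package simulates

`fedcep` implements, end to end and in a single process, a federated
learning system for binary clinical event prediction (heart failure,
stroke, cirrhosis, kidney disease, diabetes) from tabular electronic
health records. Five hospital nodes hold heterogeneous cohorts, train a
shared-architecture graph neural network locally, and ship *protected*
parameter updates to a global server, which authenticates, clusters and
aggregates them, and returns per-cluster global updates that each hospital
blends into its model with an experience-replay rule. Every step appends a
transaction to a hash-chained ledger, so the whole run is auditable and,
under a fixed seed, bit-reproducible.

Each stage is an ordinary R function over tibbles or small classed
objects, so every claim the simulator makes is testable in isolation.

## Preprocessing

A raw EHR table moves through three states. Missing cells are filled by
the *neighbour-mean* rule: each gap takes the mean of the nearest
non-missing values above and below it in the same column, boundary gaps
take their single available neighbour, and categorical gaps take the
nearer neighbour (ties resolve to the preceding one). "Neighbouring" is
read column-wise in the given row order — the only type-safe reading for a
mixed-type table. Categoricals are then one-hot encoded (levels sorted
with radix order for locale independence; exactly one indicator per
original column is 1), and every feature column is min–max normalized,
$(x - \min)/(\max - \min)$, onto $[0, 1]$. A constant column maps to all
zeros, the usual convention for the degenerate $0/0$ range.

Normalization statistics and encoding categories are recorded per table
and reused when transforming unseen records (values clipped to $[0,1]$,
unseen categories becoming all-zero indicators). They are computed per
hospital and never shared: pooling ranges across hospitals would leak
distributional information the rest of the pipeline works hard to hide.

## Temporal causal graph features

The directed influence of series $a$ on series $b$ at lag $\ell$ is the
lagged product sum
$\varepsilon\varpi_{a \to b} = \frac{1}{n_T - 1} \sum_{t=\ell+1}^{n_T} y_a(t-\ell)\, y_b(t)$.
Both series are z-scored first, so the weight is a lagged correlation and
the causality threshold band 0.3–0.6 has a fixed meaning; without
standardization the quantity is scale-dependent. For every ordered node
pair the single best lag up to `max_lag` (default 3) is kept, all weights
are normalized by the maximum absolute weight, and an edge is retained
when its correlation-scale weight clears both the minimum edge weight
(0.05) and the causality threshold (default 0.3). Thresholding acts on
the correlation scale — thresholding the max-normalized weight would make
the criterion relative to the noisiest pair and retain about half of a
pure-noise panel, which is exactly what a causality threshold must not
do. The adjacency stores the normalized weight of retained edges; an
optional pruning ratio (20–40% in the reference settings, off by default)
drops the weakest survivors.

Cross-sectional EHR tables have no clock. We take record order within
sliding windows (length 32, stride 1 — the middle of the reference
24–48-step window band) as pseudo-time and average the lagged weights
across windows. This is a modelling decision, not a property of the data:
the recovered "temporal" structure on cross-sectional cohorts reflects
feature co-variation, and the planted-edge recovery guarantees are stated
for genuine lagged panels, which the synthetic module generates with
known ground truth.

Per node we extract ten graph features (in/out degree, weighted degree as
the absolute incident weight sum, mean and max incident weight, an
edge-confidence score — the max absolute incident normalized weight,
already in $[0,1]$, since the field names this feature without giving a
formula — strongly-connected-component id and size, longest causal chain
length via the SCC condensation with cycles counted as component size
minus one, and the count of directed 2-chains through the node). Each
*record's* graph-feature block is the activity-weighted mean of the
per-feature rows: the record's normalized feature values (all in
$[0,1]$) weight the corresponding graph statistics. How per-record rows
should combine with per-feature graph statistics is genuinely open; the
weighted mean is deterministic, respects the record's feature usage, and
degrades gracefully to zeros for an all-zero record.

## The mean-centered GNN

Records are nodes of a cosine k-nearest-neighbour graph (k = 8,
symmetrized, self-loops). Per layer, each node aggregates the *mean* of
its neighbours' states, applies a learned affine map and ReLU, adds the
message to its current state (residual update), and the whole state
matrix is mean-centered column-wise. Mean aggregation (rather than sum)
keeps activations bounded and degree-independent; mean-centering removes
the shared drift that repeated averaging accumulates — the over-smoothing
pathology — while preserving node-specific deviations. The package
asserts the directional claim: after four layers, the across-node feature
variance with centering is at least that without it.

The head is a softmax over two classes trained with cross-entropy
(Adam, learning rate 0.001, batch size 32). A ReLU head cannot emit class
probabilities for a cross-entropy loss, so the softmax reading is used
and documented as the deviation it is. Training is transductive node
classification: the forward pass runs on the full record graph, the loss
on the training batch; the train split is `floor(0.8 h)` records under a
seeded shuffle. The "gradient" a hospital ships is the flattened
parameter delta of the round — the object federated practice actually
transmits. Default architecture: 3 layers (middle of the 2–4 reference
band), hidden width 32.

## Gradient protection

Robust log scaling compresses each coordinate by
$R \cdot \log(|R|/q + 1)$ (natural log, $q = 1$): sign-preserving,
strictly monotone, sub-quadratic for large magnitudes. The inverse is
recovered by monotone bisection with a $10^{-12}$ interior tolerance; the
round-trip is exact to $10^{-6}$ on $10^4$ standard-normal coordinates.

Protection is additive masking: a SHA-256 counter-mode PRG seeded by the
secret `phi` and a per-use nonce produces a uniform mask of half-width
$10^3 \times$ the plaintext RMS. Masking is exactly additively
homomorphic — summed ciphertexts unmask, with the masks of all
contributing nonces, to the summed plaintexts — and nonce reuse is a
hard error. The mask half-width is a compromise: wide enough that
per-coordinate plaintext–ciphertext correlation is negligible (the suite
bounds it at 0.1 over 1,000 fresh-nonce encryptions), narrow enough that
unmasking stays exact to float tolerance. The mask scale is stored on the
cipher record and reveals only the magnitude regime. This is a simulation
of the *contract* of additively homomorphic encryption (round-trip,
additivity, magnitude hiding), not a lattice cryptosystem; the reference
polynomial-modulus parameters are treated as deployment description.

## Authentication

A hospital's signature is $D = \mathrm{num}(T) + \gamma + \mathrm{num}(\varepsilon)$
with $\gamma = u + \exp(\mathrm{int}(T) \bmod p)$, where
$\mathrm{int}(\cdot)$ is the big-integer byte encoding and
$\mathrm{num}(\cdot)$ its reduction mod $p$. The server recomputes both
from the registered public key and accepts only on exact equality.
Numerical design: $p = 2^{31}-1$ (Mersenne prime), so the Horner
reduction stays exact in doubles; the exponential is evaluated on the
residue mod 16, so that at the fixed-point scale $10^6$ every quantity is
an exact integer below $2^{53}$ and verification is integer equality,
never float comparison. A larger modulus or exponent range would either
require big-integer arithmetic this stack does not provide or push the
additive signature into the floating-point regime where small identity
perturbations vanish — defeating the tamper-sensitivity guarantee the
scheme exists for. Passwords are stored as salted SHA-256 digests only.

## Cluster-wise aggregation

Authenticated gradients are clustered by k-means under the *Zhonghua
distance* $V = \sqrt{\sum_j r_j\, \kappa(L_j - x_j)} \cdot (1 + \vartheta(L, x))$,
with $\kappa$ the Huber function (parameter 1), $r$ uniform weights and
$\vartheta$ cosine similarity. The literal $(1+\vartheta)$ factor rewards
similarity with a *larger* distance; whether it is a typo for
$(1-\vartheta)$ cannot be resolved, so the literal form is the default
and both the conventional sign and a similarity-off switch are
configurable. With the similarity factor off and a huge Huber parameter
the distance is proportional to Euclidean, and the algorithm provably
reproduces Lloyd k-means from the same starts — the suite asserts exact
assignment agreement on 200 points.

Initialization samples 10 candidate centroid sets from the gradients,
gives each one assignment pass, and keeps the set with the highest
Calinski–Harabasz score $(\eta_1/\eta_2)\,(n-p)/(p-1)$. The reference
formulation equates the centroid itself to the CHI value, which is
dimensionally impossible; the score is therefore used as a *selection
criterion* over candidate placements, which is what centroid-placement
quality indices are for. Lloyd iterations alternate Zhonghua assignment
and mean updates; an emptied cluster seizes the point farthest from its
own centroid. Cluster aggregates are member means, so
$\sum_k n_k X_k$ conserves the gradient total exactly. With exactly one
gradient per cluster the partition is forced and CHI is undefined
(reported as `NA`); with fewer than two gradients the call degrades to a
single-cluster mean.

## Continual update

The polynomial decay factor $\Re(b) = (1 + \lambda b)^{-\tau}$ blends the
local replay gradient with the incoming global one:
$A = \Re\, G + (1-\Re)\, Y$, applied as an *increment* to the local
parameters (gradient semantics; whether the blend replaces or increments
is unstated, and replacement would discard local training entirely).
The replay buffer stores past *gradients*, never raw examples — raw-example
replay would contradict the privacy premise of the whole pipeline. A
buffered entry's sampling weight is $\Re(\text{age})$, so early-task
entries lose influence and can never dominate the replay mixture.
Defaults $\lambda = 0.05$, $\tau = 1$, capacity 20 keep $\Re$ in roughly
$[0.5, 1]$ over 20 rounds — a gentle decay chosen once so the global
update phases in without overwriting local knowledge.

## Ledger

Every framework action (registration, login, local training, privacy
preservation, authentication, aggregation, global prediction, continual
update) appends a block holding the actor, the action, the SHA-256 digest
of the canonically serialized payload (sorted keys, fixed precision), a
timestamp, the previous block's hash and its own hash. The genesis block
links to 64 zeros. Consensus machinery is deliberately absent: a
single-writer chain preserves every guarantee that is testable on one
machine — integrity, order, tamper evidence — and the suite shows any
single-field mutation in a 100-block chain is detected at the correct
index. Simulations use a logical clock for timestamps so runs are
bit-reproducible.

## The synthetic generators, and what passing tests do not show

`generate_cohort()` draws numeric features from stated normals,
categoricals from stated multinomials, the binary `event` from a logistic
model on the raw scale, and masks feature cells (never the label)
independently at the missing rate. `generate_panel()` produces
multivariate series with planted lagged linear edges as ground truth for
graph recovery. The default cohort template mirrors a heart-failure
screening schema (age, sex, resting blood pressure, chest pain type,
cholesterol, maximum heart rate).

The federated hospitals use heterogeneous task label models: each task
weights the vital-sign features with a task-specific sign pattern,
centred for ~50% prevalence, with coefficients scaled so the linear
signal is strong (roughly 24 SD of linear predictor per unit feature SD,
i.e. nearly deterministic labels) and 2% missingness. These are the
study conditions: cohorts are *designed separable* so that end-to-end
accuracy measures the pipeline, not the irreducible noise of a clinical
problem. Passing tests therefore demonstrate the mechanics — recovery,
protection, authentication, aggregation, retention, audit — on data whose
generative model is known; they say nothing about accuracy on real EHR
data, whose correlations, censoring and label noise the generators do not
emulate.

## Problem sizes and numerical choices

The suite and the acceptance script run, per invocation: a 5-hospital,
10-round simulation on 500-record cohorts (the desk-scale reading of the
100-round reference configuration); a 5-seed two-task retention
experiment (200 records per task); 20-seed planted-edge recovery on
6-node, 300-step panels; 10,000-coordinate protection round-trips; and
1,000-identity authentication scans. Tolerances: protection round-trip
$10^{-6}$, homomorphism $10^{-9}$, metric-oracle agreement $10^{-12}$,
signature equality exact. Root-finding uses 200-step bisection with
Newton-free safeguards; ties in categorical imputation resolve upward;
`which.min` ties in cluster assignment resolve to the lowest index.

## Known limitations

Single-process simulation only: no networking, stragglers or
asynchrony. The masking scheme delivers the additive-homomorphic
contract, not lattice security. The signature scheme is an
exponential-probing construction for tamper evidence, not a
standards-compliant DSA. The global model's validation accuracy on a
mixed-task cohort is reported but is expectedly weak: per-cluster
gradients from heterogeneous tasks do not compose into one
all-task model, and the framework's value is measured at the *local*
models after the continual update. Multi-class heads, attention, and
automatic choice of the cluster count are out of scope.
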