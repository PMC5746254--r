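---
title: "Modelling grating and plaid responses under specific recurrent connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grating and plaid responses under specific recurrent connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(plaidnet)
```

# The scientific question

Layer 2/3 of mouse primary visual cortex shows two puzzling properties of
responses to plaid stimuli (superpositions of two oriented gratings): many
neurons are *facilitated* by plaids beyond their best grating response, and
neurons with near-identical grating tuning can have very different plaid
tuning. Neither is expected if each neuron simply sums feedforward grating
components. `plaidnet` implements a modelling chain for asking whether the
*rule wiring local recurrent excitatory connections* can explain these
properties: if excitatory neurons are grouped into subnetworks that bind
*several distinct* preferred orientations ("feature binding"), recurrent
amplification and competition reshape plaid responses in ways that a pure
"like-to-like" rule (connections preferentially between similarly tuned
neurons) cannot.

The package provides:

1. a linear-threshold rate-network integrator and fixed-point solver;
2. a five-node analytical model for stability, competition and
   stimulus-mixture analysis;
3. generators for large-scale V1-like networks on a torus under three
   connectivity rules (random/Peters, like-to-like, feature-binding);
4. grating/plaid stimulus protocols and input-current construction;
5. response metrics (OSI, PSI, MI, pairwise signal correlations and the
   grating-versus-plaid R²), responsivity filtering, and RF-centre
   estimation;
6. a calcium-imaging-like trial variability model with a bootstrap
   component-response control;
7. synthetic ground-truth datasets for validating every analysis stage.

# Dynamics

Each neuron obeys

$$\tau \dot x_i = -x_i + \sum_j w_{ij}\,[x_j - \beta_j]^+ + I_i(t) + \sigma_i \zeta_i(t),$$

with activation current $x_i$ (pA), unitless gains
$w_{ij} = g_j n_{ij} \alpha_j$ (current per synapse × synapse count × I–F
gain of the presynaptic neuron) and firing rate
$r_i = \alpha_i [x_i - \beta_i]^+$. Defaults follow nominal cortical
parameters: $\tau = 10$ ms, $\alpha = 0.066$ Hz/pA, $\beta = 0$,
$g = 0.01$ pA/Hz per excitatory synapse and ten times that (with negative
sign) per inhibitory synapse.

Numerical choices:

* `simulate_network()` uses fixed-step Euler–Maruyama with default
  `dt = 1` ms (`dt <= tau/5` enforced). Per-step noise increments have
  standard deviation $\sigma\sqrt{dt/1\,\mathrm{s}}$, so the accumulated
  noise has standard deviation $\sigma$ after one second. The nominal
  parameter table's printed noise amplitude (5 mA) is physically
  implausible against pA-scale synaptic currents and is treated as a unit
  typo; noise defaults to zero and is a free configuration parameter.
* `fixed_point()` solves the nullcline $x = W[x]^+ + I$ by damped
  iteration. The damping factor is equivalent to an Euler step of
  $d\cdot\tau$; `"auto"` sets $d = 1.5/(2+\rho)$ from a power-iteration
  estimate $\rho$ of the spectral radius, which keeps the iteration stable
  for inhibition-stabilised weight matrices whose dominant eigenvalue is
  large and negative.
* Divergence is flagged when any $|x_i|$ exceeds $10^6$ pA, separating
  unstable regimes cleanly from slow convergence.
* `simulate_protocol()` iterates all stimuli of a battery as columns of
  one matrix (one sparse matrix product per damped step). Stimuli whose
  fixed point has not converged within `max_iterations` (oscillatory
  winner-take-all competition does this) are integrated further and
  reported as the mean rate over an averaging window, the discrete
  analogue of averaging the tail of a stimulus presentation.

# The five-node analytical model

Four excitatory neurons form two subnetworks of two, one inhibitory neuron
pools everything. A proportion $s$ of each excitatory neuron's output is
reserved for its own subnetwork. Total output weights default to the
anatomical derivation $w_E = 8142 \times 0.01 \times 0.066 \approx 5.37$
and $w_I = 8566 \times 0.1 \times 0.066 \approx 56.5$ (the published
model description does not state $w_E, w_I$ directly; this derivation
from synapse counts and gains is the package's documented default and is
overridable).

`classify_stability()` computes the Jacobian $J = (W - I)/T$ and labels:
stable + excitatory-only stable = `AS`; stable but excitatory-only
unstable = `ISN` (inhibition-stabilised); unstable with real dominant
eigenvalue = `Exp`; unstable with complex dominant pair = `IO`.

Two structural facts discovered while implementing, both verifiable with
the package:

* With the default inhibitory fraction the five-node weight matrix is
  rank-deficient in a way that makes the Jacobian spectrum *purely real*
  for every $(w_E, w_I, s)$: the complex-pair route to `IO` can never
  trigger there. The oscillation seen at very strong inhibition is a
  *threshold-induced limit cycle* invisible to linearisation. We therefore
  added an optional simulation probe (`check_oscillation`, on by default
  in `phase_diagram()`): a network classified stable by eigenvalues is
  driven with a sustained single-neuron input, and relabelled `IO` if the
  trajectory has not settled by the end of the probe window.
* At $s = 0.25$ (the value used for the mixture experiment) the
  *all-active* fixed point is already unstable: the network operates as a
  winner-take-all, and the fixed point reached under asymmetric input has
  the losing subnetwork silenced. `mixture_experiment()` therefore reports
  per-level convergence rather than requiring global stability.

`competition_current()` injects $\iota$ (default 1 pA) into one excitatory
neuron, solves the fixed point, and reports the net recurrent synaptic
current (excitatory plus inhibitory; leak and stimulus excluded) into an
excitatory neuron of the *other* subnetwork. Negative values mean
competition. At the nominal weights competition is absent at $s = 0$,
present by $s = 0.2$, and the network destabilises around $s = 0.4$ —
the regime progression that motivates "a minority of specific synapses
suffices".

# Large-scale connectivity

Neurons are placed uniformly on a flat torus (default 2.2 × 2.2 mm,
80,000 neurons = 10% of cortical density; `place_population_scaled()`
shrinks the torus as $\sqrt{n}$ to preserve density at reduced size).
18% are inhibitory. Excitatory neurons get uniform random preferred
orientations (salt-and-pepper map).

**Orientation convention.** Orientations are stored as true orientations
in $[0, \pi)$; every von Mises comparison doubles the angular difference,
so orthogonal orientations score $\cos = -1$ (maximal penalty). Subnetwork
field angles are doubled-angle orientations under the same convention.

**Peters' rule.** Axonal and dendritic fields are Gaussian densities over
the torus ($\rho_d = 75$ µm; $\rho_{a,e} = 290$ µm; $\rho_{a,i} = 100$
µm), treated as periodic (image-summed) fields. The probability of a
synapse from $j$ to $i$ is the integrated product of the fields — in
closed form a wrapped Gaussian of inter-soma distance with variance
$\rho_d^2 + \rho_a^2$ — normalised over targets, with self-connections
excluded.

**Specific rules as mixtures of normalised distributions.** The
like-to-like rule is implemented as
$p = s_1\,[\![p_\mathrm{Peters}\,p_\mathrm{ori}]\!] + (1-s_1)\,[\![p_\mathrm{Peters}]\!]$
with $p_\mathrm{ori} = \exp\{\kappa_1\cos(\theta_i-\theta_j)\}$
(doubled angles), i.e. a fraction $s_1$ of each neuron's synapses is drawn
from the orientation-specific distribution and the rest from the
non-specific one. Writing the rule instead as a single product with one
normalised factor would make the specific term $O(1/N)$ against the
$O(1)$ non-specific term, so the specificity parameter would have no
effect at any published value; the mixture form is also the only reading
under which the published decomposition of feature-binding synapses into
random/like-to-like/binding shares comes out. The feature-binding rule
adds a third component with weight $s_2$, restricted to targets in the
same subnetwork (Peters-weighted).

**Excitation/inhibition balance.** Specificity redistributes only the
*excitatory-target* share of an excitatory neuron's output; the share
directed at inhibitory targets is pinned to its Peters'-rule overlap
value. This mirrors the five-node structure (the E→I weight
$w_{ei} = w_E f_I$ is independent of $s$) and is dynamically necessary:
routing the specific mass exclusively to excitatory targets starves
feedforward inhibition and destabilises the network.

**Subnetworks.** For each of $N_S = 6$ subnetworks and $\vartheta = 2$
orientation components, a unit-magnitude complex noise field is drawn per
neuron and smoothed by Gaussian-weighted summation over neuron positions
(75 µm). Field angles at each neuron's position give that subnetwork's
local orientation pair, so composition varies smoothly across cortex.
Membership goes to the subnetwork whose best component matches the
neuron's preferred orientation (von Mises, $\kappa_2 = 4$; argmax).

**Synapse drawing.** Each neuron draws
`round(budget × density_factor)` output synapses multinomially over its
probability vector (budgets 8142 excitatory, 8566 inhibitory;
`density_factor = 0.1`), with per-synapse strength scaled by
`1/density_factor` so total output weight is density-invariant.
Inhibitory sources always use plain Peters' rule. Default parameters
follow the published network configurations
(`connectivity_spec("like_to_like")`: $s_1 = 0.8$, $\kappa_1 = 0.5$;
`"feature_binding"`: $s_1 = 0.1$, $s_2 = 0.25$, $\kappa_2 = 4$). The
alternative published parameterisation $s_1 = 0.45, s_2 = 0.225$ is kept
as the `"feature_binding_methods"` preset; the two sources conflict and
the default follows the tabulated values.

# Stimuli

A grating of orientation $\theta_g$ injects current proportional to each
excitatory neuron's input tuning curve (von Mises, width $\kappa = 4$),
renormalised so the *total* injected current equals the stimulus
amplitude $A$; inhibitory neurons receive none. A plaid injects the
linear average of its two component tuning curves, same normalisation.
Protocols: `oscillating5_plaids` (five orientations spanning ±40° around
a base plus all 10 pairwise plaids) and `drifting16_plaids` (16
directions plus full plaid sets at 45°/90°/135° relative component
orientation).

With thresholds at zero the network is positively homogeneous: scaling
$A$ scales every rate, and all downstream statistics (trial noise scales
with each neuron's peak response, the neuropil stand-in with the
population median) are invariant. The default
$A = 5\,\mathrm{pA} \times n$ simply puts peak single-neuron rates in a
physiological few-Hz band.

# Trial variability and filtering

Measured single-trial responses are modelled as
$r_{ij} = \bar r_i + \mathcal N(0, \hat\sigma\,\bar r_\mathrm{max})$,
twelve trials per stimulus, unclipped (ΔF/F-like values may be
negative). `estimate_variability()` implements both the pooled estimator
(standard deviation of all single-trial responses over all stimuli,
normalised by $\bar r_\mathrm{max}$ — which deliberately conflates tuning
variance with trial noise, following the published definition of the estimator) and
a residual estimator (per-stimulus mean removal with degrees-of-freedom
correction) used for parameter-recovery validation.

The package default $\hat\sigma = 0.5$ (`default_trial_noise()`) is a
realistic level for bulk population calcium imaging — single-trial
responses scattering by half the peak response — chosen once; an
empirical $\hat\sigma$ would require the recordings the model is meant
to stand in for.

`responsivity_filter()` mirrors the imaging inclusion criterion: the
single-trial threshold is the $1-\alpha$ quantile of neuropil samples,
the trial-mean threshold the $1-\alpha$ quantile of maxima of
neuropil-resampled pseudo-neurons matching the table's design; a neuron
must beat the latter on its best stimulus and beat the former on more
than half the trials there. For model data, where no neuropil exists, a
zero-mean Gaussian at the population noise scale stands in (and is
labelled as such). Selectivity indices are computed on trial means
rectified at zero; Pearson pair correlations use unrectified means.

# The decorrelation experiment

`decorrelation_experiment()` chains everything: build population →
draw connectivity → steady-state responses to the oscillating protocol →
trial noise → responsivity and OSI > 0.3 filters → pairwise $\rho_g$,
$\rho_p$ → squared Pearson correlation between them across pairs. Pair
scope is all included excitatory pairs (the model has no imaging-site
structure); a seeded subsample caps memory at `max_pairs`.

Problem sizes: the packaged experiment defaults to 8,000 neurons on a
proportionally shrunken torus (≈ 696 µm), the size used by the test suite
and the acceptance script; the published 80,000-neuron scale is supported
by the same functions.

**A finite-size caveat, stated plainly.** At full scale, inhibition
(100 µm axonal reach) is local relative to the torus, so winner-take-all
competition is resolved *independently in many field domains* and the
feature-binding network produces a rich diversity of subnetwork
win-patterns — the source of grating/plaid decorrelation. On a shrunken
torus the excitatory reach (290 µm) spans most of the surface: a single
subnetwork can win *globally* for most stimuli, collapsing the diversity
of win-patterns. At 8,000 neurons the feature-binding R² is therefore
strongly seed-dependent (anywhere from near 0 to above the random-rule
value on individual seeds), while the random and like-to-like values are
stable. Reproducing the published feature-binding decorrelation reliably
requires scales closer to the original. The like-to-like and random
results, and the *existence* of the feature-binding decorrelation
mechanism, are robust at reduced scale; its *magnitude* is not a
finite-size-safe quantity.

# Synthetic ground truth

`make_population()` builds populations with known rules:

* **component** — von Mises grating tuning (per-neuron widths log-normal
  around $\kappa = 4$, amplitudes log-normal, 10% untuned baseline);
  plaid mean = average of the two component means. Guarantees MI ≤ 0 and,
  noise-free, a perfect grating→plaid relation.
* **feature_binding** — subnetworks pair two protocol orientations; each
  neuron sits near one of its pair; its matched plaid is facilitated to
  `gain ×` the larger component mean (default 1.5 ⇒ ground-truth
  MI = 0.2) and other plaids attenuated (×0.7). Defaults were chosen so
  synthetic MI distributions span roughly [−0.5, 0.5] under noise.
* **random** — component-rule plaid means permuted across plaids per
  neuron, severing the grating/plaid relation while preserving scales.

`make_dataset()` adds Gaussian trial noise and a Gaussian neuropil
sample. What the generator deliberately does *not* emulate: temporally
correlated noise, neuropil contamination dynamics, negative-going
calcium artefacts, non-Gaussian trial distributions, or imaging-site
spatial structure. Tests passing on synthetic data therefore validate
the *analysis chain*, not the realism of any noise model.

`bootstrap_component_control()` implements the null model used to argue
that decorrelation is not a noise artefact: synthetic plaid trials are
built by summing randomly drawn single-trial component-grating responses
(sum convention, per the control's definition; the model's stimulus
input uses the average convention — both are exposed), and the
grating/plaid R² of such data gives the ceiling that any single
consistently applied combination rule would produce at the measured
noise level.

# Known limitations

* Finite-size dependence of the feature-binding decorrelation magnitude
  (above).
* The eigenvalue regime classification cannot see threshold-induced
  limit cycles; the simulation probe is a pragmatic detector with a
  fixed probe input and window.
* The pooled variability estimator is biased upward by construction for
  tuned neurons; use the residual method for recovery of a generative
  noise parameter.
* No spiking, conductances, synaptic dynamics, conduction delays or
  plasticity; stimuli are reduced to orientation content (no spatial
  phase, temporal frequency or contrast dynamics).
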