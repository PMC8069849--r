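---
title: "Quantum-like Bayesian networks for ecological systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-like Bayesian networks for ecological systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoqbn)
```

## Why quantum-like probability for ecology?

Ordinary Bayesian networks (BNs) are directed acyclic graphs whose
conditional probability tables propagate uncertainty by classical
probability calculus. Several recurring ecological situations sit awkwardly
in that calculus:

* **intransitive systems** — cyclic dominance or cyclic succession with no
  climax state (rock-paper-scissors games, disturbance-driven vegetation
  cycles), which defeat the acyclicity requirement and leave single
  observations uninformative ("solution-incomplete" networks);
* **noncommutative systems** — ecosystems whose fate depends on the *order*
  of disturbances, while BN conditioning is order-blind;
* **superposed uncertainty** — a site that is, for predictive purposes, in
  several states at once until an observation resolves it, with alternative
  hidden histories that can reinforce or cancel.

The quantum-like formalism replaces each table probability \(p\) with a
complex **probability amplitude** \(\psi = \sqrt{p}\,e^{i\theta}\). Squared
magnitudes recover classical probabilities (Born's rule,
\(P = \lVert P_a \psi \rVert^2\)); phases \(\theta\) only matter when
amplitudes are *added* before squaring, which is where interference — and
everything genuinely non-classical in this package — enters:
\[
\Bigl|\sum_i \psi_i\Bigr|^2 \;=\; \sum_i |\psi_i|^2 \;+\;
2\sum_{i<j} |\psi_i||\psi_j| \cos(\theta_i - \theta_j).
\]
"Quantum-like" is meant seriously: nothing here claims that ecosystems are
quantum systems, only that the amplitude calculus is a compact modelling
language for superposed, order-sensitive, cyclic uncertainty.

The package has four layers: amplitude/state-vector primitives
(`qamp()`, `superpose()`, `born_probability()`, `collapse()`,
`interfere()`), networks with amplitude-valued tables (`qbn()`,
`posterior()`, `sequential_condition()`, `information_gain()`), cyclic
transition graphs (`transition_graph()`, `multipath_superposition()`,
`apply_disturbance_sequence()`), and coupled phase oscillators
(`integrate_oscillators()`, `assess_entrainment()`).

## Amplitudes, state vectors and measurement

Amplitudes are stored in polar form `(magnitude, phase)` — the magnitude is
always the nonnegative square root, which avoids the sign ambiguity of
\(\sqrt{p}\) — and converted to rectangular complex numbers whenever they
are summed. Phases are canonicalized into \([0, 2\pi)\) on construction and
compared modularly with tolerance `1e-9`.

A `state_vector()` must have unit L2 norm within `1e-9`. Vectors violating
this are **rejected, not silently renormalized** (`renormalize()` exists
for the deliberate case): normalization failures almost always indicate a
mis-entered table, and masking them would push the error downstream.
Measurement is `born_probability()` (squared projected norm — invariant
under global phase, summing to 1 over any complete observable) and
`collapse()` (projection followed by renormalization; conditioning on an
event of probability \(\le\) `1e-12` is an error rather than a silent
renormalization, for the same reason).

A worked two-state example: a habitat that is good or poor with complete
uncertainty is the superposition with both amplitudes \(e^{i\theta}/\sqrt2\);
for *any* phases, projecting onto "poor" and squaring gives 0.5, and a prior
of 0.1 for riparian presence enters the amplitude table as the scalar
\(\sqrt{0.1} = 0.3162\).

```{r}
S <- superpose(c(good = 0.5, poor = 0.5), phases = c(0.8, 2.4))
born_probability(S, projector(S$basis, "poor"))
round(amplitude_from_probability(0.1)$magnitude, 4)
```

## Networks and the two marginalization semantics

A `qnode()` holds one amplitude vector per full parent configuration
(rows in `expand.grid()` order, first parent varying fastest); each row's
squared magnitudes must sum to 1, so squaring the table entry-wise yields an
ordinary CPT. The parent graph must be acyclic — cyclic systems are not
shoe-horned into the network class but handled by the transition-graph
layer, and the validator says so explicitly.

`posterior()` performs exact inference by enumeration (networks are capped
at \(2^{20}\) joint assignments via `options(ecoqbn.max_assignments=)`;
the intended models are small and approximate amplitude inference is a
research problem we do not take a position on). Two marginalization
semantics are exposed:

* **classical** — hidden nodes are summed out in probability; this is
  textbook enumeration and is entirely phase-blind;
* **coherent** — hidden nodes are summed out in *amplitude*
  (\(\psi_q = \sum_{\text{hidden}} \prod_{\text{nodes}} \psi\)), then
  Born's rule is applied and the result renormalized over query states.
  Hidden histories ending in the same query state interfere.

An important consequence, stated plainly because it is easy to get wrong:
**zero phase difference is not classical behaviour.** Amplitude summation
with equal phases is maximal *constructive* interference
(\(|\psi_1+\psi_2|^2 = p_1 + p_2 + 2\sqrt{p_1 p_2}\), exactly as in
two-slit physics with in-phase paths), so a coherent posterior over a
network whose phases are all zero generally differs from the classical
posterior. The coherent mode coincides with the classical one exactly when
each query state receives a single contributing history, or when the
pairwise cross terms cancel — e.g. hidden branches separated by \(\pi/2\),
where \(\cos(\Delta\theta) = 0\). Users who want classical answers should
ask for them (`mode = "classical"`); the per-state `interference` report
attached to every posterior quantifies the gap. This is a deliberate design
position: the alternative (defining coherence away so that zero phases
reproduce classical Bayes) would make the interference machinery vacuous.

```{r}
net <- qbn(
  qnode("A", c("t", "f"), probs = c(0.5, 0.5)),
  qnode("B", c("t", "f"), probs = c(0.5, 0.5), phases = rbind(c(0, pi))),
  qnode("C", c("t", "f"), parents = c("A", "B"),
        probs = rbind(c(0.8, 0.2), c(0.4, 0.6), c(0.3, 0.7), c(0.9, 0.1)))
)
posterior(net, "C", mode = "coherent")$interference
```

Phases default to 0 everywhere and files without `theta` keys load as
classical BNs. How phases should be elicited from ecological observations
is an open scientific question; the package treats them strictly as user
input and supplies no heuristic.

## Ordered evidence and noncommutativity

`sequential_condition()` maintains the joint wave function over all full
assignments and applies findings one at a time.

A finding on an ordinary (unrotated) node is Lüders projection: zero out
inconsistent assignments and renormalize. Projections associated with
*different* nodes act on different factors of the joint basis and therefore
commute — a theorem, not a modelling choice — so purely projective evidence
is order-invariant no matter how the per-node measurement bases are
rotated. Order effects require an update rule that is genuinely nonlinear
in the joint state.

The rule adopted here treats a finding on a node with a measurement-basis
rotation \(\phi\) as **uncertain evidence**: the observed outcome is not a
basis state of the node but the rotated superposition
\(u_k\) (columns of \(\begin{bmatrix}\cos\phi & -\sin\phi\\ \sin\phi &
\cos\phi\end{bmatrix}\)). It is incorporated by amplitude-space **Jeffrey
conditioning**: the node's marginal amplitude vector is revised to
\(u_k\), while each conditional slice of the joint vector (the amplitudes
over the other nodes given one node state, L2-normalized) is preserved:
\[
\psi'(x) \;=\; (u_k)_{x_N}\,
\frac{\psi(x)}{\bigl\lVert \psi(\cdot,\,x_N)\bigr\rVert_2}.
\]
Jeffrey revision is the standard probability-kinematics update for
uncertain evidence, and its non-commutativity is classical knowledge
(successive Jeffrey revisions do not commute unless they are hard
conditionings). At \(\phi = 0\), \(u_k\) is a basis vector and the rule
collapses exactly to Lüders projection, so unrotated evidence remains
order-invariant to machine precision. A slice whose norm vanishes (a
branch made impossible by earlier findings) contributes nothing; a finding
all of whose branches are impossible is an error naming the step.

On the shipped two-node example (prior \((0.3, 0.7)\), child rows
\((0.9,0.1)\) and \((0.2,0.8)\), child basis rotated \(45^\circ\)), the two
evidence orders give child marginals \((0.5, 0.5)\) versus roughly
\((0.93, 0.07)\) — observing the parent first re-prepares the child, while
observing the rotated child first pins it before the parent is known.

```{r}
net <- qbn(qnode("A", c("a1", "a2"), probs = c(0.3, 0.7)),
           qnode("B", c("b1", "b2"), parents = "A",
                 probs = rbind(c(0.9, 0.1), c(0.2, 0.8)), rotation = pi / 4))
round(marginal_distribution(
  sequential_condition(net, evidence(A = "a1", B = "b1")), "B"), 4)
round(marginal_distribution(
  sequential_condition(net, evidence(B = "b1", A = "a1")), "B"), 4)
```

`information_gain()` is the Kullback–Leibler divergence of the
single-finding classical posterior from the prior marginal; a value of 0 is
the operational definition of a solution-incomplete finding (every single
move in rock-paper-scissors scores 0 against the outcome, while two moves
determine it).

## Cyclic transition graphs and path trajectories

`transition_graph()` stores disturbance-labelled directed edges with
amplitudes \(\sqrt{p}\,e^{i\theta}\), \(p \in (0,1]\). The graph is a
*possibility* graph: out-edges of a state need not sum to 1, and
`apply_disturbance_sequence()` renormalizes among the label-matching
out-edges at use time. Cycles are first-class citizens — the boreal
fixture's spruce → bog → shrubland → spruce circuit is the canonical
example, detected by `find_intransitive_circuits()` (simple directed
cycles, canonicalized to start at the lexicographically smallest state).

Two path probabilities are exposed. The per-leg Born form squares each leg
amplitude before multiplying, so it equals the classical product rule for
every path and every phase assignment — per-path values carry no
interference by construction. Interference lives exclusively in
`multipath_superposition()`, which superposes whole trajectories: classical
totals sum per-path probabilities, coherent totals square the per-path
amplitude sum, reaching \(2\times\) the classical total for two equal
in-phase paths and 0 for two equal paths \(\pi\) apart. This split keeps the
printed per-path law intact while realizing "all pathways simultaneously"
at the ensemble level.

Enumeration control: revisits are allowed but each directed *edge* is used
at most once per path (configurable via `allow_repeated_edges`), which
bounds cycle traversal and keeps enumeration finite even on strongly
connected graphs; `max_len` is a hard cap, and ordering is deterministic
(lexicographic in label sequences).

`apply_disturbance_sequence()` walks a probability distribution over states
through a labelled event sequence. A state with no matching out-edge keeps
its mass — ecologically, a disturbance with no defined transition for a
state leaves that state unchanged — and only when *no* occupied state can
respond does the stranded-sequence warning fire, reporting the reachable
prefix. Because transitions are state-dependent, outcomes are generally
order-dependent; sequences of up to five events are checked against all
permutations and flagged.

## Signal entrainment

Two calling organisms are modelled as phase oscillators with sinusoidal
pulling:
\[
\dot\theta_1 = w_1 + A_2 \sin(\theta_2 - \theta_1), \qquad
\dot\theta_2 = w_2 + A_1 \sin(\theta_1 - \theta_2),
\]
with \(w_i\) in radians per unit time and couplings \(A_i \ge 0\). The
phase difference \(\Delta = \theta_1 - \theta_2\) obeys
\(\dot\Delta = (w_1 - w_2) - (A_1 + A_2)\sin\Delta\), giving a stable locked
difference \(\Delta^* = \arcsin\bigl((w_1-w_2)/(A_1+A_2)\bigr)\) exactly
when \(|w_1 - w_2| \le A_1 + A_2\), and unbounded drift outside.

`assess_entrainment()` reports two deliberately separate views: the
framework's *parameter definitions* (entrained iff \(A_1 = A_2\),
synchronous iff \(w_1 = w_2\)) and an *empirical* phase-lock test (range of
\(\Delta\) over the final third of the trajectory below `tol_lock`, locked
difference as the circular mean of that window mapped into
\((-\pi,\pi]\)). They disagree in general — asymmetric coupling
\(A_1 \ne A_2\) locks perfectly well — so conflating them would misreport
real duets.

Integration is fixed-step 4th-order Runge–Kutta (`deSolve::rk4`) with
default `dt = 0.01` and unwrapped phases: the system is smooth and
non-stiff, and fixed stepping makes runs bit-reproducible, which we value
over adaptive efficiency here. Halving the step changes final phases by
less than `1e-6` on the default smoke case. `signal_train()` converts
trajectories into discrete event times (linear interpolation of
emission-phase crossings): locked pairs with nonzero \(\Delta^*\) produce
trains with a constant offset (duetting), identical symmetric pairs
converge to coincident trains. `entrainment_sweep()` integrates a whole
parameter grid as one batched ODE system to map the locking tongue.

## Problem sizes, tolerances and numerical choices

* Normalization tolerances: `1e-9` on state vectors and table rows;
  `1e-12` treated as zero probability in conditioning.
* Exact enumeration only; default cap \(2^{20}\) joint assignments.
* Property tests run on randomly generated networks of 2–4 binary nodes
  (500 draws for the marginalization semantics, with a brute-force
  amplitude-summation oracle), 1000 random paths for the per-path
  equivalence, and a \(20\times20\) oscillator grid integrated to
  \(t = 150\) at `dt = 0.05` with a 5% exclusion margin around the
  locking boundary, where critical slowing makes any finite-horizon
  classifier unreliable. These sizes keep the full suite under a minute on
  one core while exercising every code path.
* Ties when reporting a dominant state are broken toward the lowest state
  ordinal.

## What the synthetic fixtures do and do not show

The fixtures (`bat_network()`, `roshambo_network()`, `spruce_graph()`)
encode the structures exactly, but most of their numbers are stand-ins:
only the riparian prior (0.1), the uniform move priors, the deterministic
game rules and the cycle topology are given quantities. The bat
conditionals are fixed, documented placeholder values (a
`randomize = TRUE` flag redraws them under the caller's seed for property
testing), and the boreal fixture ships only the three-state sub-cycle plus
a user-editable CSV template — the full regional transition network is not
available as data. Passing tests therefore demonstrate that the *calculus*
is implemented correctly (oracle agreement, invariant preservation,
closed-form limits), not that any fixture is a calibrated model of real bat
habitat, boreal succession or animal chorusing: real data would bring
elicited phases, non-binary states, measurement error and transition
probabilities estimated from observation, none of which the generator
emulates.

## Known limitations

* No density matrices or mixed states; no tensor-product entanglement
  algebra beyond what joint-assignment enumeration provides.
* No structure or parameter learning, and no approximate inference.
* Phase elicitation from field observations is unspecified by design.
* The oscillator layer covers two oscillators; choruses (N > 2) and
  inference of \(w, A\) from recordings are out of scope.
* The bridge from oscillator state to network posteriors is limited to the
  shared interference-report formalism; no tighter mapping is invented.
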