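---
title: "Aligning dynamic networks with temporal node embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning dynamic networks with temporal node embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynetalign` computes a one-to-one mapping between the node sets of two
dynamic networks — ordered sequences of undirected graph snapshots over a
shared node universe — by embedding every node into a vector that reflects
the evolution of its topological role, scoring all cross-network node pairs
by cosine similarity, and resolving the score matrix into an injective
mapping by iterative global maximization. This vignette explains the model,
the parameters that matter, the synthetic benchmark, and the design
decisions taken where more than one reasonable construction exists.

## The data model

A dynamic network is stored as its set of *events*: triples $(u, v, t)$
meaning that the undirected interaction $\{u,v\}$ is active at the integer
time point $t \in \{0, \dots, T-1\}$. Snapshot $t$ is exactly the graph of
the events at time $t$, always materialized over the full node universe, so
a node silenced in one snapshot (for example by noise injection) persists
as an isolated vertex rather than disappearing. The on-disk form is a
three-column TSV with optional `#T=<n>` and `#node <id>` directives, which
make the representation lossless for trailing empty snapshots and globally
silent nodes; writing and re-reading a network is the identity on events,
nodes and $T$.

## Temporal embedding

Each snapshot is turned into a corpus of random walks (`walks_per_node`
walks from every vertex, second-order transitions with return bias $1/p$
and in-out bias $1/q$; isolated vertices contribute singleton walks so that
every node acquires a vector). The corpus trains a Skip-Gram model: one
hidden layer of `dim` neurons, no activation on the hidden layer, and
negative sampling with the unigram$^{0.75}$ noise distribution as the
tractable surrogate for the softmax output. Training is single-threaded
with its own counter-based random stream, so a fixed seed reproduces the
embedding bitwise.

The temporal extension is the *initial state*: at time point $t$ the
input-embedding row of every node in the intersection of the current
vocabulary and the previous state is initialized from its $t-1$ vector;
nodes only in the previous state are discarded, and genuinely new nodes are
initialized afresh. At $t = 0$ the previous state is empty and the run is a
plain Skip-Gram. Training with `epochs = 0` is therefore exactly the
identity on a fully covered initial state, a property the test suite
asserts. The state returned after the last snapshot is the temporal
embedding.

Defaults (all overridable): `dim = 128`, `window = 5`,
`walks_per_node = 10`, `walk_length = 80`, `epochs = 5`,
`negative_samples = 5`, `p = q = 1`, initial learning rate `0.025` with
linear decay. These are the standard word2vec/node2vec community settings;
nothing in the method depends on them finely, and the robustness checks in
the test suite use smaller values (see *Problem sizes* below).

## Making two embedding spaces comparable

Cosine similarity between vectors from two *independently* trained
Skip-Gram models is meaningless: the objective determines the embedding
only up to a large family of equivalent solutions, so two training runs
place even identical networks in incommensurable spaces. We evaluated the
seemingly natural alternative of concatenating the two networks' corpora
(with prefix-disjoint vocabularies) into a single model: because tokens of
the two networks never co-occur in a walk, nothing in the joint objective
constrains the two halves of the space relative to each other, and
self-recovery of an identical copy collapses to near-chance after a single
epoch.

The construction used here instead trains the two temporal embeddings as
*twin trajectories*:

* every node vector is initialized deterministically from a hash of its id
  combined with the seed, so namesake nodes of the two networks start from
  identical vectors;
* walk sampling and training consume identical random streams in both
  networks at every time point.

Two identical networks then follow identical trajectories and every
namesake pair has cosine similarity exactly 1; as the inputs diverge, the
trajectories decorrelate in proportion to the structural disagreement, and
namesake similarity degrades smoothly. This is the package's central
interpretive choice: cross-network comparability comes from shared
stochastic realization anchored at a shared initialization, not from shared
parameters. A corollary worth stating plainly: the anchoring is strongest
when the two networks share most of their node set and structure (the
self-alignment and noise protocols below); for pairs in which the source is
a small induced substructure of the target, the trajectories have less in
common and alignment quality drops accordingly.

## Similarity and matching

The similarity matrix holds $\varphi(v, u) = \cos(\mathbf{v}, \mathbf{u})$
for all $(v, u) \in V \times U$, with $|V| \le |U|$ enforced (callers are
told to swap otherwise). Zero-norm vectors — possible only for degenerate
inputs — score 0 with a warning. Per-node similarity lists sorted in
descending order are available for inspection.

The default matcher realizes iterative global maximization: all $|V||U|$
pairs are swept in descending score order (ties broken lexicographically on
the source then target id, for determinism), and a pair is assigned
whenever both its endpoints are still free. Equivalently, no assignment
ever has a score exceeding that of an earlier one. This greedy rule is what
the objective's iterative formulation prescribes; it is $O(nm \log nm)$ and
deterministic. An exact maximum-weight assignment (Hungarian algorithm,
rectangular form with potentials) is available via `method = "optimal"`;
its total score bounds the greedy total from above, but it optimizes a
different criterion (total weight rather than the no-later-better
condition) and is not the default.

## The synthetic benchmark

The generator builds the first snapshot from the Barabási–Albert model
(`events_per_node` edges attached per new node, so every node has at least
one link) and evolves it: snapshot $t$ rewires a uniformly random `e_rate`
fraction of snapshot $t-1$'s edges to fresh uniformly random endpoints,
conserving the edge count exactly. "Rewiring" here conserves edge count
but not the degree sequence — the model gives no operational definition of
its shuffling, and constant density is what lets `e_rate` parameterize
similarity cleanly. The counterpart of a pair is the induced subnetwork on
`keep_nodes` uniformly sampled nodes, perturbed per snapshot by rewiring a
`delta` fraction of edges; kept nodes retain their ids, so the ground-truth
alignment is the namesake map. The perturbation is applied per snapshot
(rather than once globally) so that `delta` has the same meaning at every
time point.

Similarity between edge sets is reported two ways. The Jaccard index
$|E_1 \cap E_2|/|E_1 \cup E_2|$ is the default of `snapshot_similarity()`.
The calibration statements — consecutive snapshots "$\approx 95\%$ similar"
at `e_rate = 0.05`, pairs "$\approx 90\%$ similar" at `delta = 0.10` — are
statements about the *conserved-edge fraction*, i.e. the overlap
coefficient $|E_1 \cap E_2| / \min(|E_1|, |E_2|)$: rewiring a fraction
$r$ of $m$ edges conserves $(1-r)m$ of them, giving overlap $1-r$ but
Jaccard $(1-r)/(1+r)$ (0.905 at $r = 0.05$). `method = "overlap"` is
therefore what the calibration tests and the acceptance script use.

Noise injection follows two regimes: `"edges"` removes a fraction of
individual $(u,v,t)$ triples (interactions persist, degraded over random
time points); `"events"` removes a fraction of distinct $(u,v)$
interactions together with all their occurrences, which is more incisive.
Removed counts are exact (`round(level × population)`), and the node
universe never changes, so the namesake truth stays total.

What the generator does *not* emulate: scale-free degree evolution
(rewiring is uniform, so later snapshots drift away from the BA degree
sequence), node birth/death, weighted or directed interactions, and the
community structure of real interactomes. Passing the benchmark therefore
demonstrates correct mechanics and robustness to topological noise, not
performance on any particular real interaction network.

## Evaluation

Candidate pairs are the full Cartesian product $V \times U$. An aligned
pair is a true positive when the target is the source's namesake, a false
positive otherwise; a source node's namesake pair that was not selected is
a false negative; everything else is a true negative. Node correctness is
$\mathrm{NC} = \mathrm{TP}/|V|$; NC and TPR coincide whenever the truth is
total on $V$. The counts partition $|V||U|$ by construction, and the test
suite asserts this on randomized cases. ROC curves are assembled from one
mean $(\mathrm{FPR}, \mathrm{TPR})$ point per noise level (repeats averaged
first), anchored at $(0,0)$ and $(1,1)$, and integrated by the trapezoidal
rule; a simple unweighted moving average summarizes NC trends across noise
levels.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed through dedicated derived
  streams per operation (generation, counterpart sampling, noise, walks,
  training), so every experiment is reproducible end to end.
* Vocabulary order, edge canonicalization and matcher tie-breaks use
  C-locale (radix) string ordering, making results independent of the
  session locale.
* Empty snapshots are legal and contribute singleton walks only; a network
  with no events at all cannot be embedded and errors out, as does an
  alignment whose source has no nodes or events.
* Both edge sets empty makes snapshot similarity 1 with a warning (two
  empty graphs are indistinguishable).
* A noise level of 1 in event mode removes every event; downstream
  operations report the degenerate input rather than returning vacuous
  results.

## Problem sizes used by the checks

The self-alignment recovery check embeds 50-node, 5-time-point networks at
the full defaults over 5 seeds. The noise-robustness sweep (7 levels × 2
regimes × 5 repeats on a 100-node, 8-time-point base) uses `dim = 64`,
`walks_per_node = 5`, `walk_length = 40`, `epochs = 3`: at a tenth of the
default training cost the sweep's qualitative behavior — NC = 1 at zero
noise, monotone degradation as noise grows, event-mode noise biting harder
than edge-mode — is unchanged, and these are the package's chosen benchmark
sizes. Generator calibrations average 30 seeds at the standard 100-node,
10-time-point configuration.

## Known limitations

* Alignment quality rests on the twin-trajectory coupling; heavily
  subsampled counterparts (source much smaller than target) weaken it, and
  the package makes no claim of state-of-the-art accuracy in that regime.
* Walks never cross time points; temporal information enters only through
  the carried state. Processes with long-range temporal dependence may be
  better served by event-graph embeddings, which are out of scope.
* Edge correctness is deliberately not implemented as a quality measure:
  for dynamic networks it is known to be misleading, and node-based
  measures (NC, ROC/AUC) are used instead.
* The two networks must share their number of time points; no temporal
  warping or resampling is attempted.
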