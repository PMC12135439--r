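---
title: "Active learning for gene-regulatory-network structure discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning for gene-regulatory-network structure discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activegrn)
```

## The problem

A gene regulatory network (GRN) is a directed graph whose edges denote
regulatory influence between genes.  Observational expression data can
identify such a network only up to its Markov equivalence class (MEC):
DAGs encoding the same conditional-independence structure are
indistinguishable, and the class is summarized by the essential graph
(CPDAG), in which compelled edges are directed and reversible edges
undirected.  Knockout experiments break this symmetry — abolishing one
gene's expression and watching which genes respond orients edges — but
experiments are expensive, so the question becomes *which* gene to knock
out next.

`activegrn` implements the Bayesian answer: maintain a posterior
distribution over network structures, condense it into per-gene-pair
edge-state distributions, score candidate knockouts by how much
uncertainty they are expected to resolve, and iterate the
simulate–train–acquire–intervene cycle.

## Edge-state distributions

Given sampled structures $W^{(1)}, \dots, W^{(S)}$ (0/1 adjacency
matrices of DAGs, optionally weighted), each unordered gene pair
$(i, j)$ has three mutually exclusive states, with probabilities
estimated by weighted sample frequencies:

$$P(X_i \to X_j),\quad P(X_i \leftarrow X_j),\quad P(X_i \;\; X_j)
\;(\text{no edge}),$$

which sum to one because a DAG never carries both orientations.  Mapping
every sample through its essential graph first yields the four-state
distribution with the additional undirected state $P(X_i - X_j)$,
the natural object when the quantity of interest is the equivalence
class rather than a single DAG.

## Acquisition functions

Four scores rank gene pairs by informativeness; all are normalized by
$\log(\#\text{states})$ so they live in $[0, 1]$:

* **Edge Entropy** — Shannon entropy of the three-state distribution.
* **BALD** — mutual information between the edge state and the ensemble
  member: entropy of the ensemble-mean distribution minus mean member
  entropy.  High where members *disagree*, not merely where the pooled
  distribution is flat.
* **ECES** (equivalence-class entropy sampling) — per pair, a sampled
  Bernoulli mask $U_{ij} \sim P(X_i - X_j)$ switches between the
  *direction* entropy (binary entropy of the orientation, conditional
  on the edge being oriented) where the pair is likely undirected, and
  the four-state entropy elsewhere:
  $\mathrm{ECES}_{ij} = H_{\mathrm{dir}} U_{ij} + H_4 (1 - U_{ij})$.
* **EBALD** — the same masked switch applied to the BALD decomposition
  of the direction and four-state entropies.

Pair scores become per-gene knockout scores in two steps.  First the
incoming uncertainty of each gene, $u_j = \sum_i S_{ij}$, finds genes
with "problematic" edges.  Then a candidate knockout $i$ is scored

$$\mathrm{score}(i) = \sum_j (1 - S_{ij})\, P(X_i \to X_j)\, u_j,$$

so the best knockout is a *certain, probable parent of uncertain genes*:
perturbing it propagates through a mechanism the posterior already
trusts into the region it does not.  The batch is the arg-max set (ties
to the smallest index), or a uniform draw for the baseline.

### Notation decisions

The formulation leaves several choices open; the package resolves them
as follows and documents each switch:

* Raw 3- and 4-state entropies exceed 1 in both nats and bits, which
  would make the $(1 - S)$ certainty factor negative; every entropy is
  therefore normalized by $\log(\#\text{states})$.  $0 \log 0 := 0$.
* The direction entropy conditions on an oriented edge
  ($q = p_\to / (p_\to + p_\leftarrow)$), since the raw marginals need
  not sum to one; `direction_entropy(..., renormalize = FALSE)` gives
  the literal two-term reading.
* The non-masked branch of ECES/EBALD uses the four-state
  essential-graph entropy rather than the three-state DAG entropy: the
  scores are defined in the space of essential graphs, and the
  four-state entropy is the one consistent with the distribution they
  condition on.  (The three-state reading is available by composing
  `edge_entropy()` with the mask by hand.)
* The undirectedness mask is redrawn each acquisition round from a
  round-derived seed; negative BALD brackets from finite sampling are
  clipped at 0.
* Already-knocked-out genes stay eligible by default;
  `exclude_intervened = TRUE` removes them.  With a *fixed* pre-simulated
  interventional pool a repeat acquisition re-appends identical rows —
  duplicated evidence that biases the posterior while adding no
  information — so the bundled benchmark turns exclusion on.

### Ensembles for BALD

Both reference samplers emit hard DAGs, and the entropy of a single hard
DAG is zero, which would collapse BALD onto Edge Entropy.  The package
therefore defines ensemble members as *groups of samples* — the MCMC
chains by default (`group_ids`), or `n_groups = 8` contiguous blocks —
whose within-group edge frequencies are the member's soft edge
probabilities.  This mirrors multi-chain disagreement and reduces to
averaging over sampled models when each member is a single soft-edged
model.  The group count is exposed in both `acquire()` and
`loop_config()`.

## Essential-graph machinery

`cpdag()` orients v-structures (colliders with nonadjacent parents) and
completes them with Meek's rules R1–R4 (`meek_closure()`), which direct
an undirected edge whenever the opposite orientation would force a new
v-structure or a directed cycle in every consistent extension.  R4 is
implemented without the optional extra adjacency side condition; the
variant is sound by the standard argument and strictly stronger, and the
test suite verifies the conversion against brute-force
equivalence-class enumeration for *every* DAG on up to 4 nodes.  On
inputs that are not essential graphs (arbitrary background-knowledge
PDAGs) an orientation that would close a directed cycle is skipped,
keeping the closure total and idempotent.

Reference networks from curated gold standards are generally cyclic.
`repair_to_dag()` removes a deterministic edge set: reciprocal pairs
(2-cycles) are resolved by a topological order of the graph with all
reciprocal pairs deleted, and any remaining cycle loses its
lexicographically smallest edge (found by depth-first search).  A
greedy "most-cycles" heuristic was rejected because exact simple-cycle
counting is combinatorially explosive and because a shared forward edge
can break several back-edge cycles at once, making the removed-edge
count unpredictable; the two-phase rule is deterministic and removes
exactly one edge per independent cycle on the bundled fixture family.

Three structural Hamming distances are provided: directed (a reversed
edge counts 1 by default — one wrong unordered pair — with
`reversal_cost = 2` for the stricter entry-wise convention), undirected
(skeletons), and PDAG (per-pair states forward / reverse / undirected /
absent).

## Reference learners

The samplers exist so the acquisition layer has an honest posterior to
consume; any external structure learner can replace them by providing a
`(data, config) -> posterior_samples()` function to `loop_config()`.

The decomposable family score is Gaussian.  The default
(`bic_gaussian`) is the maximized linear-regression log-likelihood of a
gene on its parents minus $\tfrac{k}{2}\log n$ with $k = |pa| + 2$; it
has no prior hyperparameters and is score-equivalent across
Markov-equivalent DAGs.  The BGe score (Gaussian–Wishart marginal
likelihood; `score = "bge"`, $\alpha_\mu = 1$,
$\alpha_w = n_{\text{genes}} + 2$) is provided for prior-sensitivity
work and is validated in the tests against a 1-gene
numerical-integration oracle and the score-equivalence property.

Knockouts enter through the truncated factorization of a perfect
intervention: rows in which a gene is itself the target are dropped from
*that gene's* family only, while its clamped value still predicts its
targets.  A family with no contributing rows scores 0; an
under-determined regression scores $-\infty$.

`exact_posterior()` enumerates every DAG on up to 5 genes (25 on 3,
543 on 4) and weights each by its exponentiated score — the small-n
oracle.  `mcmc_posterior()` runs Metropolis–Hastings over DAG space with
single-edge add/delete/reverse proposals drawn uniformly over unordered
pairs (a symmetric proposal, so the acceptance ratio is the score
ratio), respecting acyclicity and a fan-in cap (`max_parents = 4`,
matching sparse GRN fan-in).  Chains start from the empty graph; on a
flat score the sampler's visit frequencies over the 25 3-node DAGs are
uniform within Monte-Carlo error (a detailed-balance smoke test), and on
simulated data its edge marginals agree with exact enumeration within
total variation 0.05.

## The synthetic world

The simulator stands in for GeneNetWeaver's kinetic ODE model with a
linear-Gaussian structural equation model: gene $j$ is
$x_j = b_j + o_j + \sum_{i \in pa(j)} w_{ij} x_i + \varepsilon_j$, with
edge weights drawn from $\pm[0.5, 1.5]$ (signed, avoiding
near-unidentifiable tiny effects), noise SD 1, basal expression
$b_j = 1$, and optional per-series perturbation offsets $o_j$.  A
knockout clamps the target to 0 and disables its own mechanism while the
clamped value feeds its targets.  Time points within a series are
i.i.d. draws — the benchmark protocol itself subsamples its time series,
and the statistical task (structure identifiable up to the MEC from
observational data, orientations from knockouts) is preserved at desk
scale.

Two defaults deserve justification:

* **Basal expression 1, clamp 0.** A knockout is informative because it
  moves a gene *away from its unperturbed level* and shifts its targets'
  means.  Clamping a gene to its own mean (baseline 0) is the degenerate
  case in which interventional data carries almost no orientation
  signal; basal level one noise-SD above the clamp is a conservative,
  realistic choice.
* **Per-series offsets and the i.i.d. learner.** Offsets make rows
  within a series correlated, which the i.i.d. Gaussian family score
  mis-specifies; with strong offsets the misspecification dominates and
  the posterior accumulates spurious edges regardless of experiment
  choice.  The GNW-shaped fixture keeps offsets (SD 1) because it
  emulates perturbation series; `simulated_truth_env()` defaults to
  offset-free draws so that benchmark conclusions reflect experiment
  selection rather than likelihood misspecification.  This is exactly
  the sense in which a green benchmark should be read: it establishes
  the ranking of acquisition strategies under a well-specified learner,
  not robustness to correlated perturbations, batch effects, or
  non-Gaussian expression noise, none of which the generator emulates.

`gnw_scale_fixture()` reproduces the benchmark shapes exactly: 64 genes,
207 edges (186 acyclic + 21 reciprocal back-edges removed by repair),
10 observational series × 21 time points = 210 samples, and one 21-row
knockout series per gene (1,344 interventional rows), all deterministic
given one seed.

## The active loop

`run_active_loop()` pretrains on observational data, then per round
computes the configured acquisition from the current posterior
(`entropy`/`bald` on the 3-state distribution, `eces`/`ebald` on the
4-state distribution, `uniform` ignoring the posterior), selects a
batch, appends the environment's knockout series, refits, and evaluates
the posterior before and after retraining, so learning curves come
straight from the log (`tidy()`, `autoplot()`).  The loop stops at
`max_rounds` or when a chosen metric crosses a threshold.  Everything is
derived from one seed: per-round learner seeds (`seed + 97 r`) and
acquisition seeds (`seed + 1009 r`) keep replicates exactly
reproducible.

Evaluation metrics are posterior-weighted expectations: directed and
skeleton SHD to the reference DAG, SHD between each sample's essential
graph and the reference PDAG, expected non-zero edge count (NNZ), and
recall of the reference edges.  Recall counts orientation-correct edges;
because "recall" is often reported without that qualifier, the
orientation-blind `recall_skeleton` is logged alongside.

```{r loop-example, eval = FALSE}
env <- simulated_truth_env(15, 20, seed = 1)
res <- run_active_loop(env, loop_config(
  acquisition = "entropy", batch_size = 1, max_rounds = 5,
  exclude_intervened = TRUE,
  learner = learner_config(n_samples = 600, n_chains = 4,
                           burn_in = 10000, thinning = 4),
  seed = 1))
tidy(res)
autoplot(res)
```

## Numerical choices and limitations

* Probabilities are validated to $10^{-9}$; entropy clipping absorbs
  only floating-point residue.
* MCMC schedules are chosen by convergence behaviour at the bundled
  problem sizes (for the 15-gene benchmark, 10,000 burn-in iterations
  across 4 chains), not by matching any external training budget; at
  larger gene counts the reference sampler will need proportionally
  longer chains, and a scalable external sampler is the intended plug-in.
* Degenerate inputs are defined, not errors: empty datasets give flat
  scores, a 1-gene network yields the empty posterior, pairs with no
  oriented mass have direction entropy 0.
* The uniform baseline draws without replacement within a round and
  independently across rounds.
* Interventional essential graphs are out of scope: the reference PDAG
  is the observational CPDAG of the repaired DAG, and acquisition treats
  interventional knowledge only through the posterior itself.
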