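---
title: "Methods: semi-quantitative simulation of qualitative Boolean models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantitative simulation of qualitative Boolean models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(qualsim)
```

This vignette records the modeling assumptions, numerical choices, and
limitations of the package, so that results produced with it can be
interpreted and reproduced without reading the source.

## The model class

A model is a finite set of binary **species**. *Internal* species carry
exactly one regulatory rule; *external* species are environmental inputs with
no rule. Rules can be written three ways, all lowered to the same internal
representation:

* **bio-logic rules** (`biologic_rule()`): activator clauses and inhibitor
  clauses over other species. The compiled Boolean function is

  $$x_i' \;=\; \Big(\bigvee_{A \in \mathcal{A}_i} \bigwedge_{a \in A} x_a\Big)
  \;\wedge\; \neg\Big(\bigvee_{I \in \mathcal{I}_i} \bigwedge_{b \in I} x_b\Big),$$

  i.e. *any* fully active activator clause can switch the target on, and
  *any* fully active inhibitor clause dominates and forces it off. At least
  one activator clause is required: an internal species with no positive
  regulator could never activate and is rejected by `validate_model()`.
* **Boolean expressions**, as ASTs (`bx_and()` etc.) or strings in the
  flat-text dialect (`"X AND NOT Y"`, with precedence `NOT > AND > OR`).
* **truth-table rules** (`truthfn_rule()`): an ordered regulator list plus an
  output column over all $2^k$ regulator assignments, with the *first*
  regulator as the least-significant bit. This form exists because a
  uniformly random Boolean function of $k$ inputs has no compact expression;
  it is simulated directly by table lookup. Conversion to an expression
  (needed for flat-text/SBML export) goes through a disjunctive normal form
  and is supported for $k \le 12$; tabulated rules themselves are capped at
  $k \le 20$.

## Update scheme and stochastic inputs

Updates are **synchronous**: every internal species recomputes its next state
from the complete previous state. This is the standard deterministic scheme
for Boolean networks; it makes the dynamics a function on the finite state
space, so every deterministic trajectory ends in a cycle, and it makes
brute-force verification by state-transition enumeration possible.
Asynchronous schemes are out of scope (see Limitations).

Environments are **semi-quantitative**: each external species has an activity
level $a \in [0, 100]$ (%ON). At every step each external species is set ON
by an independent Bernoulli draw with probability $a/100$, one draw per
external species per step, in model declaration order. The interpretation is
a time-averaged activity: a receptor seeing a sub-saturating ligand dose is
active some fraction of the time, and the long-run %ON of the input equals
the set level exactly in expectation. Levels 0 and 100 degenerate to
deterministic OFF/ON.

Activity of any species is read out as **%ON**, on three estimators:

* **sliding window** (`simulate_model()`): at step $t$, $100 \times$ the mean
  state over the last $\min(t{+}1, w)$ states (window $w$, default 100). The
  leading partial windows average over what exists rather than being dropped,
  so the series is defined from step 0.
* **measurement window** (`steady_pct_on()`): discard `burn_in` steps
  (default 1000), average the next `measure_steps` (default 2000). The
  defaults are deliberately generous for the model sizes used here
  (transients of random $n \le 1000$ networks are typically far shorter);
  there is *no automatic settling detection* — if a model has transients
  longer than `burn_in`, the caller must raise it.
* **attractor fraction** (`find_attractor()`): when every environment level
  is exactly 0 or 100 the dynamics are deterministic, the reached cycle is
  found exactly by hashed state iteration, and %ON is the fraction of cycle
  states in which the species is ON. `steady_pct_on()` automatically uses
  this exact path when the environment is deterministic and the initial state
  is fixed.

Initial states default to all-OFF (an unstimulated system); `"all_on"`,
`"random"` and explicit named vectors are available, and experiments may
randomize them per simulation.

## Mutations

`mutation(species, "ON"/"OFF")` models constitutive activation and knockout
by clamping: the clamp is applied to the initial state and then after every
rule evaluation and external draw, so a mutated species reads exactly 100 or
0 %ON in every mode (trajectory, attractor, experiment), regardless of rules
or environment. This "clamp beats everything, from step 0" convention is what
makes in-silico knockouts interpretable as hard perturbations.

## Experiments and dose-response curves

`run_experiment()` implements randomized-environment analysis: for each of
`n_simulations` runs, every ranged external species receives a level drawn
**uniformly** from its `[lo, hi]` range (uniform because the range is the
only stated knowledge about the input — a maximum-entropy choice), the model
is simulated with that fixed environment, and steady %ON of every species is
recorded. Each simulation gets a seed derived deterministically from the
experiment seed and its index, so results are bit-reproducible and earlier
rows do not change when `n_simulations` grows.

`dose_response()` plots/aggregates one external input against one output:
simulations are binned by input level into `n_bins` equal-width bins and bin
means are reported with bin counts; empty bins yield `NA` means rather than
interpolated values. Binning (rather than smoothing) is used because the
per-simulation noise is known binomial noise and bin means have exact
standard errors, which the test suite uses.

## Numerical and reproducibility choices

* The update loop is compiled (Rcpp). Rules are lowered once per model to
  postfix programs (expressions) or lookup tables (truth-table rules), so
  per-step cost is $O(n \cdot k)$. `precompile()` caches the lowering for
  workloads running thousands of simulations on one model.
* All stochastic draws use R's RNG; a `seed` argument fully determines every
  result, including inside the compiled code.
* Attractor search stores visited states in a hash map keyed by the packed
  state; the iteration cap (default $2^{22}$ steps) bounds memory on
  adversarial inputs.

## Interchange formats

Flat text is one `target = expression` line per internal species; external
species are implied by being referenced and never assigned. SBML export uses
the Level 3 `qual` package with all species Boolean (`maxLevel` 1), one
transition per internal species, and the rule encoded in MathML. Identifiers
are sanitized to valid SBML SIds with the original names preserved as
`qual:name` and restored on import. In the absence of an offline schema,
`check_sbml_qual()` performs structural conformance checking (namespaces,
required attributes, transition shape, MathML well-formedness) rather than
XSD validation; substantive correctness of a round trip is checked as
truth-table equality per rule.

## What the synthetic validation does and does not show

The test suite validates the machinery, not any biological claim: attractors
of $\ge 200$ random models are compared state-by-state against an
independent exhaustive transition-table oracle; the bio-logic compiler is
checked exhaustively against its set-semantics definition; input fidelity and
dose-response recovery are checked against exact binomial standard errors on
motifs whose truth is known analytically (pass-through, inverter, chains);
scaling is checked as a log-log slope in $n \cdot k$. Problem sizes used:
models up to 10 species for exhaustive enumeration, up to 500 species for
scaling, rules up to 12 regulators for exhaustive truth tables. None of this
demonstrates that a particular biological model is *right* — only that the
simulator computes the stated semantics.

## Limitations

* Synchronous updates only; asynchronous/probabilistic update orders can
  change attractor structure and are not modeled.
* Binary states only; no multi-valued logic (`maxLevel > 1` SBML models are
  rejected on import rather than coerced).
* No automatic detection of settling: `burn_in` is the user's contract.
* SBML conformance checking is structural, not schema validation.
* Truth-table rules with more than 12 regulators cannot be exported to
  expression-based formats.

## A worked example

```{r example}
model <- boolean_model(
  "growth_switch",
  rules = list(
    Raf = biologic_rule("Raf", activators = list("GF")),
    ERK = biologic_rule("ERK", activators = list("Raf"),
                        inhibitors = list("Phosphatase")),
    Growth = biologic_rule("Growth", activators = list("ERK"))
  ),
  external = c("GF", "Phosphatase")
)
validate_model(model)

steady_pct_on(model, env_levels(GF = 70, Phosphatase = 0), seed = 1)

res <- run_experiment(model,
                      env_ranges(GF = c(0, 100), Phosphatase = c(0, 0)),
                      n_simulations = 200, seed = 1)
dose_response(res, "GF", "Growth")
```
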