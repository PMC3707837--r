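---
title: "Interpreting SBML models as ODE/DDE systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting SBML models as ODE/DDE systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlode)
```

## The mathematical model behind SBML

A reaction network in SBML defines a stoichiometric matrix $\mathbf{N}$
(species $\times$ reactions) and a vector of reaction velocities
$\vec{\nu}(\vec{Q}, t)$ given by the kinetic laws.  The state vector
$\vec{Q}$ collects the sizes of all compartments, the amounts of all
species, and the values of all global parameters.  Local parameters of
kinetic laws are deliberately *not* part of $\vec{Q}$: they are bound
lexically into their kinetic-law expression when the model is read.

Solving an SBML model means integrating

$$
\dot{\vec{Q}} \;=\; \mathbf{N}\,\vec{\nu}(\vec{Q}, t) \;+\;
\vec{g}(\vec{Q}, t),
$$

where $\vec{g}$ collects the rate rules (zero in every dimension without
one), subject to three discrete-state mechanisms layered on top of the
continuous flow:

* **assignment rules** $r$, which pin a quantity to a function of the
  state at *all* times;
* **algebraic rules**, equations that must evaluate to zero at all
  times and implicitly determine one otherwise-free quantity each;
* **events**, which execute a list of assignments when a boolean
  trigger switches from false to true, possibly after a delay,
  coordinated by priorities.

Any expression may contain `delay(x, tau)`, which evaluates `x` on the
state at time $t - \tau$ and turns the system into a delay differential
equation (DDE).

This vignette documents how the package interprets each construct, the
numerical choices involved, and what the built-in fixture models do and
do not demonstrate.

## One shared syntax graph

All mathematics of a model — kinetic laws, rules, event triggers,
priorities, delays, event assignments, initial assignments, constraints
— is merged into a single hash-consed directed acyclic syntax graph
(`syntax_graph()`).  Structurally identical subexpressions are the
*same* node: the structural key covers the operator kind, the exact bits
of numeric literals, and the ordered child identities.  No algebraic
normalization is applied — `a+b` and `b+a` are distinct nodes — because
syntactic equality is the only sharing relation that can never change a
model's meaning.

Evaluation is cached per *epoch*: whenever the state or time changes,
the epoch counter advances and every node is recomputed at most once,
no matter how many expressions share it.  In a model where two kinetic
laws both reference the same species, that species node (and any shared
product) is evaluated once per state.  `graph_new_epoch(g, count =
TRUE)` exposes per-node counters so cache soundness is testable.

Two operator families bypass the plain bottom-up recursion:

* `piecewise`, `and`, `or`, `xor` evaluate lazily (short-circuit), so
  guarded expressions like `piecewise(1/x, x != 0, 0)` are safe;
* `delay` subtrees are evaluated against the interpolated historical
  state and are therefore recomputed per query rather than cached
  against the current state.

User-defined functions (SBML `functionDefinition`, a restricted lambda
calculus) are expanded at read time by capture-safe simultaneous
substitution of argument expressions into the body.  Because a body may
reference only its own parameters and global identifiers, simultaneous
substitution cannot capture; two functions reusing a parameter name
stay independent.  Recursive definitions are rejected — SBML gives them
no semantics.

## Algebraic rules and overdetermination

Each algebraic rule is converted, once, into an assignment rule.  A
bipartite graph is built between *equations* (reactions with kinetic
laws, assignment and rate rules, algebraic rules) and *determinable
variables* (non-constant compartments, species, parameters, assignable
species references).  A reaction connects to its non-boundary,
non-constant reactant and product species; an assignment or rate rule
to its target; an algebraic rule to every determinable quantity in its
expression.  A greedy matching is extended with shortest augmenting
paths (Hopcroft–Karp) until none remains, which yields a
maximum-cardinality matching.  If any equation vertex stays unmatched
the model is overdetermined and rejected.

Within each adjacency list, variables adjacent to *fewer* equations are
tried first (ties by document order).  This is a deliberate choice: an
algebraic rule is supposed to determine a variable whose value is not
already defined through other equations, and a pure document-order scan
can otherwise match the rule to a species that a reaction already
governs.  The preference is purely an ordering heuristic; it never
changes the matching cardinality or the overdetermination verdict.

The matched rule is then rearranged symbolically.  Rearrangement is
syntactic and limited to expressions *linear* in the target: the
expression is decomposed as $a \cdot x + b$ with $a, b$ free of $x$
(recursing through sums, differences, products, and quotients), and the
assignment $x := -b/a$ is interned into the graph.  Nonlinear
occurrences raise an error — a general symbolic solution is out of
scope, and run-time root bracketing was rejected for its per-step cost.
The original algebraic expressions are retained and their residuals
monitored at every accepted step; `simulate_sbml()` reports the maximum
residual observed.

## Event semantics

Event bookkeeping follows a per-event record of: the previous trigger
value, membership in the active set, an optional trigger-time snapshot,
and an ordered list of pending delayed executions.

At a time point the executable set is the union of (i) events whose
trigger switched false→true now without delay, and (ii) previously
triggered events whose delay has elapsed.  The scheduler then loops:
evaluate the priorities of all candidates *at the current state*, pick
one event of highest priority (uniformly at random among ties), execute
all of its assignments simultaneously (every right-hand side is
evaluated before any write, against the trigger-time snapshot when the
event uses trigger-time values), re-apply the assignment rules, and
re-evaluate all triggers — an execution can change the priorities and
even the trigger conditions of the others.  The loop ends when no
candidate remains; a configurable cap (10,000 executions at one time
point) guards against event cycles.

Choices where SBML or the algorithm leaves room:

* **Events without a priority** form one tie class ranked *below* every
  event with a priority at the current iteration, chosen uniformly at
  random among themselves.  Level 3 leaves their order undefined; this
  rule is deterministic in distribution and simple to reason about.
* **Priorities are never cached** — they are re-evaluated before every
  selection, since executions can change them.  (For the same reason a
  binary max-heap is pointless here: arbitrarily many keys can change
  per extraction.)
* **Trigger initial value**: Level 3 triggers carry it explicitly.  For
  Level 1/2 the value before the start time is taken to be the value
  *at* the start time, so an initially-true trigger never fires at t0.
* **Delay expressions are evaluated at trigger time**, so the same
  event may be pending several times with different delays; the pending
  list is kept sorted by execution time.
* **Cancellation of pending executions**: a delayed, nonpersistent
  event that has already been scheduled is cancelled by its trigger
  falling false only when it does not use trigger-time values.  The
  SBML test semantics here are level-dependent; this rule is the
  package's documented reading.

Event assignments to species are interpreted in the species' own units:
for a species without `hasOnlySubstanceUnits` the assigned value is a
concentration and is converted to an amount with the current
compartment size.  Consequently an event that halves a compartment
leaves species amounts untouched and doubles their concentrations.

## Time-step adaptation and event localization

The adaptive integrator is a fourth-order Rosenbrock method (Shampine's
parameter set; four stages sharing one factorization of
$I/(\gamma h) - J$ with a forward-difference Jacobian) with an embedded
third-order error estimate.  A step is accepted when the scaled error
norm $\sqrt{\tfrac1n \sum (e_i / (atol + rtol\,|Q_i|))^2} \le 1$.

After every accepted step the assignment rules are applied and the
events are processed at the new time.  If that changes the state — or
if any trigger transition occurred — the step is rewound to the
pre-step state and retried with $h := h/10$, until the processing no
longer changes anything or $h$ reaches the minimum step size.  The
precision of event timing is therefore $h_{\min}$ (default
$10^{-10}$ of the simulated span).  Localizing *transitions*, not only
state changes, is deliberate: the execution time of a delayed event and
the contents of a trigger-time snapshot both derive from the trigger
time itself, so a trigger crossing must be pinned down even when the
crossing step executes nothing.

Because rewind restores the event bookkeeping (trigger memory, pending
executions) along with the state vector, the refinement loop cannot
double-schedule an event.  Retries from the identical pre-step state
reuse the cached derivative, Jacobian, and time-derivative of the first
attempt.

Fixed-step solvers (Euler, classical RK4) process rules and events at
their step points without refinement; they are appropriate when exact
event timing is secondary.

Output is produced on an equidistant grid by cubic Hermite
interpolation between accepted steps, with rule-governed quantities
re-evaluated at each interpolated point; the output grid never
influences the accepted-step sequence (halving the number of output
points changes only the sampling).  The default maximum step size,
one twentieth of the simulated span, keeps the interpolation error
well below the integration tolerance for smooth problems.  After an
event-localized step the controller resumes from its own error-based
proposal.

## Delays

`delay(x, tau)` queries a history buffer of `(time, state)` records at
every accepted step, interpolating piecewise-linearly and clamping
queries to the integrated interval; before the start time the initial
state is returned (constant prehistory, the standard DDE convention).
Linear interpolation bounds the history error by $O(h^2)$, so the DDE
fixture caps the step size at $h_{\max} = 0.02$ (well below its delay
$\tau = 0.5$); order-3 Hermite history is a possible extension.  DDE
accuracy is validated against an independent method-of-steps reference,
not bit-exactly — the interpolation order of the history is a genuine
approximation choice.

## Species units and initialization

Species state is stored as **amount** throughout.  Expressions read a
species as amount/size when `hasOnlySubstanceUnits` is false; writes to
such species (rules, event assignments, initial assignments) are
interpreted as concentrations and converted with the current
compartment size.  Amount-based bookkeeping keeps the stoichiometric
update $\mathbf{N}\vec{\nu}$ additive even when a compartment size
changes mid-run; reported columns are converted back to concentrations
for species that were initially specified that way (overridable).

Initialization order: (1) raw initial values from the document; (2)
initial assignments and assignment rules (including converted algebraic
rules) iterated to a fixed point, with species initial concentrations
re-converted as compartment sizes settle; (3) event trigger memory.
The fixed-point pass count is bounded by the construct count, so a
genuine dependency cycle is reported rather than looped on.  Assignment
rules themselves are topologically sorted once by their variable
dependencies; chained rules therefore evaluate correctly regardless of
document order.

Constraints are evaluated at every accepted step; each violation emits
one notification (time, message) to a listener and never stops the
simulation.  Whether constraints should also be checked at interior
refinement points is unspecified; this package checks accepted steps
only and records that choice here.

## Default settings

| Setting | Default | Notes |
|---|---|---|
| solver | Rosenbrock | stiff-safe; Euler/RK4 available |
| absolute tolerance | $10^{-12}$ | error-norm weight floor |
| relative tolerance | $10^{-6}$ | per-step scaled error |
| $h_{\min}$ | $10^{-10} \cdot (t_T - t_0)$ | event-timing precision |
| $h_{\max}$ | $(t_T - t_0)/20$ | dense-output accuracy |
| start time | 0.0 | arbitrary starts accepted |

## The fixture generator

`generate_fixture()` builds small SBML documents — serialized XML, so
the reader is exercised on real markup — covering every supported
construct family: analytic decay (Levels 1 and 3), the two-reaction
reversible mass-action fragment with local rate constants, rate-only
and chained-assignment models, an algebraic conservation relation, a
threshold-crossing event, priority ties, a mutually-cancelling
nonpersistent pair, a delayed event with trigger-time snapshot, a
delayed-decay DDE, time-varying stoichiometry in both the Level 2
(`stoichiometryMath`) and Level 3 (assignable species reference)
dialects, nested function definitions, a violated constraint, a
high-frequency timer pair, and a deliberately overdetermined model.

Each fixture carries an expected-behavior descriptor (closed-form
solution, conserved linear combination, exact firing count, or an
independent reference) and recommended solver settings.  Parameter
values are fixed once: decay rate 0.7 on unit initial conditions spans
a few half-lives on a unit interval; the DDE uses $k\tau = 0.25 <
1/e$ so the delayed decay stays positive and monotone and a relative
comparison is well defined; the threshold fixture tightens the
tolerances to $10^{-10}$ because the trigger-time error is the
trajectory error plus the localization bound; the timer pair arms at
$t = 0.005$ and re-arms every $0.01$ time units over $[0, 10]$, giving
exactly 1,000 firings per event, with $h_{\min} = 10^{-6}$ — four
orders below the firing spacing.  Problem sizes throughout (networks of
up to 6 species and 8 reactions, 200 output points, 2,000 tie-break
trials, complete enumeration of 4+4 bipartite graphs) are chosen so
that every property is exercised at desk scale with independent
oracles.

What the fixtures do **not** show: they are tiny, non-stiff (except the
solver tests' dedicated stiff system), exercise no unit conversion
beyond the amount/concentration distinction, and contain none of the
combinatorial interactions of large curated models.  Passing them
demonstrates the correctness of each mechanism and their composition on
small systems, not performance or robustness on arbitrary real-world
SBML.

## Known limitations

* SBML Level 3 packages (comp, fbc, layout, qual, ...) are not
  interpreted; a model *requiring* one is rejected, otherwise package
  constructs are ignored with a warning.
* Fast/slow subsystem separation (DAE splitting) is not implemented.
* Algebraic rules nonlinear in every matchable variable cannot be
  converted.
* Unit validation beyond the amount/concentration distinction is out of
  scope.
* The delay history is piecewise-linear; extremely tight DDE tolerances
  would need a higher-order history interpolant.
* Multistep/BDF integrators are not bundled; the solver/system
  separation admits wrapping external steppers behind the same
  interface.
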