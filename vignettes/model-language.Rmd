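---
title: "A human-readable language for reaction-network models: semantics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A human-readable language for reaction-network models: semantics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antsembly)
```

## The language

`antsembly` compiles a concise, Antimony-style text notation for biochemical
networks into a validated semantic model, translates that model to and from
SBML Level 3 Version 2, and gives the notation's constructs executable ODE
semantics so that they can be checked numerically.

A model is a sequence of statements, one per line (or separated by `;`):

```{r}
cat(ant_listing(2))
```

The statement forms are:

| Form | Meaning |
|---|---|
| `J1: A + 2 B -> C; k1*A*B^2` | reaction with optional name, stoichiometries and kinetic law |
| `A = 5` | initial assignment, evaluated once at time zero |
| `X := 1 + amp*sin(time*freq)` | assignment rule, enforced continuously |
| `S' = k*S` | rate rule: dS/dt given directly |
| `alg2: 0 = S2*k2 - 20` | algebraic rule (serialization only, see below) |
| `if S1 > 10:` + indented assignments | discrete event |
| `$A` | boundary species: reactions do not change its amount |
| `A.mean = 2.4`, `A.range = {0, 5}` | uncertainty attributes |
| `OBJF: maximize R16 + R03`, `constraint c0: R16 >= 0` | flux-balance objective and bounds |
| `model name() ... end` | named model block, required when metadata is used |

Identifiers first seen in a reaction participant list become species; all
other identifiers become parameters. An uninitialized symbol defaults to 0
with a warning — models remain loadable, and the warning makes the gap
visible. Typeset punctuation (Unicode minus, en dash, curly quotes), which
text copied from formatted documents often carries, is normalised to ASCII
before lexing.

Thirteen reference models (`ant_listing(1)` … `ant_listing(13)`) exercise
every construct and double as the package's fixtures; `ant_write_fixtures()`
writes them as `.ant` files.

## Semantic restrictions

Three structural rules are enforced at build or check time:

* **Boundary marking.** A species that participates in reactions while being
  governed by a rate rule or an assignment rule must be marked `$`. Without
  the marker, the reactions and the rule would both claim the species'
  derivative; the build fails with an error naming the species.
* **`rateOf` placement.** `rateOf(x)` returns the instantaneous derivative of
  a species or a rate-rule target. Applying it to a reaction or to an
  assignment-rule target is rejected (`ant_check_rateof()`): neither has a
  state derivative in the ODE system.
* **Distribution contexts.** Distribution calls (`normal(0.5, 0.2)`, …) are
  draws, not functions of time. They may appear where a value is set once —
  initial assignments and event assignments — and are rejected in kinetic
  laws, assignment/rate/algebraic rules, and event triggers
  (`ant_check_distrib_contexts()`).

## Distributions and uncertainty

Twelve families are supported: normal, uniform, bernoulli, binomial, cauchy,
chisquare, exponential, gamma, laplace, lognormal, poisson, rayleigh. Each
has a fixed base arity; every family except `uniform` and `bernoulli` also
accepts a truncated form with two extra `min, max` arguments, giving 22
signatures in total. Arity checking is exact — `normal(0.5)` is an error.

Three numerical choices deserve note:

* **Truncation is realised by rejection sampling** with a cap of $10^6$
  iterations, rather than inverse-CDF inversion. Rejection is uniform across
  all ten truncatable families (several have no convenient closed-form
  quantile on a truncated support), and the cap turns a degenerate bound pair
  into a clean error instead of a hang.
* **`lognormal(mean, stdev)` parameters act on the log scale** — they are the
  mean and standard deviation of the underlying normal, following the SBML
  Distributions convention.
* **Count-valued families return integer-valued reals** (`3`, not `3L`),
  because every symbol in the language holds a real number.

Draws are taken from an isolated Mersenne-Twister stream (`ant_rng(seed)`)
that never touches the session's `.Random.seed`; equal seeds reproduce equal
draw sequences exactly, which is what makes stochastic initializations
testable.

Uncertainty attributes (`A.mean = x`, `A.confidenceInterval = {x, y}`,
`A.distribution = normal(x, y)`, `A.externalParameter is "http://uri"`) are
stored per symbol and serialized to the SBML Distributions package's
`uncertParameter`/`uncertSpan` vocabulary; `stdev` and `standardDeviation`
alias one slot.

## SBML translation

Export emits Level 3 Version 2 core, plus the Distributions package
(`required="true"`, as its specification dictates — draws change the model's
mathematics) and Flux Balance Constraints version 1 (`required="false"`),
each declared only when used. Import reads exactly the subset export emits
and drops unsupported constructs (function definitions, units, event delays
and priorities) with warning diagnostics; a required package the importer
does not know is a fatal error, and FBC version 2 documents are reported as
unsupported rather than silently misread.

Where the notation is silent, the exporter had to choose; the choices are:

* **Reactions are exported `reversible="true"`.** The `->` arrow carries no
  reversibility information, and mass-action laws with explicit backward
  terms (`k3*B - k4*C`) are idiomatic in this notation, so forcing
  `irreversible` would mislabel them.
* **A single implicit compartment** (`default_compartment`, size 1) owns all
  species, whose values are concentrations numerically equal to amounts.
* **Boundary species** are exported `boundaryCondition="true"` but
  `constant="false"`, since rules and events may still change them.
* **Symbolic stoichiometries** become `speciesReference` elements with ids,
  plus an initial assignment (for `=`-set symbols) or assignment rule (for
  `:=`) targeting the reference — the encoding SBML itself prescribes for
  variable stoichiometry.
* **Metadata** maps to BioModels-style annotation: `model_source` →
  `bqmodel:isDerivedFrom`, `publication` → `bqmodel:isDescribedBy`,
  `biological_system` → `bqbiol:is`, `taxon` → `bqbiol:hasTaxon`, creators →
  vCard entries, timestamps → `dcterms` W3CDTF terms, notes → an XHTML body.
  The notation names the keywords but not their RDF qualifiers, so this
  table is a documented convention of this package, not something the
  notation fixes.

The emitted document is a deterministic function of the model, so the chain
text → SBML → text → SBML reaches a byte-identical fixed point on the second
export — the property the test suite asserts for all thirteen reference
models. Canonical unparsing (`ant_unparse()`) likewise reaches a textual
fixed point after one application.

## Execution semantics

`ant_compile()` turns a model into an ODE system: state variables are the
non-boundary species that take part in reactions plus every rate-rule
target; assignment rules are topologically sorted (cycles are an error) and
re-evaluated before any rate, so forcing functions hold *exactly* at every
output point rather than being integrated. For a reaction species,

$$\frac{dS}{dt} \;=\; \sum_{\text{products}} \nu\, v \;-\; \sum_{\text{reactants}} \nu\, v,$$

with stoichiometries $\nu$ re-read on every right-hand-side call when they
are symbolic — an assignment-ruled stoichiometry therefore acts
instantaneously, one concrete choice among the behaviours simulators exhibit
for this admittedly delicate feature.

Numerical choices:

* **Integrator**: `deSolve::lsoda` (adaptive, stiff-capable), relative
  tolerance $10^{-8}$, absolute $10^{-12}$ — tight enough that the analytic
  checks below are meaningful at $10^{-6}$ relative error.
* **Events** are edge-triggered: the trigger must go false → true. An event
  whose trigger is already true at $t = 0$ does not fire until the trigger
  falls and rises again, and a fired event re-arms only after its trigger
  returns to false (standard persistent-trigger semantics). Crossings are
  located by bisection on the trigger's truth value to a tolerance of
  $10^{-9}\, t_{\text{end}}$, and all of an event's assignments are applied
  atomically, evaluated against the pre-event state. Triggers are inspected
  between output points; a trigger that rises and falls entirely inside one
  output interval can be missed, so event studies should use grids fine
  relative to their dynamics.
* **Distribution draws in initial assignments** are sampled once, before
  integration — not per output point; event assignments draw again each time
  they fire, from the same seeded stream, so a seed fixes the entire
  trajectory and event log.

Algebraic rules (`0 = f(...)`) are carried through parsing, validation and
SBML serialization but refused by the simulator: solving them would require
a DAE engine and a rule for choosing which variable each equation
determines, and the notation deliberately leaves that to downstream tools
that support it. `ant_compile()` fails with an explicit error instead of
guessing.

## What the reference models do and do not show

The thirteen bundled models are the package's test corpus. They cover every
construct but are desk-scale: a handful of species, smooth mass-action
kinetics, at most one event. Passing them shows the language semantics are
implemented as specified — the closed-form decay $A(t) = 5e^{-0.1t}$ matched
to $10^{-6}$ relative error over 101 points, mass conservation to $10^{-8}$,
rateOf agreeing with central differences on a 401-point grid — not that the
integrator is tuned for stiff genome-scale kinetics, large event cascades,
or the pathological bound sets an LP solver would face. Three models are
lightly concretised so every fixture is buildable: the event example indents
its event body (indentation is what delimits bodies), the uncertainty
example fills its placeholder formula/URI slots with a concrete call and
URI, and the flux-balance example declares the three reactions its
constraints reference, kinetic-law-free as is usual for constraint-based
models. Where uninitialized rate constants would make an event unreachable,
tests drive them with explicit values and say so.

## Limitations

* No DAE solving (algebraic rules), no stochastic (Gillespie) kinetics, no
  steady-state solver, and no LP solver behind the flux-balance records —
  `ant_bounds_table()` and FBC serialization are the deliverables.
* No hierarchical model composition, unit definitions, user-defined
  functions, or layout/render information; unsupported SBML constructs are
  dropped with warnings on import.
* Events fire only on rising edges detected at or between output points;
  `at`-style timed events, delays and priorities are not part of the
  notation.
* FBC import/export is version 1 only; later-version documents are flagged,
  not translated.
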