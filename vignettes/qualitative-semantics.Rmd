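---
title: "Qualitative dynamics of SBGN-PD maps: the general and stories semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative dynamics of SBGN-PD maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgnq)
```

## The modeling problem

An SBGN Process Description (SBGN-PD) map is a mechanistic picture of a
reaction network: *entity pool nodes* (EPNs) stand for pools of molecular
entities, *process nodes* consume and produce them through flux arcs, and
*modulation arcs* (stimulation, catalysis, inhibition, necessary
stimulation, or generic modulation) describe how pools influence processes,
possibly combined through AND/OR logical operators. Such a map is static.
`sbgnq` turns it into an executable qualitative model — no kinetic
parameters — so that the knowledge in the map can be confronted with known
behavior: which species can be produced, which configurations are stable,
whether two markers can ever co-occur.

Two semantics are implemented, both expressed as **asynchronous automata
networks** (ANs). An AN is a triple (&Sigma;, S, T): named finite automata,
their local states, and local transitions guarded by local states of other
automata; exactly one transition fires at a time, giving a
(non-deterministic) state transition graph (STG) from a chosen initial
state.

## The general semantics

Every (non-source/sink) EPN becomes a Boolean automaton (absent `0` /
present `1`) and every process an automaton (non-occurring `0` / occurring
`1`). The transition rules are:

* a process starts occurring when all its non-source reactants are present
  and its modulations permit it;
* a process stops occurring when all its non-sink products are present;
* an EPN becomes present when an occurring process produces it;
* an EPN may become absent when an occurring process consumes it and all of
  that process's products are already present.

Consumption is therefore *optional*: asynchrony decides whether the
consumption transition fires before the process de-activates, which encodes
the absence of any a-priori knowledge about reaction completeness. This is
the source of the branching one sees in the worked example below.

### The permissive modulation rule

Each modulation origin `n` gets a Boolean satisfaction formula `logic(n)`
(EPN &rarr; presence literal; AND/OR nodes &rarr; connectives). The NOT
operator has no meaning for dynamics, so any arc whose origin formula
traverses a NOT is dropped with a warning, as are generic `modulation` arcs
(unknown effect). A process `p` with necessary stimulations `R`,
stimulations/catalyses `A` and inhibitions `I` may activate when

```
mod(p) =  AND_{n in R} logic(n)                      if A = I = {}
          AND_{n in R} logic(n)
            AND ( OR_{n in A} logic(n) OR OR_{n in I} !logic(n) )  otherwise
```

with the conventions empty-AND = TRUE and empty-OR = FALSE. The rule is
deliberately permissive — a process with one stimulator and one inhibitor
may occur unless the inhibitor is present alone — so the dynamics
over-approximates every more restrictive logical refinement: absence of a
behavior here implies its absence under the true (unknown) logic.

`mod(p)` is put in disjunctive normal form (negation normal form, then
distribution, with contradiction and subsumption pruning — exact, no
minimisation heuristics, which is fine at the per-process scale) and
expanded into `cond(p)`, the sets of automata local states that enable the
activation.

## The stories semantics

A protein and its phosphorylated form are two EPNs but one molecular
entity. A **story** is a set of EPNs representing the mutually exclusive
physical states of one entity. For a candidate set the package checks:

* (i) members are pairwise connected by flux-arc paths that stay inside the
  story,
* (ii) a process producing a story member either has no (non-source)
  reactant or consumes a story member,
* (iii)/(iv) no process consumes, or produces, two story members,
* optional (v) members share an SBGN-PD label (for complexes, any member
  label counts).

Each story becomes a single automaton with one local state per member plus
an **empty** state (entity absent), so mutual exclusion holds *by
construction*. Story moves replace production-then-consumption by a single
transition, pruning the interleavings the general semantics allows; the
stories dynamics is a sub-dynamics of the general one (the package tests
the quiescent-state reachability transfer and the fixed-point projection on
the worked example exhaustively).

Story sets must be pairwise disjoint (*valid*). Among valid sets the
package computes all *maximally valid* sets (inclusion-maximal independent
sets of the story-intersection graph), *final* sets (not story-wise
dominated by another valid set) and *epn-maximal* sets (maximizing the
total number of EPNs). Any epn-maximal set is final, and any final set is
maximally valid, which the test suite checks on all fixtures.

### Design choices where the definitions leave room

* **Absence of a story EPN.** Expanding the negative literal `!e` for a
  story member can be read two ways: the set of *other member* states, or
  additionally the empty state. We include the empty state — an entity that
  is entirely absent certainly makes `e` absent — and expose
  `strict = TRUE` on `conditions_of()` for the narrower reading.
* **Sources and sinks in stories.** Source and sink glyphs are excluded
  from stories altogether (they are not pools); they are represented as
  per-process flags, never as EPNs.
* **Singleton stories** are excluded by default (`min_size = 2`): the
  automaton of a singleton story is dynamics-equivalent to the EPN's
  Boolean automaton.
* **Enumeration strategy.** Story search is exact combinatorial
  enumeration restricted to flux-connected components (a declarative/ASP
  solver would do the same job; at desk scale no solver dependency is
  warranted). Components are capped at 18 EPNs; larger maps should be
  explored with seeds and size bounds. Maximal valid sets come from a
  Bron–Kerbosch enumeration of independent sets, cross-checked against
  igraph in the tests; epn-maximal sets are obtained by weighting that
  enumeration, which is exhaustive, so ties are enumerated exactly.
* **A story holding a reactant and the sole stimulator of one process**
  would freeze the process (its stimulator can never be present while its
  reactant is); this is detected and warned about, not forbidden.

## The encoding

With a valid story set (possibly empty — the general semantics is the
special case of an empty set) the encoder emits, for each process `p` and
each enabling condition `l` in `cond(p)`:

* activation `p: 0 -> 1` guarded by `l` plus `ready(p)` — the present
  states of non-story reactants, the story states of story reactants, the
  empty story state for stories produced by a reactant-less process, and
  `q = 0` for every process `q` in conflict with `p` (two processes
  conflict when they act on a common story; this keeps their occurrences
  exclusive);
* production `f: 0 -> 1` on `p = 1` for non-story products;
* consumption `e: 1 -> 0` on `p = 1` plus `done(p)` — the present/story
  states of the products, and the empty state of stories consumed but not
  produced;
* story moves `s_e -> s_f` (or to/from the empty state) on `p = 1`;
* de-activation `p: 1 -> 0` on `done(p)`.

Three *shortcut* cases skip the process automaton when it cannot be needed
(no conflict, and: no consumption; single consumption with no production;
or a single in/out pair within one story); the conditions are then embedded
directly in the EPN/story transitions. `shortcuts = FALSE` forces process
automata everywhere — the rule-based oracle comparison needs it, because
shortcuts change the dimension of the state space. For a reactant-less
process with several products the shortcut emits one independent transition
per product, exactly as specified by the rules above, even though the
products are then unsynchronized; this is a documented property of the
encoding, not repaired silently.

Conditions that would require two local states of one automaton are
unsatisfiable and dropped at encoding time; a condition referencing the
transition's own origin state is redundant and removed, and one referencing
another state of the same automaton removes the transition. Story automata
are named after their sorted member ids (`story(a+aP+c)`) unless the caller
names them; all sets are iterated in lexicographic order so identical
inputs give identical encodings.

## Analysis

`build_stg()` explores the reachable states breadth-first and keeps the
graph explicit; `attractors()` extracts terminal strongly connected
components with igraph (linear in the graph size) and classifies them as
point or cyclic; `is_reachable()` answers partial-state queries on the fly
without retaining the graph. Phases are named marker sets: a phase is
reached when any marker is present (`e = 1`, or the story automaton sitting
in the marker's state), and `disable_markers()` removes every transition
through a marker's present state. For a story member this also blocks
story traversal *through* that state — a stronger cut than in the Boolean
case, which is inherent to collapsing the states into one automaton.

Numerical choices: the exploration cap defaults to 1,000,000 states and
fails loudly (with the frontier size) rather than truncating — genuinely
large maps should be analyzed through the PNML export with an external
unfolding-based checker, which is out of scope here. A seeded random
exploration order is available; the order-independence of the resulting
graph is a property test. The PNML export writes one place per local
state, one net transition per local transition, and — since the
place/transition dialect has no read arcs — each condition as a self-loop
arc pair, flagged in a `toolspecific` element. The reachable markings then
biject with the AN's reachable states, which the tests verify with an
independent marking-graph builder on the fixtures.

## What the random-map generator emulates

`random_map()` drives the property suites: it draws processes with 0–2
reactants and products over a small EPN universe, source/sink flags,
modulation arcs of all five classes (including generic ones, which the
semantics must ignore), and optional two-input AND/OR origins, under a
fixed seed and without touching the caller's RNG. The suites run the
encoder (shortcuts off) against an independent rule-based interpreter of
the general semantics on every reachable state of 1000 such maps with at
most 6 EPNs and 3 processes — small enough for exhaustive graphs, large
enough to hit every encoding rule. What these maps do *not* emulate:
compartments, complexes with member labels, deep operator trees, and the
scale of curated pathway maps (hundreds of nodes); agreement on random
small maps therefore validates the encoding rules, not the package's
behavior on inputs beyond the exploration cap.

Problem sizes used throughout the shipped analyses (chosen as comfortable
desk scale): the worked example (7 EPNs, 2 processes; 88 reachable states
under the general semantics and 11 under the stories semantics, recomputed
by `scripts/acceptance.R`), the two Discussion toys for the story
machinery, a 14-EPN receptor/arrestin skeleton for story-set regression,
and the random-map suites above.

## Known limitations

* Reversible processes are not detected; rewrite them as two processes.
* SBGN-AF/ER, CellDesigner files, stoichiometry, SBML-qual export and
  synchronous/general update schemes are out of scope.
* Perturbing agents are treated as ordinary EPNs that modulate but are
  never produced or consumed by the fixtures; the SBGN standard is silent
  on their dynamics.
* The formal proofs of the semantics-relation properties are not
  reproduced; they are checked empirically (exhaustively) on the worked
  example.
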