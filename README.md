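# sbgnq — qualitative dynamics for SBGN Process Description maps

SBGN-PD is the standard graphical notation for reaction networks: entity
pool nodes (EPNs) for pools of molecular entities, process nodes consuming
and producing them through flux arcs, and modulation arcs (stimulation,
catalysis, inhibition, necessary stimulation) describing influences,
possibly combined through AND/OR operators. A map drawn this way is
static. `sbgnq` makes it executable — without kinetic parameters — so that
curators and modelers can ask dynamical questions of the knowledge the map
encodes: which species are producible, which configurations are stable,
whether two markers can ever be present together.

The package compiles a map into an **asynchronous automata network**
(Σ, S, T): named finite automata with local states and condition-guarded
local transitions, one of which fires at a time. Two semantics are
provided.

* **General semantics** — every EPN is a Boolean absent/present automaton,
  every process a non-occurring/occurring automaton. A process `p` may
  activate when all its (non-source) reactants are present and its
  permissive modulation formula holds:

  `mod(p) = ⋀_{n∈req(p)} logic(n) ∧ ( ⋁_{n∈act(p)} logic(n) ∨ ⋁_{n∈inh(p)} ¬logic(n) )`

  (the second conjunct only when stimulations or inhibitions exist; empty
  conjunction = TRUE, empty disjunction = FALSE). Consumption of reactants
  is optional, so the dynamics over-approximates every stricter logic.

* **Stories semantics** — a *story* is a set of EPNs representing the
  mutually exclusive physical states of one molecular entity (free,
  phosphorylated, complexed, ...), subject to four structural constraints
  (flux-connectivity inside the story; producers must consume from the
  story; no process consumes or produces two members). Each story becomes
  a single multi-valued automaton with an extra *empty* state, so mutual
  exclusion holds by construction and the state space shrinks. The package
  enumerates stories, their maximally valid / final / epn-maximal
  combinations, and the process conflict relation `p # q` that keeps
  processes acting on a shared story mutually exclusive.

Maps are read from SBGN-ML (0.2/0.3) or a plain-text fixture format;
models are analyzed (state transition graph, attractors as terminal SCCs,
on-the-fly reachability, phase markers, marker disabling) or exported to
1-bounded Petri nets (PNML) and JSON for external model checkers.

## Worked example

The running example is a two-process map: a phosphorylation
`a + atp -> aP + adp` stimulated by `m`, and an association `a + b -> c`.

```r
library(sbgnq)
map <- fixture("worked_example")
map
#> SBGN-PD map: 7 EPNs, 2 processes, 1 modulation arcs, 0 logical operators

an <- encode(map)                                   # general semantics
an
#> Automata network: 9 automata, 11 local transitions
init <- initial_global_state(an, map, worked_example_initial())
stg <- build_stg(an, init)
stg
#> State transition graph: 88 states, 192 transitions
length(attractors(stg))
#> [1] 9
```

All nine attractors are fixed points; five of them have both `aP` and `c`
present — the two processes can both complete because each may leave the
shared reactant `a` unconsumed for the other.

Under the stories semantics, with the story `s = {a, aP, c}` (the three
states of entity `a`) and `t = {adp, atp}`:

```r
st <- worked_example_stories()
an_s <- encode(map, st)
an_s
#> Automata network: 6 automata, 8 local transitions
stg_s <- build_stg(an_s, initial_global_state(an_s, map,
                                              worked_example_initial(), st))
stg_s
#> State transition graph: 11 states, 11 transitions
head(an_transitions(an_s), 4)
#>   automaton from to              cond          tag process
#> 1         b    1  0           q=1,s=c  consumption       q
#> 2         p    0  1 m=1,q=0,s=a,t=atp   activation       p
#> 3         p    1  0        s=aP,t=adp deactivation       p
#> 4         q    0  1       b=1,p=0,s=a   activation       q
```

The 88-state dynamics collapses to 11 states with three point attractors:
two where `a` ends bound in the complex (`s = c`, with `b` either consumed
or not) and one where it ends phosphorylated (`s = aP`). `aP` and `c` can
no longer co-occur — they are two states of one entity. The conditions
`q=0` / `p=0` in the activations are the conflict relation at work.

Story discovery is automatic:

```r
sts <- enumerate_stories(fixture("toy_chain_assoc"))   # A -> B, B + C -> D
maximal_valid_sets(sts)       # {{A,B},{C,D}} and {{A,B,D}}
epn_maximal_sets(sts)         # {{A,B},{C,D}} — 4 EPNs beats 3
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/sbgnq stg mymap.sbgn --init a,atp,b,m
Rscript inst/scripts/sbgnq stories mymap.sbgn --epn-maximal --json sets.json
Rscript inst/scripts/sbgnq reach mymap.sbgn --init a,atp,b,m --goal aP=1 --goal c=1
```

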