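# Asynchronous execution of automata networks: successors, state transition
# graphs, attractors, reachability and phase queries, plus an independent
# rule-based interpreter of the general semantics used as a test oracle.

# integer compilation of a network for fast successor computation
an_compile <- function(an) {
  auts <- names(an$automata)
  sidx <- lapply(an$automata, function(s)
    stats::setNames(seq_along(s), s))
  nT <- length(an$transitions)
  ta <- integer(nT); tfrom <- integer(nT); tto <- integer(nT)
  tcond_a <- vector("list", nT); tcond_s <- vector("list", nT)
  for (k in seq_len(nT)) {
    tr <- an$transitions[[k]]
    a <- match(tr$automaton, auts)
    ta[k] <- a
    tfrom[k] <- sidx[[a]][[tr$from]]
    tto[k] <- sidx[[a]][[tr$to]]
    ca <- match(names(tr$cond), auts)
    tcond_a[[k]] <- ca
    tcond_s[[k]] <- vapply(seq_along(ca), function(j)
      unname(sidx[[ca[j]]][[tr$cond[[j]]]]), integer(1))
  }
  list(an = an, auts = auts, sidx = sidx, nA = length(auts), nT = nT,
       ta = ta, tfrom = tfrom, tto = tto,
       tcond_a = tcond_a, tcond_s = tcond_s)
}

state_to_int <- function(cmp, state) {
  missing <- setdiff(cmp$auts, names(state))
  if (length(missing))
    stop("shape error: state is missing automata ",
         paste(missing, collapse = ", "))
  vapply(seq_along(cmp$auts), function(i) {
    a <- cmp$auts[i]
    s <- cmp$sidx[[i]][state[[a]]]
    if (is.na(s))
      stop("shape error: unknown local state ", state[[a]],
           " of automaton ", a)
    unname(s)
  }, integer(1))
}

int_to_state <- function(cmp, s) {
  out <- vapply(seq_along(cmp$auts), function(i)
    cmp$an$automata[[i]][s[i]], character(1))
  stats::setNames(out, cmp$auts)
}

fireable <- function(cmp, s) {
  which(vapply(seq_len(cmp$nT), function(k) {
    if (s[cmp$ta[k]] != cmp$tfrom[k]) return(FALSE)
    ca <- cmp$tcond_a[[k]]
    length(ca) == 0L || all(s[ca] == cmp$tcond_s[[k]])
  }, logical(1)))
}

#' Asynchronous successors of a global state
#'
#' A local transition is fireable in a global state when its origin local
#' state is active and every local state of its condition is active; firing
#' it replaces the origin with the destination, one transition at a time.
#'
#' @param an an [automata_network()].
#' @param state global state: named character vector, one active local
#'   state per automaton.
#' @return list of successors, each `list(state =, transition =)` with the
#'   firing transition's index in `an$transitions`.
#' @export
successors <- function(an, state) {
  cmp <- an_compile(an)
  s <- state_to_int(cmp, state)
  lapply(fireable(cmp, s), function(k) {
    s2 <- s
    s2[cmp$ta[k]] <- cmp$tto[k]
    list(state = int_to_state(cmp, s2), transition = k)
  })
}

state_key_int <- function(s) paste(s, collapse = ",")

#' Build the state transition graph
#'
#' Breadth-first exploration of all global states reachable from the
#' initial state. Exploration stops with a bounded-exploration error when
#' the state count would exceed `cap` (the default is deliberately loud:
#' larger models should be handed to external checkers through the PNML
#' export rather than silently truncated).
#'
#' @param an an [automata_network()].
#' @param initial global state (named character vector).
#' @param cap maximum number of states to explore.
#' @param order_seed optional integer; when given, states and transitions
#'   are explored in a seeded random order (the resulting graph must not
#'   depend on it — used by the order-independence property test).
#' @return an object of class `stg`: states (list of named character
#'   vectors), `edges` data frame (`from`, `to` state indices and the
#'   firing `transition`), and `initial` (index 1).
#' @export
build_stg <- function(an, initial, cap = 1e6, order_seed = NULL) {
  cmp <- an_compile(an)
  s0 <- state_to_int(cmp, initial)
  torder <- seq_len(cmp$nT)
  if (!is.null(order_seed))
    torder <- with_seed(order_seed, sample(torder))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  states <- list(s0)
  assign(state_key_int(s0), 1L, envir = seen)
  frontier <- 1L
  ef <- integer(); et <- integer(); etr <- integer()
  while (length(frontier)) {
    if (!is.null(order_seed) && length(frontier) > 1L)
      frontier <- with_seed(order_seed + length(states), sample(frontier))
    nxt <- integer()
    for (i in frontier) {
      s <- states[[i]]
      fk <- fireable(cmp, s)
      fk <- fk[order(match(fk, torder))]
      for (k in fk) {
        s2 <- s
        s2[cmp$ta[k]] <- cmp$tto[k]
        key <- state_key_int(s2)
        j <- seen[[key]]
        if (is.null(j)) {
          if (length(states) >= cap)
            stop("bounded-exploration error: state cap ", cap,
                 " exceeded (frontier size ", length(frontier), ")")
          states[[length(states) + 1L]] <- s2
          j <- length(states)
          assign(key, j, envir = seen)
          nxt <- c(nxt, j)
        }
        ef <- c(ef, i); et <- c(et, j); etr <- c(etr, k)
      }
    }
    frontier <- nxt
  }
  structure(list(an = an, cmp = cmp,
                 states = lapply(states, int_to_state, cmp = cmp),
                 states_int = states,
                 edges = data.frame(from = ef, to = et, transition = etr),
                 initial = 1L),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State transition graph: ", length(x$states), " states, ",
      nrow(x$edges), " transitions\n", sep = "")
  invisible(x)
}

#' Number of states of a transition graph
#' @param stg an `stg` object.
#' @export
n_states <- function(stg) length(stg$states)

stg_state_keys <- function(stg)
  vapply(stg$states, function(s) paste(names(s), s, sep = "=", collapse = ","),
         character(1))

#' Attractors of a state transition graph
#'
#' An attractor is a minimal set of states closed under successors: a
#' terminal strongly connected component of the graph. Single-state
#' attractors are point attractors (fixed points), the others cyclic.
#'
#' @param stg an `stg` from [build_stg()].
#' @return list of attractors, each `list(states =, kind =)` where `states`
#'   holds the member global states and `kind` is `"point"` or `"cyclic"`;
#'   deterministically ordered by their smallest state key.
#' @export
attractors <- function(stg) {
  n <- length(stg$states)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (nrow(stg$edges))
    g <- igraph::add_edges(g, rbind(stg$edges$from, stg$edges$to))
  memb <- igraph::components(g, mode = "strong")$membership
  leaving <- unique(memb[stg$edges$from][memb[stg$edges$from] !=
                                           memb[stg$edges$to]])
  terminal <- setdiff(unique(memb), leaving)
  keys <- stg_state_keys(stg)
  atts <- lapply(terminal, function(cc) {
    idx <- which(memb == cc)
    list(states = stg$states[idx],
         kind = if (length(idx) == 1L) "point" else "cyclic")
  })
  minkey <- vapply(terminal, function(cc) min(keys[memb == cc]), character(1))
  atts[order(minkey)]
}

#' Reachability of a partial state
#'
#' On-the-fly breadth-first search: is some state reachable from `initial`
#' in which every local state of `goal` is active? The full graph is not
#' retained.
#'
#' @param an an [automata_network()].
#' @param initial global state.
#' @param goal named character vector of local states (a partial state,
#'   interpreted conjunctively).
#' @param cap bounded-exploration cap.
#' @return logical scalar.
#' @export
is_reachable <- function(an, initial, goal, cap = 1e6) {
  cmp <- an_compile(an)
  goal <- canonical_cond(goal)
  ga <- match(names(goal), cmp$auts)
  if (anyNA(ga))
    stop("goal references unknown automaton ",
         paste(names(goal)[is.na(ga)], collapse = ", "))
  gs <- vapply(seq_along(ga), function(j) {
    v <- cmp$sidx[[ga[j]]][goal[[j]]]
    if (is.na(v)) stop("goal references unknown local state ",
                       names(goal)[j], "=", goal[[j]])
    unname(v)
  }, integer(1))
  s0 <- state_to_int(cmp, initial)
  hit <- function(s) length(ga) == 0L || all(s[ga] == gs)
  if (hit(s0)) return(TRUE)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(state_key_int(s0), TRUE, envir = seen)
  frontier <- list(s0)
  count <- 1L
  while (length(frontier)) {
    nxt <- list()
    for (s in frontier) {
      for (k in fireable(cmp, s)) {
        s2 <- s
        s2[cmp$ta[k]] <- cmp$tto[k]
        key <- state_key_int(s2)
        if (is.null(seen[[key]])) {
          if (hit(s2)) return(TRUE)
          count <- count + 1L
          if (count > cap)
            stop("bounded-exploration error: state cap ", cap,
                 " exceeded (frontier size ", length(frontier), ")")
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    frontier <- nxt
  }
  FALSE
}

# -- Phases -------------------------------------------------------------------

#' Define a phase by its marker EPNs
#'
#' A phase (e.g. a cell-cycle phase) is a named set of marker EPNs; the
#' system is in the phase whenever any marker is present.
#'
#' @param name phase name.
#' @param markers character vector of EPN ids.
#' @export
phase <- function(name, markers)
  structure(list(name = name, markers = sort(unique(as.character(markers)))),
            class = "sbgnq_phase")

# local state meaning "marker e is present" under a story set
marker_ref <- function(e, stories) {
  stories <- as_story_set(stories)
  sid <- story_of(stories, e)
  if (is.na(sid)) stats::setNames("1", e) else stats::setNames(e, sid)
}

#' Phase reachability
#'
#' A phase is reachable from a state when some reachable state has at least
#' one of its markers present; a marker of a story is present when its
#' story automaton sits in the marker's state. A phase with no markers is
#' unreachable (empty disjunction).
#'
#' @param an an [automata_network()].
#' @param initial global state.
#' @param phase a [phase()].
#' @param stories the [story_set()] of the encoding (or `NULL`).
#' @param cap bounded-exploration cap.
#' @return logical scalar.
#' @export
phase_reachable <- function(an, initial, phase, stories = NULL, cap = 1e6) {
  for (e in phase$markers)
    if (is_reachable(an, initial, marker_ref(e, stories), cap)) return(TRUE)
  FALSE
}

#' @param phase_p,phase_q two [phase()]s for the simultaneous query.
#' @rdname phase_reachable
#' @export
phases_simultaneously_reachable <- function(an, initial, phase_p, phase_q,
                                            stories = NULL, cap = 1e6) {
  for (e in phase_p$markers) for (f in phase_q$markers) {
    r1 <- marker_ref(e, stories); r2 <- marker_ref(f, stories)
    if (names(r1) == names(r2)) {
      if (r1[[1]] != r2[[1]]) next   # two states of one story automaton
      goal <- r1
    } else goal <- c(r1, r2)
    if (is_reachable(an, initial, goal, cap)) return(TRUE)
  }
  FALSE
}

#' Disable phase markers
#'
#' Removes every local transition entering or leaving the present local
#' state of each marker (the marker's `1` state, or its story state).
#' Conditions referencing the state are left in place: they can simply
#' never fire once the state is unreachable.
#'
#' @param an an [automata_network()].
#' @param markers character vector of EPN ids.
#' @param stories the [story_set()] of the encoding (or `NULL`).
#' @return a new [automata_network()].
#' @export
disable_markers <- function(an, markers, stories = NULL) {
  refs <- lapply(markers, marker_ref, stories = stories)
  keep <- vapply(an$transitions, function(tr) {
    for (r in refs)
      if (tr$automaton == names(r) && (tr$from == r[[1]] || tr$to == r[[1]]))
        return(FALSE)
    TRUE
  }, logical(1))
  automata_network(an$automata, an$transitions[keep])
}

# -- Rule-based oracle for the general semantics ------------------------------

# Direct evaluation of an origin's satisfaction; NA when the subtree holds a
# NOT operator (the arc is then ignored).  Kept deliberately independent of
# the formula/DNF/cond machinery used by the encoding.
oracle_origin_sat <- function(map, node, pres) {
  if (node %in% names(map$epns)) return(isTRUE(unname(pres[node])))
  op <- map$operators[[node]]
  if (is.null(op)) stop("unknown modulation origin ", node)
  if (op$kind == "NOT") return(NA)
  vals <- vapply(op$inputs, oracle_origin_sat, logical(1),
                 map = map, pres = pres)
  if (anyNA(vals)) return(NA)
  if (op$kind == "AND") all(vals) else any(vals)
}

oracle_mod_ok <- function(map, p, pres) {
  sat <- function(origins) {
    v <- vapply(origins, oracle_origin_sat, logical(1),
                map = map, pres = pres)
    v[!is.na(v)]   # NOT-tainted arcs are ignored
  }
  req <- sat(map_req(map, p))
  act <- sat(map_act(map, p))
  inh <- sat(map_inh(map, p))
  if (!all(req)) return(FALSE)
  if (length(act) == 0L && length(inh) == 0L) return(TRUE)
  any(act) || any(!inh)
}

#' Rule-based successor oracle for the general semantics
#'
#' Interprets the map directly, independently of the automata-network
#' encoding, by the four transition rules of the general semantics:
#' * a non-occurring process may start occurring when all its (non-source)
#'   reactants are present and its modulations permit it (all necessary
#'   stimulations satisfied; some stimulation satisfied or some inhibition
#'   unsatisfied, when any exist);
#' * an occurring process may stop occurring when all its (non-sink)
#'   products are present;
#' * an absent EPN may become present when some occurring process produces
#'   it;
#' * a present EPN may become absent when some occurring process consumes
#'   it and all of that process's products are present.
#'
#' One change per successor (asynchrony). Used as the independent oracle
#' against which the encoded network's successor relation is tested.
#'
#' @param map a [pd_map()].
#' @param state `list(epns =, processes =)`: named logical vectors over all
#'   EPN and process ids (present/occurring).
#' @return list of successor states in the same shape, deduplicated.
#' @export
oracle_successors <- function(map, state) {
  pres <- state$epns; occ <- state$processes
  stopifnot(setequal(names(pres), epn_ids(map)),
            setequal(names(occ), process_ids(map)))
  out <- list()
  push <- function(s) out[[length(out) + 1L]] <<- s
  for (p in process_ids(map)) {
    if (!occ[[p]]) {
      if (all(pres[map_in(map, p)]) && oracle_mod_ok(map, p, pres)) {
        s2 <- state; s2$processes[[p]] <- TRUE; push(s2)
      }
    } else {
      if (all(pres[map_out(map, p)])) {
        s2 <- state; s2$processes[[p]] <- FALSE; push(s2)
      }
    }
  }
  for (e in epn_ids(map)) {
    if (!pres[[e]]) {
      makers <- Filter(function(p) occ[[p]] && e %in% map_out(map, p),
                       process_ids(map))
      if (length(makers)) { s2 <- state; s2$epns[[e]] <- TRUE; push(s2) }
    } else {
      eaters <- Filter(function(p)
        occ[[p]] && e %in% map_in(map, p) && all(pres[map_out(map, p)]),
        process_ids(map))
      if (length(eaters)) { s2 <- state; s2$epns[[e]] <- FALSE; push(s2) }
    }
  }
  keys <- vapply(out, function(s)
    paste(c(as.integer(s$epns[sort(names(s$epns))]),
            as.integer(s$processes[sort(names(s$processes))])),
          collapse = ","), character(1))
  out[!duplicated(keys)]
}

#' Edge list of a transition graph as TSV-ready data frame / DOT source
#'
#' @param stg an `stg` object.
#' @return `stg_edges`: data frame with readable `from`/`to` state keys and
#'   the fired transition; `stg_to_dot`: DOT source marking the initial
#'   state.
#' @export
stg_edges <- function(stg) {
  keys <- stg_state_keys(stg)
  data.frame(from = keys[stg$edges$from], to = keys[stg$edges$to],
             transition = vapply(stg$edges$transition, function(k)
               transition_key(stg$an$transitions[[k]]), character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname stg_edges
#' @export
stg_to_dot <- function(stg) {
  keys <- stg_state_keys(stg)
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph stg {",
             sprintf('  "%s" [style=filled];', esc(keys[stg$initial])))
  for (i in seq_len(nrow(stg$edges)))
    lines <- c(lines, sprintf('  "%s" -> "%s";',
                              esc(keys[stg$edges$from[i]]),
                              esc(keys[stg$edges$to[i]])))
  paste(c(lines, "}"), collapse = "\n")
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
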