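# Boolean satisfaction formulas of modulation origins, the permissive
# process-modulation formula, its disjunctive normal form, and the expansion
# into sets of automata local states.

f_lit <- function(id) structure(list(op = "lit", id = id), class = "sbgnq_formula")
f_not <- function(x) structure(list(op = "not", arg = x), class = "sbgnq_formula")
f_and <- function(xs) structure(list(op = "and", args = xs), class = "sbgnq_formula")
f_or  <- function(xs) structure(list(op = "or", args = xs), class = "sbgnq_formula")
f_true  <- function() structure(list(op = "true"), class = "sbgnq_formula")
f_false <- function() structure(list(op = "false"), class = "sbgnq_formula")
# sentinel for subtrees containing a NOT operator: the enclosing arc is ignored
f_ignored <- function() structure(list(op = "ignored"), class = "sbgnq_formula")

formula_is_ignored <- function(f) identical(f$op, "ignored")

#' Render a Boolean formula as text
#'
#' Debug rendering with `&`, `|`, `!` and EPN ids.
#'
#' @param x a formula as returned by [logic_of()] or [mod_of()].
#' @param ... unused.
#' @export
format.sbgnq_formula <- function(x, ...) {
  switch(x$op,
         lit = x$id,
         not = paste0("!", wrap_atom(x$arg)),
         and = paste(vapply(x$args, wrap_atom, character(1)), collapse = " & "),
         or = paste(vapply(x$args, wrap_atom, character(1)), collapse = " | "),
         true = "TRUE", false = "FALSE", ignored = "<ignored>")
}

wrap_atom <- function(f) {
  s <- format(f)
  if (f$op %in% c("and", "or") && length(f$args) > 1L) paste0("(", s, ")") else s
}

#' @export
print.sbgnq_formula <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Evaluate a formula under an EPN presence assignment
#'
#' @param f a formula.
#' @param presence named logical vector, EPN id to present/absent. Missing
#'   EPNs count as absent.
#' @return logical scalar; `NA` for the ignored sentinel.
#' @export
eval_formula <- function(f, presence) {
  switch(f$op,
         lit = isTRUE(unname(presence[f$id])),
         not = !eval_formula(f$arg, presence),
         and = all(vapply(f$args, eval_formula, logical(1), presence = presence)),
         or = any(vapply(f$args, eval_formula, logical(1), presence = presence)),
         true = TRUE, false = FALSE, ignored = NA)
}

formula_vars <- function(f) {
  switch(f$op,
         lit = f$id,
         not = formula_vars(f$arg),
         and = unique(unlist(lapply(f$args, formula_vars))),
         or = unique(unlist(lapply(f$args, formula_vars))),
         character())
}

#' Satisfaction formula of a modulation origin
#'
#' Recursively builds the Boolean formula `logic(n)` of a modulation origin:
#' an EPN maps to its presence literal, an AND node to the conjunction of its
#' inputs' formulas, an OR node to their disjunction. A subtree containing a
#' NOT operator has no dynamical meaning; the whole origin formula becomes an
#' *ignored* sentinel, which causes [mod_of()] to drop the arc (with a
#' warning).
#'
#' @param map a [pd_map()].
#' @param node an EPN or logical-operator id.
#' @return a formula object.
#' @export
logic_of <- function(map, node) {
  if (node %in% names(map$epns)) return(f_lit(node))
  if (!node %in% names(map$operators))
    stop("unknown modulation origin: ", node)
  if (node %in% operator_cycles(map))
    stop("logical operator ", node, " lies on an input cycle")
  op <- map$operators[[node]]
  if (op$kind == "NOT") return(f_ignored())
  args <- lapply(op$inputs, logic_of, map = map)
  if (any(vapply(args, formula_is_ignored, logical(1)))) return(f_ignored())
  if (length(args) == 1L) return(args[[1]])
  if (op$kind == "AND") f_and(args) else f_or(args)
}

#' Permissive occurrence formula of a process
#'
#' `mod(p)` is the condition on EPN presence under which process `p` may
#' switch to its occurring state. With `R` the necessary stimulations, `A`
#' the stimulations and catalyses and `I` the inhibitions of `p` (generic
#' modulation arcs and arcs traversing a NOT operator are removed first,
#' with a warning):
#' * if `A` and `I` are both empty, `mod(p)` is the conjunction of the
#'   `logic()` formulas of `R`;
#' * otherwise it is that conjunction AND (some stimulation satisfied OR
#'   some inhibition unsatisfied).
#'
#' Empty conjunctions are `TRUE` and empty disjunctions `FALSE`, so an
#' unmodulated process has `mod(p) = TRUE`. This permissive reading makes a
#' process with one stimulator `s` and one inhibitor `i` occur whenever
#' `s | !i` holds: both present, both absent, or stimulator present alone.
#'
#' @param map a [pd_map()].
#' @param process a process id.
#' @return a formula object.
#' @export
mod_of <- function(map, process) {
  if (!process %in% names(map$processes))
    stop("unknown process: ", process)
  gen <- mod_origins(map, process, "modulation")
  for (o in gen)
    warning("generic modulation arc ", o, " -> ", process,
            " has unknown effect; ignored")
  keep_logic <- function(origins) {
    fs <- lapply(origins, logic_of, map = map)
    drop <- vapply(fs, formula_is_ignored, logical(1))
    for (o in origins[drop])
      warning("modulation arc ", o, " -> ", process,
              " traverses a NOT operator; ignored")
    fs[!drop]
  }
  req <- keep_logic(map_req(map, process))
  act <- keep_logic(map_act(map, process))
  inh <- keep_logic(map_inh(map, process))

  req_part <- if (length(req) == 0L) f_true()
              else if (length(req) == 1L) req[[1]] else f_and(req)
  if (length(act) == 0L && length(inh) == 0L) return(req_part)
  alts <- c(act, lapply(inh, f_not))
  alt_part <- if (length(alts) == 1L) alts[[1]] else f_or(alts)
  if (identical(req_part$op, "true")) alt_part else f_and(list(req_part, alt_part))
}

# -- Disjunctive normal form --------------------------------------------------

# A DNF is a list of clauses; a clause is list(pos = chr, neg = chr) with
# sorted, disjoint literal sets.  TRUE is the singleton {empty clause};
# FALSE is the empty clause list.

clause <- function(pos = character(), neg = character()) {
  list(pos = sort(unique(pos)), neg = sort(unique(neg)))
}
clause_key <- function(cl)
  paste(paste0("+", cl$pos, collapse = " "),
        paste0("-", cl$neg, collapse = " "))
clause_contradictory <- function(cl) length(intersect(cl$pos, cl$neg)) > 0L
clause_subsumes <- function(a, b)  # a subset of b => a subsumes b
  all(a$pos %in% b$pos) && all(a$neg %in% b$neg)

dnf_canonical <- function(clauses) {
  clauses <- Filter(Negate(clause_contradictory), clauses)
  keys <- vapply(clauses, clause_key, character(1))
  clauses <- clauses[!duplicated(keys)]
  n <- length(clauses)
  if (n > 1L) {
    # duplicates are gone, so subsumption between distinct clauses is strict
    drop <- rep(FALSE, n)
    for (j in seq_len(n)) for (i in seq_len(n))
      if (i != j && !drop[i] && clause_subsumes(clauses[[i]], clauses[[j]])) {
        drop[j] <- TRUE
        break
      }
    clauses <- clauses[!drop]
  }
  keys <- vapply(clauses, clause_key, character(1))
  clauses[order(keys)]
}

#' Convert a formula to disjunctive normal form
#'
#' Negation is pushed to the literals (negation normal form), conjunctions
#' are distributed over disjunctions, and the result is pruned: clauses
#' containing a literal and its negation are dropped, subsumed clauses are
#' dropped, and clauses and literals are canonically ordered. `TRUE` becomes
#' the singleton set containing the empty clause and `FALSE` the empty
#' clause set. Exact (no minimisation heuristics), intended for the desk
#' scale of per-process modulation formulas.
#'
#' @param f a formula object.
#' @return a list of clauses, each `list(pos =, neg =)` of EPN ids, with
#'   class `sbgnq_dnf`.
#' @export
to_dnf <- function(f) {
  rec <- function(f, neg) {
    switch(f$op,
      lit = list(if (neg) clause(neg = f$id) else clause(pos = f$id)),
      not = rec(f$arg, !neg),
      true = if (neg) list() else list(clause()),
      false = if (neg) list(clause()) else list(),
      ignored = stop("cannot convert an ignored modulation formula to DNF"),
      and = if (neg) do.call(c, lapply(f$args, rec, neg = TRUE))
            else cross_clauses(lapply(f$args, rec, neg = FALSE)),
      or = if (neg) cross_clauses(lapply(f$args, rec, neg = TRUE))
           else do.call(c, lapply(f$args, rec, neg = FALSE)))
  }
  structure(dnf_canonical(rec(f, FALSE)), class = "sbgnq_dnf")
}

# conjunction of DNFs: cross product of clause lists, merging literal sets
cross_clauses <- function(dnfs) {
  acc <- list(clause())
  for (d in dnfs) {
    if (length(d) == 0L) return(list())
    nxt <- list()
    for (a in acc) for (b in d) {
      m <- clause(c(a$pos, b$pos), c(a$neg, b$neg))
      if (!clause_contradictory(m)) nxt[[length(nxt) + 1L]] <- m
    }
    acc <- nxt
    if (length(acc) == 0L) return(list())
  }
  acc
}

#' @export
format.sbgnq_dnf <- function(x, ...) {
  if (length(x) == 0L) return("FALSE")
  cl <- vapply(x, function(c2) {
    lits <- c(c2$pos, paste0("!", c2$neg))
    if (length(lits) == 0L) "TRUE" else paste(lits, collapse = " & ")
  }, character(1))
  paste(cl, collapse = " | ")
}

#' @export
print.sbgnq_dnf <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

eval_dnf <- function(dnf, presence) {
  any(vapply(dnf, function(cl) {
    all(vapply(cl$pos, function(e) isTRUE(unname(presence[e])), logical(1))) &&
      all(!vapply(cl$neg, function(e) isTRUE(unname(presence[e])), logical(1)))
  }, logical(1)))
}

# -- Expansion into local-state conditions ------------------------------------

# ls(x): local states matching a signed EPN literal, given a story set.
# A story EPN is "absent" when its story automaton is in any *other* state,
# including (following the prose definition of absence, not the printed
# set-builder) the empty state; strict = TRUE reproduces the printed
# set-builder, which omits the empty state.
literal_states <- function(x, positive, stories, strict = FALSE) {
  sid <- story_of(stories, x)
  if (is.na(sid)) {
    st <- if (positive) "1" else "0"
    return(list(stats::setNames(st, x)))
  }
  if (positive) return(list(stats::setNames(x, sid)))
  others <- setdiff(stories$stories[[sid]], x)
  if (!strict) others <- c(others, "empty")
  lapply(others, function(s) stats::setNames(s, sid))
}

# merge two partial conditions (named automaton -> state vectors);
# NULL when they require two different states of one automaton
merge_conditions <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (any(a[shared] != b[shared])) return(NULL)
  out <- c(a, b[setdiff(names(b), names(a))])
  out[order(names(out))]
}

condition_key <- function(cond)
  paste(names(cond), cond, sep = "=", collapse = ",")

#' Expand a process modulation into local-state conditions
#'
#' `cond(p)` lists the sets of automata local states that satisfy
#' `DNF(mod(p))` under the chosen story set: the union over DNF clauses of
#' the cross product of the local states matching each literal. A present
#' non-story EPN maps to its `1` state, a present story EPN to its story
#' state, and an absent story EPN to every *other* state of its story
#' automaton, including the empty state (use `strict = TRUE` for the
#' variant without the empty state). Conditions that would require two
#' local states of one automaton are unsatisfiable and dropped.
#'
#' An unmodulated process yields the single empty condition; a process whose
#' formula is `FALSE` (all its stimulation arcs ignored) yields an empty
#' condition set and can never activate (a warning is emitted).
#'
#' @param map a [pd_map()].
#' @param process a process id.
#' @param stories a [story_set()] or `NULL` for the general semantics.
#' @param strict omit the empty state from the absence expansion of story
#'   EPNs.
#' @return list of conditions, each a named character vector
#'   (automaton name to local-state name), deduplicated and canonically
#'   ordered.
#' @export
conditions_of <- function(map, process, stories = NULL, strict = FALSE) {
  stories <- as_story_set(stories)
  dnf <- to_dnf(mod_of(map, process))
  if (length(dnf) == 0L)
    warning("process ", process,
            " has an unsatisfiable modulation formula; it can never activate")
  conds <- list()
  for (cl in dnf) {
    partials <- list(stats::setNames(character(), character()))
    lits <- c(lapply(cl$pos, function(e) list(e = e, pos = TRUE)),
              lapply(cl$neg, function(e) list(e = e, pos = FALSE)))
    for (lit in lits) {
      opts <- literal_states(lit$e, lit$pos, stories, strict)
      nxt <- list()
      for (pa in partials) for (op in opts) {
        m <- merge_conditions(pa, op)
        if (!is.null(m)) nxt[[length(nxt) + 1L]] <- m
      }
      partials <- nxt
      if (length(partials) == 0L) break
    }
    conds <- c(conds, partials)
  }
  keys <- vapply(conds, condition_key, character(1))
  conds <- conds[!duplicated(keys)]
  conds[order(vapply(conds, condition_key, character(1)))]
}
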