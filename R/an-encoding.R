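# Encoding of an SBGN-PD map (plus an optional story set) into an
# asynchronous automata network, and the network's exchange formats.

#' Construct an automata network
#'
#' An automata network is a triple (Sigma, S, T): a set of named finite
#' automata, their local states, and condition-guarded local transitions.
#' Each transition moves one automaton between two of its local states and
#' may be conditioned on local states of *other* automata (at most one per
#' automaton).
#'
#' @param automata named list; each element the character vector of local
#'   state names of one automaton.
#' @param transitions list of transitions, each a list with elements
#'   `automaton`, `from`, `to`, `cond` (named character vector: automaton
#'   name to required local state), and optional provenance fields `tag`
#'   and `process`.
#' @return an object of class `automata_network`.
#' @export
automata_network <- function(automata = list(), transitions = list()) {
  if (length(automata)) {
    if (is.null(names(automata)) || any(!nzchar(names(automata))))
      stop("automata must be named")
    automata <- automata[order(names(automata))]
  }
  transitions <- lapply(transitions, function(tr) {
    tr$cond <- canonical_cond(tr$cond)
    validate_transition(automata, tr)
    tr$tag <- tr$tag %||% "manual"
    tr$process <- tr$process %||% NA_character_
    tr[c("automaton", "from", "to", "cond", "tag", "process")]
  })
  keys <- vapply(transitions, transition_key, character(1))
  transitions <- transitions[order(keys)][!duplicated(sort(keys))]
  structure(list(automata = automata, transitions = transitions),
            class = "automata_network")
}

canonical_cond <- function(cond) {
  if (is.null(cond) || length(cond) == 0L)
    return(stats::setNames(character(), character()))
  cond <- vapply(cond, as.character, character(1))
  cond[order(names(cond))]
}

transition_key <- function(tr)
  paste(tr$automaton, tr$from, tr$to, condition_key(tr$cond), sep = " | ")

validate_transition <- function(automata, tr) {
  a <- automata[[tr$automaton]]
  if (is.null(a)) stop("integrity error: unknown automaton ", tr$automaton)
  if (!tr$from %in% a || !tr$to %in% a)
    stop("integrity error: unknown local state of automaton ", tr$automaton)
  if (tr$from == tr$to)
    stop("a local transition must change the local state (", tr$automaton, ")")
  if (anyDuplicated(names(tr$cond)))
    stop("condition references an automaton twice")
  if (tr$automaton %in% names(tr$cond))
    stop("condition references the transition's own automaton ", tr$automaton)
  for (b in names(tr$cond)) {
    sb <- automata[[b]]
    if (is.null(sb)) stop("integrity error: condition references unknown ",
                          "automaton ", b)
    if (!tr$cond[[b]] %in% sb)
      stop("integrity error: condition references unknown local state ",
           b, "=", tr$cond[[b]])
  }
  invisible(tr)
}

#' @export
print.automata_network <- function(x, ...) {
  cat("Automata network: ", length(x$automata), " automata, ",
      length(x$transitions), " local transitions\n", sep = "")
  invisible(x)
}

#' Transitions of an automata network as a data frame
#'
#' @param an an [automata_network()].
#' @return data frame with columns `automaton`, `from`, `to`, `cond`
#'   (rendered `a=1,b=0`), `tag` and `process`.
#' @export
an_transitions <- function(an) {
  data.frame(
    automaton = vapply(an$transitions, `[[`, character(1), "automaton"),
    from = vapply(an$transitions, `[[`, character(1), "from"),
    to = vapply(an$transitions, `[[`, character(1), "to"),
    cond = vapply(an$transitions, function(tr)
      condition_key(tr$cond), character(1)),
    tag = vapply(an$transitions, `[[`, character(1), "tag"),
    process = vapply(an$transitions, `[[`, character(1), "process"),
    stringsAsFactors = FALSE)
}

# merge condition parts; NULL when jointly unsatisfiable, and with
# references to `self` dropped when they match `from` (implied) or
# rejected when they do not (unsatisfiable)
build_cond <- function(parts, self = NULL, from = NULL) {
  out <- stats::setNames(character(), character())
  for (p in parts) {
    if (length(p) == 0L) next
    out <- merge_conditions(out, canonical_cond(p))
    if (is.null(out)) return(NULL)
  }
  if (!is.null(self) && self %in% names(out)) {
    if (out[[self]] != from) return(NULL)
    out <- out[names(out) != self]
  }
  out
}

# -- Encoding -----------------------------------------------------------------

#' Encode a map as an asynchronous automata network
#'
#' Under the general semantics (empty story set) every non-source/sink EPN
#' becomes a Boolean absent/present automaton and every process a Boolean
#' non-occurring/occurring automaton. Under the stories semantics each story
#' becomes a single automaton with one state per member EPN plus an *empty*
#' state for the absence of the molecular entity, so the member EPNs are
#' mutually exclusive by construction, and processes acting on a common
#' story are kept exclusive through the conflict relation.
#'
#' A process automaton is omitted (`shortcuts = TRUE`) in the simple cases
#' where no automaton is needed to sequence consumption and production: the
#' process has no conflict and either consumes nothing, or consumes a single
#' EPN and produces nothing, or consumes a single EPN and produces a single
#' EPN of the same story. In those cases its occurrence conditions are
#' embedded directly in the EPN/story transitions. `shortcuts = FALSE`
#' forces a process automaton everywhere (the state space then has the full
#' dimension, which the rule-based oracle of the dynamics module expects).
#'
#' In the general case, with `cond(p)` from [conditions_of()]:
#' * activation `p:0 -> 1` conditioned on `l + ready(p)` for each
#'   `l in cond(p)`, where `ready(p)` contains the present states of the
#'   (non-story) reactants, the story states of the story reactants, the
#'   empty state of stories produced by a reactant-less process, and the
#'   non-occurring state of every conflicting process;
#' * production `f:0 -> 1` on `p = 1` for non-story products;
#' * consumption `e:1 -> 0` on `p = 1` plus `done(p)` for non-story
#'   reactants, where `done(p)` contains the present/story states of the
#'   products and the empty state of stories consumed but not produced
#'   (consumption is optional: it may or may not fire before de-activation);
#' * story moves `s_e -> s_f` (or to/from the empty state) on `p = 1`;
#' * de-activation `p:1 -> 0` on `done(p)`.
#'
#' Conditions rendered unsatisfiable by the story expansion (two local
#' states of one automaton) are dropped at encoding time. Every transition
#' records its process and rule tag as provenance.
#'
#' @param map a [pd_map()].
#' @param stories a [story_set()] or `NULL` (general semantics). Stories
#'   are checked against the story constraints.
#' @param shortcuts apply the three simple-case shortcuts (default) or force
#'   process automata everywhere.
#' @param strict passed to [conditions_of()].
#' @return an [automata_network()].
#' @export
encode <- function(map, stories = NULL, shortcuts = TRUE, strict = FALSE) {
  stories <- as_story_set(stories)
  for (nm in names(stories$stories)) {
    v <- check_story(map, stories$stories[[nm]], min_size = 1L)
    if (!v$ok)
      stop("invalid story ", nm, ": violates constraint(s) ",
           paste(v$violations, collapse = ", "))
  }
  in_story <- story_epns(stories)
  conflicts <- conflict_relation(map, stories)
  partners <- function(p)
    sort(c(conflicts$q[conflicts$p == p], conflicts$p[conflicts$q == p]))

  automata <- list()
  for (e in setdiff(epn_ids(map), in_story)) automata[[e]] <- c("0", "1")
  for (nm in names(stories$stories))
    automata[[nm]] <- c(stories$stories[[nm]], "empty")

  is_shortcut <- function(p) {
    if (!shortcuts || length(partners(p)) > 0L) return(FALSE)
    ip <- map_in(map, p); op <- map_out(map, p)
    if (length(ip) == 0L) return(TRUE)
    if (length(ip) == 1L && length(op) == 0L) return(TRUE)
    if (length(ip) == 1L && length(op) == 1L) {
      sid <- story_of(stories, ip)
      return(!is.na(sid) && identical(sid, story_of(stories, op)))
    }
    FALSE
  }
  for (p in process_ids(map))
    if (!is_shortcut(p)) automata[[p]] <- c("0", "1")

  state_ref <- function(e, present = TRUE) {
    sid <- story_of(stories, e)
    if (is.na(sid)) stats::setNames(if (present) "1" else "0", e)
    else stats::setNames(e, sid)
  }

  trs <- list()
  emit <- function(automaton, from, to, cond, tag, process) {
    if (is.null(cond)) return()   # unsatisfiable, dropped
    trs[[length(trs) + 1L]] <<- list(automaton = automaton, from = from,
                                     to = to, cond = cond, tag = tag,
                                     process = process)
  }

  for (p in process_ids(map)) {
    conds <- suppressWarnings(conditions_of(map, p, stories, strict))
    ip <- map_in(map, p); op <- map_out(map, p)
    if (is_shortcut(p)) {
      if (length(ip) == 0L) {
        # no consumption: each product switches on independently
        for (l in conds) for (f in op) {
          sid <- story_of(stories, f)
          if (is.na(sid))
            emit(f, "0", "1", build_cond(list(l), f, "0"), "shortcut", p)
          else
            emit(sid, "empty", f, build_cond(list(l), sid, "empty"),
                 "shortcut", p)
        }
      } else if (length(op) == 0L) {
        e <- ip
        sid <- story_of(stories, e)
        for (l in conds) {
          if (is.na(sid))
            emit(e, "1", "0", build_cond(list(l), e, "1"), "shortcut", p)
          else
            emit(sid, e, "empty", build_cond(list(l), sid, e), "shortcut", p)
        }
      } else {
        sid <- story_of(stories, ip)   # single in/out of the same story
        for (l in conds)
          emit(sid, ip, op, build_cond(list(l), sid, ip), "shortcut", p)
      }
      next
    }

    ready <- stats::setNames(character(), character())
    for (e in setdiff(ip, in_story)) ready[e] <- "1"
    for (nm in names(stories$stories)) {
      se <- intersect(ip, stories$stories[[nm]])
      so <- intersect(op, stories$stories[[nm]])
      if (length(se) == 1L) ready[nm] <- se
      else if (length(se) == 0L && length(so) > 0L) {
        if (length(ip) > 0L)
          stop("story ", nm, " is produced but not consumed by process ", p,
               " which has reactants; story constraint (ii) is violated")
        ready[nm] <- "empty"
      }
    }
    for (q in partners(p)) ready[q] <- "0"

    done <- stats::setNames(character(), character())
    for (f in setdiff(op, in_story)) done[f] <- "1"
    for (nm in names(stories$stories)) {
      se <- intersect(ip, stories$stories[[nm]])
      so <- intersect(op, stories$stories[[nm]])
      if (length(so) == 1L) done[nm] <- so
      else if (length(so) == 0L && length(se) > 0L) done[nm] <- "empty"
    }

    for (l in conds)
      emit(p, "0", "1", build_cond(list(l, ready), p, "0"), "activation", p)
    for (f in setdiff(op, in_story))
      emit(f, "0", "1", build_cond(list(stats::setNames("1", p)), f, "0"),
           "production", p)
    for (e in setdiff(ip, in_story))
      emit(e, "1", "0",
           build_cond(list(stats::setNames("1", p), done), e, "1"),
           "consumption", p)
    for (nm in names(stories$stories)) {
      se <- intersect(ip, stories$stories[[nm]])
      so <- intersect(op, stories$stories[[nm]])
      p1 <- stats::setNames("1", p)
      if (length(se) == 1L) {
        if (length(so) == 1L)
          emit(nm, se, so, build_cond(list(p1), nm, se), "stories", p)
        else
          emit(nm, se, "empty", build_cond(list(p1), nm, se), "stories", p)
      } else if (length(ip) == 0L && length(so) == 1L) {
        emit(nm, "empty", so, build_cond(list(p1), nm, "empty"), "stories", p)
      }
    }
    emit(p, "1", "0", build_cond(list(done), p, "1"), "deactivation", p)
  }

  automata_network(automata, trs)
}

#' Build the global initial state of an encoding
#'
#' The initial state of a map is the set of EPNs present at time zero. Two
#' EPNs of one story cannot both be initially present (mutual exclusion);
#' each story automaton starts in the state of its unique present member,
#' or in the empty state. All process automata start non-occurring.
#'
#' @param an the [encode()]d network.
#' @param map the source [pd_map()].
#' @param present_epns character vector of initially present EPN ids.
#' @param stories the [story_set()] used for the encoding (or `NULL`).
#' @return a global state: named character vector (automaton to active local
#'   state), sorted by automaton name.
#' @export
initial_global_state <- function(an, map, present_epns, stories = NULL) {
  stories <- as_story_set(stories)
  present_epns <- unique(as.character(present_epns))
  unknown <- setdiff(present_epns, epn_ids(map))
  if (length(unknown))
    stop("unknown EPN id(s) in initial state: ",
         paste(unknown, collapse = ", "))
  state <- character()
  for (a in names(an$automata)) {
    if (a %in% names(stories$stories)) {
      pres <- intersect(present_epns, stories$stories[[a]])
      if (length(pres) > 1L)
        stop("initial-state conflict: EPNs ", paste(pres, collapse = ", "),
             " of story ", a, " cannot both be present")
      state[a] <- if (length(pres) == 1L) pres else "empty"
    } else if (a %in% process_ids(map)) {
      state[a] <- "0"
    } else {
      state[a] <- if (a %in% present_epns) "1" else "0"
    }
  }
  state[order(names(state))]
}

#' Project a stories-semantics state onto the general semantics
#'
#' An EPN embedded in a story is present in the projected state if and only
#' if it is the current local state of its story automaton; non-story EPNs
#' and process automata present in both encodings are copied, other process
#' automata are non-occurring.
#'
#' @param state global state of a stories encoding.
#' @param map the source [pd_map()].
#' @param stories the [story_set()] of that encoding.
#' @param general_an optional general-semantics encoding of the same map;
#'   built with [encode()] (same `shortcuts` setting) when omitted.
#' @param shortcuts used when `general_an` is built here.
#' @return a global state of the general encoding.
#' @export
project_state <- function(state, map, stories, general_an = NULL,
                          shortcuts = TRUE) {
  stories <- as_story_set(stories)
  if (is.null(general_an)) general_an <- encode(map, NULL, shortcuts)
  out <- character()
  for (a in names(general_an$automata)) {
    if (a %in% process_ids(map)) {
      out[a] <- if (a %in% names(state)) unname(state[a]) else "0"
    } else {
      sid <- story_of(stories, a)
      if (is.na(sid)) {
        if (!a %in% names(state))
          stop("projection error: automaton ", a,
               " is missing from the stories-semantics state")
        out[a] <- unname(state[a])
      } else {
        if (!sid %in% names(state))
          stop("projection error: story automaton ", sid,
               " is missing from the stories-semantics state")
        out[a] <- if (identical(unname(state[sid]), a)) "1" else "0"
      }
    }
  }
  out[order(names(out))]
}

#' Add a local transition to a network
#'
#' Manual augmentation, e.g. to model a transcriptional effect by adding a
#' transition from an absent to a present state of a protein conditioned on
#' the state of its transcription factor. Idempotent: adding an existing
#' transition leaves the network unchanged.
#'
#' @param an an [automata_network()].
#' @param automaton,from,to the automaton and its local states.
#' @param cond named character vector of condition local states (other
#'   automata only).
#' @param tag provenance tag, default `"manual"`.
#' @return the augmented network.
#' @export
add_local_transition <- function(an, automaton, from, to,
                                 cond = character(), tag = "manual") {
  tr <- list(automaton = automaton, from = from, to = to,
             cond = canonical_cond(cond), tag = tag, process = NA_character_)
  validate_transition(an$automata, tr)
  automata_network(an$automata, c(an$transitions, list(tr)))
}

# -- JSON round trip ----------------------------------------------------------

#' Serialize / parse an automata network as JSON
#'
#' The JSON schema records the automata with their ordered local states and
#' every transition with its condition and provenance; the round trip
#' `parse_an(serialize_an(x))` is lossless.
#'
#' @param an an [automata_network()].
#' @param path optional output file.
#' @return `serialize_an`: the JSON string (invisibly when `path` is
#'   given); `parse_an`: an [automata_network()].
#' @export
serialize_an <- function(an, path = NULL) {
  payload <- list(
    automata = lapply(an$automata, as.list),
    transitions = lapply(an$transitions, function(tr) {
      x <- list(automaton = tr$automaton, from = tr$from, to = tr$to,
                cond = as.list(tr$cond), tag = tr$tag)
      if (!is.na(tr$process)) x$process <- tr$process
      x
    }))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @param x a JSON string or path for `parse_an`.
#' @rdname serialize_an
#' @export
parse_an <- function(x) {
  if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  payload <- jsonlite::fromJSON(paste(x, collapse = "\n"),
                                simplifyVector = FALSE)
  automata <- lapply(payload$automata, function(s)
    vapply(s, as.character, character(1)))
  transitions <- lapply(payload$transitions, function(tr) {
    cond <- if (length(tr$cond) == 0L)
      stats::setNames(character(), character())
    else vapply(tr$cond, as.character, character(1))
    list(automaton = tr$automaton, from = tr$from, to = tr$to, cond = cond,
         tag = tr$tag %||% "manual", process = tr$process %||% NA_character_)
  })
  automata_network(automata, transitions)
}

# -- Petri net export ---------------------------------------------------------

#' Export an automata network to a 1-bounded Petri net (PNML)
#'
#' One place per local state (marked iff active in the supplied initial
#' state), one Petri-net transition per local transition with one input arc
#' (origin place) and one output arc (destination place), and one read arc
#' per condition local state. The place/transition PNML dialect has no read
#' arcs, so each is emitted as a self-loop input/output arc pair; this is
#' flagged in a `toolspecific` element (`readarcs="self-loop-pairs"`).
#' Reachable markings from the encoded initial marking are in bijection
#' with the network's reachable global states.
#'
#' @param an an [automata_network()].
#' @param initial optional global state used for the initial marking.
#' @param path optional output file.
#' @return the `xml2` document (invisibly when `path` is given).
#' @export
export_pnml <- function(an, initial = NULL, path = NULL) {
  doc <- xml2::xml_new_root(
    "pnml", xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  net <- xml2::xml_add_child(
    doc, "net", id = "an",
    type = "http://www.pnml.org/version-2009/grammar/ptnet")
  ts <- xml2::xml_add_child(net, "toolspecific", tool = "sbgnq",
                            version = "1", readarcs = "self-loop-pairs")
  invisible(ts)
  page <- xml2::xml_add_child(net, "page", id = "page0")

  place_id <- character()
  idx <- 0L
  for (a in names(an$automata)) for (s in an$automata[[a]]) {
    idx <- idx + 1L
    pid <- sprintf("pl%d", idx)
    place_id[paste(a, s, sep = "\r")] <- pid
    pl <- xml2::xml_add_child(page, "place", id = pid)
    nm <- xml2::xml_add_child(pl, "name")
    xml2::xml_add_child(nm, "text", paste0(a, "=", s))
    marked <- !is.null(initial) && identical(unname(initial[a]), s)
    mk <- xml2::xml_add_child(pl, "initialMarking")
    xml2::xml_add_child(mk, "text", if (marked) "1" else "0")
  }

  arc_n <- 0L
  add_arc <- function(src, tgt) {
    arc_n <<- arc_n + 1L
    xml2::xml_add_child(page, "arc", id = sprintf("a%d", arc_n),
                        source = src, target = tgt)
  }
  for (i in seq_along(an$transitions)) {
    tr <- an$transitions[[i]]
    tid <- sprintf("tr%d", i)
    tn <- xml2::xml_add_child(page, "transition", id = tid)
    nm <- xml2::xml_add_child(tn, "name")
    xml2::xml_add_child(nm, "text", transition_key(tr))
    add_arc(place_id[[paste(tr$automaton, tr$from, sep = "\r")]], tid)
    add_arc(tid, place_id[[paste(tr$automaton, tr$to, sep = "\r")]])
    for (b in names(tr$cond)) {
      cp <- place_id[[paste(b, tr$cond[[b]], sep = "\r")]]
      add_arc(cp, tid)   # read arc as a self-loop pair
      add_arc(tid, cp)
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Render an automata network or transition graph to Graphviz DOT
#'
#' @param an an [automata_network()].
#' @return a character scalar with DOT source (clustered by automaton).
#' @export
an_to_dot <- function(an) {
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph an {", "  compound=true;")
  for (i in seq_along(an$automata)) {
    a <- names(an$automata)[i]
    lines <- c(lines,
               sprintf("  subgraph cluster_%d {", i),
               sprintf('    label="%s";', esc(a)),
               sprintf('    "%s";', esc(paste0(a, ".", an$automata[[a]]))),
               "  }")
  }
  for (tr in an$transitions) {
    lab <- condition_key(tr$cond)
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                              esc(paste0(tr$automaton, ".", tr$from)),
                              esc(paste0(tr$automaton, ".", tr$to)),
                              esc(lab)))
  }
  paste(c(lines, "}"), collapse = "\n")
}
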