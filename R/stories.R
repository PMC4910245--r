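# Stories: sets of EPNs representing mutually exclusive physical states of
# one molecular entity, and their valid / final / epn-maximal combinations.

#' Create a story set
#'
#' A story is a set of EPN ids standing for the different physical states of
#' one molecular entity; a set of stories is *valid* when its stories are
#' pairwise disjoint. Story names default to the readable canonical id
#' `story(e1+e2+...)` over the sorted member ids.
#'
#' @param stories list of character vectors of EPN ids, optionally named.
#' @param map optional [pd_map()]; when given, each story is checked against
#'   the story constraints (an invalid story is an error).
#' @return an object of class `story_set`.
#' @export
story_set <- function(stories = list(), map = NULL) {
  stories <- lapply(stories, function(s) sort(unique(as.character(s))))
  nm <- names(stories) %||% rep("", length(stories))
  if (length(nm) == 0L) nm <- character()
  auto <- !nzchar(nm)
  nm[auto] <- vapply(stories[auto], function(s)
    paste0("story(", paste(s, collapse = "+"), ")"), character(1))
  names(stories) <- nm
  if (anyDuplicated(nm))
    stop("duplicated story names: ", paste(nm[duplicated(nm)], collapse = ", "))
  all_epns <- unlist(stories, use.names = FALSE)
  if (anyDuplicated(all_epns))
    stop("story set is not valid: stories share EPN(s) ",
         paste(unique(all_epns[duplicated(all_epns)]), collapse = ", "))
  if ("empty" %in% all_epns)
    stop("'empty' is reserved for the empty local state of story automata")
  stories <- stories[order(names(stories))]
  if (!is.null(map)) {
    for (nm2 in names(stories)) {
      v <- check_story(map, stories[[nm2]], min_size = 1L)
      if (!v$ok)
        stop("story ", nm2, " violates constraint(s) ",
             paste(v$violations, collapse = ", "))
    }
  }
  structure(list(stories = stories), class = "story_set")
}

as_story_set <- function(x) {
  if (is.null(x)) return(story_set())
  if (inherits(x, "story_set")) return(x)
  story_set(x)
}

#' @export
print.story_set <- function(x, ...) {
  cat("Story set with", length(x$stories), "stories,",
      length(unlist(x$stories)), "EPNs\n")
  for (nm in names(x$stories))
    cat("  ", nm, ": {", paste(x$stories[[nm]], collapse = ", "), "}\n",
        sep = "")
  invisible(x)
}

n_stories <- function(x) length(x$stories)
story_epns <- function(x) sort(unlist(x$stories, use.names = FALSE))

# story name containing an EPN, NA if none
story_of <- function(stories, e) {
  for (nm in names(stories$stories))
    if (e %in% stories$stories[[nm]]) return(nm)
  NA_character_
}

# stories touched by process p: S(p) = { S | in(p) or out(p) meets S }
stories_of_process <- function(map, stories, p) {
  touch <- c(map_in(map, p), map_out(map, p))
  names(stories$stories)[vapply(stories$stories, function(s)
    length(intersect(s, touch)) > 0L, logical(1))]
}

# -- Constraint checking ------------------------------------------------------

# adjacency for constraint (i): two story EPNs are linked when some process
# touches both by flux arcs; a story is flux-connected when its members form
# one component under this relation (paths may only pass through members).
story_adjacent <- function(map, e, f) {
  for (p in map$processes) {
    touch <- c(p$reactants, p$products)
    if (e %in% touch && f %in% touch) return(TRUE)
  }
  FALSE
}

story_connected <- function(map, epns) {
  n <- length(epns)
  if (n <= 1L) return(TRUE)
  touch_sets <- lapply(map$processes, function(p)
    intersect(c(p$reactants, p$products), epns))
  comp <- seq_len(n)
  names(comp) <- epns
  for (ts in touch_sets) {
    if (length(ts) < 2L) next
    cs <- comp[ts]
    comp[comp %in% cs] <- min(cs)
  }
  length(unique(comp)) == 1L
}

# label set for constraint (v): own label, plus member labels for complexes
label_set <- function(map, e) {
  node <- map$epns[[e]]
  labs <- node$components
  if (nzchar(node$label)) labs <- c(labs, node$label)
  unique(labs)
}

#' Check the story constraints for a candidate EPN set
#'
#' A story must satisfy:
#' * (i) its EPNs are pairwise connected by paths of flux arcs that stay
#'   inside the story;
#' * (ii) whenever a process produces a story EPN, the process either has no
#'   (non-source) reactants or consumes a story EPN;
#' * (iii) no process consumes two story EPNs;
#' * (iv) no process produces two story EPNs;
#' * optionally (v) all story EPNs share a label (for complexes, any member
#'   label counts).
#'
#' Sources and sinks cannot belong to a story; singleton candidates are
#' rejected by default (`min_size = 2`), since a singleton story's automaton
#' is dynamics-equivalent to the EPN's Boolean automaton.
#'
#' A story holding both a reactant and the sole stimulator of one process
#' would freeze that process under the stories semantics; this is reported
#' as a warning, not a violation.
#'
#' @param map a [pd_map()].
#' @param epns candidate story as a character vector of EPN ids.
#' @param label_constraint enforce constraint (v).
#' @param min_size minimum story size.
#' @return `list(ok = logical, violations = character)`, with violation tags
#'   among `i`, `ii`, `iii`, `iv`, `v`, `too-small`.
#' @export
check_story <- function(map, epns, label_constraint = FALSE, min_size = 2L) {
  epns <- sort(unique(as.character(epns)))
  unknown <- setdiff(epns, epn_ids(map))
  if (length(unknown))
    stop("unknown EPN id(s): ", paste(unknown, collapse = ", "))
  v <- character()
  if (length(epns) < min_size) v <- c(v, "too-small")
  if (!story_connected(map, epns)) v <- c(v, "i")
  for (p in process_ids(map)) {
    ip <- map_in(map, p); op <- map_out(map, p)
    if (length(intersect(op, epns)) > 0L &&
        length(ip) > 0L && length(intersect(ip, epns)) == 0L)
      v <- c(v, "ii")
    if (length(intersect(ip, epns)) > 1L) v <- c(v, "iii")
    if (length(intersect(op, epns)) > 1L) v <- c(v, "iv")
  }
  if (label_constraint && length(epns) > 1L) {
    shared <- Reduce(intersect, lapply(epns, label_set, map = map))
    if (length(shared) == 0L) v <- c(v, "v")
  }
  v <- unique(v)
  if (length(v) == 0L) {
    for (p in process_ids(map)) {
      acts <- map_act(map, p)
      if (length(intersect(map_in(map, p), epns)) > 0L &&
          length(acts) == 1L && acts %in% epns &&
          !acts %in% map_in(map, p))
        warning("story {", paste(epns, collapse = ","),
                "} contains both a reactant and the sole stimulator of ",
                "process ", p, "; the process can never occur under the ",
                "stories semantics")
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

# -- Enumeration --------------------------------------------------------------

#' Enumerate all stories of a map
#'
#' Exhaustively lists the EPN subsets within the size bounds that satisfy
#' the story constraints (i)-(iv), and (v) when `label_constraint` is set.
#' The search is restricted to the flux-connected components of the map, so
#' it is exact; it is meant for desk-scale maps (an error is raised when a
#' component exceeds 18 EPNs).
#'
#' @inheritParams check_story
#' @param min_size,max_size story size bounds (singletons excluded by
#'   default).
#' @param seeds optional list of EPN sets that must themselves be stories;
#'   an invalid seed is an error listing its violations. Seeds are recorded
#'   in the `seeds` attribute for use by [epn_maximal_sets()].
#' @return list of stories (sorted character vectors), canonically ordered.
#' @export
enumerate_stories <- function(map, min_size = 2L, max_size = Inf,
                              label_constraint = FALSE, seeds = NULL) {
  seeds <- lapply(seeds, function(s) sort(unique(as.character(s))))
  for (s in seeds) {
    v <- check_story(map, s, label_constraint, min_size)
    if (!v$ok)
      stop("invalid seed story {", paste(s, collapse = ","),
           "}: violates ", paste(v$violations, collapse = ", "))
  }
  ids <- epn_ids(map)
  if (length(ids) == 0L) return(structure(list(), seeds = seeds))
  # flux-connected components over all EPNs
  comp <- stats::setNames(seq_along(ids), ids)
  for (p in map$processes) {
    ts <- c(p$reactants, p$products)
    if (length(ts) < 2L) next
    cs <- comp[ts]
    comp[comp %in% cs] <- min(cs)
  }
  out <- list()
  for (cid in unique(comp)) {
    members <- names(comp)[comp == cid]
    k <- length(members)
    if (k < min_size) next
    if (k > 18L)
      stop("a flux-connected component has ", k,
           " EPNs; exhaustive story enumeration is desk-scale only ",
           "(<= 18 EPNs per component)")
    lo <- max(min_size, 1L); hi <- min(k, max_size)
    if (lo > hi) next
    for (sz in seq(from = lo, to = hi)) {
      subs <- utils::combn(members, sz, simplify = FALSE)
      for (s in subs) {
        v <- suppressWarnings(check_story(map, s, label_constraint, min_size))
        if (v$ok) out[[length(out) + 1L]] <- sort(s)
      }
    }
  }
  keys <- vapply(out, paste, character(1), collapse = "+")
  out <- out[order(keys)]
  structure(out, seeds = seeds)
}

# -- Story combinations -------------------------------------------------------

# maximal independent sets of the story-intersection graph, by
# Bron-Kerbosch with pivot on the complement graph
maximal_independent_sets <- function(stories) {
  n <- length(stories)
  if (n == 0L) return(list())
  inter <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && length(intersect(stories[[i]], stories[[j]])) > 0L)
      inter[i, j] <- TRUE
  compat <- !inter; diag(compat) <- FALSE
  res <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      res[[length(res) + 1L]] <<- sort(R)
      return()
    }
    pivot_pool <- c(P, X)
    deg <- vapply(pivot_pool, function(u) sum(compat[u, P]), integer(1))
    u <- pivot_pool[which.max(deg)]
    for (v in setdiff(P, which(compat[u, ]))) {
      nv <- which(compat[v, ])
      bk(c(R, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  res
}

#' All maximally valid sets of stories
#'
#' A set of stories is valid when its stories are pairwise disjoint; the
#' maximally valid sets are the inclusion-maximal independent sets of the
#' story-intersection graph (vertices the stories, edges joining
#' intersecting pairs).
#'
#' @param stories list of stories (as from [enumerate_stories()]), each a
#'   character vector of EPN ids.
#' @return list of [story_set()] objects, canonically ordered.
#' @export
maximal_valid_sets <- function(stories) {
  stories <- lapply(stories, function(s) sort(unique(as.character(s))))
  sets <- maximal_independent_sets(stories)
  out <- lapply(sets, function(idx) story_set(stories[idx]))
  keys <- vapply(out, function(s)
    paste(names(s$stories), collapse = " / "), character(1))
  out[order(keys)]
}

# does set b dominate set a? (b != a, every story of a has a superset in b)
dominates <- function(b, a) {
  if (identical(a$stories, b$stories)) return(FALSE)
  all(vapply(a$stories, function(sa)
    any(vapply(b$stories, function(sb) all(sa %in% sb), logical(1))),
    logical(1)))
}

#' Final sets of stories
#'
#' A valid set `S` is *final* when no other valid set `S'` story-wise
#' dominates it, i.e. there is no `S' != S` such that every story of `S` has
#' a superset story in `S'`. Dominance by an arbitrary valid set implies
#' dominance by a maximally valid one, so filtering the maximally valid sets
#' against each other is exact; pass the output of [maximal_valid_sets()].
#' Every final set is also maximally valid.
#'
#' @param valid_sets list of [story_set()] objects (all maximally valid sets
#'   of the map).
#' @return the subset of `valid_sets` that is final.
#' @export
final_sets <- function(valid_sets) {
  keep <- vapply(seq_along(valid_sets), function(i)
    !any(vapply(seq_along(valid_sets), function(j)
      j != i && dominates(valid_sets[[j]], valid_sets[[i]]), logical(1))),
    logical(1))
  valid_sets[keep]
}

#' Epn-maximal sets of stories
#'
#' The valid sets of stories maximizing the total number of EPNs. Any
#' epn-maximal set is an inclusion-maximal independent set of the
#' story-intersection graph (adding a disjoint story strictly increases the
#' total), so the maximum is attained on, and the ties enumerated from, the
#' maximal valid sets. Every epn-maximal set is also final.
#'
#' @param x either a list of stories (character vectors) or a list of
#'   [story_set()] objects (the candidate valid sets).
#' @param seeds optional list of stories that every candidate set must
#'   contain (stories defined beforehand).
#' @return list of [story_set()] objects attaining the maximum total EPN
#'   count.
#' @export
epn_maximal_sets <- function(x, seeds = NULL) {
  sets <- if (length(x) && inherits(x[[1]], "story_set")) x
          else maximal_valid_sets(x)
  if (!is.null(seeds)) {
    seeds <- lapply(seeds, function(s) sort(unique(as.character(s))))
    sets <- Filter(function(st)
      all(vapply(seeds, function(sd)
        any(vapply(st$stories, identical, logical(1), y = sd)), logical(1))),
      sets)
  }
  if (length(sets) == 0L) return(list())
  w <- vapply(sets, function(s) length(unlist(s$stories)), integer(1))
  sets[w == max(w)]
}

#' Conflict relation between processes
#'
#' Two distinct processes are in conflict (`p # q`) when they act on a
#' common story; conflicting processes must not occur simultaneously, which
#' the encoding enforces by conditioning each activation on the other
#' process being non-occurring.
#'
#' @param map a [pd_map()].
#' @param stories a [story_set()] (empty set: no conflicts).
#' @return data frame with columns `p` and `q`, one row per unordered pair
#'   (`p < q`); symmetric and irreflexive by construction.
#' @export
conflict_relation <- function(map, stories) {
  stories <- as_story_set(stories)
  ps <- process_ids(map)
  touched <- lapply(ps, stories_of_process, map = map, stories = stories)
  names(touched) <- ps
  rows <- list()
  if (length(ps) >= 2L)
    for (i in seq_len(length(ps) - 1L)) for (j in seq(i + 1L, length(ps)))
      if (length(intersect(touched[[i]], touched[[j]])) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(p = ps[i], q = ps[j],
                                                stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    return(data.frame(p = character(), q = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# -- Serialization ------------------------------------------------------------

#' Serialize story sets to JSON and a TSV summary
#'
#' Flags are computed relative to the supplied candidate list: `valid`
#' (pairwise disjoint, always true for [story_set()] objects), `final`
#' (undominated within the candidates) and `epn_maximal` (attaining the
#' maximum total EPN count among the candidates).
#'
#' @param sets list of [story_set()] objects.
#' @param json_path,tsv_path optional output paths.
#' @return invisibly, a list with the JSON string and the summary data
#'   frame.
#' @export
write_story_sets <- function(sets, json_path = NULL, tsv_path = NULL) {
  fin <- final_sets(sets)
  epnmax <- epn_maximal_sets(sets)
  is_in <- function(s, lst) any(vapply(lst, function(o)
    identical(o$stories, s$stories), logical(1)))
  payload <- lapply(sets, function(s) list(
    stories = lapply(unname(s$stories), function(e) list(epns = e)),
    flags = list(valid = TRUE, final = is_in(s, fin),
                 epn_maximal = is_in(s, epnmax))))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  df <- data.frame(
    set = vapply(sets, function(s)
      paste(names(s$stories), collapse = " / "), character(1)),
    n_stories = vapply(sets, function(s) length(s$stories), integer(1)),
    n_epns = vapply(sets, function(s)
      length(unlist(s$stories)), integer(1)),
    final = vapply(sets, is_in, logical(1), lst = fin),
    epn_maximal = vapply(sets, is_in, logical(1), lst = epnmax),
    stringsAsFactors = FALSE)
  if (!is.null(json_path)) writeLines(json, json_path)
  if (!is.null(tsv_path))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(json = json, summary = df))
}
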