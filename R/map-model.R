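# -- Node constructors --------------------------------------------------------

EPN_CLASSES <- c("unspecified-entity", "simple-chemical", "macromolecule",
                 "nucleic-acid-feature", "complex", "perturbing-agent")
PROCESS_CLASSES <- c("process", "omitted-process", "uncertain-process",
                     "association", "dissociation", "phenotype")
MODULATION_CLASSES <- c("modulation", "stimulation", "catalysis", "inhibition",
                        "necessary-stimulation")

#' Create an entity pool node
#'
#' An entity pool node (EPN) stands for a pool of molecular entities:
#' a macromolecule, a simple chemical, a complex, etc. Two EPNs that share
#' class, label, compartment, state decorations and complex-component labels
#' denote the same pool (clone markers), and are merged on import.
#' Source/sink glyphs are not represented as EPNs; they are recorded as flags
#' on the processes they touch.
#'
#' @param id unique identifier.
#' @param epn_class one of `r paste(EPN_CLASSES, collapse = ", ")`.
#' @param label display label (may be empty); EPNs of a story often share it.
#' @param compartment optional compartment id; EPNs with identical attributes
#'   but different compartments are distinct pools.
#' @param state_vars character vector of `"variable=value"` state decorations
#'   (e.g. phosphorylation sites).
#' @param components labels of the members of a complex (empty otherwise).
#' @param is_clone whether the glyph carried a clone marker.
#' @return a list of class `sbgnq_epn`.
#' @export
epn <- function(id, epn_class = "macromolecule", label = "",
                compartment = NA_character_, state_vars = character(),
                components = character(), is_clone = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  epn_class <- match.arg(epn_class, EPN_CLASSES)
  structure(
    list(id = id, epn_class = epn_class, label = label,
         compartment = compartment,
         state_vars = sort(unique(as.character(state_vars))),
         components = sort(unique(as.character(components))),
         is_clone = isTRUE(is_clone)),
    class = "sbgnq_epn")
}

#' Create a process node
#'
#' Reactants and products hold the EPNs linked by consumption/production flux
#' arcs, *excluding* source and sink glyphs: those are turned into the
#' `has_source_reactant` / `has_sink_product` flags, so that `reactants` and
#' `products` are exactly the sets used by the dynamics (`in(p)` / `out(p)`).
#'
#' @param id unique identifier.
#' @param process_class one of `r paste(PROCESS_CLASSES, collapse = ", ")`.
#' @param reactants,products character vectors of EPN ids.
#' @param has_source_reactant,has_sink_product whether a source (resp. sink)
#'   glyph is consumed (resp. produced).
#' @return a list of class `sbgnq_process`.
#' @export
process_node <- function(id, process_class = "process",
                         reactants = character(), products = character(),
                         has_source_reactant = FALSE,
                         has_sink_product = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  process_class <- match.arg(process_class, PROCESS_CLASSES)
  structure(
    list(id = id, process_class = process_class,
         reactants = sort(unique(as.character(reactants))),
         products = sort(unique(as.character(products))),
         has_source_reactant = isTRUE(has_source_reactant),
         has_sink_product = isTRUE(has_sink_product)),
    class = "sbgnq_process")
}

#' Create a logical operator node
#'
#' @param id unique identifier.
#' @param kind `"AND"`, `"OR"` or `"NOT"`. NOT operators are parsed but any
#'   modulation arc whose origin formula traverses one is ignored downstream.
#' @param inputs non-empty character vector of EPN or operator ids.
#' @return a list of class `sbgnq_operator`.
#' @export
operator_node <- function(id, kind, inputs) {
  kind <- match.arg(toupper(kind), c("AND", "OR", "NOT"))
  inputs <- sort(unique(as.character(inputs)))
  if (length(inputs) == 0L) stop("operator ", id, " has no inputs")
  structure(list(id = id, kind = kind, inputs = inputs),
            class = "sbgnq_operator")
}

# -- The map ------------------------------------------------------------------

#' Assemble an SBGN-PD map
#'
#' Checks referential integrity (every arc endpoint exists, flux arcs connect
#' EPNs to processes only) and canonicalizes all orderings so that identical
#' inputs give identical maps.
#'
#' @param epns list of [epn()] nodes.
#' @param processes list of [process_node()] nodes.
#' @param operators list of [operator_node()] nodes.
#' @param modulations list of modulation arcs, each a list with elements
#'   `class` (one of `r paste(MODULATION_CLASSES, collapse = ", ")`),
#'   `origin` (EPN or operator id) and `target` (process id).
#' @param compartments named character vector of compartment labels.
#' @return an object of class `pd_map` with fields `epns`, `processes`,
#'   `operators`, `modulations`, `compartments`, each keyed by id.
#' @export
pd_map <- function(epns = list(), processes = list(), operators = list(),
                   modulations = list(), compartments = character()) {
  named_by_id <- function(xs, what) {
    ids <- vapply(xs, function(x) x$id, character(1))
    if (anyDuplicated(ids))
      stop("duplicated ", what, " id: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    xs <- xs[order(ids)]
    names(xs) <- sort(ids)
    xs
  }
  epns <- named_by_id(epns, "EPN")
  processes <- named_by_id(processes, "process")
  operators <- named_by_id(operators, "operator")
  all_ids <- c(names(epns), names(processes), names(operators))
  if (anyDuplicated(all_ids))
    stop("node ids must be unique across EPNs, processes and operators: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))

  for (p in processes) {
    bad <- setdiff(c(p$reactants, p$products), names(epns))
    if (length(bad))
      stop("integrity error: process ", p$id,
           " has a flux arc to unknown EPN ", paste(bad, collapse = ", "))
  }
  for (op in operators) {
    bad <- setdiff(op$inputs, c(names(epns), names(operators)))
    if (length(bad))
      stop("integrity error: operator ", op$id, " has unknown input ",
           paste(bad, collapse = ", "))
  }
  modulations <- lapply(modulations, function(m) {
    m$class <- match.arg(m$class, MODULATION_CLASSES)
    if (!m$origin %in% c(names(epns), names(operators)))
      stop("integrity error: modulation arc origin ", m$origin, " not found")
    if (!m$target %in% names(processes))
      stop("integrity error: modulation arc target ", m$target,
           " is not a process")
    m[c("class", "origin", "target")]
  })
  key <- vapply(modulations, function(m)
    paste(m$class, m$origin, m$target), character(1))
  modulations <- modulations[order(key)][!duplicated(sort(key))]

  if (length(compartments))
    compartments <- compartments[order(names(compartments))]
  structure(list(epns = epns, processes = processes, operators = operators,
                 modulations = modulations, compartments = compartments),
            class = "pd_map")
}

#' @export
print.pd_map <- function(x, ...) {
  cat("SBGN-PD map: ", length(x$epns), " EPNs, ", length(x$processes),
      " processes, ", length(x$modulations), " modulation arcs, ",
      length(x$operators), " logical operators\n", sep = "")
  invisible(x)
}

# in(p) / out(p): reactants / products minus sources and sinks (already
# excluded at construction), as id vectors.
map_in <- function(map, p) map$processes[[p]]$reactants
map_out <- function(map, p) map$processes[[p]]$products

# Modulation origins by effect class.  req = necessary stimulations,
# act = stimulations + catalyses, inh = inhibitions.  Generic "modulation"
# arcs have unknown effect and are not part of any of the three sets.
mod_origins <- function(map, p, classes) {
  sel <- vapply(map$modulations, function(m)
    m$target == p && m$class %in% classes, logical(1))
  vapply(map$modulations[sel], function(m) m$origin, character(1))
}
map_req <- function(map, p) mod_origins(map, p, "necessary-stimulation")
map_act <- function(map, p) mod_origins(map, p, c("stimulation", "catalysis"))
map_inh <- function(map, p) mod_origins(map, p, "inhibition")

epn_ids <- function(map) names(map$epns)
process_ids <- function(map) names(map$processes)

# -- Clone merging ------------------------------------------------------------

epn_identity <- function(e) {
  paste(e$epn_class, e$label, e$compartment,
        paste(e$state_vars, collapse = ";"),
        paste(e$components, collapse = ";"), sep = "\r")
}

# Merge EPNs denoting the same pool (clone markers): group by the identity
# tuple (class, label, compartment, state decorations, component labels),
# keep the lexicographically smallest id, remap all arcs.  Idempotent.
merge_clones <- function(map) {
  if (length(map$epns) == 0L) return(map)
  ident <- vapply(map$epns, epn_identity, character(1))
  groups <- split(names(map$epns), ident)
  remap <- character()
  for (g in groups) {
    keep <- min(g)
    remap[g] <- keep
  }
  kept <- unique(unname(remap))
  epns <- map$epns[kept]
  epns <- lapply(epns, function(e) { e$is_clone <- FALSE; e })
  processes <- lapply(map$processes, function(p) {
    p$reactants <- sort(unique(unname(remap[p$reactants])))
    p$products <- sort(unique(unname(remap[p$products])))
    p
  })
  operators <- lapply(map$operators, function(op) {
    op$inputs <- sort(unique(ifelse(op$inputs %in% names(remap),
                                    remap[op$inputs], op$inputs)))
    op
  })
  modulations <- lapply(map$modulations, function(m) {
    if (m$origin %in% names(remap)) m$origin <- unname(remap[[m$origin]])
    m
  })
  pd_map(unname(epns), unname(processes), unname(operators), modulations,
         map$compartments)
}

# -- Validation ---------------------------------------------------------------

finding <- function(class, severity, ref, message) {
  data.frame(class = class, severity = severity, ref = ref,
             message = message, stringsAsFactors = FALSE)
}

# ids of operators whose cycle check fails (input graph must be acyclic)
operator_cycles <- function(map) {
  ops <- names(map$operators)
  if (length(ops) == 0L) return(character())
  state <- new.env(parent = emptyenv())
  cyclic <- character()
  visit <- function(id) {
    st <- state[[id]]
    if (identical(st, "done")) return(FALSE)
    if (identical(st, "active")) return(TRUE)
    state[[id]] <- "active"
    found <- FALSE
    for (inp in intersect(map$operators[[id]]$inputs, ops))
      if (visit(inp)) found <- TRUE
    state[[id]] <- "done"
    if (found) cyclic <<- union(cyclic, id)
    found
  }
  for (id in ops) visit(id)
  sort(cyclic)
}

# does the formula rooted at node reach a NOT operator? (cycle-safe)
reaches_not <- function(map, node, seen = character()) {
  if (!node %in% names(map$operators)) return(FALSE)
  if (node %in% seen) return(FALSE)
  op <- map$operators[[node]]
  if (op$kind == "NOT") return(TRUE)
  any(vapply(op$inputs, reaches_not, logical(1),
             map = map, seen = c(seen, node)))
}

#' Validate an SBGN-PD map
#'
#' Report-only checks for constructs the qualitative semantics cannot, or
#' deliberately does not, interpret:
#' * modulation arcs whose origin formula traverses a NOT operator (the NOT
#'   operator has no dynamical meaning; such arcs are ignored downstream) —
#'   warning, class `not-operator-ignored`;
#' * generic `modulation` arcs (effect unknown, ignored downstream) —
#'   warning, class `generic-modulation-ignored`;
#' * cyclic logical-operator input graphs — error, class `operator-cycle`;
#' * processes with no flux arc and no source/sink flag — warning, class
#'   `disconnected-process`.
#'
#' @param map a [pd_map()].
#' @return a data frame of findings with columns `class`, `severity`
#'   (`"warning"` or `"error"`), `ref` (the offending id) and `message`;
#'   zero rows for a clean map.
#' @export
validate_map <- function(map) {
  out <- list()
  cyc <- operator_cycles(map)
  for (id in cyc)
    out[[length(out) + 1L]] <- finding(
      "operator-cycle", "error", id,
      paste0("logical operator ", id, " lies on an input cycle"))
  acyclic <- length(cyc) == 0L
  for (m in map$modulations) {
    if (m$class == "modulation")
      out[[length(out) + 1L]] <- finding(
        "generic-modulation-ignored", "warning", m$origin,
        paste0("generic modulation arc ", m$origin, " -> ", m$target,
               " has unknown effect and is ignored"))
    if (acyclic && reaches_not(map, m$origin))
      out[[length(out) + 1L]] <- finding(
        "not-operator-ignored", "warning", m$origin,
        paste0("modulation arc ", m$origin, " -> ", m$target,
               " traverses a NOT operator and is ignored"))
  }
  for (p in map$processes)
    if (length(p$reactants) == 0L && length(p$products) == 0L &&
        !p$has_source_reactant && !p$has_sink_product)
      out[[length(out) + 1L]] <- finding(
        "disconnected-process", "warning", p$id,
        paste0("process ", p$id, " has neither flux arcs nor source/sink"))
  if (length(out) == 0L)
    return(data.frame(class = character(), severity = character(),
                      ref = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
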