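# Shared helpers: state-key utilities, independent oracles (truth tables,
# brute-force subset enumeration, Petri-net marking graphs) used to
# cross-check the package's own implementations.

state_key <- function(s) paste(names(s), s, sep = "=", collapse = ",")

# oracle state (logical presence/occurrence) -> encoded global state
# (valid for general-semantics encodings without shortcuts)
oracle_to_an_state <- function(s) {
  v <- c(ifelse(s$epns, "1", "0"), ifelse(s$processes, "1", "0"))
  names(v) <- c(names(s$epns), names(s$processes))
  v[order(names(v))]
}

an_to_oracle_state <- function(map, st) {
  list(epns = st[names(map$epns)] == "1",
       processes = st[names(map$processes)] == "1")
}

# all assignments of TRUE/FALSE to vars, as a list of named logical vectors
all_assignments <- function(vars) {
  n <- length(vars)
  if (n == 0L) return(list(stats::setNames(logical(), character())))
  lapply(seq_len(2^n) - 1L, function(k) {
    stats::setNames(as.logical(bitwAnd(k %/% 2^(seq_len(n) - 1L), 1L)), vars)
  })
}

# truth-table equivalence of a formula and its DNF
dnf_equivalent <- function(f, dnf, vars) {
  eval_dnf_clause <- function(cl, a)
    all(a[cl$pos]) && !any(a[cl$neg])
  for (a in all_assignments(vars)) {
    fv <- eval_formula(f, a)
    dv <- length(dnf) > 0L && any(vapply(dnf, eval_dnf_clause, logical(1), a = a))
    if (!identical(fv, dv)) return(FALSE)
  }
  TRUE
}

# brute-force story enumeration: every EPN subset within the size bounds,
# filtered with check_story (independent of the component-restricted search)
brute_force_stories <- function(map, min_size = 2L, max_size = Inf,
                                label_constraint = FALSE) {
  ids <- names(map$epns)
  out <- list()
  n <- length(ids)
  if (n == 0L) return(out)
  for (k in 0:(2^n - 1L)) {
    s <- ids[as.logical(bitwAnd(k %/% 2^(seq_len(n) - 1L), 1L))]
    if (length(s) < min_size || length(s) > max_size) next
    v <- suppressWarnings(check_story(map, s, label_constraint, min_size))
    if (v$ok) out[[length(out) + 1L]] <- sort(s)
  }
  keys <- vapply(out, paste, character(1), collapse = "+")
  out[order(keys)]
}

# Minimal 1-bounded Petri-net marking-graph builder over a parsed PNML
# document (independent of the package's automata-network execution).
# Places are identified by their name texts; read arcs appear as self-loop
# input/output pairs and are handled by ordinary token flow.
pnml_marking_graph <- function(doc, cap = 10000L) {
  xml2::xml_ns_strip(doc)
  pl <- xml2::xml_find_all(doc, ".//place")
  pid <- xml2::xml_attr(pl, "id")
  marked <- vapply(pl, function(x)
    identical(xml2::xml_text(
      xml2::xml_find_first(x, "./initialMarking/text")), "1"), logical(1))
  trn <- xml2::xml_attr(xml2::xml_find_all(doc, ".//transition"), "id")
  arcs <- xml2::xml_find_all(doc, ".//arc")
  asrc <- xml2::xml_attr(arcs, "source")
  atgt <- xml2::xml_attr(arcs, "target")
  inputs <- lapply(trn, function(t) asrc[atgt == t])    # places -> t
  outputs <- lapply(trn, function(t) atgt[asrc == t])   # t -> places
  names(inputs) <- names(outputs) <- trn

  m0 <- stats::setNames(marked, pid)
  key <- function(m) paste(as.integer(m), collapse = "")
  seen <- new.env(parent = emptyenv())
  assign(key(m0), TRUE, envir = seen)
  states <- list(m0)
  frontier <- list(m0)
  edges <- 0L
  while (length(frontier)) {
    nxt <- list()
    for (m in frontier) {
      for (t in trn) {
        ins <- inputs[[t]]
        if (!all(m[ins])) next
        m2 <- m
        m2[ins] <- FALSE
        outs <- outputs[[t]]
        if (any(m2[outs]))   # 1-boundedness would be violated
          stop("marking-graph builder: net is not 1-bounded at ", t)
        m2[outs] <- TRUE
        k <- key(m2)
        edges <- edges + 1L
        if (is.null(seen[[k]])) {
          if (length(states) >= cap) stop("marking-graph cap exceeded")
          assign(k, TRUE, envir = seen)
          states[[length(states) + 1L]] <- m2
          nxt[[length(nxt) + 1L]] <- m2
        }
      }
    }
    frontier <- nxt
  }
  list(states = states, n = length(states))
}

# readable key sets of the reachable PN markings, restricted to marked places
marking_keys <- function(mg, doc) {
  xml2::xml_ns_strip(doc)
  pl <- xml2::xml_find_all(doc, ".//place")
  pid <- xml2::xml_attr(pl, "id")
  pname <- vapply(pl, function(x)
    xml2::xml_text(xml2::xml_find_first(x, "./name/text")), character(1))
  names(pname) <- pid
  sort(vapply(mg$states, function(m)
    paste(sort(unname(pname[names(m)[m]])), collapse = ";"), character(1)))
}

# global AN states of an STG as marking-style keys ("aut=state" sets)
stg_marking_keys <- function(stg) {
  sort(vapply(stg$states, function(s)
    paste(sort(paste0(names(s), "=", s)), collapse = ";"), character(1)))
}
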