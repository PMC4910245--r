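# SBGN-ML (XML) import.  Accepts the 0.2 and 0.3 dialects of the PD language.

sbgnml_epn_class <- function(cls) {
  # hyphenate and normalise the source/sink synonyms
  switch(cls,
         "source and sink" = "source-sink",
         "empty set" = "source-sink",
         gsub(" ", "-", cls))
}

#' Read an SBGN-ML document
#'
#' Parses an SBGN-ML (0.2 or 0.3) Process Description map into a [pd_map()].
#' Clone-marked EPNs denoting the same pool are merged; "source and sink"
#' glyphs are role-tagged from arc direction (consumed source / produced
#' sink) rather than represented as EPNs; compartments are recorded and EPNs
#' in different compartments stay distinct. Sub-maps, reference nodes,
#' equivalence arcs and unknown glyph classes are dropped with a warning.
#' Stoichiometry (cardinality) and units of information are parsed but have
#' no dynamical meaning.
#'
#' @param x path to an SBGN-ML file, a literal XML string, or an
#'   `xml2::xml_document`.
#' @return a [pd_map()].
#' @export
read_sbgnml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  xml2::xml_ns_strip(doc)
  map_node <- xml2::xml_find_first(doc, ".//map")
  if (inherits(map_node, "xml_missing"))
    stop("no <map> element found in SBGN-ML document")
  lang <- xml2::xml_attr(map_node, "language")
  if (!is.na(lang) && tolower(lang) != "process description")
    stop("unsupported SBGN language: '", lang,
         "' (only process description is interpreted)")

  glyphs <- xml2::xml_find_all(map_node, "./glyph")
  arcs <- xml2::xml_find_all(map_node, "./arc")

  epns <- list(); procs <- list(); ops <- list()
  comps <- character()
  sourcesinks <- character()
  port_owner <- character()   # port id -> glyph id
  known <- character()

  glyph_label <- function(g) {
    lab <- xml2::xml_find_first(g, "./label")
    if (inherits(lab, "xml_missing")) "" else
      xml2::xml_attr(lab, "text") %||% ""
  }
  register_ports <- function(g, id) {
    for (p in xml2::xml_find_all(g, "./port")) {
      pid <- xml2::xml_attr(p, "id")
      if (!is.na(pid)) port_owner[pid] <<- id
    }
  }

  handle_glyph <- function(g) {
    cls <- xml2::xml_attr(g, "class")
    id <- xml2::xml_attr(g, "id")
    if (is.na(cls) || is.na(id)) {
      warning("glyph without class or id skipped")
      return()
    }
    register_ports(g, id)
    ecls <- sbgnml_epn_class(cls)
    if (ecls %in% EPN_CLASSES) {
      svs <- character(); comp_labels <- character()
      for (sub in xml2::xml_find_all(g, "./glyph")) {
        scls <- xml2::xml_attr(sub, "class")
        if (identical(scls, "state variable")) {
          st <- xml2::xml_find_first(sub, "./state")
          if (!inherits(st, "xml_missing")) {
            var <- xml2::xml_attr(st, "variable"); val <- xml2::xml_attr(st, "value")
            svs <- c(svs, paste0(ifelse(is.na(var), "", var), "=",
                                 ifelse(is.na(val), "", val)))
          }
        } else if (identical(scls, "unit of information")) {
          # parsed, no dynamical meaning
        } else if (!is.na(scls) &&
                   sbgnml_epn_class(scls) %in% EPN_CLASSES) {
          comp_labels <- c(comp_labels, glyph_label(sub))
        }
      }
      clone <- length(xml2::xml_find_all(g, "./clone")) > 0L
      compartment <- xml2::xml_attr(g, "compartmentRef")
      epns[[length(epns) + 1L]] <<- epn(
        id, ecls, label = glyph_label(g), compartment = compartment,
        state_vars = svs, components = comp_labels, is_clone = clone)
      known[id] <<- "epn"
    } else if (ecls == "source-sink") {
      sourcesinks <<- c(sourcesinks, id)
      known[id] <<- "sourcesink"
    } else if (gsub(" ", "-", cls) %in% PROCESS_CLASSES) {
      procs[[id]] <<- list(id = id, class = gsub(" ", "-", cls),
                           reactants = character(), products = character(),
                           src = FALSE, snk = FALSE)
      known[id] <<- "process"
    } else if (tolower(cls) %in% c("and", "or", "not")) {
      ops[[id]] <<- list(id = id, kind = toupper(cls), inputs = character())
      known[id] <<- "operator"
    } else if (cls == "compartment") {
      comps[id] <<- glyph_label(g)
      known[id] <<- "compartment"
    } else if (cls %in% c("submap", "tag", "annotation")) {
      warning("glyph class '", cls, "' (", id, ") is not interpreted; dropped")
      known[id] <<- "dropped"
    } else {
      warning("unknown glyph class '", cls, "' (", id, ") skipped")
      known[id] <<- "dropped"
    }
  }
  for (g in glyphs) handle_glyph(g)

  resolve <- function(ref) {
    if (ref %in% names(port_owner)) unname(port_owner[[ref]]) else ref
  }

  mods <- list()
  for (a in arcs) {
    cls <- xml2::xml_attr(a, "class")
    src <- resolve(xml2::xml_attr(a, "source"))
    tgt <- resolve(xml2::xml_attr(a, "target"))
    aid <- xml2::xml_attr(a, "id")
    if (is.na(cls) || is.na(src) || is.na(tgt)) {
      warning("arc ", aid %||% "?", " with missing class/endpoints skipped")
      next
    }
    role <- function(id) if (id %in% names(known)) known[[id]] else NA_character_
    if (cls == "consumption") {
      if (is.na(role(tgt)) || role(tgt) != "process")
        stop("integrity error: consumption arc ", aid,
             " does not target a known process (", tgt, ")")
      if (identical(role(src), "sourcesink"))
        procs[[tgt]]$src <- TRUE
      else if (identical(role(src), "epn"))
        procs[[tgt]]$reactants <- c(procs[[tgt]]$reactants, src)
      else stop("integrity error: consumption arc ", aid,
                " has unknown source ", src)
    } else if (cls == "production") {
      if (is.na(role(src)) || role(src) != "process")
        stop("integrity error: production arc ", aid,
             " does not originate from a known process (", src, ")")
      if (identical(role(tgt), "sourcesink"))
        procs[[src]]$snk <- TRUE
      else if (identical(role(tgt), "epn"))
        procs[[src]]$products <- c(procs[[src]]$products, tgt)
      else stop("integrity error: production arc ", aid,
                " has unknown target ", tgt)
    } else if (gsub(" ", "-", cls) %in% MODULATION_CLASSES) {
      if (!identical(role(tgt), "process"))
        stop("integrity error: modulation arc ", aid,
             " does not target a known process (", tgt, ")")
      if (!role(src) %in% c("epn", "operator"))
        stop("integrity error: modulation arc ", aid,
             " has unknown origin ", src)
      mods[[length(mods) + 1L]] <- list(class = gsub(" ", "-", cls),
                                        origin = src, target = tgt)
    } else if (cls == "logic arc") {
      if (!identical(role(tgt), "operator"))
        stop("integrity error: logic arc ", aid,
             " does not target a logical operator (", tgt, ")")
      if (!role(src) %in% c("epn", "operator"))
        stop("integrity error: logic arc ", aid, " has unknown source ", src)
      ops[[tgt]]$inputs <- c(ops[[tgt]]$inputs, src)
    } else if (cls == "equivalence arc") {
      warning("equivalence arc ", aid %||% "?", " is not interpreted; dropped")
    } else {
      warning("unknown arc class '", cls, "' skipped")
    }
  }

  proc_nodes <- lapply(procs, function(p)
    process_node(p$id, p$class, p$reactants, p$products, p$src, p$snk))
  op_nodes <- lapply(ops, function(o) {
    if (length(o$inputs) == 0L)
      stop("integrity error: logical operator ", o$id, " has no logic arc")
    operator_node(o$id, o$kind, o$inputs)
  })
  merge_clones(pd_map(epns, unname(proc_nodes), unname(op_nodes), mods, comps))
}
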