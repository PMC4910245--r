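# Plain one-record-per-line map description, used by fixtures and tests.
#
#   epn <id> <class> [label=...] [compartment=...] [components=a;b]
#       [state=var:val;...] [clone]
#   process <id> <class>
#   consume <process> <epn>|SOURCE
#   produce <process> <epn>|SINK
#   modulate <class> <origin> <process>
#   operator <id> AND|OR|NOT <input>+
#   compartment <id> <label>
#
# Tokens are whitespace-separated; values therefore cannot contain spaces.
# Lines starting with '#' and blank lines are skipped.

#' Read a map from the plain text format
#'
#' A line-oriented description of an SBGN-PD map used for fixtures and tests;
#' see the package vignette for the record grammar. The round trip through
#' [write_pd_text()] preserves EPNs, processes, flux arcs and modulation
#' classes exactly.
#'
#' @param x path to a file, or a character vector of lines (anything
#'   containing a newline is treated as literal text).
#' @return a [pd_map()].
#' @export
read_pd_text <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  else if (length(x) == 1L)
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]

  epns <- list(); procs <- list(); ops <- list(); mods <- list()
  comps <- character()
  flux <- list()  # deferred consume/produce records

  for (line in x) {
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    kind <- tok[1]
    if (kind == "epn") {
      if (length(tok) < 3L) stop("bad epn record: ", line)
      opts <- tok[-(1:3)]
      kv <- function(key) {
        hit <- grep(paste0("^", key, "="), opts, value = TRUE)
        if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NULL
      }
      comp_labels <- kv("components")
      states <- kv("state")
      epns[[length(epns) + 1L]] <- epn(
        id = tok[2], epn_class = tok[3],
        label = kv("label") %||% "",
        compartment = kv("compartment") %||% NA_character_,
        components = if (is.null(comp_labels)) character() else
          strsplit(comp_labels, ";", fixed = TRUE)[[1]],
        state_vars = if (is.null(states)) character() else
          gsub(":", "=", strsplit(states, ";", fixed = TRUE)[[1]]),
        is_clone = "clone" %in% opts)
    } else if (kind == "process") {
      if (length(tok) < 3L) stop("bad process record: ", line)
      procs[[tok[2]]] <- process_node(tok[2], tok[3])
    } else if (kind %in% c("consume", "produce")) {
      if (length(tok) != 3L) stop("bad flux record: ", line)
      flux[[length(flux) + 1L]] <- tok
    } else if (kind == "modulate") {
      if (length(tok) != 4L) stop("bad modulate record: ", line)
      mods[[length(mods) + 1L]] <-
        list(class = tok[2], origin = tok[3], target = tok[4])
    } else if (kind == "operator") {
      if (length(tok) < 4L) stop("bad operator record: ", line)
      ops[[length(ops) + 1L]] <- operator_node(tok[2], tok[3], tok[-(1:3)])
    } else if (kind == "compartment") {
      comps[tok[2]] <- if (length(tok) >= 3L) tok[3] else tok[2]
    } else stop("unknown record type '", kind, "' in: ", line)
  }

  for (f in flux) {
    pid <- f[2]
    if (is.null(procs[[pid]]))
      stop("integrity error: flux arc references unknown process ", pid)
    if (f[1] == "consume") {
      if (f[3] == "SOURCE") procs[[pid]]$has_source_reactant <- TRUE
      else procs[[pid]]$reactants <- c(procs[[pid]]$reactants, f[3])
    } else {
      if (f[3] == "SINK") procs[[pid]]$has_sink_product <- TRUE
      else procs[[pid]]$products <- c(procs[[pid]]$products, f[3])
    }
  }
  procs <- lapply(procs, function(p)
    process_node(p$id, p$process_class, p$reactants, p$products,
                 p$has_source_reactant, p$has_sink_product))
  pd_map(epns, unname(procs), ops, mods, comps)
}

#' Write a map to the plain text format
#'
#' @param map a [pd_map()].
#' @param path optional file path; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) the character vector
#'   of lines.
#' @export
write_pd_text <- function(map, path = NULL) {
  out <- character()
  for (id in names(map$compartments))
    out <- c(out, paste("compartment", id, map$compartments[[id]]))
  for (e in map$epns) {
    rec <- c("epn", e$id, e$epn_class)
    if (nzchar(e$label)) rec <- c(rec, paste0("label=", e$label))
    if (!is.na(e$compartment))
      rec <- c(rec, paste0("compartment=", e$compartment))
    if (length(e$components))
      rec <- c(rec, paste0("components=", paste(e$components, collapse = ";")))
    if (length(e$state_vars))
      rec <- c(rec, paste0("state=",
                           paste(gsub("=", ":", e$state_vars), collapse = ";")))
    if (e$is_clone) rec <- c(rec, "clone")
    out <- c(out, paste(rec, collapse = " "))
  }
  for (p in map$processes) {
    out <- c(out, paste("process", p$id, p$process_class))
    for (e in p$reactants) out <- c(out, paste("consume", p$id, e))
    if (p$has_source_reactant) out <- c(out, paste("consume", p$id, "SOURCE"))
    for (e in p$products) out <- c(out, paste("produce", p$id, e))
    if (p$has_sink_product) out <- c(out, paste("produce", p$id, "SINK"))
  }
  for (op in map$operators)
    out <- c(out, paste("operator", op$id, op$kind,
                        paste(op$inputs, collapse = " ")))
  for (m in map$modulations)
    out <- c(out, paste("modulate", m$class, m$origin, m$target))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
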