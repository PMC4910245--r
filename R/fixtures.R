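# Worked-example builders and a seeded random-map generator for the
# property suites.

WORKED_EXAMPLE_TEXT <- "
epn a macromolecule label=a
epn aP macromolecule label=a state=site:P
epn atp simple-chemical label=atp
epn adp simple-chemical label=adp
epn b macromolecule label=b
epn c complex label=c components=a;b
epn m macromolecule label=m
process p process
consume p a
consume p atp
produce p aP
produce p adp
process q association
consume q a
consume q b
produce q c
modulate stimulation m p
"

TOY_CHAIN_ASSOC_TEXT <- "
epn A macromolecule label=A
epn B macromolecule label=B
epn C macromolecule label=C
epn D macromolecule label=D
process p1 process
consume p1 A
produce p1 B
process p2 association
consume p2 B
consume p2 C
produce p2 D
"

TOY_TRANSFORM_ASSOC_TEXT <- "
epn A macromolecule label=A
epn B macromolecule label=B
epn C macromolecule label=C
process p1 process
consume p1 A
produce p1 B
process p2 association
consume p2 A
consume p2 B
produce p2 C
"

# Reduced rendition of a 7TM-receptor / ERK activation topology: a receptor
# that is phosphorylated and then sequestered by either of two beta-arrestins,
# next to simple two-state signalling chains (G protein, PIP2/DAG, PKC, ERK).
# Used for qualitative regression of the alternative between one
# receptor-focused story and two beta-arrestin stories.
AT1AR_SKELETON_TEXT <- "
epn HR macromolecule label=HR
epn HRp macromolecule label=HR state=s1:P
epn HRb1 complex label=HRb1 components=HR;barr1
epn HRb2 complex label=HRb2 components=HR;barr2
epn barr1 macromolecule label=barr1
epn barr2 macromolecule label=barr2
epn G macromolecule label=G
epn Ga macromolecule label=G state=s:a
epn PIP2 simple-chemical label=PIP2
epn DAG simple-chemical label=DAG
epn PKC macromolecule label=PKC
epn PKCa macromolecule label=PKC state=s:a
epn ERK macromolecule label=ERK
epn ERKp macromolecule label=ERK state=s:P
process ph process
consume ph HR
produce ph HRp
process a1 association
consume a1 HRp
consume a1 barr1
produce a1 HRb1
process a2 association
consume a2 HRp
consume a2 barr2
produce a2 HRb2
process gact process
consume gact G
produce gact Ga
modulate stimulation HRp gact
process plc process
consume plc PIP2
produce plc DAG
modulate catalysis Ga plc
process pkc process
consume pkc PKC
produce pkc PKCa
modulate stimulation DAG pkc
process erk process
consume erk ERK
produce erk ERKp
modulate catalysis PKCa erk
"

#' Built-in fixture maps and networks
#'
#' * `fig2_an`: a small hand-written automata network (three automata `a`,
#'   `b`, `c` with 3/2/2 local states and four guarded transitions) used to
#'   exercise the asynchronous semantics directly;
#' * `worked_example`: the two-process map with EPNs
#'   `a, aP, atp, adp, b, c, m` — a phosphorylation `a + atp -> aP + adp`
#'   stimulated by `m`, and an association `a + b -> c`; the conventional
#'   initial present set is `a, atp, b, m`;
#' * `toy_chain_assoc`: `A -> B`, `B + C -> D`;
#' * `toy_transform_assoc`: `A -> B`, `A + B -> C`;
#' * `at1ar_skeleton`: a reduced receptor/beta-arrestin/ERK topology for
#'   qualitative story-set regression.
#'
#' @param name fixture name.
#' @return a [pd_map()], or an [automata_network()] for `fig2_an`.
#' @export
fixture <- function(name = c("worked_example", "fig2_an", "toy_chain_assoc",
                             "toy_transform_assoc", "at1ar_skeleton")) {
  name <- match.arg(name)
  if (name == "fig2_an") {
    return(automata_network(
      automata = list(a = c("0", "1", "2"), b = c("0", "1"),
                      c = c("0", "1")),
      transitions = list(
        list(automaton = "a", from = "0", to = "1", cond = c(b = "1"),
             tag = "fixture"),
        list(automaton = "a", from = "1", to = "2", cond = c(c = "1"),
             tag = "fixture"),
        list(automaton = "b", from = "1", to = "0",
             cond = c(a = "0", c = "0"), tag = "fixture"),
        list(automaton = "c", from = "0", to = "1", cond = c(a = "1"),
             tag = "fixture"))))
  }
  txt <- switch(name,
                worked_example = WORKED_EXAMPLE_TEXT,
                toy_chain_assoc = TOY_CHAIN_ASSOC_TEXT,
                toy_transform_assoc = TOY_TRANSFORM_ASSOC_TEXT,
                at1ar_skeleton = AT1AR_SKELETON_TEXT)
  read_pd_text(txt)
}

#' The worked example's conventional initial present set
#' @export
worked_example_initial <- function() c("a", "atp", "b", "m")

#' The worked example's two stories
#'
#' The final set of two stories used throughout: the protein story
#' `{a, aP, c}` (free, phosphorylated, bound to `b`) and the nucleotide
#' story `{adp, atp}`.
#'
#' @return a [story_set()] named `s` and `t`.
#' @export
worked_example_stories <- function()
  story_set(list(s = c("a", "aP", "c"), t = c("adp", "atp")),
            map = fixture("worked_example"))

#' Seeded random SBGN-PD map generator
#'
#' Generates structurally valid maps for property tests: every process has
#' at least one flux arc or a source/sink flag, logical-operator inputs are
#' acyclic, and identical parameters plus seed give identical maps. The
#' caller's RNG state is left untouched.
#'
#' @param n_epns,n_processes sizes.
#' @param mod_density expected number of modulation arcs per process.
#' @param p_operator probability that a modulation origin is a two-input
#'   AND/OR operator rather than a single EPN.
#' @param p_generic probability that a modulation arc is a generic
#'   `modulation` (ignored by the semantics).
#' @param p_source,p_sink probability of a source reactant / sink product
#'   flag on a process.
#' @param seed integer seed.
#' @return a [pd_map()].
#' @export
random_map <- function(n_epns, n_processes, mod_density = 0.5,
                       p_operator = 0, p_generic = 0, p_source = 0.15,
                       p_sink = 0.15, seed = 1L) {
  stopifnot(n_epns >= 1L, n_processes >= 0L)
  with_seed(seed, {
    eids <- sprintf("e%d", seq_len(n_epns))
    epns <- lapply(eids, function(id)
      epn(id, "macromolecule", label = id))
    procs <- list()
    ops <- list()
    mods <- list()
    op_n <- 0L
    for (i in seq_len(n_processes)) {
      pid <- sprintf("p%d", i)
      nr <- sample(0:2, 1L, prob = c(0.25, 0.5, 0.25))
      np <- sample(0:2, 1L, prob = c(0.25, 0.5, 0.25))
      reactants <- if (nr) sample(eids, min(nr, n_epns)) else character()
      products <- if (np) sample(eids, min(np, n_epns)) else character()
      src <- stats::runif(1) < p_source || length(reactants) == 0L
      snk <- stats::runif(1) < p_sink ||
        (length(products) == 0L && !src && length(reactants) == 0L)
      procs[[pid]] <- process_node(
        pid, sample(c("process", "association", "dissociation"), 1L),
        reactants, products,
        has_source_reactant = src && length(reactants) == 0L,
        has_sink_product = snk && length(products) == 0L)
      n_mods <- stats::rpois(1, mod_density)
      for (j in seq_len(n_mods)) {
        cls <- sample(c("stimulation", "catalysis", "inhibition",
                        "necessary-stimulation"), 1L)
        if (stats::runif(1) < p_generic) cls <- "modulation"
        if (stats::runif(1) < p_operator && n_epns >= 2L) {
          op_n <- op_n + 1L
          oid <- sprintf("op%d", op_n)
          ops[[oid]] <- operator_node(oid, sample(c("AND", "OR"), 1L),
                                      sample(eids, 2L))
          origin <- oid
        } else origin <- sample(eids, 1L)
        mods[[length(mods) + 1L]] <-
          list(class = cls, origin = origin, target = pid)
      }
    }
    pd_map(epns, unname(procs), unname(ops), mods)
  })
}
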