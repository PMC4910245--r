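fig2 <- fixture("fig2_an")
fig2_init <- c(a = "0", b = "1", c = "0")

test_that("asynchronous successors fire one conditioned transition at a time", {
  succ <- successors(fig2, fig2_init)
  keys <- sort(vapply(succ, function(x) state_key(x$state), character(1)))
  expect_equal(keys, c("a=0,b=0,c=0", "a=1,b=1,c=0"))
  # fixed point: no transition enabled
  expect_length(successors(fig2, c(a = "2", b = "1", c = "1")), 0)
  # a network with no transitions has no successors
  an0 <- automata_network(list(x = c("0", "1")))
  expect_length(successors(an0, c(x = "0")), 0)
  expect_error(successors(fig2, c(a = "0", b = "1")), "shape error")
})

test_that("the transition graph of the hand-written network has 5 states", {
  stg <- build_stg(fig2, fig2_init)
  expect_equal(n_states(stg), 5)
  # hand enumeration: <a0,b1,c0> -> <a1,b1,c0>, <a0,b0,c0>;
  # <a1,b1,c0> -> <a1,b1,c1> -> <a2,b1,c1>
  keys <- sort(vapply(stg$states, state_key, character(1)))
  expect_equal(keys, c("a=0,b=0,c=0", "a=0,b=1,c=0", "a=1,b=1,c=0",
                       "a=1,b=1,c=1", "a=2,b=1,c=1"))
})

test_that("exploration is capped with a loud error", {
  an <- encode(fixture("worked_example"))
  init <- initial_global_state(an, fixture("worked_example"),
                               worked_example_initial())
  expect_error(build_stg(an, init, cap = 10), "bounded-exploration")
  expect_error(is_reachable(an, init, c(zz = "1")), "unknown automaton")
})

test_that("attractors are the terminal strongly connected components", {
  stg <- build_stg(fig2, fig2_init)
  at <- attractors(stg)
  expect_length(at, 2)
  expect_true(all(vapply(at, `[[`, character(1), "kind") == "point"))
  fixed <- sort(vapply(at, function(a) state_key(a$states[[1]]),
                       character(1)))
  expect_equal(fixed, c("a=0,b=0,c=0", "a=2,b=1,c=1"))

  # a two-state cycle with no exits is one cyclic attractor
  osc <- automata_network(
    list(x = c("0", "1")),
    list(list(automaton = "x", from = "0", to = "1", cond = character()),
         list(automaton = "x", from = "1", to = "0", cond = character())))
  at2 <- attractors(build_stg(osc, c(x = "0")))
  expect_length(at2, 1)
  expect_equal(at2[[1]]$kind, "cyclic")
  expect_length(at2[[1]]$states, 2)

  # no edge leaves an attractor; every state reaches some attractor
  keys <- vapply(stg$states, state_key, character(1))
  att_keys <- unlist(lapply(at, function(a)
    vapply(a$states, state_key, character(1))))
  for (i in seq_len(nrow(stg$edges)))
    if (keys[stg$edges$from[i]] %in% att_keys)
      expect_true(keys[stg$edges$to[i]] %in% att_keys)
})

test_that("reachability answers partial-state queries on the fly", {
  expect_true(is_reachable(fig2, fig2_init, c(a = "2")))
  expect_false(is_reachable(fig2, fig2_init, c(a = "2", b = "0")))
  expect_true(is_reachable(fig2, fig2_init, character()))

  an <- encode(fixture("worked_example"))
  init <- initial_global_state(an, fixture("worked_example"),
                               worked_example_initial())
  # both aP and c can be produced, one after the other
  expect_true(is_reachable(an, init, c(aP = "1", c = "1")))
})

test_that("phase queries follow marker presence under both semantics", {
  map <- fixture("worked_example")
  st <- worked_example_stories()
  an_g <- encode(map)
  init_g <- initial_global_state(an_g, map, worked_example_initial())
  an_s <- encode(map, st)
  init_s <- initial_global_state(an_s, map, worked_example_initial(), st)

  ph_aP <- phase("phospho", "aP")
  ph_c <- phase("complexed", "c")
  expect_true(phase_reachable(an_g, init_g, ph_aP))
  expect_true(phase_reachable(an_s, init_s, ph_aP, st))
  expect_true(phase_reachable(an_s, init_s, ph_c, st))
  # empty marker set: empty disjunction
  expect_false(phase_reachable(an_g, init_g, phase("none", character())))
  # under the general semantics both phases co-occur; under the stories
  # semantics aP and c sit in one story automaton and are exclusive
  expect_true(phases_simultaneously_reachable(an_g, init_g, ph_aP, ph_c))
  expect_false(phases_simultaneously_reachable(an_s, init_s, ph_aP, ph_c, st))
})

test_that("disabling markers removes transitions through their state", {
  map <- fixture("worked_example")
  an <- encode(map)
  init <- initial_global_state(an, map, worked_example_initial())
  dis <- disable_markers(an, "aP")
  df <- an_transitions(dis)
  expect_equal(nrow(df[df$automaton == "aP", ]), 0)
  expect_false(phase_reachable(dis, init, phase("phospho", "aP")))
  # c stays reachable: only transitions through aP's present state are cut
  expect_true(phase_reachable(dis, init, phase("complexed", "c")))
  # disabling an untouched marker leaves the network unchanged
  an2 <- disable_markers(an, "m")
  df_m <- an_transitions(an2)
  expect_equal(nrow(df_m[df_m$automaton == "m", ]), 0)
  expect_identical(disable_markers(an2, "m"), an2)
  # story-member marker: transitions through the story state are removed
  st <- worked_example_stories()
  an_s <- encode(map, st)
  dis_s <- disable_markers(an_s, "aP", st)
  df_s <- an_transitions(dis_s)
  expect_equal(nrow(df_s[df_s$automaton == "s" &
                           (df_s$from == "aP" | df_s$to == "aP"), ]), 0)
})

test_that("the rule-based oracle interprets the four rules directly", {
  map <- fixture("worked_example")
  state <- list(
    epns = stats::setNames(names(map$epns) %in% worked_example_initial(),
                           names(map$epns)),
    processes = stats::setNames(rep(FALSE, 2), c("p", "q")))
  succ <- oracle_successors(map, state)
  # from the initial assignment only the two activations are possible
  expect_length(succ, 2)
  occs <- vapply(succ, function(s) names(which(s$processes)), character(1))
  expect_setequal(occs, c("p", "q"))

  # all-absent assignment without source processes: no successor
  none <- list(epns = stats::setNames(rep(FALSE, length(map$epns)),
                                      names(map$epns)),
               processes = stats::setNames(rep(FALSE, 2), c("p", "q")))
  expect_length(oracle_successors(map, none), 0)

  # a source process may start occurring from any state (empty reactant set)
  src_map <- read_pd_text("
    epn e macromolecule
    process syn process
    consume syn SOURCE
    produce syn e")
  s0 <- list(epns = c(e = FALSE), processes = c(syn = FALSE))
  succ2 <- oracle_successors(src_map, s0)
  expect_length(succ2, 1)
  expect_true(succ2[[1]]$processes[["syn"]])
})

test_that("encoded successors equal the oracle on seeded random maps", {
  set.seed(99)
  for (i in 1:60) {
    map <- random_map(n_epns = sample(2:6, 1), n_processes = sample(1:3, 1),
                      mod_density = 0.8, p_operator = 0.2, p_generic = 0.1,
                      seed = 7000 + i)
    an <- suppressWarnings(encode(map, shortcuts = FALSE))
    pres <- sample(c(TRUE, FALSE), length(map$epns), replace = TRUE)
    names(pres) <- names(map$epns)
    init <- initial_global_state(an, map, names(pres)[pres])
    stg <- build_stg(an, init, cap = 5000)
    for (j in seq_along(stg$states)) {
      osucc <- suppressWarnings(
        oracle_successors(map, an_to_oracle_state(map, stg$states[[j]])))
      want <- sort(vapply(osucc, function(s)
        state_key(oracle_to_an_state(s)), character(1)))
      got <- sort(unique(vapply(stg$states[stg$edges$to[stg$edges$from == j]],
                                state_key, character(1))))
      expect_identical(got, unname(want),
                       label = paste("map", i, "state", j))
    }
  }
})

test_that("STG construction is exploration-order independent", {
  map <- fixture("worked_example")
  an <- encode(map)
  init <- initial_global_state(an, map, worked_example_initial())
  ref <- build_stg(an, init)
  ref_states <- sort(vapply(ref$states, state_key, character(1)))
  ref_edges <- stg_edges(ref)
  ref_edge_keys <- sort(paste(ref_edges$from, "->", ref_edges$to))
  for (seed in c(1, 2, 3)) {
    alt <- build_stg(an, init, order_seed = seed)
    expect_equal(sort(vapply(alt$states, state_key, character(1))),
                 ref_states)
    alt_edges <- stg_edges(alt)
    expect_equal(sort(paste(alt_edges$from, "->", alt_edges$to)),
                 ref_edge_keys)
  }
})
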