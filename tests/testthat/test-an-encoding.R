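we_map <- fixture("worked_example")
we_stories <- worked_example_stories()

test_that("the general-semantics encoding of the worked example", {
  an <- encode(we_map)
  expect_length(an$automata, 9)
  expect_setequal(names(an$automata),
                  c("a", "aP", "atp", "adp", "b", "c", "m", "p", "q"))
  expect_true(all(lengths(an$automata) == 2))
  df <- an_transitions(an)
  act_p <- df[df$automaton == "p" & df$from == "0", ]
  expect_equal(act_p$cond, "a=1,atp=1,m=1")
  act_q <- df[df$automaton == "q" & df$from == "0", ]
  expect_equal(act_q$cond, "a=1,b=1")
  # consumption waits for all products, de-activation for done(p)
  cons_a_p <- df[df$automaton == "a" & df$process == "p", ]
  expect_equal(cons_a_p$cond, "aP=1,adp=1,p=1")
  deact <- df[df$automaton == "p" & df$from == "1", ]
  expect_equal(deact$cond, "aP=1,adp=1")
  # provenance tags cover every rule
  expect_setequal(unique(df$tag),
                  c("activation", "production", "consumption",
                    "deactivation"))
})

test_that("the stories-semantics encoding of the worked example", {
  an <- encode(we_map, we_stories)
  expect_length(an$automata, 6)
  expect_setequal(names(an$automata), c("s", "t", "b", "m", "p", "q"))
  expect_length(an$automata$s, 4)   # a, aP, c + empty
  expect_length(an$automata$t, 3)   # adp, atp + empty
  df <- an_transitions(an)
  # p # q: each activation requires the other process non-occurring
  act_p <- df[df$automaton == "p" & df$from == "0", ]
  expect_equal(act_p$cond, "m=1,q=0,s=a,t=atp")
  act_q <- df[df$automaton == "q" & df$from == "0", ]
  expect_equal(act_q$cond, "b=1,p=0,s=a")
  # story moves are conditioned on the occurring process only
  expect_true(nrow(df[df$automaton == "s" & df$from == "a" &
                        df$to == "aP" & df$cond == "p=1", ]) == 1)
  expect_true(nrow(df[df$automaton == "s" & df$from == "a" &
                        df$to == "c" & df$cond == "q=1", ]) == 1)
  expect_true(nrow(df[df$automaton == "t" & df$from == "atp" &
                        df$to == "adp" & df$cond == "p=1", ]) == 1)
  # non-story reactant b is consumed after q's products are done
  cons_b <- df[df$automaton == "b" & df$from == "1", ]
  expect_equal(cons_b$cond, "q=1,s=c")
})

test_that("shortcut cases embed conditions in EPN transitions", {
  m <- read_pd_text("
    epn e macromolecule
    epn g macromolecule
    process deg process
    consume deg e
    modulate stimulation g deg")
  an <- encode(m)
  expect_setequal(names(an$automata), c("e", "g"))   # no process automaton
  df <- an_transitions(an)
  expect_equal(nrow(df), 1)
  expect_equal(df$automaton, "e")
  expect_equal(df$from, "1")
  expect_equal(df$cond, "g=1")
  expect_equal(df$tag, "shortcut")

  # reactant-less process: one independent transition per product
  m2 <- read_pd_text("
    epn x macromolecule
    epn y macromolecule
    process syn process
    consume syn SOURCE
    produce syn x
    produce syn y")
  an2 <- encode(m2)
  expect_setequal(names(an2$automata), c("x", "y"))
  df2 <- an_transitions(an2)
  expect_equal(nrow(df2), 2)
  expect_true(all(df2$from == "0" & df2$to == "1" & df2$cond == ""))

  # single in/out within one story: a direct story move
  m3 <- read_pd_text("
    epn u macromolecule
    epn v macromolecule
    process t1 process
    consume t1 u
    produce t1 v")
  st3 <- story_set(list(w = c("u", "v")), map = m3)
  an3 <- encode(m3, st3)
  expect_equal(names(an3$automata), "w")
  df3 <- an_transitions(an3)
  expect_equal(nrow(df3), 1)
  expect_equal(df3$from, "u")
  expect_equal(df3$to, "v")

  # with shortcuts disabled all processes get automata
  an_f <- encode(m, shortcuts = FALSE)
  expect_setequal(names(an_f$automata), c("e", "g", "deg"))
})

test_that("encoding is deterministic", {
  k1 <- vapply(encode(we_map, we_stories)$transitions,
               sbgnq:::transition_key, character(1))
  k2 <- vapply(encode(we_map, we_stories)$transitions,
               sbgnq:::transition_key, character(1))
  expect_identical(k1, k2)
})

test_that("initial states follow the captioned conventions", {
  an <- encode(we_map)
  init <- initial_global_state(an, we_map, worked_example_initial())
  expect_equal(init,
               c(a = "1", aP = "0", adp = "0", atp = "1", b = "1", c = "0",
                 m = "1", p = "0", q = "0")[order(c("a", "aP", "adp", "atp",
                                                    "b", "c", "m", "p", "q"))])
  an_s <- encode(we_map, we_stories)
  init_s <- initial_global_state(an_s, we_map, worked_example_initial(),
                                 we_stories)
  expect_equal(unname(init_s[c("s", "t", "b", "m", "p", "q")]),
               c("a", "atp", "1", "1", "0", "0"))
  expect_error(
    initial_global_state(an_s, we_map, c("a", "aP"), we_stories),
    "initial-state conflict.*s")
  expect_error(initial_global_state(an, we_map, "ghost"), "unknown EPN")
})

test_that("stories states project onto the general semantics", {
  an_s <- encode(we_map, we_stories)
  init_s <- initial_global_state(an_s, we_map, worked_example_initial(),
                                 we_stories)
  proj <- project_state(init_s, we_map, we_stories)
  an_g <- encode(we_map)
  init_g <- initial_global_state(an_g, we_map, worked_example_initial())
  expect_equal(proj, init_g)
  # the empty story state projects to all members absent
  st_empty <- init_s
  st_empty["s"] <- "empty"
  proj2 <- project_state(st_empty, we_map, we_stories)
  expect_equal(unname(proj2[c("a", "aP", "c")]), c("0", "0", "0"))
  expect_error(project_state(init_s[-1], we_map, we_stories),
               "projection error")
})

test_that("add_local_transition validates and is idempotent", {
  an <- fixture("fig2_an")
  an2 <- add_local_transition(an, "c", "1", "0", c(b = "0"))
  expect_length(an2$transitions, length(an$transitions) + 1)
  expect_identical(add_local_transition(an2, "c", "1", "0", c(b = "0")),
                   an2)
  expect_error(add_local_transition(an, "c", "0", "1", c(c = "1")),
               "own automaton")
  expect_error(add_local_transition(an, "c", "0", "7"), "unknown local state")
  expect_error(add_local_transition(an, "zz", "0", "1"), "unknown automaton")
})

test_that("AN JSON serialization round trips losslessly", {
  for (an in list(fixture("fig2_an"), encode(we_map),
                  encode(we_map, we_stories))) {
    rt <- parse_an(serialize_an(an))
    expect_identical(rt$automata, an$automata)
    expect_identical(rt$transitions, an$transitions)
  }
  tmp <- tempfile(fileext = ".json")
  serialize_an(fixture("fig2_an"), tmp)
  expect_identical(parse_an(tmp)$transitions, fixture("fig2_an")$transitions)
})

test_that("PNML export has one place per local state and read-arc loops", {
  an <- fixture("fig2_an")   # 3 + 2 + 2 local states, 4 transitions
  doc <- export_pnml(an, initial = c(a = "0", b = "1", c = "0"))
  xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, ".//place"), 7)
  expect_length(xml2::xml_find_all(doc, ".//transition"), 4)
  # arcs: per transition 1 in + 1 out + 2 per condition state
  n_cond <- sum(lengths(lapply(an$transitions, `[[`, "cond")))
  expect_length(xml2::xml_find_all(doc, ".//arc"),
                2 * length(an$transitions) + 2 * n_cond)
  marks <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//place/initialMarking/text"))
  expect_equal(sum(marks == "1"), 3)
  ts <- xml2::xml_find_first(doc, ".//toolspecific")
  expect_equal(xml2::xml_attr(ts, "readarcs"), "self-loop-pairs")
  # empty network exports an empty net
  empty <- export_pnml(automata_network())
  xml2::xml_ns_strip(empty)
  expect_length(xml2::xml_find_all(empty, ".//place"), 0)
})

test_that("mutual exclusion of story EPNs holds in every reachable state", {
  an <- encode(we_map, we_stories)
  init <- initial_global_state(an, we_map, worked_example_initial(),
                               we_stories)
  stg <- build_stg(an, init)
  for (st in stg$states) {
    # a story automaton always has exactly one active state; the projection
    # therefore never shows two story EPNs present together
    proj <- project_state(st, we_map, we_stories)
    expect_lte(sum(proj[c("a", "aP", "c")] == "1"), 1)
    expect_lte(sum(proj[c("adp", "atp")] == "1"), 1)
  }
})

test_that("DOT renderings are produced", {
  an <- fixture("fig2_an")
  dot <- an_to_dot(an)
  expect_match(dot, "digraph an", fixed = TRUE)
  expect_match(dot, "a.0", fixed = TRUE)
  stg <- build_stg(an, c(a = "0", b = "1", c = "0"))
  expect_match(stg_to_dot(stg), "digraph stg", fixed = TRUE)
})
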