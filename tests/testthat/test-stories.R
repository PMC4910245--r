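test_that("check_story evaluates the constraints on the printed toys", {
  m <- fixture("toy_transform_assoc")   # A -> B, A + B -> C
  expect_true(check_story(m, c("A", "C"))$ok)
  v_bc <- check_story(m, c("B", "C"))
  expect_false(v_bc$ok)
  expect_true("ii" %in% v_bc$violations)
  v_ab <- check_story(m, c("A", "B"))
  expect_false(v_ab$ok)
  expect_true("iii" %in% v_ab$violations)
  expect_error(check_story(m, c("A", "ghost")), "unknown EPN")

  m2 <- fixture("toy_chain_assoc")      # A -> B, B + C -> D
  expect_false(check_story(m2, c("A", "D"))$ok)    # no in-story flux path
  expect_true("i" %in% check_story(m2, c("A", "D"))$violations)
  expect_true("too-small" %in% check_story(m2, "A")$violations)
})

test_that("the label constraint accepts complex-member labels", {
  m <- fixture("worked_example")
  expect_true(check_story(m, c("a", "aP", "c"), label_constraint = TRUE)$ok)
  expect_true("v" %in%
    check_story(m, c("adp", "atp"), label_constraint = TRUE)$violations)
})

test_that("enumeration matches the printed toy inventories", {
  expect_equal(enumerate_stories(fixture("toy_transform_assoc")),
               list(c("A", "C")), ignore_attr = TRUE)
  sts <- enumerate_stories(fixture("toy_chain_assoc"))
  expect_setequal(vapply(sts, paste, character(1), collapse = "+"),
                  c("A+B", "A+B+D", "C+D"))
  expect_equal(length(enumerate_stories(pd_map())), 0)
})

test_that("enumeration agrees with brute-force subset filtering", {
  set.seed(5)
  for (i in 1:12) {
    map <- random_map(n_epns = sample(3:7, 1), n_processes = sample(2:4, 1),
                      seed = 300 + i)
    got <- enumerate_stories(map)
    want <- brute_force_stories(map)
    expect_equal(unclass(got), want, ignore_attr = TRUE,
                 label = paste("map", i))
  }
  # and with the label constraint on a map with shared labels
  m <- fixture("worked_example")
  expect_equal(unclass(enumerate_stories(m, label_constraint = TRUE)),
               brute_force_stories(m, label_constraint = TRUE),
               ignore_attr = TRUE)
})

test_that("invalid seeds are rejected with their violations", {
  m <- fixture("toy_chain_assoc")
  expect_error(enumerate_stories(m, seeds = list(c("B", "C"))),
               "invalid seed")
  ok <- enumerate_stories(m, seeds = list(c("A", "B")))
  expect_equal(attr(ok, "seeds"), list(c("A", "B")))
})

test_that("maximally valid, final and epn-maximal sets on the toys", {
  sts <- enumerate_stories(fixture("toy_chain_assoc"))
  mv <- maximal_valid_sets(sts)
  expect_length(mv, 2)
  sigs <- lapply(mv, function(s) unname(s$stories))
  expect_true(any(vapply(sigs, identical, logical(1),
                         y = list(c("A", "B"), c("C", "D")))))
  expect_true(any(vapply(sigs, identical, logical(1),
                         y = list(c("A", "B", "D")))))
  # both maximal sets are final (neither story-wise dominates the other)
  fin <- final_sets(mv)
  expect_length(fin, 2)
  # only {{A,B},{C,D}} attains the maximum of 4 EPNs
  em <- epn_maximal_sets(mv)
  expect_length(em, 1)
  expect_equal(unname(em[[1]]$stories), list(c("A", "B"), c("C", "D")))

  # single candidate story
  one <- maximal_valid_sets(list(c("A", "C")))
  expect_length(one, 1)
  expect_length(epn_maximal_sets(one), 1)
})

test_that("maximal independent sets match the igraph cross-check", {
  for (nm in c("toy_chain_assoc", "worked_example", "at1ar_skeleton")) {
    sts <- enumerate_stories(fixture(nm))
    if (length(sts) == 0) next
    mine <- lapply(maximal_valid_sets(sts), function(s) unname(s$stories))
    n <- length(sts)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      if (length(intersect(sts[[i]], sts[[j]])))
        g <- igraph::add_edges(g, c(i, j))
    ref <- lapply(igraph::max_ivs(g), function(vs) {
      picks <- sts[as.integer(vs)]
      picks[order(vapply(picks, paste, character(1), collapse = "+"))]
    })
    key <- function(set) paste(vapply(set, paste, character(1),
                                      collapse = "+"), collapse = " / ")
    expect_setequal(vapply(mine, key, character(1)),
                    vapply(ref, key, character(1)))
  }
})

test_that("epn-maximal implies final implies maximally valid on fixtures", {
  for (nm in c("toy_chain_assoc", "toy_transform_assoc", "worked_example",
               "at1ar_skeleton")) {
    sts <- enumerate_stories(fixture(nm))
    if (length(sts) == 0) next
    mv <- maximal_valid_sets(sts)
    fin <- final_sets(mv)
    em <- epn_maximal_sets(mv)
    key <- function(s) paste(names(s$stories), collapse = " / ")
    expect_true(all(vapply(fin, key, character(1)) %in%
                      vapply(mv, key, character(1))), label = nm)
    expect_true(all(vapply(em, key, character(1)) %in%
                      vapply(fin, key, character(1))), label = nm)
  }
})

test_that("the worked example admits the final set of two stories", {
  sts <- enumerate_stories(fixture("worked_example"))
  mv <- maximal_valid_sets(sts)
  has_both <- vapply(mv, function(s)
    any(vapply(s$stories, identical, logical(1), y = c("a", "aP", "c"))) &&
      any(vapply(s$stories, identical, logical(1), y = c("adp", "atp"))),
    logical(1))
  expect_true(any(has_both))
})

test_that("receptor story and arrestin stories are alternative final sets", {
  m <- fixture("at1ar_skeleton")
  sts <- enumerate_stories(m)
  fin <- final_sets(maximal_valid_sets(sts))
  receptor <- c("HR", "HRb1", "HRb2", "HRp")
  has_receptor <- vapply(fin, function(s)
    any(vapply(s$stories, identical, logical(1), y = receptor)), logical(1))
  has_arrestins <- vapply(fin, function(s)
    any(vapply(s$stories, identical, logical(1), y = c("HRb1", "barr1"))) &&
      any(vapply(s$stories, identical, logical(1), y = c("HRb2", "barr2"))),
    logical(1))
  expect_true(any(has_receptor))
  expect_true(any(has_arrestins))
  expect_false(any(has_receptor & has_arrestins))
})

test_that("the conflict relation is exactly shared-story pairs", {
  m <- fixture("worked_example")
  cr <- conflict_relation(m, worked_example_stories())
  expect_equal(cr, data.frame(p = "p", q = "q", stringsAsFactors = FALSE))
  expect_equal(nrow(conflict_relation(m, story_set())), 0)
  # disjoint stories touched by different processes do not conflict
  m2 <- fixture("toy_chain_assoc")
  cr2 <- conflict_relation(m2, story_set(list(c("A", "B"), c("C", "D")),
                                         map = m2))
  # p1 touches {A,B}; p2 touches both stories: only pairs sharing a story
  expect_equal(cr2, data.frame(p = "p1", q = "p2", stringsAsFactors = FALSE))
  m3 <- fixture("at1ar_skeleton")
  st3 <- story_set(list(c("G", "Ga"), c("PIP2", "DAG")), map = m3)
  expect_equal(nrow(conflict_relation(m3, st3)), 0)
})

test_that("story sets serialize to JSON and TSV summaries", {
  mv <- maximal_valid_sets(enumerate_stories(fixture("toy_chain_assoc")))
  tmp_json <- tempfile(fileext = ".json")
  tmp_tsv <- tempfile(fileext = ".tsv")
  res <- write_story_sets(mv, tmp_json, tmp_tsv)
  parsed <- jsonlite::fromJSON(tmp_json, simplifyVector = FALSE)
  expect_length(parsed, 2)
  expect_true(all(vapply(parsed, function(x) isTRUE(x$flags$valid),
                         logical(1))))
  expect_equal(sum(vapply(parsed, function(x) isTRUE(x$flags$epn_maximal),
                          logical(1))), 1)
  df <- utils::read.delim(tmp_tsv)
  expect_equal(nrow(df), 2)
  expect_equal(sum(df$epn_maximal), 1)
})
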