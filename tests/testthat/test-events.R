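two_area <- area_scheme(c("A", "B"), focal = "A", max_range_size = 2)

fake_anc <- function(map) {
  structure(list(map = map, prob = NULL), class = "ancestral_range_table")
}

test_that("the two event rules classify a hand-worked tree correctly", {
  tr <- tree_from_newick("((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  n <- length(tr$tip.label)
  tips <- coding_table(c(a = "A", b = "A", c = "B", d = "B"), c("A", "B"))
  # internal preorder: root (5), anc(a,b) (6), anc(c,d) (7)
  anc <- fake_anc(setNames(c("B", "A", "B"), 5:7))
  ev <- classify_events(tr, anc, tips, two_area)
  expect_equal(nrow(ev), 2L)
  disp <- ev[ev$event_type == "dispersal_in", ]
  expect_equal(disp$node_id, 6L)          # gain on the edge root -> anc(a,b)
  expect_equal(disp$point_age, 1.0)
  expect_equal(c(disp$older, disp$younger), c(2.0, 1.0))  # no-HPD fallback
  ins <- ev[ev$event_type == "in_situ", ]
  expect_equal(ins$node_id, 6L)           # anc(a,b) and both children focal
  expect_true(all(diff(ev$point_age) <= 0))  # sorted old -> young
  # no focal area anywhere -> empty table
  tips_b <- coding_table(c(a = "B", b = "B", c = "B", d = "B"), c("A", "B"))
  anc_b <- fake_anc(setNames(c("B", "B", "B"), 5:7))
  expect_equal(nrow(classify_events(tr, anc_b, tips_b, two_area)), 0L)
  # a missing MAP is fatal
  expect_error(classify_events(tr, fake_anc(setNames(c("B", "A"), 5:6)),
                               tips, two_area), "MAP")
})

test_that("event timing uses HPD bounds with point-age fallback", {
  tr <- tree_from_newick("((a:9,b:9):1.2,c:10.2);")
  # tips 1-3, root = 4 (age 10.2), anc(a,b) = 5 (age 9.0)
  tr$hpd[4, ] <- c(10.50, 8.00)
  tr$hpd[5, ] <- c(9.80, 9.10)
  tm <- attach_timing(list(event_type = "dispersal_in", node_id = 5L), tr)
  expect_equal(tm$point_age, 9.0)
  expect_equal(c(tm$older, tm$younger), c(10.50, 9.10))
  tm2 <- attach_timing(list(event_type = "in_situ", node_id = 5L), tr)
  expect_equal(c(tm2$older, tm2$younger), c(9.80, 9.10))
  tr$hpd[5, ] <- NA
  tm3 <- attach_timing(list(event_type = "dispersal_in", node_id = 5L), tr)
  expect_equal(c(tm3$older, tm3$younger), c(10.50, 9.0))
  tr$hpd[4, ] <- NA
  tm4 <- attach_timing(list(event_type = "in_situ", node_id = 5L), tr)
  expect_equal(c(tm4$older, tm4$younger), c(9.0, 9.0))  # degenerate fallback
})

test_that("source regions come from unambiguous non-focal parent ranges", {
  sch13 <- area_scheme(LETTERS[1:13], "A", 2)
  tr <- tree_from_newick("((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  tips13 <- coding_table(c(a = "A", b = "AG", c = "G", d = "DF"),
                         LETTERS[1:13])
  anc13 <- fake_anc(setNames(c("G", "G", "DF"), 5:7))
  ev <- event_table(data.frame(
    clade_id = "test", event_type = "dispersal_in",
    node_id = c(6L, 4L), point_age = c(1, 0),
    older = c(2, 1.5), younger = c(1, 0), source_region = "",
    stringsAsFactors = FALSE))
  got <- assign_sources(ev, tr, anc13, tips13, sch13)
  expect_equal(got$source_region[got$node_id == 6L], "G")   # singleton parent
  expect_equal(got$source_region[got$node_id == 4L], "")    # {D,F} ambiguous
  # a parent range that already includes the focal area still resolves
  anc13b <- fake_anc(setNames(c("AG", "G", "DF"), 5:7))
  got2 <- assign_sources(ev, tr, anc13b, tips13, sch13)
  expect_equal(got2$source_region[got2$node_id == 6L], "G")
})

test_that("tally reproduces the reference arithmetic shape", {
  mk <- function(n_disp, n_ins, src = character(0)) {
    n <- n_disp + n_ins
    event_table(data.frame(
      clade_id = "pool", node_id = seq_len(n),
      event_type = rep(c("dispersal_in", "in_situ"), c(n_disp, n_ins)),
      point_age = seq(10, 0.1, length.out = n),
      older = seq(10, 0.1, length.out = n) + 0.2,
      younger = pmax(0, seq(10, 0.1, length.out = n) - 0.2),
      source_region = c(src, rep("", n - length(src))),
      stringsAsFactors = FALSE))
  }
  tl <- tally(mk(105, 26, c(rep("G", 14), rep("D", 12))))
  expect_equal(tl$n_total, 131L)
  expect_equal(round(tl$ratio, 2), 4.04)
  expect_equal(round(tl$ratio), 4)
  expect_equal(tl$n_source_assigned, 26L)
  expect_equal(round(unname(tl$source_pct["G"]), 1), 53.8)
  txt <- format_tally(tl)
  expect_match(txt, "131 total")
  expect_match(txt, "53.8%")
  # empty table: zeros and an undefined-ratio flag
  tl0 <- tally(event_table())
  expect_equal(tl0$n_total, 0L)
  expect_false(tl0$ratio_defined)
})

test_that("classification on true simulated ranges matches the simulator log", {
  sch <- area_scheme(c("A", "B"), "A", 2)
  for (r in 1:10) {
    tr <- simulate_tree(0.4, 0.1, 25, seed = 300 + r)
    sim <- simulate_ranges(tr, sch, dec_params(0.15, 0.03), "B",
                           seed = 400 + r)
    ev <- classify_events(sim$tree, sim$anc_true, sim$coding, sch)
    for (ty in c("dispersal_in", "in_situ"))
      expect_setequal(ev$node_id[ev$event_type == ty],
                      sim$true_events$node_id[sim$true_events$event_type == ty])
  }
})

test_that("event counts are invariant to area permutations fixing the focal area", {
  sch3 <- area_scheme(c("A", "B", "C"), "A", 2)
  tr <- simulate_tree(0.4, 0, 20, seed = 77)
  sim <- simulate_ranges(tr, sch3, dec_params(0.15, 0.01), "B", seed = 78)
  ev <- classify_events(sim$tree, sim$anc_true, sim$coding, sch3)
  # swap B and C everywhere; A (focal) fixed
  perm_codes <- chartr("BC", "CB", setNames(sim$coding$code, sim$coding$species))
  perm_map <- vapply(sim$anc_true$map, function(s)
    paste(sort(strsplit(chartr("BC", "CB", s), "")[[1]]), collapse = ""), "")
  ev2 <- classify_events(sim$tree, fake_anc(perm_map),
                         coding_table(perm_codes, c("A", "B", "C")), sch3)
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(ev2$node_id, ev$node_id)
  # every in-situ interval lies within [root age, 0]
  root_age <- sim$tree$age[length(sim$tree$tip.label) + 1L]
  ins <- ev[ev$event_type == "in_situ", ]
  expect_true(all(ins$older <= root_age + 1e-9 & ins$younger >= 0))
})
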