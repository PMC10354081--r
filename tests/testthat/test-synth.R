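test_that("birth-death simulation is seeded, conditioned and ultrametric", {
  tr <- simulate_tree(1, 0, 2, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(tr$Nnode, 1L)
  tr_a <- simulate_tree(0.5, 0.2, 15, seed = 7)
  tr_b <- simulate_tree(0.5, 0.2, 15, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_dated_tree(tr_a, f1); write_dated_tree(tr_b, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  n <- length(tr_a$tip.label)
  expect_equal(tr_a$age[seq_len(n)], rep(0, n))  # extant tips at the present
  expect_error(simulate_tree(0.1, 0.2, 10), "birth > death")
})

test_that("mean crown age matches the pure-birth expectation", {
  ages <- vapply(1:500, function(s) {
    tr <- simulate_tree(1, 0, 10, seed = s)
    tr$age[length(tr$tip.label) + 1L]
  }, 0)
  expected <- sum(1 / (2:10))  # sum_{i=2..n} 1/(i * lambda), lambda = 1
  expect_lt(abs(mean(ages) - expected) / expected, 0.15)
})

test_that("forward DEC simulation respects zero rates and blocked dispersal", {
  sch <- area_scheme(c("A", "B"), "A", 2)
  tr <- simulate_tree(0.5, 0, 15, seed = 11)
  sim0 <- simulate_ranges(tr, sch, dec_params(0, 0), "B", seed = 1)
  expect_true(all(sim0$coding$code == "B"))
  expect_equal(nrow(sim0$true_events), 0L)
  expect_equal(nrow(sim0$gain_log), 0L)
  # multipliers forbid any expansion into the focal area
  m <- matrix(1, 2, 2); m[2, 1] <- 0   # B -> A blocked
  schb <- area_scheme(c("A", "B"), "A", 2, multipliers = list(m))
  for (r in 1:20) {
    simb <- simulate_ranges(simulate_tree(0.5, 0, 10, seed = 700 + r),
                            schb, dec_params(0.3, 0.05), "B", seed = r)
    expect_equal(sum(simb$true_events$event_type == "dispersal_in"), 0L)
  }
  expect_error(simulate_ranges(tr, sch, dec_params(0.1, 0), "AZ", seed = 1))
})

test_that("event ensembles respect the intensity support and expectation", {
  sc <- sim_scenario(seed = 3)
  ev <- simulate_event_ensemble(sc, seed = 3)
  expect_lte(max(ev$point_age), sc$breaks[1])
  expect_true(all(ev$younger >= 0 & ev$older >= ev$point_age &
                  ev$younger <= ev$point_age))
  counts <- vapply(1:200, function(s)
    nrow(simulate_event_ensemble(sc, seed = s)), 0)
  mu <- expected_event_count(sc)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se + 1e-9)
  # same seed reproduces the table exactly
  expect_identical(simulate_event_ensemble(sc, seed = 42),
                   simulate_event_ensemble(sc, seed = 42))
  # piecewise-constant shape draws only inside its support too
  scc <- sim_scenario(shape = "constant", rates = c(1.5, 5.5, 45, 30))
  evc <- simulate_event_ensemble(scc, seed = 5)
  expect_lte(max(evc$point_age), scc$breaks[1])
  expect_warning(
    simulate_event_ensemble(sim_scenario(rates = c(0, 0, 0, 0, 0))),
    "zero")
})

test_that("the dispersal-to-in-situ mix approaches the configured 105:26", {
  sc <- sim_scenario(seed = 8)
  ev <- simulate_event_ensemble(sc, seed = 8, intensity_scale = 30)
  tl <- tally(ev)
  expect_gt(tl$ratio, 3.4)
  expect_lt(tl$ratio, 4.8)
  # dominant source region is G among assigned dispersals
  expect_equal(names(tl$source_counts)[1], "G")
})

test_that("habitat simulation matches the two-state transition law", {
  tr <- tree_from_newick("(a:1,b:1);")
  sim0 <- simulate_habitats(tr, c(0, 0), "closed", seed = 4)
  expect_true(all(sim0$coding == "closed"))
  expect_identical(simulate_habitats(tr, c(0.3, 0.1), seed = 9),
                   simulate_habitats(tr, c(0.3, 0.1), seed = 9))
  # long-branch transition frequency vs the closed-form P matrix
  long <- tree_from_newick("(a:6,b:6);")
  rates <- c(0.25, 0.25)
  flips <- vapply(1:300, function(s)
    sum(simulate_habitats(long, rates, "open", seed = s)$coding == "closed"),
    0)
  p_expected <- 0.5 * (1 - exp(-sum(rates) * 6))
  p_hat <- mean(flips) / 2
  se <- sqrt(p_expected * (1 - p_expected) / 600)
  expect_lt(abs(p_hat - p_expected), 4 * se)
})

test_that("dense ensembles let the pipeline recover every intensity kink", {
  # High event density is the identifiability regime for trend change
  # points: overlap counting correlates neighbouring slices, so the
  # BIC-selected k may be 3 or 4, but the selected breakpoints must cover
  # each true kink (7.2, 2.6, 0.6 Ma) within 0.5 Ma.
  sc <- sim_scenario(rates = c(0.5, 0.5, 12, 54, 30),
                     rel_width = 0.02, min_width = 0.1)
  ok <- 0; n_rep <- 30
  for (r in seq_len(n_rep)) {
    ev <- simulate_event_ensemble(sc, seed = 9000 + r, intensity_scale = 30)
    cv <- mde_curve(ev)
    cp <- select_changepoints(cv$mid, cv$smoothed, seed = r)
    covered <- all(vapply(c(0.6, 2.6, 7.2), function(tr0)
      min(abs(cp$best$psi - tr0)) < 0.5, logical(1)))
    if (cp$best$k %in% 3:4 && covered) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * n_rep)
})
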