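two_area <- area_scheme(c("A", "B"), focal = "A", max_range_size = 2)
three_area <- area_scheme(c("A", "B", "C"), focal = "A", max_range_size = 3)

test_that("state space enumerates bounded non-empty subsets deterministically", {
  ss <- build_state_space(two_area)
  expect_equal(ss$labels, c("", "A", "B", "AB"))
  expect_equal(ss$observable, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(sum(build_state_space(three_area)$observable), 7L)  # 2^3 - 1
  ss13 <- build_state_space(area_scheme(LETTERS[1:13], "A", 2))
  expect_equal(sum(ss13$observable), choose(13, 1) + choose(13, 2))  # 91
  expect_error(area_scheme(c("A", "B"), "A", 3), "max_range_size")
})

test_that("anagenetic rates follow the expansion/extirpation formulas", {
  ss <- build_state_space(two_area)
  Q <- anagenetic_rate_matrix(ss, dec_params(0.1, 0.05))
  expect_equal(Q["A", "AB"], 0.1)
  expect_equal(Q["AB", "A"], 0.05)
  expect_equal(unname(Q["A", 1]), 0.05)  # singleton decays to the null range
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  expect_true(all(anagenetic_rate_matrix(ss, dec_params(0, 0)) == 0))
  # a zero multiplier blocks expansion from that source area only
  m <- matrix(1, 2, 2); m[1, 2] <- 0   # A -> B blocked
  sch <- area_scheme(c("A", "B"), "A", 2, multipliers = list(m))
  Qm <- anagenetic_rate_matrix(build_state_space(sch), dec_params(0.1, 0))
  expect_equal(Qm["A", "AB"], 0)
  expect_equal(Qm["B", "AB"], 0.1)
  expect_error(anagenetic_rate_matrix(ss, list(d = -1, e = 0)), "non-negative")
})

test_that("transition matrices are stochastic for random rates", {
  ss <- build_state_space(three_area)
  set.seed(7)
  for (i in 1:5) {
    Q <- anagenetic_rate_matrix(ss, dec_params(runif(1, 0, 1), runif(1, 0, 0.5)))
    P <- as.matrix(Matrix::expm(Q * runif(1, 0.1, 10)))
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
    expect_true(all(P >= -1e-12))
  }
})

test_that("cladogenesis scenarios have equal ordered weights summing to one", {
  ss <- build_state_space(two_area)
  d1 <- cladogenesis_distribution("A", ss)
  expect_equal(d1, data.frame(left = "A", right = "A", prob = 1))
  d2 <- cladogenesis_distribution("AB", ss)
  expect_equal(nrow(d2), 6L)
  expect_true(all(d2$prob == 1 / 6))
  got <- paste(d2$left, d2$right, sep = "|")
  expect_setequal(got, c("A|AB", "B|AB", "AB|A", "AB|B", "A|B", "B|A"))
  # every observable parent in a large scheme sums to 1
  ss13 <- build_state_space(area_scheme(LETTERS[1:13], "A", 2))
  for (lbl in sample(ss13$labels[ss13$observable], 8))
    expect_equal(sum(cladogenesis_distribution(lbl, ss13)$prob), 1)
  expect_error(cladogenesis_distribution("", ss), "null")
})

test_that("cherry likelihoods match hand enumeration", {
  cherry <- tree_from_newick("(a:1,b:1);")
  sch <- two_area
  # tips {A},{B}, d=e=0: only the vicariance outcome is possible, weight 1/3
  ll <- dec_loglik(cherry, coding_table(c(a = "A", b = "B"), c("A", "B")),
                   sch, dec_params(0, 0))
  expect_equal(exp(ll$root_loglik), c(0, 0, 0, 1 / 3))
  # tips {A},{A}: sympatric inheritance is certain
  ll2 <- dec_loglik(cherry, coding_table(c(a = "A", b = "A"), c("A", "B")),
                    sch, dec_params(0, 0))
  expect_equal(exp(ll2$root_loglik)[2], 1)
  expect_error(
    dec_loglik(cherry, coding_table(c(a = "A"), c("A", "B")), sch,
               dec_params(0, 0)),
    "b")
})

test_that("pruning likelihood and marginals match brute-force enumeration", {
  newicks <- c("((a:1,b:1):1,(c:1.5,d:1.5):0.5);",
               "(((a:0.5,b:0.5):1,c:1.5):1,(d:2,e:2):0.5);")
  params <- list(c(0.3, 0.1), c(0.08, 0.02))
  codes_sets <- list(
    c(a = "A", b = "AB", c = "B", d = "C"),
    c(a = "A", b = "B", c = "BC", d = "C", e = "AC"))
  for (i in 1:2) {
    tr <- tree_from_newick(newicks[i])
    codes <- codes_sets[[i]][tr$tip.label]
    for (p in params) {
      for (bnd in list(numeric(0), 1.2)) {
        mult <- if (length(bnd)) list(matrix(1, 3, 3),
                                      matrix(0.5, 3, 3)) else NULL
        sch <- area_scheme(c("A", "B", "C"), "A", 3,
                           slice_boundaries = bnd, multipliers = mult)
        got <- dec_loglik(tr, coding_table(codes, c("A", "B", "C")), sch,
                          dec_params(p[1], p[2]))
        ora <- oracle_dec(tr, as.list(codes), c("A", "B", "C"), "A", 3,
                          p[1], p[2], boundaries = bnd, multipliers = mult)
        expect_equal(got$loglik, ora$loglik, tolerance = 1e-8)
        anc <- ancestral_ranges(tr, coding_table(codes, c("A", "B", "C")),
                                sch, dec_params(p[1], p[2]))
        expect_equal(colnames(anc$prob), ora$labels)
        expect_equal(unname(anc$prob), unname(ora$marg), tolerance = 1e-8)
        expect_equal(unname(rowSums(anc$prob)), rep(1, nrow(anc$prob)),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("likelihood is invariant under area relabeling and redundant slices", {
  tr <- tree_from_newick("((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  codes <- c(a = "A", b = "AB", c = "B", d = "B")
  p <- dec_params(0.2, 0.05)
  base <- dec_loglik(tr, coding_table(codes, c("A", "B")), two_area, p)$loglik
  # swap the two areas everywhere (focal follows the permutation)
  swapped <- chartr("AB", "BA", codes)
  sch_sw <- area_scheme(c("A", "B"), focal = "B", max_range_size = 2)
  expect_equal(dec_loglik(tr, coding_table(swapped, c("A", "B")), sch_sw,
                          p)$loglik, base, tolerance = 1e-9)
  # a slice boundary with identical multipliers on both sides changes nothing
  sch_sl <- area_scheme(c("A", "B"), "A", 2, slice_boundaries = 1.0,
                        multipliers = list(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_equal(dec_loglik(tr, coding_table(codes, c("A", "B")), sch_sl,
                          p)$loglik, base, tolerance = 1e-9)
})

test_that("ancestral MAP ranges behave on degenerate cherries", {
  cherry <- tree_from_newick("(a:1,b:1);")
  anc <- ancestral_ranges(cherry, coding_table(c(a = "A", b = "B"),
                                               c("A", "B")),
                          two_area, dec_params(0, 0))
  expect_equal(unname(anc$map), "AB")
  expect_equal(unname(anc$prob[1, "AB"]), 1)
  tr <- tree_from_newick("((a:1,b:1):1,c:2);")
  anc2 <- ancestral_ranges(tr, coding_table(c(a = "A", b = "A", c = "A"),
                                            c("A", "B")),
                           two_area, dec_params(0.05, 0.001))
  expect_true(all(anc2$map == "A"))
})

test_that("ML fit beats a coarse grid and finds no-signal boundaries", {
  tr <- tree_from_newick("(((a:1,b:1):1,c:2):1,d:3);")
  same <- coding_table(c(a = "A", b = "A", c = "A", d = "A"), c("A", "B"))
  fit0 <- fit_dec(tr, same, two_area)
  expect_lt(fit0$params$d, 1e-4)  # no expansion signal: d at the lower bound
  mixed <- coding_table(c(a = "A", b = "AB", c = "B", d = "B"), c("A", "B"))
  fit <- fit_dec(tr, mixed, two_area)
  expect_equal(fit$convergence, 0)
  for (d in c(0.01, 0.1, 0.5, 1)) for (e in c(0.01, 0.1, 1))
    expect_gte(fit$loglik + 1e-6,
               dec_loglik(tr, mixed, two_area, dec_params(d, e))$loglik)
})

test_that("simulated DEC rates are recovered within a factor of two", {
  sch <- area_scheme(c("A", "B"), "A", 2)
  ok <- 0; n_rep <- 20
  for (r in seq_len(n_rep)) {
    tr <- simulate_tree(0.3, 0.05, 200, seed = 1000 + r)
    sim <- simulate_ranges(tr, sch, dec_params(0.2, 0.02), "B",
                           seed = 2000 + r)
    fit <- fit_dec(sim$tree, sim$coding, sch)
    if (fit$params$d >= 0.1 && fit$params$d <= 0.4) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * n_rep)
})
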