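mk_events <- function(older, younger, point = NULL,
                      type = "dispersal_in", source = "") {
  n <- length(older)
  event_table(data.frame(
    clade_id = "fix", event_type = rep_len(type, n), node_id = seq_len(n),
    point_age = if (is.null(point)) (older + younger) / 2 else point,
    older = older, younger = younger,
    source_region = rep_len(source, n), stringsAsFactors = FALSE))
}

curve_bin <- function(curve, older_edge) {
  curve[abs(curve$bin_older - older_edge) < 1e-9, ]
}

test_that("slice counts follow closed-interval overlap", {
  ev <- mk_events(c(10.5, 2.0, 1.5), c(9.1, 1.0, 0.5))
  cv <- mde_curve(ev)
  expect_equal(nrow(cv), 105L)
  expect_equal(curve_bin(cv, 1.3)$raw, 2)   # slice [1.3, 1.2): two intervals
  expect_equal(curve_bin(cv, 5.1)$raw, 0)   # gap between the two clusters
  expect_equal(curve_bin(cv, 10.5)$raw, 1)
  # a degenerate point interval lands in exactly one slice
  cv1 <- mde_curve(mk_events(3.0, 3.0))
  expect_equal(sum(cv1$raw), 1)
  expect_equal(cv1$raw[cv1$bin_older == 3.0], 1)
  # smoothing a constant series leaves it unchanged
  cv2 <- mde_curve(mk_events(2.0, 0))  # one event spanning every slice
  expect_true(all(cv2$raw == 1))
  expect_true(all(cv2$smoothed == 1))
  expect_error(mde_curve(event_table()), "no events")
})

test_that("binned counts equal brute-force overlap counting on random fixtures", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    o <- round(runif(n, 0, 12), 3)
    y <- pmax(0, o - round(rexp(n, 2), 3))
    cv <- mde_curve(mk_events(o, y))
    expect_identical(cv$raw,
                     as.numeric(oracle_bin_counts(o, y, cv$bin_older,
                                                  cv$bin_younger)))
  }
  # each event overlaps at least one slice
  ev <- mk_events(c(4.05, 2), c(4.05, 1.5))
  expect_gte(sum(mde_curve(ev)$raw), nrow(ev))
})

test_that("origination is the oldest event point age; onset tracks support", {
  ev <- mk_events(c(10.50, 8.4, 2.2), c(9.10, 7.8, 1.9),
                  point = c(10.24, 8.0, 2.0))
  og <- origination(ev, mde_curve(ev))
  expect_equal(og$origination, 10.24)
  expect_equal(og$support_onset, 10.5)
  expect_lte(og$origination, max(ev$older))
  expect_equal(origination(mk_events(3, 2, point = 2.4))$origination, 2.4)
})

test_that("peak takes the midpoint of the maximal run deterministically", {
  fake_curve <- function(smoothed) {
    B <- length(smoothed)
    structure(data.frame(bin_older = (B:1) / 10, bin_younger = (B:1) / 10 - 0.1,
                         mid = (B:1) / 10 - 0.05, raw = smoothed,
                         smoothed = smoothed),
              class = c("mde_curve", "data.frame"))
  }
  # unique maximum in slice [0.8, 0.7) -> peak at its midpoint 0.75
  sm1 <- rep(0, 10); sm1[3] <- 5; sm1[4] <- 2
  cv <- fake_curve(sm1)
  pk <- peak(cv)
  expect_true(pk$defined)
  expect_equal(pk$peak, 0.75)
  # plateau over [1.1, 0.9) -> midpoint 1.0
  sm <- rep(0, 15); sm[c(5, 6)] <- 3  # slices [1.1,1.0) and [1.0,0.9)
  cv2 <- fake_curve(sm)
  expect_equal(peak(cv2)$peak, 1.0)
  # constant positive curve: flat flag, series midpoint
  cv3 <- fake_curve(rep(2, 10))
  pk3 <- peak(cv3)
  expect_true(pk3$flat)
  expect_equal(pk3$peak, mean(range(cv3$mid)))
  # all-zero curve: undefined
  expect_false(peak(fake_curve(rep(0, 6)))$defined)
})

test_that("shifting all intervals older shifts origination and peak exactly", {
  set.seed(5)
  o <- runif(40, 1, 6); y <- pmax(0.5, o - runif(40, 0, 1))
  ev <- mk_events(o, y)
  delta <- 1.7  # a whole number of slices keeps the grid aligned
  ev_s <- mk_events(o + delta, y + delta)
  expect_equal(origination(ev_s)$origination,
               origination(ev)$origination + delta)
  expect_equal(peak(mde_curve(ev_s))$peak, peak(mde_curve(ev))$peak + delta)
})

test_that("bootstrap features are seeded, and degenerate intervals collapse CIs", {
  ev_pt <- mk_events(c(5.2, 3.1, 2.0, 1.4), c(5.2, 3.1, 2.0, 1.4))
  bf <- bootstrap_features(ev_pt, n_boot = 200, seed = 42)
  expect_equal(unname(bf$origination[2] - bf$origination[3]), 0)  # zero width
  bf2 <- bootstrap_features(ev_pt, n_boot = 200, seed = 42)
  expect_identical(bf, bf2)
  ev_int <- mk_events(c(5.2, 3.1, 2.0, 1.4), c(4.0, 2.1, 1.0, 0.4))
  bfa <- bootstrap_features(ev_int, n_boot = 200, seed = 42)
  bfb <- bootstrap_features(ev_int, n_boot = 200, seed = 43)
  expect_false(identical(bfa$origination, bfb$origination))
  expect_warning(bootstrap_features(ev_pt, n_boot = 50, seed = 1), "n_boot")
})

test_that("interval-mode origination CI stays inside the dominant interval", {
  # one clearly oldest event with interval (10.5, 9.1); the rest much younger
  ev <- mk_events(c(10.5, rep(3, 20)), c(9.1, rep(1, 20)),
                  point = c(10.24, rep(2, 20)))
  bf <- bootstrap_features(ev, n_boot = 500, seed = 7, mode = "interval")
  expect_lte(bf$origination[2], 10.5)
  expect_gte(bf$origination[3], 9.1)
  # event-resample mode keeps intervals and point ages
  bf2 <- bootstrap_features(ev, n_boot = 300, seed = 7, mode = "resample")
  expect_lte(bf2$origination[2], 10.24)
})

test_that("per-source curves partition the assigned dispersal events", {
  ev <- mk_events(c(6, 5, 4, 3, 2), c(5, 4, 3, 2, 1),
                  source = c("G", "G", "D", "", ""))
  cvs <- per_source_curves(ev)
  expect_setequal(names(cvs), c("D", "G"))
  expect_gte(sum(cvs$G$raw), sum(cvs$D$raw))
  all_cv <- mde_curve(ev)
  for (r in names(cvs)) {
    m <- match(round(cvs[[r]]$bin_older, 9), round(all_cv$bin_older, 9))
    expect_true(all(cvs[[r]]$raw <= all_cv$raw[m]))
  }
  expect_length(per_source_curves(mk_events(3, 2)), 0L)
})
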