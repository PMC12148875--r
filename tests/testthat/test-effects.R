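test_that("2x2 extraction matches hand counts and dichotomizes age", {
  sc <- binary_schema(c("e", "v"))
  d <- toy_dataset(list(e = c("yes", "yes", "yes", "no", "no", "no"),
                        v = c("yes", "yes", "no", "yes", "no", "no")), sc)
  t2 <- contingency_2x2(d, c(e = "yes"), c(v = "yes"))
  expect_equal(unlist(t2[c("a", "b", "c", "d")]),
               c(a = 2L, b = 1L, c = 1L, d = 2L))
  # permutation invariance
  dp <- categorical_dataset(as.data.frame(d)[c(4, 2, 6, 1, 3, 5), ], sc)
  tp <- contingency_2x2(dp, c(e = "yes"), c(v = "yes"))
  expect_equal(unlist(tp[c("a", "b", "c", "d")]),
               unlist(t2[c("a", "b", "c", "d")]))
  # age evidence: senior vs everyone else
  dd <- forward_sample(generator_config(n = 400, seed = 15,
                                        truth = default_truth()))
  ts <- contingency_2x2(dd, c(age = "senior"), c(headache = "yes"))
  expect_equal(ts$a + ts$b, sum(dd$age == "senior"))
  expect_equal(ts$c + ts$d, sum(dd$age != "senior"))
  expect_equal(ts$a + ts$b + ts$c + ts$d, 400L)
})

test_that("odds ratios from probabilities match the published anchors", {
  expect_equal(round(odds_ratio_from_probs(0.51138, 0.26739), 3L), 2.867)
  expect_equal(round(odds_ratio_from_probs(0.51138, 0.26739), 2L), 2.87)
  expect_equal(round(odds_ratio_from_probs(0.38750, 0.06786), 3L), 8.690)
  expect_equal(round(odds_ratio_from_probs(0.55150, 0.20534), 3L), 4.759)
  expect_equal(round(odds_ratio_from_probs(0.11275, 0.32969), 3L), 0.258)
  for (p in c(0.1, 0.37, 0.8)) {
    expect_equal(odds_ratio_from_probs(p, p), 1)
  }
  d1 <- odds_ratio_from_probs(1, 0.5)
  expect_true(is.infinite(d1) && isTRUE(attr(d1, "degenerate")))
  d0 <- odds_ratio_from_probs(0, 0.5)
  expect_true(d0 == 0 && isTRUE(attr(d0, "degenerate")))
})

test_that("Woolf CIs reproduce the published reconstructions", {
  ci <- ci_from_counts(list(a = 382, b = 365, c = 442, d = 1211))
  expect_equal(round(ci$or, 3L), 2.867)
  expect_equal(round(ci$ci_low, 3L), 2.395)
  expect_equal(round(ci$ci_high, 3L), 3.433)
  ci2 <- ci_from_counts(list(a = 166, b = 135, c = 431, d = 1668))
  expect_equal(round(ci2$ci_low, 3L), 3.704)
  expect_equal(round(ci2$ci_high, 3L), 6.114)
  # symmetric table: OR 1, bounds symmetric on the log scale
  cs <- ci_from_counts(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(cs$or, 1)
  expect_equal(log(cs$ci_low), -log(cs$ci_high), tolerance = 1e-12)
})

test_that("zero cells error by default and correct on request", {
  t0 <- list(a = 0, b = 20, c = 5, d = 15)
  expect_error(ci_from_counts(t0), "zero cell")
  cc <- ci_from_counts(t0, zero_correction = TRUE)
  expect_true(cc$corrected)
  expect_equal(cc$or, (0.5 / 20.5) / (5.5 / 15.5))
})

test_that("OR identities and monotonicity hold", {
  set.seed(33)
  for (i in 1:20) {
    cells <- sample(5:500, 4L)
    t2 <- list(a = cells[1L], b = cells[2L], c = cells[3L], d = cells[4L])
    ci <- ci_from_counts(t2)
    p1 <- t2$a / (t2$a + t2$b)
    p2 <- t2$c / (t2$c + t2$d)
    expect_equal(odds_ratio_from_probs(p1, p2), ci$or, tolerance = 1e-12)
    expect_true((ci$or > 1) == (p1 > p2) || p1 == p2)
    expect_true(ci$ci_low <= ci$or && ci$or <= ci$ci_high)
    # increasing a increases OR and both bounds
    up <- ci_from_counts(within(t2, a <- a + 10L))
    expect_gt(up$or, ci$or)
    expect_gt(up$ci_low, ci$ci_low)
    expect_gt(up$ci_high, ci$ci_high)
  }
})

test_that("relationship table expands arcs as documented", {
  d <- forward_sample(generator_config(n = 2400, seed = 1,
                                       truth = default_truth()))
  g <- reference_dag()
  tab <- relationship_table(d, g)
  pain_child <- sum(g$arcs[, 2L] %in% names(pain_schema())[-(1:2)])
  n_age_arcs <- sum(g$arcs[, 1L] == "age")
  expect_equal(nrow(tab), pain_child + 2L * n_age_arcs)
  expect_equal(nrow(tab), 27L)
  # demographic rows first, age before gender
  expect_equal(tab$evidence[1:6], rep(c("age"), 6L))
  expect_equal(tab$evidence[7:9], rep("gender", 3L))
  # every row's OR sits inside its own CI and matches its counts
  with(tab, {
    expect_true(all(ci_lower <= odds_ratio & odds_ratio <= ci_upper))
    expect_equal(odds_ratio, (a / b) / (c / d), tolerance = 1e-12)
    expect_equal(yes_pct, 100 * a / (a + b), tolerance = 1e-12)
  })
  # headache -> neck within a generous sampling envelope of 2.867
  hn <- tab[tab$relationship == "headache -> neck", ]
  expect_lt(abs(hn$odds_ratio - 2.867) / 2.867, 0.25)
})

test_that("exactly independent evidence gives OR 1", {
  sc <- binary_schema(c("e", "v"))
  d <- toy_dataset(list(e = rep(c("yes", "no"), each = 40),
                        v = rep(rep(c("yes", "no"), each = 20), 2)), sc)
  g <- dag(c("e", "v"), rbind(c("e", "v")))
  tab <- relationship_table(d, g)
  expect_equal(tab$odds_ratio, 1)
})

test_that("model-based table tracks the calibration targets in direction", {
  net <- default_truth()
  mt <- model_relationship_table(net)
  ref <- reference_associations()
  expect_equal(nrow(mt), nrow(ref))
  # same direction of association as the published table for every row
  expect_true(all((mt$odds_ratio > 1) == (ref$or > 1)))
  # pairwise conditionals land near their calibration targets; the
  # log-odds additive construction deviates by up to ~7 percentage points
  # where parents are strongly correlated (documented calibration quality)
  expect_lt(max(abs(mt$yes_pct - ref$yes_pct)), 10)
  expect_lt(max(abs(mt$no_pct - ref$no_pct)), 10)
  # the headache -> neck calibration pair specifically
  hn <- mt[mt$relationship == "headache -> neck", ]
  expect_lt(abs(hn$yes_pct - 51.138), 2)
  expect_lt(abs(hn$no_pct - 26.739), 2)
})
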