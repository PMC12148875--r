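test_that("family BIC matches hand computations", {
  d <- toy_dataset(list(x = c("yes", "yes", "yes", "no")))
  # 3 ln(3/4) + 1 ln(1/4) - (1/2) ln 4
  expect_equal(family_bic_score(d, "x"),
               3 * log(0.75) + log(0.25) - 0.5 * log(4))
  expect_equal(family_bic_score(d, "x"), -2.9424878, tolerance = 1e-7)
  # constant child: point-mass likelihood is 0
  d2 <- toy_dataset(list(x = rep("yes", 7), y = rep(c("yes", "no"),
                                                    length.out = 7)))
  expect_equal(family_bic_score(d2, "x"), -0.5 * log(7))
  # zero-count terms use 0 ln 0 = 0 and unseen configurations drop out
  expect_equal(family_bic_score(d2, "x", "y"), -1 * log(7))
})

test_that("family BIC equals an independent counting oracle", {
  set.seed(21)
  sc <- binary_schema(c("a", "b", "c", "d"))
  df <- as.data.frame(lapply(sc, function(s) {
    sample(c("no", "yes"), 200, replace = TRUE, prob = c(0.6, 0.4))
  }), col.names = names(sc), stringsAsFactors = FALSE)
  d <- categorical_dataset(df, sc)
  cases <- list(list("a", character()), list("a", "b"),
                list("b", c("a", "c")), list("d", c("a", "b", "c")))
  for (cs in cases) {
    expect_equal(family_bic_score(d, cs[[1L]], cs[[2L]]),
                 oracle_family_bic(d, cs[[1L]], cs[[2L]]),
                 label = paste(cs[[1L]], "|", paste(cs[[2L]],
                                                    collapse = ",")))
  }
})

test_that("network score decomposes over families", {
  set.seed(22)
  sc <- binary_schema(c("a", "b", "c", "d"))
  df <- as.data.frame(lapply(sc, function(s) {
    sample(c("no", "yes"), 200, replace = TRUE)
  }), col.names = names(sc), stringsAsFactors = FALSE)
  d <- categorical_dataset(df, sc)
  g0 <- dag(names(sc))
  expect_equal(network_bic_score(d, g0),
               sum(vapply(names(sc), function(v) family_bic_score(d, v),
                          0)))
  g1 <- dag(names(sc), rbind(c("a", "b"), c("c", "b"), c("a", "d")))
  expect_equal(network_bic_score(d, g1),
               sum(vapply(names(sc), function(v) {
                 oracle_family_bic(d, v, parents(g1, v))
               }, 0)))
  # adding an arc changes only the child family term
  g2 <- dag(names(sc), rbind(c("a", "b"), c("c", "b"), c("a", "d"),
                             c("c", "d")))
  expect_equal(network_bic_score(d, g2) - network_bic_score(d, g1),
               family_bic_score(d, "d", c("a", "c")) -
                 family_bic_score(d, "d", "a"))
})

test_that("hill climbing finds the single arc of a strong dependence", {
  set.seed(5)
  a <- sample(c("no", "yes"), 2000, replace = TRUE)
  b <- ifelse(stats::runif(2000) < 0.95, a,
              ifelse(a == "yes", "no", "yes"))
  d <- toy_dataset(list(a = a, b = b))
  tr <- hill_climb(d)
  expect_equal(nrow(tr$dag$arcs), 1L)
  expect_setequal(as.vector(tr$dag$arcs), c("a", "b"))
  # analytic check that the arc is BIC-favored on these counts
  expect_gt(family_bic_score(d, "b", "a"), family_bic_score(d, "b"))
})

test_that("hill climbing leaves independent coins unconnected", {
  set.seed(6)
  d <- toy_dataset(list(a = sample(c("no", "yes"), 2000, replace = TRUE),
                        b = sample(c("no", "yes"), 2000, replace = TRUE)))
  tr <- hill_climb(d)
  expect_equal(nrow(tr$dag$arcs), 0L)
})

test_that("accepted moves strictly increase the network score", {
  d <- forward_sample(generator_config(n = 800, seed = 13,
                                       truth = default_truth()))
  tr <- hill_climb(d, demographic_blacklist())
  expect_true(all(diff(c(network_bic_score(d, dag(sort(names(d)))),
                         tr$trace$score)) > 0))
  # trace end matches an independent full rescoring of the final DAG
  expect_equal(tr$score, network_bic_score(d, tr$dag))
})

test_that("blacklists are never violated (fuzz over random data)", {
  set.seed(9)
  cons <- demographic_blacklist()
  for (i in 1:3) {
    d <- forward_sample(generator_config(n = 400, seed = 100 + i,
                                         truth = default_truth()))
    tr <- hill_climb(d, cons)
    expect_false(violates_constraints(tr$dag, cons))
  }
})

test_that("recovery improves with sample size (4-node truth, 3 seeds)", {
  sc <- binary_schema(c("p", "q", "r", "s"))
  g <- dag(names(sc), rbind(c("p", "q"), c("q", "r"), c("p", "s")))
  net <- make_net(g, sc, list(
    p = c(0.5, 0.5),
    q = rbind(c(0.8, 0.2), c(0.3, 0.7)),
    r = rbind(c(0.75, 0.25), c(0.35, 0.65)),
    s = rbind(c(0.6, 0.4), c(0.2, 0.8))))
  shd_at <- function(n) {
    vapply(1:3, function(s) {
      d <- forward_sample(generator_config(n = n, seed = s, truth = net))
      compare_dags(hill_climb(d)$dag, g)$shd
    }, 0)
  }
  expect_lte(stats::median(shd_at(1e5)), stats::median(shd_at(1e3)))
})

test_that("deterministic tie-breaking yields reproducible searches", {
  d <- forward_sample(generator_config(n = 500, seed = 77,
                                       truth = default_truth()))
  t1 <- hill_climb(d, demographic_blacklist())
  t2 <- hill_climb(d, demographic_blacklist())
  expect_identical(t1$dag$arcs, t2$dag$arcs)
  expect_identical(t1$trace, t2$trace)
})
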