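test_that("joint probability is the chain-rule product", {
  sc1 <- binary_schema("x")
  n1 <- make_net(dag("x"), sc1, list(x = c(0.7, 0.3)))
  expect_equal(joint_probability(n1, c(x = "yes")), 0.3)
  sc2 <- binary_schema(c("a", "b"))
  n2 <- make_net(dag(c("a", "b"), rbind(c("a", "b"))), sc2,
                 list(a = c(0.5, 0.5),
                      b = rbind(c(0.9, 0.1), c(0.2, 0.8))))
  expect_equal(joint_probability(n2, c(a = "yes", b = "yes")), 0.4)
  expect_error(joint_probability(n2, c(a = "yes")), "every node")
})

test_that("the full joint of the default truth network sums to 1", {
  fj <- painbn:::full_joint(default_truth())
  expect_equal(nrow(fj$grid), 2^10 * 3 * 2)
  expect_equal(sum(fj$prob), 1, tolerance = 1e-12)
})

test_that("conditional queries reduce correctly in closed form", {
  net <- default_truth()
  # no evidence on a root node: its marginal CPT entry
  expect_equal(query_conditional(net, c(gender = "female")), 0.5)
  expect_equal(query_conditional(net, c(age = "senior")), 0.085)
  # 3-node chain checked against hand enumeration
  sc <- binary_schema(c("a", "b", "c"))
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  n3 <- make_net(g, sc, list(
    a = c(0.4, 0.6),
    b = rbind(c(0.7, 0.3), c(0.2, 0.8)),
    c = rbind(c(0.9, 0.1), c(0.5, 0.5))))
  # P(b=yes | a=yes, c=yes) by hand:
  #   num = .6*.8*.5, den = .6*(.8*.5 + .2*.1)
  expect_equal(query_conditional(n3, c(b = "yes"),
                                 c(a = "yes", c = "yes")),
               (0.8 * 0.5) / (0.8 * 0.5 + 0.2 * 0.1))
  # full evidence on all other nodes, target's children unassigned:
  # equals the target's CPT entry given its parents
  expect_equal(query_conditional(n3, c(c = "yes"),
                                 c(a = "no", b = "yes")), 0.5)
})

test_that("enumeration, variable elimination, and oracle agree", {
  set.seed(50)
  for (rep in 1:8) {
    g <- random_dag(letters[1:5], p = 0.45)
    net <- random_net(g)
    for (q in 1:6) {
      tn <- sample(g$nodes, 1L)
      evn <- sample(setdiff(g$nodes, tn), sample(0:2, 1L))
      ev <- stats::setNames(sample(c("no", "yes"), length(evn),
                                   replace = TRUE), evn)
      tgt <- stats::setNames(sample(c("no", "yes"), 1L), tn)
      p_enum <- query_conditional(net, tgt, ev, method = "enumeration")
      p_ve <- query_conditional(net, tgt, ev, method = "ve")
      p_oracle <- oracle_query(net, tgt, ev)
      expect_equal(p_enum, p_ve, tolerance = 1e-12)
      expect_equal(p_enum, p_oracle, tolerance = 1e-12)
    }
  }
})

test_that("law of total probability holds for conditionals", {
  net <- default_truth()
  evs <- list(c(headache = "yes"), c(age = "senior", foot = "yes"),
              c(gender = "female", back = "yes", hand = "yes"))
  for (ev in evs) {
    tot <- query_conditional(net, c(knee = "yes"), ev) +
      query_conditional(net, c(knee = "no"), ev)
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("colliders leave marginally independent parents independent", {
  sc <- binary_schema(c("a", "b", "c"))
  g <- dag(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
  net <- make_net(g, sc, list(
    a = c(0.6, 0.4), b = c(0.3, 0.7),
    c = rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.5, 0.5), c(0.2, 0.8))))
  expect_equal(query_conditional(net, c(a = "yes"), c(b = "yes")),
               query_conditional(net, c(a = "yes")), tolerance = 1e-12)
})

test_that("multi-evidence query shapes of the survey report are supported", {
  net <- default_truth()
  p1 <- query_conditional(net, c(knee = "yes"),
                          c(age = "senior", foot = "yes", back = "yes"))
  p2 <- query_conditional(net, c(knee = "yes"))
  expect_true(p1 > p2)  # compounding risk factors raise the probability
  p3 <- query_conditional(net, c(all_body = "yes"),
                          c(back = "yes", hand = "yes"))
  expect_true(p3 > query_conditional(net, c(all_body = "yes")))
})

test_that("impossible evidence is rejected", {
  sc <- binary_schema(c("a", "b"))
  net <- make_net(dag(c("a", "b"), rbind(c("a", "b"))), sc,
                  list(a = c(1, 0), b = rbind(c(0.5, 0.5), c(0.5, 0.5))))
  expect_error(query_conditional(net, c(b = "yes"), c(a = "yes")),
               "probability zero")
})
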