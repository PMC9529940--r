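# Windowed-threshold update, schemes, period detection, regimes.

pair_adj <- binary_adjacency(matrix(c(0, 1, 1, 0), 2))

test_that("local_sum counts active neighbours, excluding the node itself", {
  adj <- binary_adjacency(rbind(c(0, 1, 1, 1),
                                c(1, 0, 0, 0),
                                c(1, 0, 0, 0),
                                c(1, 0, 0, 0)))
  expect_equal(local_sum(c(1, 1, 1, 1), adj, 1), 3L)  # 3 neighbours on
  expect_equal(local_sum(c(1, 0, 0, 0), adj, 1), 0L)  # own state excluded
  iso <- binary_adjacency(matrix(0, 3, 3))
  expect_equal(local_sum(c(1, 1, 1), iso, 2), 0L)     # isolated node
  expect_error(local_sum(c(1, 0, 0, 0), adj, 9), "out of range")
  # random instances equal an explicit loop-sum
  set.seed(1)
  for (rep in 1:20) {
    a <- rand_adjacency(8)
    s <- as.integer(runif(8) < 0.5)
    i <- sample(8, 1)
    expect_equal(local_sum(s, a, i),
                 sum(vapply(1:8, function(j) a$matrix[i, j] * s[j], numeric(1))))
  }
})

test_that("apply_rule implements the activation window in both modes", {
  incl <- threshold_rule(1, 4)
  strict <- threshold_rule(1, 4, "strict")
  expect_equal(apply_rule(2, incl), 1L)
  expect_equal(apply_rule(2, strict), 1L)
  expect_equal(apply_rule(0, incl), 0L)
  expect_equal(apply_rule(1, incl), 1L)    # boundary, inclusive fires
  expect_equal(apply_rule(1, strict), 0L)  # boundary, strict does not
  expect_equal(apply_rule(4, incl), 1L)
  expect_equal(apply_rule(4, strict), 0L)
  expect_equal(apply_rule(0:5, incl), c(0L, 1L, 1L, 1L, 1L, 0L))
  expect_error(threshold_rule(3, 2), "b >= a")
  expect_error(threshold_rule(-1, 2), "a >= 0")
})

test_that("perturb is an involution on valid indices", {
  s <- c(0L, 0L, 0L)
  expect_equal(perturb(s, integer(0)), s)
  expect_equal(perturb(s, 1), c(1L, 0L, 0L))
  expect_equal(perturb(perturb(s, c(1, 3)), c(1, 3)), s)
  expect_error(perturb(s, 4), "out of range")
})

test_that("CRBN two-node dynamics match hand enumeration", {
  rule <- threshold_rule(1, 1)
  tr <- simulate_bn(c(1L, 0L), pair_adj, rule, 4)
  expect_equal(tr$states,
               rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, 1L), c(1L, 0L)))
  tr11 <- simulate_bn(c(1L, 1L), pair_adj, rule, 3)
  expect_true(all(tr11$states == 1L))  # fixed point
  # all-zero is absorbing whenever a >= 1 (inclusive)
  tr00 <- simulate_bn(c(0L, 0L), pair_adj, threshold_rule(1, 2), 3)
  expect_true(all(tr00$states == 0L))
})

test_that("CRBN is deterministic bit for bit", {
  set.seed(9)
  adj <- rand_adjacency(12)
  init <- as.integer(runif(12) < 0.5)
  rule <- threshold_rule(1, 3)
  t1 <- simulate_bn(init, adj, rule, 100)
  t2 <- simulate_bn(init, adj, rule, 100)
  expect_identical(t1$states, t2$states)
})

test_that("all-zero absorption holds for random adjacencies (a >= 1)", {
  set.seed(30)
  for (rep in 1:25) {
    adj <- rand_adjacency(sample(3:12, 1))
    a <- sample(1:3, 1)
    tr <- simulate_bn(rep(0L, adj$n_nodes), adj,
                      threshold_rule(a, a + sample(0:4, 1)), 10)
    expect_true(all(tr$states == 0L))
  }
})

test_that("ARBN/GARBN are seed-reproducible and change <=1 / <=g nodes", {
  set.seed(2)
  adj <- rand_adjacency(10)
  init <- as.integer(runif(10) < 0.5)
  rule <- threshold_rule(1, 3)
  arbn <- update_scheme("ARBN", seed = 4)
  t1 <- simulate_bn(init, adj, rule, 50, arbn)
  t2 <- simulate_bn(init, adj, rule, 50, arbn)
  expect_identical(t1$states, t2$states)
  flips <- rowSums(t1$states[-1, , drop = FALSE] !=
                   t1$states[-nrow(t1$states), , drop = FALSE])
  expect_true(all(flips <= 1))

  garbn <- update_scheme("GARBN", g = 3, seed = 4)
  g1 <- simulate_bn(init, adj, rule, 50, garbn)
  expect_identical(g1$states,
                   simulate_bn(init, adj, rule, 50, garbn)$states)
  gflips <- rowSums(g1$states[-1, , drop = FALSE] !=
                    g1$states[-nrow(g1$states), , drop = FALSE])
  expect_true(all(gflips <= 3))
  expect_error(update_scheme("ARBN"), "seed")
  expect_error(update_scheme("GARBN", g = 0, seed = 1), "g >= 1")
})

test_that("DARBN updates eligible nodes sequentially, DGARBN simultaneously", {
  # 2-node pair, p = 1, q = 0: every node eligible every step.
  rule <- threshold_rule(1, 1)
  darbn <- update_scheme("DARBN", p = 1, q = 0)
  tr <- simulate_bn(c(1L, 0L), pair_adj, rule, 3, darbn)
  # sequential: node 1 sees sigma = 0 -> off; node 2 then sees sigma = 0 -> off
  expect_equal(tr$states[2, ], c(0L, 0L))
  dgarbn <- update_scheme("DGARBN", p = 1, q = 0)
  tg <- simulate_bn(c(1L, 0L), pair_adj, rule, 3, dgarbn)
  # simultaneous: behaves like CRBN here, the pair flip-flops
  expect_equal(tg$states[1:3, ], rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L)))
  expect_error(update_scheme("DARBN", p = 2, q = 2), "q < p")
})

test_that("detect_period finds transients and cycles, with replay validity", {
  rule <- threshold_rule(1, 1)
  # flip-flop: period 2, no transient
  pr <- detect_period(c(1L, 0L), pair_adj, rule)
  expect_equal(pr$transient, 0L)
  expect_equal(pr$period, 2L)
  expect_equal(classify_regime(pr), "ordered")
  # all-zero fixed point: period 1
  pr0 <- detect_period(c(0L, 0L), pair_adj, rule)
  expect_equal(pr0$transient, 0L)
  expect_equal(pr0$period, 1L)
  # stochastic schemes are rejected
  expect_error(detect_period(c(1L, 0L), pair_adj, rule,
                             update_scheme("ARBN", seed = 1)),
               "deterministic")
  # replay validity on random instances: whenever a (transient, period) is
  # reported, direct replay confirms states[t] == states[t + period] for
  # every t from the transient to the end of the horizon
  set.seed(3)
  found <- 0L
  for (rep in 1:25) {
    adj <- rand_adjacency(10)
    init <- as.integer(runif(10) < 0.5)
    r <- threshold_rule(1, sample(1:4, 1))
    res <- detect_period(init, adj, r, horizon = 200)
    if (is.na(res$period)) next
    found <- found + 1L
    tr <- simulate_bn(init, adj, r, 200)
    ts <- seq(res$transient, 200 - res$period)
    expect_identical(tr$states[ts + 1L, , drop = FALSE],
                     tr$states[ts + res$period + 1L, , drop = FALSE])
  }
  expect_gt(found, 15L)  # threshold dynamics collapse quickly on dense nets
})

test_that("detect_period agrees with the brute-force oracle on small nets", {
  set.seed(4)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    adj <- rand_adjacency(n)
    init <- as.integer(runif(n) < 0.5)
    a <- sample(0:2, 1); b <- a + sample(0:3, 1)
    for (mode in c("inclusive", "strict")) {
      res <- detect_period(init, adj, threshold_rule(a, b, mode),
                           horizon = 2L^n + 2L)
      orc <- oracle_period(init, adj$matrix, a, b, mode == "inclusive")
      expect_equal(res$transient, orc$transient)
      expect_equal(res$period, orc$period)
    }
  }
})

test_that("warm-started period search reports absolute transients", {
  rule <- threshold_rule(1, 1)
  pr <- detect_period(c(1L, 0L), pair_adj, rule, warm_start = 10)
  expect_equal(pr$period, 2L)
  expect_equal(pr$transient, 10L)  # first tracked revisit is at the offset
})

test_that("DARBN period detection accounts for the update phase", {
  # p = 2 on both nodes: nodes only update on even steps, so raw states
  # repeat with the scheme's phase folded in.
  darbn <- update_scheme("DARBN", p = 2, q = 0)
  pr <- detect_period(c(1L, 0L), pair_adj, threshold_rule(1, 1), darbn,
                      horizon = 50)
  tr <- simulate_bn(c(1L, 0L), pair_adj, threshold_rule(1, 1), 50, darbn)
  expect_false(is.na(pr$period))
  expect_equal(tr$states[pr$transient + 1, ],
               tr$states[pr$transient + pr$period + 1, ])
  expect_equal(pr$period %% 2L, 0L)  # a full phase cycle
})

test_that("regime classification follows the period map conventions", {
  expect_equal(classify_regime(NA_integer_), "chaotic")
  expect_equal(classify_regime(199L), "complex")
  expect_equal(classify_regime(48L), "complex")
  expect_equal(classify_regime(2L), "ordered")
  expect_equal(classify_regime(9L, complex_cutoff = 8L), "complex")
  expect_equal(classify_regime(8L, complex_cutoff = 8L), "ordered")
})
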