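test_that("the transition matrix reproduces the two conditional coin flips", {
  # brute force over the 2x2 move outcomes per state, for arbitrary vectors
  set.seed(3)
  for (rep in 1:5) {
    p <- runif(4); s <- runif(4)
    M <- transition_matrix(p, s)
    sb <- c(s[1], s[3], s[2], s[4])
    for (i in 1:4) {
      for (ma in c(1, 0)) {
        for (mb in c(1, 0)) {
          j <- which(c("CC", "CD", "DC", "DD") ==
                       paste0(if (ma) "C" else "D", if (mb) "C" else "D"))
          want <- (if (ma) p[i] else 1 - p[i]) *
                  (if (mb) sb[i] else 1 - sb[i])
          expect_equal(M[i, j], want)
        }
      }
    }
    expect_equal(unname(rowSums(M)), rep(1, 4))
  }
  # mutual cooperators reach CC surely
  Mcc <- transition_matrix(rep(1, 4), rep(1, 4))
  expect_equal(unname(Mcc), matrix(rep(c(1, 0, 0, 0), each = 4), 4, 4))
  # TFT vs AD: DD is absorbing
  Mta <- transition_matrix(c(1, 0, 1, 0), rep(0, 4))
  expect_equal(unname(Mta["DD", ]), c(0, 0, 0, 1))
})

test_that("state evolution preserves normalisation and finds fixed points", {
  Mcc <- transition_matrix(rep(1, 4), rep(1, 4))
  expect_equal(unname(evolve_state(c(1, 0, 0, 0), Mcc)), c(1, 0, 0, 0))
  # TFT vs AD from CC: CC -> CD -> DD, absorbing after two steps
  Mta <- transition_matrix(c(1, 0, 1, 0), rep(0, 4))
  phi <- evolve_state(evolve_state(c(1, 0, 0, 0), Mta), Mta)
  expect_equal(unname(phi), c(0, 0, 0, 1))
  set.seed(4)
  M <- transition_matrix(runif(4), runif(4))
  phi <- evolve_state(c(0.2, 0.3, 0.1, 0.4), M)
  expect_equal(sum(phi), 1)
  expect_error(evolve_state(c(1, 0, 0, 0), matrix(1, 4, 4)), "stochastic")
})

test_that("stationarity: determinant payoff equals the stationary expectation", {
  pairs <- list(c("random", "zde"), c("random", "zdg"), c("gtft", "zde"),
                c("ad", "gtft"), c("random", "random"), c("wsls", "zde"))
  Sx <- c(3, 0, 5, 1)
  for (pr in pairs) {
    p <- memory_one_vector(pr[1]); s <- memory_one_vector(pr[2])
    M <- transition_matrix(p, s)
    # stationary vector from the eigen problem, independent of the determinant
    ev <- eigen(t(M))
    i <- which.min(abs(ev$values - 1))
    st <- Re(ev$vectors[, i]); st <- st / sum(st)
    expect_lt(max(abs(drop(st %*% M) - st)), 1e-10)
    e <- expected_payoff(pr[1], pr[2])
    expect_identical(e$method, "determinant")
    expect_lt(abs(sum(st * Sx) - e$value), 1e-10)
  }
})

test_that("expected payoffs reproduce independently computed exact values", {
  # frozen values from an external oracle (stationary linear algebra / exact
  # chain enumeration), to 1e-6
  cases <- list(
    list("random", "zde", 1.520833333),    # fair coin vs extortioner
    list("gtft", "zde", 1.538720539),
    list("zde", "gtft", 2.616161616),
    list("random", "hard_joss", 2.075),
    list("hard_joss", "random", 2.325),
    list("gtft", "hard_joss", 2.541666667),
    list("zdg", "hard_joss", 2.450410613),
    list("wsls", "hard_joss", 1.896551724),
    list("tf2t", "random", 1.875),         # 15/8
    list("random", "tf2t", 3.125),         # 25/8
    list("hard_tft", "random", 2.8125),    # 45/16
    list("random", "hard_tft", 0.9375),    # 15/16
    list("hard_tf2t", "random", 2.0625),
    list("random", "hard_tf2t", 2.6875),   # 43/16
    list("gtft", "ad", 2 / 3),
    list("zdg", "ad", 9 / 13),
    list("ad", "zdg", 29 / 13),
    list("zde", "ac", 41 / 11),
    list("ac", "zde", 21 / 11),
    list("grim", "random", 3),
    list("random", "grim", 0.5),
    list("tf2t", "hard_joss", 1),          # slow absorption into DD
    list("ac", "ad", 0),
    list("zde", "zde", 1))
  for (cs in cases) {
    e <- expected_payoff(cs[[1]], cs[[2]])
    expect_lt(abs(e$value - cs[[3]]), 1e-6)
    expect_identical(e$se, 0)
  }
})

test_that("deterministic pairs resolve by exact cycle analysis", {
  cyc <- function(a, b) expected_payoff(a, b)
  e <- cyc("tft", "tft")
  expect_identical(e$method, "cycle"); expect_equal(e$value, 3)
  # hard majority vs TFT locks into the exploitation alternation
  e <- cyc("hard_majo", "tft")
  expect_identical(e$method, "cycle"); expect_equal(e$value, 2.5)
  expect_equal(cyc("tft", "hard_majo")$value, 2.5)
  # drifting majority counters: provably frozen sign
  expect_equal(cyc("hard_majo", "ac")$value, 3)   # counter drifts up
  expect_equal(cyc("hard_majo", "ad")$value, 1)   # counter drifts down
  expect_equal(cyc("hard_majo", "grim")$value, 1)
  expect_equal(cyc("hard_majo", "hard_majo")$value, 1)
  expect_equal(cyc("hard_majo", "wsls")$value, 3)
  expect_equal(cyc("wsls", "hard_majo")$value, 0.5)
  expect_equal(cyc("grim", "ad")$value, 1)
  expect_equal(cyc("wsls", "ad")$value, 0.5)
  expect_equal(cyc("ad", "wsls")$value, 3)
})

test_that("determinant values agree with long simulations for ergodic pairs", {
  pairs <- list(c("random", "zde"), c("gtft", "zde"), c("random", "zdg"),
                c("ad", "gtft"), c("random", "hard_joss"))
  set.seed(20)
  for (pr in pairs) {
    e1 <- expected_payoff(pr[1], pr[2])
    expect_identical(e1$method, "determinant")
    # continuous trajectory, burn-in discarded: valid for ergodic pairs
    m <- ipdnet:::sim_pair_cpp(ipdnet:::strategy_code(pr[1]),
                               ipdnet:::strategy_code(pr[2]),
                               50000L, 10000L, 20L, c(3, 0, 5, 1))
    se <- sd(m[, 1]) / sqrt(nrow(m))
    expect_lt(abs(mean(m[, 1]) - e1$value), 4 * se + 1e-6)
  }
})

test_that("zero-determinant identities hold against all 14 opponents", {
  P <- 1; R <- 3
  for (x in strategy_ids()) {
    set.seed(31)
    exe <- expected_payoff("zde", x)
    exb <- expected_payoff(x, "zde")
    tol <- if (exe$method == "simulated") {
      4 * sqrt(exe$se^2 + 9 * exb$se^2) + 0.02
    } else 1e-6
    expect_lt(abs((exe$value - P) - 3 * (exb$value - P)), tol)
    set.seed(31)
    ege <- expected_payoff("zdg", x)
    egb <- expected_payoff(x, "zdg")
    tol <- if (ege$method == "simulated") {
      4 * sqrt(ege$se^2 + 9 * egb$se^2) + 0.02
    } else 1e-6
    expect_lt(abs((ege$value - R) - 3 * (egb$value - R)), tol)
  }
})

test_that("delta statistics match the published gap values", {
  expect_equal(payoff_delta("random", "ad"), -0.75)
  expect_equal(payoff_delta("ad", "random"), 0.5)
  expect_equal(payoff_delta("tf2t", "random"), -0.125)
  expect_equal(payoff_delta("random", "tf2t"), 0.375)
  expect_equal(round_half_up(payoff_delta("zde", "random"), 2), -0.52)
  expect_equal(payoff_delta("hard_majo", "tft"), -1.5)
  expect_equal(payoff_delta("tft", "hard_majo"), 0.5)
  expect_equal(payoff_delta("zdg", "zde"), 0.5)
  expect_equal(payoff_delta("zde", "zdg"), -0.5)
  expect_equal(payoff_delta("tft", "tft"), 0) # identity
})

test_that("simulated pairs report a positive standard error and valid range", {
  set.seed(8)
  e <- expected_payoff("hard_majo", "random")
  expect_identical(e$method, "simulated")
  expect_gt(e$se, 0)
  expect_gte(e$value, 0); expect_lte(e$value, 5)
})
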