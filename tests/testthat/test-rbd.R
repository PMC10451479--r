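test_that("the optimal criterion has its closed form and expected symmetries", {
  sym <- payoff_structure(p_reward_given_correct_rich = 0.4,
                          p_reward_given_correct_lean = 0.4)
  expect_equal(optimal_criterion(sym, 1.3), 0)

  p <- payoff_structure(p_reward_given_correct_rich = 0.6,
                        p_reward_given_correct_lean = 0.2)
  expect_equal(optimal_criterion(p, 1), log(1 / 3), tolerance = 1e-9)
  expect_equal(optimal_criterion(p, 1), -1.0986, tolerance = 1e-4)

  doubled <- payoff_structure(reward_cents = 40,
                              p_reward_given_correct_rich = 0.6,
                              p_reward_given_correct_lean = 0.2)
  expect_equal(optimal_criterion(doubled, 1), optimal_criterion(p, 1))
  expect_error(optimal_criterion(p, 0), "undefined")
})

test_that("expected value reaches the enumerated limits and is maximized at c*", {
  p <- payoff_structure(p_reward_given_correct_rich = 0.6,
                        p_reward_given_correct_lean = 0.2)
  # near-perfect discrimination at the optimum earns both reward streams
  expect_equal(expected_value(optimal_criterion(p, 20), p, 20), 8.0,
               tolerance = 1e-4)
  # always responding rich earns only the rich stream
  expect_equal(expected_value(-50, p, 2), 6.0, tolerance = 1e-9)

  set.seed(23)
  grid <- seq(-6, 6, length.out = 1000L)
  for (i in 1:50) {
    pp <- payoff_structure(
      reward_cents = runif(1, 5, 50),
      p_reward_given_correct_rich = runif(1, 0.3, 0.9),
      p_reward_given_correct_lean = runif(1, 0.05, 0.3),
      stimulus_probability_rich = runif(1, 0.2, 0.8))
    dp <- runif(1, 0.2, 3)
    ev_opt <- expected_value(optimal_criterion(pp, dp), pp, dp)
    expect_gte(ev_opt + 1e-10, max(expected_value(grid, pp, dp)))
  }
})

test_that("the EV shortfall is zero only at the optimum and grows with distance from it", {
  p <- payoff_structure(p_reward_given_correct_rich = 0.6,
                        p_reward_given_correct_lean = 0.2)
  set.seed(41)
  for (i in 1:30) {
    dp <- runif(1, 0.3, 2.5)
    c_opt <- optimal_criterion(p, dp)
    expect_equal(rbd_shortfall(c_opt, dp, p), 0, tolerance = 1e-9)
    offs <- c(0, 0.5, 1.0, 1.5)
    up <- rbd_shortfall(c_opt + offs, dp, p)
    dn <- rbd_shortfall(c_opt - offs, dp, p)
    expect_true(all(diff(up) > 0))
    expect_true(all(diff(dn) > 0))
    expect_true(all(c(up, dn) >= 0))
  }
})

test_that("compute_rbd scores an optimal agent near zero and a random responder at its enumerated shortfall", {
  p <- payoff_structure(p_reward_given_correct_rich = 0.6,
                        p_reward_given_correct_lean = 0.2)
  # exact operating point at the optimum, huge n
  dp <- 1.4
  opt_counts <- counts_from_point(optimal_criterion(p, dp), dp)
  expect_equal(compute_rbd(opt_counts, p)$rbd, 0, tolerance = 1e-4)

  # uniform random responder: hit = fa = 1/2, EV enumerates to
  # 0.5 * 0.5 * 12 + 0.5 * 0.5 * 4 = 4 cents/trial; reference d' fixed at 2
  rnd <- counts_row(50, 50, 50, 50)
  ev_opt <- expected_value(optimal_criterion(p, 2), p, 2)
  got <- compute_rbd(rnd, p, d_prime = 2)$rbd
  expect_equal(got, ev_opt - 4.0, tolerance = 1e-9)

  expect_error(compute_rbd(counts_row(0, 0, 50, 50), p),
               "insufficient data")
  expect_error(compute_rbd(rnd, p, method = "nope"), "unknown RBD method")
})

test_that("RBD is invariant to relabeling rich and lean jointly with the payoff", {
  p <- payoff_structure(p_reward_given_correct_rich = 0.6,
                        p_reward_given_correct_lean = 0.2,
                        stimulus_probability_rich = 0.4)
  p_swapped <- payoff_structure(p_reward_given_correct_rich = 0.2,
                                p_reward_given_correct_lean = 0.6,
                                stimulus_probability_rich = 0.6)
  set.seed(7)
  for (i in 1:20) {
    cells <- as.integer(rmultinom(1L, 200L, runif(4L, 0.05, 1)))
    a <- counts_row(cells[1L], cells[2L], cells[3L], cells[4L])
    b <- counts_row(cells[3L], cells[4L], cells[1L], cells[2L])
    expect_equal(compute_rbd(a, p)$rbd, compute_rbd(b, p_swapped)$rbd,
                 tolerance = 1e-12)
  }
})

test_that("the method registry accepts new forms and stamps the tag on output", {
  expect_true("ev_shortfall" %in% rbd_methods())
  register_rbd_method("criterion_distance", function(op, d_used, payoff)
    abs(op$c_hat - optimal_criterion(payoff, d_used)))
  on.exit(rm("criterion_distance", envir = rbdprt:::.rbd_registry))
  out <- compute_rbd(counts_row(70, 30, 60, 40), method = "criterion_distance")
  expect_equal(out$method_tag, "criterion_distance")
  expect_true(is.finite(out$rbd))
})
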