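test_that("mass-action derivatives match hand-evaluated terms", {
  rt <- rate_constants(10, 12, 2.8e-3, 1e-3)
  d <- mass_action_rhs(mixture_state(A = 1, AT = 0, AS = 0, T = 1, S = 1), rt)
  expect_equal(d[["AT"]], 10)
  expect_equal(d[["AS"]], 12)
  expect_equal(d[["A"]], -22)
  expect_equal(d[["T"]], -10)
  expect_equal(d[["S"]], -12)

  # absent species stays absent
  d0 <- mass_action_rhs(mixture_state(A = 1, AT = 0.5, T = 2, S = 0), rt)
  expect_identical(d0[["AS"]], 0)
  expect_identical(d0[["S"]], 0)

  # actin species derivatives sum to zero exactly
  set.seed(4)
  for (i in 1:20) {
    st <- mixture_state(A = runif(1, 0, 5), AT = runif(1, 0, 5),
                        AS = runif(1, 0, 5), T = runif(1, 0, 30),
                        S = runif(1, 0, 10))
    dd <- mass_action_rhs(st, random_rates())
    # zero up to one rounding of the re-summation
    expect_lt(abs(dd[["A"]] + dd[["AT"]] + dd[["AS"]]),
              1e-15 * max(abs(dd)))
  }

  expect_error(mixture_state(A = -1), "non-negative")
})

test_that("the analytic equilibrium zeroes the rate equations", {
  rt <- ref_rates()
  eq <- competitive_equilibrium(5, 15, 5, rt)
  expect_lt(max(abs(mass_action_rhs(eq, rt))), 1e-10)
  # two-ligand competition at these totals leaves ~44% of actin on the label
  expect_equal(eq[["AS"]] / 5, 0.44, tolerance = 0.02)

  # single-ligand limit agrees with the closed-form quadratic
  KT <- kd(rt)[["Kd_T"]]
  A_tot <- 2; T_tot <- 6
  b <- A_tot + T_tot + KT
  AT_quad <- (b - sqrt(b^2 - 4 * A_tot * T_tot)) / 2
  eq1 <- competitive_equilibrium(A_tot, T_tot, 0, rt)
  expect_equal(eq1[["AT"]], AT_quad, tolerance = 1e-10)
  expect_equal(eq1[["AT"]], 2, tolerance = 1e-3)   # essentially fully bound
  expect_identical(eq1[["AS"]], 0)

  # symmetric ligands bind symmetrically
  rts <- rate_constants(5, 5, 1e-3, 1e-3)
  eqs <- competitive_equilibrium(2, 4, 4, rts)
  expect_equal(eqs[["AT"]], eqs[["AS"]], tolerance = 1e-12)

  # empty system
  eq0 <- competitive_equilibrium(0, 0, 0, rt)
  expect_equal(unclass(eq0), c(A = 0, AT = 0, AS = 0, T = 0, S = 0))
})

test_that("simulated trajectories conserve mass and reach the equilibrium oracle", {
  set.seed(101)
  for (i in 1:25) {
    rt <- random_rates()
    A_tot <- runif(1, 0.5, 5)
    S_tot <- runif(1, 0.05, 2)
    T_tot <- 3 * A_tot
    t_end <- 50 / min(rt["k_off_T"], rt["k_off_S"])
    ex <- exchange_experiment(A_total = A_tot, S_total = S_tot,
                              T_total = T_tot,
                              duration = t_end, dt = t_end / 4)
    sim <- simulate_exchange(ex, rt)
    totals <- cbind(sim$A + sim$AT + sim$AS, sim$T + sim$AT, sim$S + sim$AS)
    expect_lt(max(abs(sweep(totals, 2, c(A_tot, T_tot, S_tot)) /
                        rep(c(A_tot, T_tot, S_tot), each = nrow(totals)))),
              1e-9)
    eq <- competitive_equilibrium(A_tot, T_tot, S_tot, rt)
    final <- as.numeric(sim[nrow(sim), c("A", "AT", "AS", "T", "S")])
    expect_lt(max(abs(final - as.numeric(eq)) / pmax(as.numeric(eq), 1e-6)),
              1e-4)
  }
})

test_that("integration accuracy is tolerance-robust", {
  ex <- exchange_experiment(A_total = 2, S_total = 0.2, duration = 1800)
  rt <- ref_rates()
  s1 <- simulate_exchange(ex, rt)
  s2 <- simulate_exchange(ex, rt, rtol = 5e-11, atol = 5e-13)
  expect_lt(max(abs(as.matrix(s1[-1]) - as.matrix(s2[-1]))), 1e-6)
})

test_that("no labelled nucleotide means no labelled complex, ever", {
  ex <- exchange_experiment(A_total = 2, S_total = 0, duration = 600)
  sim <- simulate_exchange(ex, ref_rates())
  expect_true(all(sim$AS == 0))
  expect_true(all(sim$S == 0))
})

test_that("bound-analogue rise is monotone in the reference association regime", {
  for (S_tot in c(0.025, 0.2)) {
    ex <- exchange_experiment(A_total = 2, S_total = S_tot, duration = 1800)
    sim <- simulate_exchange(ex, ref_rates())
    expect_true(all(diff(sim$AS) >= -1e-12))
  }
})

test_that("initial exchange speed scales linearly with the scenario multiplier", {
  # from fully loaded actin the release of bound ATP is rate-limiting, so
  # early AS(t) is proportional to the dissociation multiplier
  base <- NULL
  for (m in c(0.2, 1, 2)) {
    ex <- exchange_experiment(A_total = 2, S_total = 0.2, duration = 10,
                              dt = 5, scenario = scenario_modifiers(m))
    sim <- simulate_exchange(ex, ref_rates())
    as10 <- sim$AS[sim$time == 10]
    if (m == 0.2) base <- as10 / 0.2
    expect_equal(as10 / m, base, tolerance = 0.05)
  }
})

test_that("chase addition is an instantaneous step of free ATP", {
  ex <- exchange_experiment(A_total = 2, S_total = 0.2, duration = 3600,
                            dt = 10, chase = list(time = 1800, T_add = 100))
  sim <- simulate_exchange(ex, ref_rates())
  i <- which(sim$time == 1800)
  pre <- sim[i - 1L, ]
  expect_gt(sim$T[i] - pre$T, 99)          # the 100 uM step, minus rebinding
  expect_true(all(diff(sim$AS[sim$time >= 1800]) < 0))  # label chased off

  # conservation still holds across the discontinuity (totals shift by T_add)
  post <- sim[sim$time >= 1800, ]
  expect_lt(max(abs(post$T + post$AT - (6 + 100))) / 106, 1e-9)

  expect_error(
    exchange_experiment(A_total = 2, S_total = 0.2, duration = 1800,
                        chase = list(time = 2000, T_add = 100)),
    "inside")
})

test_that("experiment validation enforces the loading convention", {
  expect_error(exchange_experiment(A_total = 2, S_total = 0.2, T_total = 1),
               "T_total >= A_total")
  expect_error(exchange_experiment(A_total = 2, S_total = 0.2, duration = 0),
               "duration")
  ex <- exchange_experiment(A_total = 2, S_total = 0.2)
  expect_equal(unclass(ex$init),
               c(A = 0, AT = 2, AS = 0, T = 4, S = 0.2))
  # custom initial state must match the declared totals
  expect_error(
    exchange_experiment(A_total = 2, S_total = 0.2,
                        init = mixture_state(A = 1, AT = 0.5, T = 1, S = 0.2)),
    "inconsistent")
})
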