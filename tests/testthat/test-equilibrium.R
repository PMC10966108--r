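test_that("trio assembly keeps one offspring per family and drops thin rows", {
  ped <- data.frame(
    id = 1:9,
    father_id = c(0, 0, 0, 0, 1, 1, 3, 3, 3),
    mother_id = c(0, 0, 0, 0, 2, 2, 4, 4, 4),
    sex = c(1, 2, 1, 2, 1, 2, 1, 2, 1),
    generation = c(0, 0, 0, 0, 1, 1, 1, 1, 1)
  )
  pgi <- data.frame(id = 1:9, pgi = c(0.1, 0.2, NA, NA, 0.3, 0.4, 0.5, 0.6, 0.7))
  set.seed(1)
  td <- assemble_trios(ped, pgi)
  # family (3,4): parents unobserved, child-only rows excluded
  expect_equal(nrow(td$data), 1L)
  expect_equal(unname(td$data[1, c("m", "f")]), c(0.2, 0.1))
  # the retained child is one of the family's children, chosen by seed
  expect_true(td$data[1, "o"] %in% c(0.3, 0.4))
})

test_that("FIML recovers structured trio parameters and the transmission identity", {
  set.seed(101)
  td <- simulate_trios(30000, v_p = 1, c_mf = 0.14, v_o = 1.07,
                       means = c(0.05, -0.02, 0.1))
  fit <- fiml_fit(td)
  expect_equal(fit$v_p, 1, tolerance = 0.02)
  expect_equal(fit$c_mf, 0.14, tolerance = 0.1)
  expect_equal(fit$v_o, 1.07, tolerance = 0.02)
  expect_equal(unname(fit$means), c(0.05, -0.02, 0.1), tolerance = 0.3)
  # d is structural, not free: holds exactly at the optimum
  expect_identical(fit$d, (fit$v_p + fit$c_mf) / 2)
  expect_identical(fit$v_o, fit$d + fit$v_kf)
  # the constrained fit satisfies v_o = v_p exactly
  fit_c <- fiml_fit(td, constrained = TRUE)
  expect_equal(fit_c$v_o, fit_c$v_p, tolerance = 1e-12)
  expect_equal(fit_c$q, 1, tolerance = 1e-12)
  expect_equal(fit_c$u, 1, tolerance = 1e-9)
})

test_that("the free-fit variance ratio matches the sample ratio on complete data", {
  set.seed(102)
  td <- simulate_trios(20000, v_p = 1, c_mf = 0.2, v_o = 1.08)
  fit <- fiml_fit(td)
  q_sample <- var(td$data[, "o"]) / mean(c(var(td$data[, "m"]),
                                           var(td$data[, "f"])))
  expect_equal(fit$q, q_sample, tolerance = 0.01)
})

test_that("FIML on heavily incomplete data agrees with complete-case analysis", {
  set.seed(103)
  mix <- c(mfo = 0.4, mf = 0.15, mo = 0.3, fo = 0.15)
  td <- simulate_trios(30000, v_p = 1, c_mf = 0.14, v_o = 1.07,
                       pattern_probs = mix)
  fit_fiml <- fiml_fit(td)
  complete <- td$data[rowSums(is.na(td$data)) == 0L, ]
  fit_cc <- fiml_fit(complete)
  expect_equal(fit_fiml$q, fit_cc$q, tolerance = 0.03)
  expect_equal(fit_fiml$u, fit_cc$u, tolerance = 0.1)
  # FIML uses all patterns: tighter profile interval than complete-case
  ci_fiml <- profile_ci(fit_fiml, "q")
  ci_cc <- profile_ci(fit_cc, "q")
  expect_lt(diff(ci_fiml), diff(ci_cc))
})

test_that("the equilibrium LRT behaves as a 1-df chi-square test", {
  set.seed(104)
  td <- simulate_trios(20000, v_p = 1, c_mf = 0.14, v_o = 1) # equilibrium
  et <- equilibrium_test(td)
  expect_gt(et$lrt$p_value, 0.001)
  expect_equal(et$lrt$df, 1L)
  expect_gte(et$lrt$statistic, 0)
  # CI for q straddles 1 under the null
  expect_lt(et$q_ci[1], 1)
  expect_gt(et$q_ci[2], 1)

  # strong disequilibrium is detected
  td2 <- simulate_trios(20000, v_p = 1, c_mf = 0.14, v_o = 1.07)
  et2 <- equilibrium_test(td2)
  expect_lt(et2$lrt$p_value, 1e-6)
  expect_gt(et2$q_ci[1], 1)
})

test_that("profile intervals shrink like 1/sqrt(n) and bracket the estimate", {
  set.seed(105)
  td_small <- simulate_trios(4000, v_p = 1, c_mf = 0.14, v_o = 1.05)
  td_big <- simulate_trios(36000, v_p = 1, c_mf = 0.14, v_o = 1.05)
  ci_s <- profile_ci(fiml_fit(td_small), "q")
  ci_b <- profile_ci(fiml_fit(td_big), "q")
  expect_equal(diff(ci_s) / diff(ci_b), 3, tolerance = 0.35)
  fit <- fiml_fit(td_big)
  expect_lt(ci_b[1], fit$q)
  expect_gt(ci_b[2], fit$q)
  u_ci <- profile_ci(fit, "u")
  expect_lt(u_ci[1], fit$u)
  expect_gt(u_ci[2], fit$u)
})

test_that("the U estimator ties back to the theoretical trajectory", {
  # generate parent/offspring generation pairs from the recursion's
  # moments and check that the fitted u reproduces the theoretical U
  h2_0 <- 0.5; mu <- 0.28
  for (g in c(1L, 3L)) {
    traj <- disequilibrium_trajectory(mu, h2_0, g)
    v_p <- traj$v_a[g]; rho <- traj$rho_t[g]
    set.seed(200 + g)
    td <- simulate_trios(50000, v_p = v_p, c_mf = rho * v_p,
                         v_o = (v_p + rho * v_p) / 2 + 0.5)
    fit <- fiml_fit(td)
    u_theory <- expected_u_after_generations(mu, h2_0, g)
    expect_equal(fit$u, u_theory, tolerance = 0.05)
  }
  # at the fixed point u is 1
  v_eq <- equilibrium_additive_variance(mu, h2_0)
  rho_eq <- mu * v_eq / (v_eq + 1)
  set.seed(300)
  td_eq <- simulate_trios(50000, v_p = v_eq, c_mf = rho_eq * v_eq, v_o = v_eq)
  expect_equal(fiml_fit(td_eq)$u, 1, tolerance = 0.05)
})

test_that("degenerate and inconsistent fits are rejected cleanly", {
  set.seed(106)
  td <- simulate_trios(5000)
  fit_f <- fiml_fit(td); fit_c <- fiml_fit(td, constrained = TRUE)
  expect_error(lrt_equilibrium(fit_c, fit_f), "constrained")
  # swapping loglik order to fake a negative statistic trips the guard
  fake <- fit_f; fake$loglik <- fit_c$loglik - 1
  expect_error(lrt_equilibrium(fake, fit_c), "optimizer failure")
  expect_equal(profile_ci(fit_c, "q"), c(1, 1))
})
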