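test_that("partner and first-degree equilibrium correlations follow the path algebra", {
  expect_equal(partner_genotypic_correlation(trait_params(0.50, 0.50)), 0.25)
  expect_equal(partner_genotypic_correlation(trait_params(0, 0.8)), 0)
  expect_equal(partner_genotypic_correlation(trait_params(0.23, 0.80)), 0.184)
  # symmetric in the sign of mu
  expect_equal(partner_genotypic_correlation(trait_params(-0.23, 0.80)), -0.184)

  expect_equal(first_degree_equilibrium(0.25), 0.625)
  expect_equal(first_degree_equilibrium(0), 0.5)
  expect_equal(first_degree_equilibrium(1), 1)
})

test_that("PGI partner correlations attenuate by the genetic signal", {
  expect_equal(pgi_partner_correlation(trait_params(0.5, 0.5, 1)), 0.25)
  expect_equal(pgi_partner_correlation(trait_params(0.5, 0.5, 1 / 3)),
               0.25 / 3, tolerance = 1e-12)
  expect_equal(pgi_partner_correlation(trait_params(0.7, 0.3, 0)), 0)

  # squared PGI-phenotype correlation as the h2*s2 estimate
  expect_equal(signif(pgi_partner_correlation_from_validity(0.11, 0.14), 2),
               0.0017)
  expect_equal(pgi_partner_correlation_from_validity(1, 0.3), 0.3)
  expect_equal(pgi_partner_correlation_from_validity(0.5, 0.2), 0.05)

  expect_equal(pgi_first_degree_equilibrium(0.14), 0.57)
  expect_equal(pgi_first_degree_equilibrium(0), 0.5)
  expect_equal(pgi_first_degree_equilibrium(0.25), 0.625)
})

test_that("k-th degree expectations and relative increases match hand values", {
  expect_equal(round(kth_degree_equilibrium(0.25, 3), 3), 0.244)
  expect_equal(round(kth_degree_equilibrium(0.25, 5), 3), 0.095)
  expect_equal(kth_degree_equilibrium(0, 1:6), 0.5^(1:6))
  # degree 1 reduces exactly to the first-degree formula for any rho
  for (rho in seq(-0.9, 0.9, by = 0.15)) {
    expect_equal(kth_degree_equilibrium(rho, 1), first_degree_equilibrium(rho))
  }
  expect_equal(relative_increase(0.25, 1), 25)
  expect_equal(round(relative_increase(0.25, 3)), 95)
  expect_equal(relative_increase(0, 4), 0)
  expect_error(kth_degree_equilibrium(0.25, 0), "degree")
  expect_error(kth_degree_equilibrium(0.25, 2.5), "degree")
})

test_that("assortment's effect grows with degree in ratio, peaks at degree 2 in absolute terms", {
  for (rho in seq(0.01, 0.5, by = 0.035)) {
    ratio <- kth_degree_equilibrium(rho, 1:6) / 0.5^(1:6)
    expect_true(all(diff(ratio) > 0))
    absinc <- kth_degree_equilibrium(rho, 1:6) - 0.5^(1:6)
    expect_equal(which.max(absinc), 2L)
  }
})

test_that("affinal chains multiply blood segments and copaths", {
  sil <- relationship_spec("affinal", chain = list(1, "partner"))
  expect_equal(affinal_correlation(sil, 0.25), 0.625 * 0.25)
  # a chain with one blood segment and two copaths
  cil <- relationship_spec("affinal", chain = list(1, "partner", "partner"))
  expect_equal(affinal_correlation(cil, 0.25), 0.625 * 0.0625)
  expect_equal(affinal_correlation(sil, 0), 0)
  expect_error(relationship_spec("affinal", chain = list()), "chain")
  expect_error(relationship_spec("affinal", chain = list(1, 2)), "copath")
  expect_error(relationship_spec("blood", degree = 1, chain = list(1)), "chain")
})

test_that("segregation variance keeps unit phenotypic variance at equilibrium", {
  expect_equal(recombination_variance(trait_params(0.5, 0.5)), 0.375)
  expect_equal(recombination_variance(trait_params(0, 0.9)), 0.5)
  expect_equal(recombination_variance(trait_params(1, 1)), 0)
})

test_that("the variance recursion reproduces hand-computed values and converges", {
  traj <- disequilibrium_trajectory(mu = 0.28, h2_0 = 0.5, n_gens = 60)
  expect_equal(traj$v_a[1], 1)
  expect_equal(traj$rho_t[1], 0.14)
  expect_equal(traj$v_a[2], 1.07) # 0.5 * 1 * 1.14 + 0.5
  v_fix <- equilibrium_additive_variance(0.28, 0.5)
  expect_equal(v_fix, 1 / sqrt(0.72), tolerance = 1e-12) # 0.36 v^2 = 0.5
  # monotone convergence to the fixed point
  gap <- abs(traj$v_a - v_fix)
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[61], 1e-8)
  # at convergence the parent-offspring correlation recovers (1 + rho)/2
  rho_eq <- 0.28 * v_fix / (v_fix + 1)
  expect_equal(parent_offspring_correlation_at(traj, 59),
               (1 + rho_eq) / 2, tolerance = 1e-8)
  # random mating leaves everything flat
  flat <- disequilibrium_trajectory(0, 0.5, 5)
  expect_equal(flat$v_a, rep(1, 6))
  expect_equal(parent_offspring_correlation_at(flat, 2), 0.5)
  expect_error(disequilibrium_trajectory(1, 1, 5), "diverges")
})

test_that("parent-offspring correlation during disequilibrium is depressed", {
  traj <- disequilibrium_trajectory(0.28, 0.5, 5)
  expect_equal(parent_offspring_correlation_at(traj, 0),
               0.57 / sqrt(1.07), tolerance = 1e-10)
  # below the naive equilibrium prediction from the same generation's rho
  expect_lt(parent_offspring_correlation_at(traj, 0),
            first_degree_equilibrium(traj$rho_t[1]))
  expect_error(parent_offspring_correlation_at(traj, 5), "offspring generation")
})

test_that("U rises from ~73% at first-generation assortment towards 100%", {
  # hand recursion: r_po = 0.57 / sqrt(1.07), U = (2 r_po - 1) / 0.14
  expect_equal(expected_u_after_generations(0.28, 0.5, 1),
               (2 * 0.57 / sqrt(1.07) - 1) / 0.14, tolerance = 1e-12)
  expect_equal(round(expected_u_after_generations(0.28, 0.5, 1), 2), 0.73)
  expect_equal(round(expected_u_after_generations(0.28, 0.5, 3), 4), 0.9113)
  expect_equal(expected_u_after_generations(0.28, 0.5, Inf), 1)
  u_seq <- vapply(1:12, function(g) expected_u_after_generations(0.28, 0.5, g),
                  numeric(1))
  expect_true(all(diff(u_seq) > 0))
  expect_true(all(u_seq <= 1))
  expect_error(expected_u_after_generations(0, 0.5, 2), "undefined")
})

test_that("founder heritability calibration hits the target equilibrium h2", {
  h2_0 <- founder_h2_for_equilibrium(0.5, 0.5)
  expect_equal(h2_0, 3 / 7, tolerance = 1e-12)
  traj <- disequilibrium_trajectory(0.5, h2_0, 80)
  expect_equal(traj$h2_t[81], 0.5, tolerance = 1e-9)
  expect_equal(traj$rho_t[81], 0.25, tolerance = 1e-9)
})

test_that("PGI variance ratios scale up by the genetic signal", {
  expect_equal(true_variance_ratio(1.0246, 1 / 3), 1 + 0.0246 * 3)
  expect_equal(true_variance_ratio(1.5, 1), 1.5)
})

test_that("equilibrium_expectations collects consistent tables", {
  ee <- equilibrium_expectations(trait_params(0.5, 0.5, 0.5), max_degree = 4)
  expect_equal(ee$rho_g, 0.25)
  expect_equal(ee$rho_pgi, 0.125)
  expect_equal(unname(ee$r_g_by_degree), kth_degree_equilibrium(0.25, 1:4))
  expect_true(all(diff(ee$r_g_by_degree) < 0))
  expect_equal(ee$v_k, 0.375)
})
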