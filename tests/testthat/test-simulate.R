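test_that("founders satisfy the configured heritability and are reproducible", {
  cfg <- sim_config(n_per_generation = 4000, n_loci = 400, h2_0 = 0.5, seed = 3)
  set.seed(cfg$seed)
  pop <- init_founders(cfg)
  h2_emp <- var(pop$ped$a) / var(pop$ped$p)
  expect_equal(h2_emp, 0.5, tolerance = 0.05)
  expect_equal(var(pop$ped$a), 1, tolerance = 0.1)
  expect_equal(sum(pop$ped$sex == 1), sum(pop$ped$sex == 2))
  # same seed, bitwise-identical population
  pop2 <- run_cohort(cfg)
  pop3 <- run_cohort(cfg)
  expect_identical(pop2$ped, pop3$ped)
})

test_that("copula rank matching realizes the target partner correlation", {
  set.seed(11)
  pf <- rnorm(20000); pm <- rnorm(20000)
  pr <- assortative_pairing(pf, pm, mu = 0.5)
  expect_equal(cor(pf[pr$f_idx], pm[pr$m_idx]), 0.5, tolerance = 0.02)
  # mu = 0: a uniform random permutation, near-zero correlation
  pr0 <- assortative_pairing(pf, pm, mu = 0)
  expect_lt(abs(cor(pf[pr0$f_idx], pm[pr0$m_idx])), 0.03)
  # mu = 1: rank-for-rank matching
  pr1 <- assortative_pairing(pf, pm, mu = 1)
  expect_identical(rank(pf[pr1$f_idx]), rank(pm[pr1$m_idx]))
  expect_error(assortative_pairing(pf, pm, 1.5), "mu")
})

test_that("every child genotype is Mendelian-consistent with its parents", {
  cfg <- sim_config(n_per_generation = 200, n_loci = 60, n_generations = 3,
                    mu = 0.4, seed = 21)
  pop <- run_cohort(cfg, keep_genotypes = TRUE)
  ped <- pop$ped
  for (g in 1:2) {
    kids <- which(ped$generation == g)
    G <- pop$genotypes[[as.character(g)]]
    Gp <- pop$genotypes[[as.character(g - 1L)]]
    par_rows <- which(ped$generation == g - 1L)
    fa <- match(ped$father_id[kids], ped$id[par_rows])
    mo <- match(ped$mother_id[kids], ped$id[par_rows])
    gm <- Gp[mo, , drop = FALSE]
    gf <- Gp[fa, , drop = FALSE]
    # a homozygous parent forces its allele; count bounds per locus
    lower <- (gm == 2L) + (gf == 2L)
    upper <- 2L - (gm == 0L) - (gf == 0L)
    expect_true(all(G >= lower & G <= upper))
  }
})

test_that("parent-offspring genotypic correlation is 1/2 under random mating", {
  cfg <- sim_config(n_per_generation = 8000, n_loci = 300, mu = 0,
                    n_generations = 2, seed = 5)
  pop <- run_cohort(cfg)
  kids <- pop$ped[pop$ped$generation == 1L, ]
  a_by_id <- setNames(pop$ped$a, pop$ped$id)
  r_po <- cor(kids$a, a_by_id[as.character(kids$mother_id)])
  expect_equal(r_po, 0.5, tolerance = 0.04)
})

test_that("the first-generation variance inflation matches the recursion", {
  cfg <- sim_config(n_per_generation = 20000, n_loci = 500, mu = 0.5,
                    h2_0 = 0.5, n_generations = 2, seed = 13)
  pop <- run_cohort(cfg)
  vt <- variance_by_generation(pop)
  rho0 <- 0.5 * vt$h2[1]
  expect_equal(vt$var_a[2] / vt$var_a[1], 0.5 * (1 + rho0) + 0.5,
               tolerance = 0.03)
})

test_that("the realized genetic signal reflects the PGI locus subset", {
  cfg <- sim_config(n_per_generation = 6000, n_loci = 900, pgi_fraction = 1,
                    mu = 0, n_generations = 2, seed = 7)
  pop <- run_cohort(cfg)
  expect_equal(unname(pop$realized_s2["founders"]), 1, tolerance = 1e-10)

  cfg3 <- sim_config(n_per_generation = 6000, n_loci = 900,
                     pgi_fraction = 1 / 3, mu = 0, n_generations = 2, seed = 7)
  pop3 <- run_cohort(cfg3)
  # under linkage equilibrium the signal is the subset's genic-variance
  # share, which is ~1/3 up to the luck of the subset draw
  gvar <- pop3$effects^2 * 2 * pop3$freqs * (1 - pop3$freqs)
  share <- sum(gvar[pop3$pgi_loci]) / sum(gvar)
  expect_equal(unname(pop3$realized_s2["founders"]), share, tolerance = 0.03)
  expect_equal(share, 1 / 3, tolerance = 0.2)

  # under assortment, induced linkage disequilibrium inflates the signal
  cfg_am <- sim_config(n_per_generation = 6000, n_loci = 900,
                       pgi_fraction = 1 / 3, mu = 0.6, h2_0 = 0.6,
                       n_generations = 6, seed = 7)
  pop_am <- run_cohort(cfg_am)
  expect_gt(pop_am$realized_s2["last"], pop_am$realized_s2["founders"])
})

test_that("an imperfect PGI biases dyad correlations towards random-mating values", {
  # low genetic signal shrinks the partner PGI correlation towards 0 and
  # first-degree PGI correlations towards the coefficient of relationship
  cfg <- sim_config(n_per_generation = 8000, n_loci = 600, mu = 0.5,
                    h2_0 = 0.5, pgi_fraction = 0.25, n_generations = 8,
                    seed = 37)
  pop <- run_cohort(cfg)
  sub <- truncate_pedigree(pop$ped[, c("id", "father_id", "mother_id", "sex",
                                       "generation")], 5)
  dy <- enumerate_dyads(sub, types = c("partner", "full-sibling"))
  set.seed(37)
  est_a <- dyad_correlation(data.frame(id = pop$ped$id, value = pop$ped$a), dy)
  set.seed(37)
  est_p <- dyad_correlation(data.frame(id = pop$ped$id, value = pop$ped$pgi), dy)
  r_a <- setNames(est_a$r, est_a$label)
  r_p <- setNames(est_p$r, est_p$label)
  expect_lt(r_p[["partner"]], r_a[["partner"]])
  expect_gt(r_p[["partner"]], 0)
  expect_lt(r_p[["full-sibling"]], r_a[["full-sibling"]])
  expect_gt(r_p[["full-sibling"]], 0.5)
})

test_that("emitted cohort files round-trip and honor the missingness mix", {
  cfg <- sim_config(n_per_generation = 2000, n_loci = 100, n_generations = 3,
                    mu = 0.3, seed = 17)
  pop <- run_cohort(cfg)
  dir <- tempfile("cohort")
  set.seed(99)
  out <- emit_cohort(pop, dir,
                     missingness = c(complete = 0.4, partners_only = 0.1,
                                     mother_child = 0.3, father_child = 0.05,
                                     unusable = 0.15))
  ped <- read_pedigree(out$pedigree)
  pgi <- read_pgi_table(out$pgi)
  expect_equal(ped$id, pop$ped$id)
  expect_equal(ped$a, pop$ped$a, tolerance = 1e-10)
  expect_equal(nrow(pgi), nrow(pop$ped))
  # pattern draws within multinomial error of the requested mix
  n_fam <- sum(out$pattern_counts)
  p_hat <- as.numeric(out$pattern_counts["complete"]) / n_fam
  expect_equal(p_hat, 0.4, tolerance = 4 * sqrt(0.4 * 0.6 / n_fam))
  # terminal-generation families reflect the pattern in their NA structure
  expect_true(anyNA(pgi$pgi))
})

test_that("a planted couple-level confounder biases the partner correlation until residualized", {
  cfg <- sim_config(n_per_generation = 4000, n_loci = 200, n_generations = 3,
                    mu = 0, seed = 23)
  pop <- run_cohort(cfg)
  dir <- tempfile("conf")
  set.seed(1)
  out <- emit_cohort(pop, dir, confound = 0.4)
  ped <- read_pedigree(out$pedigree)
  pgi <- read_pgi_table(out$pgi)
  dy <- enumerate_dyads(ped, types = "partner")
  raw <- dyad_correlation(data.frame(id = pgi$id, value = pgi$pgi), dy)
  expect_gt(raw$r, 0.02) # spurious correlation from the shared covariate
  clean <- residualize(pgi, "pgi", c("cov1", "cov2"))
  adj <- dyad_correlation(data.frame(id = clean$id, value = clean$pgi), dy)
  expect_lt(abs(adj$r), 3 / sqrt(adj$n_dyads))
})
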