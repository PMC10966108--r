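#' Configuration for a forward-time assortative-mating cohort simulation
#'
#' Defines a discrete-generation, monogamous, constant-size diploid
#' population with a polygenic trait under direct phenotypic assortment.
#' Founders are drawn in linkage equilibrium; later generations arise by
#' Mendelian segregation at independent biallelic loci, so segregation
#' variance emerges mechanically rather than being assumed.
#'
#' @param n_per_generation Individuals per generation (even; half per sex).
#' @param n_loci Number of biallelic causal loci.
#' @param maf_range Interval from which per-locus allele frequencies are
#'   drawn uniformly.
#' @param mu Target phenotypic partner correlation.
#' @param h2_0 Heritability in the founder generation.
#' @param pgi_fraction Fraction of causal loci entering the polygenic index;
#'   values below 1 produce an imperfect PGI whose realized genetic signal is
#'   reported by [compute_pgi()].
#' @param n_generations Total number of generations including founders.
#' @param offspring_per_pair Children per couple (2 keeps the size constant).
#' @param vertical_gamma Per-parent phenotypic transmission coefficient: each
#'   child's phenotype gains `vertical_gamma * (p_mother + p_father)`,
#'   generating gene-environment correlation.
#' @param sib_env Variance of an environmental component shared by siblings.
#' @param seed RNG seed used by [run_cohort()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_per_generation = 4000L, n_loci = 1000L,
                       maf_range = c(0.1, 0.9), mu = 0.5, h2_0 = 0.5,
                       pgi_fraction = 1, n_generations = 3L,
                       offspring_per_pair = 2L, vertical_gamma = 0,
                       sib_env = 0, seed = 1L) {
  stopifnot(n_per_generation >= 4, n_per_generation %% 2 == 0,
            n_loci >= 1, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
            mu >= -1, mu <= 1, h2_0 > 0, h2_0 <= 1,
            pgi_fraction > 0, pgi_fraction <= 1,
            n_generations >= 1, offspring_per_pair >= 1,
            vertical_gamma >= 0, sib_env >= 0)
  structure(list(n_per_generation = as.integer(n_per_generation),
                 n_loci = as.integer(n_loci), maf_range = maf_range,
                 mu = mu, h2_0 = h2_0, pgi_fraction = pgi_fraction,
                 n_generations = as.integer(n_generations),
                 offspring_per_pair = as.integer(offspring_per_pair),
                 vertical_gamma = vertical_gamma, sib_env = sib_env,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Initialize the founder generation
#'
#' Draws per-locus allele frequencies, genotypes in linkage equilibrium,
#' and normally distributed effect sizes scaled so that the founder additive
#' variance is 1 in expectation. Environmental deviations are drawn so the
#' founder heritability equals `h2_0`. Sexes are assigned in balanced
#' numbers. Uses the current RNG state ([run_cohort()] seeds it).
#'
#' @param config A [sim_config()].
#' @return An object of class `"am_population"`: a list with the pedigree
#'   data frame (`ped`), per-generation genotype matrices (`genotypes`),
#'   locus effects, allele frequencies, and the PGI locus subset.
#' @export
init_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_generation
  L <- config$n_loci
  freqs <- stats::runif(L, config$maf_range[1], config$maf_range[2])
  beta <- stats::rnorm(L)
  beta <- beta / sqrt(sum(beta^2 * 2 * freqs * (1 - freqs)))
  geno <- matrix(stats::rbinom(n * L, 2L, rep(freqs, each = n)), n, L)
  storage.mode(geno) <- "integer"
  a <- drop(geno %*% beta) - sum(2 * freqs * beta)
  v_e <- (1 - config$h2_0) / config$h2_0
  e <- stats::rnorm(n, 0, sqrt(v_e))
  p <- a + e
  n_pgi <- max(1L, round(config$pgi_fraction * L))
  pgi_loci <- sort(sample.int(L, n_pgi))
  ped <- data.frame(
    id = seq_len(n), father_id = 0L, mother_id = 0L,
    sex = sample(rep(c(1L, 2L), n %/% 2)), generation = 0L,
    a = a, e = e, p = p, pgi = NA_real_
  )
  structure(list(config = config, freqs = freqs, effects = beta,
                 pgi_loci = pgi_loci, v_e = v_e, ped = ped,
                 genotypes = list(`0` = geno)),
            class = "am_population")
}

#' @export
print.am_population <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d individuals in %d generation(s), %d loci\n",
              nrow(x$ped), length(unique(x$ped$generation)),
              x$config$n_loci))
  invisible(x)
}

#' Pair two sexes with a target phenotypic correlation
#'
#' Gaussian-copula rank matching: latent bivariate-normal pairs with
#' correlation `mu` are drawn, each margin is sorted, and same-rank
#' individuals (after sorting the observed phenotypes) are paired. The
#' realized cross-partner phenotypic correlation then has expectation `mu`
#' for approximately normal phenotypes. `mu = 0` yields a uniformly random
#' pairing; `mu = 1` matches rank for rank.
#'
#' @param pheno_f,pheno_m Phenotypes of the two sexes (equal lengths).
#' @param mu Target partner correlation, in \[-1, 1\].
#' @return A data frame with columns `f_idx`, `m_idx`: indices into
#'   `pheno_f` and `pheno_m` defining the couples.
#' @export
assortative_pairing <- function(pheno_f, pheno_m, mu) {
  n <- length(pheno_f)
  stopifnot(length(pheno_m) == n, n >= 1)
  check_correlation(mu, "mu")
  zf <- stats::rnorm(n)
  zm <- mu * zf + sqrt(1 - mu^2) * stats::rnorm(n)
  f_idx <- order(pheno_f)[rank(zf, ties.method = "first")]
  m_idx <- order(pheno_m)[rank(zm, ties.method = "first")]
  data.frame(f_idx = f_idx, m_idx = m_idx)
}

#' Breed the next generation
#'
#' Each couple produces `offspring_per_pair` children by independent
#' Mendelian segregation at every locus. Children receive fresh
#' environmental deviations; optional vertical transmission adds
#' `vertical_gamma * (p_mother + p_father)` and `sib_env` adds a shared
#' sibling component to the phenotype. Offspring sexes are assigned in
#' balanced numbers.
#'
#' @param pop An `"am_population"` whose latest generation is to reproduce.
#' @param pairs A data frame of couples as returned by
#'   [assortative_pairing()], with `f_idx`/`m_idx` indexing the latest
#'   generation's females and males (in pedigree row order within sex).
#' @param config The simulation configuration.
#' @return The population with the new generation appended.
#' @export
reproduce <- function(pop, pairs, config = pop$config) {
  t_par <- max(pop$ped$generation)
  par_rows <- which(pop$ped$generation == t_par)
  par_ped <- pop$ped[par_rows, ]
  G_par <- pop$genotypes[[as.character(t_par)]]
  fem <- which(par_ped$sex == 2L)
  mal <- which(par_ped$sex == 1L)
  mother_row <- fem[pairs$f_idx]
  father_row <- mal[pairs$m_idx]

  k <- config$offspring_per_pair
  n_off <- nrow(pairs) * k
  # family index of each child (children of one couple are adjacent)
  fam <- rep(seq_len(nrow(pairs)), each = k)
  Gm <- G_par[mother_row[fam], , drop = FALSE]
  Gf <- G_par[father_row[fam], , drop = FALSE]
  # one transmitted allele per parent: Bernoulli(g/2) per locus
  G_off <- matrix(stats::rbinom(length(Gm), 1L, Gm / 2) +
                    stats::rbinom(length(Gf), 1L, Gf / 2),
                  n_off, ncol(G_par))
  storage.mode(G_off) <- "integer"

  a <- drop(G_off %*% pop$effects) - sum(2 * pop$freqs * pop$effects)
  e <- stats::rnorm(n_off, 0, sqrt(pop$v_e))
  p <- a + e
  if (config$vertical_gamma > 0) {
    p <- p + config$vertical_gamma *
      (par_ped$p[mother_row[fam]] + par_ped$p[father_row[fam]])
  }
  if (config$sib_env > 0) {
    p <- p + rep(stats::rnorm(nrow(pairs), 0, sqrt(config$sib_env)), each = k)
  }
  next_id <- max(pop$ped$id)
  ped_off <- data.frame(
    id = next_id + seq_len(n_off),
    father_id = par_ped$id[father_row[fam]],
    mother_id = par_ped$id[mother_row[fam]],
    sex = sample(rep(c(1L, 2L), length.out = n_off)),
    generation = t_par + 1L,
    a = a, e = e, p = p, pgi = NA_real_
  )
  pop$ped <- rbind(pop$ped, ped_off)
  pop$genotypes[[as.character(t_par + 1L)]] <- G_off
  pop
}

#' Compute polygenic indices and the realized genetic signal
#'
#' The PGI is the true-effect-weighted allele-count sum over the locus
#' subset chosen at initialization (a fraction `pgi_fraction` of causal
#' loci), centered and scaled by the founder-generation moments so that
#' intergenerational variance differences are preserved. The realized
#' genetic signal `s2` -- the squared correlation between PGI and true
#' breeding value -- is reported separately for founders and for the last
#' generation: under assortment the assortment-induced linkage
#' disequilibrium inflates it above the subset's naive variance share.
#'
#' @param pop An `"am_population"` with genotype matrices retained (the
#'   incremental path inside [run_cohort()] does not need them all at once).
#' @return The population with the `pgi` pedigree column filled and an
#'   element `realized_s2` (named vector with entries `founders` and
#'   `last`).
#' @export
compute_pgi <- function(pop) {
  gens <- sort(unique(pop$ped$generation))
  if (!all(as.character(gens) %in% names(pop$genotypes)))
    stop("genotype matrices for every generation are required; ",
         "run_cohort() computes the PGI incrementally instead")
  for (g in gens) pop <- pgi_raw_generation(pop, g)
  finalize_pgi(pop)
}

# raw PGI (effect-weighted allele counts over the subset) for one generation
pgi_raw_generation <- function(pop, g) {
  beta_sub <- pop$effects[pop$pgi_loci]
  rows <- which(pop$ped$generation == g)
  if (is.null(pop$pgi_raw)) pop$pgi_raw <- rep(NA_real_, nrow(pop$ped))
  if (length(pop$pgi_raw) < nrow(pop$ped))
    pop$pgi_raw <- c(pop$pgi_raw,
                     rep(NA_real_, nrow(pop$ped) - length(pop$pgi_raw)))
  G <- pop$genotypes[[as.character(g)]]
  pop$pgi_raw[rows] <- drop(G[, pop$pgi_loci, drop = FALSE] %*% beta_sub)
  pop
}

# standardize by founder moments (so intergenerational variance ratios
# survive) and record the realized genetic signal
finalize_pgi <- function(pop) {
  raw <- pop$pgi_raw
  g0 <- which(pop$ped$generation == 0L)
  pop$ped$pgi <- (raw - mean(raw[g0])) / stats::sd(raw[g0])
  gl <- which(pop$ped$generation == max(pop$ped$generation))
  pop$realized_s2 <- c(
    founders = stats::cor(raw[g0], pop$ped$a[g0])^2,
    last = stats::cor(raw[gl], pop$ped$a[gl])^2
  )
  pop
}

#' Run a full multigeneration cohort simulation
#'
#' Seeds the RNG from the configuration, initializes founders, then
#' alternates assortative pairing and reproduction for
#' `n_generations - 1` rounds, computing PGIs at the end. Deterministic
#' given the seed.
#'
#' @param config A [sim_config()].
#' @param keep_genotypes Retain per-generation genotype matrices (memory
#'   heavy for large runs); breeding values, phenotypes and PGIs are always
#'   retained.
#' @return An `"am_population"` spanning all generations.
#' @examples
#' pop <- run_cohort(sim_config(n_per_generation = 200, n_loci = 50,
#'                              n_generations = 3, seed = 7))
#' table(pop$ped$generation)
#' @export
run_cohort <- function(config, keep_genotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pop <- init_founders(config)
  pop <- pgi_raw_generation(pop, 0L)
  for (t in seq_len(config$n_generations - 1L)) {
    cur <- pop$ped[pop$ped$generation == t - 1L, ]
    pairs <- assortative_pairing(cur$p[cur$sex == 2L], cur$p[cur$sex == 1L],
                                 config$mu)
    pop <- reproduce(pop, pairs, config)
    pop <- pgi_raw_generation(pop, t)
    # parents older than the breeding generation are no longer needed
    if (t >= 2L && !keep_genotypes) pop$genotypes[[as.character(t - 2L)]] <- NULL
  }
  pop <- finalize_pgi(pop)
  if (!keep_genotypes) pop$genotypes <- list()
  pop
}

#' Per-generation variance of true breeding values
#'
#' Convenience summary used to compare the simulator against the
#' deterministic variance recursion of [disequilibrium_trajectory()].
#'
#' @param pop An `"am_population"`.
#' @return A data frame with columns `generation`, `var_a`, `var_p`, `h2`.
#' @export
variance_by_generation <- function(pop) {
  gens <- sort(unique(pop$ped$generation))
  out <- lapply(gens, function(g) {
    rows <- pop$ped$generation == g
    data.frame(generation = g,
               var_a = stats::var(pop$ped$a[rows]),
               var_p = stats::var(pop$ped$p[rows]),
               h2 = stats::var(pop$ped$a[rows]) / stats::var(pop$ped$p[rows]))
  })
  do.call(rbind, out)
}

#' Write cohort files with covariates and trio missingness
#'
#' Emits the pedigree and PGI tables as plain TSV, the way a cohort release
#' would look. Two nuisance covariates are attached: `cov1`, a couple- and
#' family-shared factor (a stand-in for ancestry principal components or
#' genotyping batch) that, with `confound > 0`, also contaminates the
#' emitted PGI and plants a spurious partner correlation that
#' [residualize()] must remove; and `cov2`, pure noise. A missingness
#' pattern over mother/father/child PGI availability is applied to the
#' nuclear families of the terminal two generations.
#'
#' @param pop An `"am_population"`.
#' @param dir Output directory (created if needed).
#' @param missingness Named probabilities over
#'   `c("complete", "partners_only", "mother_child", "father_child",
#'   "unusable")`; normalized to sum to 1. `NULL` leaves everything
#'   observed.
#' @param confound Coefficient of the shared covariate added to the emitted
#'   PGI (0 = clean PGI).
#' @return Invisibly, a list with the two file paths and the per-family
#'   pattern counts.
#' @export
emit_cohort <- function(pop, dir, missingness = NULL, confound = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- pop$ped
  n <- nrow(ped)

  # couple/family-shared covariate: founders get couple values, children
  # inherit the parental mean plus noise (PC/batch-like structure)
  cov1 <- rep(NA_real_, n)
  founders <- ped$father_id == 0L
  cov1[founders] <- stats::rnorm(sum(founders))
  for (g in sort(unique(ped$generation))[-1]) {
    rows <- which(ped$generation == g)
    fa <- match(ped$father_id[rows], ped$id)
    mo <- match(ped$mother_id[rows], ped$id)
    cov1[rows] <- 0.5 * (cov1[fa] + cov1[mo]) +
      stats::rnorm(length(rows), 0, 0.5)
  }
  if (confound > 0) {
    # every couple shares a latent value (regional/batch stratification);
    # children inherit half of it: plants a spurious partner correlation
    non_founder <- which(!founders)
    ck <- paste(ped$father_id[non_founder], ped$mother_id[non_founder])
    first <- non_founder[!duplicated(ck)]
    fam_val <- stats::rnorm(length(first))
    fam_of_child <- match(ck, ck[!duplicated(ck)])
    shared <- rep(0, n)
    shared[match(ped$father_id[first], ped$id)] <-
      shared[match(ped$father_id[first], ped$id)] + fam_val
    shared[match(ped$mother_id[first], ped$id)] <-
      shared[match(ped$mother_id[first], ped$id)] + fam_val
    shared[non_founder] <- shared[non_founder] + 0.5 * fam_val[fam_of_child]
    cov1 <- cov1 + shared
  }
  cov2 <- stats::rnorm(n)
  pgi_out <- ped$pgi + confound * cov1

  if (!is.null(missingness)) {
    pat <- c(complete = 0, partners_only = 0, mother_child = 0,
             father_child = 0, unusable = 0)
    pat[names(missingness)] <- missingness
    pat <- pat / sum(pat)
    t_max <- max(ped$generation)
    child_rows <- which(ped$generation == t_max)
    fams <- split(child_rows,
                  paste(ped$father_id[child_rows], ped$mother_id[child_rows]))
    drawn <- sample(names(pat), length(fams), replace = TRUE, prob = pat)
    for (i in seq_along(fams)) {
      kids <- fams[[i]]
      fa <- match(ped$father_id[kids[1]], ped$id)
      mo <- match(ped$mother_id[kids[1]], ped$id)
      drop <- switch(drawn[i],
                     complete = integer(0),
                     partners_only = kids,
                     mother_child = fa,
                     father_child = mo,
                     unusable = c(kids, fa, mo))
      pgi_out[drop] <- NA_real_
    }
    pattern_counts <- table(factor(drawn, levels = names(pat)))
  } else {
    pattern_counts <- NULL
  }

  ped_path <- file.path(dir, "pedigree.tsv")
  pgi_path <- file.path(dir, "pgi.tsv")
  write_pedigree(ped, ped_path)
  pgi_tab <- data.frame(id = ped$id, pgi = pgi_out, cov1 = cov1, cov2 = cov2)
  utils::write.table(pgi_tab, pgi_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(pedigree = ped_path, pgi = pgi_path,
                 pattern_counts = pattern_counts))
}
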