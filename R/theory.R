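#' Trait parameters for assortative-mating theory
#'
#' Bundle of the three quantities that determine genotypic and
#' polygenic-index (PGI) correlations between relatives under direct
#' phenotypic assortative mating: the phenotypic partner correlation
#' attributable to assortment (`mu`), the trait heritability (`h2`), and the
#' genetic signal (`s2`) -- the shared variance between the PGI and the true
#' additive genetic factor. The environmental path is always derived as
#' `sqrt(1 - h2)` and never stored.
#'
#' @param mu Phenotypic partner correlation attributable to assortment, in
#'   \[-1, 1\]. Negative values describe disassortative mating.
#' @param h2 Heritability at the reference generation, in \[0, 1\].
#' @param s2 Genetic signal: shared variance between the PGI and the true
#'   additive genetic factor, in \[0, 1\]. Defaults to 1 (a perfect PGI), in
#'   which case PGI expectations reduce to genotypic ones. Note that
#'   assortment-induced linkage disequilibrium is part of the signal, so `s2`
#'   can exceed the squared accuracy of the PGI weights.
#'
#' @return An object of class `"trait_params"`: a list with elements `mu`,
#'   `h2`, `s2`.
#' @examples
#' tp <- trait_params(mu = 0.5, h2 = 0.5)
#' partner_genotypic_correlation(tp) # 0.25
#' @export
trait_params <- function(mu, h2, s2 = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(h2), length(h2) == 1L, is.finite(h2),
            is.numeric(s2), length(s2) == 1L, is.finite(s2))
  if (mu < -1 || mu > 1) stop("`mu` must lie in [-1, 1]")
  if (h2 < 0 || h2 > 1) stop("`h2` must lie in [0, 1]")
  if (s2 < 0 || s2 > 1) stop("`s2` must lie in [0, 1]")
  structure(list(mu = mu, h2 = h2, s2 = s2), class = "trait_params")
}

#' @export
print.trait_params <- function(x, ...) {
  cat(sprintf("Trait parameters: mu = %.4g, h2 = %.4g, s2 = %.4g\n",
              x$mu, x$h2, x$s2))
  cat(sprintf("  partner genotypic correlation rho_g  = %.4g\n",
              partner_genotypic_correlation(x)))
  cat(sprintf("  partner PGI correlation       rho_pgi = %.4g\n",
              pgi_partner_correlation(x)))
  invisible(x)
}

as_trait_params <- function(x) {
  if (inherits(x, "trait_params")) x else do.call(trait_params, as.list(x))
}

#' Genotypic correlation between partners
#'
#' Under direct phenotypic assortment the only path connecting the partners'
#' additive genetic factors runs through the two phenotypes and the
#' assortment copath, so the cross-partner correlation of true additive
#' genetic factors is the assortment strength weighted by the heritability:
#' `rho_g = mu * h2`.
#'
#' @param params A [trait_params()] object (or a list coercible to one).
#' @return The genotypic partner correlation, a scalar.
#' @examples
#' partner_genotypic_correlation(trait_params(0.5, 0.5)) # 0.25
#' @export
partner_genotypic_correlation <- function(params) {
  params <- as_trait_params(params)
  params$mu * params$h2
}

#' Equilibrium genotypic correlation between first-degree relatives
#'
#' At intergenerational equilibrium, parent-offspring pairs and full siblings
#' share the same genotypic correlation, raised above the random-mating
#' coefficient of relationship (1/2) by half the genotypic partner
#' correlation: `(1 + rho_g) / 2`.
#'
#' @param rho_g Genotypic partner correlation, in \[-1, 1\].
#' @return Correlation between first-degree relatives' additive genetic
#'   factors at equilibrium.
#' @examples
#' first_degree_equilibrium(0.25) # 0.625
#' @export
first_degree_equilibrium <- function(rho_g) {
  check_correlation(rho_g, "rho_g")
  (1 + rho_g) / 2
}

#' Polygenic-index correlation between partners
#'
#' The PGI is an imperfect proxy for the true additive genetic factor; the
#' expected cross-partner PGI correlation attenuates the genotypic one by the
#' genetic signal: `rho_pgi = mu * h2 * s2`.
#'
#' @inheritParams partner_genotypic_correlation
#' @return The PGI partner correlation, a scalar.
#' @examples
#' pgi_partner_correlation(trait_params(0.5, 0.5, s2 = 1/3))
#' @export
pgi_partner_correlation <- function(params) {
  params <- as_trait_params(params)
  params$mu * params$h2 * params$s2
}

#' PGI partner correlation implied by the PGI-phenotype correlation
#'
#' When `h2` and `s2` are unknown but the PGI-phenotype correlation is, their
#' product can be estimated as that correlation squared, giving the expected
#' PGI partner correlation `r_pgi_pheno^2 * mu` under direct assortment.
#' Useful for judging whether a null partner correlation is informative: a
#' weak PGI makes the expectation tiny even under real assortment.
#'
#' @param r_pgi_pheno Correlation between the PGI and the phenotype.
#' @param mu Phenotypic partner correlation attributable to assortment.
#' @return Expected PGI partner correlation.
#' @examples
#' # depression: a PGI-phenotype correlation of .11 and partner correlation
#' # .14 imply an expected PGI partner correlation of only ~.0017
#' pgi_partner_correlation_from_validity(0.11, 0.14)
#' @export
pgi_partner_correlation_from_validity <- function(r_pgi_pheno, mu) {
  check_correlation(r_pgi_pheno, "r_pgi_pheno")
  check_correlation(mu, "mu")
  r_pgi_pheno^2 * mu
}

#' Equilibrium PGI correlation between first-degree relatives
#'
#' Same form as [first_degree_equilibrium()] with the PGI partner correlation
#' in place of the genotypic one. Because the PGI measurement error is itself
#' shared between relatives, the PGI correlation is biased towards the
#' coefficient of relationship (1/2), not towards zero.
#'
#' @param rho_pgi PGI partner correlation, in \[-1, 1\].
#' @return Expected PGI correlation between first-degree relatives.
#' @examples
#' pgi_first_degree_equilibrium(0.14) # 0.57
#' @export
pgi_first_degree_equilibrium <- function(rho_pgi) {
  check_correlation(rho_pgi, "rho_pgi")
  (1 + rho_pgi) / 2
}

#' Equilibrium genotypic correlation between k-th degree relatives
#'
#' All chains between the genotypes of k-th degree blood relatives pass
#' sequentially through the genotypes of intermediate first-degree relatives,
#' so the equilibrium correlation is the first-degree correlation raised to
#' the degree of relatedness: `((1 + rho) / 2)^k`. With `rho = rho_pgi` this
#' is the stated approximation for PGI correlations (the true PGI value can
#' be slightly higher when the genetic signal is low).
#'
#' @param rho Partner correlation (genotypic or PGI), in \[-1, 1\].
#' @param k Degree of relatedness: positive integer (1 = parent-offspring or
#'   full siblings, 2 = avuncular or grandparent, 3 = first cousins, ...).
#'   May be a vector.
#' @return Expected correlation(s) between k-th degree relatives.
#' @examples
#' kth_degree_equilibrium(0.25, 1:5)
#' @export
kth_degree_equilibrium <- function(rho, k) {
  check_correlation(rho, "rho")
  check_degree(k)
  ((1 + rho) / 2)^k
}

#' Relative increase over random mating for k-th degree relatives
#'
#' Percentage increase of the equilibrium correlation between k-th degree
#' relatives over the random-mating coefficient of relationship `0.5^k`.
#' Grows with `k`: assortment has a proportionally larger effect on distant
#' relatives.
#'
#' @inheritParams kth_degree_equilibrium
#' @return Percent increase (e.g. 25 means 25\%).
#' @examples
#' relative_increase(0.25, c(1, 3)) # 25% for siblings, ~95% for cousins
#' @export
relative_increase <- function(rho, k) {
  100 * (kth_degree_equilibrium(rho, k) / 0.5^k - 1)
}

#' Describe a relationship for correlation expectations
#'
#' Blood relationships are described by their degree `k`; affinal (in-law)
#' relationships by a chain of blood segments joined by partner copaths.
#' The chain is an ordered list whose elements are either a positive integer
#' (a blood segment of that degree) or the string `"partner"` (a copath).
#' Examples: sibling-in-law is `list(1, "partner")`; the partner of a child
#' (child-in-law as seen by a parent, through the child's own partnership
#' and the in-law family) can chain more copaths.
#'
#' @param kind `"blood"` or `"affinal"`.
#' @param degree For blood relationships, the degree `k >= 1`.
#' @param chain For affinal relationships, the chain as described above; must
#'   contain at least one `"partner"` copath.
#' @return An object of class `"relationship_spec"`.
#' @examples
#' relationship_spec("affinal", chain = list(1, "partner"))
#' @export
relationship_spec <- function(kind = c("blood", "affinal"), degree = NULL,
                              chain = NULL) {
  kind <- match.arg(kind)
  if (kind == "blood") {
    check_degree(degree)
    if (!is.null(chain) && length(chain) > 0)
      stop("blood relationships take no chain")
    chain <- list()
  } else {
    if (is.null(chain) || length(chain) == 0)
      stop("affinal relationships need a non-empty chain")
    ok <- vapply(chain, function(el) {
      identical(el, "partner") ||
        (is.numeric(el) && length(el) == 1L && el >= 1 && el == as.integer(el))
    }, logical(1))
    if (!all(ok))
      stop("chain elements must be positive integer degrees or \"partner\"")
    if (!any(vapply(chain, identical, logical(1), "partner")))
      stop("affinal chains must contain at least one partner copath")
    degree <- NA_integer_
  }
  structure(list(kind = kind, degree = degree, chain = chain),
            class = "relationship_spec")
}

#' Genotypic correlation between affinal (in-law) relatives
#'
#' Under assortative mating, non-blood relatives acquire non-zero genotypic
#' correlations through chains of blood segments linked by partner copaths.
#' Each blood segment of degree `k` contributes `((1 + rho) / 2)^k` and each
#' copath contributes `rho`; the chain's correlation is the product. For
#' example a sibling-in-law (chain `list(1, "partner")`) has correlation
#' `r_g1 * rho`.
#'
#' @param spec A [relationship_spec()] with `kind = "affinal"`.
#' @param rho Partner correlation (genotypic or PGI), in \[-1, 1\].
#' @return Expected correlation along the chain.
#' @examples
#' sil <- relationship_spec("affinal", chain = list(1, "partner"))
#' affinal_correlation(sil, 0.25) # 0.625 * 0.25 = 0.15625
#' @export
affinal_correlation <- function(spec, rho) {
  stopifnot(inherits(spec, "relationship_spec"))
  if (spec$kind != "affinal") stop("`spec` must describe an affinal relationship")
  check_correlation(rho, "rho")
  prod(vapply(spec$chain, function(el) {
    if (identical(el, "partner")) rho else kth_degree_equilibrium(rho, el)
  }, numeric(1)))
}

#' Recombination (segregation) variance at equilibrium
#'
#' Within-family genetic variance created by Mendelian segregation. Under
#' unit phenotypic variance at equilibrium it equals `(1 - mu * h2) / 2`,
#' the value that keeps the phenotypic variance at unity across generations.
#'
#' @inheritParams partner_genotypic_correlation
#' @return The segregation variance `V_K`.
#' @examples
#' recombination_variance(trait_params(0.5, 0.5)) # 0.375
#' @export
recombination_variance <- function(params) {
  params <- as_trait_params(params)
  (1 - params$mu * params$h2) / 2
}

#' Full set of equilibrium expectations for a trait
#'
#' Convenience wrapper collecting the partner correlations, by-degree
#' relative correlations (genotypic and the PGI approximation), and the
#' segregation variance for one trait.
#'
#' @inheritParams partner_genotypic_correlation
#' @param max_degree Largest degree of relatedness to tabulate.
#' @return A list of class `"equilibrium_expectations"` with elements
#'   `rho_g`, `rho_pgi`, `r_g_by_degree`, `r_pgi_by_degree` (named numeric
#'   vectors over degrees `1:max_degree`), and `v_k`.
#' @examples
#' equilibrium_expectations(trait_params(0.5, 0.5), max_degree = 5)
#' @export
equilibrium_expectations <- function(params, max_degree = 5L) {
  params <- as_trait_params(params)
  check_degree(max_degree)
  k <- seq_len(max_degree)
  rho_g <- partner_genotypic_correlation(params)
  rho_pgi <- pgi_partner_correlation(params)
  structure(list(
    rho_g = rho_g,
    rho_pgi = rho_pgi,
    r_g_by_degree = stats::setNames(kth_degree_equilibrium(rho_g, k), k),
    r_pgi_by_degree = stats::setNames(kth_degree_equilibrium(rho_pgi, k), k),
    v_k = recombination_variance(params)
  ), class = "equilibrium_expectations")
}

# ---- disequilibrium: the approach to equilibrium -------------------------

#' Deterministic trajectory of genetic variance under assortative mating
#'
#' Generation-by-generation recursion for a trait under the infinitesimal
#' model when phenotypic assortment of constant strength `mu` begins in a
#' previously random-mating population. Variances are expressed in units of
#' the baseline genic (additive) variance, so `v_a(0) = 1`; the environmental
#' variance `v_e = (1 - h2_0) / h2_0` and the segregation variance (half the
#' baseline genic variance, 1/2) stay fixed, while the realized additive
#' variance, heritability and genotypic partner correlation evolve:
#' \deqn{v_a(t+1) = \tfrac12 v_a(t) (1 + \rho_t) + \tfrac12,\quad
#'       h^2_t = v_a(t) / (v_a(t) + v_e),\quad \rho_t = \mu h^2_t.}
#' `v_a` converges monotonically to the fixed point of the recursion, where
#' the familial correlations attain their equilibrium values.
#'
#' @param mu Phenotypic partner correlation attributable to assortment.
#' @param h2_0 Heritability in the baseline (generation 0) population,
#'   in (0, 1\].
#' @param n_gens Number of assorting generations to iterate (>= 1).
#' @return A data frame with one row per generation `t = 0, ..., n_gens` and
#'   columns `t`, `v_a`, `h2_t`, `rho_t`; attribute `v_k_base = 0.5`.
#' @examples
#' traj <- disequilibrium_trajectory(mu = 0.28, h2_0 = 0.5, n_gens = 10)
#' traj$v_a[2] # 1.07 after one assorting generation
#' @seealso [equilibrium_additive_variance()] for the closed-form fixed
#'   point, [expected_u_after_generations()] for the U statistic along the
#'   trajectory.
#' @export
disequilibrium_trajectory <- function(mu, h2_0, n_gens) {
  check_correlation(mu, "mu")
  stopifnot(is.numeric(h2_0), length(h2_0) == 1L, h2_0 > 0, h2_0 <= 1,
            is.numeric(n_gens), length(n_gens) == 1L, n_gens >= 1,
            n_gens == as.integer(n_gens))
  if (abs(mu) >= 1 && h2_0 >= 1)
    stop("mu * h2 = 1: variance diverges, no equilibrium exists")
  v_e <- (1 - h2_0) / h2_0
  v_a <- numeric(n_gens + 1L)
  v_a[1L] <- 1
  h2 <- rho <- numeric(n_gens + 1L)
  for (i in seq_len(n_gens + 1L)) {
    h2[i] <- v_a[i] / (v_a[i] + v_e)
    rho[i] <- mu * h2[i]
    if (i <= n_gens) v_a[i + 1L] <- 0.5 * v_a[i] * (1 + rho[i]) + 0.5
  }
  structure(
    data.frame(t = 0:n_gens, v_a = v_a, h2_t = h2, rho_t = rho),
    v_k_base = 0.5, mu = mu, h2_0 = h2_0
  )
}

#' Equilibrium additive variance under stable assortment
#'
#' Closed-form fixed point of the recursion in
#' [disequilibrium_trajectory()]: the positive root of
#' `(1 - mu) v^2 + (v_e - 1) v - v_e = 0` with `v_e = (1 - h2_0) / h2_0`
#' (and `v = 1 / (1 - mu)` in the limiting case `h2_0 = 1`).
#'
#' @inheritParams disequilibrium_trajectory
#' @return Equilibrium additive variance in units of the baseline genic
#'   variance.
#' @examples
#' equilibrium_additive_variance(0.28, 0.5) # 1/sqrt(0.72)
#' @export
equilibrium_additive_variance <- function(mu, h2_0) {
  check_correlation(mu, "mu")
  stopifnot(h2_0 > 0, h2_0 <= 1)
  if (abs(mu) >= 1 && h2_0 >= 1)
    stop("mu * h2 = 1: variance diverges, no equilibrium exists")
  v_e <- (1 - h2_0) / h2_0
  if (mu == 1) return(-v_e / (v_e - 1)) # degenerate linear case, v_e > 1 only
  a <- 1 - mu; b <- v_e - 1; cc <- -v_e
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

#' Parent-offspring genotypic correlation along a trajectory
#'
#' The transmission covariance between a parent in generation `t` and their
#' offspring in generation `t + 1` is half the parental variance times
#' `1 + rho_t` (the direct Mendelian half plus the path through the other,
#' assorted parent); standardizing by the two generations' variances gives
#' the correlation. During disequilibrium this falls short of the
#' equilibrium value `(1 + rho) / 2` because the offspring generation has
#' more variance.
#'
#' @param traj A trajectory from [disequilibrium_trajectory()].
#' @param t Parental generation index, `0 <= t <= n_gens - 1`.
#' @return The parent-offspring genotypic correlation for that generation
#'   pair.
#' @examples
#' traj <- disequilibrium_trajectory(0.28, 0.5, 5)
#' parent_offspring_correlation_at(traj, 0) # ~0.5511
#' @export
parent_offspring_correlation_at <- function(traj, t) {
  stopifnot(is.data.frame(traj), all(c("t", "v_a", "rho_t") %in% names(traj)),
            length(t) == 1L, t == as.integer(t))
  i <- match(t, traj$t)
  if (is.na(i) || i >= nrow(traj))
    stop("`t` must index a generation with an offspring generation in `traj`")
  covar <- 0.5 * traj$v_a[i] * (1 + traj$rho_t[i])
  covar / sqrt(traj$v_a[i] * traj$v_a[i + 1L])
}

#' Expected U statistic after g generations of stable assortment
#'
#' U is the observed increase in the parent-offspring correlation over the
#' increase expected at equilibrium given the parental partner correlation:
#' `U = (2 * r_po - 1) / rho`, with `r_po` the standardized parent-offspring
#' correlation and `rho` the parental-generation genotypic partner
#' correlation. If the parental generation is the first ever to assort
#' (`g = 1`), U is about 70--73\%; U rises towards 100\% as the trait
#' approaches intergenerational equilibrium.
#'
#' Generation counting: `g` assorting generations means generations
#' `0, ..., g - 1` mate assortatively and U is evaluated on the
#' (g-1, g) parent-offspring pair. `g = Inf` returns the equilibrium value 1.
#'
#' @inheritParams disequilibrium_trajectory
#' @param g Number of assorting generations (>= 1), or `Inf`.
#' @return U as a fraction (0.73 means 73\%).
#' @examples
#' expected_u_after_generations(0.28, 0.5, 1) # ~0.73
#' expected_u_after_generations(0.28, 0.5, 3) # ~0.91
#' @export
expected_u_after_generations <- function(mu, h2_0, g) {
  check_correlation(mu, "mu")
  stopifnot(h2_0 > 0, h2_0 <= 1, length(g) == 1L, g >= 1)
  if (mu == 0) stop("U is undefined when there is no assortment (rho = 0)")
  if (is.infinite(g)) return(1)
  stopifnot(g == as.integer(g))
  traj <- disequilibrium_trajectory(mu, h2_0, n_gens = g)
  r_po <- parent_offspring_correlation_at(traj, g - 1L)
  (2 * r_po - 1) / traj$rho_t[g]
}

#' Founder heritability that yields a target equilibrium heritability
#'
#' Because additive variance grows under assortment while the environmental
#' variance stays fixed, heritability rises along the approach to
#' equilibrium. To simulate or reason about a trait whose heritability is
#' `h2_eq` *at equilibrium* (the state in which the equilibrium path model
#' is drawn), the founding random-mating population must start lower. With
#' `rho = mu * h2_eq`, the equilibrium additive variance in baseline genic
#' units is `1 / (1 - rho)`, giving `v_e = (1 - h2_eq) / (h2_eq (1 - rho))`
#' and founder heritability `1 / (1 + v_e)`.
#'
#' @param mu Assortment strength.
#' @param h2_eq Desired heritability at equilibrium.
#' @return Founder-generation heritability.
#' @examples
#' founder_h2_for_equilibrium(0.5, 0.5) # 3/7: h2 rises to 0.5 at equilibrium
#' @export
founder_h2_for_equilibrium <- function(mu, h2_eq) {
  check_correlation(mu, "mu")
  stopifnot(h2_eq > 0, h2_eq < 1)
  rho <- mu * h2_eq
  if (rho >= 1) stop("mu * h2_eq must be below 1")
  v_eq <- 1 / (1 - rho)
  v_e <- v_eq * (1 - h2_eq) / h2_eq
  1 / (1 + v_e)
}

#' Implied true-variance ratio from an observed PGI variance ratio
#'
#' The intergenerational variance ratio measured on a PGI understates the
#' true genetic one: if the PGI captures a fraction `s2` of the true additive
#' factor, an observed PGI excess variance of `q_pgi - 1` implies a true
#' excess of `(q_pgi - 1) / s2`.
#'
#' @param q_pgi Observed ratio of offspring to parental PGI variance.
#' @param s2 Genetic signal of the PGI, in (0, 1\].
#' @return Implied ratio of offspring to parental true genetic variance.
#' @examples
#' true_variance_ratio(1.0246, 1/3) # ~1.074: a 2.46% PGI excess implies ~7.4%
#' @export
true_variance_ratio <- function(q_pgi, s2) {
  stopifnot(is.numeric(q_pgi), q_pgi > 0, is.numeric(s2), s2 > 0, s2 <= 1)
  1 + (q_pgi - 1) / s2
}

# ---- shared validators ---------------------------------------------------

check_correlation <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < -1 || x > 1)
    stop(sprintf("`%s` must be a single correlation in [-1, 1]", name))
  invisible(x)
}

check_degree <- function(k) {
  if (!is.numeric(k) || length(k) < 1L || any(!is.finite(k)) ||
      any(k < 1) || any(k != as.integer(k)))
    stop("degree `k` must consist of positive integers")
  invisible(k)
}
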