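#' Assemble mother-father-child trios from cohort tables
#'
#' One offspring is sampled uniformly per mother-father couple (so families
#' contribute a single trio), and PGI availability defines the per-cell
#' missingness. Trios with fewer than two observed members carry no
#' information about any covariance parameter and are excluded.
#'
#' @param ped Pedigree data frame (or path to a pedigree TSV).
#' @param pgi_tab PGI data frame (or path) with `id` and `pgi` columns.
#' @return An object of class `"trio_dataset"`: list with `data` (n x 3
#'   matrix, columns `m`, `f`, `o`, `NA` for unobserved) and
#'   `pattern_counts` (named vector over observed patterns).
#' @export
assemble_trios <- function(ped, pgi_tab) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  if (is.character(pgi_tab)) pgi_tab <- read_pgi_table(pgi_tab)
  check_pedigree(ped)
  kids <- ped[ped$father_id != 0L & ped$mother_id != 0L, ]
  if (nrow(kids) == 0L) stop("no usable families in pedigree")
  key <- paste(kids$father_id, kids$mother_id)
  picked <- vapply(split(kids$id, key), function(v)
    if (length(v) == 1L) v else sample(v, 1L), numeric(1))
  fam <- kids[match(picked, kids$id), c("id", "father_id", "mother_id")]
  val <- stats::setNames(pgi_tab$pgi, pgi_tab$id)
  dat <- cbind(m = unname(val[as.character(fam$mother_id)]),
               f = unname(val[as.character(fam$father_id)]),
               o = unname(val[as.character(fam$id)]))
  n_obs <- rowSums(!is.na(dat))
  dat <- dat[n_obs >= 2L, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no trios with at least two observed members")
  new_trio_dataset(dat)
}

new_trio_dataset <- function(dat) {
  pat <- apply(!is.na(dat), 1L, function(b)
    paste(c("m", "f", "o")[b], collapse = ""))
  structure(list(data = dat, pattern_counts = table(pat)),
            class = "trio_dataset")
}

#' Simulate trio PGI data with structured covariance and missingness
#'
#' Draws mother/father/offspring PGI triples from a multivariate normal
#' with the transmission-structured covariance (equal parental variances
#' `v_p`, partner covariance `c`, parent-offspring covariance
#' `(v_p + c) / 2`, offspring variance `v_o`), then masks cells according to
#' the requested observed-pattern mix. Used for calibration and power
#' studies of the equilibrium test.
#'
#' @param n Number of trios.
#' @param v_p Parental variance.
#' @param c_mf Partner covariance.
#' @param v_o Offspring variance (equilibrium: `v_o = v_p`).
#' @param means Length-3 means (mother, father, offspring).
#' @param pattern_probs Named probabilities over patterns `"mfo"`, `"mf"`,
#'   `"mo"`, `"fo"`; default all complete.
#' @return A `"trio_dataset"`.
#' @export
simulate_trios <- function(n, v_p = 1, c_mf = 0.14, v_o = v_p,
                           means = c(0, 0, 0),
                           pattern_probs = c(mfo = 1)) {
  d <- (v_p + c_mf) / 2
  sigma <- matrix(c(v_p, c_mf, d,
                    c_mf, v_p, d,
                    d, d, v_o), 3L, 3L)
  ch <- chol(sigma)
  dat <- matrix(stats::rnorm(3L * n), n, 3L) %*% ch
  dat <- sweep(dat, 2L, means, "+")
  colnames(dat) <- c("m", "f", "o")
  pats <- c("mfo", "mf", "mo", "fo")
  stopifnot(all(names(pattern_probs) %in% pats))
  pp <- stats::setNames(numeric(4), pats)
  pp[names(pattern_probs)] <- pattern_probs
  draw <- sample(pats, n, replace = TRUE, prob = pp)
  dat[draw == "mf", "o"] <- NA
  dat[draw == "mo", "f"] <- NA
  dat[draw == "fo", "m"] <- NA
  new_trio_dataset(dat)
}

# per-pattern sufficient statistics: n, mean, ML covariance of observed cols
trio_suffstats <- function(dat) {
  obs <- !is.na(dat)
  key <- apply(obs, 1L, function(b) paste(which(b), collapse = ","))
  lapply(split(seq_len(nrow(dat)), key), function(rows) {
    cols <- which(!is.na(dat[rows[1L], ]))
    x <- dat[rows, cols, drop = FALSE]
    n <- nrow(x)
    xbar <- colMeans(x)
    xc <- sweep(x, 2L, xbar)
    list(cols = cols, n = n, xbar = xbar, S = crossprod(xc) / n)
  })
}

# FIML log-likelihood from sufficient statistics
# theta: list(mu = length-3, v_p, c_mf, v_kf); Var(o) = (v_p+c)/2 + v_kf
trio_loglik <- function(ss, mu, v_p, c_mf, v_kf) {
  d <- (v_p + c_mf) / 2
  sigma <- matrix(c(v_p, c_mf, d,
                    c_mf, v_p, d,
                    d, d, d + v_kf), 3L, 3L)
  ll <- 0
  for (p in ss) {
    s_sub <- sigma[p$cols, p$cols, drop = FALSE]
    det_s <- det(s_sub)
    if (!is.finite(det_s) || det_s <= 0) return(-Inf)
    inv <- solve(s_sub)
    dm <- p$xbar - mu[p$cols]
    ll <- ll - 0.5 * p$n * (length(p$cols) * log(2 * pi) + log(det_s) +
                              sum(inv * p$S) + drop(dm %*% inv %*% dm))
  }
  ll
}

# moment-based starting values
trio_start <- function(dat) {
  v_m <- stats::var(dat[, "m"], na.rm = TRUE)
  v_f <- stats::var(dat[, "f"], na.rm = TRUE)
  v_p <- mean(c(v_m, v_f), na.rm = TRUE)
  c_mf <- stats::cov(dat[, "m"], dat[, "f"], use = "pairwise.complete.obs")
  if (is.na(c_mf)) c_mf <- 0
  v_o <- stats::var(dat[, "o"], na.rm = TRUE)
  if (is.na(v_o)) v_o <- v_p
  v_kf <- max(v_o - (v_p + c_mf) / 2, 0.05 * v_p)
  list(mu = colMeans(dat, na.rm = TRUE), v_p = v_p,
       rc = max(min(c_mf / v_p, 0.99), -0.99), v_kf = v_kf)
}

#' Fit the trio transmission model by full-information maximum likelihood
#'
#' Mother, father and offspring PGIs are modeled as multivariate normal with
#' role-specific means and the covariance structure implied by genetic
#' transmission under assortment: equal parental variances `v_p`, partner
#' covariance `c`, parent-offspring covariance fixed structurally at
#' `d = (v_p + c) / 2`, and offspring variance `v_o = d + v_kf` with `v_kf`
#' the free residual transmission (segregation) variance. All observed-data
#' patterns (complete trios, partner-only, single-parent-child) contribute
#' their own multivariate-normal likelihood. The equilibrium-constrained
#' model replaces `v_kf` by `(v_p - c) / 2`, forcing `v_o = v_p`; the
#' constraint is a single degree of freedom, testable by
#' [lrt_equilibrium()].
#'
#' Derived quantities: `q = v_o / v_p` (the intergenerational variance
#' ratio) and `u = (2 d / sqrt(v_p v_o) - 1) / (c / v_p)` (observed over
#' expected-at-equilibrium increase in the parent-offspring correlation).
#' Optimization is quasi-Newton on log-variance / atanh-correlation
#' transforms, so the implied covariance stays positive definite.
#'
#' @param trios A `"trio_dataset"` (or a 3-column matrix `m`, `f`, `o`).
#' @param constrained Fit the equilibrium-constrained model.
#' @return An object of class `"trio_fit"`: estimates (`v_p`, `c_mf`,
#'   `v_kf`, `d`, `v_o`, `means`), `q`, `u`, `loglik`, `n`,
#'   `pattern_counts`, convergence info, and the sufficient statistics
#'   needed for profiling.
#' @export
fiml_fit <- function(trios, constrained = FALSE) {
  if (is.matrix(trios)) trios <- new_trio_dataset(trios)
  stopifnot(inherits(trios, "trio_dataset"))
  dat <- trios$data
  ss <- trio_suffstats(dat)
  st <- trio_start(dat)

  if (!constrained) {
    par0 <- c(st$mu, log(st$v_p), atanh(st$rc), log(st$v_kf))
    negll <- function(th) {
      v_p <- exp(th[4L]); c_mf <- v_p * tanh(th[5L]); v_kf <- exp(th[6L])
      -trio_loglik(ss, th[1:3], v_p, c_mf, v_kf)
    }
  } else {
    par0 <- c(st$mu, log(st$v_p), atanh(st$rc))
    negll <- function(th) {
      v_p <- exp(th[4L]); c_mf <- v_p * tanh(th[5L])
      v_kf <- (v_p - c_mf) / 2
      if (v_kf <= 0) return(Inf)
      -trio_loglik(ss, th[1:3], v_p, c_mf, v_kf)
    }
  }
  opt <- stats::nlminb(unname(par0), negll,
                       control = list(rel.tol = 1e-12, iter.max = 500L))
  if (!opt$convergence %in% c(0L, 1L) && opt$message != "" &&
      !grepl("converge", opt$message, ignore.case = TRUE))
    warning("optimizer reports: ", opt$message)
  th <- opt$par
  v_p <- exp(th[4L]); c_mf <- v_p * tanh(th[5L])
  v_kf <- if (constrained) (v_p - c_mf) / 2 else exp(th[6L])
  d <- (v_p + c_mf) / 2
  v_o <- d + v_kf
  structure(list(
    v_p = v_p, c_mf = c_mf, v_kf = v_kf, d = d, v_o = v_o,
    means = stats::setNames(th[1:3], c("m", "f", "o")),
    q = v_o / v_p,
    u = (2 * d / sqrt(v_p * v_o) - 1) / (c_mf / v_p),
    loglik = -opt$objective, n = nrow(dat),
    pattern_counts = trios$pattern_counts,
    constrained = constrained, suffstats = ss, convergence = opt$convergence
  ), class = "trio_fit")
}

#' @export
print.trio_fit <- function(x, ...) {
  cat(sprintf("Trio FIML fit (%s), n = %d, loglik = %.3f\n",
              if (x$constrained) "equilibrium-constrained" else "free",
              x$n, x$loglik))
  cat(sprintf("  v_p = %.4f  c = %.4f  v_o = %.4f  (d = %.4f, v_kf = %.4f)\n",
              x$v_p, x$c_mf, x$v_o, x$d, x$v_kf))
  cat(sprintf("  Q = %.4f  U = %.4f\n", x$q, x$u))
  invisible(x)
}

#' Likelihood-ratio test of intergenerational equilibrium
#'
#' Compares the free trio model with the model constrained to equal
#' variance across generations; twice the log-likelihood difference is
#' referred to chi-square with 1 degree of freedom.
#'
#' @param fit_free,fit_constrained Nested [fiml_fit()] results on the same
#'   data.
#' @param tol Tolerance for the constrained log-likelihood exceeding the
#'   free one (an optimizer failure beyond it is an error).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_equilibrium <- function(fit_free, fit_constrained, tol = 1e-6) {
  stopifnot(inherits(fit_free, "trio_fit"), inherits(fit_constrained, "trio_fit"),
            !fit_free$constrained, fit_constrained$constrained,
            fit_free$n == fit_constrained$n)
  stat <- 2 * (fit_free$loglik - fit_constrained$loglik)
  if (stat < -tol * max(1, abs(fit_free$loglik)))
    stop("constrained log-likelihood exceeds the free one: optimizer failure")
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

# profile negative log-likelihood at a fixed q or u, optimizing the rest.
# returns the profiled loglik; warm starts through `env`.
trio_profile_ll <- function(fit, target, value, env) {
  ss <- fit$suffstats
  negll <- function(th) {
    v_p <- exp(th[4L]); c_mf <- v_p * tanh(th[5L])
    d <- (v_p + c_mf) / 2
    if (target == "q") {
      v_kf <- value * v_p - d
    } else {
      rc <- c_mf / v_p
      den <- 1 + value * rc
      if (den <= 0) return(Inf)
      v_o <- 4 * d^2 / (v_p * den^2)
      v_kf <- v_o - d
    }
    if (v_kf <= 0) return(Inf)
    -trio_loglik(ss, th[1:3], v_p, c_mf, v_kf)
  }
  start <- if (!is.null(env$last)) env$last else
    unname(c(fit$means, log(fit$v_p), atanh(fit$c_mf / fit$v_p)))
  opt <- stats::nlminb(start, negll,
                       control = list(rel.tol = 1e-12, iter.max = 300L))
  if (is.finite(opt$objective)) env$last <- opt$par
  -opt$objective
}

#' Profile-likelihood confidence interval for Q or U
#'
#' Endpoints are the values of the target at which the profile
#' log-likelihood drops by `qchisq(level, 1) / 2` (1.9207 for 95\%) from its
#' maximum, located by root-finding on a monotone bracket on each side of
#' the estimate. At the constrained optimum both targets are identically 1
#' and the interval is degenerate.
#'
#' @param fit A free-model [fiml_fit()].
#' @param target `"q"` or `"u"`.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
profile_ci <- function(fit, target = c("q", "u"), level = 0.95) {
  stopifnot(inherits(fit, "trio_fit"))
  target <- match.arg(target)
  if (fit$constrained) {
    if (abs(fit$q - 1) < 1e-10) return(c(1, 1))
    stop("profile_ci needs a free-model fit")
  }
  drop_ll <- stats::qchisq(level, 1L) / 2
  ll_max <- fit$loglik
  hat <- fit[[target]]
  env <- new.env(parent = emptyenv())
  f <- function(x) trio_profile_ll(fit, target, x, env) - (ll_max - drop_ll)

  find_endpoint <- function(dir) {
    step <- max(0.25 * abs(hat), 0.01) / sqrt(fit$n / 100)
    x_in <- hat
    for (i in 1:60) {
      x_out <- hat + dir * step
      env$last <- NULL
      if (f(x_out) < 0) {
        return(stats::uniroot(f, lower = min(x_in, x_out),
                              upper = max(x_in, x_out),
                              tol = 1e-6 * max(1, abs(hat)))$root)
      }
      x_in <- x_out
      step <- step * 2
    }
    stop("no profile bracket found for ", target,
         " in direction ", if (dir > 0) "up" else "down")
  }
  lo <- find_endpoint(-1)
  hi <- find_endpoint(+1)
  c(lo, hi)
}

#' One-call equilibrium analysis of a trio dataset
#'
#' Fits the free and constrained models, runs the likelihood-ratio test and
#' computes profile CIs for Q and U.
#'
#' @param trios A `"trio_dataset"`.
#' @param level Confidence level for the profile intervals.
#' @return List with `fit_free`, `fit_constrained`, `lrt`, `q`, `q_ci`,
#'   `u`, `u_ci`.
#' @export
equilibrium_test <- function(trios, level = 0.95) {
  fit_free <- fiml_fit(trios, constrained = FALSE)
  fit_con <- fiml_fit(trios, constrained = TRUE)
  list(fit_free = fit_free, fit_constrained = fit_con,
       lrt = lrt_equilibrium(fit_free, fit_con),
       q = fit_free$q, q_ci = profile_ci(fit_free, "q", level),
       u = fit_free$u, u_ci = profile_ci(fit_free, "u", level))
}
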