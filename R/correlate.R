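#' Residualize polygenic indices on nuisance covariates
#'
#' Ordinary least-squares residuals of each PGI column on the covariate
#' columns (ancestry principal components, batch indicators, ...),
#' re-standardized to zero mean and unit variance within the analysis
#' sample. Rows with a missing PGI stay missing; covariates must be complete
#' and of full column rank among the used rows.
#'
#' @param tab Data frame with an `id` column, PGI column(s) and covariates.
#' @param pgi_cols Names of the PGI columns (default `"pgi"`).
#' @param covariate_cols Names of the covariate columns.
#' @return `tab` with the PGI columns replaced by standardized residuals.
#' @export
residualize <- function(tab, pgi_cols = "pgi", covariate_cols) {
  stopifnot(is.data.frame(tab), all(pgi_cols %in% names(tab)),
            all(covariate_cols %in% names(tab)))
  X <- as.matrix(tab[, covariate_cols, drop = FALSE])
  if (!is.numeric(X)) stop("covariates must be numeric")
  for (pc in pgi_cols) {
    y <- tab[[pc]]
    use <- !is.na(y)
    if (anyNA(X[use, ])) stop("missing covariate values among used rows")
    Xu <- cbind(1, X[use, , drop = FALSE])
    qrx <- qr(Xu)
    if (qrx$rank < ncol(Xu))
      stop("covariate matrix is rank-deficient (constant or collinear column)")
    res <- qr.resid(qrx, y[use])
    tab[[pc]][use] <- (res - mean(res)) / stats::sd(res)
  }
  tab
}

#' Dyadic correlations with Fisher confidence intervals
#'
#' Pearson correlation of a value across the members of each dyad type, with
#' 95\% confidence intervals from the Fisher z transform
#' (`se = 1/sqrt(n - 3)`). Symmetric dyads (siblings, cousins, partners in
#' simulated data) are entered once, in randomized member order, to avoid
#' the artifactual CI shrinkage of double entry.
#'
#' @param values Data frame with columns `id` and `value`, or a named
#'   numeric vector keyed by id. Missing values drop the affected dyads.
#' @param dyads Data frame from [enumerate_dyads()] (`id_a`, `id_b`,
#'   `label`, `degree`).
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame with one row per label: `label`, `degree`,
#'   `n_dyads`, `r`, `ci_low`, `ci_high`.
#' @export
dyad_correlation <- function(values, dyads, conf_level = 0.95) {
  if (is.data.frame(values)) {
    stopifnot(all(c("id", "value") %in% names(values)))
    v <- stats::setNames(values$value, values$id)
  } else {
    v <- values
  }
  stopifnot(!is.null(names(v)), is.data.frame(dyads),
            all(c("id_a", "id_b", "label") %in% names(dyads)))
  if (nrow(dyads) < 3L) stop("need at least 3 dyads")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- lapply(split(dyads, dyads$label), function(d) {
    x <- v[as.character(d$id_a)]
    y <- v[as.character(d$id_b)]
    # randomized member order for symmetric dyads
    swap <- stats::runif(length(x)) < 0.5
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    deg <- if ("degree" %in% names(d)) d$degree[1] else NA_integer_
    if (n < 3L) {
      warning("fewer than 3 complete dyads for label ", d$label[1])
      return(data.frame(label = d$label[1], degree = deg, n_dyads = n,
                        r = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance among dyad members for label ", d$label[1])
    r <- stats::cor(x, y)
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    data.frame(label = d$label[1], degree = deg, n_dyads = n, r = r,
               ci_low = tanh(z - zq * se), ci_high = tanh(z + zq * se))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Random-mating and equilibrium expectations per dyad type
#'
#' Given the observed partner correlation, attaches to each dyad label its
#' expected correlation under random mating (the coefficient of
#' relationship for blood dyads, 0 for partners and in-laws) and at
#' equilibrium (`((1 + r) / 2)^k` for degree-k blood dyads, chain products
#' for affinal dyads, the partner correlation itself for partners).
#'
#' @param partner_r Observed partner correlation for the trait.
#' @param labels Character vector of dyad labels (see [enumerate_dyads()]).
#' @return Data frame with `label`, `degree`, `expected_random`,
#'   `expected_equilibrium`.
#' @examples
#' expectation_overlay(0.14, c("full-sibling", "first-cousin"))
#' @export
expectation_overlay <- function(partner_r, labels) {
  check_correlation(partner_r, "partner_r")
  rows <- lapply(unique(labels), function(lb) {
    info <- dyad_label_info(lb)
    if (info$kind == "partner") {
      er <- 0; ee <- partner_r
    } else if (info$kind == "blood") {
      er <- 0.5^info$degree
      ee <- kth_degree_equilibrium(partner_r, info$degree)
    } else {
      er <- 0
      ee <- affinal_correlation(
        relationship_spec("affinal", chain = info$chain), partner_r)
    }
    data.frame(label = lb, degree = info$degree, expected_random = er,
               expected_equilibrium = ee)
  })
  do.call(rbind, rows)
}

#' Dyadic correlation table with theoretical overlays
#'
#' The full empirical pipeline on one cohort: residualize the PGI on the
#' covariates, enumerate dyads from the pedigree, estimate per-type
#' correlations, and attach random-mating and equilibrium expectations
#' anchored at the observed partner correlation.
#'
#' @param ped Pedigree data frame (or path to a pedigree TSV).
#' @param pgi_tab PGI data frame (or path to a PGI TSV) with an `id`, a
#'   `pgi` and optional covariate columns.
#' @param covariate_cols Covariate columns to residualize on (`NULL` skips
#'   residualization).
#' @param types Dyad labels to include (default: all available).
#' @return Data frame with one row per dyad type: `label`, `degree`,
#'   `n_dyads`, `r`, `ci_low`, `ci_high`, `expected_random`,
#'   `expected_equilibrium`.
#' @export
correlate_cohort <- function(ped, pgi_tab, covariate_cols = NULL,
                             types = NULL) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  if (is.character(pgi_tab)) pgi_tab <- read_pgi_table(pgi_tab)
  if (!is.null(covariate_cols))
    pgi_tab <- residualize(pgi_tab, "pgi", covariate_cols)
  dyads <- enumerate_dyads(ped, types)
  est <- dyad_correlation(data.frame(id = pgi_tab$id, value = pgi_tab$pgi),
                          dyads)
  partner_r <- est$r[est$label == "partner"]
  if (length(partner_r) != 1L || is.na(partner_r))
    stop("partner dyads are required to anchor the equilibrium expectations")
  ov <- expectation_overlay(partner_r, est$label)
  merge(est, ov[, c("label", "expected_random", "expected_equilibrium")],
        by = "label", sort = FALSE)
}
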