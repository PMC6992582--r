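#' Fit a negative-binomial (Gamma-Poisson) distribution to counts
#'
#' First stage of the validation pipeline: decide whether the marginal
#' per-patient euploid-blastocyst counts are overdispersed. Fits the negative
#' binomial by maximum likelihood in the (mu, k) parameterization (variance
#' `mu + mu^2/k`; the MLE of `mu` is the sample mean for any `k`, so only a
#' one-dimensional profile search over `log k` is needed) and compares it with
#' a Poisson fit by small-sample-corrected AIC. The NB is declared preferred
#' when its AICc is lower. A `k` estimate above `1e4` (or a likelihood flat
#' up to the boundary) is flagged as the Poisson boundary.
#'
#' @param counts Non-negative integer vector, `n >= 30`, at least two
#'   distinct values (otherwise a boundary flag is returned, no NB fit).
#' @return List of class `nb_fit`: `mu`, `k`, `loglik`, `aicc`,
#'   `poisson_loglik`, `poisson_aicc`, `nb_preferred`, `boundary`.
#' @examples
#' set.seed(1)
#' fit_count_distribution(rnbinom(500, mu = 0.9, size = 1))
#' @export
fit_count_distribution <- function(counts) {
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- length(counts)
  if (n < 30) stop("need at least 30 observations", call. = FALSE)
  mu <- mean(counts)
  pois_ll <- sum(stats::dpois(counts, mu, log = TRUE))
  pois_aicc <- aicc(pois_ll, 1, n)
  if (length(unique(counts)) < 2) {
    return(structure(list(mu = mu, k = NA_real_, loglik = NA_real_,
                          aicc = NA_real_, poisson_loglik = pois_ll,
                          poisson_aicc = pois_aicc, nb_preferred = FALSE,
                          boundary = "degenerate: all counts equal"),
                     class = "nb_fit"))
  }
  nll <- function(logk) -sum(stats::dnbinom(counts, mu = mu,
                                            size = exp(logk), log = TRUE))
  opt <- stats::optimize(nll, c(-10, log(1e6)))
  k <- exp(opt$minimum)
  ll <- -opt$objective
  boundary <- if (k > 1e4) "Poisson boundary: dispersion not identifiable" else NA_character_
  out_aicc <- aicc(ll, 2, n)
  structure(list(mu = mu, k = k, loglik = ll, aicc = out_aicc,
                 poisson_loglik = pois_ll, poisson_aicc = pois_aicc,
                 nb_preferred = is.na(boundary) && out_aicc < pois_aicc,
                 boundary = boundary),
            class = "nb_fit")
}

aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("<nb_fit>\n")
  if (!is.na(x$boundary)) cat("  flag:", x$boundary, "\n")
  cat(sprintf("  NB: mu = %.4f, k = %.4g, loglik = %.3f, AICc = %.3f\n",
              x$mu, x$k, x$loglik, x$aicc))
  cat(sprintf("  Poisson: loglik = %.3f, AICc = %.3f\n",
              x$poisson_loglik, x$poisson_aicc))
  cat("  negative binomial preferred:", x$nb_preferred, "\n")
  invisible(x)
}

#' Adaptive-lasso covariate selection for euploid counts
#'
#' Second pipeline stage: a negative-binomial log-link regression of the
#' euploid count `m` on standardized candidate covariates with `log(N)` as an
#' offset ("including MII oocytes to adjust the data"; under the per-oocyte
#' model the expected euploid count is proportional to the oocyte number).
#' Adaptive weights are `1/|beta~|` from an unpenalized initial NB fit
#' (ridge-stabilized if that fit fails); the penalized path is solved over a
#' log-spaced lambda grid with the NB dispersion held at the initial
#' estimate, and the selected set is the support at the AICc optimum, with
#' the AICc degrees of freedom equal to the intercept plus the number of
#' nonzero coefficients. Patients with `N = 0` are excluded. Exactly
#' collinear duplicate candidates resolve deterministically to whichever
#' comes first in input order (the duplicate's adaptive weight is tied; the
#' path keeps the first).
#'
#' @param records Cohort data frame; rows with `n_mii >= 1` are used.
#' @param candidates Character vector (length >= 2) of numeric covariate
#'   columns in `records` to screen. Factor-type model terms should be
#'   pre-encoded as numeric contrast columns.
#' @param mii_mode `"offset"` (default) enters `log(N)` as an offset;
#'   `"covariate"` enters it as a standardized candidate instead
#'   (sensitivity switch).
#' @param nlambda Number of grid points (default 100, log-spaced by glmnet).
#' @return List of class `lasso_path`: `candidates`, `lambda`, `beta`
#'   (coefficient trajectories, candidates x lambda), `aicc` per grid point,
#'   `selected` (names at the AICc optimum), `lambda_opt`, `theta`,
#'   `initial_fit` coefficients.
#' @export
adaptive_lasso_nb <- function(records, candidates, mii_mode = c("offset", "covariate"),
                              nlambda = 100) {
  mii_mode <- match.arg(mii_mode)
  records <- validate_records(records)
  keep <- records$n_mii >= 1
  records <- records[keep, , drop = FALSE]
  if (length(candidates) < 2) stop("need at least 2 candidate covariates", call. = FALSE)
  miss <- setdiff(candidates, names(records))
  if (length(miss)) stop("candidate columns not in records: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(records[candidates])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("candidate covariates must be finite", call. = FALSE)
  y <- records$n_euploid
  off <- log(records$n_mii)
  if (mii_mode == "covariate") {
    X <- cbind(X, log_mii = off)
    candidates <- c(candidates, "log_mii")
    off <- rep(0, length(y))
  }
  Xs <- scale(X)
  # constant columns carry no signal: zero them so they can never be selected
  const <- attr(Xs, "scaled:scale") == 0
  if (any(const)) Xs[, const] <- 0
  # exact collinear duplicates resolve deterministically: the first column in
  # input order stays on the path, later copies are frozen at zero
  dup <- duplicated(t(Xs)) | const
  if (all(dup)) stop("all candidate columns are constant", call. = FALSE)
  Xa <- Xs[, !dup, drop = FALSE]
  init <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ Xa + offset(off))),
    error = function(e) NULL)
  if (!is.null(init) && init$converged) {
    beta0 <- stats::coef(init)[-1]
    theta <- init$theta
  } else {
    # ridge-stabilized fallback: Poisson ridge for weights, moment theta
    rr <- glmnet::glmnet(Xa, y, family = "poisson", offset = off,
                         alpha = 0, lambda = 0.01)
    beta0 <- as.numeric(rr$beta)
    fitmu <- as.numeric(exp(off + rr$a0 + Xa %*% rr$beta))
    theta <- max(0.1, mean(fitmu)^2 / max(stats::var(y) - mean(fitmu), 1e-6))
  }
  beta0[is.na(beta0)] <- 0
  w <- 1 / pmax(abs(beta0), 1e-8)
  fam <- MASS::negative.binomial(theta = theta)
  fit <- glmnet::glmnet(Xa, y, family = fam, offset = off,
                        penalty.factor = w, nlambda = nlambda,
                        lambda.min.ratio = 1e-4)
  Ba <- as.matrix(fit$beta)
  B <- matrix(0, length(candidates), ncol(Ba),
              dimnames = list(candidates, colnames(Ba)))
  B[!dup, ] <- Ba
  n <- length(y)
  ll <- vapply(seq_along(fit$lambda), function(j) {
    mu <- as.numeric(exp(off + fit$a0[j] + Xa %*% Ba[, j]))
    sum(stats::dnbinom(y, mu = mu, size = theta, log = TRUE))
  }, numeric(1))
  df <- 1 + colSums(abs(B) > 1e-8)
  aiccs <- mapply(aicc, ll, df, MoreArgs = list(n = n))
  ok <- is.finite(aiccs)
  if (!any(ok)) stop("no lambda grid point converged", call. = FALSE)
  jopt <- which(ok)[which.min(aiccs[ok])]
  selected <- candidates[abs(B[, jopt]) > 1e-8]
  structure(list(candidates = candidates, lambda = fit$lambda, beta = B,
                 loglik = ll, aicc = aiccs, df = df,
                 lambda_opt = fit$lambda[jopt], selected = selected,
                 theta = theta, initial_beta = beta0, mii_mode = mii_mode,
                 n = n),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("<lasso_path>  n =", x$n, " candidates =", length(x$candidates),
      " grid =", length(x$lambda), "\n")
  cat(sprintf("  theta (NB dispersion) = %.4g, MII mode = %s\n",
              x$theta, x$mii_mode))
  cat("  AICc optimum at lambda =", signif(x$lambda_opt, 4), "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# Design columns of the final model for a cohort, ages centered at `center`.
logit_design <- function(records, center) {
  k <- profile_contrasts(records)
  ac <- records$female_age - center
  cbind(d1_age = k$d1 * ac, d2_age = k$d2 * ac, d1 = k$d1,
        e1 = k$e1, e2 = k$e2)
}

#' Fit the per-oocyte binomial logistic model
#'
#' Third pipeline stage: maximizes the aggregated binomial likelihood
#' \eqn{\prod_i \binom{N_i}{m_i} p_i^{m_i} (1-p_i)^{N_i - m_i}} over the
#' final-model structure — age-by-sperm interactions on the two sperm
#' contrasts, the sperm main contrast, and the two center contrasts — with
#' age centered at the mean female age of the fitting records. The MLE is
#' identical whether the data enter as aggregated `(m, N)` pairs or as `N`
#' expanded per-oocyte 0/1 rows; the reported `loglik` is the Bernoulli
#' (expanded-row) log-likelihood so the two representations agree exactly,
#' and `loglik_aggregated` adds the `lchoose(N, m)` terms.
#'
#' @param records Cohort data frame; rows with `n_mii >= 1` are used.
#' @param include_center Include the two center contrasts (default `TRUE`;
#'   with `FALSE` the emitted set is center-free).
#' @param representation `"aggregated"` (default) or `"expanded"`; both give
#'   the same estimates, the switch exists for verification.
#' @param age_center Centering constant in years; default `NULL` centers at
#'   the fitting cohort's mean female age. An explicit value matters when
#'   comparing coefficients against a model centered elsewhere, because the
#'   sperm main-effect contrast (and the intercept) are not invariant to the
#'   centering constant.
#' @return List of class `logit_fit`: `coefs` (a [coefficient_set()] usable
#'   by the calculator), `se`, `vcov`, `loglik`, `loglik_aggregated`,
#'   `loglik_null`, `loglik_null_aggregated`, `n_patients`, `n_oocytes`,
#'   `converged`.
#' @export
fit_binomial_logit <- function(records, include_center = TRUE,
                               representation = c("aggregated", "expanded"),
                               age_center = NULL) {
  representation <- match.arg(representation)
  records <- validate_records(records)
  records <- records[records$n_mii >= 1, , drop = FALSE]
  if (nrow(records) == 0)
    stop("no records with at least one MII oocyte", call. = FALSE)
  m <- records$n_euploid; N <- records$n_mii
  if (sum(m) == 0 || sum(m) == sum(N))
    stop("complete separation: the response is all-",
         if (sum(m) == 0) "zero" else "one",
         " at the oocyte level; no coefficient set can be estimated",
         call. = FALSE)
  center_age <- age_center %||% mean(records$female_age)
  X <- logit_design(records, center_age)
  terms <- c("d1_age", "d2_age", "d1", if (include_center) c("e1", "e2"))
  X <- X[, terms, drop = FALSE]
  # drop contrast columns that are constant in this cohort (e.g. single center)
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) stop("all model terms are constant in this cohort", call. = FALSE)
  Xf <- X[, keep, drop = FALSE]
  dat <- data.frame(Xf)
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  if (representation == "aggregated") {
    fit <- stats::glm(cbind(m, N - m) ~ ., family = stats::binomial(),
                      data = dat, control = ctrl)
  } else {
    idx <- rep(seq_len(nrow(dat)), N)
    y <- unlist(mapply(function(mi, Ni) c(rep(1L, mi), rep(0L, Ni - mi)),
                       m, N, SIMPLIFY = FALSE))
    fit <- stats::glm(y ~ ., family = stats::binomial(),
                      data = dat[idx, , drop = FALSE], control = ctrl)
  }
  if (!fit$converged)
    stop("binomial logit did not converge (possible quasi-separation)",
         call. = FALSE)
  cf <- stats::setNames(rep(0, length(terms) + 1), c("(Intercept)", terms))
  cf[names(stats::coef(fit))[1]] <- stats::coef(fit)[1]
  cf[colnames(Xf)] <- stats::coef(fit)[-1]
  if (any(abs(cf) > 50))
    stop("diverging coefficients (quasi-separation); no coefficient set emitted",
         call. = FALSE)
  semap <- c("(Intercept)" = "intercept", d1_age = "b_ej_noa_age",
             d2_age = "b_surg_noa_age", d1 = "s_ej_noa",
             e1 = "g_anat_andro", e2 = "g_gen_anat")
  se_raw <- sqrt(diag(stats::vcov(fit)))
  se <- stats::setNames(as.numeric(se_raw), semap[names(se_raw)])
  cs <- coefficient_set(cf["(Intercept)"], center_age,
                        cf["d1_age"], cf["d2_age"], cf["d1"],
                        if ("e1" %in% terms) cf["e1"] else 0,
                        if ("e2" %in% terms) cf["e2"] else 0,
                        label = sprintf("refit on %d couples", nrow(records)),
                        se = se)
  p <- euploidy_probability(linear_predictor(records, cs))
  ll_bern <- sum(m * log(p) + (N - m) * log1p(-p))
  p0 <- sum(m) / sum(N)
  ll0_bern <- sum(m) * log(p0) + (sum(N) - sum(m)) * log1p(-p0)
  lch <- sum(lchoose(N, m))
  structure(list(coefs = cs, se = se, vcov = stats::vcov(fit),
                 loglik = ll_bern, loglik_aggregated = ll_bern + lch,
                 loglik_null = ll0_bern, loglik_null_aggregated = ll0_bern + lch,
                 n_patients = nrow(records), n_oocytes = sum(N),
                 representation = representation,
                 converged = fit$converged),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit>  %d couples, %d oocytes, loglik (Bernoulli) = %.3f\n",
              x$n_patients, x$n_oocytes, x$loglik))
  print(x$coefs)
  invisible(x)
}
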