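#' Holdout split
#'
#' Simple random (unstratified) split of patient indices into training and
#' validation sets. The training size is `round(fraction * n)`.
#'
#' @param records Cohort data frame (or anything with rows).
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return List of class `holdout_split` with integer index vectors
#'   `training` and `validation`, plus `fraction` and `seed`.
#' @examples
#' s <- holdout_split(generate_cohort(cohort_spec(100, seed = 2)), seed = 9)
#' length(s$training)  # 75
#' @export
holdout_split <- function(records, fraction = 0.75, seed = 1L) {
  n <- nrow(records)
  if (is.null(n) || n < 8) stop("need at least 8 records to split", call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly in (0, 1)", call. = FALSE)
  set.seed(seed)
  n_train <- round(fraction * n)
  tr <- sort(sample.int(n, n_train))
  structure(list(training = tr, validation = setdiff(seq_len(n), tr),
                 fraction = fraction, seed = as.integer(seed)),
            class = "holdout_split")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC with midrank tie correction: the probability that a
#' randomly chosen positive outranks a randomly chosen negative, ties
#' counting one half.
#'
#' @param scores Numeric predicted scores (here: per-oocyte predicted
#'   probabilities; each patient contributes `N` rows of which `m` are
#'   positive).
#' @param outcomes 0/1 vector of the same length; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8, 0.7, 0.4), c(1, 0, 1, 0))  # 0.75
#' @export
auc <- function(scores, outcomes) {
  if (length(scores) != length(outcomes))
    stop("scores and outcomes must have equal length", call. = FALSE)
  outcomes <- as.integer(outcomes)
  if (any(!outcomes %in% c(0L, 1L))) stop("outcomes must be 0/1", call. = FALSE)
  n1 <- sum(outcomes); n0 <- sum(1L - outcomes)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Expand a cohort to per-oocyte rows: score = predicted p, outcome = 0/1.
oocyte_rows <- function(records, coefs) {
  records <- records[records$n_mii >= 1, , drop = FALSE]
  p <- euploidy_probability(linear_predictor(records, coefs))
  idx <- rep(seq_len(nrow(records)), records$n_mii)
  y <- unlist(mapply(function(m, N) c(rep(1L, m), rep(0L, N - m)),
                     records$n_euploid, records$n_mii, SIMPLIFY = FALSE))
  list(scores = p[idx], outcomes = y)
}

#' Oocyte- or patient-level AUC for a cohort under a coefficient set
#'
#' `level = "oocyte"` (default, matching the model's response unit) expands
#' each patient into `N` rows scored with the predicted per-oocyte `p`, `m`
#' of them positive. `level = "patient"` scores each patient with
#' `1 - (1 - p)^N` against the outcome `m >= 1`.
#'
#' @param records Cohort data frame.
#' @param coefs A [coefficient_set()].
#' @param level `"oocyte"` or `"patient"`.
#' @return AUC in `[0, 1]`.
#' @export
cohort_auc <- function(records, coefs, level = c("oocyte", "patient")) {
  level <- match.arg(level)
  records <- validate_records(records)
  if (level == "oocyte") {
    rows <- oocyte_rows(records, coefs)
    auc(rows$scores, rows$outcomes)
  } else {
    keep <- records$n_mii >= 1
    r <- records[keep, , drop = FALSE]
    p <- euploidy_probability(linear_predictor(r, coefs))
    auc(achieved_success(p, r$n_mii), as.integer(r$n_euploid >= 1))
  }
}

#' Generalized R-squared (Nagelkerke / Cragg-Uhler)
#'
#' \deqn{R^2 = \frac{1 - \exp(2 (\ell_0 - \ell_1) / n)}{1 - \exp(2 \ell_0 / n)}}
#'
#' where \eqn{\ell_0} and \eqn{\ell_1} are the null and model log-likelihoods
#' and `n` the number of rows. Equals 0 when the model adds nothing and 1 for
#' a saturated binary model (\eqn{\ell_1 = 0}).
#'
#' @param loglik_null,loglik_model Log-likelihoods, `loglik_model >=
#'   loglik_null`.
#' @param n_rows Positive row count used by the fit.
#' @return Value in `[0, 1]`.
#' @export
generalized_r2 <- function(loglik_null, loglik_model, n_rows) {
  if (!is.finite(n_rows) || n_rows <= 0) stop("n_rows must be positive", call. = FALSE)
  if (loglik_model < loglik_null - 1e-8)
    stop("loglik_model must be >= loglik_null", call. = FALSE)
  num <- 1 - exp(2 * (loglik_null - loglik_model) / n_rows)
  den <- 1 - exp(2 * loglik_null / n_rows)
  if (den <= 0) return(0)
  max(0, min(1, num / den))
}

#' Compare two coefficient sets over evaluation profiles
#'
#' Mirrors the published model-vs-calculator comparison: Pearson (and
#' Spearman) correlation of predicted per-oocyte probabilities over a set of
#' profiles, the correlation of MIImin at each target success probability,
#' and the median and mean absolute probability difference.
#'
#' @param coefs_a,coefs_b Two [coefficient_set()] objects.
#' @param profiles A [patient_profile()] grid with at least 10 rows.
#' @param pi_levels Success probabilities at which MIImin is compared.
#' @return List of class `model_comparison`: `r_p` (Pearson), `rho_p`
#'   (Spearman), `r_mii` named by pi level, `median_abs_dp`, `mean_abs_dp`,
#'   `n_profiles`. Correlations over a zero-variance vector are reported as
#'   `NA` with a note, not an error.
#' @export
compare_models <- function(coefs_a, coefs_b, profiles,
                           pi_levels = c(0.7, 0.8, 0.9)) {
  profiles <- as_profile(profiles)
  if (nrow(profiles) < 10) stop("need at least 10 evaluation profiles", call. = FALSE)
  pa <- euploidy_probability(linear_predictor(profiles, coefs_a))
  pb <- euploidy_probability(linear_predictor(profiles, coefs_b))
  safe_cor <- function(x, y, method = "pearson") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  mii_at <- function(p, s) vapply(p, function(pp) mii_min(pp, s)$mii_min, integer(1))
  r_mii <- vapply(pi_levels, function(s)
    safe_cor(mii_at(pa, s), mii_at(pb, s)), numeric(1))
  names(r_mii) <- paste0("pi_", format(pi_levels))
  structure(list(r_p = safe_cor(pa, pb),
                 rho_p = safe_cor(pa, pb, "spearman"),
                 r_mii = r_mii,
                 median_abs_dp = stats::median(abs(pa - pb)),
                 mean_abs_dp = mean(abs(pa - pb)),
                 n_profiles = nrow(profiles)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison>  %d profiles\n", x$n_profiles))
  cat(sprintf("  r(p) = %.3f (Pearson), %.3f (Spearman)\n", x$r_p, x$rho_p))
  cat("  r(MIImin):", paste(sprintf("%s %.3f", names(x$r_mii), x$r_mii),
                            collapse = "  "), "\n")
  cat(sprintf("  |dp|: median %.4f, mean %.4f\n", x$median_abs_dp, x$mean_abs_dp))
  invisible(x)
}

new_ppv_table <- function(pi, counts) {
  # counts: 2x2 matrix, rows = reached MIImin yes/no, cols = >=1 euploid yes/no
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  dimnames(counts) <- list(reached = c("yes", "no"), euploid = c("yes", "no"))
  rs <- rowSums(counts)
  ppv <- if (rs[1] > 0) 100 * counts[1, 1] / rs[1] else NA_real_
  rate_no <- if (rs[2] > 0) 100 * counts[2, 1] / rs[2] else NA_real_
  structure(list(pi = pi, counts = counts, n = sum(counts),
                 ppv = as.numeric(ppv),
                 rate_not_reached = as.numeric(rate_no)),
            class = "ppv_table")
}

#' Positive-predictive-value table
#'
#' For each patient, computes MIImin for their profile at success probability
#' `pi`, classifies the patient as having reached it (`n_mii >= MIImin`), and
#' cross-tabulates against the observed outcome (`n_euploid >= 1`). The PPV
#' is the percentage with at least one euploid blastocyst among those who
#' reached MIImin. An empty "reached" row yields an undefined (`NA`) PPV,
#' never 0.
#'
#' @param records Cohort data frame.
#' @param coefs A [coefficient_set()].
#' @param pi Target success probability in (0, 1).
#' @return Object of class `ppv_table`: `pi`, 2x2 `counts` (reached yes/no x
#'   euploid yes/no), `ppv` (%), `rate_not_reached` (% with >= 1 euploid
#'   among non-reachers), `n`.
#' @seealso [ppv_table_from_counts()] for pre-tabulated counts.
#' @export
ppv_table <- function(records, coefs, pi) {
  records <- validate_records(records)
  p <- euploidy_probability(linear_predictor(records, coefs))
  mm <- vapply(p, function(pp) mii_min(pp, pi)$mii_min, integer(1))
  reached <- records$n_mii >= mm
  eup <- records$n_euploid >= 1
  counts <- rbind(c(sum(reached & eup), sum(reached & !eup)),
                  c(sum(!reached & eup), sum(!reached & !eup)))
  new_ppv_table(pi, counts)
}

#' @param counts_reached Length-2 integer vector `c(yes, no)`: patients who
#'   reached MIImin with / without at least one euploid blastocyst.
#' @param counts_not_reached Length-2 integer vector for patients who did not
#'   reach MIImin.
#' @rdname ppv_table
#' @export
ppv_table_from_counts <- function(counts_reached, counts_not_reached, pi) {
  new_ppv_table(pi, rbind(counts_reached, counts_not_reached))
}

#' @export
print.ppv_table <- function(x, ...) {
  cat(sprintf("<ppv_table>  pi = %.2f, n = %d\n", x$pi, x$n))
  print(x$counts)
  cat(sprintf("  PPV = %s  (>=1 euploid among non-reachers: %s)\n",
              if (is.na(x$ppv)) "undefined" else sprintf("%.1f%%", x$ppv),
              if (is.na(x$rate_not_reached)) "undefined"
              else sprintf("%.1f%%", x$rate_not_reached)))
  invisible(x)
}

#' Tukey-Kramer HSD multiple comparisons of group means
#'
#' All pairwise mean differences with studentized-range critical values,
#' using the Kramer adjustment for unequal group sizes: the standard error of
#' a pair is `sqrt(MSE/2 * (1/ni + 1/nj))` and significance at level `alpha`
#' compares `|diff| / se` with `qtukey(1 - alpha, k, df)`. Exact at equal
#' sizes, conservative otherwise. Used here to compare per-center 2PN
#' fertilization and blastulation rates.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each `n >= 2`).
#' @param alpha Familywise significance level, default 0.05.
#' @return Data frame of class `tukey_hsd`: one row per pair with `diff`,
#'   `se`, `q` (studentized-range statistic), `lwr`/`upr` (simultaneous CI),
#'   `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of >= 2 numeric vectors", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  k <- length(groups)
  n_tot <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- n_tot - k
  mse <- sse / df
  if (mse <= 0)
    stop("zero within-group variance in all groups; HSD undefined", call. = FALSE)
  qcrit <- stats::qtukey(1 - alpha, k, df)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    d <- means[j] - means[i]
    q <- abs(d) / se
    data.frame(pair = paste(names(groups)[j], "-", names(groups)[i]),
               diff = d, se = se, q = q,
               lwr = d - qcrit * se, upr = d + qcrit * se,
               p_adj = stats::ptukey(q, k, df, lower.tail = FALSE),
               significant = q > qcrit,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "df") <- df
  attr(out, "mse") <- mse
  class(out) <- c("tukey_hsd", class(out))
  out
}
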