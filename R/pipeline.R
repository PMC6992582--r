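#' Configuration for the validation pipeline
#'
#' @param seed Integer seed driving the holdout split (and any other
#'   randomness in the run).
#' @param train_fraction Training fraction for [holdout_split()].
#' @param pi_levels Success probabilities for MIImin and PPV stages.
#' @param reference Optional [coefficient_set()] to compare the refit model
#'   against and to use for the PPV tables (mirroring the evaluation of an
#'   external calculator on the validation set). When `NULL`, the refit model
#'   itself is used for PPV and the comparison stage is skipped.
#' @param candidates Optional character vector of numeric covariate columns
#'   to screen in the adaptive-lasso stage. Default `NULL` screens the
#'   model's own encoded predictors (centered age, the two sperm contrasts
#'   and two center contrasts) plus any extra numeric columns found in the
#'   records.
#' @param include_center Keep center contrasts in the final model.
#' @param auc_level `"oocyte"` (default) or `"patient"` (see [cohort_auc()]).
#' @return List of class `validation_config`.
#' @export
validation_config <- function(seed = 1L, train_fraction = 0.75,
                              pi_levels = c(0.7, 0.8, 0.9),
                              reference = NULL, candidates = NULL,
                              include_center = TRUE,
                              auc_level = c("oocyte", "patient")) {
  auc_level <- match.arg(auc_level)
  if (any(pi_levels <= 0 | pi_levels >= 1))
    stop("pi_levels must lie strictly in (0, 1)", call. = FALSE)
  if (!is.null(reference)) validate_coefficient_set(reference)
  structure(list(seed = as.integer(seed), train_fraction = train_fraction,
                 pi_levels = pi_levels, reference = reference,
                 candidates = candidates, include_center = include_center,
                 auc_level = auc_level),
            class = "validation_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

# Candidate covariate columns for the selection stage: encoded model terms
# plus any extra numeric CRF columns.
default_candidates <- function(records) {
  k <- profile_contrasts(records)
  extra <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                   c(crf_required, "female_age"))
  cand <- cbind(age_centered = records$female_age - mean(records$female_age),
                d1 = k$d1, d2 = k$d2, e1 = k$e1, e2 = k$e2)
  if (length(extra)) cand <- cbind(cand, as.matrix(records[extra]))
  as.data.frame(cand)
}

#' Run the full validation pipeline
#'
#' Executes the stages of the validation roadmap in order: marginal
#' count-distribution identification (negative binomial vs Poisson), holdout
#' split, adaptive-lasso covariate screening on the training set, final
#' aggregated binomial logit on the training set, AUC and generalized
#' R-squared on both training and validation sets, per-patient MIImin at the
#' configured success probabilities, comparison against a reference
#' coefficient set (when supplied), and PPV tables on the validation set. Any
#' stage failure halts with the stage name and cause.
#'
#' @param records Cohort data frame (see [crf-schema]).
#' @param config A [validation_config()].
#' @return List of class `validation_report`; serialize with
#'   [write_validation_report()].
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 400, seed = 5))
#' rep <- run_validation_pipeline(co, validation_config(seed = 5))
#' rep$metrics$auc_validation
#' @export
run_validation_pipeline <- function(records, config = validation_config()) {
  stopifnot(inherits(config, "validation_config"))
  records <- run_stage("input-validation", validate_records(records))
  nb <- run_stage("count-distribution",
                  fit_count_distribution(records$n_euploid))
  split <- run_stage("holdout-split",
                     holdout_split(records, config$train_fraction, config$seed))
  train <- records[split$training, , drop = FALSE]
  val <- records[split$validation, , drop = FALSE]
  lasso <- run_stage("lasso-selection", {
    if (is.null(config$candidates)) {
      cand <- default_candidates(train)
      aug <- cbind(train, cand[setdiff(names(cand), names(train))])
      adaptive_lasso_nb(validate_records(aug), names(cand))
    } else {
      adaptive_lasso_nb(train, config$candidates)
    }
  })
  fit <- run_stage("final-logit",
                   fit_binomial_logit(train, include_center = config$include_center))
  metrics <- run_stage("holdout-metrics", {
    set_metrics <- function(rr) {
      rr <- rr[rr$n_mii >= 1, , drop = FALSE]
      m <- rr$n_euploid; N <- rr$n_mii
      p <- euploidy_probability(linear_predictor(rr, fit$coefs))
      lch <- sum(lchoose(N, m))
      ll <- sum(m * log(p) + (N - m) * log1p(-p)) + lch
      p0 <- sum(m) / sum(N)
      ll0 <- sum(m) * log(p0) + (sum(N) - sum(m)) * log1p(-p0) + lch
      list(auc = cohort_auc(rr, fit$coefs, level = config$auc_level),
           r2 = generalized_r2(ll0, ll, nrow(rr)))
    }
    tr <- set_metrics(train); va <- set_metrics(val)
    list(auc_level = config$auc_level,
         auc_training = tr$auc, auc_validation = va$auc,
         r2_training = tr$r2, r2_validation = va$r2)
  })
  mii <- run_stage("mii-min", {
    p <- euploidy_probability(linear_predictor(val, fit$coefs))
    lapply(config$pi_levels, function(s) {
      mm <- vapply(p, function(pp) mii_min(pp, s)$mii_min, integer(1))
      list(pi = s, median = stats::median(mm), mean = mean(mm),
           q25 = as.numeric(stats::quantile(mm, 0.25)),
           q75 = as.numeric(stats::quantile(mm, 0.75)))
    })
  })
  comparison <- NULL
  if (!is.null(config$reference)) {
    comparison <- run_stage("model-comparison",
                            compare_models(fit$coefs, config$reference, val,
                                           config$pi_levels))
  }
  ppv_coefs <- config$reference %||% fit$coefs
  ppv <- run_stage("ppv-tables",
                   lapply(config$pi_levels,
                          function(s) ppv_table(val, ppv_coefs, s)))
  structure(list(
    provenance = list(package = "euploidcalc",
                      version = as.character(utils::packageVersion("euploidcalc")),
                      seed = config$seed,
                      train_fraction = config$train_fraction,
                      pi_levels = config$pi_levels,
                      auc_level = config$auc_level,
                      n_patients = nrow(records),
                      reference_label = if (!is.null(config$reference))
                        config$reference$label else NA_character_),
    nb_fit = nb, split_sizes = c(training = length(split$training),
                                 validation = length(split$validation)),
    lasso = lasso, logit = fit, metrics = metrics, mii = mii,
    comparison = comparison, ppv = ppv),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>  seed =", x$provenance$seed,
      " n =", x$provenance$n_patients, "\n")
  cat(sprintf("  split: %d training / %d validation\n",
              x$split_sizes["training"], x$split_sizes["validation"]))
  cat(sprintf("  NB preferred: %s (mu = %.3f, k = %.3g)\n",
              x$nb_fit$nb_preferred, x$nb_fit$mu, x$nb_fit$k))
  cat("  lasso selected:", if (length(x$lasso$selected))
    paste(x$lasso$selected, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  AUC (%s level): training %.3f, validation %.3f\n",
              x$metrics$auc_level, x$metrics$auc_training,
              x$metrics$auc_validation))
  cat(sprintf("  generalized R2: training %.3f, validation %.3f\n",
              x$metrics$r2_training, x$metrics$r2_validation))
  if (!is.null(x$comparison))
    cat(sprintf("  vs reference: r(p) = %.3f, median |dp| = %.4f\n",
                x$comparison$r_p, x$comparison$median_abs_dp))
  for (t in x$ppv)
    cat(sprintf("  PPV at pi = %.2f: %s\n", t$pi,
                if (is.na(t$ppv)) "undefined" else sprintf("%.1f%%", t$ppv)))
  invisible(x)
}

report_to_list <- function(x) {
  list(
    provenance = x$provenance,
    split_sizes = as.list(x$split_sizes),
    nb_fit = unclass(x$nb_fit),
    lasso = list(candidates = x$lasso$candidates, selected = x$lasso$selected,
                 lambda_opt = x$lasso$lambda_opt, theta = x$lasso$theta,
                 n = x$lasso$n, mii_mode = x$lasso$mii_mode),
    logit = list(coefs = unclass(x$logit$coefs)[coef_names],
                 age_center = x$logit$coefs$age_center,
                 se = as.list(x$logit$se),
                 loglik = x$logit$loglik,
                 loglik_aggregated = x$logit$loglik_aggregated,
                 n_patients = x$logit$n_patients,
                 n_oocytes = x$logit$n_oocytes),
    metrics = x$metrics,
    mii = x$mii,
    comparison = if (is.null(x$comparison)) NULL else
      list(r_p = x$comparison$r_p, rho_p = x$comparison$rho_p,
           r_mii = as.list(x$comparison$r_mii),
           median_abs_dp = x$comparison$median_abs_dp,
           mean_abs_dp = x$comparison$mean_abs_dp,
           n_profiles = x$comparison$n_profiles),
    ppv = lapply(x$ppv, function(t)
      list(pi = t$pi, counts = as.vector(t$counts), n = t$n, ppv = t$ppv,
           rate_not_reached = t$rate_not_reached)))
}

#' Serialize a validation report to JSON
#'
#' Numbers are written at full precision; counts as integers. The JSON embeds
#' the seed and configuration echo so any stage can be reproduced from the
#' report alone.
#'
#' @param report A `validation_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
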