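#' Sperm-source and center factor levels
#'
#' Three sperm-source levels are modelled: `ejaculate` (ejaculated sperm),
#' `surgical_non_noa` (epididymal or testicular sperm from men without
#' non-obstructive azoospermia, e.g. obstructive azoospermia), and
#' `testicular_noa` (testicular sperm from men with non-obstructive
#' azoospermia, NOA). Centers are the three study sites plus `unspecified`
#' (center-free prediction, zero center contribution).
#'
#' @name factor-levels
#' @keywords internal
NULL

sperm_levels  <- c("ejaculate", "surgical_non_noa", "testicular_noa")
center_levels <- c("anatolia", "androfert", "genera", "unspecified")
center_platform <- c(anatolia = "NGS", androfert = "NGS",
                     genera = "qPCR", unspecified = NA_character_)

match_level <- function(x, levels, what) {
  x <- tolower(as.character(x))
  bad <- !(x %in% levels)
  if (any(bad))
    stop(sprintf("invalid %s: %s (must be one of %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  x
}

#' Construct patient profiles
#'
#' A profile carries the three predictors of the euploidy model. Vector
#' arguments are recycled to a common length, so `patient_profile` doubles as
#' a profile-grid constructor.
#'
#' @param female_age Female age in years, each in `[18, 50]`.
#' @param sperm_source One of `"ejaculate"`, `"surgical_non_noa"`,
#'   `"testicular_noa"`.
#' @param center One of `"anatolia"`, `"androfert"`, `"genera"`,
#'   `"unspecified"`. Default `"unspecified"` (center-free mode).
#' @return A data frame of class `patient_profile` with columns `female_age`,
#'   `sperm_source`, `center`.
#' @examples
#' patient_profile(35, "ejaculate")
#' patient_profile(25:45, "testicular_noa", "genera")
#' @export
patient_profile <- function(female_age, sperm_source = "ejaculate",
                            center = "unspecified") {
  female_age <- as.numeric(female_age)
  if (any(!is.finite(female_age) | female_age < 18 | female_age > 50))
    stop("female_age must lie in [18, 50]", call. = FALSE)
  sperm_source <- match_level(sperm_source, sperm_levels, "sperm_source")
  center <- match_level(center, center_levels, "center")
  n <- max(length(female_age), length(sperm_source), length(center))
  out <- data.frame(female_age = rep_len(female_age, n),
                    sperm_source = rep_len(sperm_source, n),
                    center = rep_len(center, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("patient_profile", class(out))
  out
}

as_profile <- function(x) {
  if (inherits(x, "patient_profile")) return(x)
  if (is.data.frame(x)) {
    need <- c("female_age", "sperm_source", "center")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("profile data frame missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    return(patient_profile(x$female_age, x$sperm_source, x$center))
  }
  stop("cannot interpret object as patient profiles", call. = FALSE)
}

# Contrast codes for a profile: d1, d2 (sperm), e1, e2 (center).
profile_contrasts <- function(profile) {
  ss <- profile$sperm_source
  ce <- profile$center
  list(d1 = (ss == "ejaculate") - (ss == "testicular_noa"),
       d2 = (ss == "surgical_non_noa") - (ss == "testicular_noa"),
       e1 = (ce == "anatolia") - (ce == "androfert"),
       e2 = (ce == "genera") - (ce == "anatolia"))
}

#' Linear predictor of the euploidy model
#'
#' Evaluates the logit-scale linear predictor `Y` for one or more patient
#' profiles under a coefficient set (see [coefficient_set()] for the
#' contrast encoding). At `female_age == age_center` both age-interaction
#' terms contribute exactly zero.
#'
#' @param profile A [patient_profile()] (or a data frame with the same
#'   columns).
#' @param coefs A [coefficient_set()]; default [validation_model()].
#' @return Numeric vector `Y`, one value per profile row.
#' @examples
#' linear_predictor(patient_profile(39.414, "ejaculate", "androfert"))
#' @export
linear_predictor <- function(profile, coefs = validation_model()) {
  profile <- as_profile(profile)
  validate_coefficient_set(coefs)
  k <- profile_contrasts(profile)
  ac <- profile$female_age - coefs$age_center
  coefs$intercept +
    coefs$b_ej_noa_age * k$d1 * ac +
    coefs$b_surg_noa_age * k$d2 * ac +
    coefs$s_ej_noa * k$d1 +
    coefs$g_anat_andro * k$e1 +
    coefs$g_gen_anat * k$e2
}

#' Per-oocyte euploidy probability
#'
#' Inverse-logit map from the linear predictor: `p = 1 / (1 + exp(-Y))`,
#' strictly increasing in `Y`.
#'
#' @param Y Finite numeric vector of linear-predictor values.
#' @return Probabilities in (0, 1).
#' @export
euploidy_probability <- function(Y) {
  if (any(!is.finite(Y))) stop("Y must be finite", call. = FALSE)
  stats::plogis(Y)
}

# Achieved success after N oocytes at per-oocyte probability p,
# computed on the log scale for stability: 1 - (1-p)^N.
achieved_success <- function(p, N) -expm1(N * log1p(-p))

# Absolute boundary tolerance for the MIImin integer search: guards
# floating-point noise when (1-p)^N sits on the success threshold.
MII_TOL <- 1e-9

#' Minimum number of MII oocytes for a target success probability
#'
#' Under the per-oocyte model, the chance of at least one euploid blastocyst
#' from `N` MII oocytes is `1 - (1 - p)^N`. `mii_min` returns the smallest
#' integer `N >= 0` with `1 - (1 - p)^N >= pi`, i.e. the geometric bound
#' `MIImin >= log(1 - pi) / log(1 - p)` rounded up to an integer — computed
#' by an integer search seeded at the log-ratio (never a raw `ceiling`, which
#' is fragile when the ratio is near-integer; a `1e-9` tolerance on the
#' achieved-success comparison absorbs floating-point boundary noise).
#'
#' @param p Per-oocyte euploidy probability, strictly in (0, 1). A `p` at or
#'   below 0 makes the target unreachable and is reported as a domain error,
#'   not an overflow.
#' @param pi Target success probability, strictly in (0, 1).
#' @return An object of class `mii_estimate`: list with `p`, `pi`, `mii_min`
#'   (non-negative integer), `risk = 1 - pi`, and `achieved_success =
#'   1 - (1-p)^mii_min`.
#' @examples
#' mii_min(0.22, 0.7)   # 5 oocytes
#' mii_min(0.22, 0.9)   # 10 oocytes
#' @export
mii_min <- function(p, pi) {
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1)
    stop("p must be a single probability strictly inside (0, 1); ",
         "p <= 0 makes the success target unreachable", call. = FALSE)
  if (length(pi) != 1 || !is.finite(pi) || pi <= 0 || pi >= 1)
    stop("pi must be a single probability strictly inside (0, 1)", call. = FALSE)
  # log-ratio seed, then local integer search downward/upward
  seed <- log1p(-pi) / log1p(-p)
  n <- max(0L, as.integer(floor(seed)) - 2L)
  while (achieved_success(p, n) < pi - MII_TOL) n <- n + 1L
  while (n > 0L && achieved_success(p, n - 1L) >= pi - MII_TOL) n <- n - 1L
  structure(list(p = p, pi = pi, mii_min = n, risk = 1 - pi,
                 achieved_success = achieved_success(p, n)),
            class = "mii_estimate")
}

#' @export
print.mii_estimate <- function(x, ...) {
  cat(sprintf("MIImin = %d oocytes  (p = %.4f, target pi = %.2f, risk = %.2f, achieved = %.4f)\n",
              x$mii_min, x$p, x$pi, x$risk, x$achieved_success))
  invisible(x)
}

#' Predict MIImin for a patient profile
#'
#' Composition of [linear_predictor()], [euploidy_probability()] and
#' [mii_min()]: evaluates the per-oocyte probability for the profile and
#' returns the MIImin estimate(s) at the requested success probabilities.
#'
#' @param profile A single-row [patient_profile()].
#' @param pi Vector of target success probabilities, each in (0, 1).
#' @param coefs A [coefficient_set()]; default [validation_model()].
#' @param conf_level If non-`NULL` and the coefficient set carries standard
#'   errors, a normal-approximation confidence interval for `p` on the logit
#'   scale is attached (coefficient covariances are not published, so the
#'   interval ignores them and is approximate).
#' @return A data frame with one row per `pi`: columns `pi`, `p`, `mii_min`,
#'   `risk`, `achieved_success` (and `p_lo`, `p_hi`, `mii_min_lo`,
#'   `mii_min_hi` when intervals are requested).
#' @examples
#' predict_mii(patient_profile(35, "ejaculate"), pi = c(0.7, 0.8, 0.9))
#' @export
predict_mii <- function(profile, pi = c(0.7, 0.8, 0.9),
                        coefs = validation_model(), conf_level = NULL) {
  profile <- as_profile(profile)
  if (nrow(profile) != 1)
    stop("predict_mii expects a single-row profile", call. = FALSE)
  Y <- linear_predictor(profile, coefs)
  p <- euploidy_probability(Y)
  est <- lapply(pi, function(s) mii_min(p, s))
  out <- data.frame(pi = pi,
                    p = p,
                    mii_min = vapply(est, `[[`, integer(1), "mii_min"),
                    risk = 1 - pi,
                    achieved_success = vapply(est, `[[`, numeric(1),
                                              "achieved_success"))
  if (!is.null(conf_level)) {
    if (is.null(coefs$se))
      stop("coefficient set carries no standard errors; cannot form intervals",
           call. = FALSE)
    se_y <- linear_predictor_se(profile, coefs)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    p_lo <- stats::plogis(Y - z * se_y)
    p_hi <- stats::plogis(Y + z * se_y)
    out$p_lo <- p_lo
    out$p_hi <- p_hi
    # wider p interval -> fewer oocytes needed at p_hi, more at p_lo
    out$mii_min_lo <- vapply(pi, function(s) mii_min(p_hi, s)$mii_min, integer(1))
    out$mii_min_hi <- vapply(pi, function(s) mii_min(p_lo, s)$mii_min, integer(1))
  }
  out
}

# SE of the linear predictor ignoring coefficient covariances (they are not
# published); approximate by design.
linear_predictor_se <- function(profile, coefs) {
  k <- profile_contrasts(profile)
  ac <- profile$female_age - coefs$age_center
  x <- c(intercept = 1,
         b_ej_noa_age = k$d1 * ac,
         b_surg_noa_age = k$d2 * ac,
         s_ej_noa = k$d1,
         g_anat_andro = k$e1,
         g_gen_anat = k$e2)
  se <- rep(0, length(coef_names)); names(se) <- coef_names
  se[names(coefs$se)] <- coefs$se
  sqrt(sum((x[coef_names] * se)^2))
}
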