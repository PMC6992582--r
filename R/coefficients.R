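#' Coefficient sets for the per-oocyte euploidy model
#'
#' A `coefficient_set` holds the fitted logistic model that maps a patient
#' profile (female age, sperm source, study center) to the probability `p`
#' that one MII oocyte becomes a euploid blastocyst. The linear predictor is
#'
#' \deqn{Y = a + b_1 d_1 (age - c) + b_2 d_2 (age - c) + s_1 d_1 +
#'       g_1 e_1 + g_2 e_2}
#'
#' with indicator-difference contrasts
#' \eqn{d_1 = I(\mathrm{ejaculate}) - I(\mathrm{testicular\_noa})},
#' \eqn{d_2 = I(\mathrm{surgical\_non\_noa}) - I(\mathrm{testicular\_noa})},
#' \eqn{e_1 = I(\mathrm{anatolia}) - I(\mathrm{androfert})},
#' \eqn{e_2 = I(\mathrm{genera}) - I(\mathrm{anatolia})}, and
#' \eqn{p = 1/(1+e^{-Y})}. An `unspecified` center sets \eqn{e_1 = e_2 = 0}
#' ("center-free" mode, mimicking the public calculator which has no center
#' input).
#'
#' @param intercept Intercept `a` on the logit scale.
#' @param age_center Centering constant `c` in years; must lie in `[18, 50]`.
#' @param b_ej_noa_age Coefficient of `d1 * (age - c)` (per year).
#' @param b_surg_noa_age Coefficient of `d2 * (age - c)` (per year).
#' @param s_ej_noa Sperm-source main-effect contrast coefficient (on `d1`).
#' @param g_anat_andro Center contrast coefficient (on `e1`).
#' @param g_gen_anat Center contrast coefficient (on `e2`).
#' @param label Free-text label for the set.
#' @param platform_note Free-text note on the genetic-testing platform(s).
#' @param se Optional named numeric vector of standard errors, names among
#'   `c("intercept","b_ej_noa_age","b_surg_noa_age","s_ej_noa",
#'   "g_anat_andro","g_gen_anat")`.
#' @return An object of class `coefficient_set`.
#' @examples
#' cs <- coefficient_set(-2.7, 39.4, -0.14, -0.13, 0.49, 0, 0, label = "toy")
#' euploidy_probability(linear_predictor(patient_profile(35, "ejaculate"), cs))
#' @export
coefficient_set <- function(intercept, age_center,
                            b_ej_noa_age, b_surg_noa_age, s_ej_noa,
                            g_anat_andro = 0, g_gen_anat = 0,
                            label = "", platform_note = "", se = NULL) {
  cs <- structure(
    list(intercept = as.numeric(intercept),
         age_center = as.numeric(age_center),
         b_ej_noa_age = as.numeric(b_ej_noa_age),
         b_surg_noa_age = as.numeric(b_surg_noa_age),
         s_ej_noa = as.numeric(s_ej_noa),
         g_anat_andro = as.numeric(g_anat_andro),
         g_gen_anat = as.numeric(g_gen_anat),
         label = as.character(label),
         platform_note = as.character(platform_note),
         se = se),
    class = "coefficient_set")
  validate_coefficient_set(cs)
}

coef_names <- c("intercept", "b_ej_noa_age", "b_surg_noa_age",
                "s_ej_noa", "g_anat_andro", "g_gen_anat")

validate_coefficient_set <- function(cs) {
  num <- unlist(cs[coef_names])
  if (!all(is.finite(num)))
    stop("coefficient_set: all coefficients must be finite", call. = FALSE)
  if (!is.finite(cs$age_center) || cs$age_center < 18 || cs$age_center > 50)
    stop("coefficient_set: age_center must lie in [18, 50]", call. = FALSE)
  if (!is.null(cs$se)) {
    se <- cs$se
    if (is.null(names(se)) || !all(names(se) %in% coef_names))
      stop("coefficient_set: se must be named after coefficients", call. = FALSE)
    if (any(!is.finite(se) | se <= 0))
      stop("coefficient_set: standard errors must be positive", call. = FALSE)
  }
  cs
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set>", if (nzchar(x$label)) x$label else "(unlabelled)", "\n")
  cat(sprintf("  intercept      %+.6f\n", x$intercept))
  cat(sprintf("  age_center     %.3f years\n", x$age_center))
  cat(sprintf("  b_ej_noa_age   %+.6f  (d1 x centered age)\n", x$b_ej_noa_age))
  cat(sprintf("  b_surg_noa_age %+.6f  (d2 x centered age)\n", x$b_surg_noa_age))
  cat(sprintf("  s_ej_noa       %+.6f  (d1)\n", x$s_ej_noa))
  cat(sprintf("  g_anat_andro   %+.6f  (e1)\n", x$g_anat_andro))
  cat(sprintf("  g_gen_anat     %+.6f  (e2)\n", x$g_gen_anat))
  if (nzchar(x$platform_note)) cat("  platform:", x$platform_note, "\n")
  invisible(x)
}

#' The published multicenter validation-model coefficient set
#'
#' Returns the final validation model fitted to 1,464 couples from three
#' centers (Anatolia and Androfert on NGS, GENERA on qPCR): intercept
#' −2.728414, age interactions −0.138868 (ejaculate vs testicular-NOA) and
#' −0.13032 (surgical non-NOA vs testicular-NOA), sperm main contrast
#' 0.4928267, center contrasts 0.0807783 (Anatolia−Androfert) and 0.3765617
#' (GENERA−Anatolia), age centered at 39.414 years. Standard errors from the
#' published coefficient table are attached.
#'
#' The set is stored as plain JSON under
#' `system.file("extdata", "validation_model.json", package = "euploidcalc")`.
#'
#' @return A [coefficient_set()].
#' @examples
#' validation_model()
#' @export
validation_model <- function() {
  read_coefficient_set(system.file("extdata", "validation_model.json",
                                   package = "euploidcalc", mustWork = TRUE))
}

#' Read / write coefficient-set JSON files
#'
#' The JSON layout uses the field names of [coefficient_set()] verbatim, plus
#' an optional `se` object. Round-trips are lossless at full double precision.
#'
#' @param path File path.
#' @param cs A `coefficient_set`.
#' @return `read_coefficient_set` returns a `coefficient_set`;
#'   `write_coefficient_set` returns `path` invisibly.
#' @export
read_coefficient_set <- function(path) {
  if (!file.exists(path)) stop("coefficient-set file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("intercept", "age_center", coef_names[-1])
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("coefficient-set file missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  se <- NULL
  if (!is.null(j$se)) se <- unlist(j$se)
  coefficient_set(j$intercept, j$age_center,
                  j$b_ej_noa_age, j$b_surg_noa_age, j$s_ej_noa,
                  j$g_anat_andro, j$g_gen_anat,
                  label = j$label %||% "", platform_note = j$platform_note %||% "",
                  se = se)
}

#' @rdname read_coefficient_set
#' @export
write_coefficient_set <- function(cs, path) {
  stopifnot(inherits(cs, "coefficient_set"))
  out <- unclass(cs)
  out$se <- if (is.null(cs$se)) NULL else as.list(cs$se)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
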