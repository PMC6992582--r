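#' Specify a synthetic IVF/PGT-A cohort
#'
#' The generator emulates the structure of a multicenter PGT-A case series:
#' female ages from a truncated normal, a sperm-source mixture dominated by
#' ejaculated sperm with rare surgical retrievals, a three-center mixture,
#' per-patient MII-oocyte counts from a negative binomial, and a hierarchical
#' binomial cascade MII -> 2PN zygotes -> blastocysts -> euploid blastocysts
#' whose composition leaves the marginal law `m | N ~ Binomial(N, p)` with
#' `p` given by the ground-truth coefficient set.
#'
#' Defaults reproduce the published cohort: mean age 39.4 (sd 3.4, truncated
#' to `[30, 46]`, leaving the 95% interval at about 33–44), sperm mixture
#' 92.7/3.7/3.6% (ejaculate / surgical non-NOA / testicular NOA), center
#' weights 620:257:587 (Anatolia:Androfert:GENERA), MII counts with mean 6.7
#' (dispersion `k = 5`), fertilization rate 0.72 and blastulation rate 0.52.
#' The lower age bound is 30 rather than lower because the truth model's
#' per-oocyte probability at very young ages would exceed the fertilization x
#' blastulation product, which the thinning identity forbids (see the methods
#' vignette).
#'
#' @param n_patients Number of couples to simulate.
#' @param age_mean,age_sd,age_bounds Truncated-normal age model (years).
#' @param sperm_mix Named or ordered probability vector over
#'   `c("ejaculate","surgical_non_noa","testicular_noa")`; must sum to 1.
#' @param center_mix Named or ordered probability vector over
#'   `c("anatolia","androfert","genera")`; must sum to 1.
#' @param mii_mean,mii_k Negative-binomial mean and dispersion (size) for the
#'   per-patient MII count; variance is `mu + mu^2/k`.
#' @param fert_rate,blast_rate Per-center 2PN-fertilization and blastulation
#'   rates in (0, 1]; scalars are recycled across centers.
#' @param truth Ground-truth [coefficient_set()]; default [validation_model()].
#' @param seed Integer seed; every draw flows from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1464,
                        age_mean = 39.4, age_sd = 3.4, age_bounds = c(30, 46),
                        sperm_mix = c(ejaculate = 0.927,
                                      surgical_non_noa = 0.037,
                                      testicular_noa = 0.036),
                        center_mix = c(anatolia = 620, androfert = 257,
                                       genera = 587) / 1464,
                        mii_mean = 6.7, mii_k = 5,
                        fert_rate = 0.72, blast_rate = 0.52,
                        truth = validation_model(), seed = 1L) {
  stopifnot(n_patients >= 1, age_sd > 0, length(age_bounds) == 2,
            age_bounds[1] < age_bounds[2], mii_mean > 0, mii_k > 0)
  sperm_mix <- normalize_mix(sperm_mix, sperm_levels[1:3], "sperm_mix")
  center_mix <- normalize_mix(center_mix, center_levels[1:3], "center_mix")
  fert_rate <- rep_len(fert_rate, 3); blast_rate <- rep_len(blast_rate, 3)
  names(fert_rate) <- names(blast_rate) <- center_levels[1:3]
  if (any(fert_rate <= 0 | fert_rate > 1) || any(blast_rate <= 0 | blast_rate > 1))
    stop("stage rates must lie in (0, 1]", call. = FALSE)
  validate_coefficient_set(truth)
  structure(list(n_patients = as.integer(n_patients),
                 age_mean = age_mean, age_sd = age_sd,
                 age_bounds = as.numeric(age_bounds),
                 sperm_mix = sperm_mix, center_mix = center_mix,
                 mii_mean = mii_mean, mii_k = mii_k,
                 fert_rate = fert_rate, blast_rate = blast_rate,
                 truth = truth, seed = as.integer(seed)),
            class = "cohort_spec")
}

normalize_mix <- function(mix, levels, what) {
  if (is.null(names(mix))) names(mix) <- levels[seq_along(mix)]
  miss <- setdiff(levels, names(mix))
  mix <- c(mix, stats::setNames(rep(0, length(miss)), miss))[levels]
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop(what, " must be a non-negative vector summing to 1", call. = FALSE)
  mix
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` case-report-form records under a [cohort_spec()]. Per
#' patient: age, sperm source and center from the spec's mixtures; MII count
#' `N ~ NegBin(mu, k)`; `n_2pn ~ Binomial(N, f)`;
#' `n_blast ~ Binomial(n_2pn, b)`; and
#' `m ~ Binomial(n_blast, p / (f b))` with `p` from the truth coefficient
#' set, so that marginally `m | N ~ Binomial(N, p)`. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `cohort` with columns `patient_id`,
#'   `female_age`, `sperm_source`, `center`, `n_mii`, `n_2pn`, `n_blast`,
#'   `n_euploid`.
#' @examples
#' head(generate_cohort(cohort_spec(n_patients = 20, seed = 7)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  age <- rtruncnorm(n, spec$age_mean, spec$age_sd,
                    spec$age_bounds[1], spec$age_bounds[2])
  sperm <- sample(names(spec$sperm_mix), n, replace = TRUE, prob = spec$sperm_mix)
  center <- sample(names(spec$center_mix), n, replace = TRUE, prob = spec$center_mix)
  prof <- patient_profile(pmin(pmax(age, 18), 50), sperm, center)
  p <- euploidy_probability(linear_predictor(prof, spec$truth))
  f <- spec$fert_rate[center]; b <- spec$blast_rate[center]
  e <- p / (f * b)
  if (any(e > 1))
    stop(sprintf(paste0("cohort_spec inconsistent with truth model: per-oocyte ",
                        "p exceeds fert_rate * blast_rate for %d patient(s) ",
                        "(max p = %.3f, min f*b = %.3f); raise the stage rates ",
                        "or narrow the age bounds"),
                 sum(e > 1), max(p), min(f * b)), call. = FALSE)
  N <- as.integer(stats::rnbinom(n, mu = spec$mii_mean, size = spec$mii_k))
  n_2pn <- as.integer(stats::rbinom(n, N, f))
  n_blast <- as.integer(stats::rbinom(n, n_2pn, b))
  m <- as.integer(stats::rbinom(n, n_blast, e))
  out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                    female_age = prof$female_age,
                    sperm_source = prof$sperm_source,
                    center = prof$center,
                    n_mii = N, n_2pn = n_2pn, n_blast = n_blast,
                    n_euploid = m,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort", class(out))
  attr(out, "seed") <- spec$seed
  out
}

#' Summarize a cohort
#'
#' Demographics-and-treatment style summary: sample size, mean and quantiles
#' of age and of each stage count, sperm-source and center frequencies, and
#' the overall euploid-per-blastocyst percentage.
#'
#' @param records A cohort data frame (see [generate_cohort()] / [read_crf()]).
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  qs <- function(x) c(mean = mean(x),
                      stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  num <- c("female_age", "n_mii", "n_2pn", "n_blast", "n_euploid")
  tab <- t(vapply(records[num], qs, numeric(6)))
  blast_tot <- sum(records$n_blast)
  structure(list(
    n = nrow(records),
    numeric_summary = tab,
    sperm_source = table(factor(records$sperm_source, sperm_levels)),
    center = table(factor(records$center, center_levels)),
    pct_euploid_per_blastocyst =
      if (blast_tot > 0) 100 * sum(records$n_euploid) / blast_tot else NA_real_,
    pct_euploid_per_mii =
      100 * sum(records$n_euploid) / max(1, sum(records$n_mii))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>  n =", x$n, "couples\n")
  print(round(x$numeric_summary, 2))
  cat("sperm source:\n"); print(x$sperm_source)
  cat("center:\n"); print(x$center)
  cat(sprintf("euploid per blastocyst: %.1f%%   euploid per MII oocyte: %.1f%%\n",
              x$pct_euploid_per_blastocyst, x$pct_euploid_per_mii))
  invisible(x)
}
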