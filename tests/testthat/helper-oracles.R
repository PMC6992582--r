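# Independent oracles and shared fixtures. These deliberately avoid the code
# paths they check.

# Brute-force MIImin: iterate the cumulative failure product upward from N = 0,
# with the same 1e-9 boundary tolerance as the implementation contract.
oracle_mii_min <- function(p, pi, tol = 1e-9) {
  n <- 0L
  fail <- 1
  while (1 - fail < pi - tol) {
    fail <- fail * (1 - p)
    n <- n + 1L
    if (n > 1e6) stop("oracle runaway")
  }
  n
}

# Hand-coded re-implementation of the published linear predictor: explicit
# indicator evaluation, no shared code with linear_predictor().
oracle_linear_predictor <- function(age, sperm, center, cs) {
  I <- function(x) as.numeric(x)
  d1 <- I(sperm == "ejaculate") - I(sperm == "testicular_noa")
  d2 <- I(sperm == "surgical_non_noa") - I(sperm == "testicular_noa")
  e1 <- I(center == "anatolia") - I(center == "androfert")
  e2 <- I(center == "genera") - I(center == "anatolia")
  cs$intercept +
    cs$b_ej_noa_age * d1 * (age - cs$age_center) +
    cs$b_surg_noa_age * d2 * (age - cs$age_center) +
    cs$s_ej_noa * d1 + cs$g_anat_andro * e1 + cs$g_gen_anat * e2
}

# O(n^2) pairwise-count AUC: concordant pairs + half ties.
oracle_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Published PPV contingency counts (reached-MIImin row, not-reached row) at
# pi = 0.7 / 0.8 / 0.9 from the original multicenter validation cohort.
reference_ppv_counts <- list(
  `0.7` = list(reached = c(317, 57), not_reached = c(334, 756)),
  `0.8` = list(reached = c(217, 31), not_reached = c(434, 782)),
  `0.9` = list(reached = c(135, 15), not_reached = c(516, 798)))

# Small default spec for fast tests.
small_spec <- function(n = 200, seed = 1, ...) {
  cohort_spec(n_patients = n, seed = seed, ...)
}

# Spec with a single fixed profile (degenerate age) for conditional-law checks.
fixed_profile_spec <- function(n, seed, age = 40, sperm = "ejaculate",
                               center = "anatolia") {
  mix_s <- stats::setNames(as.numeric(sperm_levels_test == sperm),
                           sperm_levels_test)
  mix_c <- stats::setNames(as.numeric(center_levels_test == center),
                           center_levels_test)
  cohort_spec(n_patients = n, age_mean = age, age_sd = 1e-6,
              age_bounds = c(age - 0.1, age + 0.1),
              sperm_mix = mix_s, center_mix = mix_c, seed = seed)
}

sperm_levels_test <- c("ejaculate", "surgical_non_noa", "testicular_noa")
center_levels_test <- c("anatolia", "androfert", "genera")
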