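test_that("holdout split reproduces the published 75/25 arithmetic", {
  co <- generate_cohort(cohort_spec(n_patients = 1464, seed = 91))
  s <- holdout_split(co, 0.75, seed = 91)
  expect_identical(length(s$training), 1098L)
  expect_identical(length(s$validation), 366L)
  expect_identical(sort(c(s$training, s$validation)), 1:1464)
  expect_length(intersect(s$training, s$validation), 0)
  expect_identical(holdout_split(co, 0.75, seed = 91), s)
  expect_false(identical(holdout_split(co, 0.75, seed = 92)$training, s$training))
  expect_error(holdout_split(co, 1.2, 1), "fraction")
  expect_error(holdout_split(co[1:5, ], 0.75, 1), "at least 8")
})

test_that("auc matches hand-counted and degenerate cases", {
  expect_identical(auc(c(0.9, 0.8, 0.7, 0.4), c(1, 0, 1, 0)), 0.75)
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both outcome classes")
  expect_error(auc(0.5, c(0, 1)), "equal length")
})

test_that("auc equals the O(n^2) pairwise oracle, ties included", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    outcomes <- stats::rbinom(n, 1, 0.4)
    if (sum(outcomes) %in% c(0, n)) next
    expect_equal(auc(scores, outcomes), oracle_auc(scores, outcomes),
                 tolerance = 1e-12)
  }
})

test_that("generalized R2 follows the Nagelkerke form", {
  expect_identical(generalized_r2(-10, -10, 50), 0)
  expect_identical(generalized_r2(-6.93, 0, 10), 1)
  # hand-sized case evaluated through an independently coded expression
  l0 <- -6.93; l1 <- -5; n <- 10
  want <- (1 - (exp(l0) / exp(l1))^(2 / n)) / (1 - exp(l0)^(2 / n))
  expect_equal(generalized_r2(l0, l1, n), want, tolerance = 1e-12)
  expect_error(generalized_r2(-5, -6, 10), "loglik_model")
  expect_error(generalized_r2(-5, -4, 0), "n_rows")
})

test_that("model comparison is exact for self and monotone transforms", {
  cs <- validation_model()
  grid <- patient_profile(seq(30, 45, by = 0.5), "ejaculate", "anatolia")
  self <- compare_models(cs, cs, grid)
  expect_equal(self$r_p, 1)
  expect_identical(self$median_abs_dp, 0)
  expect_equal(unname(self$r_mii), rep(1, 3), tolerance = 1e-12)
  shifted <- cs; shifted$intercept <- cs$intercept - 0.1
  cmp <- compare_models(cs, shifted, grid)
  expect_equal(cmp$rho_p, 1)  # monotone transform preserves ranks
  expect_gt(cmp$median_abs_dp, 0)
  expect_error(compare_models(cs, cs, grid[1:5, ]), "at least 10")
})

test_that("model comparison is robust to small coefficient perturbations", {
  cs <- validation_model()
  set.seed(111)
  pert <- cs
  for (nm in c("intercept", "b_ej_noa_age", "b_surg_noa_age", "s_ej_noa",
               "g_anat_andro", "g_gen_anat"))
    pert[[nm]] <- cs[[nm]] * stats::runif(1, 0.95, 1.05)
  grid <- patient_profile(rep(seq(30, 45, by = 0.5), 3),
                          rep(sperm_levels_test, each = 31), "anatolia")
  cmp <- compare_models(cs, pert, grid)
  expect_gt(cmp$r_p, 0.95)
  # constant predictions have undefined correlation, reported as NA
  flat <- coefficient_set(-2, 39.4, 0, 0, 0)
  cmp2 <- compare_models(cs, flat, grid)
  expect_true(is.na(cmp2$r_p))
})

test_that("ppv_table_from_counts reproduces the published contingency arithmetic", {
  for (pi in names(reference_ppv_counts)) {
    cc <- reference_ppv_counts[[pi]]
    t3 <- ppv_table_from_counts(cc$reached, cc$not_reached, as.numeric(pi))
    want <- c(`0.7` = 84.8, `0.8` = 87.5, `0.9` = 90.0)[[pi]]
    expect_equal(round(t3$ppv, 1), want)
    expect_identical(t3$n, sum(cc$reached, cc$not_reached))
  }
})

test_that("ppv_table classifies reached patients and handles empty cells", {
  cs <- validation_model()
  co <- generate_cohort(cohort_spec(n_patients = 500, seed = 121))
  t7 <- ppv_table(co, cs, 0.7)
  expect_identical(t7$n, 500L)
  expect_identical(sum(t7$counts), 500L)
  # recompute one patient by hand
  i <- 17
  p_i <- euploidy_probability(linear_predictor(co[i, ], cs))
  reached_i <- co$n_mii[i] >= mii_min(p_i, 0.7)$mii_min
  eup_i <- co$n_euploid[i] >= 1
  expect_identical(unname(t7$counts[ifelse(reached_i, 1, 2),
                                    ifelse(eup_i, 1, 2)] >= 1), TRUE)
  # a cohort where nobody reaches MIImin: undefined PPV, not zero
  co2 <- co; co2$n_mii <- 0L; co2$n_2pn <- 0L; co2$n_blast <- 0L
  co2$n_euploid <- 0L
  t_empty <- ppv_table(co2, cs, 0.9)
  expect_true(is.na(t_empty$ppv))
})

test_that("tukey_hsd controls type I error and detects a 5-SD shift", {
  # identical groups: zero difference, not significant
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  t0 <- tukey_hsd(g)
  expect_identical(t0$diff, 0)
  expect_false(t0$significant)
  # type-I: three null groups, few false positives across seeds
  fp <- vapply(1:20, function(sd) {
    set.seed(700 + sd)
    gr <- list(x = stats::rnorm(200), y = stats::rnorm(200), z = stats::rnorm(200))
    any(tukey_hsd(gr)$significant)
  }, logical(1))
  expect_lte(mean(fp), 0.10 + 0.15)  # alpha 0.05 familywise + binomial noise
  # power: one group shifted by 5 pooled SDs
  set.seed(701)
  gr <- list(x = stats::rnorm(50), y = stats::rnorm(50), z = stats::rnorm(50) + 5)
  tt <- tukey_hsd(gr)
  expect_true(all(tt$significant[grepl("z", tt$pair)]))
  expect_error(tukey_hsd(list(a = c(1, 1), b = c(2, 2))), "zero within-group")
  expect_error(tukey_hsd(list(a = 1:3)), ">= 2")
})

test_that("tukey_hsd agrees with the stats::TukeyHSD oracle", {
  set.seed(131)
  gr <- list(anatolia = stats::rnorm(40, 0.7, 0.1),
             androfert = stats::rnorm(25, 0.72, 0.1),
             genera = stats::rnorm(60, 0.76, 0.1))
  mine <- tukey_hsd(gr)
  df <- data.frame(rate = unlist(gr),
                   center = factor(rep(names(gr), lengths(gr)),
                                   levels = names(gr)))
  ref <- stats::TukeyHSD(stats::aov(rate ~ center, df))$center
  ord <- match(gsub(" ", "", rownames(ref)), gsub(" ", "", mine$pair))
  expect_equal(mine$diff[ord], unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(mine$lwr[ord], unname(ref[, "lwr"]), tolerance = 1e-10)
  expect_equal(mine$upr[ord], unname(ref[, "upr"]), tolerance = 1e-10)
  expect_equal(mine$p_adj[ord], unname(ref[, "p adj"]), tolerance = 1e-8)
})
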