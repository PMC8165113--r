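make_toy_clinical <- function(age, sex) {
  data.frame(patient_id = paste0("P", seq_along(age)), sex = sex, age = age,
             stringsAsFactors = FALSE)
}

test_that("propensity scores are 0.5 with no information", {
  cl <- make_toy_clinical(rep(60, 8), rep(c("M", "F"), each = 4))
  fit <- fit_propensity(cl, covariates = "age")
  expect_equal(unname(fit$scores), rep(0.5, 8), tolerance = 1e-8)
})

test_that("propensity coefficients match a grid-search MLE oracle", {
  cl <- make_toy_clinical(c(70, 75, 80, 62, 66, 77),
                          c("M", "M", "M", "F", "F", "F"))
  fit <- fit_propensity(cl, covariates = "age")

  # independent oracle: iteratively refined exhaustive grid search over
  # (intercept, slope) maximizing the Bernoulli log-likelihood
  y <- as.numeric(cl$sex == "M")
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * cl$age
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  centre <- c(0, 0); width <- c(40, 2)
  for (it in 1:30) {
    b0s <- seq(centre[1] - width[1], centre[1] + width[1], length.out = 41)
    b1s <- seq(centre[2] - width[2], centre[2] + width[2], length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    centre <- c(b0s[best[1]], b1s[best[2]])
    # halve the window around the grid argmax; the step size stays far
    # below the window so a concave surface cannot escape it
    width <- width / 2
  }
  expect_equal(unname(fit$coefficients), centre, tolerance = 1e-4)
})

test_that("perfect separation is flagged but scores are returned", {
  cl <- make_toy_clinical(c(80, 81, 82, 60, 61, 62),
                          c("M", "M", "M", "F", "F", "F"))
  expect_warning(fit <- fit_propensity(cl, covariates = "age"), "separation")
  expect_true(fit$separation)
  expect_length(fit$scores, 6)
})

test_that("greedy matching honours caliper and score order", {
  sex <- setNames(rep(c("M", "F"), each = 3), paste0("P", 1:6))
  equal <- setNames(rep(0.5, 6), names(sex))
  m <- greedy_match(equal, caliper = Inf, seed = 1, sex = sex)
  expect_equal(nrow(m$pairs), 3)

  distinct <- setNames(c(0.9, 0.7, 0.5, 0.3, 0.2, 0.1), names(sex))
  expect_equal(nrow(greedy_match(distinct, caliper = 0, seed = 1,
                                 sex = sex)$pairs), 0)

  # pair count is monotone non-decreasing in caliper
  counts <- vapply(c(0, 0.1, 0.25, 0.5, 1),
                   function(cal) nrow(greedy_match(distinct, caliper = cal,
                                                   seed = 1, sex = sex)$pairs),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("greedy matching equals the optimal assignment on a 3v3 toy", {
  sex <- setNames(rep(c("M", "F"), each = 3), paste0("P", 1:6))
  scores <- setNames(c(0.8, 0.5, 0.2, 0.75, 0.45, 0.25), names(sex))
  m <- greedy_match(scores, caliper = Inf, seed = 1, sex = sex)

  # oracle: enumerate all 3! assignments, take minimum total distance
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  males <- paste0("P", 1:3); females <- paste0("P", 4:6)
  costs <- vapply(perms, function(pm)
    sum(abs(scores[males] - scores[females[pm]])), numeric(1))
  best <- perms[[which.min(costs)]]
  expected <- data.frame(male = males, female = females[best],
                         stringsAsFactors = FALSE)
  got <- m$pairs[order(m$pairs$male), c("male", "female")]
  rownames(got) <- NULL
  expect_equal(got, expected)
})

test_that("standardized differences reproduce printed cohort diagnostics", {
  # continuous: age
  expect_equal(round(standardized_difference(c(75.3, 5.7), c(74.4, 5.2),
                                             "continuous"), 2), 0.16)
  # binary: CABG 9/18 vs 5/18
  expect_equal(round(standardized_difference(9 / 18, 5 / 18, "binary"), 2),
               0.47)
  # multicategory: smoking (never, former, current)
  expect_equal(round(standardized_difference(c(7, 11, 0) / 18,
                                             c(8, 8, 1) / 17,
                                             "multicategory"), 2), 0.42)
  # identical summaries give exactly zero
  expect_equal(standardized_difference(c(5, 1), c(5, 1), "continuous"), 0)
  expect_equal(standardized_difference(0.3, 0.3, "binary"), 0)
})

test_that("standardized difference properties hold", {
  # symmetry under group swap
  expect_equal(standardized_difference(c(10, 2), c(12, 3), "continuous"),
               standardized_difference(c(12, 3), c(10, 2), "continuous"))
  # invariance to affine rescaling of a continuous covariate
  d1 <- standardized_difference(c(10, 2), c(12, 3), "continuous")
  d2 <- standardized_difference(c(10 * 7 + 1, 2 * 7), c(12 * 7 + 1, 3 * 7),
                                "continuous")
  expect_equal(d1, d2)
  # multicategory with K = 2 equals the binary formula
  for (pp in list(c(0.2, 0.5), c(0.7, 0.6), c(0.05, 0.3))) {
    expect_equal(
      standardized_difference(c(pp[1], 1 - pp[1]), c(pp[2], 1 - pp[2]),
                              "multicategory"),
      standardized_difference(pp[1], pp[2], "binary"), tolerance = 1e-12)
  }
})

test_that("balance table is computed on matched patients only", {
  cfg <- sim_config(n_pool_per_sex = 40, n_pairs_target = 30,
                    covariate_params = list(cabg = list(p = 0.4),
                                            diabetes = list(p = 0.2)))
  cl <- simulate_clinical(cfg, seed = 21)
  fit <- fit_propensity(cl)
  m <- greedy_match(fit, seed = 22)
  bal <- balance_table(cl, m)
  expect_equal(nrow(bal), 6)
  expect_true(all(bal$std_diff >= 0))

  # constant covariate in both groups gives d = 0
  cl$ckd <- 0
  bal2 <- balance_table(cl, m)
  expect_equal(bal2$std_diff[bal2$covariate == "ckd"], 0)
})

test_that("a balanced cohort yields small standardized differences", {
  # equal covariate distributions by construction; only sampling noise left
  cfg <- sim_config(n_pool_per_sex = 2000, n_pairs_target = 2000,
                    covariate_params = list(cabg = list(p = 0.4),
                                            diabetes = list(p = 0.2),
                                            smoking = list(p_m = c(0.4, 0.5, 0.1),
                                                           p_f = c(0.4, 0.5, 0.1))))
  cl <- simulate_clinical(cfg, seed = 31)
  bal <- balance_table(cl, match = NULL)
  expect_true(all(bal$std_diff < 0.1))
})
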