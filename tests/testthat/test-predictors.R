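test_that("cv_partition covers samples, balances folds and honours groups", {
  # leave-one-out when grouping is off and k = n
  f <- cv_partition(rep("g", 6), cv = cv_config(k = 6, group_by_patient = FALSE))
  expect_setequal(f, 1:6)

  # 6 patients x 2 samples, k = 3: no patient split across folds
  groups <- rep(paste0("P", 1:6), each = 2)
  f <- cv_partition(groups, labels = rep(0:1, 6), cv = cv_config(k = 3))
  for (g in unique(groups))
    expect_length(unique(f[groups == g]), 1)
  # fold sizes differ by at most one group
  sizes <- table(f[!duplicated(groups)])
  expect_lte(diff(range(sizes)), 1)

  expect_error(cv_partition(rep("g1", 5), cv = cv_config(k = 2)), "exceeds")
})

test_that("grouped CV never splits a patient (exhaustive over seeds)", {
  groups <- rep(sprintf("P%02d", 1:18), each = 2)
  labels <- rep(0:1, 18)
  for (s in 1:25) {
    f <- cv_partition(groups, labels, cv = cv_config(k = 6, seed = s))
    split_counts <- tapply(f, groups, function(v) length(unique(v)))
    expect_true(all(split_counts == 1))
    expect_setequal(unique(f), 1:6)
  }
})

test_that("cv_evaluate reproduces a manual fold loop exactly", {
  set.seed(15)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- as.integer(x[, 1] + rnorm(40, 0, 0.5) > 0)
  folds <- cv_partition(seq_len(40), labels = y,
                        cv = cv_config(k = 4, group_by_patient = FALSE))
  spec <- model_bench("naive_bayes")$naive_bayes
  perf <- cv_evaluate(spec, x, y, folds)

  accs <- vapply(1:4, function(k) {
    fit <- spec$fit(x[folds != k, ], y[folds != k])
    mean(as.integer(spec$prob(fit, x[folds == k, , drop = FALSE]) > 0.5) ==
           y[folds == k])
  }, numeric(1))
  expect_equal(perf$mean_accuracy, mean(accs), tolerance = 1e-12)
  expect_equal(perf$per_fold$accuracy, accs, tolerance = 1e-12)
})

test_that("constant features fall back to the majority baseline", {
  set.seed(16)
  y <- rep(c(0, 1), times = c(28, 12))
  x <- matrix(1, 40, 2)
  folds <- cv_partition(seq_len(40), labels = y,
                        cv = cv_config(k = 4, group_by_patient = FALSE,
                                       seed = 2))
  perf <- cv_evaluate(model_bench("naive_bayes")$naive_bayes, x, y, folds)
  maj <- 28 / 40
  expect_lt(abs(perf$mean_accuracy - maj), 3 * sqrt(maj * (1 - maj) / 40))
})

test_that("separable data is classified perfectly by forest and logistic", {
  set.seed(17)
  x <- cbind(c(rnorm(20, -4, 0.5), rnorm(20, 4, 0.5)), rnorm(40))
  y <- rep(c(0, 1), each = 20)
  folds <- cv_partition(seq_len(40), labels = y,
                        cv = cv_config(k = 4, group_by_patient = FALSE))
  for (nm in c("random_forest", "logistic")) {
    perf <- cv_evaluate(model_bench(nm, seed = 3)[[nm]], x, y, folds)
    expect_equal(perf$mean_accuracy, 1.0)
  }
})

test_that("degenerate GA reduces to argmax over singleton masks", {
  set.seed(18)
  x <- cbind(f1 = rnorm(30), f2 = c(rnorm(15, 0), rnorm(15, 5)),
             f3 = rnorm(30))
  y <- rep(c(0, 1), each = 15)
  init <- diag(3) == 1
  res <- ga_select(x, y,
                   ga = ga_config(population = 3, generations = 1, seed = 4,
                                  mutation_p = 0, crossover_p = 0),
                   cv = cv_config(k = 3, group_by_patient = FALSE, seed = 4),
                   initial = init)
  expect_true(res$mask[2])
  expect_gte(res$fitness, 0.9)
})

test_that("GA fitness history is non-decreasing under elitism", {
  set.seed(19)
  x <- matrix(rnorm(30 * 4), 30, 4)
  x[, 2] <- x[, 2] + rep(c(0, 3), each = 15)
  y <- rep(c(0, 1), each = 15)
  res <- ga_select(x, y,
                   ga = ga_config(population = 6, generations = 5,
                                  elitism = 1, fitness_trees = 10, seed = 5),
                   cv = cv_config(k = 3, group_by_patient = FALSE, seed = 5))
  expect_true(all(diff(res$history) >= 0))
  expect_gte(res$fitness, max(res$history))
})

test_that("the empty mask is assigned fitness zero", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(0:1, 5)
  res <- ga_select(x, y,
                   ga = ga_config(population = 2, generations = 1,
                                  mutation_p = 0, crossover_p = 0, seed = 6),
                   cv = cv_config(k = 2, group_by_patient = FALSE, seed = 6),
                   initial = rbind(c(FALSE, FALSE), c(TRUE, TRUE)))
  # the all-zero individual cannot win against any informative mask
  expect_true(any(res$mask))
})

test_that("fit_models is honest on random labels and perfect on separated ones", {
  set.seed(20)
  n <- 50
  x <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, 0.5)
  rep0 <- fit_models(x, y, cv = cv_config(k = 5, group_by_patient = FALSE),
                     models = model_bench(c("naive_bayes", "random_forest"),
                                          seed = 21), seed = 21)
  sm <- summary(rep0)
  # AUC of held-out predictions on random labels: null SE ~ sqrt(1/12) on
  # ~25 per class; 3 SE band around 0.5
  expect_true(all(abs(sm$pooled_auc - 0.5) < 3 * sqrt(1 / 12) / sqrt(25)))

  x2 <- x; x2[, 1] <- x2[, 1] + y * 10
  rep1 <- fit_models(x2, y, cv = cv_config(k = 5, group_by_patient = FALSE),
                     models = model_bench(c("random_forest", "gbt"),
                                          seed = 22), seed = 22)
  sm1 <- summary(rep1)
  expect_equal(sm1$mean_accuracy, c(1, 1))

  # ROC of a perfect scorer passes through (0, 1)
  roc <- roc_points(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
})

test_that("sex-chromosome subsetting filters by annotation", {
  mat <- matrix(rnorm(10 * 4), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  ann <- data.frame(gene_id = paste0("g", 1:10),
                    chromosome = c("X", "2", "X", "Y", "3", "X", "5", "7",
                                   "11", "22"))
  sub <- subset_sex_chromosomes(mat, ann)
  expect_equal(rownames(sub), c("g1", "g3", "g4", "g6"))

  ann_auto <- ann; ann_auto$chromosome <- "1"
  expect_error(subset_sex_chromosomes(mat, ann_auto), "no sex-chromosome")

  ann_x <- ann; ann_x$chromosome <- "X"
  expect_equal(subset_sex_chromosomes(mat, ann_x), mat)
})
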