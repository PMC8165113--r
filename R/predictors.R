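#' Cross-validation configuration
#'
#' @param k Fold count (default 6).
#' @param group_by_patient Keep all samples of a patient in one fold
#'   (default on, so calcified and nondiseased samples of the same valve can
#'   never sit on opposite sides of a split — information leakage is
#'   structurally impossible).
#' @param stratify_by_class Balance class counts across folds at the group
#'   level where possible.
#' @param seed Seed for the fold shuffle.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(k = 6L, group_by_patient = TRUE,
                      stratify_by_class = TRUE, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  structure(list(k = as.integer(k), group_by_patient = group_by_patient,
                 stratify_by_class = stratify_by_class,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Partition samples into cross-validation folds
#'
#' Folds are disjoint, cover all samples, and differ by at most one group in
#' size. With grouping on, every sample of a group (patient) shares a fold.
#' With stratification, groups are shuffled within class strata before being
#' dealt out, balancing classes across folds where group sizes allow.
#'
#' @param groups Group id per sample (patient ids); ignored when
#'   `cv$group_by_patient` is FALSE.
#' @param labels Optional class label per sample for stratification.
#' @param cv A [cv_config()].
#' @return Integer fold assignment (1..k) per sample.
#' @export
cv_partition <- function(groups, labels = NULL, cv = cv_config()) {
  n <- length(groups)
  if (!cv$group_by_patient) groups <- seq_len(n)
  ug <- unique(groups)
  if (cv$k > length(ug))
    stop("k exceeds the number of groups (", length(ug), ")")
  glabel <- if (!is.null(labels) && cv$stratify_by_class) {
    vapply(ug, function(g) {
      tab <- table(labels[groups == g])
      names(tab)[which.max(tab)]
    }, character(1))
  } else rep("all", length(ug))
  fold_of_group <- with_seed(cv$seed, {
    ordered <- unlist(lapply(unique(glabel), function(l) {
      gs <- ug[glabel == l]
      gs[sample.int(length(gs))]
    }), use.names = FALSE)
    stats::setNames(rep_len(seq_len(cv$k), length(ordered)),
                    as.character(ordered))
  })
  unname(fold_of_group[as.character(groups)])
}

#' Cross-validated evaluation of one model
#'
#' Conventional k-fold: for each fold, train on the other k-1 folds and
#' predict the held-out fold. (The inverse reading — train on one partition,
#' validate on the rest — is available via `invert = TRUE` for comparison.)
#' Reports per-fold and mean accuracy and AUC, plus held-out scores pooled
#' across folds for ROC construction.
#'
#' @param spec A `model_spec` from [model_bench()].
#' @param x Feature matrix (samples x features).
#' @param y Binary labels.
#' @param folds Integer fold assignment from [cv_partition()].
#' @param invert Train on one fold, validate on the rest.
#' @return List of class `cv_performance`: `per_fold` data.frame,
#'   `mean_accuracy`, `mean_auc`, `pooled_scores`, `pooled_labels`,
#'   `pooled_auc`, `roc`.
#' @export
cv_evaluate <- function(spec, x, y, folds, invert = FALSE) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  kset <- sort(unique(folds))
  acc <- auc <- rep(NA_real_, length(kset))
  pooled_scores <- numeric(0)
  pooled_labels <- numeric(0)
  for (i in seq_along(kset)) {
    test <- if (invert) folds != kset[i] else folds == kset[i]
    train <- !test
    if (length(unique(y[train])) < 2) {
      warning("fold ", kset[i], " skipped: single-class training split")
      next
    }
    fit <- spec$fit(x[train, , drop = FALSE], y[train])
    pr <- spec$prob(fit, x[test, , drop = FALSE])
    acc[i] <- mean(as.integer(pr > 0.5) == y[test])
    auc[i] <- auc_score(pr, y[test])
    pooled_scores <- c(pooled_scores, pr)
    pooled_labels <- c(pooled_labels, y[test])
  }
  structure(list(
    per_fold = data.frame(fold = kset, accuracy = acc, auc = auc),
    mean_accuracy = mean(acc, na.rm = TRUE),
    mean_auc = mean(auc, na.rm = TRUE),
    pooled_scores = pooled_scores, pooled_labels = pooled_labels,
    pooled_auc = auc_score(pooled_scores, pooled_labels),
    roc = roc_points(pooled_scores, pooled_labels)),
    class = "cv_performance")
}

#' Genetic-algorithm configuration
#'
#' Pinned defaults for the wrapper search (the upstream tool's defaults are
#' not published, so these are the package's own, documented once):
#' population 20, 12 generations, tournament selection of size 2, uniform
#' crossover with probability 0.8, per-bit mutation 1/p, elitism 1. Fitness
#' is the mean k-fold CV accuracy of a random forest on the masked features
#' (`fitness_trees` trees, default 25, a smaller forest than the final
#' models purely for search speed).
#'
#' @param population Population size (>= 2).
#' @param generations Generations to evolve.
#' @param mutation_p Per-bit mutation probability; default 1/n_features.
#' @param crossover_p Probability of uniform crossover.
#' @param elitism Elite individuals copied unchanged (< population).
#' @param fitness_trees Trees in the fitness forest.
#' @param seed Integer seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population = 20L, generations = 12L, mutation_p = NULL,
                      crossover_p = 0.8, elitism = 1L, fitness_trees = 25L,
                      seed = 1L) {
  if (population < 2) stop("population must be >= 2")
  if (elitism >= population) stop("elitism must be < population")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_p = mutation_p, crossover_p = crossover_p,
                 elitism = as.integer(elitism),
                 fitness_trees = as.integer(fitness_trees),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm wrapper feature selection
#'
#' Evolves binary feature masks by tournament selection, uniform crossover,
#' bit-flip mutation and elitism. The fitness of a mask is the mean k-fold
#' cross-validated accuracy of a random forest trained on the masked
#' features (the nested subprocess); the empty mask scores 0. Returns the
#' best mask ever seen. Fitness values are cached per mask, and folds are
#' fixed once per call so fitness is a deterministic function of the mask.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param ga A [ga_config()].
#' @param cv A [cv_config()].
#' @param groups Group ids per sample for grouped folds (default: each
#'   sample its own group).
#' @param initial Optional initial population matrix (individuals x
#'   features, 0/1).
#' @return List of class `ga_result`: `mask` (logical), `features`,
#'   `fitness`, `history` (best fitness per generation), `evaluations`.
#' @export
ga_select <- function(x, y, ga = ga_config(), cv = cv_config(),
                      groups = NULL, initial = NULL) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  p <- ncol(x)
  if (p < 1) stop("need at least one feature")
  if (is.null(groups)) groups <- seq_len(nrow(x))
  folds <- cv_partition(groups, labels = y, cv = cv)
  mut_p <- ga$mutation_p %||% (1 / p)
  rf_spec <- model_spec(
    "ga_fitness_forest",
    fit = function(xx, yy) random_forest(xx, yy, n_trees = ga$fitness_trees,
                                         seed = child_seed(ga$seed, 999)),
    prob = function(fit, xx) predict(fit, xx, type = "prob"))

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (!any(mask)) 0 else {
      n_eval <<- n_eval + 1L
      cv_evaluate(rf_spec, x[, mask, drop = FALSE], y, folds)$mean_accuracy
    }
    cache[[key]] <- val
    val
  }

  with_seed(ga$seed, {
    pop <- initial
    if (is.null(pop))
      pop <- matrix(stats::runif(ga$population * p) < 0.5, ga$population, p)
    pop <- pop > 0
    if (all(rowSums(pop) == 0)) {
      warning("all-zero initial population; reinitialized")
      pop <- matrix(stats::runif(nrow(pop) * p) < 0.5, nrow(pop), p)
    }
    npop <- nrow(pop)
    fit_vals <- apply(pop, 1, fitness)
    best_mask <- pop[which.max(fit_vals), ]
    best_fit <- max(fit_vals)
    history <- numeric(ga$generations)
    for (gen in seq_len(ga$generations)) {
      elite_idx <- order(-fit_vals)[seq_len(ga$elitism)]
      children <- matrix(FALSE, npop, p)
      if (ga$elitism > 0)
        children[seq_len(ga$elitism), ] <- pop[elite_idx, , drop = FALSE]
      tournament <- function() {
        cand <- sample.int(npop, 2)
        cand[which.max(fit_vals[cand])]
      }
      ci <- ga$elitism
      while (ci < npop) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        if (stats::runif(1) < ga$crossover_p) {
          swap <- stats::runif(p) < 0.5
          tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
        }
        for (child in list(p1, p2)) {
          if (ci >= npop) break
          flip <- stats::runif(p) < mut_p
          child[flip] <- !child[flip]
          ci <- ci + 1
          children[ci, ] <- child
        }
      }
      pop <- children
      fit_vals <- apply(pop, 1, fitness)
      if (max(fit_vals) > best_fit) {
        best_fit <- max(fit_vals)
        best_mask <- pop[which.max(fit_vals), ]
      }
      history[gen] <- best_fit
    }
    structure(list(mask = best_mask,
                   features = (colnames(x) %||% paste0("f", seq_len(p)))[best_mask],
                   fitness = best_fit, history = history,
                   evaluations = n_eval),
              class = "ga_result")
  })
}

#' Evaluate the six-model prediction bench
#'
#' Runs every model of [model_bench()] under the same cross-validation
#' folds, reporting per-fold and mean accuracy, pooled AUC and ROC points.
#' A model that errors is recorded as failed; the others proceed.
#'
#' @param x Feature matrix (samples x features).
#' @param y Binary labels (calcified vs nondiseased).
#' @param groups Group ids per sample (patients) for grouped folds.
#' @param cv A [cv_config()].
#' @param models Model specs; default the full bench.
#' @param seed Seed forwarded to the stochastic learners.
#' @return List of class `model_report`: per-model `cv_performance` (or a
#'   failure record), plus `folds`.
#' @export
fit_models <- function(x, y, groups = NULL, cv = cv_config(),
                       models = NULL, seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  if (is.null(groups)) groups <- seq_len(nrow(x))
  if (is.null(models)) models <- model_bench(seed = seed)
  folds <- cv_partition(groups, labels = y, cv = cv)
  results <- lapply(models, function(spec) {
    tryCatch(cv_evaluate(spec, x, y, folds),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "model_failure"))
  })
  structure(list(models = results, folds = folds), class = "model_report")
}

#' Summarise a model report
#'
#' @param object A `model_report`.
#' @param ... Unused.
#' @return data.frame with one row per model: mean accuracy, mean AUC,
#'   pooled AUC.
#' @export
summary.model_report <- function(object, ...) {
  rows <- lapply(names(object$models), function(nm) {
    r <- object$models[[nm]]
    if (inherits(r, "model_failure"))
      return(data.frame(model = nm, mean_accuracy = NA_real_,
                        mean_auc = NA_real_, pooled_auc = NA_real_,
                        error = r$error, stringsAsFactors = FALSE))
    data.frame(model = nm, mean_accuracy = r$mean_accuracy,
               mean_auc = r$mean_auc, pooled_auc = r$pooled_auc,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subset an expression matrix to sex-chromosome genes
#'
#' Retains genes annotated to chromosome X or Y, preserving order — the
#' unbiased gene selection used for the sex-chromosome-only prediction
#' variant.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param annotation Gene annotation with columns gene_id, chromosome;
#'   taken from rowData for a SummarizedExperiment.
#' @return Object of the same type as `expr` with X/Y genes only.
#' @export
subset_sex_chromosomes <- function(expr, annotation = NULL) {
  ann <- expr_annotation(expr, annotation)
  mat <- expr_matrix(expr)
  idx <- match(rownames(mat), ann$gene_id)
  if (anyNA(idx)) stop("annotation does not cover all genes")
  keep <- which(ann$chromosome[idx] %in% c("X", "Y"))
  if (length(keep) == 0) stop("no sex-chromosome genes found")
  subset_genes(expr, keep)
}
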