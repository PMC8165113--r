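#' Fit a propensity model for male sex
#'
#' Maximum-likelihood logistic regression of sex (male = 1) on the matching
#' covariates. Categorical covariates are one-hot encoded against a stated
#' reference level (first factor level; for smoking the reference is
#' "never"). The fitted probabilities are the propensity scores used for
#' 1:1 matching.
#'
#' @param clinical Clinical covariate table (one row per patient) with a
#'   `sex` column in `{M, F}`.
#' @param covariates Character vector of covariate column names.
#' @return List of class `propensity_fit`: `scores` (named by patient_id),
#'   `coefficients`, `separation` flag, and the model frame used.
#' @export
fit_propensity <- function(clinical,
                           covariates = c("age", "bmi", "cabg", "diabetes",
                                          "smoking", "ckd")) {
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov) > 0)
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  if (sum(clinical$sex == "M") < 2 || sum(clinical$sex == "F") < 2)
    stop("need at least 2 patients per sex")
  df <- clinical[, covariates, drop = FALSE]
  df$.male <- as.numeric(clinical$sex == "M")
  form <- stats::as.formula(paste(".male ~", paste(covariates, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  scores <- stats::fitted(fit)
  # A score pinned to 0/1 means a covariate separates the sexes perfectly;
  # scores are still returned (matching remains defined) but flagged.
  if (any(scores < 1e-8 | scores > 1 - 1e-8)) separation <- TRUE
  if (separation)
    warning("possible separation in the propensity model; scores may be degenerate")
  structure(list(scores = stats::setNames(scores, clinical$patient_id),
                 coefficients = stats::coef(fit),
                 separation = separation,
                 sex = stats::setNames(clinical$sex, clinical$patient_id)),
            class = "propensity_fit")
}

#' Greedy 1:1 propensity matching without replacement
#'
#' Males are processed in descending propensity score order; each is paired
#' with the unmatched female whose score is nearest, provided the distance
#' does not exceed the caliper. The seed only breaks exact score ties;
#' otherwise the procedure is deterministic.
#'
#' @param fit A `propensity_fit`, or a named numeric score vector combined
#'   with `sex` (named vector of "M"/"F").
#' @param caliper Maximum allowed |score_m - score_f|. Default is 0.2 times
#'   the SD of the logit scores (a common matching heuristic).
#' @param seed Seed used only to break exact ties.
#' @param sex Optional named sex vector when `fit` is a raw score vector.
#' @return List of class `match_result`: `pairs` (data.frame male, female,
#'   distance), `unmatched`, `caliper`, `scores`.
#' @export
greedy_match <- function(fit, caliper = NULL, seed = 1L, sex = NULL) {
  if (inherits(fit, "propensity_fit")) {
    scores <- fit$scores
    sex <- fit$sex
  } else {
    scores <- fit
    if (is.null(sex)) stop("sex vector required with raw scores")
  }
  if (is.null(caliper)) {
    lg <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
    caliper <- 0.2 * stats::sd(lg)
    if (!is.finite(caliper)) caliper <- Inf
  }
  males <- names(scores)[sex[names(scores)] == "M"]
  females <- names(scores)[sex[names(scores)] == "F"]
  pairs <- data.frame(male = character(0), female = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  with_seed(seed, {
    # random keys decide order among exactly tied scores
    tie_m <- stats::setNames(stats::runif(length(males)), males)
    tie_f <- stats::setNames(stats::runif(length(females)), females)
    males <- males[order(-scores[males], tie_m[males])]
    avail <- females
    for (m in males) {
      if (length(avail) == 0) break
      d <- abs(scores[avail] - scores[m])
      eligible <- d <= caliper + 1e-15
      if (!any(eligible)) next
      dmin <- min(d[eligible])
      cand <- avail[eligible & d <= dmin + 1e-15]
      f <- if (length(cand) == 1) cand else cand[which.min(tie_f[cand])]
      pairs <- rbind(pairs, data.frame(male = m, female = f,
                                       distance = abs(scores[f] - scores[m]),
                                       stringsAsFactors = FALSE))
      avail <- setdiff(avail, f)
    }
  })
  matched <- c(pairs$male, pairs$female)
  structure(list(pairs = pairs,
                 unmatched = setdiff(c(males, females), matched),
                 caliper = caliper, scores = scores),
            class = "match_result")
}

#' Standardized difference between two group summaries
#'
#' Scale-free balance diagnostic used to judge whether matching worked.
#' Continuous: |m_a - m_b| / sqrt((s_a^2 + s_b^2) / 2). Binary:
#' |p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2). Multicategory
#' (K levels): the Mahalanobis form sqrt(T' S^-1 T), where T is the
#' difference of the first K-1 category proportions and S the average of the
#' two multinomial covariance matrices.
#'
#' @param summary_a,summary_b For `kind = "continuous"`: `c(mean, sd)`. For
#'   `"binary"`: a single proportion. For `"multicategory"`: a proportion
#'   vector over the K categories (summing to 1).
#' @param kind One of "continuous", "binary", "multicategory".
#' @return Absolute standardized difference (>= 0).
#' @export
standardized_difference <- function(summary_a, summary_b,
                                    kind = c("continuous", "binary",
                                             "multicategory")) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    stopifnot(length(summary_a) == 2, length(summary_b) == 2)
    num <- abs(summary_a[1] - summary_b[1])
    den <- sqrt((summary_a[2]^2 + summary_b[2]^2) / 2)
    if (den == 0) {
      if (num == 0) return(0)
      stop("zero pooled SD with non-zero mean difference")
    }
    return(unname(num / den))
  }
  if (kind == "binary") {
    pa <- summary_a[1]; pb <- summary_b[1]
    stopifnot(pa >= 0, pa <= 1, pb >= 0, pb <= 1)
    num <- abs(pa - pb)
    den <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
    if (den == 0) {
      if (num == 0) return(0)
      stop("degenerate proportions with non-zero difference")
    }
    return(unname(num / den))
  }
  # multicategory
  pa <- summary_a; pb <- summary_b
  stopifnot(length(pa) == length(pb), length(pa) >= 2)
  K <- length(pa)
  Ta <- pa[-K]; Tb <- pb[-K]
  Tdiff <- Ta - Tb
  covmat <- function(p) diag(p, nrow = K - 1) - tcrossprod(p)
  S <- (covmat(Ta) + covmat(Tb)) / 2
  if (all(abs(Tdiff) < 1e-14)) return(0)
  if (abs(det(S)) > 1e-12) return(unname(sqrt(drop(t(Tdiff) %*% solve(S, Tdiff)))))
  # Singular S (e.g. a category empty in both groups): Moore-Penrose
  # pseudo-inverse restricts the quadratic form to the range of S, which
  # reduces to the binary formula when only two categories are occupied.
  Sp <- MASS::ginv(S)
  resid <- Tdiff - S %*% (Sp %*% Tdiff)
  if (any(abs(resid) > 1e-10))
    stop("degenerate covariance in multicategory d with difference outside its range")
  unname(sqrt(drop(t(Tdiff) %*% Sp %*% Tdiff)))
}

#' Balance table on the matched cohort
#'
#' One row per covariate, computed on matched patients only: group summaries
#' by sex plus the standardized difference. Continuous, binary and
#' multicategory covariates are detected from the data (factors with more
#' than 2 levels are multicategory; 0/1 or two-level columns are binary).
#'
#' @param clinical Clinical covariate table.
#' @param match A `match_result` from [greedy_match()], or NULL to use all
#'   patients.
#' @param covariates Covariate names to tabulate.
#' @return data.frame of class `balance_table` with columns covariate, kind,
#'   summary_male, summary_female, std_diff.
#' @export
balance_table <- function(clinical, match = NULL,
                          covariates = c("age", "bmi", "cabg", "diabetes",
                                         "smoking", "ckd")) {
  if (!is.null(match)) {
    keep <- c(match$pairs$male, match$pairs$female)
    clinical <- clinical[clinical$patient_id %in% keep, , drop = FALSE]
  }
  male <- clinical[clinical$sex == "M", , drop = FALSE]
  female <- clinical[clinical$sex == "F", , drop = FALSE]
  rows <- lapply(covariates, function(cv) {
    x_m <- male[[cv]]; x_f <- female[[cv]]
    if (is.numeric(x_m) && length(unique(c(x_m, x_f))) > 2) {
      d <- standardized_difference(c(mean(x_m), stats::sd(x_m)),
                                   c(mean(x_f), stats::sd(x_f)), "continuous")
      data.frame(covariate = cv, kind = "continuous",
                 summary_male = sprintf("%.2f ± %.2f", mean(x_m), stats::sd(x_m)),
                 summary_female = sprintf("%.2f ± %.2f", mean(x_f), stats::sd(x_f)),
                 std_diff = d, stringsAsFactors = FALSE)
    } else if (is.factor(x_m) && nlevels(x_m) > 2) {
      p_m <- as.numeric(table(x_m) / length(x_m))
      p_f <- as.numeric(table(factor(x_f, levels(x_m))) / length(x_f))
      d <- standardized_difference(p_m, p_f, "multicategory")
      data.frame(covariate = cv, kind = "multicategory",
                 summary_male = paste(sprintf("%.2f", p_m), collapse = "/"),
                 summary_female = paste(sprintf("%.2f", p_f), collapse = "/"),
                 std_diff = d, stringsAsFactors = FALSE)
    } else {
      p_m <- mean(as.numeric(x_m) == max(as.numeric(c(x_m, x_f))))
      p_f <- mean(as.numeric(x_f) == max(as.numeric(c(x_m, x_f))))
      d <- standardized_difference(p_m, p_f, "binary")
      data.frame(covariate = cv, kind = "binary",
                 summary_male = sprintf("%.2f", p_m),
                 summary_female = sprintf("%.2f", p_f),
                 std_diff = d, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("balance_table", class(out))
  out
}
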