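#' Derive a child seed from a global seed
#'
#' A single pipeline seed is fanned out to per-stage child seeds by a counter
#' scheme so that adding a stage never perturbs the random stream of earlier
#' stages. Children stay below 2^31 (R integers are 32-bit).
#'
#' @param seed Integer global seed.
#' @param index Stage counter (non-negative integer).
#' @return An integer seed.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.double(seed)) %% m)
  as.integer((s * 48271 + 12345 * (as.double(index) + 1)) %% m)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: order p-values increasingly,
#' compute p * m / rank, and enforce monotonicity from the largest rank down.
#' Used by every differential-expression stage, over exactly the genes tested
#' at that stage.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  o <- order(p, na.last = TRUE)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels Logical or 0/1 vector of true labels.
#' @return AUC in `[0, 1]`, or NA if only one class is present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Staircase from (0, 0) to (1, 1): thresholds swept from the largest score
#' down, tied scores collapsed into a single step.
#'
#' @inheritParams auc_score
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[keep]
  fp <- cumsum(!l)[keep]
  data.frame(fpr = c(0, fp / max(sum(!labels), 1)),
             tpr = c(0, tp / max(sum(labels), 1)))
}

# Internal: run expr with a temporary RNG state seeded at `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

TISSUE_LEVELS <- c("nondiseased", "intermediate", "calcified")

# Ordinal disease-degree encoding used throughout: nondiseased 0,
# intermediate 0.5, calcified 1.
tissue_score_of <- function(tissue) {
  idx <- match(tissue, TISSUE_LEVELS)
  if (anyNA(idx)) stop("unknown tissue grade: ",
                       paste(unique(tissue[is.na(idx)]), collapse = ", "))
  c(0, 0.5, 1)[idx]
}
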