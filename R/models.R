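# The six-classifier prediction bench. Each model spec is a small S3 object
# with fit / prob functions sharing one interface, so cross-validation code
# never special-cases a learner. "Default hyperparameters" are pinned here
# (not taken from any library's moving defaults) so results are reproducible
# across library versions: forest 100 trees, kNN k = 5, GBT 100 rounds of
# depth 3 at rate 0.1, feedforward net one hidden layer of 64 with early
# stopping.

model_spec <- function(name, fit, prob) {
  structure(list(name = name, fit = fit, prob = prob), class = "model_spec")
}

#' Model specifications for the prediction bench
#'
#' Returns the pinned model specs: logistic regression, k-nearest
#' neighbour, Gaussian naive Bayes, gradient boosted trees, random forest,
#' and a small feedforward ("deep learning") network. Logistic regression
#' is deliberately left unregularised beyond base glm behaviour: with many
#' more genes than samples its failure is part of the comparison, not a bug
#' to be fixed.
#'
#' @param which Character vector of model names to return; default all six.
#' @param seed Base seed passed to the stochastic learners.
#' @return Named list of `model_spec` objects.
#' @export
model_bench <- function(which = c("logistic", "knn", "naive_bayes", "gbt",
                                  "random_forest", "deep_net"),
                        seed = 1L) {
  specs <- list(
    logistic = model_spec(
      "logistic",
      fit = function(x, y) {
        x <- as_feature_matrix(x)
        suppressWarnings(
          stats::glm.fit(cbind(`(Intercept)` = 1, x), as_binary_label(y),
                         family = stats::binomial()))
      },
      prob = function(fit, x) {
        b <- fit$coefficients
        b[is.na(b)] <- 0
        stats::plogis(drop(cbind(1, as_feature_matrix(x)) %*% b))
      }),
    knn = model_spec(
      "knn",
      fit = function(x, y) list(x = as_feature_matrix(x),
                                y = as_binary_label(y), k = 5L),
      prob = function(fit, x) {
        k <- min(fit$k, nrow(fit$x))
        pred <- FNN::knn(fit$x, as_feature_matrix(x),
                         cl = factor(fit$y, levels = c(0, 1)), k = k,
                         prob = TRUE)
        win <- attr(pred, "prob")
        ifelse(pred == "1", win, 1 - win)
      }),
    naive_bayes = model_spec("naive_bayes", fit = nb_fit, prob = nb_prob),
    gbt = model_spec(
      "gbt",
      fit = function(x, y) gradient_boosted_trees(x, y, seed = seed),
      prob = function(fit, x) predict(fit, x, type = "prob")),
    random_forest = model_spec(
      "random_forest",
      fit = function(x, y) random_forest(x, y, seed = seed),
      prob = function(fit, x) predict(fit, x, type = "prob")),
    deep_net = model_spec(
      "deep_net",
      fit = function(x, y) mlp_fit(x, y, seed = seed),
      prob = mlp_prob)
  )
  specs[match.arg(which, names(specs), several.ok = TRUE)]
}

# Gaussian naive Bayes with variance smoothing (1e-9 of the largest feature
# variance), matching common practice for continuous features.
nb_fit <- function(x, y) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  eps <- 1e-9 * max(apply(x, 2, stats::var), 1e-12)
  stat <- function(cls) {
    xs <- x[y == cls, , drop = FALSE]
    list(mean = colMeans(xs),
         var = apply(xs, 2, stats::var) + eps,
         prior = nrow(xs) / nrow(x))
  }
  list(c0 = stat(0), c1 = stat(1))
}

nb_prob <- function(fit, x) {
  x <- as_feature_matrix(x)
  loglik <- function(s) {
    v <- pmax(s$var, 1e-12)
    ll <- -0.5 * sweep(sweep(x, 2, s$mean)^2, 2, v, "/") -
      0.5 * matrix(log(2 * pi * v), nrow(x), ncol(x), byrow = TRUE)
    rowSums(ll) + log(s$prior)
  }
  l0 <- loglik(fit$c0)
  l1 <- loglik(fit$c1)
  1 / (1 + exp(pmin(pmax(l0 - l1, -700), 700)))
}

# Minimal feedforward network: one ReLU hidden layer (64 units), sigmoid
# output, full-batch Adam on the cross-entropy, inputs standardised to the
# training moments, early stopping on loss plateau.
mlp_fit <- function(x, y, hidden = 64L, lr = 0.01, max_epochs = 400L,
                    patience = 30L, seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  p <- ncol(xs); n <- nrow(xs)
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * hidden, 0, 1 / sqrt(max(p, 1))), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1)
    b2 <- 0
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    mstate <- lapply(params, function(p) p * 0)
    vstate <- lapply(params, function(p) p * 0)
    best_loss <- Inf; stall <- 0L; tstep <- 0
    beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
    for (epoch in seq_len(max_epochs)) {
      h <- pmax(xs %*% params$W1 +
                  matrix(params$b1, n, hidden, byrow = TRUE), 0)
      z <- drop(h %*% params$W2) + params$b2
      prob <- stats::plogis(z)
      loss <- -mean(y * log(pmax(prob, 1e-12)) +
                      (1 - y) * log(pmax(1 - prob, 1e-12)))
      if (loss < best_loss - 1e-5) { best_loss <- loss; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= patience || loss < 1e-4) break
      dz <- cbind((prob - y) / n)
      dh <- (dz %*% t(params$W2)) * (h > 0)
      grads <- list(
        W1 = t(xs) %*% dh,
        b1 = colSums(dh),
        W2 = t(h) %*% dz,
        b2 = sum(dz))
      tstep <- tstep + 1
      for (nm in names(params)) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mstate[[nm]] / (1 - beta1^tstep)
        vhat <- vstate[[nm]] / (1 - beta2^tstep)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
      }
    }
    list(params = params, mu = mu, sd = sdv, hidden = hidden)
  })
}

mlp_prob <- function(fit, x) {
  x <- as_feature_matrix(x)
  xs <- sweep(sweep(x, 2, fit$mu), 2, fit$sd, "/")
  h <- pmax(xs %*% fit$params$W1 +
              matrix(fit$params$b1, nrow(xs), fit$hidden, byrow = TRUE), 0)
  stats::plogis(drop(h %*% fit$params$W2) + fit$params$b2)
}
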