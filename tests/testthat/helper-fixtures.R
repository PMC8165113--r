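# Shared fixtures and independent oracles. Everything is generated in code;
# nothing is read from disk except the tiny hand-written TSV fixtures under
# the test directory.

# Small cohort with strong planted structure, used by several suites.
tiny_cohort <- function(n_pool = 8, n_genes = 300, noise_sd = 0.3,
                        effect = 2, seed = 11) {
  per_role <- max(1L, n_genes %/% 30L)
  per_chrom <- n_genes %/% 60L
  cfg <- sim_config(n_pool_per_sex = n_pool, n_pairs_target = n_pool,
                    n_genes = n_genes, n_sex_genes = per_role,
                    n_cal_genes = per_role,
                    n_interaction_genes = per_role, n_sexcal_genes = per_role,
                    n_x_genes = per_chrom, n_y_genes = per_chrom,
                    effect_sex = effect,
                    effect_cal = effect, effect_interaction = effect,
                    noise_sd = noise_sd, seed = seed)
  clinical <- simulate_clinical(cfg, seed = seed)
  sim <- simulate_expression(clinical, cfg, seed = seed + 1)
  list(cfg = cfg, clinical = clinical, expr = sim$expr, truth = sim$truth)
}

# Pair every male with the same-index female (bypasses propensity matching
# where the matching itself is not under test).
index_pairs <- function(clinical) {
  m <- clinical$patient_id[clinical$sex == "M"]
  f <- clinical$patient_id[clinical$sex == "F"]
  k <- min(length(m), length(f))
  structure(list(pairs = data.frame(male = m[seq_len(k)],
                                    female = f[seq_len(k)],
                                    stringsAsFactors = FALSE)),
            class = "match_result")
}

# Brute-force BH step-up oracle, written independently of bh_adjust():
# literal textbook procedure with an explicit loop.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Gini impurity of a 0/1 label vector.
gini_of <- function(y) {
  if (length(y) == 0) return(0)
  p <- mean(y)
  2 * p * (1 - p)
}

# Brute-force recomputation of per-feature improvement sums for one tree by
# routing the supplied training rows through the stored node table and
# recomputing each split's Gini improvement from the data.
tree_importance_oracle <- function(tree, x, y, rows = seq_len(nrow(x))) {
  nd <- tree$nodes
  w <- setNames(numeric(length(tree$features)), tree$features)
  recurse <- function(node, idx) {
    if (nd$feature[node + 1] < 0) return(invisible())
    f <- nd$feature[node + 1] + 1
    thr <- nd$threshold[node + 1]
    go_left <- x[idx, f] <= thr
    yl <- y[idx[go_left]]; yr <- y[idx[!go_left]]
    impr <- gini_of(y[idx]) -
      length(yl) / length(idx) * gini_of(yl) -
      length(yr) / length(idx) * gini_of(yr)
    w[tree$features[f]] <<- w[tree$features[f]] + impr
    recurse(nd$left[node + 1], idx[go_left])
    recurse(nd$right[node + 1], idx[!go_left])
  }
  recurse(0, rows)
  w
}

# Feature matrix / labels for calcified-vs-nondiseased classification.
classification_xy <- function(expr, genes = NULL) {
  ss <- as.data.frame(SummarizedExperiment::colData(expr))
  use <- ss$tissue %in% c("calcified", "nondiseased")
  mat <- SummarizedExperiment::assay(expr, "log2")
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  list(x = t(mat[, use, drop = FALSE]),
       y = as.integer(ss$tissue[use] == "calcified"),
       groups = ss$patient_id[use])
}
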