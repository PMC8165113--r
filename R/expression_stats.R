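#' Variance rank filter
#'
#' Retains the genes with the highest sample variance, removing genes with
#' little difference in expression across the groups of interest. Ties are
#' broken deterministically by gene id.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param keep Number of genes to retain (mutually exclusive with
#'   `threshold`).
#' @param threshold Minimum variance to retain.
#' @return Object of the same type as `expr`, with rows subset.
#' @export
variance_rank_filter <- function(expr, keep = NULL, threshold = NULL) {
  mat <- expr_matrix(expr)
  if (nrow(mat) == 0) stop("empty expression matrix")
  v <- apply(mat, 1, stats::var)
  if (!is.null(keep)) {
    if (keep > nrow(mat)) stop("keep exceeds the number of genes")
    o <- order(-v, rownames(mat))
    idx <- sort(o[seq_len(keep)])
  } else if (!is.null(threshold)) {
    idx <- which(v >= threshold)
  } else stop("supply keep or threshold")
  subset_genes(expr, idx)
}

subset_genes <- function(expr, idx) {
  if (is.matrix(expr)) expr[idx, , drop = FALSE] else expr[idx, ]
}

#' Projection-score guided choice of variance threshold
#'
#' For each candidate variance threshold, the genes at or above it are
#' retained, the submatrix is gene-centred and its PCA variance fraction in
#' the first `k` components, alpha = sum of the top-k eigenvalues over the
#' total, is compared with its expectation under within-gene permutation
#' (each retained gene's values independently shuffled across samples,
#' which preserves per-gene variance but destroys between-sample structure):
#' \deqn{score(\tau) = \sqrt{\alpha_{obs}(\tau)} - mean_{perm} \sqrt{\alpha_{perm}(\tau)}}
#' The chosen threshold maximizes the score; on pure noise the score is
#' close to 0 for every threshold.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param k_components Number of leading components (default 2, matching
#'   2-D PCA visualisation).
#' @param threshold_grid Candidate variance thresholds; default: variance
#'   quantiles 0, 0.1, ..., 0.9 of the gene variances.
#' @param n_perm Permutations per threshold (>= 1).
#' @param seed Seed for the permutations.
#' @return List of class `projection_score_result`: data.frame `grid`
#'   (threshold, n_retained, alpha_obs, alpha_perm_mean, score), chosen
#'   `threshold`, and the filtered matrix indices `retained`.
#' @export
projection_score_optimize <- function(expr, k_components = 2,
                                      threshold_grid = NULL, n_perm = 20,
                                      seed = 1L) {
  mat <- expr_matrix(expr)
  if (n_perm < 1) stop("n_perm must be >= 1")
  v <- apply(mat, 1, stats::var)
  if (is.null(threshold_grid))
    threshold_grid <- unname(stats::quantile(v, seq(0, 0.9, by = 0.1)))
  if (length(threshold_grid) == 0) stop("empty threshold grid")

  alpha_of <- function(m, k) {
    mc <- m - rowMeans(m)
    d2 <- svd(mc, nu = 0, nv = 0)$d^2
    k <- min(k, length(d2))
    sum(d2[seq_len(k)]) / sum(d2)
  }

  rows <- with_seed(seed, {
    lapply(threshold_grid, function(tau) {
      idx <- which(v >= tau)
      if (length(idx) < 1 || ncol(mat) < 2) {
        warning("threshold ", signif(tau, 4), " leaves a degenerate submatrix; skipped")
        return(NULL)
      }
      sub <- mat[idx, , drop = FALSE]
      a_obs <- alpha_of(sub, k_components)
      a_perm <- vapply(seq_len(n_perm), function(b) {
        perm <- t(apply(sub, 1, sample))
        alpha_of(perm, k_components)
      }, numeric(1))
      data.frame(threshold = tau, n_retained = length(idx),
                 alpha_obs = a_obs, alpha_perm_mean = mean(a_perm),
                 score = sqrt(a_obs) - mean(sqrt(a_perm)))
    })
  })
  grid <- do.call(rbind, rows)
  if (is.null(grid) || nrow(grid) == 0) stop("no usable threshold in grid")
  best <- which.max(grid$score)
  structure(list(grid = grid, threshold = grid$threshold[best],
                 retained = which(v >= grid$threshold[best])),
            class = "projection_score_result")
}

#' PCA embedding of samples
#'
#' Gene-centred principal component analysis; sample coordinates are
#' reproducible up to component sign.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param k Number of components.
#' @return List of class `pca_result`: `coordinates` (samples x k),
#'   `variance_fraction` (length k, non-increasing).
#' @export
pca_embed <- function(expr, k = 2) {
  mat <- expr_matrix(expr)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  if (k > min(dim(mat))) stop("k exceeds matrix dimensions")
  mc <- mat - rowMeans(mat)
  sv <- svd(mc, nu = 0, nv = k)
  lambda <- sv$d^2
  coords <- sv$v * rep(sv$d[seq_len(k)], each = ncol(mat))
  rownames(coords) <- colnames(mat)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 variance_fraction = lambda[seq_len(k)] / sum(lambda)),
            class = "pca_result")
}

#' Paired differential expression between tissue grades
#'
#' Tissue comparisons are repeated measures (samples come from the same
#' valve), so each gene is tested with a paired t-test across patients on
#' within-patient differences, with Benjamini-Hochberg adjustment over all
#' tested genes. Delta is the mean within-patient log2 difference and
#' FC = 2^Delta the linear fold change.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param samples Sample sheet when `expr` is a matrix.
#' @param contrast Character pair `c(numerator, denominator)` of tissue
#'   grades; default calcified vs nondiseased.
#' @return data.frame of class `de_result` with columns gene_id,
#'   delta_log2, fc, t, p, q; attribute `n_patients`.
#' @export
paired_de <- function(expr, samples = NULL,
                      contrast = c("calcified", "nondiseased")) {
  mat <- expr_matrix(expr)
  ss <- expr_samples(expr, samples)
  pats <- unique(ss$patient_id)
  c1 <- vapply(pats, function(p)
    which(ss$patient_id == p & ss$tissue == contrast[1])[1] %||% NA_integer_,
    integer(1))
  c2 <- vapply(pats, function(p)
    which(ss$patient_id == p & ss$tissue == contrast[2])[1] %||% NA_integer_,
    integer(1))
  ok <- !is.na(c1) & !is.na(c2)
  if (sum(ok) < 2) stop("need at least 2 patients with both tissue samples")
  D <- mat[, c1[ok], drop = FALSE] - mat[, c2[ok], drop = FALSE]
  n <- ncol(D)
  delta <- rowMeans(D)
  sdd <- sqrt(rowSums((D - delta)^2) / (n - 1))
  tstat <- delta / (sdd / sqrt(n))
  tstat[sdd == 0 & delta == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[sdd == 0 & delta == 0] <- 1
  de_result(rownames(mat), delta, tstat, p, n_patients = n)
}

de_result <- function(gene_id, delta, tstat, p, ...) {
  out <- data.frame(gene_id = gene_id, delta_log2 = delta, fc = 2^delta,
                    t = tstat, p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  extras <- list(...)
  for (nm in names(extras)) attr(out, nm) <- extras[[nm]]
  class(out) <- c("de_result", class(out))
  out
}

#' Sex differential expression adjusted for tissue grade
#'
#' Removes the tissue-grade effect by centring each gene within each tissue
#' grade, then compares male and female samples with a two-sample t-test on
#' the residuals (pooled variance by default; Welch available). Delta is the
#' male minus female mean residual difference. All samples of a patient are
#' treated as independent observations, mirroring a three-samples-per-valve
#' design analysed at the sample level; `average_patients = TRUE` collapses
#' to one residual mean per patient first.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param samples Sample sheet when `expr` is a matrix.
#' @param welch Use Welch's unequal-variance t-test instead of pooled.
#' @param average_patients Average residuals within patient before testing.
#' @return A `de_result` data.frame (delta_log2 = male - female).
#' @export
sex_de_adjusted <- function(expr, samples = NULL, welch = FALSE,
                            average_patients = FALSE) {
  mat <- expr_matrix(expr)
  ss <- expr_samples(expr, samples)
  for (tt in unique(ss$tissue)) {
    idx <- ss$tissue == tt
    if (length(unique(ss$sex[idx])) < 2)
      stop("tissue grade ", tt, " has samples from one sex only")
    mat[, idx] <- mat[, idx, drop = FALSE] -
      rowMeans(mat[, idx, drop = FALSE])
  }
  if (average_patients) {
    pats <- unique(ss$patient_id)
    mat <- vapply(pats, function(p)
      rowMeans(mat[, ss$patient_id == p, drop = FALSE]), numeric(nrow(mat)))
    sex <- vapply(pats, function(p) ss$sex[ss$patient_id == p][1], character(1))
  } else {
    sex <- ss$sex
  }
  m <- mat[, sex == "M", drop = FALSE]
  f <- mat[, sex == "F", drop = FALSE]
  n1 <- ncol(m); n2 <- ncol(f)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per sex")
  m1 <- rowMeans(m); m2 <- rowMeans(f)
  v1 <- rowSums((m - m1)^2) / (n1 - 1)
  v2 <- rowSums((f - m2)^2) / (n2 - 1)
  delta <- m1 - m2
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(delta))
  }
  tstat <- delta / se
  zero <- se == 0 & delta == 0
  tstat[zero] <- 0
  df[!is.finite(df)] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[zero] <- 1
  de_result(rownames(mat), delta, tstat, p, n_male = n1, n_female = n2)
}

#' Fold-change filter
#'
#' Removes genes with linear fold change strictly inside (low, high); the
#' conventional band 0.8 < FC < 1.2 is the default, so FC exactly 0.8 or
#' 1.2 is retained. FC is 2^Delta with Delta the mean log2 difference.
#'
#' @param de A `de_result`.
#' @param low,high Open-interval bounds on FC.
#' @return Character vector of retained gene ids.
#' @export
fc_filter <- function(de, low = 0.8, high = 1.2) {
  if (low >= high) stop("low must be < high")
  de$gene_id[de$fc <= low | de$fc >= high]
}

#' Two-stage selection of sex-differential genes
#'
#' Stage 1 excludes genes not differentially expressed between calcified and
#' nondiseased tissue: keep q < `q_cut` in the paired tissue test and
#' outside the fold-change band (both criteria by default; either can be
#' switched off). Stage 2 tests the survivors for a sex difference adjusted
#' for tissue grade and keeps q < `q_cut` again, with BH applied within each
#' stage over exactly the genes tested at that stage.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param samples Sample sheet when `expr` is a matrix.
#' @param q_cut Significance cutoff on BH q (default 0.05).
#' @param fc_low,fc_high Fold-change band removed at stage 1.
#' @param use_q,use_fc Toggle the two stage-1 criteria.
#' @param welch Passed to [sex_de_adjusted()].
#' @return List of class `sex_de_selection`: `genes` (stage-2 survivors),
#'   `stage1` and `stage2` `de_result`s, `stage1_genes`.
#' @export
select_sex_de_genes <- function(expr, samples = NULL, q_cut = 0.05,
                                fc_low = 0.8, fc_high = 1.2, use_q = TRUE,
                                use_fc = TRUE, welch = FALSE) {
  de1 <- paired_de(expr, samples)
  keep <- rep(TRUE, nrow(de1))
  if (use_q) keep <- keep & de1$q < q_cut
  if (use_fc) keep <- keep & de1$gene_id %in% fc_filter(de1, fc_low, fc_high)
  stage1_genes <- de1$gene_id[keep]
  if (length(stage1_genes) == 0) {
    out <- list(genes = character(0), stage1 = de1, stage2 = NULL,
                stage1_genes = stage1_genes)
    class(out) <- "sex_de_selection"
    return(out)
  }
  idx <- match(stage1_genes, rownames(expr_matrix(expr)))
  de2 <- sex_de_adjusted(subset_genes(expr, idx),
                         samples = expr_samples(expr, samples),
                         welch = welch)
  out <- list(genes = de2$gene_id[de2$q < q_cut], stage1 = de1, stage2 = de2,
              stage1_genes = stage1_genes)
  class(out) <- "sex_de_selection"
  out
}

#' Hierarchical clustering leaf orders
#'
#' Average-linkage agglomerative clustering of genes and of samples under
#' correlation distance (1 - Pearson r). Constant items, whose correlation
#' is undefined, are treated as maximally distant (distance 2) with a
#' warning.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param linkage Agglomeration method (default "average").
#' @return List with `gene_order`, `sample_order` (leaf orders), and the
#'   two `hclust` objects.
#' @export
hclust_order <- function(expr, linkage = "average") {
  mat <- expr_matrix(expr)
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need at least 2 genes and 2 samples")
  cor_dist <- function(m) {
    # cor() warns "sd is zero" on constant rows; we detect and report the
    # condition ourselves
    d <- 1 - suppressWarnings(stats::cor(t(m)))
    if (anyNA(d)) {
      warning("constant items treated as maximally distant in clustering")
      d[is.na(d)] <- 2
    }
    diag(d) <- 0
    stats::as.dist(d)
  }
  hg <- stats::hclust(cor_dist(mat), method = linkage)
  hs <- stats::hclust(cor_dist(t(mat)), method = linkage)
  list(gene_order = rownames(mat)[hg$order],
       sample_order = colnames(mat)[hs$order],
       gene_hclust = hg, sample_hclust = hs)
}
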