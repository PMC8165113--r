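#' Simulation configuration for a synthetic matched valve cohort
#'
#' Describes the stated world the generator emulates: a pool of male and
#' female surgical patients (default 18 matched pairs), three valve tissue
#' samples per patient graded nondiseased / intermediate / calcified, and a
#' log2 expression matrix with planted sex effects, calcification effects,
#' sex-by-calcification interactions, X-inactivation-escape-like genes
#' (elevated in females, XIST-like) and Y-linked genes (background level in
#' females).
#'
#' The generative model for gene g in sample (patient i, tissue t) is
#' \deqn{x = \mu_g + \alpha_g 1[male] + \beta_g t + \gamma_g 1[male] t + u_i + \epsilon}
#' with ordinal tissue score t = 0, 0.5, 1 for nondiseased, intermediate,
#' calcified; patient intercept u_i ~ N(0, patient_sd^2) (default 0); and
#' i.i.d. Gaussian noise on the log2 scale.
#'
#' @param n_pool_per_sex Patients of each sex in the pre-matching pool.
#' @param n_pairs_target Matched pairs aimed for downstream (default 18).
#' @param n_genes Total genes simulated.
#' @param n_sex_genes,n_cal_genes,n_interaction_genes Counts of genes with a
#'   planted sex main effect, calcification main effect, and
#'   sex-by-calcification interaction.
#' @param n_sexcal_genes Genes carrying both a sex main effect and a
#'   calcification main effect (XIST-like sex-differential calcification
#'   markers; these are what two-stage selection retains and what makes
#'   calcification predictable from sex-differential genes in both sexes).
#' @param n_x_genes,n_y_genes Counts of X-escape-like and Y-linked genes.
#' @param effect_sex,effect_cal,effect_interaction Planted effect sizes, in
#'   log2 units (signs alternate across genes for the autosomal effects).
#' @param noise_sd Residual SD on the log2 scale.
#' @param patient_sd SD of the per-patient random intercept (default 0;
#'   positive values exercise the repeated-measures pairing).
#' @param y_background Baseline log2 level of Y-linked genes in females.
#' @param covariate_params Per-covariate distribution parameters; see
#'   defaults. Continuous covariates take `mean` and `sd` (each a scalar or a
#'   length-2 `c(M=, F=)` vector, allowing sex imbalance so propensity
#'   matching is non-trivially exercised); binary covariates take `p`
#'   likewise; smoking takes a 3-probability vector (never, former, current)
#'   per sex.
#' @param seed Default seed carried in the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pool_per_sex = 18, n_pairs_target = 18,
                       n_genes = 2000, n_sex_genes = 50, n_cal_genes = 50,
                       n_interaction_genes = 50, n_sexcal_genes = 0,
                       n_x_genes = 20,
                       n_y_genes = 20, effect_sex = 1, effect_cal = 1,
                       effect_interaction = 1, noise_sd = 0.5,
                       patient_sd = 0, y_background = 4,
                       covariate_params = NULL, seed = 1L) {
  default_cov <- list(
    age      = list(mean = 75, sd = 5.5),
    bmi      = list(mean = 29.2, sd = 5.1),
    cabg     = list(p = c(M = 0.50, F = 0.28)),
    diabetes = list(p = c(M = 0.22, F = 0.11)),
    ckd      = list(p = 0.25),
    smoking  = list(p_m = c(0.39, 0.61, 0.00), p_f = c(0.47, 0.47, 0.06))
  )
  cov <- default_cov
  if (!is.null(covariate_params)) cov[names(covariate_params)] <- covariate_params

  cfg <- list(n_pool_per_sex = n_pool_per_sex, n_pairs_target = n_pairs_target,
              n_genes = n_genes, n_sex_genes = n_sex_genes,
              n_cal_genes = n_cal_genes,
              n_interaction_genes = n_interaction_genes,
              n_sexcal_genes = n_sexcal_genes,
              n_x_genes = n_x_genes, n_y_genes = n_y_genes,
              effect_sex = effect_sex, effect_cal = effect_cal,
              effect_interaction = effect_interaction, noise_sd = noise_sd,
              patient_sd = patient_sd, y_background = y_background,
              covariate_params = cov, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- unlist(cfg[c("n_pool_per_sex", "n_pairs_target", "n_genes",
                         "n_sex_genes", "n_cal_genes", "n_interaction_genes",
                         "n_sexcal_genes", "n_x_genes", "n_y_genes")])
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("configuration error: counts must be non-negative integers")
  planted <- cfg$n_sex_genes + cfg$n_cal_genes + cfg$n_interaction_genes +
    cfg$n_sexcal_genes + cfg$n_x_genes + cfg$n_y_genes
  if (planted > cfg$n_genes)
    stop("configuration error: planted gene counts exceed n_genes")
  if (cfg$noise_sd < 0 || cfg$patient_sd < 0)
    stop("configuration error: noise SDs must be >= 0")
  probs <- c(cfg$covariate_params$cabg$p, cfg$covariate_params$diabetes$p,
             cfg$covariate_params$ckd$p, cfg$covariate_params$smoking$p_m,
             cfg$covariate_params$smoking$p_f)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (any(c(cfg$covariate_params$age$sd, cfg$covariate_params$bmi$sd) < 0))
    stop("configuration error: covariate SDs must be >= 0")
  invisible(cfg)
}

sexed_param <- function(x, sex) {
  if (length(x) == 1) return(rep(x, length(sex)))
  unname(x[sex])
}

#' Simulate a clinical covariate table
#'
#' Draws one row per patient in the pool, with the matching covariates used
#' in the study design: age, BMI, concomitant CABG, diabetes, smoking
#' (never / former / current) and chronic kidney disease. Covariate
#' distributions may differ by sex (see [sim_config()]), which is what makes
#' propensity matching do real work downstream.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) gives identical tables.
#' @return data.frame with columns patient_id, sex, age, bmi, cabg,
#'   diabetes, ckd, smoking.
#' @export
simulate_clinical <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_pool_per_sex
  if (n < config$n_pairs_target)
    stop("configuration error: n_pool_per_sex < n_pairs_target")
  cp <- config$covariate_params
  with_seed(seed, {
    sex <- rep(c("M", "F"), each = n)
    id <- c(sprintf("M%03d", seq_len(n)), sprintf("F%03d", seq_len(n)))
    if (n == 0) {
      sex <- character(0); id <- character(0)
    }
    smoking_levels <- c("never", "former", "current")
    draw_smoking <- function(p) {
      if (abs(sum(p) - 1) > 1e-8) stop("configuration error: smoking probabilities must sum to 1")
      smoking_levels[1 + findInterval(runif(1), cumsum(p)[-3])]
    }
    df <- data.frame(
      patient_id = id,
      sex = sex,
      age = rnorm(2 * n, sexed_param(cp$age$mean, sex),
                  sexed_param(cp$age$sd, sex)),
      bmi = rnorm(2 * n, sexed_param(cp$bmi$mean, sex),
                  sexed_param(cp$bmi$sd, sex)),
      cabg = rbinom(2 * n, 1, sexed_param(cp$cabg$p, sex)),
      diabetes = rbinom(2 * n, 1, sexed_param(cp$diabetes$p, sex)),
      ckd = rbinom(2 * n, 1, sexed_param(cp$ckd$p, sex)),
      stringsAsFactors = FALSE
    )
    df$smoking <- vapply(sex, function(s) {
      draw_smoking(if (s == "M") cp$smoking$p_m else cp$smoking$p_f)
    }, character(1), USE.NAMES = FALSE)
    df$smoking <- factor(df$smoking, levels = smoking_levels)
    df
  })
}

#' Simulate an expression matrix with planted truth
#'
#' Emits three tissue samples (nondiseased, intermediate, calcified) per
#' patient and a genes-by-samples log2 matrix drawn from the generative
#' model described in [sim_config()]. Gene roles are planted in blocks:
#' sex main effects, calcification main effects, sex-by-calcification
#' interactions, X-escape-like genes (female-high, on chromosome X), and
#' Y-linked genes (chromosome Y; exactly at `y_background` in females when
#' `noise_sd = 0`). Remaining genes are null.
#'
#' @param clinical A clinical table from [simulate_clinical()] (only
#'   patient_id and sex are used).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `expr`, a [SummarizedExperiment::SummarizedExperiment]
#'   whose `log2` assay is the expression matrix, with sample annotations
#'   (sample_id, patient_id, sex, tissue) in `colData` and gene annotation
#'   (gene_id, symbol, chromosome) in `rowData`; and `truth`, a data.frame
#'   of per-gene roles and coefficients (the planted-truth oracle).
#' @export
simulate_expression <- function(clinical, config, seed = config$seed) {
  validate_sim_config(config)
  if (nrow(clinical) == 0) stop("clinical table is empty")
  G <- config$n_genes
  roles <- rep("null", G)
  i <- 0
  assign_block <- function(role, k) {
    if (k > 0) roles[i + seq_len(k)] <<- role
    i <<- i + k
  }
  assign_block("sex", config$n_sex_genes)
  assign_block("calcification", config$n_cal_genes)
  assign_block("interaction", config$n_interaction_genes)
  assign_block("sex_calcification", config$n_sexcal_genes)
  assign_block("chrX_escape", config$n_x_genes)
  assign_block("chrY", config$n_y_genes)

  alt_sign <- function(k) if (k == 0) numeric(0) else rep_len(c(1, -1), k)
  alpha <- beta <- gamma <- numeric(G)
  alpha[roles == "sex"] <- config$effect_sex * alt_sign(sum(roles == "sex"))
  beta[roles == "calcification"] <-
    config$effect_cal * alt_sign(sum(roles == "calcification"))
  gamma[roles == "interaction"] <-
    config$effect_interaction * alt_sign(sum(roles == "interaction"))
  sc <- roles == "sex_calcification"
  alpha[sc] <- config$effect_sex * alt_sign(sum(sc))
  # calcification consistently up-regulates these markers; keeping beta
  # positive while alpha alternates ensures the four sex-by-tissue groups
  # are jointly separable rather than aliased
  beta[sc] <- abs(config$effect_cal)
  # X-escape genes are female-high (male - female < 0), XIST-like.
  alpha[roles == "chrX_escape"] <- -abs(config$effect_sex)
  # Y-linked genes: background in females, background + shift in males.
  alpha[roles == "chrY"] <- abs(config$effect_sex)

  patients <- clinical$patient_id
  sex <- clinical$sex
  tissues <- TISSUE_LEVELS
  sample_patient <- rep(patients, each = 3)
  sample_sex <- rep(sex, each = 3)
  sample_tissue <- rep(tissues, times = length(patients))
  t_score <- tissue_score_of(sample_tissue)
  male <- as.numeric(sample_sex == "M")
  sample_id <- paste0(sample_patient, "_",
                      c("nd", "im", "ca")[match(sample_tissue, tissues)])

  with_seed(seed, {
    mu <- runif(G, 5, 11)
    mu[roles == "chrY"] <- config$y_background
    chrom <- sample(as.character(1:22), G, replace = TRUE)
    chrom[roles == "chrX_escape"] <- "X"
    chrom[roles == "chrY"] <- "Y"

    signal <- outer(alpha, male) + outer(beta, t_score) +
      outer(gamma, rep(1, length(male))) * outer(rep(1, G), male * t_score)
    u <- rnorm(length(patients), 0, config$patient_sd)
    mat <- mu + signal +
      matrix(rep(u, each = 3), nrow = G, ncol = length(sample_id),
             byrow = TRUE) +
      matrix(rnorm(G * length(sample_id), 0, config$noise_sd), nrow = G)

    gene_id <- sprintf("G%05d", seq_len(G))
    dimnames(mat) <- list(gene_id, sample_id)
    coldata <- S4Vectors::DataFrame(
      sample_id = sample_id, patient_id = sample_patient,
      sex = sample_sex, tissue = sample_tissue, row.names = sample_id)
    rowdata <- S4Vectors::DataFrame(
      gene_id = gene_id, symbol = paste0("SYM", seq_len(G)),
      chromosome = chrom, row.names = gene_id)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2 = mat), colData = coldata, rowData = rowdata)
    truth <- data.frame(gene_id = gene_id, role = roles, alpha = alpha,
                        beta = beta, gamma = gamma, mu = mu,
                        stringsAsFactors = FALSE)
    list(expr = se, truth = truth)
  })
}

#' Expected contrasts implied by the planted truth
#'
#' Closed-form per-gene expectations of the contrasts the pipeline
#' estimates, used as the oracle in recovery tests: the calcified minus
#' nondiseased difference (per sex and cohort mean over a balanced cohort)
#' and the male minus female difference within each tissue grade.
#'
#' @param truth The `truth` data.frame from [simulate_expression()].
#' @return data.frame of per-gene expected log2 differences.
#' @export
truth_contrasts <- function(truth) {
  stopifnot(all(c("alpha", "beta", "gamma") %in% names(truth)))
  data.frame(
    gene_id = truth$gene_id,
    cal_vs_nondis_male = truth$beta + truth$gamma,
    cal_vs_nondis_female = truth$beta,
    cal_vs_nondis_mean = truth$beta + truth$gamma / 2,
    mf_nondiseased = truth$alpha,
    mf_intermediate = truth$alpha + truth$gamma * 0.5,
    mf_calcified = truth$alpha + truth$gamma,
    stringsAsFactors = FALSE
  )
}

# Internal accessors tolerant of both SummarizedExperiment and plain matrix
# + sample sheet inputs.
expr_matrix <- function(expr) {
  if (methods::is(expr, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(expr, "log2"))
  if (is.matrix(expr)) return(expr)
  stop("expr must be a SummarizedExperiment or a matrix")
}

expr_samples <- function(expr, samples = NULL) {
  if (!is.null(samples)) return(as.data.frame(samples))
  if (methods::is(expr, "SummarizedExperiment"))
    return(as.data.frame(SummarizedExperiment::colData(expr)))
  stop("sample annotations required (pass a SummarizedExperiment or samples=)")
}

expr_annotation <- function(expr, annotation = NULL) {
  if (!is.null(annotation)) return(as.data.frame(annotation))
  if (methods::is(expr, "SummarizedExperiment"))
    return(as.data.frame(SummarizedExperiment::rowData(expr)))
  stop("gene annotation required")
}
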