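# File formats: expression TSV (gene_id + one column per sample), sample
# sheet TSV (sample_id, patient_id, sex, tissue), gene annotation TSV
# (gene_id, symbol, chromosome), clinical CSV. All numeric round-trips are
# lossless at 1e-12 (values are written with full precision).

#' @rdname pipeline_io
#' @param expr SummarizedExperiment or matrix.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  mat <- expr_matrix(expr)
  df <- data.frame(gene_id = rownames(mat),
                   signif(mat, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write pipeline files
#'
#' Readers validate the schema: required columns must be present (the error
#' names the missing column), gene and sample ids must be unique, and every
#' expression cell must be numeric (the error gives the gene and sample of
#' the first offender).
#'
#' @name pipeline_io
#' @return Readers return a matrix or data.frame; writers return the path.
NULL

#' @rdname pipeline_io
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression file lacks column: gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  if (anyDuplicated(names(df)[-1])) stop("duplicate sample ids in ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(mat), nrow(mat)))) &
                   !is.na(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at gene ", df$gene_id[bad[1]],
         ", sample ", colnames(mat)[bad[2]])
  }
  rownames(mat) <- df$gene_id
  mat
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(what, " lacks required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' @rdname pipeline_io
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "patient_id", "sex", "tissue"),
                "sample sheet")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(df$tissue %in% TISSUE_LEVELS))
    stop("tissue must be one of: ", paste(TISSUE_LEVELS, collapse = ", "))
  df
}

#' @rdname pipeline_io
#' @param df Data frame to write.
#' @export
write_sample_sheet <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  check_columns(df, c("gene_id", "symbol", "chromosome"), "annotation")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  df
}

#' @rdname pipeline_io
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "sex"), "clinical table")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient ids in ", path)
  if ("smoking" %in% names(df))
    df$smoking <- factor(df$smoking, levels = c("never", "former", "current"))
  df
}

#' @rdname pipeline_io
#' @export
write_clinical <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a SummarizedExperiment from pipeline files
#'
#' @param mat Expression matrix (genes x samples).
#' @param samples Sample sheet data.frame.
#' @param annotation Gene annotation data.frame.
#' @return A SummarizedExperiment with a `log2` assay.
#' @export
make_expression_se <- function(mat, samples, annotation = NULL) {
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx)) stop("sample sheet lacks sample(s): ",
                       paste(colnames(mat)[is.na(idx)], collapse = ", "))
  coldata <- S4Vectors::DataFrame(samples[idx, , drop = FALSE],
                                  row.names = colnames(mat))
  rowdata <- if (!is.null(annotation)) {
    ridx <- match(rownames(mat), annotation$gene_id)
    if (anyNA(ridx)) stop("annotation lacks gene(s)")
    S4Vectors::DataFrame(annotation[ridx, , drop = FALSE],
                         row.names = rownames(mat))
  } else {
    S4Vectors::DataFrame(gene_id = rownames(mat), row.names = rownames(mat))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat), colData = coldata, rowData = rowdata)
}

#' Pipeline configuration
#'
#' Either a [sim_config()] (synthetic mode) or the four input paths
#' (real-data mode) must be supplied.
#'
#' @param sim A [sim_config()], or NULL for real-data mode.
#' @param expression_path,sample_sheet_path,annotation_path,clinical_path
#'   Input files for real-data mode.
#' @param covariates Matching covariates.
#' @param caliper Matching caliper (NULL = 0.2 SD of logit scores).
#' @param concordance_fraction Extreme-quadrant fraction.
#' @param k_components PCA components for the projection score.
#' @param n_perm Projection-score permutations.
#' @param q_cut,fc_low,fc_high Differential-expression thresholds.
#' @param ga A [ga_config()].
#' @param cv A [cv_config()].
#' @param out_dir Output directory (NULL = no files written).
#' @param seed Global seed, fanned out to stage seeds via [child_seed()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, expression_path = NULL,
                            sample_sheet_path = NULL, annotation_path = NULL,
                            clinical_path = NULL,
                            covariates = c("age", "bmi", "cabg", "diabetes",
                                           "smoking", "ckd"),
                            caliper = NULL, concordance_fraction = 0.25,
                            k_components = 2, n_perm = 20, q_cut = 0.05,
                            fc_low = 0.8, fc_high = 1.2, ga = ga_config(),
                            cv = cv_config(), out_dir = NULL, seed = 1L) {
  if (is.null(sim) && (is.null(expression_path) || is.null(sample_sheet_path)
                       || is.null(clinical_path)))
    stop("supply either sim (synthetic mode) or the input paths (real-data mode)")
  structure(list(sim = sim, expression_path = expression_path,
                 sample_sheet_path = sample_sheet_path,
                 annotation_path = annotation_path,
                 clinical_path = clinical_path, covariates = covariates,
                 caliper = caliper,
                 concordance_fraction = concordance_fraction,
                 k_components = k_components, n_perm = n_perm, q_cut = q_cut,
                 fc_low = fc_low, fc_high = fc_high, ga = ga, cv = cv,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_abort <- function(stage, e) {
  stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate/load, propensity matching, concordance scoring,
#' projection-score filtering with PCA, two-stage differential expression,
#' genetic-algorithm feature selection, the six-model classification bench,
#' and the sex-chromosome-only variant. Fully reproducible from (config,
#' seed); each stage draws its randomness from a child seed so adding a
#' stage never perturbs earlier ones. Artifacts are written under
#' `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report` with one entry per executed stage.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list()
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  save_tsv <- function(df, name) {
    if (!is.null(out))
      utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }

  # -- stage: data -----------------------------------------------------
  dat <- tryCatch({
    if (!is.null(config$sim)) {
      clinical <- simulate_clinical(config$sim, seed = child_seed(seed, 1))
      sim <- simulate_expression(clinical, config$sim,
                                 seed = child_seed(seed, 2))
      list(clinical = clinical, expr = sim$expr, truth = sim$truth)
    } else {
      mat <- read_expression(config$expression_path)
      samples <- read_sample_sheet(config$sample_sheet_path)
      ann <- if (!is.null(config$annotation_path))
        read_annotation(config$annotation_path) else NULL
      clinical <- read_clinical(config$clinical_path)
      list(clinical = clinical,
           expr = make_expression_se(mat, samples, ann), truth = NULL)
    }
  }, error = function(e) stage_abort("data", e))
  report$data <- list(n_patients = nrow(dat$clinical),
                      n_genes = nrow(dat$expr),
                      n_samples = ncol(dat$expr))

  # -- stage: matching -------------------------------------------------
  match_res <- tryCatch({
    prop <- fit_propensity(dat$clinical, config$covariates)
    greedy_match(prop, caliper = config$caliper,
                 seed = child_seed(seed, 3))
  }, error = function(e) stage_abort("matching", e))
  bal <- balance_table(dat$clinical, match_res, config$covariates)
  save_tsv(match_res$pairs, "pairs.tsv")
  save_tsv(bal, "balance.tsv")
  report$matching <- list(n_pairs = nrow(match_res$pairs),
                          n_unmatched = length(match_res$unmatched),
                          max_std_diff = max(bal$std_diff),
                          balance = bal)

  # -- stage: concordance ----------------------------------------------
  conc <- tryCatch({
    sc <- score_genes(dat$expr, match_res)
    list(scores = sc,
         quadrants = quadrant_extremes(sc, config$concordance_fraction))
  }, error = function(e) stage_abort("concordance", e))
  save_tsv(conc$scores, "concordance_scores.tsv")
  report$concordance <- list(
    n_pairs = attr(conc$scores, "n_pairs"),
    quadrant_sizes = vapply(conc$quadrants[1:4], length, integer(1)))

  # -- stage: filter / PCA ---------------------------------------------
  filt <- tryCatch({
    ps <- projection_score_optimize(dat$expr, k = config$k_components,
                                    n_perm = config$n_perm,
                                    seed = child_seed(seed, 4))
    fexpr <- subset_genes(dat$expr, ps$retained)
    list(ps = ps, expr = fexpr,
         pca = pca_embed(fexpr, k = config$k_components))
  }, error = function(e) stage_abort("filter", e))
  save_tsv(filt$ps$grid, "projection_score.tsv")
  report$filter <- list(threshold = filt$ps$threshold,
                        n_retained = length(filt$ps$retained),
                        pc_variance = filt$pca$variance_fraction)

  # -- stage: differential expression ----------------------------------
  sel <- tryCatch(
    select_sex_de_genes(dat$expr, q_cut = config$q_cut,
                        fc_low = config$fc_low, fc_high = config$fc_high),
    error = function(e) stage_abort("de", e))
  save_tsv(sel$stage1, "de_tissue.tsv")
  if (!is.null(sel$stage2)) save_tsv(sel$stage2, "de_sex_adjusted.tsv")
  report$de <- list(stage1_genes = length(sel$stage1_genes),
                    selected_genes = length(sel$genes),
                    genes = sel$genes)
  if (length(sel$genes) < 2)
    stage_abort("de", simpleError(
      "fewer than 2 sex-differential genes selected; downstream models undefined"))

  # feature table: calcified vs nondiseased samples, selected genes
  ss <- expr_samples(dat$expr)
  use <- ss$tissue %in% c("calcified", "nondiseased")
  x <- t(expr_matrix(dat$expr)[sel$genes, use, drop = FALSE])
  y <- as.integer(ss$tissue[use] == "calcified")
  groups <- ss$patient_id[use]

  # -- stage: GA selection ---------------------------------------------
  ga_cfg <- config$ga
  ga_cfg$seed <- child_seed(seed, 5)
  ga_res <- tryCatch(
    ga_select(x, y, ga = ga_cfg, cv = config$cv, groups = groups),
    error = function(e) stage_abort("ga", e))
  if (!is.null(out))
    writeLines(ga_res$features, file.path(out, "ga_selected_features.txt"))
  report$ga <- list(n_selected = sum(ga_res$mask), fitness = ga_res$fitness,
                    features = ga_res$features)

  # -- stage: classification bench -------------------------------------
  cv_cfg <- config$cv
  cv_cfg$seed <- child_seed(seed, 6)
  bench <- tryCatch(
    fit_models(x, y, groups = groups, cv = cv_cfg,
               seed = child_seed(seed, 6)),
    error = function(e) stage_abort("classify", e))
  bench_sum <- summary(bench)
  save_tsv(bench_sum, "model_report.tsv")
  rf <- random_forest(x, y, seed = child_seed(seed, 7))
  gbt <- gradient_boosted_trees(x, y, seed = child_seed(seed, 7))
  imp_rf <- importance_weights(rf)
  imp_gbt <- importance_weights(gbt)
  save_tsv(imp_rf, "importance_random_forest.tsv")
  save_tsv(imp_gbt, "importance_gbt.tsv")
  pure <- extract_pure_trees(rf, x, y)
  if (!is.null(out))
    writeLines(unlist(pure$rules) %||% character(0),
               file.path(out, "pure_tree_rules.txt"))
  report$classify <- list(summary = bench_sum,
                          importance_rf = imp_rf, importance_gbt = imp_gbt,
                          n_pure_trees = length(pure$index))

  # -- stage: sex-chromosome variant -----------------------------------
  sexchrom <- tryCatch({
    xy <- subset_sex_chromosomes(dat$expr)
    xs <- t(expr_matrix(xy)[, use, drop = FALSE])
    cv2 <- config$cv
    cv2$seed <- child_seed(seed, 8)
    fit_models(xs, y, groups = groups, cv = cv2, seed = child_seed(seed, 8))
  }, error = function(e) structure(list(error = conditionMessage(e)),
                                   class = "model_failure"))
  report$sexchrom <- if (inherits(sexchrom, "model_failure"))
    list(error = sexchrom$error) else list(summary = summary(sexchrom))
  if (!inherits(sexchrom, "model_failure"))
    save_tsv(report$sexchrom$summary, "model_report_sexchrom.tsv")

  report$fingerprint <- list(
    package = as.character(utils::packageVersion("valvesex")),
    r_version = R.version.string, seed = seed)
  if (!is.null(out))
    jsonlite::write_json(
      report_json(report), file.path(out, "run_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "run_report"
  report
}

# JSON-safe view of the run report (drops data.frames kept in the R object).
report_json <- function(report) {
  lapply(report, function(stage) {
    if (!is.list(stage)) return(stage)
    lapply(stage, function(x) {
      if (is.data.frame(x)) lapply(x, function(col) col) else x
    })
  })
}
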