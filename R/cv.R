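#' Repeated k-fold fold assignments
#'
#' For each repeat, a random partition of `n` individuals into `k` folds
#' of size `floor(n/k)` or `ceiling(n/k)` (the `n %% k` larger folds come
#' first). Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param n number of individuals.
#' @param k folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed (mandatory — every CV experiment must be
#'   reproducible).
#' @return a `cv_folds` object: list of integer vectors (length `n`, fold
#'   label per individual), with `n`, `k`, `repeats`, `seed` attached.
#' @export
make_folds <- function(n, k = 10L, repeats = 10L, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (k > n) stop("k must not exceed n")
  assignments <- withr::with_seed(seed, lapply(seq_len(repeats), function(r) {
    base <- rep(seq_len(k), length.out = n)  # n %% k larger folds first
    sample(base)
  }))
  structure(list(assignments = assignments, n = n, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_folds")
}

#' Cross-validated accuracy of one model configuration
#'
#' Runs repeated k-fold cross-validation of a GBLUP/WGBLUP configuration
#' and reports the per-fold Pearson correlation between predicted GEBVs
#' and the observed phenotypes of the held-out fold.
#'
#' The `weights` argument selects the relationship matrix:
#' * `NULL` — plain GBLUP on `grm_method`;
#' * a [weight_vector()] — WGBLUP with fixed externally supplied weights
#'   (e.g. ML variable importance, or simulated-truth oracle weights);
#' * a model name from [dosage_models()] — WGBLUP with weights from a
#'   kinship-corrected [gwas_scan()] under that model.
#'
#' `leakage` controls where scan weights are estimated: `"nested"`
#' (default) rescans inside every training fold, the honest
#' generalization estimate; `"mimic_paper"` scans once on the full data
#' before splitting, which leaks test phenotypes into the weights and
#' typically inflates accuracy — reports carry the flag so the two are
#' never confused. Variance components are re-estimated by REML on each
#' training fold under both modes.
#'
#' @param d a [dosage_matrix()] (filtered, no missing values).
#' @param y phenotype vector aligned to `d`.
#' @param folds a [make_folds()] object with `n = nrow(d)`.
#' @param grm_method `"vanraden"` or `"full_autotetraploid"`.
#' @param weights `NULL`, a [weight_vector()], or a gene-action model name.
#' @param leakage `"nested"` or `"mimic_paper"` (scan weights only).
#' @param denominator passed to the GRM builders.
#' @param normalization weight normalization for scan weights.
#' @param label configuration label for reports; default autogenerated.
#' @return a `cv_report`: data.frame `results` (label, repeat, fold, r,
#'   n_test), `summary` (mean, sd over non-missing folds), the
#'   configuration, and the folds (for paired comparison).
#' @export
run_cv <- function(d, y, folds, grm_method = c("vanraden", "full_autotetraploid"),
                   weights = NULL, leakage = c("nested", "mimic_paper"),
                   denominator = "ploidy_scaled",
                   normalization = "mean_one", label = NULL) {
  stopifnot(inherits(d, "dosage_matrix"), inherits(folds, "cv_folds"))
  grm_method <- match.arg(grm_method)
  leakage <- match.arg(leakage)
  y <- as.numeric(y)
  n <- nrow(d$values)
  if (length(y) != n || folds$n != n) stop("inputs not aligned")

  scan_model <- NULL
  if (is.character(weights)) {
    scan_model <- match.arg(weights, dosage_models())
    weights <- NULL
  }
  build_K <- function(dd, wv) {
    if (!is.null(wv)) weighted_grm(dd, wv, denominator)
    else switch(grm_method,
                vanraden = vanraden_grm(dd, denominator),
                full_autotetraploid = slater_grm(dd))
  }
  if (is.null(label)) {
    label <- if (!is.null(scan_model))
      sprintf("wgblup:gwas-%s:%s", scan_model, leakage)
    else if (!is.null(weights)) paste0("wgblup:", weights$source)
    else paste0("gblup:", grm_method)
  }

  # configurations whose weights do not depend on the training fold can
  # build the kinship once
  K_fixed <- NULL
  if (is.null(scan_model)) {
    K_fixed <- build_K(d, weights)
  } else if (leakage == "mimic_paper") {
    K0 <- build_K(d, NULL)
    sc <- gwas_scan(d, y, K0, models = scan_model)
    wv <- scores_to_weights(sc, scan_model, normalization = normalization)
    K_fixed <- build_K(d, wv)
  }

  rows <- list()
  for (r in seq_len(folds$repeats)) {
    fa <- folds$assignments[[r]]
    for (f in seq_len(folds$k)) {
      te <- which(fa == f); tr <- which(fa != f)
      K <- K_fixed
      if (is.null(K)) { # nested scan weights from the training fold only
        dtr <- subset_samples(d, tr)
        K0tr <- build_K(dtr, NULL)
        sc <- gwas_scan(dtr, y[tr], K0tr, models = scan_model)
        wv <- scores_to_weights(sc, scan_model, normalization = normalization)
        K <- build_K(d, wv)
      }
      vc <- reml_fit(y[tr], K$values[tr, tr, drop = FALSE])
      pred <- gblup_predict(y[tr], K, tr, te, vc)
      g_te <- pred$gebv$gebv[pred$gebv$set == "test"]
      r_val <- if (stats::sd(y[te]) == 0) {
        warning(sprintf("constant test phenotype in repeat %d fold %d", r, f))
        NA_real_
      } else if (stats::sd(g_te) == 0) 0 else stats::cor(g_te, y[te])
      rows[[length(rows) + 1L]] <- data.frame(
        label = label, rep = r, fold = f, r = r_val, n_test = length(te),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  structure(list(results = res,
                 summary = data.frame(
                   label = label,
                   mean_r = mean(res$r, na.rm = TRUE),
                   sd_r = stats::sd(res$r, na.rm = TRUE),
                   n_folds = sum(!is.na(res$r))),
                 config = list(grm_method = grm_method,
                               scan_model = scan_model,
                               weight_source = if (!is.null(weights))
                                 weights$source else NULL,
                               leakage = if (!is.null(scan_model)) leakage
                               else "none",
                               denominator = denominator,
                               seed = folds$seed),
                 folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s\n  mean r = %.4f (sd %.4f) over %d folds (%d x %d CV, seed %d)\n",
              x$summary$label, x$summary$mean_r, x$summary$sd_r,
              x$summary$n_folds, x$folds$repeats, x$folds$k, x$folds$seed))
  if (x$config$leakage == "mimic_paper")
    cat("  NOTE: weights computed on the full data (leakage_mode = mimic_paper)\n")
  invisible(x)
}

#' Paired comparison of CV reports
#'
#' Compares configurations run on identical fold assignments (so
#' differences are attributable to the model, not the split). Reports are
#' ranked by mean accuracy; paired per-fold differences are taken against
#' the first report supplied (the reference).
#'
#' @param reports list of `cv_report`s sharing the same [make_folds()].
#' @return data.frame with one row per configuration: `label`, `mean_r`,
#'   `sd_r`, `mean_diff_vs_ref` (paired), `sd_diff`, `rank`, `leakage`.
#' @export
compare_cv <- function(reports) {
  if (length(reports) < 2) stop("need at least two reports")
  folds0 <- reports[[1]]$folds$assignments
  for (rep_i in reports)
    if (!identical(rep_i$folds$assignments, folds0))
      stop("reports use different fold assignments; comparisons must be paired")
  ref <- reports[[1]]$results$r
  tab <- do.call(rbind, lapply(reports, function(x) {
    dif <- x$results$r - ref
    data.frame(label = x$summary$label, mean_r = x$summary$mean_r,
               sd_r = x$summary$sd_r,
               mean_diff_vs_ref = mean(dif, na.rm = TRUE),
               sd_diff = stats::sd(dif, na.rm = TRUE),
               leakage = x$config$leakage, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$mean_r), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Write a CV report (per-fold CSV + JSON summary)
#'
#' @param x a `cv_report`; `path` CSV path; `json_path` optional summary
#'   JSON path.
#' @export
write_cv_report <- function(x, path, json_path = NULL) {
  stopifnot(inherits(x, "cv_report"))
  data.table::fwrite(x$results, path)
  if (!is.null(json_path))
    jsonlite::write_json(list(summary = x$summary, config = x$config),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(path)
}
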