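#' Allele-dosage gene-action models
#'
#' The eight single-marker gene-action models for tetraploid biallelic
#' SNPs (GWASpoly-style). Each model maps the five dosage classes
#' 0..4 (AAAA, AAAB, AABB, ABBB, BBBB; A = reference, B = alternate) to a
#' phenotypic-effect design:
#'
#' * `additive`: one column with codes 0.00, 0.25, 0.50, 0.75, 1.00;
#' * `diplo-additive`: one column 0, 0.5, 1 after collapsing dosages 1-3;
#' * `diplo-general`: indicator block over homA / heterozygote / homB
#'   (heterozygous effect unconstrained; 2 df when all classes observed);
#' * `general`: indicator block over observed dosage classes (up to 4 df);
#' * `1-dom-ref` (A > B simplex): codes 1, 1, 1, 1, 0;
#' * `2-dom-ref` (A > B duplex): codes 1, 1, 1, 0, 0;
#' * `1-dom-alt` (B > A simplex): codes 0, 1, 1, 1, 1;
#' * `2-dom-alt` (B > A duplex): codes 0, 0, 1, 1, 1.
#'
#' @return `dosage_models()`: character vector of the eight model names.
#' @export
dosage_models <- function() {
  c("additive", "diplo-additive", "diplo-general", "general",
    "1-dom-ref", "1-dom-alt", "2-dom-ref", "2-dom-alt")
}

scalar_codes <- list(
  "additive"       = c(0, 0.25, 0.5, 0.75, 1),
  "diplo-additive" = c(0, 0.5, 0.5, 0.5, 1),
  "1-dom-ref"      = c(1, 1, 1, 1, 0),
  "1-dom-alt"      = c(0, 1, 1, 1, 1),
  "2-dom-ref"      = c(1, 1, 1, 0, 0),
  "2-dom-alt"      = c(0, 0, 1, 1, 1)
)

scalar_codes_diploid <- list(
  "additive"       = c(0, 0.5, 1),
  "diplo-additive" = c(0, 0.5, 1),
  "1-dom-ref"      = c(1, 1, 0),
  "1-dom-alt"      = c(0, 1, 1)
)

#' Effect-design block for one marker under a gene-action model
#'
#' Builds the fixed-effect columns testing a marker under the named model
#' (see [dosage_models()]). Constant columns carry no contrast and are
#' dropped; for the class-factor models (`general`, `diplo-general`)
#' classes observed fewer than `min_class` times are absorbed into the
#' baseline and the degrees of freedom reduced accordingly. A zero-column
#' result means the marker is untestable under that model.
#'
#' @param model one of [dosage_models()].
#' @param dosage integer dosages in `0..ploidy` for the marker.
#' @param ploidy 4 (full model set) or 2 (pseudodiploid-coded input, where
#'   additive/diplo-additive use codes 0, 0.5, 1, the general and
#'   diplo-general models coincide, and simplex-dominant codes collapse to
#'   their diploid dominance patterns; duplex models are undefined).
#' @param min_class minimum observations per class for the factor models.
#' @return numeric matrix with `length(dosage)` rows and `df` columns
#'   (possibly zero).
#' @export
design_columns <- function(model, dosage, ploidy = 4L, min_class = 2L) {
  if (!model %in% dosage_models()) stop("unknown dosage model: ", model)
  if (!ploidy %in% c(2L, 4L)) stop("dosage models are defined for ploidy 2 or 4")
  dosage <- round(as.numeric(dosage))
  if (any(dosage < 0 | dosage > ploidy)) stop("dosages must lie in 0..ploidy")
  drop_const <- function(M) M[, apply(M, 2, function(x) length(unique(x)) > 1),
                              drop = FALSE]
  codes <- if (ploidy == 4L) scalar_codes else scalar_codes_diploid
  if (model %in% names(scalar_codes)) {
    cd <- codes[[model]]
    if (is.null(cd)) stop(model, " is undefined for diploid coding")
    M <- matrix(cd[dosage + 1L], ncol = 1, dimnames = list(NULL, model))
    return(drop_const(M))
  }
  cls <- if (model == "diplo-general" && ploidy == 4L) {
    c("homA", "het", "het", "het", "homB")[dosage + 1L]
  } else as.character(dosage)
  tab <- table(cls)
  lev <- names(tab)[tab >= min_class]
  lev <- lev[order(match(lev, unique(cls[order(dosage)])))]
  if (length(lev) < 2) return(matrix(0, length(dosage), 0))
  M <- vapply(lev[-1], function(l) as.numeric(cls == l),
              numeric(length(dosage)))
  M <- matrix(M, ncol = length(lev) - 1L,
              dimnames = list(NULL, paste0(model, ".", lev[-1])))
  drop_const(M)
}

#' Kinship-corrected single-marker association scan
#'
#' Tests every marker under each requested gene-action model, producing a
#' marker x model matrix of `-log10` p-values. The covariance structure is
#' handled P3D-style: variance components are estimated once under the
#' null model (no marker) by [reml_fit()], the data are rotated by the
#' inverse square root of `K + delta I`, and each marker's effect block is
#' then an ordinary F-test (its df = number of independent effect columns)
#' against the rotated null. With `K = NULL` the scan is uncorrected
#' (identity covariance). Scores are capped at 300 to avoid infinities on
#' perfect fits.
#'
#' @param d a [dosage_matrix()] (tetraploid, integer dosages, no missing
#'   values).
#' @param y phenotype vector aligned to `d` (named or ordered).
#' @param K optional `kinship_matrix` on the same individuals.
#' @param models character vector of model names; default all eight.
#' @param covariates optional numeric matrix of fixed covariates.
#' @param min_class passed to [design_columns()].
#' @param p3d logical; `FALSE` refits REML per marker (slow, reference
#'   behaviour).
#' @return a `gwas_scan` object: `scores` (m x models, `NA` when skipped),
#'   `reasons` (skip reason or `"tested"`), `map`, `models`, `vc`.
#' @export
gwas_scan <- function(d, y, K = NULL, models = dosage_models(),
                      covariates = NULL, min_class = 2L, p3d = TRUE) {
  stopifnot(inherits(d, "dosage_matrix"))
  bad <- setdiff(models, dosage_models())
  if (length(bad)) stop("unknown dosage model: ", paste(bad, collapse = ", "))
  if (anyNA(d$values)) stop("missing values present; run impute_missing() first")
  y <- as.numeric(y)
  n <- nrow(d$values)
  if (length(y) != n) stop("phenotype length != individuals")
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (n <= ncol(X0) + 4L) stop("too few individuals for the fixed effects")

  vc <- NULL
  if (!is.null(K)) {
    vc <- reml_fit(y, K, X0)
    rot <- rotation_p3d(K, vc)
  } else rot <- NULL
  tr <- function(A) if (is.null(rot)) A else rot %*% A
  ys <- as.numeric(tr(y))
  X0s <- tr(X0)
  qr0 <- qr(X0s)
  rss0 <- sum(qr.resid(qr0, ys)^2)

  m <- ncol(d$values)
  scores <- matrix(NA_real_, m, length(models),
                   dimnames = list(marker_ids(d), models))
  reasons <- matrix("tested", m, length(models),
                    dimnames = dimnames(scores))
  for (i in seq_len(m)) {
    dos <- d$values[, i]
    for (j in seq_along(models)) {
      S <- design_columns(models[j], dos, d$ploidy, min_class)
      if (ncol(S) == 0L) { reasons[i, j] <- "no contrast"; next }
      if (!is.null(vc) && !p3d) {
        vci <- reml_fit(y, K, cbind(X0, S))
        roti <- rotation_p3d(K, vci)
        ysi <- as.numeric(roti %*% y)
        Xfi <- roti %*% cbind(X0, S)
        qrf <- qr(Xfi)
        X0i <- roti %*% X0
        qr0i <- qr(X0i)
        sc <- f_score(qr0i, qrf, ysi, n)
      } else {
        qrf <- qr(cbind(X0s, tr(S)))
        sc <- f_score(qr0, qrf, ys, n, rss0)
      }
      if (is.na(sc)) reasons[i, j] <- "collinear" else scores[i, j] <- sc
    }
  }
  structure(list(scores = scores, reasons = reasons, map = d$map,
                 models = models, vc = vc,
                 n_tested = colSums(!is.na(scores)),
                 n_skipped = colSums(is.na(scores))),
            class = "gwas_scan")
}

# inverse square root of (K + delta I) from its eigendecomposition;
# identity rotation when the genetic variance vanished
rotation_p3d <- function(K, vc) {
  if (!is.finite(vc$delta) || vc$h2 < 1e-8) return(NULL)
  Kv <- kinship_values(K)
  eg <- eigen((Kv + t(Kv)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0) + vc$delta
  t(eg$vectors) / sqrt(lam)  # rows scaled: D^{-1/2} U'
}

f_score <- function(qr0, qrf, ys, n, rss0 = NULL) {
  df1 <- qrf$rank - qr0$rank
  if (df1 <= 0L) return(NA_real_)
  if (is.null(rss0)) rss0 <- sum(qr.resid(qr0, ys)^2)
  rss1 <- sum(qr.resid(qrf, ys)^2)
  df2 <- n - qrf$rank
  if (df2 <= 0L) return(NA_real_)
  Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (!is.finite(Fst) || Fst < 0) Fst <- max(Fst, 0)
  lp <- -stats::pf(Fst, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  min(lp, 300)
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan: %d markers x %d models%s\n", nrow(x$scores),
              length(x$models),
              if (is.null(x$vc)) " (uncorrected)" else " (kinship-corrected)"))
  print(rbind(tested = x$n_tested, skipped = x$n_skipped))
  invisible(x)
}

#' Convert scan scores into a marker weight vector
#'
#' Takes one model's `-log10` p-values as per-marker weights for the
#' weighted relationship matrix: `w_i = max(score_i, floor_eps)`, skipped
#' markers getting the floor. No multiple-testing adjustment is applied —
#' raw scores are the weights.
#'
#' @param s a `gwas_scan`.
#' @param model model column to extract.
#' @param floor_eps positive floor keeping excluded/zero-score markers at
#'   a negligible but nonzero weight.
#' @param normalization passed to [weight_vector()].
#' @return a [weight_vector()] tagged `gwas:<model>`.
#' @export
scores_to_weights <- function(s, model, floor_eps = 1e-6,
                              normalization = c("mean_one", "raw")) {
  stopifnot(inherits(s, "gwas_scan"))
  if (!model %in% colnames(s$scores)) stop("model not in scan: ", model)
  sc <- s$scores[, model]
  w <- pmax(ifelse(is.na(sc), floor_eps, sc), floor_eps)
  weight_vector(w, source = paste0("gwas:", model),
                normalization = match.arg(normalization))
}

#' Pearson correlation between weight sources
#'
#' Pairwise Pearson correlations across weight vectors defined on the same
#' markers, used to compare association-derived and importance-derived
#' weightings. A zero-variance vector yields `NA` against every partner.
#'
#' @param weights named list of [weight_vector()]s (or numeric vectors)
#'   over identical markers.
#' @return symmetric correlation matrix.
#' @export
weight_correlations <- function(weights) {
  if (length(weights) < 2) stop("need at least two weight vectors")
  ws <- lapply(weights, function(w)
    if (inherits(w, "weight_vector")) w$w else as.numeric(w))
  lens <- lengths(ws)
  if (length(unique(lens)) != 1) stop("weight vectors differ in length")
  W <- do.call(cbind, ws)
  sdv <- apply(W, 2, stats::sd)
  out <- suppressWarnings(stats::cor(W))
  out[sdv == 0, ] <- NA_real_
  out[, sdv == 0] <- NA_real_
  diag(out)[sdv > 0] <- 1
  out
}

#' Write scan results as a long-format CSV
#'
#' Columns: `marker_id`, `chrom`, `pos`, `model`, `score`, `reason`.
#' @param s a `gwas_scan`; `path` output path.
#' @export
write_scan <- function(s, path) {
  stopifnot(inherits(s, "gwas_scan"))
  long <- do.call(rbind, lapply(s$models, function(mod)
    data.frame(marker_id = rownames(s$scores), chrom = s$map$chrom,
               pos = s$map$pos, model = mod, score = s$scores[, mod],
               reason = s$reasons[, mod], stringsAsFactors = FALSE)))
  data.table::fwrite(long, path)
  invisible(path)
}
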