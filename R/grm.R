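#' Kinship (genomic relationship) matrices
#'
#' Internal constructor for the `kinship_matrix` class: an n x n symmetric
#' relationship matrix with its construction tag and scaling constant.
#' @noRd
new_kinship <- function(values, method, c_scale = NA_real_,
                        weight_source = NULL) {
  values <- (values + t(values)) / 2  # enforce exact symmetry
  structure(list(values = values, method = method, c_scale = c_scale,
                 weight_source = weight_source),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s): %d x %d, scaling c = %.6g\n",
              x$method, nrow(x$values), ncol(x$values), x$c_scale))
  if (!is.null(x$weight_source))
    cat("  weight source:", x$weight_source, "\n")
  cat(sprintf("  mean diagonal %.4f\n", mean(diag(x$values))))
  invisible(x)
}

#' @export
dim.kinship_matrix <- function(x) dim(x$values)

centered_dosage <- function(d) {
  p <- allele_freq(d)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic markers present; run filter_maf() first")
  sweep(d$values, 2, d$ploidy * p)
}

grm_denominator <- function(d, denominator = c("ploidy_scaled", "paper_literal")) {
  denominator <- match.arg(denominator)
  p <- allele_freq(d)
  mult <- if (denominator == "ploidy_scaled") d$ploidy else 2
  mult * sum(p * (1 - p))
}

#' VanRaden genomic relationship matrix for dosage genotypes
#'
#' `G = Wc Wc' / c` where `Wc` is the column-centered dosage matrix
#' (column mean `ploidy * p_i`) and the scaling constant is
#' `c = ploidy * sum(p_i (1 - p_i))` (`denominator = "ploidy_scaled"`,
#' the generalization whose expected diagonal is ~1 for dosages `0..ploidy`)
#' or the diploid literal `c = 2 * sum(p_i (1 - p_i))`
#' (`denominator = "paper_literal"`). The choice rescales G, hence the
#' variance components, but not GBLUP prediction accuracy.
#'
#' @param d a polymorphic [dosage_matrix()] without missing values
#'   (see [impute_missing()], [filter_maf()]).
#' @param denominator `"ploidy_scaled"` (default) or `"paper_literal"`.
#' @return a `kinship_matrix` (method `"vanraden"`). Rows and columns are
#'   ordered and named by sample id; every row sums to zero (centering).
#' @export
vanraden_grm <- function(d, denominator = c("ploidy_scaled", "paper_literal")) {
  stopifnot(inherits(d, "dosage_matrix"))
  if (anyNA(d$values)) stop("missing values present; run impute_missing() first")
  Wc <- centered_dosage(d)
  cs <- grm_denominator(d, denominator)
  new_kinship(tcrossprod(Wc) / cs, "vanraden", cs)
}

#' Allele-frequency-standardized (Yang et al.) relationship matrix
#'
#' Diploid-coded GRM with per-marker standardization by `2 p_i (1 - p_i)`:
#' off-diagonal `G_jk = mean_i (w_ij - 2 p_i)(w_ik - 2 p_i) / (2 p_i (1-p_i))`
#' and diagonal
#' `G_jj = 1 + mean_i (w_ij^2 - (1 + 2 p_i) w_ij + 2 p_i^2) / (2 p_i (1-p_i))`,
#' with `w` the alternate-allele count in `{0, 1, 2}`. Tetraploid panels
#' must first be collapsed with [pseudodiploid_recode()]. (The source
#' formula's printed class labels conflict with its own `2p` centering;
#' the standard alt-allele-count coding 0=AA, 1=AB, 2=BB is used.)
#'
#' @param d a diploid-coded [dosage_matrix()] (ploidy 2), polymorphic, no
#'   missing values.
#' @return a `kinship_matrix` (method `"yang"`).
#' @export
yang_grm <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  if (d$ploidy != 2L)
    stop("Yang GRM needs diploid coding; use pseudodiploid_recode() for tetraploids")
  if (anyNA(d$values)) stop("missing values present; run impute_missing() first")
  p <- allele_freq(d)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic markers present; run filter_maf() first")
  W <- d$values
  N <- ncol(W)
  denom <- 2 * p * (1 - p)
  S <- sweep(sweep(W, 2, 2 * p), 2, sqrt(denom), "/")
  G <- tcrossprod(S) / N
  # diagonal uses its own expression, not (w - 2p)^2
  num <- W^2 - sweep(W, 2, 1 + 2 * p, "*") + matrix(2 * p^2, nrow(W), N, byrow = TRUE)
  diag(G) <- 1 + rowSums(sweep(num, 2, denom, "/")) / N
  new_kinship(G, "yang", N)
}

#' Full-autotetraploid (genotype-class) relationship matrix
#'
#' Treats each of the five tetraploid genotype classes as its own allele:
#' markers are one-hot expanded ([indicator_expand()]) and
#' `G_jk = 1 + (1/M) sum_i (w_ij - p_i)(w_ik - p_i) / (p_i (1 - p_i))`
#' over indicator columns `i` with class frequency `p_i` strictly inside
#' (0, 1); `M = 5 * markers`. The `1 +` offset applies to diagonal and
#' off-diagonal alike, as the source formula prints it (the diagonal
#' expression `w^2 - 2 p w + p^2` is `(w - p)^2`). Classes with frequency
#' 0 or 1 are skipped; a marker whose classes are all skipped (i.e. a
#' monomorphic marker) is dropped with a warning and excluded from `M`.
#'
#' @param d a tetraploid [dosage_matrix()], integer dosages, no missing
#'   values.
#' @return a `kinship_matrix` (method `"full_autotetraploid"`) with
#'   attribute `M` (indicator-column count used in the denominator).
#' @export
slater_grm <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  ex <- indicator_expand(d)
  pf <- ex$class_freq
  usable <- pf > 0 & pf < 1
  by_marker <- tapply(usable, ex$marker, any)
  dead <- names(by_marker)[!by_marker]
  if (length(dead)) {
    warning(length(dead), " monomorphic marker(s) dropped from full-autotetraploid GRM")
    keep_cols <- usable & !(ex$marker %in% dead)
  } else keep_cols <- usable
  M <- 5L * sum(by_marker)
  X <- ex$indicators[, keep_cols, drop = FALSE]
  p <- pf[keep_cols]
  S <- sweep(sweep(X, 2, p), 2, sqrt(p * (1 - p)), "/")
  G <- 1 + tcrossprod(S) / M
  K <- new_kinship(G, "full_autotetraploid", M)
  attr(K, "M") <- M
  K
}

#' Per-marker weight vector (diagonal of D)
#'
#' Nonnegative per-marker weights forming the diagonal matrix `D` of the
#' weighted relationship matrix `G* = Wc D Wc' / c`. Weights typically come
#' from association scores (-log10 p-values) or machine-learning variable
#' importance. Under `normalization = "mean_one"` (default) weights are
#' rescaled to mean 1 before use, keeping `trace(G*)` comparable to
#' `trace(G)` so genetic-variance estimates stay on the same scale;
#' `"raw"` uses them verbatim.
#'
#' @param w numeric vector of finite weights `>= 0` (zero excludes a
#'   marker; an all-zero vector is an error), optionally named by marker.
#' @param source provenance tag, e.g. `"gwas:additive"`,
#'   `"importance:rf"`, `"uniform"`, `"file"`.
#' @param normalization `"mean_one"` or `"raw"`.
#' @return a `weight_vector` object.
#' @export
weight_vector <- function(w, source = "file",
                          normalization = c("mean_one", "raw")) {
  normalization <- match.arg(normalization)
  nm <- names(w)
  w <- as.numeric(w)
  names(w) <- nm
  if (any(!is.finite(w))) stop("weights must be finite")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (all(w == 0)) stop("all-zero weight vector")
  structure(list(w = w, source = source, normalization = normalization),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector: %d markers, source %s, normalization %s\n",
              length(x$w), x$source, x$normalization))
  invisible(x)
}

#' @export
length.weight_vector <- function(x) length(x$w)

effective_weights <- function(wv) {
  if (wv$normalization == "mean_one") wv$w / mean(wv$w) else wv$w
}

#' Weighted genomic relationship matrix (WGBLUP G*)
#'
#' `G* = Wc D Wc' / c` with `D = diag(w)` carrying per-marker weights and
#' `Wc`, `c` as in [vanraden_grm()]. With unit weights G* reduces exactly
#' to the VanRaden G.
#'
#' @inheritParams vanraden_grm
#' @param w a [weight_vector()] (or bare numeric vector, treated as raw
#'   weights with mean-one normalization) of length `ncol(d)`.
#' @return a `kinship_matrix` (method `"weighted"`, `weight_source` tagged).
#' @export
weighted_grm <- function(d, w,
                         denominator = c("ploidy_scaled", "paper_literal")) {
  stopifnot(inherits(d, "dosage_matrix"))
  if (!inherits(w, "weight_vector")) w <- weight_vector(w, source = "file")
  if (length(w$w) != ncol(d$values))
    stop("weight length != marker count")
  if (anyNA(d$values)) stop("missing values present; run impute_missing() first")
  ww <- effective_weights(w)
  Wc <- centered_dosage(d)
  cs <- grm_denominator(d, denominator)
  G <- tcrossprod(sweep(Wc, 2, ww, "*"), Wc) / cs
  new_kinship(G, "weighted", cs, weight_source = w$source)
}

#' Read / write kinship matrices and weight tables
#'
#' Kinship matrices are stored as square CSV with a leading `sample_id`
#' column and sample ids as header; weight tables as CSV with columns
#' `marker_id`, `weight`, `source`.
#'
#' @param K a `kinship_matrix`; `path` file path.
#' @export
write_kinship <- function(K, path) {
  stopifnot(inherits(K, "kinship_matrix"))
  out <- data.frame(sample_id = rownames(K$values), K$values,
                    check.names = FALSE)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_kinship
#' @param method construction tag to attach on read.
#' @export
read_kinship <- function(path, method = "file") {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  v <- as.matrix(dt[, -1, drop = FALSE])
  rownames(v) <- as.character(dt[[1]])
  new_kinship(v, method)
}

#' @rdname write_kinship
#' @param wv a [weight_vector()]; markers taken from its names.
#' @export
write_weights <- function(wv, path) {
  stopifnot(inherits(wv, "weight_vector"))
  data.table::fwrite(data.frame(
    marker_id = names(wv$w) %||% paste0("mk", seq_along(wv$w)),
    weight = wv$w, source = wv$source), path)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_weights <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  weight_vector(stats::setNames(dt$weight, dt$marker_id),
                source = dt$source[1] %||% "file")
}
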