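#' Marker-mean imputation of missing dosages
#'
#' Replaces each missing entry by the mean observed dosage of its marker
#' (so imputed matrices are real-valued). Allele frequencies are unchanged
#' by construction. Markers with no observed call at all are dropped with
#' a warning.
#'
#' @param d a [dosage_matrix()].
#' @return a [dosage_matrix()] without missing values; attribute
#'   `n_imputed` counts replaced entries, `dropped_markers` the fully
#'   missing markers removed.
#' @export
impute_missing <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  v <- d$values
  all_na <- colSums(!is.na(v)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " fully missing marker(s) dropped")
    d <- subset_markers(d, !all_na)
    v <- d$values
  }
  n_imp <- sum(is.na(v))
  if (n_imp > 0) {
    mu <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2]]
    d <- dosage_matrix(v, d$ploidy, d$map)
  }
  attr(d, "n_imputed") <- n_imp
  attr(d, "dropped_markers") <- sum(all_na)
  d
}

#' Minor-allele-frequency filter
#'
#' Removes markers whose minor allele frequency `min(p, 1-p)` falls below
#' `maf_min`. Monomorphic markers (`p` of exactly 0 or 1) are always
#' removed regardless of the threshold: with `p(1-p) = 0` they break every
#' relationship-matrix denominator.
#'
#' @param d a [dosage_matrix()].
#' @param maf_min threshold in `[0, 0.5)`; default 0.05.
#' @return filtered [dosage_matrix()]; attribute `n_removed`.
#' @export
filter_maf <- function(d, maf_min = 0.05) {
  stopifnot(inherits(d, "dosage_matrix"))
  if (maf_min < 0 || maf_min >= 0.5) stop("`maf_min` must lie in [0, 0.5)")
  p <- allele_freq(d)
  keep <- p > 0 & p < 1 & pmin(p, 1 - p) >= maf_min
  if (!any(keep)) stop("no markers pass MAF filter")
  out <- subset_markers(d, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Pseudodiploid recoding of tetraploid dosages
#'
#' Collapses the five autotetraploid genotype classes to three diploid-like
#' classes: both homozygotes keep their extreme codes while every
#' heterozygote (AAAB, AABB, ABBB) is assigned the same effect, i.e.
#' `0 -> 0`, `{1,2,3} -> 1`, `4 -> 2`. The result is a ploidy-2 matrix.
#' Applying it to anything but an integer tetraploid matrix is an error
#' (so an already collapsed matrix cannot be silently collapsed twice).
#'
#' @param d a tetraploid [dosage_matrix()] with integer dosages
#'   (recode before imputation, which makes entries real-valued).
#' @return a ploidy-2 [dosage_matrix()].
#' @export
pseudodiploid_recode <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  if (d$ploidy != 4L)
    stop("pseudodiploid recoding is defined for tetraploid input (ploidy 4)")
  v <- d$values
  if (any(abs(v - round(v)) > 1e-9, na.rm = TRUE))
    stop("recoding needs integer dosage classes; apply before imputation")
  codes <- c(0, 1, 1, 1, 2)
  idx <- !is.na(v)
  v[idx] <- codes[round(v[idx]) + 1L]
  dosage_matrix(v, ploidy = 2L, map = d$map)
}

#' One-hot genotype-class expansion of a tetraploid matrix
#'
#' Expands each marker into five indicator columns, one per genotype class
#' AAAA, AAAB, AABB, ABBB, BBBB, as used by the full-autotetraploid
#' relationship matrix. The expanded matrix has `M = 5 * markers` columns
#' and exactly one 1 per individual per marker; column means are the
#' genotype-class frequencies.
#'
#' @param d a tetraploid [dosage_matrix()], no missing values, integer
#'   dosages.
#' @return list with `indicators` (n x 5m binary matrix, columns named
#'   `<marker>.<class>`), `class_freq` (column means), `marker` (marker id
#'   per column), `class` (dosage class 0..4 per column).
#' @export
indicator_expand <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  if (d$ploidy != 4L) stop("indicator expansion is defined for ploidy 4")
  v <- d$values
  if (anyNA(v)) stop("missing values present; run impute_missing() first (or drop)")
  if (any(abs(v - round(v)) > 1e-9))
    stop("indicator expansion needs integer dosage classes")
  n <- nrow(v); m <- ncol(v)
  classes <- 0:4
  ind <- matrix(0, n, 5L * m)
  for (k in seq_along(classes))
    ind[, (seq_len(m) - 1L) * 5L + k] <- (round(v) == classes[k]) + 0
  marker <- rep(marker_ids(d), each = 5L)
  class <- rep(classes, m)
  colnames(ind) <- paste(marker, class, sep = ".")
  rownames(ind) <- sample_ids(d)
  list(indicators = ind, class_freq = colMeans(ind),
       marker = marker, class = class)
}
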