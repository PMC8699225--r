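#' Allele-dosage genotype matrix
#'
#' The central genotype container: an `n` individuals x `m` markers numeric
#' matrix of alternate-allele dosages coded `0..ploidy` (an autotetraploid
#' biallelic SNP takes values 0 = AAAA, 1 = AAAB, 2 = AABB, 3 = ABBB,
#' 4 = BBBB), together with per-marker metadata and alternate-allele
#' frequencies. Entries may be `NA` (missing call) or, after marker-mean
#' imputation, real-valued.
#'
#' @param values numeric matrix, individuals in rows, markers in columns.
#'   Row names are sample ids, column names marker ids (generated when
#'   absent). Non-missing entries must lie in `[0, ploidy]`.
#' @param ploidy integer >= 2, number of allele copies per locus (4 for
#'   autotetraploids such as alfalfa and potato).
#' @param map optional `data.frame` of marker metadata with columns
#'   `marker`, `chrom`, `pos`, `ref`, `alt`; a skeleton map is generated
#'   when omitted.
#' @return An object of class `dosage_matrix`: a list with elements
#'   `values`, `ploidy`, `map`.
#' @examples
#' g <- dosage_matrix(matrix(c(0, 2, 4, 1, 3, 0), nrow = 3,
#'                    dimnames = list(paste0("ind", 1:3), c("m1", "m2"))),
#'                    ploidy = 4)
#' allele_freq(g)
#' @export
dosage_matrix <- function(values, ploidy = 4L, map = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 2L)
    stop("`ploidy` must be an integer >= 2")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("ind", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("mk", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicated marker ids")
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > ploidy))
    stop("dosages must lie in [0, ploidy]")
  if (is.null(map)) {
    map <- data.frame(marker = colnames(values),
                      chrom = "0", pos = seq_len(ncol(values)),
                      ref = "A", alt = "T",  # nucleotide stand-ins for the A/B allele labels
                      stringsAsFactors = FALSE)
  } else {
    map <- as.data.frame(map, stringsAsFactors = FALSE)
    need <- c("marker", "chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(map))
    if (length(miss)) stop("map lacks columns: ", paste(miss, collapse = ", "))
    if (nrow(map) != ncol(values) ||
        !identical(as.character(map$marker), colnames(values)))
      stop("map rows must match marker columns (same ids, same order)")
  }
  structure(list(values = values, ploidy = ploidy, map = map),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d markers, ploidy %d\n",
              nrow(x$values), ncol(x$values), x$ploidy))
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat(sprintf("  missing entries: %d\n", nmiss))
  p <- allele_freq(x)
  cat(sprintf("  alt-allele frequency: min %.3f / median %.3f / max %.3f\n",
              min(p), stats::median(p), max(p)))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' @rdname dosage_matrix
#' @param d a `dosage_matrix`.
#' @return `allele_freq()`: per-marker alternate-allele frequency
#'   `p_i = mean(dosage_i) / ploidy` over non-missing calls.
#' @export
allele_freq <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  colMeans(d$values, na.rm = TRUE) / d$ploidy
}

#' @rdname dosage_matrix
#' @return `sample_ids()` / `marker_ids()`: character vectors of labels.
#' @export
sample_ids <- function(d) rownames(d$values)

#' @rdname dosage_matrix
#' @export
marker_ids <- function(d) colnames(d$values)

subset_markers <- function(d, keep) {
  dosage_matrix(d$values[, keep, drop = FALSE], d$ploidy,
                d$map[keep, , drop = FALSE])
}

subset_samples <- function(d, keep) {
  dosage_matrix(d$values[keep, , drop = FALSE], d$ploidy, d$map)
}

#' Read / write a delimited dosage matrix
#'
#' Plain-text interchange format: CSV/TSV with individuals as rows, a
#' leading `sample_id` column and one column per marker (header = marker
#' id). Marker metadata travels in an optional side-car map file
#' (`marker, chrom, pos, ref, alt`).
#'
#' @param path genotype table path.
#' @param ploidy ploidy of the stored dosages.
#' @param map_path optional marker-map CSV path.
#' @return `read_dosage_csv()`: a [dosage_matrix()].
#' @export
read_dosage_csv <- function(path, ploidy = 4L, map_path = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  values <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  map <- if (!is.null(map_path))
    data.table::fread(map_path, header = TRUE, data.table = FALSE)
  dosage_matrix(values, ploidy = ploidy, map = map)
}

#' @rdname read_dosage_csv
#' @param d a [dosage_matrix()].
#' @export
write_dosage_csv <- function(d, path, map_path = NULL) {
  stopifnot(inherits(d, "dosage_matrix"))
  out <- data.frame(sample_id = sample_ids(d), d$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(out, path)
  if (!is.null(map_path)) data.table::fwrite(d$map, map_path)
  invisible(path)
}

#' Read / write phenotypes
#'
#' Phenotypes are adjusted trait values (BLUEs), one per individual, stored
#' as CSV with columns `sample_id`, `trait`, `value`.
#'
#' @param path phenotype CSV path.
#' @param trait trait name to extract; default the first trait present.
#' @return a named numeric vector (names = sample ids) with attribute
#'   `trait`.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("sample_id", "trait", "value")
  if (!all(need %in% names(dt)))
    stop("phenotype file needs columns: ", paste(need, collapse = ", "))
  if (is.null(trait)) trait <- dt$trait[1]
  dt <- dt[dt$trait == trait, , drop = FALSE]
  if (!nrow(dt)) stop("trait not found: ", trait)
  if (any(!is.finite(dt$value))) stop("non-finite phenotype values")
  y <- stats::setNames(as.numeric(dt$value), as.character(dt$sample_id))
  attr(y, "trait") <- trait
  y
}

#' @rdname read_phenotypes
#' @param y named numeric phenotype vector.
#' @export
write_phenotypes <- function(y, path, trait = attr(y, "trait") %||% "trait") {
  data.table::fwrite(data.frame(sample_id = names(y), trait = trait,
                                value = as.numeric(y)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align genotypes and phenotypes by sample id
#'
#' Takes the intersection of sample ids (order of the genotype matrix) and
#' returns both objects restricted and ordered identically.
#'
#' @param d a [dosage_matrix()].
#' @param y named phenotype vector.
#' @return list with elements `d`, `y`, and `dropped` (ids not shared).
#' @export
align_samples <- function(d, y) {
  stopifnot(inherits(d, "dosage_matrix"), !is.null(names(y)))
  common <- intersect(sample_ids(d), names(y))
  if (!length(common)) stop("no samples shared between genotypes and phenotypes")
  dropped <- union(setdiff(sample_ids(d), common), setdiff(names(y), common))
  list(d = subset_samples(d, match(common, sample_ids(d))),
       y = y[common], dropped = dropped)
}
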