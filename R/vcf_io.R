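#' Read tetraploid (or any-ploidy) dosages from a VCF
#'
#' Parses a VCF 4.x file and returns the alternate-allele dosage matrix of
#' the biallelic SNP records. Multiallelic records and indels are dropped
#' (biallelic SNPs are the standard marker set for polyploid genomic
#' selection) and counted in the attached filter report.
#'
#' Two field policies are supported: `"genotype"` counts alternate alleles
#' in the `GT` call (a tetraploid `0/1/1/1` gives dosage 3; any missing
#' allele gives `NA`); `"dosage"` reads a numeric dosage FORMAT field
#' (default `DS`) and rounds it to the nearest integer class.
#'
#' @param path VCF file (plain or bgzipped).
#' @param ploidy expected GT arity; a record whose call arity differs is an
#'   error naming the record.
#' @param field_policy `"genotype"` or `"dosage"`.
#' @param dosage_field FORMAT tag holding dosages when
#'   `field_policy = "dosage"`.
#' @return a [dosage_matrix()] with attribute `filter_report` (counts of
#'   records read / kept / dropped by reason).
#' @export
read_vcf_dosage <- function(path, ploidy = 4L,
                            field_policy = c("genotype", "dosage"),
                            dosage_field = "DS") {
  field_policy <- match.arg(field_policy)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF files")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1] <- vapply(as.list(altl[n_alt >= 1]),
                             function(a) as.character(a[1]), "")
  is_multi <- n_alt != 1L
  is_snp <- !is_multi & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  keep <- which(is_snp)
  report <- list(records = length(ref),
                 kept = length(keep),
                 dropped_multiallelic = sum(is_multi),
                 dropped_non_snp = sum(!is_multi & !is_snp))
  if (!length(keep)) stop("no biallelic SNP records in ", path)

  samples <- colnames(vcf)
  if (field_policy == "genotype") {
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    gt <- gt[keep, , drop = FALSE]
    ids <- rownames(gt)
    vals <- vapply(seq_along(samples), function(j) {
      vapply(seq_along(keep), function(i) {
        g <- gt[i, j]
        if (is.na(g) || g == "." || g == "") return(NA_real_)
        al <- strsplit(g, "[/|]")[[1]]
        if (length(al) != ploidy)
          stop(sprintf("record %s sample %s: GT arity %d != ploidy %d",
                       ids[i], samples[j], length(al), ploidy))
        if (any(al == ".")) return(NA_real_)
        sum(al != "0")
      }, 0)
    }, numeric(length(keep)))
  } else {
    ds <- VariantAnnotation::geno(vcf)[[dosage_field]]
    if (is.null(ds)) stop("VCF has no ", dosage_field, " field")
    ds <- ds[keep, , drop = FALSE]
    storage.mode(ds) <- "double"
    if (any(ds < -0.5 | ds > ploidy + 0.5, na.rm = TRUE))
      stop("dosage field values outside [0, ploidy]")
    vals <- round(ds)
    ids <- rownames(ds)
  }
  vals <- matrix(vals, nrow = length(keep),
                 dimnames = list(ids, samples))
  map <- data.frame(marker = ids,
                    chrom = as.character(as.vector(GenomicRanges::seqnames(rr)))[keep],
                    pos = BiocGenerics::start(rr)[keep],
                    ref = ref[keep], alt = alt1[keep],
                    stringsAsFactors = FALSE)
  d <- dosage_matrix(t(vals), ploidy = as.integer(ploidy), map = map)
  attr(d, "filter_report") <- report
  d
}

#' Write a dosage matrix as VCF
#'
#' Emits a minimal VCF 4.3 file with one biallelic SNP record per marker
#' and unphased GT calls of arity `ploidy` (dosage `k` becomes
#' `0/..of ploidy-k../1/..of k..`). Missing entries become `./...`.
#' Real-valued (imputed) dosages cannot be represented as GT calls and are
#' an error; write the CSV form instead.
#'
#' @param d a [dosage_matrix()] with integer dosages.
#' @param path output path.
#' @export
write_vcf_dosage <- function(d, path) {
  stopifnot(inherits(d, "dosage_matrix"))
  v <- d$values
  ok <- is.na(v) | (abs(v - round(v)) < 1e-9)
  if (!all(ok)) stop("non-integer dosages cannot be written as GT; use write_dosage_csv()")
  phi <- d$ploidy
  gt_codes <- vapply(0:phi, function(k)
    paste(c(rep("0", phi - k), rep("1", k)), collapse = "/"), "")
  miss <- paste(rep(".", phi), collapse = "/")
  header <- c("##fileformat=VCFv4.3",
              "##source=polyblup",
              sprintf("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (ploidy %d)\">", phi),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids(d)), collapse = "\t"))
  m <- ncol(v)
  body <- vapply(seq_len(m), function(i) {
    calls <- ifelse(is.na(v[, i]), miss, gt_codes[round(v[, i]) + 1L])
    paste(c(d$map$chrom[i], d$map$pos[i], d$map$marker[i], d$map$ref[i],
            d$map$alt[i], ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
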