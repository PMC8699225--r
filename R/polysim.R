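#' Simulation configuration for synthetic autotetraploid panels
#'
#' The generator emulates the shape of a GBS-derived breeding-panel
#' dataset: by default 265 individuals x 6796 tetraploid biallelic SNPs
#' with an adjusted (BLUE-like) phenotype — the dimensions of the alfalfa
#' salt-stress case the package's workflow is designed around. Genotypes
#' are drawn marker-wise as Binomial(ploidy, p) under random bivalent
#' pairing (an HWE approximation; no double reduction), optionally with
#' local LD blocks in which markers copy a latent founder column with a
#' per-individual mutation rate.
#'
#' @param n individuals (default 265).
#' @param m markers (default 6796).
#' @param ploidy default 4.
#' @param freq_range alternate-allele frequency range markers are drawn
#'   from (default `c(0.05, 0.95)`).
#' @param ld_block markers per LD block (1 = independent markers).
#' @param mutation_rate per-individual probability that a marker in a
#'   block deviates from its founder column (default 0.05).
#' @param n_qtl number of causal markers (default 5).
#' @param architecture `"major"` (few large effects), `"polygenic"`
#'   (many small effects; `n_qtl` is raised to at least `m/10`), or
#'   `"mixed"`.
#' @param gene_action gene-action name(s) from [dosage_models()] assigned
#'   to QTLs (recycled); default `"additive"`.
#' @param h2 target narrow-sense heritability in `[0, 1]` (default 0.5).
#' @param seed integer seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 265L, m = 6796L, ploidy = 4L,
                       freq_range = c(0.05, 0.95), ld_block = 1L,
                       mutation_rate = 0.05, n_qtl = 5L,
                       architecture = c("major", "polygenic", "mixed"),
                       gene_action = "additive", h2 = 0.5, seed) {
  architecture <- match.arg(architecture)
  if (missing(seed)) stop("`seed` is mandatory")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (n_qtl > m) stop("n_qtl must not exceed m")
  stopifnot(all(gene_action %in% dosage_models()))
  structure(list(n = as.integer(n), m = as.integer(m),
                 ploidy = as.integer(ploidy), freq_range = freq_range,
                 ld_block = as.integer(ld_block),
                 mutation_rate = mutation_rate, n_qtl = as.integer(n_qtl),
                 architecture = architecture, gene_action = gene_action,
                 h2 = h2, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate tetraploid genotype dosages
#'
#' Per marker, an alternate-allele frequency `p` is drawn uniformly from
#' `cfg$freq_range` and each individual's dosage is Binomial(ploidy, p).
#' With `ld_block > 1`, consecutive markers in a block share a founder
#' dosage column; each individual's call copies the founder except with
#' probability `mutation_rate`, where it is redrawn — giving positive
#' within-block LD. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [dosage_matrix()] with markers laid out on one synthetic
#'   chromosome; attribute `sim_p` stores the generating frequencies.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n; m <- cfg$m; phi <- cfg$ploidy
    block <- rep(seq_len(ceiling(m / cfg$ld_block)), each = cfg$ld_block)[seq_len(m)]
    p_block <- stats::runif(max(block), cfg$freq_range[1], cfg$freq_range[2])
    p <- p_block[block]
    v <- matrix(0, n, m)
    founder <- NULL; cur_block <- -1L
    for (i in seq_len(m)) {
      if (block[i] != cur_block) {
        founder <- stats::rbinom(n, phi, p[i])
        cur_block <- block[i]
        v[, i] <- founder
      } else {
        mut <- stats::runif(n) < cfg$mutation_rate
        col <- founder
        if (any(mut)) col[mut] <- stats::rbinom(sum(mut), phi, p[i])
        v[, i] <- col
      }
    }
    dimnames(v) <- list(sprintf("ind%03d", seq_len(n)),
                        sprintf("snp%05d", seq_len(m)))
    map <- data.frame(marker = colnames(v), chrom = "1",
                      pos = seq_len(m) * 100L, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
    d <- dosage_matrix(v, ploidy = phi, map = map)
    attr(d, "sim_p") <- p
    d
  })
}

#' Simulate phenotypes with controlled QTL architecture and heritability
#'
#' Chooses `n_qtl` causal markers among those with MAF >= 0.05, assigns
#' each an effect size and a gene action, and builds the true genetic
#' value `g_true = sum_q effect_q * code_q(dosage_q)` where `code_q` is
#' the 0-1 scaled effect function of the QTL's gene action (the same code
#' vectors the association models test, so a matched scan model is by
#' construction the best detector). Effect sizes: `"major"` draws
#' `|N(0,1)| + 0.5` (few, large); `"polygenic"` draws `N(0, 1/sqrt(q))`
#' (many, small); `"mixed"` gives half the QTL major-style and half
#' polygenic-style effects. Residual noise is scaled so the *expected*
#' heritability matches `cfg$h2`; the realized value
#' `var(g_true)/var(y)` is recorded, not assumed. `h2 = 0` zeroes the
#' genetic contribution; `h2 = 1` returns `y = g_true` exactly.
#'
#' @param d a [dosage_matrix()] from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return list with `y` (named phenotype vector) and `truth`
#'   (`sim_truth`: `qtl`, `effects`, `gene_action`, `g_true`,
#'   `realized_h2`).
#' @export
simulate_phenotypes <- function(d, cfg) {
  stopifnot(inherits(d, "dosage_matrix"), inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    p <- allele_freq(d)
    eligible <- which(pmin(p, 1 - p) >= 0.05)
    n_qtl <- cfg$n_qtl
    if (cfg$architecture == "polygenic")
      n_qtl <- max(n_qtl, ceiling(cfg$m / 10))
    if (length(eligible) < n_qtl)
      stop("not enough polymorphic markers (MAF >= 0.05) for the QTL count")
    qtl <- sort(sample(eligible, n_qtl))
    ga <- rep(cfg$gene_action, length.out = n_qtl)
    effects <- switch(cfg$architecture,
      major = (abs(stats::rnorm(n_qtl)) + 0.5) * sign(stats::rnorm(n_qtl)),
      polygenic = stats::rnorm(n_qtl, 0, 1 / sqrt(n_qtl)),
      mixed = {
        half <- n_qtl %/% 2
        c((abs(stats::rnorm(half)) + 0.5) * sign(stats::rnorm(half)),
          stats::rnorm(n_qtl - half, 0, 1 / sqrt(max(1, n_qtl - half))))
      })
    g_true <- rep(0, cfg$n)
    for (k in seq_len(n_qtl)) {
      codes <- if (cfg$ploidy == 4L) scalar_codes[[ga[k]]] else
        scalar_codes_diploid[[ga[k]]]
      if (is.null(codes)) { # factor-action QTL: one effect per class
        codes <- stats::runif(cfg$ploidy + 1L)
      }
      g_true <- g_true + effects[k] * codes[round(d$values[, qtl[k]]) + 1L]
    }
    vg <- stats::var(g_true)
    if (cfg$h2 == 0) {
      g_true <- rep(0, cfg$n)
      y <- stats::rnorm(cfg$n)
    } else if (cfg$h2 == 1) {
      if (vg == 0) stop("h2 = 1 with zero genetic variance")
      y <- g_true
    } else {
      if (vg == 0) stop("zero genetic variance; increase n_qtl or MAF range")
      ve <- vg * (1 - cfg$h2) / cfg$h2
      y <- g_true + stats::rnorm(cfg$n, 0, sqrt(ve))
    }
    names(y) <- sample_ids(d)
    vy <- stats::var(y)
    truth <- structure(list(qtl = marker_ids(d)[qtl], effects = effects,
                            gene_action = ga,
                            g_true = stats::setNames(g_true, sample_ids(d)),
                            realized_h2 = if (vy > 0) stats::var(g_true) / vy
                            else 0),
                       class = "sim_truth")
    list(y = y, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d QTL, realized h2 = %.3f\n",
              length(x$qtl), x$realized_h2))
  invisible(x)
}

#' Oracle weights from simulated truth
#'
#' Builds the best-case weight vector an association scan could hope to
#' deliver: `|effect|` at the causal markers, `floor_eps` elsewhere. Used
#' as the upper reference configuration in weighted-GBLUP benchmarks.
#'
#' @param d the simulated [dosage_matrix()].
#' @param truth the matching `sim_truth`.
#' @param floor_eps weight for non-causal markers.
#' @param normalization passed to [weight_vector()].
#' @return a [weight_vector()] tagged `oracle:true-effects`.
#' @export
oracle_weights <- function(d, truth, floor_eps = 1e-6,
                           normalization = "mean_one") {
  stopifnot(inherits(truth, "sim_truth"))
  w <- stats::setNames(rep(floor_eps, ncol(d$values)), marker_ids(d))
  w[truth$qtl] <- pmax(abs(truth$effects), floor_eps)
  weight_vector(w, source = "oracle:true-effects",
                normalization = normalization)
}

#' Write a simulated dataset to disk
#'
#' Emits the genotypes as CSV and VCF, the phenotype CSV, and the
#' simulation truth as JSON.
#'
#' @param d,y,truth outputs of [simulate_genotypes()] /
#'   [simulate_phenotypes()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisible named vector of the paths written.
#' @export
write_simulation <- function(d, y, truth, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genotypes_csv = file.path(dir, paste0(prefix, "_genotypes.csv")),
    map_csv = file.path(dir, paste0(prefix, "_map.csv")),
    genotypes_vcf = file.path(dir, paste0(prefix, "_genotypes.vcf")),
    phenotypes_csv = file.path(dir, paste0(prefix, "_phenotypes.csv")),
    truth_json = file.path(dir, paste0(prefix, "_truth.json")))
  write_dosage_csv(d, paths["genotypes_csv"], paths["map_csv"])
  write_vcf_dosage(d, paths["genotypes_vcf"])
  write_phenotypes(y, paths["phenotypes_csv"], trait = "sim_trait")
  jsonlite::write_json(list(qtl = truth$qtl, effects = truth$effects,
                            gene_action = truth$gene_action,
                            g_true = as.list(truth$g_true),
                            realized_h2 = truth$realized_h2),
                       paths["truth_json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
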