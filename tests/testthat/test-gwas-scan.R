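test_that("gene-action design codes reproduce the published coding table", {
  dos <- 0:4
  expect_equal(as.numeric(design_columns("additive", dos)),
               c(0, 0.25, 0.50, 0.75, 1.00))
  expect_equal(as.numeric(design_columns("diplo-additive", dos)),
               c(0, 0.5, 0.5, 0.5, 1))
  expect_equal(as.numeric(design_columns("1-dom-ref", dos)), c(1, 1, 1, 1, 0))
  expect_equal(as.numeric(design_columns("2-dom-ref", dos)), c(1, 1, 1, 0, 0))
  expect_equal(as.numeric(design_columns("1-dom-alt", dos)), c(0, 1, 1, 1, 1))
  expect_equal(as.numeric(design_columns("2-dom-alt", dos)), c(0, 0, 1, 1, 1))
  expect_error(design_columns("dominance", dos), "unknown dosage model")
})

test_that("factor models build observed-class indicator blocks with correct df", {
  dos <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)
  Mg <- design_columns("general", dos)
  expect_equal(ncol(Mg), 4L)             # 5 classes observed -> 4 df
  Md <- design_columns("diplo-general", dos)
  expect_equal(ncol(Md), 2L)             # homA / het / homB -> 2 df
  expect_equal(as.numeric(Md[, 1]), as.numeric(dos %in% 1:3))
  expect_equal(as.numeric(Md[, 2]), as.numeric(dos == 4))
  # rare class absorbed into baseline: dosage 4 seen once with min_class 2
  dos2 <- c(0, 0, 0, 2, 2, 2, 4)
  expect_equal(ncol(design_columns("general", dos2, min_class = 2)), 1L)
  # no contrast at a constant marker
  expect_equal(ncol(design_columns("general", rep(2, 8))), 0L)
  expect_equal(ncol(design_columns("additive", rep(3, 8))), 0L)
})

test_that("a perfectly additive marker reaches the capped score", {
  withr::with_seed(201, {
    v <- replicate(10, sample(0:4, 40, TRUE))
    v[, 1] <- sample(0:4, 40, TRUE)
  })
  d <- dosage_matrix(v, ploidy = 4)
  y <- d$values[, 1] / 4  # zero-noise additive signal
  s <- gwas_scan(d, y, K = NULL, models = "additive")
  expect_equal(unname(s$scores[1, "additive"]), 300)
})

test_that("monomorphic markers are skipped with reason 'no contrast'", {
  v <- cbind(rep(2, 20), withr::with_seed(202, sample(0:4, 20, TRUE)))
  d <- dosage_matrix(v, ploidy = 4)
  y <- withr::with_seed(203, rnorm(20))
  s <- gwas_scan(d, y, K = NULL, models = c("additive", "general"))
  expect_true(all(is.na(s$scores[1, ])))
  expect_true(all(s$reasons[1, ] == "no contrast"))
  expect_true(all(s$reasons[2, ] == "tested"))
})

test_that("diplo-additive on tetraploid data equals additive on the recoded matrix", {
  d <- filter_maf(simulate_genotypes(sim_config(n = 120, m = 150, seed = 204)), 0.05)
  y <- withr::with_seed(205, rnorm(120))
  K <- vanraden_grm(d)
  s4 <- gwas_scan(d, y, K, models = "diplo-additive")
  s2 <- gwas_scan(pseudodiploid_recode(d), y, K, models = "additive")
  expect_equal(unname(s4$scores[, "diplo-additive"]),
               unname(s2$scores[, "additive"]), tolerance = 1e-8)
})

test_that("scores_to_weights maps scores to floored weights in marker order", {
  d <- dosage_matrix(withr::with_seed(206, replicate(3, sample(0:4, 30, TRUE))),
                     ploidy = 4)
  y <- withr::with_seed(207, rnorm(30))
  s <- gwas_scan(d, y, K = NULL, models = "additive")
  s$scores[, 1] <- c(1, 2, 3)  # fixed scores for the mapping contract
  wv <- scores_to_weights(s, "additive", normalization = "raw")
  expect_equal(unname(wv$w), c(1, 2, 3))
  expect_equal(wv$source, "gwas:additive")
  s$scores[, 1] <- c(0, 0, NA); s$reasons[3, 1] <- "no contrast"
  wu <- scores_to_weights(s, "additive", floor_eps = 1e-6)
  expect_equal(unname(wu$w / mean(wu$w)), rep(1, 3))  # no-information -> uniform
})

test_that("skipped markers keep their weight-slot ordering under permutation", {
  d <- filter_maf(simulate_genotypes(sim_config(n = 50, m = 40, seed = 208)), 0.05)
  y <- withr::with_seed(209, rnorm(50))
  s <- gwas_scan(d, y, K = NULL, models = "additive")
  w <- scores_to_weights(s, "additive", normalization = "raw")$w
  perm <- withr::with_seed(210, sample(ncol(d$values)))
  dp <- dosage_matrix(d$values[, perm], 4, d$map[perm, ])
  wp <- scores_to_weights(gwas_scan(dp, y, K = NULL, models = "additive"),
                          "additive", normalization = "raw")$w
  expect_equal(unname(wp), unname(w[perm]), tolerance = 1e-10)
})

test_that("weight correlations: identity, formula oracle, degenerate cases", {
  withr::with_seed(211, {
    a <- runif(10); b <- runif(10)
  })
  W <- weight_correlations(list(a = a, b = b, a2 = a))
  expect_equal(W["a", "a"], 1)
  expect_equal(W["a", "a2"], 1, tolerance = 1e-12)
  # direct covariance / sd oracle
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(W["a", "b"], r_oracle, tolerance = 1e-12)
  Wz <- weight_correlations(list(a = a, z = rep(1, 10)))
  expect_true(is.na(Wz["a", "z"]))
  withr::with_seed(212, {
    u <- runif(5000); v <- runif(5000)
  })
  expect_lt(abs(weight_correlations(list(u = u, v = v))["u", "v"]), 0.05)
  expect_error(weight_correlations(list(a = a)), "at least two")
})

test_that("kinship-corrected scan controls inflation under population structure", {
  # two differentiated subpopulations; phenotype drawn from the fitted
  # covariance model y ~ N(0, 2K + I), so calibrated p-values are the target
  withr::with_seed(213, {
    p1 <- runif(400, 0.1, 0.5); p2 <- pmin(p1 + runif(400, 0, 0.4), 0.95)
    v <- rbind(sapply(p1, function(p) rbinom(100, 4, p)),
               sapply(p2, function(p) rbinom(100, 4, p)))
  })
  d <- filter_maf(dosage_matrix(v, ploidy = 4), 0.02)
  K <- vanraden_grm(d)
  ev <- eigen(K$values, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(2 * ev$values, 0)))
  y <- withr::with_seed(214, as.numeric(L %*% rnorm(200)) + rnorm(200))
  s <- gwas_scan(d, y, K, models = "additive")
  pvals <- 10^(-s$scores[, "additive"])
  lambda_gc <- stats::median(stats::qchisq(pvals, 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, 1, lower.tail = FALSE)
  expect_gt(lambda_gc, 0.8)
  expect_lt(lambda_gc, 1.2)
})

test_that("scan output CSV is long format with reasons", {
  d <- filter_maf(simulate_genotypes(sim_config(n = 40, m = 20, seed = 215)), 0.05)
  y <- withr::with_seed(216, rnorm(40))
  s <- gwas_scan(d, y, K = NULL, models = c("additive", "general"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_scan(s, f)
  out <- data.table::fread(f)
  expect_equal(nrow(out), 2L * ncol(d$values))
  expect_true(all(c("marker_id", "model", "score", "reason") %in% names(out)))
})
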