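make_instance <- function(n, m, h2 = 0.5, seed) {
  cfg <- sim_config(n = n, m = m, n_qtl = min(m, 10L), h2 = h2, seed = seed)
  d <- filter_maf(simulate_genotypes(cfg), 0.05)
  sim <- simulate_phenotypes(d, cfg)
  list(d = d, y = sim$y, truth = sim$truth)
}

test_that("REML delta matches the dense grid-search oracle on a small instance", {
  inst <- make_instance(12, 20, seed = 101)
  K <- vanraden_grm(inst$d)
  vc <- reml_fit(inst$y, K)
  logd_oracle <- oracle_reml_grid(inst$y, K$values)
  # clip to the oracle's grid: boundary fits compare at the shared edge
  expect_lt(abs(max(min(log(vc$delta), 6), -6) - logd_oracle), 0.01)
  expect_equal(vc$delta, vc$sigma_e2 / vc$sigma_g2, tolerance = 1e-8)
  expect_equal(vc$h2, vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2), tolerance = 1e-8)
})

test_that("REML guards: constant phenotype, non-PSD kinship", {
  K <- vanraden_grm(random_panel(10, 15, seed = 102))
  expect_error(reml_fit(rep(1, 10), K), "constant")
  bad <- diag(10); bad[1, 1] <- -1
  expect_error(reml_fit(rnorm(10), bad), "positive semidefinite")
})

test_that("null phenotypes yield near-zero heritability estimates", {
  # scaled down from 50 reps at n = 500 to keep the default run fast;
  # the structured-K null consistency is unchanged
  d <- simulate_genotypes(sim_config(n = 300, m = 400, seed = 103))
  K <- vanraden_grm(filter_maf(d, 0.05))
  h2s <- withr::with_seed(104, vapply(1:25, function(i)
    reml_fit(rnorm(300), K)$h2, 0))
  expect_lt(mean(h2s), 0.05)
})

test_that("REML is invariant to rescaling the kinship", {
  inst <- make_instance(80, 100, seed = 105)
  K <- vanraden_grm(inst$d)
  vc1 <- reml_fit(inst$y, K)
  vc2 <- reml_fit(inst$y, K$values * 4)
  expect_equal(vc2$delta, 4 * vc1$delta, tolerance = 1e-4)
  expect_equal(vc2$reml_loglik, vc1$reml_loglik, tolerance = 1e-6)
  expect_equal(vc2$sigma_g2 * 4, vc1$sigma_g2, tolerance = 1e-4)
})

test_that("GBLUP: unrelated test individual predicts to the fixed-effect mean", {
  K <- diag(10)
  K[10, ] <- K[, 10] <- 0  # individual 10 unrelated to everyone
  K[10, 10] <- 1e-12       # (and to itself: zero genetic variance share)
  rownames(K) <- colnames(K) <- paste0("i", 1:10)
  y <- withr::with_seed(106, rnorm(9))
  vc <- structure(list(sigma_g2 = 1, sigma_e2 = 1, delta = 1, h2 = 0.5,
                       reml_loglik = 0, boundary = FALSE),
                  class = "variance_components")
  pred <- gblup_predict(y, K, 1:9, 10, vc)
  expect_equal(pred$gebv$gebv[pred$gebv$set == "test"], 0, tolerance = 1e-9)
})

test_that("GBLUP: infinite shrinkage drives all GEBVs to zero", {
  inst <- make_instance(30, 40, seed = 107)
  K <- vanraden_grm(inst$d)
  vc <- structure(list(sigma_g2 = 1, sigma_e2 = 1e12, delta = 1e12, h2 = 1e-12,
                       reml_loglik = 0, boundary = TRUE),
                  class = "variance_components")
  pred <- gblup_predict(inst$y[1:25], K, 1:25, 26:30, vc)
  expect_lt(max(abs(pred$gebv$gebv)), 1e-6)
})

test_that("RRBLUP matches the independent normal-equations closed form", {
  withr::with_seed(108, {
    Zm <- scale(matrix(rnorm(10 * 4), 10, 4), scale = FALSE)
    y <- rnorm(10)
  })
  lambda <- 2.5
  fit <- rrblup_solve(y, Zm, lambda = lambda)
  # oracle: m-dimensional normal equations (Zm'Zm + lambda I)^-1 Zm'(y - beta)
  X <- matrix(1, 10, 1)
  V <- tcrossprod(Zm) + lambda * diag(10)
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, y)))
  u_oracle <- solve(crossprod(Zm) + lambda * diag(4), crossprod(Zm, y - X %*% beta))
  expect_equal(unname(fit$u), as.numeric(u_oracle), tolerance = 1e-8)
})

test_that("RRBLUP symmetry and no-signal properties", {
  withr::with_seed(109, {
    z <- scale(matrix(rnorm(20 * 3), 20, 3), scale = FALSE)
    Zm <- cbind(z, z[, 1])  # duplicated marker column
    y <- rnorm(20)
  })
  fit <- rrblup_solve(y, Zm, lambda = 1)
  expect_equal(fit$u[1], fit$u[4], tolerance = 1e-10)

  # phenotype orthogonal to every centered marker column -> u = 0
  withr::with_seed(110, Z2 <- scale(matrix(rnorm(15 * 3), 15, 3), scale = FALSE))
  y2 <- residuals(lm(rnorm(15) ~ Z2))
  fit2 <- rrblup_solve(y2, Z2, lambda = 3)
  expect_lt(max(abs(fit2$u)), 1e-10)
})

test_that("RRBLUP and GBLUP GEBVs coincide on matched instances", {
  for (seed in c(111, 112)) {
    inst <- make_instance(40, 60, seed = seed)
    K <- vanraden_grm(inst$d)
    vc <- reml_fit(inst$y, K)
    pred <- gblup_predict(inst$y, K, seq_len(40), integer(0), vc)
    Zm <- scale(inst$d$values, center = 4 * allele_freq(inst$d), scale = FALSE)
    fit <- rrblup_solve(inst$y, Zm, lambda = vc$delta, c_scale = K$c_scale)
    expect_equal(pred$gebv$gebv, fit$gebv, tolerance = 1e-6)
  }
})

test_that("predictions are invariant to sample ordering", {
  inst <- make_instance(30, 50, seed = 113)
  K <- vanraden_grm(inst$d)
  vc <- reml_fit(inst$y[1:24], K$values[1:24, 1:24])
  p1 <- gblup_predict(inst$y[1:24], K, 1:24, 25:30, vc)
  perm <- withr::with_seed(114, sample(24))
  vc2 <- reml_fit(inst$y[perm], K$values[perm, perm])
  p2 <- gblup_predict(inst$y[perm], K, perm, 25:30, vc2)
  expect_equal(p1$gebv$gebv[p1$gebv$set == "test"],
               p2$gebv$gebv[p2$gebv$set == "test"], tolerance = 1e-6)
})

test_that("varcomp and gebv writers emit readable files", {
  inst <- make_instance(20, 30, seed = 115)
  K <- vanraden_grm(inst$d)
  vc <- reml_fit(inst$y, K)
  jf <- withr::local_tempfile(fileext = ".json")
  write_varcomp(vc, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$h2, vc$h2, tolerance = 1e-9)
  pred <- gblup_predict(inst$y[1:15], K, 1:15, 16:20, vc)
  cf <- withr::local_tempfile(fileext = ".csv")
  write_gebv(pred, cf)
  expect_equal(nrow(data.table::fread(cf)), 20)
})
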