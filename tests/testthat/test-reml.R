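# The AI-REML engine: exactness on balanced designs, agreement with direct
# dense likelihood evaluation, boundary behaviour, prediction, and AIC.

test_that("REML equals closed-form ANOVA estimators on balanced clonal data", {
  set.seed(5)
  q <- 40; m <- 3
  g <- rep(sprintf("g%02d", 1:q), each = m)
  y <- rep(rnorm(q, 0, 2), each = m) + rnorm(q * m, 0, 1.5)
  K <- diag(q); dimnames(K) <- list(unique(g), unique(g))
  ph <- data.frame(plant_id = paste0(g, "_", rep(1:m, q)), genotype_id = g,
                   block = "b1", row = seq_len(q * m), col = 1, T = y)
  d <- build_design(ph, "T", relationship_matrix(K, "pedigree"))
  d$block <- NULL
  fit <- clonal_blup(d, spatial = FALSE, include_pe = FALSE)
  ms <- anova(stats::lm(y ~ g))$`Mean Sq`
  sig_g <- (ms[1] - ms[2]) / m            # expected-mean-squares estimators
  expect_equal(fit$vc[["additive"]], sig_g, tolerance = 1e-6)
  expect_equal(fit$vc[["residual"]], ms[2], tolerance = 1e-6)
})

test_that("engine log-likelihood matches direct dense evaluation (<= 30 obs)", {
  st <- small_trial(n_fam = 4, gpf = 2, ramets = 3, seed = 9,
                    spatial = 1.5, rho_row = 0.4, rho_col = 0.3)
  d <- build_design(st$trial$pheno, "T", st$trial$kinship)
  expect_lte(length(d$y), 30)
  vc <- c(additive = 2.5, pe = 1.0, block = 0.5, spatial = 1.2, residual = 2.0)
  for (rho in list(c(0.4, 0.3), c(-0.2, 0.55))) {
    V <- oracle_build_V(d, vc, spatial = TRUE, rho = rho)
    expect_equal(reml_loglik(d, vc, spatial = TRUE, rho = rho),
                 oracle_reml_loglik(d$y, d$X, V), tolerance = 1e-8)
  }
  # non-spatial variant
  vc2 <- vc[c("additive", "pe", "block", "residual")]
  V2 <- oracle_build_V(d, vc2, spatial = FALSE)
  expect_equal(reml_loglik(d, vc2), oracle_reml_loglik(d$y, d$X, V2),
               tolerance = 1e-8)
})

test_that("accepted iterations never decrease the log-likelihood and the
           gradient vanishes at interior optima", {
  st <- small_trial(n_fam = 12, gpf = 5, ramets = 3, seed = 21,
                    spatial = 1.5, rho_row = 0.5, rho_col = 0.5)
  d <- build_design(st$trial$pheno, "T", st$trial$kinship)
  fit <- clonal_blup(d, spatial = TRUE)
  expect_true(all(diff(fit$convergence$trace$logL) >= -1e-8))
  interior <- !fit$boundary
  expect_lt(max(abs(fit$convergence$score[interior])), 1e-2 * length(d$y))
})

test_that("a zero additive variance lands on the boundary floor as theory
           predicts", {
  # under the null the REML variance estimate is a half-mixture: a point mass
  # at the boundary (about half the replicates) and small positive values
  n_rep <- 20
  at_floor <- logical(n_rep)
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    st <- small_trial(n_fam = 10, gpf = 5, ramets = 3, seed = 100 + r,
                      additive = 0, pe = 2, block = 0, residual = 2)
    d <- build_design(st$trial$pheno, "T", st$trial$kinship)
    d$block <- NULL
    fit <- clonal_blup(d, spatial = FALSE)
    at_floor[r] <- fit$boundary[["additive"]]
    est[r] <- fit$vc[["additive"]]
  }
  expect_gte(sum(at_floor), n_rep / 2)
  expect_lt(mean(est), 0.25 * 2)     # no systematic inflation
  expect_equal(stats::median(est), 0, tolerance = 1e-6)
})

test_that("EBV prediction matches multivariate-normal conditioning", {
  st <- small_trial(n_fam = 5, gpf = 2, ramets = 3, seed = 31)
  ph <- st$trial$pheno
  genos <- unique(ph$genotype_id)
  expect_equal(length(genos), 10)
  masked <- genos[7]
  train <- ph[ph$genotype_id != masked, ]
  d <- build_design(train, "T", st$trial$kinship)
  fit <- clonal_blup(d, spatial = FALSE)
  pred <- predict(fit, masked)

  K <- unclass(st$trial$kinship)
  V <- oracle_build_V(d, fit$vc, spatial = FALSE)
  k_t <- K[masked, d$genotype]
  expect_equal(pred$ebv,
               oracle_gls_ebv(d$y, d$X, V, k_t, fit$vc[["additive"]]),
               tolerance = 1e-6)

  # training targets reproduce the fit's own solutions
  expect_identical(predict(fit, fit$ebv$genotype[3])$ebv, fit$ebv$ebv[3])
  expect_error(predict(fit, "nobody"), "unknown genotype")
})

test_that("a genotype with no kinship ties to the data has EBV zero", {
  st <- small_trial(n_fam = 5, gpf = 2, ramets = 3, seed = 33)
  K <- unclass(st$trial$kinship)
  Kx <- rbind(cbind(K, loner = 0), loner = c(rep(0, nrow(K)), 1))
  colnames(Kx) <- rownames(Kx)
  d <- build_design(st$trial$pheno, "T",
                    relationship_matrix(Kx, "pedigree"))
  fit <- clonal_blup(d, spatial = FALSE)
  expect_equal(predict(fit, "loner")$ebv, 0)
})

test_that("EBVs sum to about zero under a centered genomic kinship", {
  st <- small_trial(n_fam = 8, gpf = 4, ramets = 3, seed = 35)
  mk <- gene_drop(st$ped, n_markers = 400, seed = 36)
  clones <- unique(st$trial$pheno$genotype_id)
  G <- stabilize(genomic_relationship(
    marker_matrix(unclass(mk)[clones, , drop = FALSE])))
  d <- build_design(st$trial$pheno, "T", G)
  fit <- clonal_blup(d, spatial = FALSE)
  ebv <- fit$ebv$ebv
  expect_lt(abs(sum(ebv)) / stats::sd(ebv), 0.05)
})

test_that("AIC counts covariance parameters and respects model nesting", {
  expect_equal(model_aic(list(logLik = -100, n_par = 5)), 210)

  # with both autocorrelations at zero the spatial model collapses onto the
  # non-spatial one (the spatial variance merges into the residual)
  st <- small_trial(n_fam = 6, gpf = 3, ramets = 3, seed = 41)
  d <- build_design(st$trial$pheno, "T", st$trial$kinship)
  vc_sp <- c(additive = 2, pe = 1, block = 0.4, spatial = 1.1, residual = 1.9)
  vc_ns <- c(additive = 2, pe = 1, block = 0.4, residual = 3.0)
  expect_equal(reml_loglik(d, vc_sp, spatial = TRUE, rho = c(0, 0)),
               reml_loglik(d, vc_ns), tolerance = 1e-6)
})
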