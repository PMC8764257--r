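# Heritability arithmetic and bivariate genetic correlations.

test_that("heritability reproduces the published worked examples", {
  # initial height, pedigree components
  expect_equal(round(heritability(15.41, pe = 11.50, residual = 14.04)$h2, 2),
               0.38)
  # initial carbon isotope composition, pedigree components
  expect_equal(round(heritability(0.11, pe = 0.08, residual = 0.47)$h2, 2),
               0.17)
  expect_equal(heritability(0, pe = 1, residual = 2)$h2, 0)
  expect_error(heritability(0, pe = 0, residual = 0), "positive")
})

test_that("heritability is scale invariant and the denominator is the
           genetic-plus-independent-residual variance", {
  h <- heritability(2.2, pe = 1.1, residual = 3.3)$h2
  for (c in c(0.01, 7, 1e4)) {
    expect_equal(heritability(2.2 * c, pe = 1.1 * c, residual = 3.3 * c)$h2, h)
  }
  # from a fit: block and spatial variances are excluded unless requested
  st <- small_trial(n_fam = 8, gpf = 4, ramets = 3, seed = 51, block = 2)
  d <- build_design(st$trial$pheno, "T", st$trial$kinship)
  fit <- clonal_blup(d, spatial = FALSE)
  vc <- fit$vc
  expect_equal(heritability(fit)$h2,
               vc[["additive"]] / (vc[["additive"]] + vc[["pe"]] + vc[["residual"]]))
  expect_lt(heritability(fit, full_denominator = TRUE)$h2, heritability(fit)$h2)
})

test_that("genetic correlation arithmetic and clamping", {
  expect_equal(genetic_correlation(0, 4, 9)$r, 0)
  expect_equal(genetic_correlation(6, 4, 9)$r, 1)
  expect_equal(genetic_correlation(3, 4, 9)$r, 0.5)
  out <- genetic_correlation(6.5, 4, 9)
  expect_true(out$clamped)
  expect_equal(out$r, 1)
  expect_error(genetic_correlation(1, 0, 9), "positive")
})

test_that("a duplicated trait has genetic correlation one", {
  st <- small_trial(n_fam = 10, gpf = 4, ramets = 3, seed = 61, block = 0)
  ph <- st$trial$pheno
  ph$T2 <- ph$T
  d1 <- build_design(ph, "T", st$trial$kinship); d1$block <- NULL
  d2 <- build_design(ph, "T2", st$trial$kinship); d2$block <- NULL
  bf <- fit_bivariate(d1, d2)
  expect_gt(bf$r_a$r, 0.99)
})

test_that("constraining both covariances to zero recovers the sum of the
           single-trait likelihoods", {
  st <- small_trial(n_fam = 8, gpf = 4, ramets = 3, seed = 63, block = 1)
  ph <- st$trial$pheno
  set.seed(64)
  ph$T2 <- 5 + 0.8 * (ph$T - mean(ph$T)) + rnorm(nrow(ph), 0, 1.5)
  d1 <- build_design(ph, "T", st$trial$kinship)
  d2 <- build_design(ph, "T2", st$trial$kinship)
  bf0 <- fit_bivariate(d1, d2, constrain = c("additive_cov", "residual_cov"))
  f1 <- clonal_blup(d1, spatial = FALSE)
  f2 <- clonal_blup(d2, spatial = FALSE)
  expect_equal(bf0$logLik, f1$logLik + f2$logLik,
               tolerance = 1e-6 * abs(f1$logLik + f2$logLik))
})

test_that("bivariate REML recovers a zero additive correlation on average", {
  # needs a reasonable number of families: the additive correlation is
  # identified through between-family covariance
  n_rep <- 20
  r_hat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sc <- simulation_scenario(
      n_parents = 40, n_families = 40, genotypes_per_family = 8, ramets = 3,
      grid_rows = 32, grid_cols = 30, block_size = 30, n_markers = 50,
      traits = list(
        list(name = "T1", mean = 10, additive = 4, pe = 2, block = 0,
             spatial = 0, residual = 4, rho_row = 0, rho_col = 0),
        list(name = "T2", mean = 5, additive = 3, pe = 1.5, block = 0,
             spatial = 0, residual = 5, rho_row = 0, rho_col = 0)),
      additive_correlation = 0)
    ped <- simulate_pedigree(sc, seed = 700 + r)
    trial <- simulate_trial(ped, sc, seed = 900 + r)
    d1 <- build_design(trial$pheno, "T1", trial$kinship); d1$block <- NULL
    d2 <- build_design(trial$pheno, "T2", trial$kinship); d2$block <- NULL
    r_hat[r] <- fit_bivariate(d1, d2)$r_a$r
  }
  expect_lt(abs(mean(r_hat)), 0.1)
})

test_that("pairwise correlation matrices assemble symmetric with unit
           diagonal", {
  pairs <- data.frame(trait1 = c("H", "H", "BD"),
                      trait2 = c("BD", "d13C", "d13C"),
                      r = c(0.8, 0.3, 0.45))
  m <- assemble_correlations(c("H", "BD", "d13C"), pairs)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(H = 1, BD = 1, d13C = 1))
  expect_equal(m["H", "BD"], 0.8)
  expect_error(assemble_correlations(c("H", "BD"), pairs), "not in")
})
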