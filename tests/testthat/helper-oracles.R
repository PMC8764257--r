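# Independent oracles used to verify the implementation. These deliberately
# avoid the package's own computational paths.

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# founders get unique allele labels, alleles are transmitted down the sorted
# pedigree, and the relationship between i and j is estimated as twice the
# probability that random alleles drawn from each are identical by descent
# (with the self-pair convention a_ii = 1 + F).
oracle_gene_drop_A <- function(ped, n_rep = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$id)
  si <- unname(pos[ped$sire]); di <- unname(pos[ped$dam])
  h1 <- vector("list", n); h2 <- vector("list", n)
  next_label <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      h1[[i]] <- rep.int(next_label, n_rep); next_label <- next_label + 1L
      h2[[i]] <- rep.int(next_label, n_rep); next_label <- next_label + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      h1[[i]] <- ifelse(pick, h1[[si[i]]], h2[[si[i]]])
      pick <- runif(n_rep) < 0.5
      h2[[i]] <- ifelse(pick, h1[[di[i]]], h2[[di[i]]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        f_self <- 0.25 * (2 + 2 * mean(h1[[i]] == h2[[i]]))
        A[i, i] <- 2 * f_self
      } else {
        kin <- 0.25 * (mean(h1[[i]] == h1[[j]]) + mean(h1[[i]] == h2[[j]]) +
                         mean(h2[[i]] == h1[[j]]) + mean(h2[[i]] == h2[[j]]))
        A[i, j] <- A[j, i] <- 2 * kin
      }
    }
  }
  A
}

# Direct dense evaluation of the REML log-likelihood (textbook formula,
# determinants via determinant()).
oracle_reml_loglik <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# Brute-force separable AR1 correlation by double loop.
oracle_spatial <- function(rows, cols, rho_row, rho_col) {
  n <- length(rows)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- rho_row^abs(rows[i] - rows[j]) * rho_col^abs(cols[i] - cols[j])
    }
  }
  S
}

# Hand-computed one-way ANOVA F from sums of squares.
oracle_anova_F <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  k <- length(g); n <- length(values)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# GLS / multivariate-normal conditioning oracle for breeding values of a
# masked genotype: E[a_t | y] = sig_a * K[t, obs] V^{-1} (y - X beta_hat).
oracle_gls_ebv <- function(y, X, V, k_t_obs, sig_a) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  drop(sig_a * k_t_obs %*% Vi %*% (y - X %*% beta))
}

# Dense covariance matrix of the univariate clonal model, built by loops,
# independent of the package's term machinery.
oracle_build_V <- function(design, vc, spatial = FALSE, rho = c(0, 0),
                           include_pe = TRUE) {
  n <- length(design$y)
  K <- unclass(design$kinship)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- vc[["additive"]] * K[design$genotype[i], design$genotype[j]]
      if (include_pe && design$genotype[i] == design$genotype[j])
        V[i, j] <- V[i, j] + vc[["pe"]]
      if (!is.null(design$block) && "block" %in% names(vc) &&
          design$block[i] == design$block[j])
        V[i, j] <- V[i, j] + vc[["block"]]
      if (spatial)
        V[i, j] <- V[i, j] + vc[["spatial"]] *
          rho[1]^abs(design$row[i] - design$row[j]) *
          rho[2]^abs(design$col[i] - design$col[j])
      if (i == j) V[i, j] <- V[i, j] + vc[["residual"]]
    }
  }
  V
}

# Small clonal trial helper shared across tests.
small_trial <- function(n_fam = 10, gpf = 5, ramets = 3, seed = 1,
                        additive = 4, pe = 2, block = 1, spatial = 0,
                        residual = 3, rho_row = 0, rho_col = 0,
                        grid_rows = NULL, grid_cols = NULL, mean = 10) {
  n_plants <- n_fam * gpf * ramets
  if (is.null(grid_rows)) grid_rows <- ceiling(sqrt(n_plants))
  if (is.null(grid_cols)) grid_cols <- ceiling(n_plants / grid_rows)
  sc <- simulation_scenario(
    n_parents = max(6, n_fam), n_families = n_fam,
    genotypes_per_family = gpf, ramets = ramets,
    grid_rows = grid_rows, grid_cols = grid_cols,
    block_size = max(10, ramets * gpf), n_markers = 50,
    traits = list(list(name = "T", mean = mean, additive = additive, pe = pe,
                       block = block, spatial = spatial, residual = residual,
                       rho_row = rho_row, rho_col = rho_col)))
  ped <- simulate_pedigree(sc, seed = seed)
  trial <- simulate_trial(ped, sc, seed = seed + 1000)
  list(scenario = sc, ped = ped, trial = trial)
}
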