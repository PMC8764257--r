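# Average-information REML for the individual-tree clonal mixed model.
#
# The engine works on the phenotypic covariance directly:
#   V(theta) = sum_k theta_k C_k  (+ sigma_xi^2 * S(rho_row, rho_col))
# where the C_k are constant symmetric matrices (kinship expansion, clone and
# block indicators, identity) and S is the separable AR1xAR1 correlation at
# the observed grid positions.  Updates are Newton steps with the average
# information matrix under Levenberg-Marquardt damping, with an EM-type
# multiplicative fallback; accepted steps never decrease the restricted
# log-likelihood.  Internally variances are estimated on the log scale,
# autocorrelations on the atanh scale, and covariance components on the
# natural scale constrained to keep their 2x2 blocks positive semi-definite.
# Variances are floored at 1e-8 times the phenotypic variance and flagged as
# boundary estimates when pinned there.

default_control <- function(max_iter = 200, tol_logL = 1e-8, tol_par = 1e-6,
                            verbose = FALSE) {
  list(max_iter = max_iter, tol_logL = tol_logL, tol_par = tol_par,
       verbose = verbose)
}

# ---- structured covariance terms -------------------------------------------
#
# Each covariance term is a list of "pieces" so that stacked multi-trait
# matrices (whose terms live in one quadrant) never touch their zero blocks:
#   full  : dense matrix covering all observations
#   sub   : dense block over index sets (ri, ci); mirrored when ri != ci
#   diag  : diagonal with values d (length n)
#   pairs : unit entries at (i_k, j_k) and (j_k, i_k)

term_full <- function(M) list(list(type = "full", M = M))
term_sub <- function(ri, ci, M)
  list(list(type = "sub", ri = ri, ci = ci, M = M, sym = !identical(ri, ci)))
term_diag <- function(d) list(list(type = "diag", d = d))
term_pairs <- function(i, j) list(list(type = "pairs", i = i, j = j))

# block-diagonal indicator of a grouping (e.g. clone or incomplete block)
# over the observation indices `idx`: unit entries at every ordered
# same-group pair, with group sums for fast matrix-vector products
term_group <- function(idx, labels) {
  g <- as.integer(factor(labels))
  members <- split(idx, g)
  pairs <- do.call(rbind, lapply(members, function(m) {
    k <- length(m)
    cbind(rep(m, each = k), rep.int(m, k))
  }))
  list(list(type = "group", idx = idx, g = g, pairs = pairs))
}

q_addV <- function(V, term, coef) {
  for (pc in term) {
    if (pc$type == "full") {
      V <- V + coef * pc$M
    } else if (pc$type == "sub") {
      V[pc$ri, pc$ci] <- V[pc$ri, pc$ci] + coef * pc$M
      if (pc$sym) V[pc$ci, pc$ri] <- V[pc$ci, pc$ri] + coef * t(pc$M)
    } else if (pc$type == "diag") {
      idx <- cbind(seq_along(pc$d), seq_along(pc$d))
      V[idx] <- V[idx] + coef * pc$d
    } else if (pc$type == "group") {
      V[pc$pairs] <- V[pc$pairs] + coef
    } else {
      V[cbind(pc$i, pc$j)] <- V[cbind(pc$i, pc$j)] + coef
      V[cbind(pc$j, pc$i)] <- V[cbind(pc$j, pc$i)] + coef
    }
  }
  V
}

q_trace <- function(P, term) {
  s <- 0
  for (pc in term) {
    if (pc$type == "full") {
      s <- s + sum(P * pc$M)
    } else if (pc$type == "sub") {
      v <- sum(P[pc$ri, pc$ci] * pc$M)
      s <- s + if (pc$sym) 2 * v else v
    } else if (pc$type == "diag") {
      s <- s + sum(P[cbind(seq_along(pc$d), seq_along(pc$d))] * pc$d)
    } else if (pc$type == "group") {
      s <- s + sum(P[pc$pairs])
    } else {
      s <- s + 2 * sum(P[cbind(pc$i, pc$j)])
    }
  }
  s
}

q_matvec <- function(term, v, n) {
  w <- numeric(n)
  for (pc in term) {
    if (pc$type == "full") {
      w <- w + drop(pc$M %*% v)
    } else if (pc$type == "sub") {
      w[pc$ri] <- w[pc$ri] + drop(pc$M %*% v[pc$ci])
      if (pc$sym) w[pc$ci] <- w[pc$ci] + drop(crossprod(pc$M, v[pc$ri]))
    } else if (pc$type == "diag") {
      w <- w + pc$d * v
    } else if (pc$type == "group") {
      gs <- rowsum(v[pc$idx], pc$g)
      w[pc$idx] <- w[pc$idx] + gs[pc$g, 1]
    } else {
      w[pc$i] <- w[pc$i] + v[pc$j]
      w[pc$j] <- w[pc$j] + v[pc$i]
    }
  }
  w
}

# Constant covariance terms for a univariate design.
model_cov_terms <- function(design, spatial = FALSE, include_pe = TRUE) {
  n <- length(design$y)
  K <- unclass(design$kinship)
  gidx <- match(design$genotype, rownames(K))
  C <- list(additive = term_full(K[gidx, gidx, drop = FALSE]))
  meta <- data.frame(name = "additive", type = "var",
                     b1 = NA_character_, b2 = NA_character_,
                     stringsAsFactors = FALSE)
  if (include_pe) {
    C$pe <- term_group(seq_len(n), design$genotype)
    meta <- rbind(meta, data.frame(name = "pe", type = "var",
                                   b1 = NA_character_, b2 = NA_character_))
  }
  if (!is.null(design$block)) {
    C$block <- term_group(seq_len(n), design$block)
    meta <- rbind(meta, data.frame(name = "block", type = "var",
                                   b1 = NA_character_, b2 = NA_character_))
  }
  sp <- NULL
  if (spatial) {
    if (is.null(design$row) || is.null(design$col) ||
        anyNA(design$row) || anyNA(design$col))
      stopf("spatial model requested but plants have missing layout positions")
    sp <- list(sigmas = list(spatial = list(
      idx = NULL,
      Drow = abs(outer(design$row, design$row, "-")),
      Dcol = abs(outer(design$col, design$col, "-")))))
  }
  C$residual <- term_diag(rep(1, n))
  meta <- rbind(meta, data.frame(name = "residual", type = "var",
                                 b1 = NA_character_, b2 = NA_character_))
  list(C = C, meta = meta, spatial = sp, n = n)
}

# ---- engine ----------------------------------------------------------------

# AR1xAR1 correlation (and rho-derivative) terms per spatial variance, at the
# current autocorrelations.
spatial_terms <- function(spatial, rho, derivatives = FALSE) {
  out <- list(S = list(), dSr = list(), dSc = list())
  for (sn in names(spatial$sigmas)) {
    sg <- spatial$sigmas[[sn]]
    Sr <- pow_int(rho[1], sg$Drow)
    Sc <- pow_int(rho[2], sg$Dcol)
    mk <- function(M) if (is.null(sg$idx)) term_full(M)
                      else term_sub(sg$idx, sg$idx, M)
    out$S[[sn]] <- mk(Sr * Sc)
    if (derivatives) {
      Er <- sg$Drow - 1; Er[Er < 0] <- 0
      Ec <- sg$Dcol - 1; Ec[Ec < 0] <- 0
      out$dSr[[sn]] <- mk(sg$Drow * pow_int(rho[1], Er) * Sc)
      out$dSc[[sn]] <- mk(sg$Dcol * pow_int(rho[2], Ec) * Sr)
    }
  }
  out
}

# Build V for linear parameters `lin` (named, including spatial sigma
# parameters) and autocorrelations `rho` (length 2 when spatial).
engine_build_V <- function(Clist, spatial, lin, rho, n, sp_terms = NULL) {
  V <- matrix(0, n, n)
  for (nm in names(Clist)) V <- q_addV(V, Clist[[nm]], lin[[nm]])
  if (!is.null(spatial)) {
    if (is.null(sp_terms)) sp_terms <- spatial_terms(spatial, rho)
    for (sn in names(spatial$sigmas))
      V <- q_addV(V, sp_terms$S[[sn]], lin[[sn]])
  }
  V
}

engine_logL <- function(y, X, V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  n <- length(y); p <- ncol(X)
  Viy <- backsolve(R, backsolve(R, y, transpose = TRUE))
  ViX <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
  ytPy <- sum(y * Viy) - sum(XtViy * beta)
  logdetV <- 2 * sum(log(diag(R)))
  logdetX <- 2 * sum(log(diag(cX)))
  logL <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetX + ytPy)
  list(logL = logL, R = R, beta = drop(beta), XtViX = XtViX)
}

engine_full <- function(y, X, V) {
  base <- engine_logL(y, X, V)
  if (is.null(base)) return(NULL)
  Vi <- chol2inv(base$R)
  ViX <- Vi %*% X
  W <- solve(base$XtViX)
  P <- Vi - ViX %*% tcrossprod(W, ViX)
  Py <- drop(P %*% y)
  c(base, list(P = P, Py = Py, W = W))
}

# Trace against P and product with Py of dV/d(internal parameter).
# Internal scales: variances psi = log sigma^2 (chain factor sigma^2);
# covariances gamma = atanh(cov / sqrt(v1 v2)), so a variance parameter that
# bounds a covariance picks up an extra 0.5 * cov * C_cov term; spatial
# autocorrelations phi = atanh(rho) (chain factor 1 - rho^2).
engine_dV_stats <- function(pname, Clist, spatial, lin, rho, meta, sp_terms,
                            P, Py, n) {
  sig_names <- if (is.null(spatial)) character(0) else names(spatial$sigmas)
  if (pname %in% names(Clist)) {
    if (meta$type[meta$name == pname] == "var") {
      tr <- lin[[pname]] * q_trace(P, Clist[[pname]])
      w <- lin[[pname]] * q_matvec(Clist[[pname]], Py, n)
      partners <- meta$name[meta$type == "cov" &
                              (meta$b1 == pname | meta$b2 == pname)]
      for (cv in partners) {
        tr <- tr + 0.5 * lin[[cv]] * q_trace(P, Clist[[cv]])
        w <- w + 0.5 * lin[[cv]] * q_matvec(Clist[[cv]], Py, n)
      }
      return(list(tr = tr, w = w))
    }
    i <- which(meta$name == pname)
    cap <- sqrt(lin[[meta$b1[i]]] * lin[[meta$b2[i]]])
    r_c <- if (cap > 0) lin[[pname]] / cap else 0
    coef <- cap * (1 - r_c^2)
    return(list(tr = coef * q_trace(P, Clist[[pname]]),
                w = coef * q_matvec(Clist[[pname]], Py, n)))
  }
  if (pname %in% sig_names) {
    return(list(tr = lin[[pname]] * q_trace(P, sp_terms$S[[pname]]),
                w = lin[[pname]] * q_matvec(sp_terms$S[[pname]], Py, n)))
  }
  if (pname %in% c("rho_row", "rho_col")) {
    which_r <- if (pname == "rho_row") 1L else 2L
    dS <- if (which_r == 1L) sp_terms$dSr else sp_terms$dSc
    chain <- 1 - rho[which_r]^2
    tr <- 0; w <- numeric(n)
    for (sn in sig_names) {
      tr <- tr + lin[[sn]] * q_trace(P, dS[[sn]])
      w <- w + lin[[sn]] * q_matvec(dS[[sn]], Py, n)
    }
    return(list(tr = chain * tr, w = chain * w))
  }
  stopf("unknown parameter '%s'", pname)
}

# internal <-> natural parameter maps
to_internal <- function(lin, phi, meta, floor_val) {
  v <- numeric(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    if (meta$type[i] == "var") {
      v[i] <- log(max(lin[[nm]], floor_val))
    } else {
      cap <- sqrt(lin[[meta$b1[i]]] * lin[[meta$b2[i]]])
      r_c <- if (cap > 0) lin[[nm]] / cap else 0
      v[i] <- atanh(max(min(r_c, 1 - 1e-10), -1 + 1e-10))
      v[i] <- max(min(v[i], 7), -7)
    }
  }
  c(stats::setNames(v, meta$name), phi)
}

to_natural <- function(theta_int, meta, floor_val, has_sp) {
  lin <- stats::setNames(vector("list", nrow(meta)), meta$name)
  for (i in which(meta$type == "var")) {
    nm <- meta$name[i]
    lin[[nm]] <- max(exp(min(theta_int[[nm]], 700)), floor_val)
  }
  for (i in which(meta$type == "cov")) {
    nm <- meta$name[i]
    gam <- max(min(theta_int[[nm]], 7), -7)
    lin[[nm]] <- tanh(gam) * sqrt(lin[[meta$b1[i]]] * lin[[meta$b2[i]]])
  }
  phi <- if (has_sp)
    pmin(pmax(unlist(theta_int[c("rho_row", "rho_col")]), -3), 3)
  else numeric(0)
  list(lin = lin, phi = phi)
}

#' @keywords internal
#' @noRd
reml_engine <- function(y, X, Clist, meta, spatial = NULL, start,
                        control = default_control()) {
  n <- length(y)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  floor_val <- 1e-8 * vy
  log_floor <- log(floor_val)

  has_sp <- !is.null(spatial)
  lin_names <- meta$name
  lin <- lapply(as.list(start$lin[lin_names]), function(v) {
    if (is.finite(v)) v else vy / 3
  })
  names(lin) <- lin_names
  phi <- if (has_sp) stats::setNames(atanh(start$rho), c("rho_row", "rho_col"))
         else numeric(0)
  # round-trip through the internal scale to sanitize starts (variance floor,
  # covariance blocks positive semi-definite)
  nat0 <- to_natural(as.list(to_internal(lin, phi, meta, floor_val)),
                     meta, floor_val, has_sp)
  lin <- nat0$lin
  if (has_sp) phi <- stats::setNames(nat0$phi, c("rho_row", "rho_col"))
  par_names <- c(lin_names, if (has_sp) c("rho_row", "rho_col"))
  is_var <- stats::setNames(c(meta$type == "var", if (has_sp) c(FALSE, FALSE)),
                            par_names)

  get_rho <- function(phi) if (has_sp) tanh(phi) else NULL

  # light evaluation (one Cholesky) for line-search candidates; an accepted
  # point is upgraded with the explicit inverse and derivative structures
  eval_light <- function(lin, phi) {
    rho <- get_rho(phi)
    base <- engine_logL(y, X, engine_build_V(Clist, spatial, lin, rho, n))
    if (is.null(base)) return(NULL)
    c(base, list(rho = rho))
  }
  upgrade <- function(lt) {
    Vi <- chol2inv(lt$R)
    ViX <- Vi %*% X
    W <- solve(lt$XtViX)
    P <- Vi - ViX %*% tcrossprod(W, ViX)
    Py <- drop(P %*% y)
    sp_terms <- if (has_sp) spatial_terms(spatial, lt$rho, derivatives = TRUE)
                else NULL
    c(lt, list(P = P, Py = Py, W = W, sp_terms = sp_terms))
  }

  lt0 <- eval_light(lin, phi)
  if (is.null(lt0))
    stopf("phenotypic covariance not positive definite at the starting values")
  cur <- upgrade(lt0)

  trace <- data.frame(iter = 0L, logL = cur$logL)
  converged <- FALSE
  lambda <- 0
  n_iter <- 0L
  score <- NULL; AI <- NULL; free <- NULL
  trPdV <- NULL; ytPdVPy <- NULL

  derive <- function(pt) {
    np <- length(par_names)
    score <- numeric(np); trPdV <- numeric(np); ytPdVPy <- numeric(np)
    Wmat <- matrix(0, n, np)
    for (k in seq_len(np)) {
      st <- engine_dV_stats(par_names[k], Clist, spatial, lin, pt$rho, meta,
                            pt$sp_terms, pt$P, pt$Py, n)
      trPdV[k] <- st$tr
      Wmat[, k] <- st$w
      ytPdVPy[k] <- sum(pt$Py * st$w)
      score[k] <- -0.5 * (trPdV[k] - ytPdVPy[k])
    }
    AI <- 0.5 * crossprod(Wmat, pt$P %*% Wmat)
    dimnames(AI) <- list(par_names, par_names)
    names(score) <- par_names
    list(score = score, AI = AI, trPdV = trPdV, ytPdVPy = ytPdVPy)
  }

  for (iter in seq_len(control$max_iter)) {
    n_iter <- iter
    dv <- derive(cur)
    score <- dv$score; AI <- dv$AI
    trPdV <- dv$trPdV; ytPdVPy <- dv$ytPdVPy

    # active set: log-variances pinned at the floor whose score pushes them
    # further down are held fixed this iteration
    at_floor <- vapply(par_names, function(nm) {
      is_var[nm] && lin[[nm]] <= floor_val * 1.0001
    }, logical(1))
    held <- at_floor & score <= 0
    free <- which(!held)

    theta_old <- to_internal(lin, phi, meta, floor_val)

    # Newton decrement: the improvement the quadratic model still predicts.
    # When it is negligible the optimum has been reached even if correlated
    # parameters keep trading off in the last decimals.
    AIf0 <- AI[free, free, drop = FALSE]
    AIf0 <- AIf0 + diag(1e-10 * (abs(diag(AIf0)) + 1e-12), nrow(AIf0))
    delta0 <- tryCatch(drop(solve(AIf0, score[free])), error = function(e) NULL)
    if (!is.null(delta0) && iter > 1) {
      decrement <- 0.5 * sum(score[free] * delta0)
      if (is.finite(decrement) && decrement >= 0 &&
          decrement < 1e-6 * control$tol_logL * (abs(cur$logL) + 1)) {
        converged <- TRUE
        break
      }
    }

    propose <- function(delta, alpha) {
      theta_new <- theta_old
      theta_new[free] <- theta_old[free] + alpha * delta
      vn <- lin_names[meta$type == "var"]
      theta_new[names(theta_new) %in% vn] <-
        pmax(theta_new[names(theta_new) %in% vn], log_floor)
      nat <- to_natural(as.list(theta_new), meta, floor_val, has_sp)
      ev <- eval_light(nat$lin, nat$phi)
      if (is.null(ev)) NULL else list(lin = nat$lin, phi = nat$phi, pt = ev)
    }

    accepted <- NULL
    lam <- lambda
    for (try in seq_len(10)) {
      AIf <- AI[free, free, drop = FALSE]
      damp <- diag(pmax(abs(diag(AIf)), 1e-12) * lam, nrow(AIf)) +
        diag(1e-10, nrow(AIf))
      delta <- tryCatch(drop(solve(AIf + damp, score[free])),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        # cap any single internal-scale move at 3 units (a factor e^3 on a
        # variance) to keep steps inside a trust region
        big <- max(abs(delta))
        if (big > 3) delta <- delta * (3 / big)
        cand <- propose(delta, 1)
        if (!is.null(cand) && cand$pt$logL >= cur$logL - 1e-12) {
          # near the optimum a full Newton step can oscillate across it; when
          # gains turn tiny, also try the half step and keep the better
          if (cand$pt$logL - cur$logL <
              1e3 * control$tol_logL * (abs(cur$logL) + 1)) {
            half <- propose(delta, 0.5)
            if (!is.null(half) && half$pt$logL > cand$pt$logL) cand <- half
          }
          accepted <- cand
          lambda <- lam / 5
          if (lambda < 1e-8) lambda <- 0
          break
        }
      }
      lam <- if (lam <= 0) 1e-4 else lam * 10
    }
    if (is.null(accepted)) {
      # EM-type fallback: multiplicative fixed-point update for variances,
      # holding covariance correlations fixed so their blocks stay PSD
      lin_new <- lin
      for (k in seq_along(lin_names)) {
        if (meta$type[k] == "var" && trPdV[k] > 0) {
          ratio <- ytPdVPy[k] / trPdV[k]
          ratio <- min(max(ratio, 0.2), 5)
          lin_new[[lin_names[k]]] <- max(lin[[lin_names[k]]] * ratio, floor_val)
        }
      }
      for (i in which(meta$type == "cov")) {
        nm <- meta$name[i]
        cap_old <- sqrt(lin[[meta$b1[i]]] * lin[[meta$b2[i]]])
        r_c <- if (cap_old > 0) lin[[nm]] / cap_old else 0
        lin_new[[nm]] <- r_c * sqrt(lin_new[[meta$b1[i]]] * lin_new[[meta$b2[i]]])
      }
      ev <- eval_light(lin_new, phi)
      if (!is.null(ev) && ev$logL >= cur$logL - 1e-12) {
        accepted <- list(lin = lin_new, phi = phi, pt = ev)
      }
    }

    if (is.null(accepted)) {
      # no direction improves the likelihood: numerically at the optimum
      converged <- TRUE
      break
    }

    rel_logL <- abs(accepted$pt$logL - cur$logL) / (abs(cur$logL) + 1)
    theta_new <- to_internal(accepted$lin, accepted$phi, meta, floor_val)
    rel_par <- max(abs(theta_new - theta_old) /
                     pmax(abs(theta_old), 1))  # internal scales are O(1)

    lin <- accepted$lin
    phi <- accepted$phi
    cur <- upgrade(accepted$pt)
    trace <- rbind(trace, data.frame(iter = iter, logL = cur$logL))
    if (control$verbose)
      message(sprintf("iter %d logL %.6f lambda %.2g | %s", iter, cur$logL,
                      lambda,
                      paste(sprintf("%s=%.4g", par_names,
                                    c(unlist(lin), if (has_sp) get_rho(phi))),
                            collapse = " ")))

    if (rel_logL < control$tol_logL && rel_par < control$tol_par) {
      converged <- TRUE
      break
    }
  }

  if (!converged) {
    cnd <- simpleError(sprintf(
      "REML did not converge in %d iterations (last logL %.6f)",
      control$max_iter, cur$logL))
    cnd$trace <- trace
    stop(cnd)
  }

  # score/AI at the accepted optimum, for SEs and diagnostics
  dv <- derive(cur)
  score <- dv$score; AI <- dv$AI
  rho <- cur$rho

  at_floor <- vapply(par_names, function(nm) {
    is_var[nm] && lin[[nm]] <= floor_val * 1.0001
  }, logical(1))
  boundary <- stats::setNames(at_floor, par_names)
  free <- which(!boundary | score > 0)

  # SEs on the natural scale: the AI matrix lives in internal coordinates
  # (log-variance, atanh-correlation, atanh-autocorrelation), so transform
  # its inverse with the full Jacobian of the natural parameters
  np <- length(par_names)
  J <- matrix(0, np, np, dimnames = list(par_names, par_names))
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    if (meta$type[i] == "var") {
      J[nm, nm] <- lin[[nm]]
    } else {
      cap <- sqrt(lin[[meta$b1[i]]] * lin[[meta$b2[i]]])
      r_c <- if (cap > 0) lin[[nm]] / cap else 0
      J[nm, nm] <- cap * (1 - r_c^2)
      J[nm, meta$b1[i]] <- 0.5 * lin[[nm]]
      J[nm, meta$b2[i]] <- 0.5 * lin[[nm]]
    }
  }
  if (has_sp) {
    J["rho_row", "rho_row"] <- 1 - rho[1]^2
    J["rho_col", "rho_col"] <- 1 - rho[2]^2
  }
  se <- rep(NA_real_, np); names(se) <- par_names
  vcov_nat <- NULL
  if (length(free)) {
    AIf <- AI[free, free, drop = FALSE]
    covf <- tryCatch(solve(AIf), error = function(e) NULL)
    if (!is.null(covf)) {
      Jf <- J[free, free, drop = FALSE]
      vcov_nat <- Jf %*% covf %*% t(Jf)
      dimnames(vcov_nat) <- list(par_names[free], par_names[free])
      se[free] <- sqrt(pmax(diag(vcov_nat), 0))
    }
  }
  se[boundary] <- NA_real_
  # a covariance whose bounding variance is pinned has no meaningful SE
  for (i in which(meta$type == "cov")) {
    if (boundary[[meta$b1[i]]] || boundary[[meta$b2[i]]])
      se[meta$name[i]] <- NA_real_
  }

  theta <- stats::setNames(c(unlist(lin), if (has_sp) rho), par_names)

  list(theta = theta, se = se, boundary = boundary, logL = cur$logL,
       beta = cur$beta, W = cur$W, P = cur$P, Py = cur$Py,
       score = score, AI = AI, vcov_free = vcov_nat, free = free,
       iterations = n_iter, trace = trace, floor = floor_val,
       par_names = par_names, converged = converged)
}

# ---- user-facing fit -------------------------------------------------------

#' Fit the clonal individual-tree mixed model by AI-REML
#'
#' Fits \eqn{y = X\beta + Z a + Z\,pe + Z b + e} with additive genetic effects
#' `a ~ N(0, K sigma_a^2)` (K the pedigree A or genomic G relationship matrix),
#' clone-level non-additive effects `pe`, incomplete-block effects `b`, and a
#' residual that is either independent or, with `spatial = TRUE`, partitioned
#' into a separable AR1(row) x AR1(col) spatial component plus an independent
#' component.  ABLUP and GBLUP are the same fit with a different relationship
#' matrix injected through the design.
#'
#' @param design A `model_design` from [build_design()].
#' @param spatial Logical: include the autoregressive spatial residual.
#' @param include_pe Include the clone-level non-additive term (default TRUE;
#'   set FALSE for designs without clonal replication or for two-component
#'   genotype + residual models).
#' @param control List from `default_control()`-style arguments:
#'   `max_iter` (200), `tol_logL` (1e-8, relative log-likelihood change),
#'   `tol_par` (1e-6, relative parameter change), `verbose`.
#' @param start Optional named numeric vector of starting values
#'   (`additive`, `pe`, `block`, `spatial`, `residual`, `rho_row`, `rho_col`).
#'   Defaults: genetic and residual variances at var(y)/3, block and spatial
#'   at var(y)/10, autocorrelations at 0.1.
#' @return An object of class `clonal_blup`: variance components with
#'   approximate standard errors (from the inverse average-information
#'   matrix), REML log-likelihood, AIC, fixed effects, EBVs with
#'   prediction-error variances for every individual in the kinship matrix,
#'   clone/block/spatial solutions, and the convergence record.
#' @seealso [predict.clonal_blup()], [heritability()], [fit_bivariate()]
#' @export
clonal_blup <- function(design, spatial = FALSE, include_pe = TRUE,
                        control = default_control(), start = NULL) {
  stopifnot(inherits(design, "model_design"))
  tm <- model_cov_terms(design, spatial = spatial, include_pe = include_pe)
  vy <- stats::var(design$y)
  st_lin <- stats::setNames(rep(vy / 3, nrow(tm$meta)), tm$meta$name)
  if ("block" %in% tm$meta$name) st_lin["block"] <- vy / 10
  meta <- tm$meta
  if (spatial) {
    st_lin <- c(st_lin, spatial = vy / 10)
    meta <- rbind(meta, data.frame(name = "spatial", type = "var",
                                   b1 = NA_character_, b2 = NA_character_))
  }
  st_rho <- if (spatial) c(0.1, 0.1) else NULL
  if (!is.null(start)) {
    for (nm in intersect(names(start), names(st_lin))) st_lin[nm] <- start[nm]
    if (spatial && "rho_row" %in% names(start)) st_rho[1] <- start["rho_row"]
    if (spatial && "rho_col" %in% names(start)) st_rho[2] <- start["rho_col"]
  }
  eng <- reml_engine(design$y, design$X, tm$C, meta, tm$spatial,
                     start = list(lin = st_lin, rho = st_rho),
                     control = control)

  n_par <- length(eng$par_names)
  aic <- -2 * eng$logL + 2 * n_par

  K <- unclass(design$kinship)
  labels <- rownames(K)
  gidx <- match(design$genotype, labels)
  sig_a <- eng$theta[["additive"]]
  Tm <- K[, gidx, drop = FALSE]              # all labels x observations
  ebv <- drop(sig_a * (Tm %*% eng$Py))
  PT <- eng$P %*% t(Tm)
  pev <- sig_a * diag(K) - sig_a^2 * colSums(t(Tm) * PT)
  pev <- pmax(pev, 0)
  rel <- ifelse(sig_a * diag(K) > 0, pmax(1 - pev / (sig_a * diag(K)), 0), NA_real_)
  ebv_tab <- data.frame(genotype = labels, ebv = ebv, pev = pev,
                        reliability = rel, row.names = NULL,
                        stringsAsFactors = FALSE)

  pe_hat <- if (include_pe)
    eng$theta[["pe"]] * rowsum(eng$Py, design$genotype, reorder = TRUE)[, 1]
  else NULL
  block_hat <- if (!is.null(design$block))
    eng$theta[["block"]] * rowsum(eng$Py, design$block, reorder = TRUE)[, 1]
  else NULL
  xi_hat <- NULL
  if (spatial) {
    st <- spatial_terms(tm$spatial, eng$theta[c("rho_row", "rho_col")])
    xi_hat <- eng$theta[["spatial"]] *
      q_matvec(st$S$spatial, eng$Py, length(design$y))
  }
  eta_hat <- eng$theta[["residual"]] * eng$Py
  fitted <- design$y - eta_hat

  structure(list(
    design = design, spatial = spatial, include_pe = include_pe,
    vc = eng$theta, se = eng$se, boundary = eng$boundary,
    logLik = eng$logL, AIC = aic, n_par = n_par,
    beta = stats::setNames(eng$beta, colnames(design$X)),
    ebv = ebv_tab,
    solutions = list(pe = pe_hat, block = block_hat, spatial = xi_hat,
                     residual = eta_hat),
    fitted = fitted,
    convergence = list(iterations = eng$iterations, converged = eng$converged,
                       trace = eng$trace, score = eng$score,
                       floor = eng$floor),
    vcov_free = eng$vcov_free, free = eng$free, par_names = eng$par_names,
    Py = eng$Py
  ), class = "clonal_blup")
}

#' Evaluate the REML log-likelihood at fixed variance components
#'
#' Direct evaluation of the restricted likelihood for a design at
#' user-supplied components, without any optimisation. Useful for model
#' nesting checks and numerical verification.
#'
#' @param design A `model_design`.
#' @param vc Named numeric: `additive`, `pe`, `residual`, optionally `block`
#'   and `spatial`.
#' @param spatial Logical; when `TRUE`, `rho` must be supplied.
#' @param rho Length-2 numeric `(rho_row, rho_col)`.
#' @param include_pe Include the clone-level non-additive term.
#' @return The REML log-likelihood (scalar).
#' @export
reml_loglik <- function(design, vc, spatial = FALSE, rho = c(0, 0),
                        include_pe = TRUE) {
  tm <- model_cov_terms(design, spatial = spatial, include_pe = include_pe)
  lin <- as.list(vc[tm$meta$name])
  if (spatial) lin$spatial <- unname(vc[["spatial"]])
  ev <- engine_logL(design$y, design$X,
                    engine_build_V(tm$C, tm$spatial, lin,
                                   if (spatial) rho else NULL, tm$n))
  if (is.null(ev)) stopf("covariance matrix not positive definite at these components")
  ev$logL
}

# ---- methods ---------------------------------------------------------------

#' @export
print.clonal_blup <- function(x, ...) {
  cat(sprintf("Clonal mixed model (%s), trait '%s'\n",
              if (x$spatial) "AR1xAR1 spatial residual" else "independent residual",
              x$design$trait))
  cat(sprintf("  %d plants, %d genotypes, kinship: %s\n", length(x$design$y),
              length(unique(x$design$genotype)), attr(x$design$kinship, "kind")))
  cat(sprintf("  REML logLik %.4f, AIC %.4f, %d iterations\n",
              x$logLik, x$AIC, x$convergence$iterations))
  print(summary(x)$components)
  invisible(x)
}

#' @export
summary.clonal_blup <- function(object, ...) {
  comp <- data.frame(
    component = object$par_names,
    estimate = unname(object$vc[object$par_names]),
    se = unname(object$se[object$par_names]),
    boundary = unname(object$boundary[object$par_names]),
    row.names = NULL
  )
  h2 <- tryCatch(heritability(object), error = function(e) NULL)
  out <- list(components = comp, beta = object$beta, heritability = h2,
              logLik = object$logLik, AIC = object$AIC,
              trait = object$design$trait)
  class(out) <- "summary.clonal_blup"
  out
}

#' @export
print.summary.clonal_blup <- function(x, ...) {
  cat(sprintf("Trait '%s': REML logLik %.4f, AIC %.4f\n", x$trait, x$logLik, x$AIC))
  print(x$components)
  if (!is.null(x$heritability))
    cat(sprintf("Narrow-sense heritability: %.4f (SE %s)\n",
                x$heritability$h2,
                ifelse(is.na(x$heritability$se), "n/a",
                       sprintf("%.4f", x$heritability$se))))
  invisible(x)
}

#' @export
coef.clonal_blup <- function(object, ...) object$beta

#' @export
logLik.clonal_blup <- function(object, ...) {
  structure(object$logLik, df = object$n_par, class = "logLik")
}

#' Predict breeding values for target genotypes
#'
#' EBVs are solved through the relationship matrix, so targets may be
#' unphenotyped (e.g. parents, or genotypes whose records were masked): any
#' individual present in the kinship labels can be predicted. Phenotyped
#' genotypes reproduce the fit's own solutions.
#'
#' @param object A `clonal_blup` fit.
#' @param genotypes Character vector of target ids; default all kinship labels.
#' @param ... Unused.
#' @return Data frame with `genotype`, `ebv`, `pev`, `reliability`.
#' @export
predict.clonal_blup <- function(object, genotypes = NULL, ...) {
  tab <- object$ebv
  if (is.null(genotypes)) return(tab)
  unknown <- setdiff(genotypes, tab$genotype)
  if (length(unknown))
    stopf("unknown genotype id(s): %s", paste(utils::head(unknown, 5), collapse = ", "))
  tab[match(genotypes, tab$genotype), , drop = FALSE]
}

#' @export
fitted.clonal_blup <- function(object, ...) object$fitted

#' @export
residuals.clonal_blup <- function(object, ...) object$solutions$residual

#' Diagnostic plot of a clonal mixed-model fit
#'
#' Left: estimated spatial residual surface over the trial grid (or fitted vs
#' observed when the model has no spatial term). Right: EBV distribution of
#' phenotyped genotypes.
#'
#' @param x A `clonal_blup` fit.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.clonal_blup <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  d <- x$design
  if (x$spatial && !is.null(x$solutions$spatial)) {
    nr <- max(d$row); nc <- max(d$col)
    z <- matrix(NA_real_, nr, nc)
    z[cbind(d$row, d$col)] <- x$solutions$spatial
    graphics::image(seq_len(nc), seq_len(nr), t(z), xlab = "column", ylab = "row",
                    main = "spatial residual", ...)
  } else {
    graphics::plot(x$fitted, d$y, xlab = "fitted", ylab = "observed",
                   main = "fitted vs observed", ...)
    graphics::abline(0, 1, lty = 2)
  }
  phen <- x$ebv$genotype %in% unique(d$genotype)
  graphics::hist(x$ebv$ebv[phen], main = "EBVs (phenotyped genotypes)",
                 xlab = "EBV", ...)
  invisible(x)
}

#' Akaike information criterion of a REML fit
#'
#' `AIC = -2 logL + 2 k` with `k` the number of estimated covariance
#' parameters (variances, covariances and autocorrelations).
#'
#' @param fit A `clonal_blup` or `bivariate_fit`.
#' @return AIC value.
#' @export
model_aic <- function(fit) {
  stopifnot(!is.null(fit$logLik), !is.null(fit$n_par))
  -2 * fit$logLik + 2 * fit$n_par
}
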