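# Locally sparse varying coefficient mixed model (LSVCMM).
#
# Per-taxon model on the CLR scale: y_ij = sum_k x_ik beta_k(t_j) + b_i +
# e_ij with a mouse random intercept b_i ~ N(0, sigma_b^2) (compound
# symmetry) and e_ij ~ N(0, sigma_e^2).  Coefficient functions are
# represented pointwise on the observed week grid.  The penalized
# objective couples an adaptive-lasso penalty on individual (coefficient,
# week) values -- giving exact local zeros -- with a squared-difference
# smoothness penalty across adjacent weeks.  Optimization alternates
# FISTA proximal-gradient steps on the coefficients with EM updates of
# the two variance components.
#
# All fitting runs on per-mouse sufficient statistics with optional
# cluster multiplicities, which makes the cluster bootstrap a re-weighted
# refit rather than a data rebuild.

#' Assemble a longitudinal design for one OTU
#'
#' @param clr a `clr_matrix` from [clr_transform()] (or a samples x OTUs
#'   numeric matrix).
#' @param meta sample metadata (`sample_id`, `mouse_id`, `genotype`, `sex`,
#'   `week`, `diagnosis`); covariates must be constant within mouse.
#' @param otu OTU identifier (column of the CLR matrix).
#' @param variant `"interaction"` (intercept, KO, OSCC, KO:OSCC, Female),
#'   `"genotype"` (intercept, KO, Female) or `"diagnosis"` (intercept,
#'   OSCC, Female).  Reference levels: WT, ED/CIS, Male.
#' @param weeks optional week grid; defaults to the sorted unique weeks in
#'   `meta`.
#' @return An object of class `lsvcmm_design`.
#' @export
build_design <- function(clr, meta, otu,
                         variant = c("interaction", "genotype", "diagnosis"),
                         weeks = NULL) {
  variant <- match.arg(variant)
  values <- if (inherits(clr, "clr_matrix")) clr$values else as.matrix(clr)
  if (!otu %in% colnames(values)) stop("OTU ", otu, " not in CLR matrix")
  meta <- as.data.frame(meta)
  meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  for (v in c("genotype", "sex", "diagnosis")) {
    bad <- tapply(meta[[v]], meta$mouse_id, function(z) length(unique(z)) > 1)
    if (any(bad)) stop("mouse with inconsistent ", v, " across visits: ",
                       paste(names(bad)[bad], collapse = ", "))
  }
  weeks <- weeks %||% sort(unique(meta$week))
  if (!all(meta$week %in% weeks)) stop("metadata weeks outside the grid")
  y <- values[, otu]
  ko <- as.numeric(meta$genotype == "KO")
  oscc <- as.numeric(meta$diagnosis == "OSCC")
  fem <- as.numeric(meta$sex == "F")
  X <- switch(variant,
              interaction = cbind("(Intercept)" = 1, KO = ko, OSCC = oscc,
                                  "KO:OSCC" = ko * oscc, Female = fem),
              genotype = cbind("(Intercept)" = 1, KO = ko, Female = fem),
              diagnosis = cbind("(Intercept)" = 1, OSCC = oscc, Female = fem))
  structure(list(y = as.numeric(y), X = X,
                 week_idx = match(meta$week, weeks), weeks = weeks,
                 mouse = factor(meta$mouse_id), otu = otu, variant = variant),
            class = "lsvcmm_design")
}

# --- sufficient statistics ------------------------------------------------

# Expand the design into per-mouse sufficient statistics for the
# vectorized coefficient beta (length P = K * n_weeks, week index fastest).
lsvcmm_suffstats <- function(design) {
  K <- ncol(design$X); nw <- length(design$weeks); P <- K * nw
  N <- length(design$y)
  Z <- matrix(0, N, P)
  for (k in seq_len(K))
    Z[cbind(seq_len(N), (k - 1L) * nw + design$week_idx)] <- design$X[, k]
  m_id <- as.integer(design$mouse)
  m <- nlevels(design$mouse)
  S_ZZ <- matrix(0, m, P * P)
  S_Zy <- matrix(0, m, P)
  S_m <- matrix(0, m, P)
  s_y <- numeric(m); s_yy <- numeric(m); n_i <- integer(m)
  for (i in seq_len(m)) {
    r <- which(m_id == i)
    Zi <- Z[r, , drop = FALSE]; yi <- design$y[r]
    S_ZZ[i, ] <- as.numeric(crossprod(Zi))
    S_Zy[i, ] <- as.numeric(crossprod(Zi, yi))
    S_m[i, ] <- colSums(Zi)
    s_y[i] <- sum(yi); s_yy[i] <- sum(yi^2); n_i[i] <- length(r)
  }
  coef_names <- colnames(design$X)
  list(S_ZZ = S_ZZ, S_Zy = S_Zy, S_m = S_m, s_y = s_y, s_yy = s_yy,
       n = n_i, m = m, K = K, nw = nw, P = P, N = N, Z = Z,
       coef_names = coef_names, weeks = design$weeks,
       mouse_levels = levels(design$mouse))
}

# Second-difference-free smoothness operator: T'T for first differences
# along the week grid, one block per coefficient.
smooth_penalty_matrix <- function(K, nw) {
  T1 <- diff(diag(nw))
  TT <- crossprod(T1)
  M <- matrix(0, K * nw, K * nw)
  for (k in seq_len(K)) {
    ix <- (k - 1L) * nw + seq_len(nw)
    M[ix, ix] <- TT
  }
  M
}

#' Control parameters for the LSVCMM optimizer
#'
#' @param max_outer maximum alternations between coefficient and variance
#'   updates.
#' @param tol relative objective-change tolerance for the outer loop.
#' @param max_inner maximum FISTA iterations per coefficient update.
#' @param inner_tol relative objective tolerance for FISTA.
#' @param var_em_iter EM iterations per variance update.
#' @return list of control parameters.
#' @export
lsvcmm_control <- function(max_outer = 100L, tol = 1e-8, max_inner = 500L,
                           inner_tol = 1e-10, var_em_iter = 5L) {
  list(max_outer = max_outer, tol = tol, max_inner = max_inner,
       inner_tol = inner_tol, var_em_iter = var_em_iter)
}

# Gaussian log-likelihood with compound-symmetric clusters, from
# per-mouse residual aggregates (sr = sum residual, srr = sum squared
# residual per cluster), with cluster multiplicities k.
cs_loglik <- function(sr, srr, n, k, s2b, s2e) {
  w <- s2b / (s2e + n * s2b)
  Nk <- sum(k * n)
  -0.5 * (Nk * log(2 * pi) +
            sum(k * (n * log(s2e) + log1p(n * s2b / s2e))) +
            (sum(k * srr) - sum(k * w * sr^2)) / s2e)
}

# Core penalized fit on sufficient statistics.  When relax = TRUE (the
# default for sparse fits), the final estimates are a relaxed refit:
# unpenalized GLS restricted to the selected support, which removes the
# soft-thresholding shrinkage bias while keeping the exact zeros.
lsvcmm_core <- function(ss, lambda_s, lambda_m, wvec, k = NULL,
                        beta_init = NULL, sigma_init = NULL,
                        fix_sigma_b = NULL, control = lsvcmm_control(),
                        relax = TRUE) {
  P <- ss$P
  k <- k %||% rep(1, ss$m)
  TT <- smooth_penalty_matrix(ss$K, ss$nw)
  beta <- beta_init %||% numeric(P)
  if (is.null(sigma_init)) {
    ybar_all <- sum(k * ss$s_y) / sum(k * ss$n)
    s2e <- max(sum(k * (ss$s_yy - 2 * ybar_all * ss$s_y +
                          ss$n * ybar_all^2)) / sum(k * ss$n), 1e-6)
    s2b <- s2e / 2
  } else {
    s2b <- sigma_init[1]^2
    s2e <- max(sigma_init[2]^2, 1e-10)
  }
  if (!is.null(fix_sigma_b)) s2b <- fix_sigma_b^2
  obj_old <- Inf; converged <- FALSE; iter <- 0L
  pen_l1 <- function(b) if (lambda_s > 0) lambda_s * sum(wvec * abs(b)) else 0

  resid_aggregates <- function(beta) {
    bb <- tcrossprod(beta)  # P x P
    srr <- ss$s_yy - 2 * as.numeric(ss$S_Zy %*% beta) +
      as.numeric(ss$S_ZZ %*% as.numeric(bb))
    sr <- ss$s_y - as.numeric(ss$S_m %*% beta)
    srr <- pmax(srr, 0)
    list(sr = sr, srr = srr)
  }

  for (iter in seq_len(control$max_outer)) {
    ## GLS quantities at current variances
    w <- s2b / (s2e + ss$n * s2b)
    kw <- k * w
    A <- (matrix(colSums(ss$S_ZZ * k), P, P) -
            crossprod(ss$S_m, ss$S_m * kw)) / s2e
    cvec <- (colSums(ss$S_Zy * k) - as.numeric(crossprod(ss$S_m, kw * ss$s_y))) / s2e
    H <- A + 2 * lambda_m * TT
    if (lambda_s == 0) {
      beta <- solve(H + diag(1e-10 * max(diag(H)), P), cvec)
    } else {
      L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
      th <- lambda_s * wvec / L
      bacc <- beta; bprev <- beta; tt <- 1
      f <- function(b) 0.5 * sum(b * (H %*% b)) - sum(cvec * b) + pen_l1(b)
      fo <- f(beta)
      for (it in seq_len(control$max_inner)) {
        g <- as.numeric(H %*% bacc) - cvec
        bnew <- soft_threshold(bacc - g / L, th)
        tnew <- (1 + sqrt(1 + 4 * tt^2)) / 2
        bacc <- bnew + ((tt - 1) / tnew) * (bnew - bprev)
        bprev <- bnew; tt <- tnew
        fn <- f(bnew)
        if (fn > fo) { bacc <- bnew; tt <- 1 }  # restart on non-monotone step
        if (abs(fo - fn) <= control$inner_tol * (abs(fo) + 1e-12)) { fo <- fn; break }
        fo <- fn
      }
      beta <- bprev
    }
    ## EM variance updates
    ra <- resid_aggregates(beta)
    for (em in seq_len(control$var_em_iter)) {
      denom <- s2e + ss$n * s2b
      bhat <- ss$n * s2b * (ra$sr / ss$n) / denom
      v <- s2b * s2e / denom
      if (is.null(fix_sigma_b)) s2b <- sum(k * (bhat^2 + v)) / sum(k)
      sse <- ra$srr - 2 * bhat * ra$sr + ss$n * bhat^2
      s2e <- max(sum(k * (sse + ss$n * v)) / sum(k * ss$n), 1e-10)
      if (!is.null(fix_sigma_b)) s2b <- fix_sigma_b^2
    }
    ll <- cs_loglik(ra$sr, ra$srr, ss$n, k, s2b, s2e)
    obj <- -ll + pen_l1(beta) + lambda_m * sum(beta * (TT %*% beta))
    if (is.finite(obj_old) &&
        abs(obj_old - obj) <= control$tol * (abs(obj_old) + 1e-12)) {
      converged <- TRUE; obj_old <- obj; break
    }
    obj_old <- obj
  }
  beta_pen <- beta
  ra_pen <- resid_aggregates(beta_pen)
  ll_pen <- cs_loglik(ra_pen$sr, ra_pen$srr, ss$n, k, s2b, s2e)
  if (relax && lambda_s > 0 && any(beta != 0)) {
    sup <- which(beta != 0)
    for (rx in seq_len(10L)) {
      w <- s2b / (s2e + ss$n * s2b)
      kw <- k * w
      A <- (matrix(colSums(ss$S_ZZ * k), P, P) -
              crossprod(ss$S_m, ss$S_m * kw)) / s2e
      cvec <- (colSums(ss$S_Zy * k) - as.numeric(crossprod(ss$S_m, kw * ss$s_y))) / s2e
      bS <- solve(A[sup, sup, drop = FALSE] +
                    diag(1e-10 * max(diag(A)), length(sup)), cvec[sup])
      bold <- beta
      beta <- numeric(P); beta[sup] <- bS
      ra <- resid_aggregates(beta)
      for (em in seq_len(control$var_em_iter)) {
        denom <- s2e + ss$n * s2b
        bhat <- ss$n * s2b * (ra$sr / ss$n) / denom
        v <- s2b * s2e / denom
        if (is.null(fix_sigma_b)) s2b <- sum(k * (bhat^2 + v)) / sum(k)
        sse <- ra$srr - 2 * bhat * ra$sr + ss$n * bhat^2
        s2e <- max(sum(k * (sse + ss$n * v)) / sum(k * ss$n), 1e-10)
        if (!is.null(fix_sigma_b)) s2b <- fix_sigma_b^2
      }
      if (max(abs(beta - bold)) < 1e-8) break
    }
  }
  ra <- resid_aggregates(beta)
  list(beta = beta, beta_penalized = beta_pen,
       sigma_b = sqrt(s2b), sigma_e = sqrt(s2e),
       loglik = cs_loglik(ra$sr, ra$srr, ss$n, k, s2b, s2e),
       loglik_penalized = ll_pen,
       objective = obj_old, converged = converged, n_iter = iter)
}

#' Fit a locally sparse varying coefficient mixed model
#'
#' Minimizes the penalized negative Gaussian log-likelihood with a mouse
#' random intercept (compound symmetry),
#' an adaptive-lasso penalty `lambda_sparsity * sum w_kj |beta_k(t_j)|`
#' (intercept unpenalized; weights `1/|beta_tilde|` from the unpenalized
#' fit, capped at 1e6) and a smoothness penalty
#' `lambda_smooth * sum_k sum_j (beta_k(t_{j+1}) - beta_k(t_j))^2`.
#' Soft thresholding yields exact zeros, i.e. local sparsity on the week
#' grid.  Reported estimates are a relaxed refit (unpenalized GLS on the
#' selected support), removing the soft-thresholding shrinkage bias while
#' keeping the exact zeros.
#'
#' @param design an `lsvcmm_design` from [build_design()].
#' @param lambda_sparsity,lambda_smooth nonnegative penalties.
#' @param adaptive_weights optional coefficient x week matrix of penalty
#'   weights; computed from the unpenalized fit when `NULL` and
#'   `lambda_sparsity > 0`.
#' @param fix_sigma_b optionally fix the random-intercept SD (e.g. 0 for a
#'   fixed-effects-only fit).
#' @param control see [lsvcmm_control()].
#' @return An object of class `lsvcmm` with components `beta`
#'   (coefficients x weeks), `sigma_b`, `sigma_e`, `penalty`, `loglik`,
#'   `df`, `sparsity_mask`, `converged`.  Non-convergence is flagged, not
#'   an error.
#' @export
fit_lsvcmm <- function(design, lambda_sparsity = 0, lambda_smooth = 0,
                       adaptive_weights = NULL, fix_sigma_b = NULL,
                       control = lsvcmm_control()) {
  stopifnot(inherits(design, "lsvcmm_design"))
  if (lambda_sparsity < 0 || lambda_smooth < 0) stop("penalties must be >= 0")
  if (length(unique(design$week_idx)) < 2) stop("need >= 2 observed weeks")
  ss <- lsvcmm_suffstats(design)
  wmat <- adaptive_weights
  if (is.null(wmat) && lambda_sparsity > 0) {
    base <- lsvcmm_core(ss, 0, 0, wvec = numeric(ss$P),
                        fix_sigma_b = fix_sigma_b, control = control)
    wmat <- adaptive_weight_matrix(base$beta, ss)
  }
  wvec <- if (is.null(wmat)) numeric(ss$P) else as.numeric(t(wmat))
  fit <- lsvcmm_core(ss, lambda_sparsity, lambda_smooth, wvec,
                     fix_sigma_b = fix_sigma_b, control = control)
  as_lsvcmm(fit, ss, design, c(lambda_sparsity, lambda_smooth), wmat,
            fix_sigma_b, control)
}

# weights matrix (K x nw) from an unpenalized coefficient vector
adaptive_weight_matrix <- function(beta_vec, ss) {
  B <- matrix(beta_vec, ss$K, ss$nw, byrow = TRUE)
  W <- pmin(1 / pmax(abs(B), 1e-6), 1e6)
  W[1, ] <- 0  # intercept unpenalized
  dimnames(W) <- list(ss$coef_names, paste0("w", ss$weeks))
  W
}

as_lsvcmm <- function(fit, ss, design, penalty, wmat, fix_sigma_b, control) {
  B <- matrix(fit$beta, ss$K, ss$nw, byrow = TRUE,
              dimnames = list(ss$coef_names, paste0("w", ss$weeks)))
  Bp <- matrix(fit$beta_penalized %||% fit$beta, ss$K, ss$nw, byrow = TRUE,
               dimnames = dimnames(B))
  structure(list(beta = B, beta_penalized = Bp,
                 sigma_b = fit$sigma_b, sigma_e = fit$sigma_e,
                 penalty = c(lambda_sparsity = penalty[1], lambda_smooth = penalty[2]),
                 loglik = fit$loglik, df = sum(fit$beta != 0),
                 ebic = NA_real_,
                 sparsity_mask = B == 0,
                 converged = fit$converged, n_iter = fit$n_iter,
                 weights = wmat, fix_sigma_b = fix_sigma_b,
                 control = control, design = design, suffstats = ss,
                 variant = design$variant, otu = design$otu),
            class = "lsvcmm")
}

#' @export
print.lsvcmm <- function(x, ...) {
  cat("LSVCMM fit (", x$variant, " variant) for ", x$otu, "\n", sep = "")
  cat("  sigma_b =", format(x$sigma_b, digits = 4),
      " sigma_e =", format(x$sigma_e, digits = 4),
      " ICC =", format(x$sigma_b^2 / (x$sigma_b^2 + x$sigma_e^2), digits = 3), "\n")
  cat("  penalty: lambda_sparsity =", format(x$penalty[1], digits = 4),
      " lambda_smooth =", format(x$penalty[2], digits = 4), "\n")
  cat("  nonzero coefficient values:", x$df, "of", length(x$beta),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
summary.lsvcmm <- function(object, ...) {
  print(object)
  cat("\nCoefficient functions (rows) over weeks (columns):\n")
  print(round(object$beta, 4))
  invisible(object)
}

#' @export
coef.lsvcmm <- function(object, ...) object$beta

#' @export
fitted.lsvcmm <- function(object, level = c("population", "mouse"), ...) {
  level <- match.arg(level)
  ss <- object$suffstats
  mu <- as.numeric(ss$Z %*% as.numeric(t(object$beta)))
  if (level == "mouse") {
    r <- object$design$y - mu
    sr <- tapply(r, object$design$mouse, sum)
    n <- tabulate(as.integer(object$design$mouse))
    bhat <- (n * object$sigma_b^2 / (object$sigma_e^2 + n * object$sigma_b^2)) * (sr / n)
    mu <- mu + bhat[as.integer(object$design$mouse)]
  }
  mu
}

#' @export
residuals.lsvcmm <- function(object, level = c("population", "mouse"), ...) {
  object$design$y - fitted(object, level = match.arg(level))
}

#' Simulate responses from a fitted LSVCMM
#'
#' Draws new responses at the observed design points from the fitted
#' Gaussian model (new random intercepts and residuals).
#'
#' @param object an `lsvcmm` fit.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.lsvcmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object, level = "population")
  m <- nlevels(object$design$mouse)
  id <- as.integer(object$design$mouse)
  out <- replicate(nsim, mu + rnorm(m, 0, object$sigma_b)[id] +
                     rnorm(length(mu), 0, object$sigma_e))
  as.data.frame(out)
}

#' Plot fitted coefficient functions
#'
#' @param x an `lsvcmm` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lsvcmm <- function(x, ...) {
  matplot(x$design$weeks, t(x$beta), type = "b", pch = 16, lty = 1,
          xlab = "week", ylab = "coefficient", ...)
  abline(h = 0, col = "grey70", lty = 2)
  legend("topleft", legend = rownames(x$beta), col = seq_len(nrow(x$beta)),
         lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
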