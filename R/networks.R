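# Conditional-dependence networks for zero-inflated compositions:
# modified CLR, truncated-Gaussian-copula latent correlation from
# Kendall's tau, nodewise-lasso neighborhood selection along a penalty
# path, and StARS stability tuning.  This is an in-package
# re-implementation of the SPRING-style pipeline (copula bridge +
# neighborhood selection), kept deliberately small and fully testable.

#' Modified CLR transform preserving exact zeros
#'
#' Nonzero relative abundances are log-transformed and centered by their
#' mean (the CLR of the nonzero part), then shifted so the minimum
#' transformed nonzero value equals `eps > 0`; zeros stay exactly 0.  On a
#' zero-free sample this is the CLR plus a constant shift.
#'
#' @param x nonnegative counts of one sample; total > 0.
#' @param eps positive offset of the minimum transformed nonzero value.
#' @return Numeric vector: 0 where `x == 0`, strictly positive elsewhere.
#' @export
mclr_transform <- function(x, eps = 1) {
  if (any(x < 0)) stop("negative counts")
  if (sum(x) <= 0) stop("all-zero sample")
  out <- numeric(length(x))
  nz <- x > 0
  v <- log(x[nz] / sum(x))
  v <- v - mean(v)
  out[nz] <- v + (eps - min(v))
  out
}

# Matrix-level mclr: per-sample CLR centering of the nonzero parts, then
# ONE global shift so every nonzero entry of the matrix exceeds 0 by eps.
# A global (rather than per-sample) shift keeps values comparable across
# samples, which the rank-based latent correlation relies on.
mclr_matrix <- function(counts, eps = 1) {
  V <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    if (sum(x) <= 0) stop("all-zero sample: ", rownames(counts)[i])
    nz <- x > 0
    v <- log(x[nz] / sum(x))
    V[i, nz] <- v - mean(v)
  }
  nzall <- counts > 0
  V[nzall] <- V[nzall] + (eps - min(V[nzall]))
  V
}

# --- truncated-copula Kendall bridge --------------------------------------

# Kendall's tau_a (ties from zeros counted in the denominator), via the
# tie-corrected tau_b returned by stats::cor.
kendall_tau_a <- function(x, y) {
  n <- length(x)
  n2 <- n * (n - 1) / 2
  tb <- suppressWarnings(cor(x, y, method = "kendall"))
  if (is.na(tb)) stop("constant vector: Kendall's tau undefined")
  ties <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  tb * sqrt((n2 - ties(x)) * (n2 - ties(y))) / n2
}

# Forward bridge: population Kendall tau of a truncated Gaussian copula
# pair with latent correlation r and truncation thresholds d1, d2
# (d = qnorm(zero proportion)).  Evaluated with a fixed local RNG state so
# the randomized quasi-Monte-Carlo integration is deterministic.
bridge_forward <- function(r, d1, d2, abseps = 1e-5) {
  if (!is.finite(d1) && !is.finite(d2)) return(2 * asin(r) / pi)
  s <- sqrt(2)
  S4a <- matrix(c(1, 0, 1 / s, -r / s,
                  0, 1, -r / s, 1 / s,
                  1 / s, -r / s, 1, -r,
                  -r / s, 1 / s, -r, 1), 4, 4)
  S4b <- matrix(c(1, r, 1 / s, r / s,
                  r, 1, r / s, 1 / s,
                  1 / s, r / s, 1, r,
                  r / s, 1 / s, r, 1), 4, 4)
  u <- c(-d1, -d2, 0, 0)
  with_local_seed(20260101, {
    -2 * as.numeric(mvtnorm::pmvnorm(upper = u, corr = S4a,
                                     algorithm = mvtnorm::GenzBretz(abseps = abseps))) +
      2 * as.numeric(mvtnorm::pmvnorm(upper = u, corr = S4b,
                                      algorithm = mvtnorm::GenzBretz(abseps = abseps)))
  })
}

# Invert the bridge for one (tau, d1, d2) by root finding on the exact
# forward function (monotone increasing in r).
bridge_inverse_exact <- function(tau, d1, d2, tol = 1e-6) {
  lo <- -0.999; hi <- 0.999
  flo <- bridge_forward(lo, d1, d2); fhi <- bridge_forward(hi, d1, d2)
  if (tau <= flo) return(lo)
  if (tau >= fhi) return(hi)
  uniroot(function(r) bridge_forward(r, d1, d2) - tau,
          c(lo, hi), f.lower = flo - tau, f.upper = fhi - tau,
          tol = tol)$root
}

# Interpolation table of the bridge over (r, pi0_1, pi0_2), built lazily
# once per session; estimation-path inversions interpolate monotonically
# in r and bilinearly in the zero proportions.
bridge_grid <- function() {
  g <- .longisal_cache$bridge_grid
  if (!is.null(g)) return(g)
  r_grid <- seq(-0.99, 0.99, length.out = 34)
  p_grid <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.65, 0.8)
  np <- length(p_grid)
  F <- array(NA_real_, c(length(r_grid), np, np))
  for (a in seq_len(np)) for (b in a:np) {
    d1 <- qnorm(p_grid[a]); d2 <- qnorm(p_grid[b])
    vals <- vapply(r_grid, bridge_forward, numeric(1), d1 = d1, d2 = d2,
                   abseps = 1e-4)
    F[, a, b] <- vals; F[, b, a] <- vals
  }
  g <- list(r = r_grid, p = p_grid, F = F)
  .longisal_cache$bridge_grid <- g
  g
}

bridge_inverse_interp <- function(tau, p1, p2) {
  g <- bridge_grid()
  w <- function(p) {
    p <- min(max(p, g$p[1]), g$p[length(g$p)])
    i <- findInterval(p, g$p, rightmost.closed = TRUE)
    i <- min(i, length(g$p) - 1L)
    c(i = i, t = (p - g$p[i]) / (g$p[i + 1] - g$p[i]))
  }
  w1 <- w(p1); w2 <- w(p2)
  i1 <- w1["i"]; t1 <- w1["t"]; i2 <- w2["i"]; t2 <- w2["t"]
  Fv <- (1 - t1) * (1 - t2) * g$F[, i1, i2] +
    t1 * (1 - t2) * g$F[, i1 + 1, i2] +
    (1 - t1) * t2 * g$F[, i1, i2 + 1] +
    t1 * t2 * g$F[, i1 + 1, i2 + 1]
  if (tau <= Fv[1]) return(g$r[1])
  if (tau >= Fv[length(Fv)]) return(g$r[length(Fv)])
  as.numeric(stats::approx(Fv, g$r, xout = tau, ties = "ordered")$y)
}

#' Latent correlation of two zero-inflated vectors
#'
#' Kendall's tau on the observed pairs is mapped to the latent Pearson
#' correlation of a truncated Gaussian copula via the bridge function,
#' numerically inverted.  Zero-free input reduces to the classical
#' `sin(pi * tau / 2)` bridge.
#'
#' @param x,y numeric vectors (zeros = structural absences); each needs
#'   >= 5 nonzero entries and must not be constant.
#' @param method `"interp"` (default; session-cached interpolation table)
#'   or `"exact"` (root finding on `mvtnorm` 4-dimensional normal CDFs,
#'   tolerance 1e-6).
#' @return Latent correlation clamped to `[-0.999, 0.999]`.
#' @export
latent_correlation <- function(x, y, method = c("interp", "exact")) {
  method <- match.arg(method)
  if (sum(x != 0) < 5 || sum(y != 0) < 5) stop("need >= 5 nonzero entries per vector")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) stop("constant vector")
  tau <- kendall_tau_a(x, y)
  p1 <- mean(x == 0); p2 <- mean(y == 0)
  r <- if (p1 == 0 && p2 == 0) {
    sin(pi * tau / 2)
  } else if (method == "exact") {
    bridge_inverse_exact(tau, qnorm(p1), qnorm(p2))
  } else {
    bridge_inverse_interp(tau, p1, p2)
  }
  min(max(r, -0.999), 0.999)
}

# Latent correlation matrix of a samples x taxa matrix, projected to
# positive semidefiniteness (eigenvalue clipping) with unit diagonal.
# All Kendall taus come from one C-level call; tau_b is tie-corrected to
# tau_a per pair before the bridge inversion.
latent_correlation_matrix <- function(X, method = "interp") {
  p <- ncol(X); n <- nrow(X)
  n2 <- n * (n - 1) / 2
  Tb <- suppressWarnings(cor(X, method = "kendall"))
  tie <- vapply(seq_len(p), function(j) {
    t <- table(X[, j]); sum(t * (t - 1) / 2)
  }, numeric(1))
  adj <- sqrt(outer(n2 - tie, n2 - tie)) / n2
  Ta <- Tb * adj
  p0 <- colMeans(X == 0)
  R <- diag(p)
  for (a in seq_len(p - 1)) for (b in (a + 1):p) {
    r <- if (p0[a] == 0 && p0[b] == 0) {
      sin(pi * Ta[a, b] / 2)
    } else if (method == "exact") {
      bridge_inverse_exact(Ta[a, b], qnorm(p0[a]), qnorm(p0[b]))
    } else {
      bridge_inverse_interp(Ta[a, b], p0[a], p0[b])
    }
    R[a, b] <- R[b, a] <- min(max(r, -0.999), 0.999)
  }
  eg <- eigen(R, symmetric = TRUE)
  if (any(eg$values < 0)) {
    lam <- pmax(eg$values, 1e-6)
    R <- eg$vectors %*% (lam * t(eg$vectors))
    D <- sqrt(diag(R))
    R <- R / tcrossprod(D)
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}

# --- neighborhood selection and StARS -------------------------------------

#' Neighborhood-selection graph path over a penalty sequence
#'
#' Nodewise L1 regressions on a latent correlation matrix; an edge is kept
#' when either endpoint selects the other (OR rule), signed by the
#' averaged regression coefficients.  Each nodewise lasso is solved
#' exactly through `glmnet` on the Cholesky factor of the correlation
#' matrix, whose Gram matrix reproduces the normal equations.
#'
#' @param R correlation matrix (positive semidefinite).
#' @param lambda_seq decreasing penalty sequence (on the scale of the
#'   correlation-matrix objective `0.5 b'R b - r'b + lambda |b|_1`).
#' @return list of signed adjacency matrices (0 / +1 / -1), one per
#'   lambda.
#' @export
graph_path <- function(R, lambda_seq) {
  p <- ncol(R)
  eg_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (eg_min < -1e-8) stop("correlation matrix is not positive semidefinite")
  if (is.unsorted(rev(lambda_seq))) stop("lambda_seq must be decreasing")
  U <- chol(R + diag(1e-8, p))
  nl <- length(lambda_seq)
  coefs <- array(0, c(p, p, nl))
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    fit <- glmnet::glmnet(U[, others, drop = FALSE], U[, j],
                          lambda = pmax(lambda_seq, 1e-10) / p,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-9)
    B <- as.matrix(fit$beta)
    # glmnet may drop trailing lambdas if the path saturates; pad by
    # repeating the last column
    if (ncol(B) < nl) B <- cbind(B, B[, rep(ncol(B), nl - ncol(B)), drop = FALSE])
    coefs[others, j, ] <- B[, seq_len(nl)]
  }
  out <- vector("list", nl)
  for (li in seq_len(nl)) {
    cf <- coefs[, , li]
    S <- (cf + t(cf)) / 2
    present <- (cf != 0) | (t(cf) != 0)              # OR rule
    A <- ifelse(present, ifelse(sign(S) != 0, sign(S), 1), 0)
    diag(A) <- 0
    dimnames(A) <- dimnames(R)
    out[[li]] <- A
  }
  out
}

#' StARS stability selection of the network penalty
#'
#' For each penalty, edge-selection instability is the mean over node
#' pairs of `2 p (1 - p)` with `p` the edge's selection frequency across
#' subsamples drawn without replacement (size `min(floor(10 sqrt(n)),
#' n - 1)` by default).  The selected penalty is the largest whose
#' monotonized instability is at most `beta_threshold`; the final graph is
#' fit on the full data at that penalty, with edge signs averaged over
#' subsamples.
#'
#' @param X samples x taxa data matrix (mclr-transformed abundances).
#' @param lambda_seq decreasing penalty sequence; defaults to 15 log-spaced
#'   values below the largest absolute latent correlation.
#' @param n_subsamples number of subsamples (>= 10).
#' @param subsample_size rows per subsample.
#' @param beta_threshold instability bound (default 0.05).
#' @param seed integer seed.
#' @param method latent-correlation inversion method.
#' @return An object of class `network_estimate`: `nodes`, signed `edges`
#'   data.frame, `adjacency`, `lambda_selected`, `instability_path`.
#' @export
stars_select <- function(X, lambda_seq = NULL, n_subsamples = 20L,
                         subsample_size = NULL, beta_threshold = 0.05,
                         seed = 1L, method = "interp") {
  if (n_subsamples < 10) stop("n_subsamples must be >= 10")
  n <- nrow(X); p <- ncol(X)
  b <- subsample_size %||% min(floor(10 * sqrt(n)), n - 1L)
  R_full <- latent_correlation_matrix(X, method = method)
  if (is.null(lambda_seq)) {
    lmax <- max(abs(R_full[upper.tri(R_full)]))
    lambda_seq <- exp(seq(log(lmax), log(max(lmax * 0.05, 1e-3)), length.out = 15))
  }
  nl <- length(lambda_seq)
  freq <- array(0, c(p, p, nl))
  sgn <- array(0, c(p, p, nl))
  set.seed(derive_seed(seed, 8L))
  for (s in seq_len(n_subsamples)) {
    rows <- sample.int(n, b)
    Rs <- latent_correlation_matrix(X[rows, , drop = FALSE], method = method)
    path <- graph_path(Rs, lambda_seq)
    for (li in seq_len(nl)) {
      freq[, , li] <- freq[, , li] + (path[[li]] != 0)
      sgn[, , li] <- sgn[, , li] + path[[li]]
    }
  }
  phat <- freq / n_subsamples
  ut <- upper.tri(diag(p))
  instability <- vapply(seq_len(nl), function(li) {
    ph <- phat[, , li][ut]
    mean(2 * ph * (1 - ph))
  }, numeric(1))
  mono <- cummax(instability)  # lambda_seq is decreasing: sup toward denser
  ok <- which(mono <= beta_threshold)
  if (length(ok)) {
    # StARS rule: densest graph whose monotonized instability stays <= beta
    sel <- max(ok)
  } else {
    warning("all instabilities above beta; selecting the densest penalty")
    sel <- nl
  }
  A_full <- graph_path(R_full, lambda_seq)[[sel]]
  S <- sgn[, , sel]
  edge_sign <- sign(S + t(S))
  A <- (A_full != 0) * ifelse(edge_sign != 0, edge_sign, A_full)
  dimnames(A) <- dimnames(R_full)
  idx <- which(A != 0 & ut, arr.ind = TRUE)
  edges <- data.frame(node1 = colnames(X)[idx[, 1]],
                      node2 = colnames(X)[idx[, 2]],
                      sign = A[idx], stringsAsFactors = FALSE)
  structure(list(nodes = colnames(X), edges = edges, adjacency = A,
                 lambda_selected = lambda_seq[sel], lambda_seq = lambda_seq,
                 instability_path = instability,
                 beta_threshold = beta_threshold,
                 n_subsamples = n_subsamples, subsample_size = b),
            class = "network_estimate")
}

#' @export
print.network_estimate <- function(x, ...) {
  cat("Network:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      "( lambda =", format(x$lambda_selected, digits = 4), ")\n")
  if (!is.null(x$genotype)) cat("  genotype:", x$genotype, " period:", x$period, "\n")
  invisible(x)
}

# Regress the Female indicator out of the nonzero mclr values of each
# taxon (confounder adjustment); zeros stay zero so the truncation
# structure used by the copula bridge is preserved.
adjust_sex <- function(M, female) {
  for (j in seq_len(ncol(M))) {
    nz <- M[, j] != 0
    if (sum(nz) > 2 && length(unique(female[nz])) > 1) {
      f <- female[nz]
      fit <- stats::lm.fit(cbind(1, f), M[nz, j])
      M[nz, j] <- mean(M[nz, j]) + fit$residuals
    }
  }
  M
}

#' Genotype- and period-specific conditional-dependence networks
#'
#' Aggregates counts to the requested rank, pools samples within each week
#' period for one genotype, filters taxa below 10% prevalence within the
#' pooled set, mclr-transforms, regresses sex out of the nonzero values,
#' and estimates a StARS-tuned network per period.
#'
#' @param table an [otu_count_table()].
#' @param rank `"family"` or `"genus"`.
#' @param genotype `"WT"` or `"KO"`.
#' @param prevalence_min prevalence filter within each pooled period.
#' @param periods list of week vectors (default 0-4, 8-12, 16-22).
#' @param min_samples periods with fewer samples are skipped with a
#'   warning.
#' @param ... passed to [stars_select()].
#' @return Named list of `network_estimate`s (one per period), each
#'   annotated with `genotype` and `period`.
#' @export
build_period_networks <- function(table, rank = c("family", "genus"),
                                  genotype = c("WT", "KO"),
                                  prevalence_min = 0.10,
                                  periods = list("0-4" = c(0, 4),
                                                 "8-12" = c(8, 12),
                                                 "16-22" = c(16, 22)),
                                  min_samples = 10L, ...) {
  rank <- match.arg(rank); genotype <- match.arg(genotype)
  agg <- aggregate_taxonomy(table, rank)
  meta <- agg$sample_meta
  in_geno <- meta$genotype == genotype
  if (!any(in_geno)) {
    warning("no samples for genotype ", genotype)
    return(list())
  }
  out <- list()
  for (pn in names(periods)) {
    sel <- in_geno & meta$week %in% periods[[pn]]
    if (sum(sel) < min_samples) {
      warning("period ", pn, " has ", sum(sel), " samples (< ", min_samples,
              "); skipped")
      next
    }
    counts <- agg$counts[sel, , drop = FALSE]
    keep <- colMeans(counts > 0) >= prevalence_min
    counts <- counts[, keep, drop = FALSE]
    M <- mclr_matrix(counts)
    M <- adjust_sex(M, as.numeric(meta$sex[sel] == "F"))
    net <- stars_select(M, ...)
    net$genotype <- genotype
    net$period <- pn
    out[[pn]] <- net
  }
  out
}

#' Classify edges as core, genotype-stable or period-specific
#'
#' @param networks list of `network_estimate`s covering the genotype x
#'   period cells (each annotated with `genotype` and `period`).
#' @return An object of class `differential_network_report`: per-edge
#'   presence matrix across cells and a `class` partition --- `core`
#'   (present in every cell), `genotype_stable_<G>` (all periods of
#'   exactly one genotype) or `period_specific`.
#' @export
compare_networks <- function(networks) {
  if (length(networks) < 2) stop("need >= 2 networks")
  cells <- vapply(networks, function(n)
    paste(n$genotype %||% "all", n$period %||% "all", sep = ":"), character(1))
  edge_key <- function(net) {
    if (!nrow(net$edges)) return(character(0))
    paste(pmin(net$edges$node1, net$edges$node2),
          pmax(net$edges$node1, net$edges$node2), sep = "--")
  }
  keys <- sort(unique(unlist(lapply(networks, edge_key))))
  pres <- matrix(FALSE, length(keys), length(networks),
                 dimnames = list(keys, cells))
  for (i in seq_along(networks)) pres[edge_key(networks[[i]]), i] <- TRUE
  genos <- vapply(networks, function(n) n$genotype %||% "all", character(1))
  cls <- character(length(keys))
  for (e in seq_along(keys)) {
    if (all(pres[e, ])) { cls[e] <- "core"; next }
    full_in <- vapply(unique(genos), function(g) all(pres[e, genos == g]),
                      logical(1))
    cls[e] <- if (sum(full_in) == 1)
      paste0("genotype_stable_", unique(genos)[full_in])
    else "period_specific"
  }
  structure(list(presence = pres, class = setNames(cls, keys)),
            class = "differential_network_report")
}

#' @export
print.differential_network_report <- function(x, ...) {
  cat("Differential network report:", nrow(x$presence), "edges over",
      ncol(x$presence), "cells\n")
  print(table(x$class))
  invisible(x)
}
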