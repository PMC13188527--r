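# Penalty selection (EBIC), cluster-bootstrap simultaneous bands and
# cross-OTU significance summaries for the LSVCMM.

#' Default penalty grids for EBIC selection
#'
#' Sparsity penalties are log-spaced from the smallest value that zeroes
#' every penalized coefficient down to a factor `1e-3` below it; the
#' smoothness grid spans none to strong smoothing on the scale of the GLS
#' quadratic.
#'
#' @param n_sparsity number of sparsity penalties.
#' @keywords internal
default_lambda_smooth <- function() c(0, 1, 4.64, 21.5, 100)

#' Select LSVCMM penalties by the extended BIC
#'
#' Fits every point of the (sparsity x smoothness) grid with shared
#' adaptive weights and returns the fit minimizing
#' `EBIC = -2 loglik + df log(N) + 2 gamma df log(P)` where `df` is the
#' number of nonzero coefficient values, `N` the number of observations
#' and `P` the number of coefficient values (coefficients x weeks).  Ties
#' go to the sparser model.
#'
#' @param design an `lsvcmm_design`.
#' @param lambda_sparsity optional vector of sparsity penalties; default
#'   `n_lambda` log-spaced values below the data-derived maximum.
#' @param lambda_smooth optional vector of smoothness penalties.
#' @param n_lambda size of the default sparsity grid.
#' @param gamma EBIC model-space weight (0 recovers BIC).
#' @param control see [lsvcmm_control()].
#' @return The selected `lsvcmm` fit, with `ebic` and an `ebic_table` of
#'   all grid points.
#' @export
ebic_select <- function(design, lambda_sparsity = NULL, lambda_smooth = NULL,
                        n_lambda = 20L, gamma = 0.5,
                        control = lsvcmm_control()) {
  stopifnot(inherits(design, "lsvcmm_design"))
  ss <- lsvcmm_suffstats(design)
  base <- lsvcmm_core(ss, 0, 0, wvec = numeric(ss$P), control = control)
  wmat <- adaptive_weight_matrix(base$beta, ss)
  wvec <- as.numeric(t(wmat))
  if (is.null(lambda_sparsity)) {
    # gradient of the GLS loss at beta = 0, at the unpenalized variances
    s2b <- base$sigma_b^2; s2e <- base$sigma_e^2
    w <- s2b / (s2e + ss$n * s2b)
    cvec <- (colSums(ss$S_Zy) - as.numeric(crossprod(ss$S_m, w * ss$s_y))) / s2e
    pen <- wvec > 0
    lmax <- 1.05 * max(abs(cvec[pen]) / wvec[pen])
    lambda_sparsity <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
  }
  lambda_smooth <- lambda_smooth %||% default_lambda_smooth()
  if (!length(lambda_sparsity) || !length(lambda_smooth)) stop("empty penalty grid")
  grid <- expand.grid(ls = sort(lambda_sparsity, decreasing = TRUE),
                      lm = lambda_smooth)
  best <- NULL; rows <- vector("list", nrow(grid))
  sigma0 <- c(base$sigma_b, base$sigma_e)
  for (im in seq_along(lambda_smooth)) {
    warm <- NULL
    for (is in seq_along(sort(lambda_sparsity, decreasing = TRUE))) {
      ls <- sort(lambda_sparsity, decreasing = TRUE)[is]
      lm <- lambda_smooth[im]
      fit <- lsvcmm_core(ss, ls, lm, wvec, beta_init = warm,
                         sigma_init = sigma0, control = control)
      warm <- fit$beta_penalized
      df <- sum(fit$beta != 0)
      ll <- fit$loglik_penalized %||% fit$loglik
      ebic <- -2 * ll + df * log(ss$N) + 2 * gamma * df * log(ss$P)
      g <- (im - 1L) * length(lambda_sparsity) + is
      rows[[g]] <- data.frame(lambda_sparsity = ls, lambda_smooth = lm,
                              df = df, loglik = ll, ebic = ebic,
                              converged = fit$converged)
      if (fit$converged &&
          (is.null(best) || ebic < best$ebic - 1e-12 ||
           (abs(ebic - best$ebic) <= 1e-12 && df < best$df))) {
        best <- list(fit = fit, ebic = ebic, df = df,
                     penalty = c(ls, lm))
      }
    }
  }
  if (is.null(best)) stop("no converged fit on the penalty grid")
  out <- as_lsvcmm(best$fit, ss, design, best$penalty, wmat, NULL, control)
  out$ebic <- best$ebic
  out$ebic_table <- do.call(rbind, rows)
  out$gamma <- gamma
  out
}

# Contrast definitions (linear combinations of coefficient functions) per
# model variant.  Reference levels: WT genotype, ED/CIS diagnosis.
lsvcmm_contrasts <- function(variant) {
  switch(variant,
         interaction = list(
           "KO-WT|ED/CIS"    = c(KO = 1),
           "KO-WT|OSCC"      = c(KO = 1, "KO:OSCC" = 1),
           "OSCC-ED/CIS|WT"  = c(OSCC = 1),
           "OSCC-ED/CIS|KO"  = c(OSCC = 1, "KO:OSCC" = 1)),
         genotype = list("KO-WT" = c(KO = 1)),
         diagnosis = list("OSCC-ED/CIS" = c(OSCC = 1)))
}

contrast_curve <- function(beta, contrast) {
  v <- numeric(ncol(beta))
  for (nm in names(contrast)) v <- v + contrast[[nm]] * beta[nm, ]
  v
}

#' Cluster-bootstrap simultaneous confidence bands for LSVCMM contrasts
#'
#' Resamples mice (clusters) with replacement, refits at the selected
#' penalty and adaptive weights, and builds sup-t simultaneous bands: for
#' each contrast `c(t)`, `estimate +/- q * SE_boot(t)` where `q` is the
#' `level` quantile across replicates of
#' `sup_t |(c_b(t) - c_hat(t)) / SE_boot(t)|`.  Weeks with a degenerate
#' (zero) bootstrap SE collapse to the point estimate with a warning.
#' The bands characterize the penalized estimator whose support EBIC
#' selected (bootstrap refits are not relaxed), so `estimate` here is the
#' penalized contrast; the fit's `beta` remains the relaxed coefficients.
#'
#' @param fit a converged `lsvcmm` fit.
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @param level simultaneous coverage level.
#' @return An object of class `lsvcmm_bands`: data.frame with columns
#'   `contrast`, `week`, `estimate`, `lower`, `upper`, `significant`.
#' @export
bootstrap_bands <- function(fit, n_boot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "lsvcmm"))
  if (n_boot < 200) stop("n_boot must be >= 200")
  if (!fit$converged) stop("refusing to bootstrap a non-converged fit")
  ss <- fit$suffstats
  wvec <- if (is.null(fit$weights)) numeric(ss$P) else as.numeric(t(fit$weights))
  contrasts <- lsvcmm_contrasts(fit$variant)
  weeks <- ss$weeks; nw <- ss$nw
  Bpen <- fit$beta_penalized %||% fit$beta
  est <- lapply(contrasts, function(ct) contrast_curve(Bpen, ct))
  boot <- array(NA_real_, c(n_boot, nw, length(contrasts)),
                dimnames = list(NULL, paste0("w", weeks), names(contrasts)))
  set.seed(derive_seed(seed, 6L))
  beta0 <- as.numeric(t(Bpen))
  sigma0 <- c(fit$sigma_b, fit$sigma_e)
  ctl <- fit$control
  ctl$max_outer <- min(ctl$max_outer, 50L)
  for (b in seq_len(n_boot)) {
    k <- tabulate(sample.int(ss$m, ss$m, replace = TRUE), ss$m)
    fb <- lsvcmm_core(ss, fit$penalty[1], fit$penalty[2], wvec, k = k,
                      beta_init = beta0, sigma_init = sigma0,
                      fix_sigma_b = fit$fix_sigma_b, control = ctl,
                      relax = FALSE)
    B <- matrix(fb$beta, ss$K, nw, byrow = TRUE,
                dimnames = list(ss$coef_names, NULL))
    for (ci in seq_along(contrasts))
      boot[b, , ci] <- contrast_curve(B, contrasts[[ci]])
  }
  out <- vector("list", length(contrasts))
  degenerate <- FALSE
  for (ci in seq_along(contrasts)) {
    se <- apply(boot[, , ci, drop = FALSE], 2, sd)
    ok <- se > 0
    if (!all(ok)) degenerate <- TRUE
    if (any(ok)) {
      dev <- abs(sweep(boot[, ok, ci, drop = FALSE], 2, est[[ci]][ok])) /
        rep(se[ok], each = n_boot)
      sup <- apply(matrix(dev, n_boot), 1, max)
      q <- as.numeric(quantile(sup, level, names = FALSE))
    } else q <- 0
    half <- ifelse(ok, q * se, 0)
    lower <- est[[ci]] - half
    upper <- est[[ci]] + half
    out[[ci]] <- data.frame(contrast = names(contrasts)[ci], week = weeks,
                            estimate = est[[ci]], lower = lower, upper = upper,
                            significant = lower > 0 | upper < 0,
                            stringsAsFactors = FALSE)
  }
  if (degenerate)
    warning("degenerate bootstrap SE at some weeks; band collapsed to the estimate there")
  bands <- do.call(rbind, out)
  rownames(bands) <- NULL
  attr(bands, "n_boot") <- n_boot
  attr(bands, "level") <- level
  attr(bands, "otu") <- fit$otu
  class(bands) <- c("lsvcmm_bands", "data.frame")
  bands
}

#' @export
print.lsvcmm_bands <- function(x, ...) {
  cat("Simultaneous", paste0(100 * attr(x, "level"), "%"),
      "bands (", attr(x, "n_boot"), "bootstrap replicates )\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Plot a contrast with its simultaneous band
#'
#' @param x an `lsvcmm_bands` object.
#' @param contrast contrast name (default first).
#' @param ... passed to plot.
#' @export
plot.lsvcmm_bands <- function(x, contrast = NULL, ...) {
  contrast <- contrast %||% x$contrast[1]
  d <- x[x$contrast == contrast, ]
  plot(d$week, d$estimate, type = "n", ylim = range(d$lower, d$upper, 0),
       xlab = "week", ylab = contrast, ...)
  polygon(c(d$week, rev(d$week)), c(d$lower, rev(d$upper)),
          col = "grey85", border = NA)
  lines(d$week, d$estimate, type = "b", pch = 16)
  abline(h = 0, lty = 2, col = "grey50")
  points(d$week[d$significant], d$estimate[d$significant], pch = 8, col = 2)
  invisible(x)
}

#' Summarize significance across OTUs, contrasts and weeks
#'
#' @param bands named list (by OTU) of `lsvcmm_bands`.
#' @return An object of class `significance_table`: long data.frame with
#'   one row per (otu, contrast, week) and an attribute `reported_otus` --
#'   OTUs with at least one significant (contrast, week) cell.
#' @export
summarize_significance <- function(bands) {
  if (!length(bands)) stop("no OTUs analyzed")
  if (is.null(names(bands)))
    names(bands) <- vapply(bands, function(b) attr(b, "otu") %||% NA_character_,
                           character(1))
  tab <- do.call(rbind, lapply(names(bands), function(o)
    cbind(otu = o, as.data.frame(bands[[o]]))))
  rownames(tab) <- NULL
  reported <- unique(tab$otu[tab$significant])
  attr(tab, "reported_otus") <- reported
  class(tab) <- c("significance_table", "data.frame")
  tab
}

#' @export
print.significance_table <- function(x, ...) {
  rep_otus <- attr(x, "reported_otus")
  cat("Significance table:", length(unique(x$otu)), "OTUs x",
      length(unique(x$contrast)), "contrasts x",
      length(unique(x$week)), "weeks\n")
  cat("Reported OTUs (>= 1 significant cell):",
      if (length(rep_otus)) paste(rep_otus, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Differential abundance analysis over many OTUs
#'
#' Runs [ebic_select()] and [bootstrap_bands()] for each OTU of a CLR
#' matrix and assembles the cross-OTU significance summary.
#'
#' @param clr a `clr_matrix` (or samples x OTUs matrix).
#' @param meta sample metadata.
#' @param variant model variant, see [build_design()].
#' @param otus OTUs to analyze (default all retained).
#' @param n_boot bootstrap replicates per OTU.
#' @param seed integer seed.
#' @param gamma EBIC gamma.
#' @param ... passed to [ebic_select()].
#' @return An object of class `lsvcmm_analysis`: list with `fits`,
#'   `bands` and `table` (a `significance_table`).
#' @export
lsvcmm <- function(clr, meta, variant = c("interaction", "genotype", "diagnosis"),
                   otus = NULL, n_boot = 1000L, seed = 1L, gamma = 0.5, ...) {
  variant <- match.arg(variant)
  values <- if (inherits(clr, "clr_matrix")) clr$values else as.matrix(clr)
  otus <- otus %||% colnames(values)
  fits <- list(); bands <- list()
  for (o in otus) {
    d <- build_design(clr, meta, o, variant)
    f <- ebic_select(d, gamma = gamma, ...)
    fits[[o]] <- f
    bands[[o]] <- bootstrap_bands(f, n_boot = n_boot, seed = seed + match(o, otus))
  }
  structure(list(fits = fits, bands = bands,
                 table = summarize_significance(bands), variant = variant),
            class = "lsvcmm_analysis")
}

#' @export
print.lsvcmm_analysis <- function(x, ...) {
  cat("LSVCMM analysis (", x$variant, " variant ), ",
      length(x$fits), " OTUs\n", sep = "")
  print(x$table)
  invisible(x)
}
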