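# Trajectory-shape analysis: per-(mouse, OTU) CLR trajectories on the
# week grid, functional PCA tolerant of missing visits, 99%-variance
# component selection, and per-genotype Lasso logistic prediction of
# diagnosis from the fPC scores.

#' Build centered per-(mouse, OTU) trajectories
#'
#' For every mouse and OTU, the CLR abundances over the week grid form a
#' vector with missing entries at unsampled weeks; each trajectory is
#' centered by its observed-entry mean, so trends rather than levels are
#' retained.  Mice with fewer than 2 visits are excluded with a warning.
#'
#' @param clr a `clr_matrix` or samples x OTUs matrix.
#' @param meta sample metadata.
#' @param weeks optional week grid (default observed weeks).
#' @return An object of class `trajectory_matrix`: list with `traj`
#'   (mouse x week x OTU array, NA = missing), `centering_record`
#'   (mouse x OTU matrix of removed means) and `mouse_meta`.
#' @export
build_trajectories <- function(clr, meta, weeks = NULL) {
  values <- if (inherits(clr, "clr_matrix")) clr$values else as.matrix(clr)
  meta <- as.data.frame(meta)
  meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples")
  weeks <- weeks %||% sort(unique(meta$week))
  visits <- table(meta$mouse_id)
  drop <- names(visits)[visits < 2]
  if (length(drop)) {
    warning("excluding ", length(drop), " mouse/mice with < 2 visits: ",
            paste(drop, collapse = ", "))
    keep <- !meta$mouse_id %in% drop
    values <- values[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  mice <- sort(unique(meta$mouse_id))
  traj <- array(NA_real_, c(length(mice), length(weeks), ncol(values)),
                dimnames = list(mice, paste0("w", weeks), colnames(values)))
  mi <- match(meta$mouse_id, mice)
  wi <- match(meta$week, weeks)
  for (s in seq_len(nrow(values))) traj[mi[s], wi[s], ] <- values[s, ]
  centering <- apply(traj, c(1, 3), mean, na.rm = TRUE)
  traj <- sweep(traj, c(1, 3), centering)
  mm <- unique(meta[, c("mouse_id", "genotype", "sex", "diagnosis")])
  mm <- mm[match(mice, mm$mouse_id), ]
  rownames(mm) <- NULL
  structure(list(traj = traj, centering_record = centering,
                 mouse_meta = mm, weeks = weeks),
            class = "trajectory_matrix")
}

#' Functional PCA of centered trajectories with missing entries
#'
#' On complete data this is the eigendecomposition of the sample
#' covariance of the centered week-grid vectors (classical PCA).  With
#' missingness, the covariance is estimated from pairwise-complete
#' products, projected to positive semidefiniteness by clipping negative
#' eigenvalues at zero, and scores are best linear predictions given each
#' trajectory's observed entries (which reduce to classical PCA scores
#' when nothing is missing).  Eigenfunctions are signed so their
#' largest-magnitude entry is positive.
#'
#' @param X trajectories: an n x n_weeks numeric matrix (rows centered,
#'   NA = missing), or a `trajectory_matrix` plus `otu`.
#' @param otu OTU identifier when `X` is a `trajectory_matrix`.
#' @param threshold cumulative variance ratio for component selection.
#' @return An object of class `fpca_model`: `eigenfunctions` (components x
#'   weeks, orthonormal rows), `eigenvalues` (nonincreasing, >= 0),
#'   `n_components` (smallest count reaching `threshold`), `scores`
#'   (trajectories x components for all positive-eigenvalue components).
#' @export
fit_fpca <- function(X, otu = NULL, threshold = 0.99) {
  if (inherits(X, "trajectory_matrix")) {
    if (is.null(otu)) stop("give an OTU when passing a trajectory_matrix")
    weeks <- X$weeks
    X <- X$traj[, , otu]
  } else {
    X <- as.matrix(X)
    weeks <- seq_len(ncol(X))
  }
  if (nrow(X) < 10) stop("need >= 10 trajectories")
  nw <- ncol(X)
  obs <- !is.na(X)
  pairs <- crossprod(obs)
  if (any(pairs < 2)) {
    bad <- which(pairs < 2, arr.ind = TRUE)[1, ]
    stop("fewer than 2 pairwise-complete observations for week pair (",
         weeks[bad[1]], ", ", weeks[bad[2]], ")")
  }
  X0 <- X; X0[!obs] <- 0
  C <- crossprod(X0) / (pairs - 1)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)           # PSD projection
  phi <- eg$vectors
  # sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(phi))) {
    i <- which.max(abs(phi[, j]))
    if (phi[i, j] < 0) phi[, j] <- -phi[, j]
  }
  if (all(lam == 0)) stop("degenerate covariance: all eigenvalues zero")
  npos <- sum(lam > max(lam) * 1e-12)
  k_sel <- select_components(lam, threshold)
  Sigma <- phi %*% (lam * t(phi))
  scores <- matrix(NA_real_, nrow(X), npos)
  complete <- rowSums(obs) == nw
  if (any(complete))
    scores[complete, ] <- X[complete, , drop = FALSE] %*% phi[, seq_len(npos)]
  for (i in which(!complete)) {
    o <- obs[i, ]
    So <- Sigma[o, o, drop = FALSE]
    # best linear predictor: lambda_k phi_k(o)' pinv(Sigma_oo) x_o
    eo <- eigen(So, symmetric = TRUE)
    pos <- eo$values > max(eo$values, 0) * 1e-10
    pinv <- if (any(pos))
      eo$vectors[, pos, drop = FALSE] %*% (t(eo$vectors[, pos, drop = FALSE]) / eo$values[pos])
    else matrix(0, sum(o), sum(o))
    scores[i, ] <- lam[seq_len(npos)] *
      as.numeric(t(phi[o, seq_len(npos), drop = FALSE]) %*% (pinv %*% X[i, o]))
  }
  dimnames(scores) <- list(rownames(X), paste0("fPC", seq_len(npos)))
  structure(list(eigenfunctions = t(phi[, seq_len(npos), drop = FALSE]),
                 eigenvalues = lam, n_components = k_sel,
                 scores = scores, weeks = weeks, otu = otu,
                 threshold = threshold),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  ratio <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  cat("fPCA", if (!is.null(x$otu)) paste0("(", x$otu, ")"), ":",
      x$n_components, "component(s) reach",
      paste0(100 * x$threshold, "%"), "variance\n")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 3), collapse = ", "), "\n")
  cat("  cumulative ratio:", paste(format(ratio, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fpca_model <- function(x, k = NULL, ...) {
  k <- k %||% x$n_components
  matplot(x$weeks, t(x$eigenfunctions[seq_len(k), , drop = FALSE]),
          type = "b", pch = 16, lty = 1, xlab = "week",
          ylab = "eigenfunction", ...)
  abline(h = 0, lty = 2, col = "grey60")
  legend("topleft", legend = paste0("fPC", seq_len(k)), col = seq_len(k),
         lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Number of components reaching a cumulative variance threshold
#'
#' @param eigenvalues nonnegative eigenvalues (or an `fpca_model`).
#' @param threshold cumulative variance ratio in (0, 1].
#' @return Smallest `k` with `sum(lambda[1:k]) / sum(lambda) >= threshold`.
#' @export
select_components <- function(eigenvalues, threshold = 0.99) {
  if (inherits(eigenvalues, "fpca_model")) eigenvalues <- eigenvalues$eigenvalues
  lam <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  if (all(lam <= 0)) stop("all eigenvalues zero: variance ratio undefined")
  ratio <- cumsum(lam) / sum(lam)
  which(ratio >= threshold - 1e-12)[1]
}

#' Lasso logistic regression of diagnosis on fPC scores (one genotype)
#'
#' L1-penalized logistic regression with the regularization parameter
#' chosen by stratified 5-fold cross-validation on the binomial deviance
#' (plain minimum, no one-standard-error rule).
#'
#' @param scores feature matrix, rows = mice of one genotype, columns =
#'   (otu, component) score features.
#' @param labels diagnosis factor/character (`"ED/CIS"` / `"OSCC"`).
#' @param nfolds CV folds.
#' @param seed integer seed (controls fold assignment).
#' @return list with `lambda`, `coefficients` (at the selected lambda),
#'   `predictive_features`, `predictive_otus` and `cv_deviance`; `NULL`
#'   (with a warning) if only one class is present.
#' @export
lasso_logistic_cv <- function(scores, labels, nfolds = 5L, seed = 1L) {
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2) {
    warning("single-class stratum; Lasso logistic skipped")
    return(NULL)
  }
  if (min(table(droplevels(y))) < 3) {
    warning("a diagnosis class has < 3 mice in this stratum; Lasso logistic skipped")
    return(NULL)
  }
  scores <- as.matrix(scores)
  set.seed(derive_seed(seed, 7L))
  foldid <- integer(length(y))
  for (lev in levels(y)) {             # stratified folds
    i <- which(y == lev)
    foldid[i] <- sample(rep_len(seq_len(nfolds), length(i)))
  }
  cv <- glmnet::cv.glmnet(scores, y, family = "binomial", alpha = 1,
                          foldid = foldid, type.measure = "deviance")
  co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  sel <- names(co)[co != 0]
  otus <- unique(sub("\\.fPC[0-9]+$", "", sel))
  list(lambda = cv$lambda.min, coefficients = co,
       predictive_features = sel, predictive_otus = otus,
       cv_deviance = min(cv$cvm))
}

# Reference shapes on the week grid for trend labeling: a low-to-high
# transition between weeks 8 and 16, and a parabola-like dip reaching its
# minimum near week 12.
reference_shapes <- function(weeks) {
  s1 <- stats::plogis((weeks - 12) / 2.5); s1 <- s1 - mean(s1)
  s2 <- (weeks - 12)^2;                   s2 <- s2 - mean(s2)
  rbind(rise_8_16 = s1 / sqrt(sum(s1^2)),
        dip_at_12 = s2 / sqrt(sum(s2^2)))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Group-average fPC scores with trend-shape matching
#'
#' Mean fPC score per (otu, component, genotype, diagnosis).  Each fitted
#' eigenfunction is compared (by absolute cosine similarity) with two
#' reference trend shapes -- a low-to-high transition between weeks 8 and
#' 16 and a dip bottoming near week 12 -- and a trend label is attached
#' only when the fitted shape matches.
#'
#' @param models named list (by OTU) of `fpca_model`s (or a single model).
#' @param mouse_meta data.frame with `mouse_id`, `genotype`, `diagnosis`
#'   aligned with the score rows.
#' @param match_min minimum |cosine| to declare a shape match.
#' @return list with `table` (group means) and `shape_report` (per otu and
#'   component: best-matching reference shape, cosine, matched flag).
#' @export
group_average_scores <- function(models, mouse_meta, match_min = 0.8) {
  if (inherits(models, "fpca_model")) models <- list(otu = models)
  rows <- list(); shapes <- list()
  for (o in names(models)) {
    m <- models[[o]]
    refs <- reference_shapes(m$weeks)
    n_comp <- m$n_components
    for (j in seq_len(n_comp)) {
      ef <- m$eigenfunctions[j, ]
      cs <- apply(refs, 1, cosine_sim, b = ef)
      best <- which.max(abs(cs))
      shapes[[length(shapes) + 1L]] <- data.frame(
        otu = o, component = paste0("fPC", j),
        best_shape = rownames(refs)[best], cosine = cs[best],
        matched = abs(cs[best]) >= match_min)
      sc <- m$scores[, j]
      mm <- mouse_meta[match(rownames(m$scores), mouse_meta$mouse_id), ]
      ag <- aggregate(sc, list(genotype = mm$genotype, diagnosis = mm$diagnosis),
                      mean, na.rm = TRUE)
      nn <- aggregate(sc, list(genotype = mm$genotype, diagnosis = mm$diagnosis),
                      function(z) sum(!is.na(z)))
      rows[[length(rows) + 1L]] <- data.frame(
        otu = o, component = paste0("fPC", j),
        genotype = ag$genotype, diagnosis = ag$diagnosis,
        mean_score = ag$x, n = nn$x)
    }
  }
  list(table = do.call(rbind, rows), shape_report = do.call(rbind, shapes))
}

#' Predictive trend analysis: fPCA scores + per-genotype Lasso logistic
#'
#' Runs [fit_fpca()] per OTU on centered trajectories, pools the retained
#' fPC scores into a feature matrix, and fits one Lasso logistic model of
#' diagnosis per genotype with CV-selected regularization.
#'
#' @param clr a `clr_matrix` or matrix.
#' @param meta sample metadata.
#' @param otus OTUs to analyze (default all).
#' @param threshold fPCA cumulative-variance threshold.
#' @param nfolds CV folds.
#' @param seed integer seed.
#' @return An object of class `fpca_report`: per-genotype Lasso results,
#'   `group_mean_scores`, `shape_report` and the fitted `models`.
#' @export
fpca_trend <- function(clr, meta, otus = NULL, threshold = 0.99,
                       nfolds = 5L, seed = 1L) {
  tr <- build_trajectories(clr, meta)
  otus <- otus %||% dimnames(tr$traj)[[3]]
  models <- list()
  feats <- list()
  for (o in otus) {
    m <- try(fit_fpca(tr, otu = o, threshold = threshold), silent = TRUE)
    if (inherits(m, "try-error")) next
    models[[o]] <- m
    sc <- m$scores[, seq_len(m$n_components), drop = FALSE]
    colnames(sc) <- paste0(o, ".fPC", seq_len(ncol(sc)))
    feats[[o]] <- sc
  }
  if (!length(models)) stop("no OTU admitted an fPCA fit")
  features <- do.call(cbind, feats)
  features[is.na(features)] <- 0
  mm <- tr$mouse_meta
  per_genotype <- list()
  for (g in unique(mm$genotype)) {
    i <- which(mm$genotype == g)
    per_genotype[[g]] <- lasso_logistic_cv(features[i, , drop = FALSE],
                                           mm$diagnosis[i], nfolds = nfolds,
                                           seed = seed + match(g, unique(mm$genotype)))
  }
  gas <- group_average_scores(models, mm)
  structure(list(per_genotype = per_genotype,
                 group_mean_scores = gas$table,
                 shape_report = gas$shape_report,
                 models = models, features = features, mouse_meta = mm),
            class = "fpca_report")
}

#' @export
print.fpca_report <- function(x, ...) {
  cat("fPCA predictive trend analysis:", length(x$models), "OTUs\n")
  for (g in names(x$per_genotype)) {
    r <- x$per_genotype[[g]]
    cat("  ", g, ": ", sep = "")
    if (is.null(r)) cat("skipped (single class)\n")
    else cat(length(r$predictive_otus), "predictive OTU(s)",
             if (length(r$predictive_otus))
               paste0("[", paste(r$predictive_otus, collapse = ", "), "]"),
             "\n")
  }
  invisible(x)
}
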