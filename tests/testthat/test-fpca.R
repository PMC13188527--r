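test_that("trajectory building centers, shifts and tracks missingness", {
  meta <- balanced_meta(8)
  keep <- !(meta$mouse_id == "M001" & meta$week %in% c(4, 8, 16))
  meta <- meta[keep, ]
  v <- matrix(rnorm(nrow(meta)), ncol = 1,
              dimnames = list(meta$sample_id, "OtuX"))
  tr <- build_trajectories(v, meta)
  expect_equal(dim(tr$traj), c(8, 6, 1))
  expect_equal(sum(is.na(tr$traj["M001", , "OtuX"])), 3)
  mu <- apply(tr$traj[, , 1], 1, mean, na.rm = TRUE)
  expect_lt(max(abs(mu)), 1e-9)

  # constant trajectory -> all zero; shifts are removed
  v2 <- v; v2[meta$mouse_id == "M002", 1] <- 3.3
  tr2 <- build_trajectories(v2, meta)
  expect_equal(unname(tr2$traj["M002", , 1]), rep(0, 6))
  v3 <- v; v3[meta$mouse_id == "M003", 1] <- v[meta$mouse_id == "M003", 1] + 7
  tr3 <- build_trajectories(v3, meta)
  expect_equal(tr3$traj["M003", , 1], tr$traj["M003", , 1])

  # a mouse with a single visit is excluded with a warning
  meta4 <- meta[!(meta$mouse_id == "M004" & meta$week != 0), ]
  v4 <- v[meta4$sample_id, , drop = FALSE]
  expect_warning(tr4 <- build_trajectories(v4, meta4), "M004")
  expect_false("M004" %in% rownames(tr4$traj))
})

test_that("complete-data fPCA equals classical PCA and reconstructs exactly", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  X <- X - rowMeans(X)
  m <- fit_fpca(X)
  # independent oracle: eigendecomposition of the sample second-moment
  C <- crossprod(X) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  expect_equal(m$eigenvalues, pmax(eg$values, 0), tolerance = 1e-10)
  npos <- nrow(m$eigenfunctions)
  for (j in seq_len(npos)) {
    v <- eg$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(m$eigenfunctions[j, ]), v, tolerance = 1e-8)
    expect_equal(unname(m$scores[, j]), unname(X %*% v)[, 1], tolerance = 1e-8)
  }
  # orthonormal eigenfunctions, exact reconstruction from all components
  G <- tcrossprod(m$eigenfunctions)
  expect_equal(G, diag(npos), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m$scores %*% m$eigenfunctions, X,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a single planted shape is recovered with one component", {
  set.seed(6)
  shape <- c(-1, -0.8, -0.2, 0.4, 0.8, 0.8)
  shape <- shape - mean(shape); shape <- shape / sqrt(sum(shape^2))
  A <- rnorm(60, 0, 3)
  X <- outer(A, shape) + matrix(rnorm(60 * 6, 0, 0.02), 60, 6)
  X <- X - rowMeans(X)
  m <- fit_fpca(X)
  expect_equal(m$n_components, 1)
  cs <- sum(m$eigenfunctions[1, ] * shape) /
    sqrt(sum(m$eigenfunctions[1, ]^2) * sum(shape^2))
  expect_gt(abs(cs), 0.99)
})

test_that("missing-entry handling agrees with the complete path", {
  set.seed(7)
  lam <- c(3, 1)
  phi <- qr.Q(qr(cbind(c(-1,-1,-1,1,1,1), c(1,0,-1,-1,0,1), rnorm(6))))[, 1:2]
  X <- matrix(rnorm(80 * 2), 80) %*% (sqrt(lam) * t(phi)) +
    matrix(rnorm(80 * 6, 0, 0.1), 80, 6)
  X <- X - rowMeans(X)
  Xm <- X
  Xm[cbind(sample(80, 25), sample(6, 25, replace = TRUE))] <- NA
  Xm <- Xm - rowMeans(Xm, na.rm = TRUE)
  m <- fit_fpca(Xm)
  expect_true(all(m$eigenvalues >= 0))
  expect_true(!is.unsorted(rev(m$eigenvalues)))
  # complete rows get their classical scores even in the missing-data fit
  complete <- rowSums(is.na(Xm)) == 0
  cls <- Xm[complete, ] %*% t(m$eigenfunctions)
  expect_equal(m$scores[complete, ], cls, tolerance = 1e-8, ignore_attr = TRUE)
  # scores exist and are finite for incomplete rows
  expect_true(all(is.finite(m$scores[!complete, ])))
})

test_that("component selection follows the cumulative variance rule", {
  expect_equal(select_components(c(98, 1.5, 0.5), 0.99), 2)
  expect_equal(select_components(c(5, 0, 0), 0.99), 1)
  expect_equal(select_components(c(3, 2, 1, 0), 1.0), 3)
  expect_error(select_components(c(0, 0)), "eigenvalues zero")
})

test_that("Lasso logistic CV selects separating scores and skips degenerate strata", {
  expect_warning(r <- lasso_logistic_cv(matrix(rnorm(40), 20), rep("OSCC", 20)),
                 "single-class")
  expect_null(r)
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    lab <- rep(c("ED/CIS", "OSCC"), each = n / 2)
    sc <- matrix(rnorm(n * 8), n, 8,
                 dimnames = list(NULL, paste0("Otu", 1:8, ".fPC1")))
    sc[, "Otu3.fPC1"] <- sc[, "Otu3.fPC1"] + (lab == "OSCC") * 3
    r <- lasso_logistic_cv(sc, lab, seed = s)
    "Otu3" %in% r$predictive_otus
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("group averages are near zero for symmetric groups and structured", {
  g <- small_cohort(seed = 23, n_otus = 20, dropout = 0)
  clr <- clr_transform(g$table, 0.05)
  rep <- suppressWarnings(fpca_trend(clr, g$table$sample_meta,
                                     otus = clr$retained_otus[1:4], seed = 2))
  tab <- rep$group_mean_scores
  expect_true(all(c("otu", "component", "genotype", "diagnosis",
                    "mean_score", "n") %in% names(tab)))
  expect_false(any(duplicated(tab[, c("otu", "component", "genotype", "diagnosis")])))
  expect_true(all(c("best_shape", "cosine", "matched") %in%
                    names(rep$shape_report)))
})
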