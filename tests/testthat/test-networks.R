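test_that("mclr preserves zeros and reduces to shifted CLR without zeros", {
  x <- c(0, 10, 0, 5, 35)
  m <- mclr_transform(x)
  expect_equal(m[x == 0], c(0, 0))
  expect_true(all(m[x > 0] > 0))
  y <- c(2, 2, 8)
  my <- mclr_transform(y)
  clr_y <- log(y) - mean(log(y))
  expect_equal(my - my[1], clr_y - clr_y[1], tolerance = 1e-12)
  expect_error(mclr_transform(c(0, 0)), "all-zero")
  set.seed(4)
  for (i in 1:200) {
    x <- rpois(15, 3)
    if (sum(x) == 0) next
    m <- mclr_transform(x)
    expect_true(all(m[x > 0] > 0))
    expect_true(all(m[x == 0] == 0))
  }
})

test_that("tau_a matches a brute-force concordance count under ties", {
  tau_naive <- function(x, y) {
    n <- length(x); s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    s / (n * (n - 1) / 2)
  }
  set.seed(9)
  for (i in 1:10) {
    x <- rpois(25, 2); y <- rpois(25, 2)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(longisal:::kendall_tau_a(x, y), tau_naive(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the copula bridge matches its continuous limit and references", {
  for (r in c(-0.7, -0.2, 0.4, 0.8)) {
    expect_equal(longisal:::bridge_forward(r, -Inf, -Inf), 2 * asin(r) / pi)
    # infinite thresholds through the pmvnorm path agree with the closed form
    expect_equal(longisal:::bridge_forward(r, qnorm(1e-12), -Inf),
                 2 * asin(r) / pi, tolerance = 1e-3)
  }
  # values verified against Monte Carlo simulation of truncated copula pairs
  expect_equal(longisal:::bridge_forward(0.3, qnorm(0.3), qnorm(0.3)),
               0.1774, tolerance = 2e-3)
  expect_equal(longisal:::bridge_forward(0.7, qnorm(0.3), qnorm(0.3)),
               0.4511, tolerance = 2e-3)
  expect_equal(longisal:::bridge_forward(-0.6, qnorm(0.6), qnorm(0.2)),
               -0.3003, tolerance = 2e-3)
  # monotone in r
  taus <- vapply(seq(-0.9, 0.9, by = 0.2), longisal:::bridge_forward,
                 numeric(1), d1 = qnorm(0.3), d2 = qnorm(0.4))
  expect_true(all(diff(taus) > 0))
})

test_that("latent correlation estimates are sane and the two paths agree", {
  set.seed(11)
  n <- 300
  z <- matrix(rnorm(2 * n), ncol = 2) %*% chol(matrix(c(1, .5, .5, 1), 2))
  d <- qnorm(0.3)
  x <- ifelse(z[, 1] > d, exp(z[, 1]), 0)
  y <- ifelse(z[, 2] > d, exp(z[, 2]), 0)
  ri <- latent_correlation(x, y, method = "interp")
  re <- latent_correlation(x, y, method = "exact")
  expect_lt(abs(ri - re), 0.02)
  expect_lt(abs(re - 0.5), 0.15)
  xc <- rnorm(50)
  expect_equal(latent_correlation(xc, xc), 0.999)
  expect_error(latent_correlation(rep(1, 50), rnorm(50)), "constant")
  expect_error(latent_correlation(c(1, 2, 3, 0, 0, 0), rnorm(6)), ">= 5 nonzero")
})

test_that("graph path spans empty to complete and flags bad input", {
  set.seed(12)
  R <- cov2cor(crossprod(matrix(rnorm(100 * 6), 100, 6)))
  colnames(R) <- rownames(R) <- paste0("V", 1:6)
  lmax <- max(abs(R[upper.tri(R)]))
  gp <- graph_path(R, c(lmax * 1.01, 1e-9))
  expect_equal(sum(gp[[1]] != 0), 0)
  expect_equal(sum(gp[[2]] != 0 & upper.tri(gp[[2]])), choose(6, 2))
  expect_error(graph_path(R, c(0.1, 0.5)), "decreasing")
  Rbad <- R; Rbad[1, 2] <- Rbad[2, 1] <- 2
  expect_error(graph_path(Rbad, c(0.5, 0.1)), "positive semidefinite")
})

test_that("StARS instability is bounded, monotonized and deterministic", {
  set.seed(13)
  p <- 8; n <- 120
  Om <- diag(p); for (i in 1:(p - 1)) Om[i, i + 1] <- Om[i + 1, i] <- 0.4
  X <- matrix(rnorm(n * p), n) %*% chol(solve(Om))
  colnames(X) <- paste0("V", 1:p)
  net1 <- suppressWarnings(stars_select(X, n_subsamples = 10, seed = 3))
  net2 <- suppressWarnings(stars_select(X, n_subsamples = 10, seed = 3))
  expect_identical(net1$edges, net2$edges)
  expect_true(all(net1$instability_path >= 0 & net1$instability_path <= 0.5))
  mono <- cummax(net1$instability_path)
  sel_i <- which(net1$lambda_seq == net1$lambda_selected)
  if (any(mono <= net1$beta_threshold)) {
    # densest penalty within the stable prefix
    expect_equal(sel_i, max(which(mono <= net1$beta_threshold)))
  } else {
    expect_equal(sel_i, length(mono))
  }
  expect_error(stars_select(X, n_subsamples = 5), ">= 10")
})

test_that("period networks honour filters and degenerate inputs", {
  g <- small_cohort(seed = 33, n_otus = 40)
  tab <- g$table
  # a genotype with no samples
  tab_wt <- subset_table(tab, samples = which(tab$sample_meta$genotype == "WT"))
  expect_warning(nets <- build_period_networks(tab_wt, "family", "KO",
                                               n_subsamples = 10),
                 "no samples")
  expect_length(nets, 0)
  # sparse periods skipped
  w <- capture_warnings(
    nets2 <- build_period_networks(tab_wt, "family", "WT",
                                   n_subsamples = 10, min_samples = 1000))
  expect_true(all(grepl("skipped", w)))
  expect_length(nets2, 0)
})

test_that("network comparison partitions edges into the documented classes", {
  mk <- function(edges, genotype, period) {
    structure(list(nodes = c("A", "B", "C", "D"),
                   edges = data.frame(node1 = edges[, 1], node2 = edges[, 2],
                                      sign = 1, stringsAsFactors = FALSE),
                   genotype = genotype, period = period),
              class = "network_estimate")
  }
  core_e <- rbind(c("A", "B"))
  ko_e <- rbind(c("A", "B"), c("C", "D"))
  nets <- list(mk(core_e, "WT", "0-4"), mk(core_e, "WT", "8-12"),
               mk(core_e, "WT", "16-22"),
               mk(ko_e, "KO", "0-4"), mk(ko_e, "KO", "8-12"),
               mk(rbind(ko_e, c("B", "C")), "KO", "16-22"))
  cmp <- compare_networks(nets)
  expect_equal(unname(cmp$class["A--B"]), "core")
  expect_equal(unname(cmp$class["C--D"]), "genotype_stable_KO")
  expect_equal(unname(cmp$class["B--C"]), "period_specific")
  expect_equal(sum(table(cmp$class)), nrow(cmp$presence))
  # identical everywhere -> everything core
  same <- lapply(1:6, function(i)
    mk(core_e, rep(c("WT", "KO"), each = 3)[i], rep(c("0-4", "8-12", "16-22"), 2)[i]))
  expect_true(all(compare_networks(same)$class == "core"))
})
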