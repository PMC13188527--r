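test_that("design assembly produces the documented coefficient sets", {
  meta <- balanced_meta(8)
  y <- gaussian_response(meta, seed = 1)
  d_full <- build_design(y, meta, "OtuX", "interaction")
  expect_equal(colnames(d_full$X),
               c("(Intercept)", "KO", "OSCC", "KO:OSCC", "Female"))
  d_gen <- build_design(y, meta, "OtuX", "genotype")
  expect_equal(colnames(d_gen$X), c("(Intercept)", "KO", "Female"))
  d_dia <- build_design(y, meta, "OtuX", "diagnosis")
  expect_equal(colnames(d_dia$X), c("(Intercept)", "OSCC", "Female"))
  expect_error(build_design(y, meta, "OtuX", "bogus"))
  # interaction column is the product of the indicators
  expect_equal(d_full$X[, "KO:OSCC"], d_full$X[, "KO"] * d_full$X[, "OSCC"])

  bad <- meta
  bad$genotype[bad$sample_id == "M001_w4"] <- "KO"
  expect_error(build_design(y, bad, "OtuX", "genotype"), "inconsistent")
})

test_that("unpenalized fixed-effects fit equals per-week OLS", {
  meta <- balanced_meta(24)
  set.seed(3)
  y <- gaussian_response(meta, beta_fun = function(w) 0.5 * sin(w / 5),
                         sigma_b = 0, sigma_e = 1, seed = 3)
  d <- build_design(y, meta, "OtuX", "interaction")
  fit <- fit_lsvcmm(d, fix_sigma_b = 0)
  for (j in seq_along(std_weeks)) {
    i <- meta$week == std_weeks[j]
    X <- cbind(1, meta$genotype[i] == "KO", meta$diagnosis[i] == "OSCC",
               (meta$genotype[i] == "KO") * (meta$diagnosis[i] == "OSCC"),
               meta$sex[i] == "F")
    expect_equal(unname(fit$beta[, j]), unname(qr.solve(X, y[i, 1])),
                 tolerance = 1e-6)
  }
  expect_equal(fit$sigma_b, 0)
})

test_that("penalty dominance and monotone sparsity hold", {
  meta <- balanced_meta(16)
  y <- gaussian_response(meta, beta_fun = function(w) (w >= 12) * 1.5, seed = 5)
  d <- build_design(y, meta, "OtuX", "genotype")
  f_inf <- fit_lsvcmm(d, lambda_sparsity = 1e8)
  expect_true(all(f_inf$beta[-1, ] == 0))
  expect_false(all(f_inf$beta[1, ] == 0))

  dfs <- vapply(c(0.01, 0.1, 1, 10, 100, 1e4), function(l)
    fit_lsvcmm(d, lambda_sparsity = l)$df, numeric(1))
  expect_true(all(diff(dfs) <= 0))
})

test_that("EBIC reduces to BIC at gamma 0 and respects ties and grids", {
  meta <- balanced_meta(16)
  y <- gaussian_response(meta, beta_fun = function(w) (w >= 12) * 1.5, seed = 7)
  d <- build_design(y, meta, "OtuX", "genotype")
  f <- ebic_select(d, lambda_sparsity = c(0.5), lambda_smooth = 0, gamma = 0.5)
  expect_equal(unname(f$penalty), c(0.5, 0))     # single grid point returned
  f0 <- ebic_select(d, lambda_sparsity = c(0.5, 2), lambda_smooth = 0, gamma = 0)
  tab <- f0$ebic_table
  # at gamma = 0 the criterion is plain BIC on the recorded likelihood
  expect_equal(tab$ebic, -2 * tab$loglik + tab$df * log(length(d$y)),
               tolerance = 1e-10)
  g5 <- ebic_select(d, lambda_sparsity = c(0.5, 2), lambda_smooth = 0, gamma = 0.5)
  expect_equal(g5$ebic_table$ebic - f0$ebic_table$ebic,
               2 * 0.5 * f0$ebic_table$df * log(3 * 6), tolerance = 1e-10)
})

test_that("variance components are recovered on a large null cohort", {
  meta <- balanced_meta(200)
  y <- gaussian_response(meta, sigma_b = 0.7, sigma_e = 1, seed = 9)
  d <- build_design(y, meta, "OtuX", "genotype")
  f <- fit_lsvcmm(d)
  expect_lt(abs(f$sigma_b - 0.7) / 0.7, 0.15)
  expect_lt(abs(f$sigma_e - 1) / 1, 0.15)
})

test_that("interaction and genotype-only variants agree when no diagnosis effect", {
  meta <- balanced_meta(200)
  y <- gaussian_response(meta, beta_fun = function(w) 0.8 * sin(w / 7),
                         sigma_b = 0.5, sigma_e = 1, seed = 11)
  d1 <- build_design(y, meta, "OtuX", "interaction")
  d2 <- build_design(y, meta, "OtuX", "genotype")
  # force the interaction coefficient function to exactly zero via an
  # infinite relative penalty weight on its row only
  W <- matrix(0, 5, 6, dimnames = list(colnames(d1$X), paste0("w", std_weeks)))
  W["KO:OSCC", ] <- 1e6
  f1 <- fit_lsvcmm(d1, lambda_sparsity = 1e3, adaptive_weights = W)
  expect_true(all(f1$beta["KO:OSCC", ] == 0))
  f2 <- fit_lsvcmm(d2)
  expect_lt(max(abs(f1$beta["KO", ] - f2$beta["KO", ])), 0.1)
})

test_that("sign-flipping the response flips estimates and band endpoints", {
  meta <- balanced_meta(16)
  y <- gaussian_response(meta, beta_fun = function(w) (w >= 12) * 2, seed = 13)
  d_pos <- build_design(y, meta, "OtuX", "genotype")
  d_neg <- build_design(-y, meta, "OtuX", "genotype")
  f_pos <- fit_lsvcmm(d_pos, lambda_sparsity = 0.5)
  f_neg <- fit_lsvcmm(d_neg, lambda_sparsity = 0.5)
  expect_equal(f_neg$beta, -f_pos$beta, tolerance = 1e-6)
  b_pos <- suppressWarnings(bootstrap_bands(f_pos, 200, seed = 2))
  b_neg <- suppressWarnings(bootstrap_bands(f_neg, 200, seed = 2))
  expect_equal(b_neg$estimate, -b_pos$estimate, tolerance = 1e-6)
  expect_equal(b_neg$lower, -b_pos$upper, tolerance = 1e-6)
  expect_equal(b_neg$upper, -b_pos$lower, tolerance = 1e-6)
  expect_equal(b_neg$significant, b_pos$significant)
})

test_that("bands keep the estimate inside and flag significance coherently", {
  meta <- balanced_meta(24)
  y <- gaussian_response(meta, beta_fun = function(w) (w >= 12) * 2, seed = 15)
  d <- build_design(y, meta, "OtuX", "genotype")
  f <- ebic_select(d, n_lambda = 10, lambda_smooth = c(0, 1))
  b <- suppressWarnings(bootstrap_bands(f, 200, seed = 3))
  expect_true(all(b$lower <= b$estimate + 1e-12))
  expect_true(all(b$estimate <= b$upper + 1e-12))
  expect_equal(b$significant, b$lower > 0 | b$upper < 0)
  expect_error(bootstrap_bands(f, 100), ">= 200")
})

test_that("significance summary has the documented shape", {
  meta <- balanced_meta(16)
  bands <- list()
  for (o in c("OtuA", "OtuB")) {
    y <- gaussian_response(meta, seed = match(o, c("OtuA", "OtuB")) + 20)
    colnames(y) <- o
    d <- build_design(y, meta, o, "interaction")
    f <- ebic_select(d, n_lambda = 6, lambda_smooth = 0)
    bands[[o]] <- suppressWarnings(bootstrap_bands(f, 200, seed = 4))
  }
  tab <- summarize_significance(bands)
  expect_equal(nrow(tab), 2 * 4 * 6)   # otus x contrasts x weeks
  expect_true(all(attr(tab, "reported_otus") %in% c("OtuA", "OtuB")))
  expect_error(summarize_significance(list()), "no OTUs")
})
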