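# Shared fixtures built in code.

std_weeks <- c(0L, 4L, 8L, 12L, 16L, 22L)

# Balanced complete longitudinal metadata with non-collinear covariates.
balanced_meta <- function(n_mice = 24, weeks = std_weeks) {
  stopifnot(n_mice %% 4 == 0)
  mouse <- sprintf("M%03d", seq_len(n_mice))
  geno <- rep(c("WT", "KO"), each = n_mice / 2)
  sex <- rep(c("M", "F"), n_mice / 2)
  diagn <- rep(c("ED/CIS", "OSCC", "OSCC", "ED/CIS"), n_mice / 4)
  meta <- expand.grid(mouse_id = mouse, week = weeks,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  i <- match(meta$mouse_id, mouse)
  meta$genotype <- geno[i]; meta$sex <- sex[i]; meta$diagnosis <- diagn[i]
  meta$sample_id <- paste0(meta$mouse_id, "_w", meta$week)
  meta
}

# Gaussian longitudinal response with mouse random intercept.
gaussian_response <- function(meta, beta_fun = function(w) 0 * w,
                              sigma_b = 0.7, sigma_e = 1, seed = 1) {
  set.seed(seed)
  mice <- unique(meta$mouse_id)
  b <- stats::setNames(rnorm(length(mice), 0, sigma_b), mice)
  mu <- (meta$genotype == "KO") * beta_fun(meta$week)
  y <- mu + b[meta$mouse_id] + rnorm(nrow(meta), 0, sigma_e)
  matrix(y, ncol = 1, dimnames = list(meta$sample_id, "OtuX"))
}

# Small synthetic cohort for structural tests.
small_cohort <- function(seed = 1, n_otus = 25, dropout = 0.1, ...) {
  des <- study_design(c(WT_M = 4, KO_M = 4, WT_F = 4, KO_F = 4),
                      n_otus = n_otus, depth_mean = 3000,
                      dropout_rate = dropout, seed = seed, ...)
  generate_cohort(des)
}

# Dirichlet-multinomial null community (one composition, two arbitrary
# group labels): the null case for AMOVA calibration.
dm_null_counts <- function(seed, n = 40, n_taxa = 30, depth = 2000,
                           conc = 50, base = NULL) {
  set.seed(seed)
  if (is.null(base)) {
    base <- exp(rnorm(n_taxa, 0, 1.5)); base <- base / sum(base)
  }
  al <- conc * base
  counts <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(n_taxa, al)
    as.integer(rmultinom(1, depth, g / sum(g)))
  }, integer(n_taxa)))
  dimnames(counts) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(n_taxa)))
  counts
}
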