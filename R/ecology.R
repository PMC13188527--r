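# Community ecology: Yue-Clayton theta dissimilarity, diversity/richness,
# permutation AMOVA on a distance matrix, and NMDS plumbing.

#' Inverse Simpson diversity of one sample
#'
#' `1 / sum(p_i^2)` over relative abundances; equals the number of taxa
#' for a perfectly even community.
#'
#' @param x nonnegative counts (or abundances) of one sample; total > 0.
#' @return Numeric diversity value >= 1.
#' @export
inverse_simpson <- function(x) {
  if (any(x < 0)) stop("negative abundances")
  tot <- sum(x)
  if (tot <= 0) stop("empty sample")
  p <- x / tot
  1 / sum(p^2)
}

#' Observed richness of one sample
#'
#' @param x nonnegative counts.
#' @return Number of taxa with count > 0.
#' @export
observed_richness <- function(x) sum(x > 0)

#' Yue-Clayton theta dissimilarity between two compositions
#'
#' `d = 1 - sum(p*q) / (sum(p^2) + sum(q^2) - sum(p*q))`: 0 for identical
#' compositions, 1 for disjoint supports.
#'
#' @param p,q nonnegative relative-abundance vectors on the same taxon
#'   index, each summing to 1 (within 1e-9).
#' @return Dissimilarity in `[0, 1]`.
#' @export
theta_yc <- function(p, q) {
  if (length(p) != length(q)) stop("compositions differ in length")
  if (any(p < 0) || any(q < 0)) stop("negative abundances")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("compositions must sum to 1 (within 1e-9)")
  pq <- sum(p * q)
  1 - pq / (sum(p^2) + sum(q^2) - pq)
}

#' Pairwise Yue-Clayton distance matrix
#'
#' @param table an [otu_count_table()] or counts matrix (samples x taxa);
#'   rows are converted to relative abundances.
#' @return An object of class `distance_matrix`: list with `ids`, symmetric
#'   matrix `d` (zero diagonal, entries in `[0, 1]`) and `metric_name`.
#' @export
theta_yc_dist <- function(table) {
  counts <- if (inherits(table, "otu_count_table")) table$counts else as.matrix(table)
  if (any(rowSums(counts) <= 0)) stop("empty sample(s) in table")
  P <- counts / rowSums(counts)
  ss <- rowSums(P^2)
  G <- P %*% t(P)
  D <- 1 - G / (outer(ss, rep(1, length(ss))) + outer(rep(1, length(ss)), ss) - G)
  diag(D) <- 0
  D[D < 0] <- 0; D[D > 1] <- 1
  structure(list(ids = rownames(counts), d = D, metric_name = "thetayc"),
            class = "distance_matrix")
}

#' Permutation AMOVA on a distance matrix
#'
#' Partitions the total sum of squared pairwise distances into among- and
#' within-group components (Excoffier partition: `SS_total` from all pairs
#' divided by N, `SS_within` from within-group pairs divided by group
#' size), forms the pseudo-F ratio, and assesses it by permuting
#' sample-to-group assignments.  The p-value uses the add-one estimator
#' `(#{F_perm >= F_obs} + 1) / (n_perm + 1)`.
#'
#' @param dm a `distance_matrix` (e.g. from [theta_yc_dist()]).
#' @param groups group labels aligned with `dm$ids` (>= 2 groups, each with
#'   >= 2 samples).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return An object of class `amova`: list with `F_statistic`, `p_value`,
#'   sums of squares and degrees of freedom.
#' @export
amova <- function(dm, groups, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(dm, "distance_matrix"))
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm$d)) stop("groups length != number of samples")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  if (n_perm < 99) stop("n_perm must be >= 99")
  d2 <- dm$d^2
  n <- nrow(d2)
  G <- nlevels(groups)
  ss_total <- sum(d2) / (2 * n)
  ss_within_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      s <- s + sum(d2[i, i]) / (2 * length(i))
    }
    s
  }
  f_of <- function(g) {
    ssw <- ss_within_of(g)
    ((ss_total - ssw) / (G - 1)) / (ssw / (n - G))
  }
  f_obs <- f_of(groups)
  set.seed(derive_seed(seed, 4L))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_of(sample(groups)) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(F_statistic = f_obs,
                 p_value = (exceed + 1) / (n_perm + 1),
                 ss_total = ss_total, ss_within = ss_within_of(groups),
                 ss_among = ss_total - ss_within_of(groups),
                 df_among = G - 1, df_within = n - G, n_perm = n_perm),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA: F =", format(x$F_statistic, digits = 4),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Two-sample pooled-variance t test for diversity metrics
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t` and `p` (two-sided).  A zero pooled variance
#'   yields `p = 1` with a warning.
#' @export
diversity_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each arm needs n >= 2")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    warning("zero pooled variance; p set to 1")
    return(list(t = 0, p = 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2))
}

#' NMDS embedding of a distance matrix (plumbing)
#'
#' Kruskal nonmetric MDS via `vegan::monoMDS` with a classical-scaling
#' start plus seeded random restarts; the lowest-stress solution is kept.
#'
#' @param dm a `distance_matrix`.
#' @param k embedding dimension.
#' @param seed integer seed for the random restarts.
#' @param n_starts number of random restarts beyond the metric start.
#' @return list with `points` (n x k), `stress` and `ids`.
#' @export
nmds_embed <- function(dm, k = 2L, seed = 1L, n_starts = 4L) {
  stopifnot(inherits(dm, "distance_matrix"))
  d <- stats::as.dist(dm$d)
  best <- vegan::monoMDS(d, y = stats::cmdscale(d, k = k), k = k)
  set.seed(derive_seed(seed, 5L))
  for (i in seq_len(n_starts)) {
    y0 <- matrix(rnorm(nrow(dm$d) * k), ncol = k)
    fit <- vegan::monoMDS(d, y = y0, k = k)
    if (fit$stress < best$stress) best <- fit
  }
  list(points = best$points, stress = best$stress, ids = dm$ids)
}
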