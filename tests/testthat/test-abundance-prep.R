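test_that("half-minimum zero replacement follows the stated rule", {
  expect_equal(replace_zeros_half_min(c(0, 3, 5)), c(1.5, 3, 5))
  expect_equal(replace_zeros_half_min(c(4, 4, 4)), c(4, 4, 4))
  expect_error(replace_zeros_half_min(c(0, 0, 0)), "all-zero")
  expect_error(replace_zeros_half_min(c(-1, 2)), "nonnegative")
})

test_that("CLR transform matches direct evaluation and its invariances", {
  counts <- rbind(a = c(1, 1, 1, 1), b = c(2, 2, 8, 4))
  colnames(counts) <- paste0("o", 1:4)
  clr <- clr_transform(counts, 0)
  expect_equal(unname(clr$values["a", ]), rep(0, 4))

  # worked 3-part example: (2, 2, 8) -> (-0.4621, -0.4621, 0.9242)
  c3 <- rbind(s = c(2, 2, 8)); colnames(c3) <- paste0("o", 1:3)
  v <- clr_transform(c3, 0)$values["s", ]
  m <- (2 * log(2) + log(8)) / 3
  expect_equal(unname(v), c(log(2) - m, log(2) - m, log(8) - m), tolerance = 1e-12)
  expect_equal(unname(round(v, 4)), c(-0.4621, -0.4621, 0.9242))

  # rows sum to zero; per-sample scaling leaves CLR unchanged
  g <- small_cohort(seed = 3)
  clr1 <- clr_transform(g$table, 0.05)
  expect_lt(max(abs(rowSums(clr1$values))), 1e-9 * ncol(clr1$values))
  scaled <- g$table$counts * 10L
  clr2 <- clr_transform(scaled, 0.05)
  expect_equal(clr2$values, clr1$values, tolerance = 1e-12)
})

test_that("prevalence filter uses a strict 'below' rule and is monotone", {
  counts <- matrix(0L, 20, 3, dimnames = list(paste0("s", 1:20), paste0("o", 1:3)))
  counts[1:10, 1] <- 5L    # prevalence 0.50
  counts[1, 2] <- 7L       # prevalence 0.05
  counts[, 3] <- 1L        # keeps samples nonzero
  expect_equal(unname(prevalence(counts)), c(0.5, 0.05, 1))
  clr <- clr_transform(counts, 0.05)
  expect_true("o2" %in% clr$retained_otus)   # exactly at threshold: retained
  clr2 <- clr_transform(counts, 0.051)
  expect_false("o2" %in% clr2$retained_otus)
  for (p in c(0, 0.05, 0.2, 0.6)) {
    r1 <- clr_transform(counts, p)$retained_otus
    r2 <- clr_transform(counts, min(p + 0.2, 0.99))$retained_otus
    expect_true(all(r2 %in% r1))
  }
})

test_that("samples all-zero after filtering are dropped with a warning", {
  counts <- matrix(c(5L, 0L, 7L, 8L,
                     0L, 1L, 0L, 0L), 4, 2,
                   dimnames = list(paste0("s", 1:4), c("o1", "o2")))
  # o2 (prevalence 0.25) is filtered at 0.5, leaving s2 all-zero
  expect_warning(clr <- clr_transform(counts, 0.5), "all-zero")
  expect_false("s2" %in% rownames(clr$values))
  expect_equal(clr$dropped_samples, "s2")
})

test_that("rarefaction conserves depth, is seeded, and drops shallow samples", {
  g <- small_cohort(seed = 9)
  depth <- 2500L
  r1 <- suppressWarnings(rarefy(g$table, depth, seed = 4))
  r2 <- suppressWarnings(rarefy(g$table, depth, seed = 4))
  expect_identical(r1$counts, r2$counts)
  expect_true(all(rowSums(r1$counts) == depth))
  # richness can only shrink under subsampling
  common <- rownames(r1$counts)
  expect_true(all(rowSums(r1$counts[common, ] > 0) <=
                    rowSums(g$table$counts[common, ] > 0)))
  # a sample already at depth is untouched
  tot <- rowSums(g$table$counts)
  ex <- suppressWarnings(rarefy(g$table, as.integer(min(tot)), seed = 1))
  at_depth <- names(tot)[tot == min(tot)]
  expect_identical(ex$counts[at_depth, ], g$table$counts[at_depth, ])
  expect_warning(empty <- rarefy(g$table, 10^7, seed = 1), "below")
  expect_equal(nrow(empty$counts), 0)
  expect_error(rarefy(g$table, 0), "depth")
})

test_that("rarefied counts match the hypergeometric expectation", {
  g <- small_cohort(seed = 13, n_otus = 15, dropout = 0)
  s <- g$table$counts[1, , drop = FALSE]
  depth <- 500L
  p <- s[1, ] / sum(s)
  draws <- vapply(1:200, function(i) {
    tab <- otu_count_table(s, g$table$sample_meta[1, ], g$table$taxonomy)
    rarefy(tab, depth, seed = i)$counts[1, ]
  }, numeric(ncol(s)))
  se <- sqrt(depth * p * (1 - p)) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - p * depth) <= 3 * se + 1e-9))
})

test_that("taxonomy aggregation is additive, conservative and monotone", {
  counts <- matrix(c(3L, 4L, 10L, 1L,
                     2L, 5L, 1L, 7L), 2, 4, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("Otu", 1:4)))
  tax <- data.frame(
    otu = paste0("Otu", 1:4),
    size = 0L,
    lineage = c("Bacteria;P1;C1;O1;FamA;G1",
                "Bacteria;P1;C1;O1;FamA;G2",
                "Bacteria;P1;C1;O2;FamB;G3",
                "Bacteria;P2;C2;O3;unclassified;unclassified"))
  meta <- data.frame(sample_id = c("s1", "s2"), mouse_id = c("m1", "m2"),
                     genotype = "WT", sex = "F", week = 0L,
                     diagnosis = "ED/CIS")
  tab <- otu_count_table(counts, meta, tax)
  fam <- aggregate_taxonomy(tab, "family")
  expect_equal(fam$counts[, "FamA"], c(s1 = 7, s2 = 7))
  expect_equal(rowSums(fam$counts), rowSums(counts))
  expect_true("unclassified_O3" %in% colnames(fam$counts))
  gen <- aggregate_taxonomy(tab, "genus")
  expect_gte(ncol(gen$counts), ncol(fam$counts))
})
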