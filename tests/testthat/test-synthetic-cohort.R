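test_that("generation is deterministic and respects the design", {
  g1 <- small_cohort(seed = 11)
  g2 <- small_cohort(seed = 11)
  expect_identical(g1$table$counts, g2$table$counts)
  expect_identical(g1$table$sample_meta, g2$table$sample_meta)
  g3 <- small_cohort(seed = 12)
  expect_false(identical(g1$table$counts, g3$table$counts))

  # no dropout -> every mouse at every week
  g0 <- small_cohort(seed = 5, dropout = 0)
  expect_true(all(g0$truth$visit_mask))
  expect_equal(nrow(g0$table$counts), 16 * 6)

  # counts rows sum to the drawn library sizes exactly (multinomial mode)
  expect_identical(unname(rowSums(g1$table$counts)),
                   unname(as.numeric(g1$truth$depths)))
})

test_that("design and truth validation rejects bad input", {
  expect_error(study_design(weeks = c(0, 4, 4, 12)), "strictly increasing")
  expect_error(study_design(n_otus = 5), "n_otus")
  expect_error(study_design(dropout_rate = 1), "dropout_rate")
  expect_error(cohort_truth(sigma_e = 0), "sigma_e")
  expect_error(cohort_truth(zero_inflation = 1), "zero_inflation")

  tr <- cohort_truth()
  e <- effect_profile(3, "genotype", rep(1, 6))
  tr <- inject_effect(tr, e)
  expect_error(inject_effect(tr, e), "duplicate")
  # wrong profile length caught at generation
  des <- study_design(c(WT_M = 2, KO_M = 2, WT_F = 2, KO_F = 2),
                      n_otus = 12, depth_mean = 500, seed = 1)
  bad <- cohort_truth(effects = list(effect_profile(1, "genotype", c(1, 2))))
  expect_error(generate_cohort(des, bad), "profile length")
})

test_that("every mouse keeps >= 2 visits under heavy dropout", {
  des <- study_design(c(WT_M = 6, KO_M = 6, WT_F = 6, KO_F = 6),
                      n_otus = 12, depth_mean = 500, dropout_rate = 0.6,
                      seed = 21)
  g <- generate_cohort(des)
  expect_true(all(rowSums(g$truth$visit_mask) >= 2))
})

test_that("latent within-mouse correlation is compound symmetric", {
  # sigma_b = sigma_e = 1 -> correlation between any two weeks = 0.5
  des <- study_design(c(WT_M = 125, KO_M = 125, WT_F = 125, KO_F = 125),
                      n_otus = 12, depth_mean = 1000, dropout_rate = 0,
                      seed = 31)
  g <- generate_cohort(des, cohort_truth(sigma_b = 1, sigma_e = 1,
                                         zero_inflation = 0))
  lat <- g$truth$latent
  meta <- g$table$sample_meta
  cors <- c()
  for (pair in list(c(0, 4), c(0, 22), c(8, 16))) {
    a <- lat[meta$week == pair[1], ]
    b <- lat[meta$week == pair[2], ]
    cors <- c(cors, mean(vapply(seq_len(ncol(lat)),
                                function(k) cor(a[, k], b[, k]), numeric(1))))
  }
  expect_true(all(abs(cors - 0.5) < 0.05))
})

test_that("with no effects and no mouse heterogeneity, genotype gap vanishes", {
  des <- study_design(c(WT_M = 50, KO_M = 50, WT_F = 50, KO_F = 50),
                      n_otus = 20, depth_mean = 10000, dropout_rate = 0,
                      seed = 41)
  g <- generate_cohort(des, cohort_truth(sigma_b = 0, sigma_e = 1,
                                         zero_inflation = 0))
  clr <- clr_transform(g$table, 0)
  meta <- g$table$sample_meta
  gap <- colMeans(clr$values[meta$genotype == "KO", ]) -
    colMeans(clr$values[meta$genotype == "WT", ])
  expect_lt(max(abs(gap)), 0.1)
})

test_that("injecting a zero-profile effect leaves the cohort unchanged", {
  des <- study_design(c(WT_M = 4, KO_M = 4, WT_F = 4, KO_F = 4),
                      n_otus = 15, depth_mean = 2000, seed = 51)
  g0 <- generate_cohort(des)
  tr <- inject_effect(cohort_truth(),
                      effect_profile(3, "genotype", rep(0, 6)))
  g1 <- generate_cohort(des, tr)
  expect_identical(g0$table$counts, g1$table$counts)
})

test_that("an injected week-16 genotype effect appears in the CLR gap", {
  # pointwise OLS oracle on a large cohort: gap ~ 2 at week 16, ~ 0 elsewhere
  des <- study_design(c(WT_M = 25, KO_M = 25, WT_F = 25, KO_F = 25),
                      n_otus = 30, depth_mean = 10000, dropout_rate = 0,
                      seed = 61)
  tr <- cohort_truth(sigma_b = 0, sigma_e = 1, zero_inflation = 0,
                     baseline = rep(0, 30))
  tr <- inject_effect(tr, effect_profile(4, "genotype", c(0, 0, 0, 0, 2, 0)))
  g <- generate_cohort(des, tr)
  clr <- clr_transform(g$table, 0)
  meta <- g$table$sample_meta
  for (w in std_weeks) {
    i <- meta$week == w
    ko <- clr$values[i & meta$genotype == "KO", "Otu0004"]
    wt <- clr$values[i & meta$genotype == "WT", "Otu0004"]
    gap <- mean(ko) - mean(wt)
    se <- sqrt(var(ko) / length(ko) + var(wt) / length(wt))
    target <- if (w == 16) 2 * (1 - 1 / 30) else 0
    expect_lt(abs(gap - target), 3 * se + 0.02)
  }
})

test_that("marginal zero fraction grows with configured zero inflation", {
  fr <- vapply(c(0, 0.3, 0.6), function(z) {
    des <- study_design(c(WT_M = 5, KO_M = 5, WT_F = 5, KO_F = 5),
                        n_otus = 30, depth_mean = 3000, seed = 71)
    mean(generate_cohort(des, cohort_truth(zero_inflation = z))$table$counts == 0)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("fixtures round-trip losslessly and regenerate identically", {
  g <- small_cohort(seed = 81, n_otus = 18)
  dir <- withr::local_tempdir()
  paths <- write_cohort_fixture(g$table, g$truth, dir)
  expect_true(all(file.exists(paths)))

  tab <- read_otu_table(paths["shared"], paths["taxonomy"], paths["metadata"])
  expect_equal(unname(tab$counts), unname(g$table$counts))
  expect_equal(tab$sample_meta$mouse_id, g$table$sample_meta$mouse_id)
  expect_equal(tab$taxonomy$lineage, g$table$taxonomy$lineage)
  expect_equal(nrow(read_cons_taxonomy(paths["taxonomy"])), 18)

  reloaded <- read_cohort_truth(paths["truth"])
  g2 <- generate_cohort(reloaded$design, reloaded$truth)
  expect_identical(g2$table$counts, g$table$counts)
})
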