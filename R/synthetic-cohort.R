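# Synthetic cohort generator.
#
# Emulates a two-genotype (WT / KO), two-sex murine carcinogenesis cohort
# sampled on a fixed week grid, with mouse-level random intercepts
# (compound-symmetric within-mouse correlation on the latent log scale),
# per-OTU structural zeros, time-localized covariate effects on the log
# scale, and multinomial count sampling at a drawn library size.  The
# generator carries its ground truth so downstream recovery tests can
# compare estimates against the injected effects.

#' Specify the study design of a synthetic cohort
#'
#' @param n_mice named integer vector of arm sizes for the four
#'   genotype x sex cells, names `WT_M`, `KO_M`, `WT_F`, `KO_F`.  Defaults
#'   mirror a 76-mouse cohort (22/13/20/21).
#' @param weeks strictly increasing integer visit grid (weeks
#'   post-carcinogen initiation).
#' @param n_otus number of OTUs (>= 10).
#' @param depth_mean expected library size in reads; per-sample depths are
#'   drawn Poisson around this.
#' @param dropout_rate per-visit missingness probability in `[0, 1)`
#'   (missing completely at random).
#' @param diagnosis_model named probabilities `c(WT = , KO = )` of an OSCC
#'   endpoint diagnosis (versus ED/CIS) per genotype.
#' @param seed integer seed; every draw in [generate_cohort()] derives from
#'   it.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_mice = c(WT_M = 22L, KO_M = 13L, WT_F = 20L, KO_F = 21L),
                         weeks = c(0L, 4L, 8L, 12L, 16L, 22L),
                         n_otus = 200L,
                         depth_mean = 20000,
                         dropout_rate = 0.1,
                         diagnosis_model = c(WT = 0.35, KO = 0.65),
                         seed = 1L) {
  cells <- c("WT_M", "KO_M", "WT_F", "KO_F")
  if (!all(cells %in% names(n_mice))) stop("n_mice needs names ", paste(cells, collapse = ", "))
  n_mice <- as.integer(n_mice[cells])
  if (any(n_mice < 1)) stop("each arm needs at least one mouse")
  weeks <- as.integer(weeks)
  if (length(weeks) < 2 || any(diff(weeks) <= 0)) stop("weeks must be strictly increasing")
  if (n_otus < 10) stop("n_otus must be >= 10")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (!all(c("WT", "KO") %in% names(diagnosis_model)) ||
      any(diagnosis_model < 0 | diagnosis_model > 1))
    stop("diagnosis_model must give probabilities in [0, 1] for WT and KO")
  structure(list(n_mice = setNames(n_mice, cells), weeks = weeks,
                 n_otus = as.integer(n_otus), depth_mean = depth_mean,
                 dropout_rate = dropout_rate,
                 diagnosis_model = diagnosis_model[c("WT", "KO")],
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Time-localized covariate effect on the log-abundance scale
#'
#' An effect profile is a per-week additive shift of one OTU's latent log
#' abundance, attached to a mouse-level covariate.  A profile that is zero
#' on some weeks and nonzero on others is exactly the locally sparse
#' signal the varying-coefficient model is built to recover.
#'
#' @param otu OTU index (column of the generated table).
#' @param covariate one of `"genotype"` (KO indicator), `"diagnosis"`
#'   (OSCC indicator), `"interaction"` (KO x OSCC) or `"sex"` (Female
#'   indicator).
#' @param profile numeric vector of per-week effect sizes (log scale),
#'   length equal to the design's week grid.
#' @param conditioning optional named list restricting the effect to a
#'   subgroup, e.g. `list(genotype = "KO")`.
#'
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(otu, covariate = c("genotype", "diagnosis", "interaction", "sex"),
                           profile, conditioning = NULL) {
  covariate <- match.arg(covariate)
  structure(list(otu = as.integer(otu), covariate = covariate,
                 profile = as.numeric(profile), conditioning = conditioning),
            class = "effect_profile")
}

#' Ground-truth configuration for the synthetic cohort
#'
#' @param sigma_b mouse random-intercept SD on the latent log scale
#'   (per mouse x OTU); with `sigma_e` it implies a compound-symmetric
#'   within-mouse correlation `sigma_b^2 / (sigma_b^2 + sigma_e^2)`.
#' @param sigma_e residual (visit-level) SD on the latent log scale.
#' @param zero_inflation per-OTU structural-zero probability in `[0, 1)`;
#'   a scalar is recycled.  Structural zeros are drawn per mouse x OTU, so
#'   an absent taxon stays absent across a mouse's visits.
#' @param baseline optional length-`n_otus` vector of baseline log
#'   abundances; if `NULL`, drawn `N(0, 2)` from the assignment stream.
#' @param effects list of [effect_profile()] objects.
#' @param taxon_correlations optional list of planted latent associations,
#'   each `list(pair = c(i, j), rho = r)`: the latent noise (random
#'   intercept and visit noise) of OTU `j` is correlated at `r` with OTU
#'   `i`, inducing a conditional-dependence edge between their taxa.
#'
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(sigma_b = 0.7, sigma_e = 1, zero_inflation = 0.3,
                         baseline = NULL, effects = list(),
                         taxon_correlations = list()) {
  if (sigma_b < 0) stop("sigma_b must be >= 0")
  if (sigma_e <= 0) stop("sigma_e must be > 0")
  if (any(zero_inflation < 0 | zero_inflation >= 1))
    stop("zero_inflation must be in [0, 1)")
  for (tc in taxon_correlations)
    if (length(tc$pair) != 2 || abs(tc$rho) > 1)
      stop("taxon_correlations entries need pair = c(i, j) and |rho| <= 1")
  structure(list(sigma_b = sigma_b, sigma_e = sigma_e,
                 zero_inflation = zero_inflation, baseline = baseline,
                 effects = effects, taxon_correlations = taxon_correlations),
            class = "cohort_truth")
}

#' Add an effect profile to a cohort truth
#'
#' @param truth a [cohort_truth()] object.
#' @param effect an [effect_profile()].
#' @return The truth with the effect appended.  Duplicate
#'   (otu, covariate, conditioning) combinations are rejected.
#' @export
inject_effect <- function(truth, effect) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(effect, "effect_profile"))
  key <- function(e) paste(e$otu, e$covariate,
                           paste(deparse(e$conditioning), collapse = ""), sep = "|")
  if (key(effect) %in% vapply(truth$effects, key, character(1)))
    stop("duplicate effect for (otu, covariate, conditioning)")
  truth$effects <- c(truth$effects, list(effect))
  truth
}

# Synthetic hierarchical taxonomy: domain;phylum;class;order;family;genus.
# A fraction of OTUs is left unclassified at the genus rank, as real
# consensus taxonomies are.
synth_taxonomy <- function(n_otus, unclassified_frac = 0.15) {
  n_gen <- max(6L, ceiling(n_otus / 4))
  n_fam <- max(5L, ceiling(n_gen / 2.5))
  n_ord <- max(4L, ceiling(n_fam / 2.5))
  n_cls <- max(3L, ceiling(n_ord / 2))
  n_phy <- max(2L, min(6L, ceiling(n_cls / 2)))
  fam_of_gen <- sample.int(n_fam, n_gen, replace = TRUE)
  ord_of_fam <- sample.int(n_ord, n_fam, replace = TRUE)
  cls_of_ord <- sample.int(n_cls, n_ord, replace = TRUE)
  phy_of_cls <- sample.int(n_phy, n_cls, replace = TRUE)
  gen <- sample.int(n_gen, n_otus, replace = TRUE)
  uncls <- runif(n_otus) < unclassified_frac
  fam <- fam_of_gen[gen]; ord <- ord_of_fam[fam]
  cls <- cls_of_ord[ord]; phy <- phy_of_cls[cls]
  lineage <- sprintf("Bacteria;Phylum_%02d;Class_%02d;Order_%02d;Family_%03d;%s",
                     phy, cls, ord, fam,
                     ifelse(uncls, "unclassified", sprintf("Genus_%03d", gen)))
  data.frame(otu = sprintf("Otu%04d", seq_len(n_otus)), size = 0L,
             lineage = lineage, stringsAsFactors = FALSE)
}

# Covariate value of an effect for each mouse, including conditioning.
effect_x <- function(effect, assign) {
  x <- switch(effect$covariate,
              genotype = as.numeric(assign$genotype == "KO"),
              diagnosis = as.numeric(assign$diagnosis == "OSCC"),
              interaction = as.numeric(assign$genotype == "KO" & assign$diagnosis == "OSCC"),
              sex = as.numeric(assign$sex == "F"))
  if (!is.null(effect$conditioning)) {
    for (nm in names(effect$conditioning))
      x <- x * as.numeric(assign[[nm]] == effect$conditioning[[nm]])
  }
  x
}

#' Generate a synthetic cohort with ground truth
#'
#' Latent per-sample log abundance is
#' `baseline + sum(active effects) + mouse intercept + noise`; counts are
#' drawn multinomially from the softmax of the latent vector (structural
#' zeros excluded) at a Poisson-drawn library size, so row sums equal the
#' drawn depths exactly.  Two RNG streams are used: cohort structure
#' (assignments, taxonomy, baseline, visit mask) and measurement (random
#' effects, noise, structural zeros, depths, counts), so injecting an
#' effect never perturbs the cohort structure.  Identical seeds give
#' identical output.
#'
#' @param design a [study_design()].
#' @param truth a [cohort_truth()]; defaults to a null cohort.
#' @param keep_latent keep the latent log-abundance matrix in the returned
#'   truth (useful for calibration tests).
#' @param dropout_action `"regenerate"` redraws a mouse's visit mask until
#'   it keeps >= 2 visits; `"error"` fails instead.
#'
#' @return list with `table` (an [otu_count_table()]) and `truth` (the
#'   input truth augmented with realized `baseline`, `assignments`,
#'   `visit_mask` and, optionally, `latent`).
#' @export
generate_cohort <- function(design, truth = cohort_truth(), keep_latent = TRUE,
                            dropout_action = c("regenerate", "error")) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "cohort_truth"))
  dropout_action <- match.arg(dropout_action)
  weeks <- design$weeks; n_wk <- length(weeks); n_otus <- design$n_otus
  zi <- rep_len(truth$zero_inflation, n_otus)
  for (e in truth$effects)
    if (length(e$profile) != n_wk)
      stop("effect profile length ", length(e$profile), " != number of weeks ", n_wk)
  for (e in truth$effects)
    if (e$otu < 1 || e$otu > n_otus) stop("effect otu index out of range")

  ## --- stream A: cohort structure -------------------------------------
  set.seed(derive_seed(design$seed, 1L))
  cells <- names(design$n_mice)
  genotype <- rep(sub("_.*", "", cells), design$n_mice)
  sex <- rep(sub(".*_", "", cells), design$n_mice)
  n_mice <- length(genotype)
  mouse_id <- sprintf("M%03d", seq_len(n_mice))
  diagnosis <- ifelse(runif(n_mice) < design$diagnosis_model[genotype], "OSCC", "ED/CIS")
  assign <- data.frame(mouse_id = mouse_id, genotype = genotype, sex = sex,
                       diagnosis = diagnosis, stringsAsFactors = FALSE)
  taxonomy <- synth_taxonomy(n_otus)
  # draw unconditionally so stream consumption does not depend on whether
  # a baseline was supplied (keeps regeneration from a stored truth exact)
  base_draw <- rnorm(n_otus, 0, 2)
  baseline <- truth$baseline %||% base_draw
  if (length(baseline) != n_otus) stop("baseline length != n_otus")
  visit_mask <- matrix(runif(n_mice * n_wk) >= design$dropout_rate, n_mice, n_wk,
                       dimnames = list(mouse_id, paste0("w", weeks)))
  short <- rowSums(visit_mask) < 2
  if (any(short) && dropout_action == "error")
    stop("dropout left ", sum(short), " mice with < 2 visits")
  while (any(short)) {
    visit_mask[short, ] <- runif(sum(short) * n_wk) >= design$dropout_rate
    short <- rowSums(visit_mask) < 2
  }

  ## --- stream B: measurement ------------------------------------------
  set.seed(derive_seed(design$seed, 2L))
  b <- matrix(rnorm(n_mice * n_otus, 0, truth$sigma_b), n_mice, n_otus)
  idx <- which(visit_mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n_samp <- nrow(idx)
  eps <- matrix(rnorm(n_samp * n_otus, 0, truth$sigma_e), n_samp, n_otus)
  for (tc in truth$taxon_correlations %||% list()) {
    i1 <- tc$pair[1]; i2 <- tc$pair[2]; rho <- tc$rho
    b[, i2] <- rho * b[, i1] + sqrt(1 - rho^2) * b[, i2]
    eps[, i2] <- rho * eps[, i1] + sqrt(1 - rho^2) * eps[, i2]
  }
  structural <- matrix(runif(n_mice * n_otus) < rep(zi, each = n_mice), n_mice, n_otus)
  # guard: a mouse must retain at least one taxon
  all_zero <- rowSums(!structural) == 0
  if (any(all_zero)) structural[all_zero, which.max(baseline)] <- FALSE
  depths <- rpois(n_samp, design$depth_mean)
  depths[depths < 1] <- 1L

  eta <- matrix(baseline, n_samp, n_otus, byrow = TRUE) + b[idx[, 1], , drop = FALSE] + eps
  for (e in truth$effects) {
    x <- effect_x(e, assign)[idx[, 1]]
    eta[, e$otu] <- eta[, e$otu] + x * e$profile[idx[, 2]]
  }

  counts <- matrix(0L, n_samp, n_otus)
  for (s in seq_len(n_samp)) {
    p <- exp(eta[s, ] - max(eta[s, ]))
    p[structural[idx[s, 1], ]] <- 0
    counts[s, ] <- as.integer(rmultinom(1, depths[s], p))
  }
  sample_id <- sprintf("%s_w%02d", mouse_id[idx[, 1]], weeks[idx[, 2]])
  dimnames(counts) <- list(sample_id, taxonomy$otu)
  meta <- data.frame(sample_id = sample_id,
                     mouse_id = mouse_id[idx[, 1]],
                     genotype = assign$genotype[idx[, 1]],
                     sex = assign$sex[idx[, 1]],
                     week = weeks[idx[, 2]],
                     diagnosis = assign$diagnosis[idx[, 1]],
                     stringsAsFactors = FALSE)
  taxonomy$size <- colSums(counts)
  table <- otu_count_table(counts, meta, taxonomy)
  truth$baseline <- baseline
  truth$zero_inflation <- zi
  truth$design <- design
  truth$assignments <- assign
  truth$visit_mask <- visit_mask
  truth$structural_zeros <- structural
  truth$depths <- setNames(depths, sample_id)
  if (keep_latent) truth$latent <- `dimnames<-`(eta, list(sample_id, taxonomy$otu))
  list(table = table, truth = truth)
}

#' Write a synthetic cohort to disk as plain-text fixture files
#'
#' Emits a mothur-dialect `.shared` count file, a `.cons.taxonomy` file, a
#' metadata TSV and a truth JSON sufficient to regenerate the identical
#' cohort via [read_cohort_truth()] + [generate_cohort()].
#'
#' @param table,truth output of [generate_cohort()].
#' @param dir writable output directory (created if absent).
#' @param stem file name stem.
#' @return Named vector of written paths.
#' @export
write_cohort_fixture <- function(table, truth, dir, stem = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(shared = file.path(dir, paste0(stem, ".shared")),
             taxonomy = file.path(dir, paste0(stem, ".cons.taxonomy")),
             metadata = file.path(dir, paste0(stem, ".metadata.tsv")),
             truth = file.path(dir, paste0(stem, ".truth.json")))
  write_shared(table$counts, paths["shared"])
  write_cons_taxonomy(table$taxonomy, paths["taxonomy"])
  write.table(table$sample_meta, paths["metadata"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  des <- unclass(truth$design)
  des$n_mice <- as.list(des$n_mice)              # keep names in JSON
  des$diagnosis_model <- as.list(des$diagnosis_model)
  tj <- list(design = des,
             sigma_b = truth$sigma_b, sigma_e = truth$sigma_e,
             zero_inflation = truth$zero_inflation,
             baseline = truth$baseline,
             effects = lapply(truth$effects, function(e)
               list(otu = e$otu, covariate = e$covariate, profile = e$profile,
                    conditioning = e$conditioning)),
             taxon_correlations = truth$taxon_correlations %||% list())
  jsonlite::write_json(tj, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Reload a cohort truth JSON written by [write_cohort_fixture()]
#'
#' @param path truth JSON path.
#' @return list with `design` ([study_design()]) and `truth`
#'   ([cohort_truth()]); passing these to [generate_cohort()] reproduces
#'   the identical cohort.
#' @export
read_cohort_truth <- function(path) {
  tj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- tj$design
  design <- study_design(n_mice = unlist(d$n_mice), weeks = d$weeks,
                         n_otus = d$n_otus, depth_mean = d$depth_mean,
                         dropout_rate = d$dropout_rate,
                         diagnosis_model = unlist(d$diagnosis_model),
                         seed = d$seed)
  effects <- lapply(
    if (is.data.frame(tj$effects)) split(tj$effects, seq_len(nrow(tj$effects))) else tj$effects,
    function(e) effect_profile(e$otu, e$covariate, unlist(e$profile),
                               as.list(e$conditioning %||% NULL)))
  if (length(effects) && any(vapply(effects, function(e) length(e$conditioning) == 0, logical(1))))
    effects <- lapply(effects, function(e) { if (length(e$conditioning) == 0) e$conditioning <- NULL; e })
  tcs <- lapply(tj$taxon_correlations %||% list(), function(tc)
    list(pair = unlist(tc$pair), rho = tc$rho))
  truth <- cohort_truth(sigma_b = tj$sigma_b, sigma_e = tj$sigma_e,
                        zero_inflation = tj$zero_inflation,
                        baseline = tj$baseline, effects = effects,
                        taxon_correlations = tcs)
  list(design = design, truth = truth)
}
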