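# End-to-end orchestration: configuration, stage execution, artifact
# manifest.

#' Pipeline configuration
#'
#' Builds and validates the configuration driving
#' [run_full_analysis()].  Either simulation parameters (`design`) or
#' input file paths (`shared`, `taxonomy`, `metadata`) must be given.
#'
#' @param output_dir artifact directory.
#' @param seed global seed; every stage derives its own stream from it.
#' @param stages named logical toggles for
#'   `simulate`, `prep`, `diversity`, `lsvcmm`, `fpca`, `network`,
#'   `stats`; missing names default to `TRUE`.
#' @param design arguments for [study_design()] when simulating.
#' @param truth arguments for [cohort_truth()] when simulating.
#' @param shared,taxonomy,metadata input paths when ingesting real data.
#' @param rarefaction_depth reads per sample for the diversity stage.
#' @param prevalence_lsvcmm,prevalence_network prevalence filters.
#' @param clr_on_rarefied run the CLR stage on rarefied counts instead of
#'   raw counts.
#' @param variant LSVCMM model variant.
#' @param max_otus cap on the number of OTUs modeled by the LSVCMM/fPCA
#'   stages (most prevalent first); `Inf` for all retained.
#' @param n_boot bootstrap replicates per OTU.
#' @param ebic_gamma EBIC gamma.
#' @param folds CV folds for the Lasso logistic stage.
#' @param network_rank `"family"` or `"genus"`.
#' @param stars_subsamples,stars_beta StARS settings.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L, stages = list(),
                            design = list(), truth = list(),
                            shared = NULL, taxonomy = NULL, metadata = NULL,
                            rarefaction_depth = 9484L,
                            prevalence_lsvcmm = 0.05,
                            prevalence_network = 0.10,
                            clr_on_rarefied = FALSE,
                            variant = "interaction",
                            max_otus = 10L, n_boot = 200L,
                            ebic_gamma = 0.5, folds = 5L,
                            network_rank = "family",
                            stars_subsamples = 20L, stars_beta = 0.05) {
  all_stages <- c("simulate", "prep", "diversity", "lsvcmm", "fpca",
                  "network", "stats")
  st <- setNames(rep(TRUE, length(all_stages)), all_stages)
  for (nm in names(stages)) {
    if (!nm %in% all_stages) stop("unknown stage: ", nm)
    st[nm] <- isTRUE(stages[[nm]])
  }
  if (!st["simulate"]) {
    for (p in c(shared, taxonomy, metadata))
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    if (is.null(shared) || is.null(taxonomy) || is.null(metadata))
      stop("either enable the simulate stage or give shared/taxonomy/metadata paths")
  }
  stopifnot(rarefaction_depth >= 1,
            prevalence_lsvcmm >= 0, prevalence_lsvcmm < 1,
            prevalence_network >= 0, prevalence_network < 1,
            n_boot >= 200, folds >= 2, stars_subsamples >= 10,
            stars_beta > 0, stars_beta <= 0.5)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = as.list(st), design = design, truth = truth,
                 shared = shared, taxonomy = taxonomy, metadata = metadata,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 prevalence_lsvcmm = prevalence_lsvcmm,
                 prevalence_network = prevalence_network,
                 clr_on_rarefied = clr_on_rarefied,
                 variant = variant, max_otus = max_otus,
                 n_boot = as.integer(n_boot), ebic_gamma = ebic_gamma,
                 folds = as.integer(folds), network_rank = network_rank,
                 stars_subsamples = as.integer(stars_subsamples),
                 stars_beta = stars_beta),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns the path invisibly.  A write/read
#'   round trip is the identity.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full longitudinal microbiome analysis
#'
#' Executes the enabled stages in order (simulate/ingest, compositional
#' prep, diversity/ecology, LSVCMM differential abundance, fPCA trend
#' prediction, conditional-dependence networks, contingency statistics),
#' writing every artifact plus a manifest recording inputs, parameters,
#' seeds and file hashes.  Reruns with the same config are bit-identical
#' for seeded stages.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `manifest` and
#'   the per-stage result objects.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  results <- list()
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      params = params,
      seed = derive_seed(config$seed, match(stage, names(config$stages))),
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  }
  run_stage <- function(stage, fn) {
    if (!isTRUE(config$stages[[stage]])) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- function(...) file.path(config$output_dir, ...)

  ## simulate or ingest -------------------------------------------------
  table <- NULL; truth <- NULL
  run_stage("simulate", function() {
    des <- do.call(study_design, modifyList(list(seed = config$seed), config$design))
    tru <- do.call(cohort_truth, config$truth)
    g <- generate_cohort(des, tru, keep_latent = FALSE)
    table <<- g$table; truth <<- g$truth
    paths <- write_cohort_fixture(g$table, g$truth, out("fixtures"))
    record("simulate", list(design = unclass(des)), paths)
    results$simulate <<- g["truth"]
  })
  if (is.null(table)) {
    table <- read_otu_table(config$shared, config$taxonomy, config$metadata)
    if (isTRUE(config$stages$simulate))
      stop("stage 'simulate' failed: no cohort generated")
  }

  ## prep ----------------------------------------------------------------
  clr <- NULL; rarefied <- NULL
  run_stage("prep", function() {
    rarefied <<- suppressWarnings(
      rarefy(table, config$rarefaction_depth, seed = config$seed))
    base <- if (config$clr_on_rarefied) rarefied else table
    clr <<- clr_transform(base, config$prevalence_lsvcmm)
    paths <- write_clr(clr, out("prep"))
    record("prep", list(prevalence = config$prevalence_lsvcmm,
                        depth = config$rarefaction_depth,
                        clr_on_rarefied = config$clr_on_rarefied), paths)
    results$prep <<- clr
  })

  ## diversity / ecology --------------------------------------------------
  run_stage("diversity", function() {
    if (is.null(rarefied)) stop("prep stage required first")
    tab <- if (nrow(rarefied$counts) >= 4) rarefied else table
    meta <- tab$sample_meta
    base <- meta$week == min(meta$week)
    dm <- theta_yc_dist(subset_table(tab, samples = which(base)))
    am <- amova(dm, meta$genotype[base], n_perm = 999, seed = config$seed)
    div <- apply(tab$counts, 1, inverse_simpson)
    rich <- apply(tab$counts, 1, observed_richness)
    tt_div <- diversity_t_test(div[meta$genotype == "WT"], div[meta$genotype == "KO"])
    tt_rich <- diversity_t_test(rich[meta$genotype == "WT"], rich[meta$genotype == "KO"])
    nm <- nmds_embed(dm, seed = config$seed)
    paths <- c(out("ecology.distance.tsv"), out("ecology.report.json"))
    write.table(data.frame(sample_id = dm$ids, dm$d, check.names = FALSE),
                paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(amova = list(F = am$F_statistic, p = am$p_value),
                              diversity_t = tt_div, richness_t = tt_rich,
                              nmds_stress = nm$stress),
                         paths[2], auto_unbox = TRUE, digits = NA)
    record("diversity", list(n_perm = 999), paths)
    results$diversity <<- list(amova = am, diversity_t = tt_div,
                               richness_t = tt_rich, nmds = nm)
  })

  ## lsvcmm ----------------------------------------------------------------
  otus_used <- NULL
  run_stage("lsvcmm", function() {
    if (is.null(clr)) stop("prep stage required first")
    prev <- sort(clr$prevalence[clr$retained_otus], decreasing = TRUE)
    otus_used <<- head(names(prev), config$max_otus)
    an <- lsvcmm(clr, table$sample_meta, variant = config$variant,
                 otus = otus_used, n_boot = config$n_boot,
                 seed = derive_seed(config$seed, 10L) %% 100000,
                 gamma = config$ebic_gamma)
    p <- out("lsvcmm.significance.tsv")
    write.table(as.data.frame(an$table), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    record("lsvcmm", list(variant = config$variant, n_boot = config$n_boot,
                          gamma = config$ebic_gamma, otus = otus_used), p)
    results$lsvcmm <<- an
  })

  ## fpca -------------------------------------------------------------------
  run_stage("fpca", function() {
    if (is.null(clr)) stop("prep stage required first")
    prev <- sort(clr$prevalence[clr$retained_otus], decreasing = TRUE)
    otus <- otus_used %||% head(names(prev), config$max_otus)
    rep <- fpca_trend(clr, table$sample_meta, otus = otus,
                      nfolds = config$folds,
                      seed = derive_seed(config$seed, 11L) %% 100000)
    paths <- c(out("fpca.scores.tsv"), out("fpca.report.json"))
    write.table(data.frame(mouse_id = rownames(rep$features), rep$features,
                           check.names = FALSE),
                paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(rep$per_genotype, function(r) if (is.null(r)) NULL else
        list(lambda = r$lambda, predictive_otus = r$predictive_otus)),
      paths[2], auto_unbox = TRUE, digits = NA)
    record("fpca", list(threshold = 0.99, folds = config$folds), paths)
    results$fpca <<- rep
  })

  ## networks ----------------------------------------------------------------
  run_stage("network", function() {
    nets <- list()
    for (g in c("WT", "KO")) {
      ng <- suppressWarnings(build_period_networks(
        table, rank = config$network_rank, genotype = g,
        prevalence_min = config$prevalence_network,
        n_subsamples = config$stars_subsamples,
        beta_threshold = config$stars_beta,
        seed = derive_seed(config$seed, 12L) %% 100000))
      nets <- c(nets, ng)
    }
    edges <- do.call(rbind, lapply(nets, function(n)
      if (nrow(n$edges)) cbind(n$edges, genotype = n$genotype, period = n$period)))
    p1 <- out("network.edges.tsv")
    write.table(edges %||% data.frame(), p1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- p1
    if (length(nets) >= 2) {
      cmp <- compare_networks(nets)
      p2 <- out("network.presence.tsv")
      write.table(data.frame(edge = rownames(cmp$presence), cmp$presence,
                             class = cmp$class, check.names = FALSE),
                  p2, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p2)
      results$network_comparison <<- cmp
    }
    record("network", list(rank = config$network_rank,
                           beta = config$stars_beta), paths)
    results$networks <<- nets
  })

  ## contingency stats --------------------------------------------------------
  run_stage("stats", function() {
    mice <- unique(table$sample_meta[, c("mouse_id", "genotype", "sex", "diagnosis")])
    tab2 <- table(mice$genotype, mice$diagnosis)
    strata <- table(mice$genotype, mice$diagnosis, mice$sex)
    res <- suppressWarnings(contingency_tests(
      tab2, stratum = if (dim(strata)[3] >= 2) strata else NULL))
    p <- out("stats.contingency.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
    record("stats", list(), p)
    results$stats <<- res
  })

  mpath <- out("manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  structure(c(list(manifest = manifest, manifest_path = mpath), results),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", length(x$manifest$stages), "stage(s) executed\n")
  cat("  ", paste(names(x$manifest$stages), collapse = ", "), "\n")
  invisible(x)
}
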