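#' Run configuration for the full pipeline
#'
#' One object drives simulate -> preprocess -> calibrate -> predict ->
#' genetic parameters -> selection index. The default is a scaled-down
#' demonstration; pass a [sim_config] matching the experimental design for
#' a full-size run. A YAML file with the same field names may be given
#' instead of arguments.
#'
#' @param simulation a [sim_config].
#' @param recipe a [preprocess_recipe] (the retained pre-treatment).
#' @param recipe_grid optional list of recipes to search by SECV first.
#' @param n_select calibration-set size.
#' @param n_groups cross-validation groups.
#' @param ncomp_grid candidate latent-variable counts.
#' @param traits traits to analyze genetically (measured + predicted).
#' @param chain,burn_in,thin Gibbs settings.
#' @param seed master seed propagated to every stochastic stage.
#' @param file optional YAML path; fields present in the file override the
#'   corresponding arguments.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(simulation = sim_config(n_crossbreds = 300,
                                               n_dams = 80, n_sires = 16,
                                               n_common = 140,
                                               n_muscovy = 40,
                                               spectral_grid = seq(350, 2500, by = 8)),
                       recipe = preprocess_recipe(),
                       recipe_grid = NULL,
                       n_select = 100, n_groups = 5, ncomp_grid = 1:8,
                       traits = c("mMR", "pMR"),
                       chain = 4000, burn_in = 1000, thin = 1,
                       seed = 1L, file = NULL) {
  cfg <- list(simulation = simulation, recipe = recipe,
              recipe_grid = recipe_grid, n_select = n_select,
              n_groups = n_groups, ncomp_grid = ncomp_grid,
              traits = traits, chain = chain, burn_in = burn_in,
              thin = thin, seed = seed)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (nm in intersect(names(y), c("n_select", "n_groups", "ncomp_grid",
                                     "traits", "chain", "burn_in", "thin",
                                     "seed")))
      cfg[[nm]] <- y[[nm]]
    if (!is.null(y$simulation))
      cfg$simulation <- do.call(sim_config, y$simulation)
    if (!is.null(y$recipe))
      cfg$recipe <- do.call(preprocess_recipe, y$recipe)
  }
  class(cfg) <- "run_config"
  cfg
}

.write_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages, in order: (1) simulate pedigrees, breeding values, crossbred
#' phenotypes and surface spectra; (2) preprocess spectra with the recipe
#' (after an optional recipe search by SECV); (3) calibrate the measured
#' melting rate on a representative subset and validate externally;
#' (4) predict the melting rate for every liver from its spectra;
#' (5) estimate crossbred genetic parameters for the measured and
#' NIRS-predicted melting rates jointly; (6) compute the selection-index
#' accuracy of predicting the measured-trait breeding value from the
#' predicted trait. Every stage writes plain CSV into `outdir` and is
#' recorded in `manifest.json`. A failed stage halts with its name.
#'
#' @param config a [run_config].
#' @param outdir output directory (created if needed).
#' @param seed overrides `config$seed`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = run_config(), outdir, seed = config$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, started = NULL, stages = list())
  step <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(outputs = attr(res, "outputs"))
    res
  }

  sim <- step("simulate", {
    st <- simulate_study(config$simulation, seed = seed,
                         spectra = "surface")
    outs <- c(
      write_pedigree(st$pedigrees$dam, file.path(outdir, "pedigree_common.csv")),
      write_pedigree(st$pedigrees$sire, file.path(outdir, "pedigree_muscovy.csv")),
      .write_csv(st$phenotypes, file.path(outdir, "phenotypes.csv")),
      .write_csv(st$truth, file.path(outdir, "truth.csv")),
      write_spectra(st$spectra$surface, file.path(outdir, "spectra_raw.csv")))
    attr(st, "outputs") <- basename(unlist(outs))
    st
  })

  recipe <- config$recipe
  if (!is.null(config$recipe_grid)) {
    recipe <- step("recipe_search", {
      mr <- sim$phenotypes$mMR
      names(mr) <- sim$phenotypes$id
      gs <- grid_search_recipes(config$recipe_grid, sim$spectra$surface,
                                mr, config$ncomp_grid,
                                config$n_groups, seed = seed)
      .write_csv(gs$table, file.path(outdir, "recipe_search.csv"))
      r <- gs$best
      attr(r, "outputs") <- "recipe_search.csv"
      r
    })
  }

  proc <- step("preprocess", {
    pr <- apply_recipe(sim$spectra$surface, recipe)
    write_spectra(pr, file.path(outdir, "spectra_processed.csv"))
    attr(pr, "outputs") <- "spectra_processed.csv"
    pr
  })

  cal <- step("calibrate", {
    mr <- sim$phenotypes$mMR
    names(mr) <- sim$phenotypes$id
    cc <- nirs_calibration(sim$spectra$surface, mr, recipe,
                           n_select = min(config$n_select,
                                          length(mr) - config$n_groups),
                           ncomp_grid = config$ncomp_grid,
                           n_groups = config$n_groups, seed = seed)
    s <- cc$stats
    .write_csv(data.frame(n = s$n, mean = s$mean, sd = s$sd, sec = s$sec,
                          r2 = s$r2, secv = s$secv, ncomp = s$ncomp,
                          n_ext = s$n_ext, sep = s$sep, bias = s$bias),
               file.path(outdir, "calibration_stats.csv"))
    writeLines(jsonlite::toJSON(list(
      recipe = unclass(recipe),
      ncomp = cc$model$ncomp, intercept = cc$model$intercept,
      x_mean = cc$model$x_mean, coefficients = cc$model$coefficients),
      digits = NA, auto_unbox = TRUE),
      file.path(outdir, "calibration_model.json"))
    attr(cc, "outputs") <- c("calibration_stats.csv", "calibration_model.json")
    cc
  })

  pred <- step("predict", {
    p <- predict(cal$model, as.matrix(proc))
    d <- data.frame(id = proc$sample_id, pMR = p)
    .write_csv(d, file.path(outdir, "predicted_traits.csv"))
    attr(d, "outputs") <- "predicted_traits.csv"
    d
  })

  fit <- step("genpar", {
    phen <- merge(sim$phenotypes, pred, by = "id")
    phen <- phen[order(phen$id), ]
    f <- cross_gibbs(cbind(mMR, pMR) ~ factor(level), phen,
                     sim$pedigrees$dam, sim$pedigrees$sire,
                     chain = config$chain, burn_in = config$burn_in,
                     thin = config$thin, seed = seed)
    sm <- summary(f)
    .write_csv(sm$h2, file.path(outdir, "heritabilities.csv"))
    .write_csv(sm$rg, file.path(outdir, "genetic_correlations.csv"))
    ed <- ebv(f, "dam"); es <- ebv(f, "sire")
    .write_csv(data.frame(id = rownames(ed), ed, check.names = FALSE),
               file.path(outdir, "ebv_common.csv"))
    .write_csv(data.frame(id = rownames(es), es, check.names = FALSE),
               file.path(outdir, "ebv_muscovy.csv"))
    attr(f, "outputs") <- c("heritabilities.csv", "genetic_correlations.csv",
                            "ebv_common.csv", "ebv_muscovy.csv")
    f
  })

  idx <- step("index", {
    rows <- do.call(rbind, lapply(c("dam", "sire"), function(line) {
      ia <- index_from_components(fit, target = "mMR", line = line)
      data.frame(line = line, target = "mMR", predictors = "pMR",
                 accuracy = ia$accuracy)
    }))
    .write_csv(rows, file.path(outdir, "index_accuracy.csv"))
    attr(rows, "outputs") <- "index_accuracy.csv"
    rows
  })

  manifest$config_hash <- unname(tools::md5sum(
    .write_csv(data.frame(key = "seed", value = seed),
               file.path(outdir, "run_seed.csv"))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null"),
             file.path(outdir, "manifest.json"))
  invisible(list(sim = sim, recipe = recipe, calibration = cal,
                 predictions = pred, fit = fit, index = idx,
                 manifest = manifest, outdir = outdir))
}

#' Human-readable report of a pipeline run
#'
#' Renders the calibration-statistics table and the genetic-parameter
#' tables from the CSV outputs of [run_all]. Missing stage outputs produce
#' warnings and a partial report rather than an error.
#'
#' @param run_dir directory written by [run_all].
#' @return Invisibly, a list of the tables found; printed to the console.
#' @export
report <- function(run_dir) {
  get <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) {
      warning("missing output: ", f)
      return(NULL)
    }
    utils::read.csv(p, check.names = FALSE)
  }
  out <- list(calibration = get("calibration_stats.csv"),
              heritabilities = get("heritabilities.csv"),
              genetic_correlations = get("genetic_correlations.csv"),
              index = get("index_accuracy.csv"))
  if (!is.null(out$calibration)) {
    cat("== Calibration (SEC / SECV / SEP in trait units) ==\n")
    print(out$calibration, row.names = FALSE, digits = 3)
  }
  if (!is.null(out$heritabilities)) {
    cat("\n== Partial heritabilities ==\n")
    print(out$heritabilities, row.names = FALSE, digits = 3)
  }
  if (!is.null(out$genetic_correlations)) {
    cat("\n== Genetic correlations ==\n")
    print(out$genetic_correlations, row.names = FALSE, digits = 3)
  }
  if (!is.null(out$index)) {
    cat("\n== Selection-index accuracy ==\n")
    print(out$index, row.names = FALSE, digits = 3)
  }
  invisible(out)
}
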