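family_from_config <- function(cfg) {
  cfg <- cfg %||% list(name = "linear")
  nm <- cfg$name %||% "linear"
  switch(nm,
    linear = family_linear(),
    lasso = family_regularized("l1", lambda = cfg$lambda %||% "auto"),
    ridge = family_regularized("l2", lambda = cfg$lambda %||% "auto"),
    random_forest = family_random_forest(n_trees = cfg$n_trees %||% 500,
                                         seed = cfg$seed %||% 1),
    lnm = family_lnm(prior_sigma2 = cfg$prior_sigma2 %||% 1),
    hurdle = family_hurdle(),
    abort(sprintf("unknown family '%s'", nm), "medipath_config_error")
  )
}

roles_from_config <- function(cfg) {
  sel <- function(x) {
    if (is.list(x) && !is.null(x$prefix)) return(starts_with(x$prefix))
    if (is.list(x)) return(lapply(x, sel))
    x
  }
  role_map(treatment = unlist(cfg$treatment),
           mediators = sel(cfg$mediators),
           outcomes = sel(cfg$outcomes),
           pretreatment = sel(cfg$pretreatment %||% character()))
}

default_seed <- function(x, stage) {
  if (is.null(x)) {
    message(sprintf("[%s] no seed supplied; defaulting to 1", stage))
    1L
  } else {
    as.integer(x)
  }
}

known_config_keys <- c("input", "roles", "mediator_family", "outcome_family",
                       "contrast", "bootstrap", "fdr", "sensitivity",
                       "output_dir")

#' Run the end-to-end mediation workflow from a configuration
#'
#' Reads a sample table, assigns roles, fits the mediation model, and runs
#' the selected stages, writing tidy CSV/JSON artifacts plus a manifest
#' (config echo, package version, seeds) to the output directory.  Stage
#' errors abort with the stage named; artifacts from earlier stages are
#' preserved.
#'
#' @param config a named list, or path to a YAML file, with entries `input`
#'   (`path`, `format`), `roles` (`treatment`, `mediators`, `outcomes`,
#'   `pretreatment`; selections may be literal names or `list(prefix = )`),
#'   `mediator_family` / `outcome_family` (`name` plus settings), `contrast`
#'   (pair or list of pairs), `bootstrap` (`B`, `alpha`, `seed`), `fdr`
#'   (`q`, `null_edges`, `statistic`, `seed`), `sensitivity` (`rho_grid`,
#'   `G`, `n_reps`, `seed`), and `output_dir`.  Unknown top-level keys are
#'   rejected.
#' @param stages subset of `c("fit", "effects", "bootstrap", "fdr",
#'   "sensitivity")`.
#' @return invisibly, a list with the fitted model and stage outputs.
#' @export
run_pipeline <- function(config,
                         stages = c("fit", "effects", "bootstrap", "fdr",
                                    "sensitivity")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read config files",
            "medipath_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  extra <- setdiff(names(config), known_config_keys)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
          "medipath_config_error")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "medipath_stage_error")
    })
  }
  results <- list()

  message("[fit] reading data and estimating models")
  fitted <- run_stage("fit", {
    tab <- read_table(config$input$path,
                      format = config$input$format %||% "auto")
    data <- mediation_data(tab, roles_from_config(config$roles))
    model <- multimedia(data,
                        outcome_family = family_from_config(config$outcome_family),
                        mediator_family = family_from_config(config$mediator_family))
    list(model = estimate(model, data), data = data)
  })
  model <- results$model <- fitted$model
  data <- results$data <- fitted$data
  contrast <- config$contrast

  if ("effects" %in% stages) {
    message("[effects] computing direct, overall and pathwise effects")
    results$effects <- run_stage("effects", {
      eff <- rbind(as.data.frame(direct_effect(model, data, contrast))[
                     , c("outcome", "contrast", "effect_type",
                         "component_1", "component_2", "estimate")],
                   as.data.frame(indirect_overall(model, data, contrast))[
                     , c("outcome", "contrast", "effect_type",
                         "component_1", "component_2", "estimate")])
      eff$mediator <- NA_character_
      pw <- as.data.frame(indirect_pathwise(model, data, contrast))
      eff <- rbind(eff[, names(pw)], pw)
      utils::write.csv(eff, file.path(out_dir, "effects.csv"), row.names = FALSE)
      eff
    })
  }

  if ("bootstrap" %in% stages) {
    bcfg <- config$bootstrap %||% list()
    message("[bootstrap] percentile intervals")
    results$bootstrap <- run_stage("bootstrap", {
      br <- bootstrap(
        model, data,
        stat_fns = list(
          direct = function(m, d) {
            e <- direct_effect(m, d, contrast); stats::setNames(e$estimate, e$outcome)
          },
          indirect = function(m, d) {
            e <- indirect_overall(m, d, contrast); stats::setNames(e$estimate, e$outcome)
          }
        ),
        B = bcfg$B %||% 1000, alpha = bcfg$alpha %||% 0.05,
        seed = default_seed(bcfg$seed, "bootstrap")
      )
      utils::write.csv(br$ci, file.path(out_dir, "bootstrap_ci.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(br$replicates),
                       file.path(out_dir, "bootstrap_replicates.csv"),
                       row.names = FALSE)
      br
    })
  }

  if ("fdr" %in% stages) {
    fcfg <- config$fdr %||% list()
    message("[fdr] synthetic-null calibration")
    results$fdr <- run_stage("fdr", {
      edges <- fcfg$null_edges %||% "T->Y"
      nm <- model
      for (e in edges) nm <- nullify(nm, e)
      nm <- estimate(nm, data)
      null_data <- synthetic_null_data(nm, data,
                                       seed = default_seed(fcfg$seed, "fdr"))
      null_model <- estimate(model, null_data)
      stat <- fcfg$statistic %||% "direct"
      fn <- if (stat == "direct") direct_effect else indirect_overall
      real <- fn(model, data, contrast)
      null <- fn(null_model, null_data, contrast)
      ft <- fdr_summary(stats::setNames(real$estimate, real$outcome),
                        stats::setNames(null$estimate, null$outcome),
                        q = fcfg$q %||% 0.15)
      utils::write.csv(as.data.frame(ft), file.path(out_dir, "fdr.csv"),
                       row.names = FALSE)
      ft
    })
  }

  if ("sensitivity" %in% stages) {
    scfg <- config$sensitivity %||% list()
    message("[sensitivity] correlated-noise sweep")
    results$sensitivity <- run_stage("sensitivity", {
      G <- scfg$G %||% cbind(1, 1)
      sc <- sensitivity_config(
        rho_grid = unlist(scfg$rho_grid %||% seq(-0.6, 0.6, by = 0.3)),
        G = G, n_reps = scfg$n_reps %||% 20,
        seed = default_seed(scfg$seed, "sensitivity"), contrast = contrast
      )
      curve <- sensitivity(model, data, sc)
      write_sensitivity(curve, file.path(out_dir, "sensitivity.csv"))
      curve
    })
  }

  manifest <- list(
    package = "medipath",
    version = as.character(utils::packageVersion("medipath")),
    r_version = R.version.string,
    stages = stages,
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Simulate a dataset from a config and write CSV artifacts
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (data.csv, truth.csv, spec.json).
#' @return invisibly, the [simulate_mediation()] result.
#' @export
write_simulation <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_mediation(spec)
  tab <- as_table(sim$data)
  utils::write.csv(cbind(sample_id = sim$data$sample_ids, tab),
                   file.path(out_dir, "data.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$truth), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sim)
}
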