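# End-to-end pipeline: simulate -> stocks -> indices -> stats, with a
# resolved config, a plain-text log and a checksum manifest so a run is
# fully re-derivable from config + seed.

#' Pipeline run configuration
#'
#' Either `design` (a [design_spec()]; the simulate stage then generates
#' the data) or `profiles_path`/`yields_path` (measured data; simulate is
#' skipped) must be given. The global `seed` overrides the design's seed
#' and feeds every stochastic stage.
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param design optional [design_spec()].
#' @param profiles_path,yields_path optional measured-data CSV paths.
#' @param scoring a [scoring_config()].
#' @param esm list of ESM flags: `scope`, `aggregation`, `max_depth_cm`,
#'   `c_extra` (see [esm_table()]).
#' @param stats list of stats flags: `alpha`, `rf_trees`,
#'   `rf_permutations`.
#' @param seed global integer seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       design = NULL,
                       profiles_path = NULL, yields_path = NULL,
                       scoring = scoring_config(),
                       esm = list(),
                       stats = list(),
                       seed = 1L) {
  if (is.null(design) && is.null(profiles_path)) {
    stop("either a design_spec or a profiles_path is required")
  }
  esm_defaults <- list(scope = "year", aggregation = "per-replicate",
                       max_depth_cm = 40, c_extra = "next-layer")
  stats_defaults <- list(alpha = 0.05, rf_trees = 500, rf_permutations = 50)
  structure(
    list(output_dir = output_dir, design = design,
         profiles_path = profiles_path, yields_path = yields_path,
         scoring = scoring,
         esm = utils::modifyList(esm_defaults, esm),
         stats = utils::modifyList(stats_defaults, stats),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# YAML-friendly view of a design spec (matrices become row-named lists).
spec_to_list <- function(spec) {
  mat_to_list <- function(m) {
    if (is.null(m)) return(NULL)
    c(list(bands = colnames(m)),
      setNames(lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])),
               rownames(m)))
  }
  param_to_list <- function(p) {
    list(surface_mean = p$surface_mean, depth_decay = p$depth_decay,
         plot_sd = p$plot_sd, residual_cv = p$residual_cv,
         year_factors = as.list(p$year_factors),
         multipliers = mat_to_list(p$multipliers))
  }
  list(
    years = spec$years,
    treatments = spec$treatments$treatment,
    replicates = spec$replicates,
    layers = list(top_cm = spec$layers$top_cm,
                  bottom_cm = spec$layers$bottom_cm),
    seed = spec$seed,
    variables = lapply(spec$variables, param_to_list),
    loc_fraction = param_to_list(spec$loc_fraction),
    yield = list(mean = spec$yield$mean, plot_sd = spec$yield$plot_sd,
                 residual_cv = spec$yield$residual_cv,
                 multipliers = as.list(spec$yield$multipliers),
                 year_factors = as.list(spec$yield$year_factors))
  )
}

RF_PREDICTORS <- c("mbc_mg_kg", "loc_g_kg", "soc_g_kg", "doc_mg_kg",
                   "nloc_g_kg", "bd_g_cm3")
CORR_VARS <- c("bd_g_cm3", "soc_g_kg", "loc_g_kg", "nloc_g_kg",
               "doc_mg_kg", "mbc_mg_kg", "invertase", "urease",
               "phosphatase", "sqi", "emf")
ANOVA_RESPONSES <- c("bd_g_cm3", "soc_g_kg", "loc_g_kg", "nloc_g_kg",
                     "doc_mg_kg", "mbc_mg_kg", "invertase", "urease",
                     "phosphatase", "sqi", "emf")
LETTER_RESPONSES <- c("soc_g_kg", "sqi", "emf")

#' Run the full pipeline
#'
#' Executes simulate (if a design is configured), equivalent-soil-mass
#' stocks, SQI/EMF indices, and the trial statistics; writes every
#' artifact as CSV plus a resolved `config.yaml`, a `run.log` recording
#' every decision flag in effect, and a `manifest.json` with MD5
#' checksums of all artifacts. The same config and seed always reproduce
#' byte-identical artifacts.
#'
#' @param cfg a [run_config()].
#' @return the manifest (named list), invisibly.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  art <- function(name) file.path(cfg$output_dir, name)
  files <- character()

  # --- simulate (or load) -------------------------------------------------
  if (!is.null(cfg$design)) {
    design <- cfg$design
    design$seed <- cfg$seed
    d <- generate_dataset(design)
    note("stage=simulate seed=", cfg$seed)
  } else {
    d <- read_dataset(cfg$profiles_path, cfg$yields_path)
    note("stage=simulate skipped=true input=", cfg$profiles_path)
  }
  write_dataset(d, art("profiles.csv"), art("yields.csv"))
  files <- c(files, "profiles.csv", "yields.csv")
  if (nrow(d$validation) > 0) {
    readr::write_csv(d$validation, art("validation.csv"), progress = FALSE)
    files <- c(files, "validation.csv")
  }

  resolved <- list(
    seed = cfg$seed,
    design = if (!is.null(cfg$design)) spec_to_list(design),
    input = cfg$profiles_path,
    esm = cfg$esm,
    scoring = cfg$scoring[c("indicators", "normalization_scope",
                            "standardization_scope", "sd_convention",
                            "sqi_method")],
    stats = cfg$stats
  )
  yaml::write_yaml(resolved, art("config.yaml"))
  files <- c(files, "config.yaml")

  # --- stocks -------------------------------------------------------------
  stocks <- esm_table(d, scope = cfg$esm$scope,
                      aggregation = cfg$esm$aggregation,
                      max_depth_cm = cfg$esm$max_depth_cm,
                      c_extra = cfg$esm$c_extra)
  readr::write_csv(stocks, art("stocks.csv"), progress = FALSE)
  files <- c(files, "stocks.csv")
  note("stage=stocks scope=", cfg$esm$scope, " aggregation=",
       cfg$esm$aggregation, " max_depth_cm=", cfg$esm$max_depth_cm,
       " c_extra=", cfg$esm$c_extra)

  # --- indices ------------------------------------------------------------
  idx <- indices_table(d, cfg$scoring)
  readr::write_csv(idx, art("indices.csv"), progress = FALSE)
  files <- c(files, "indices.csv")
  note("stage=indices normalization_scope=",
       cfg$scoring$normalization_scope, " standardization_scope=",
       cfg$scoring$standardization_scope, " sd_convention=",
       cfg$scoring$sd_convention, " sqi_method=", cfg$scoring$sqi_method)

  # --- stats --------------------------------------------------------------
  samples <- left_join(
    sample_table(d),
    idx[, c("year", "treatment", "replicate", "top_cm", "sqi", "emf")],
    by = c("year", "treatment", "replicate", "top_cm")
  )
  multi_year <- length(unique(samples$year)) > 1

  anova_rows <- list()
  for (resp in ANOVA_RESPONSES) {
    fac <- if (multi_year) c("year", "depth", "treatment")
           else c("depth", "treatment")
    tab <- factorial_anova(samples, resp, factors = fac)
    tab$response <- resp
    tab$error_df <- attr(tab, "error_df")
    tab$error_ms <- attr(tab, "error_ms")
    anova_rows[[resp]] <- tab
  }
  storage_resp <- stocks
  storage_resp$depth <- storage_resp$level
  fac_storage <- if (multi_year) c("year", "depth", "treatment")
                 else c("depth", "treatment")
  if (cfg$esm$aggregation == "per-replicate") {
    tab <- factorial_anova(storage_resp, "storage_Mg_ha",
                           factors = fac_storage)
    tab$response <- "soc_storage"
    tab$error_df <- attr(tab, "error_df")
    tab$error_ms <- attr(tab, "error_ms")
    anova_rows[["soc_storage"]] <- tab
  }
  if (!is.null(d$yields)) {
    yl <- d$yields
    yl$treatment <- treatment_label(yl$wheat_tillage, yl$maize_tillage)
    fac_y <- if (multi_year) c("year", "treatment") else "treatment"
    tab <- factorial_anova(yl, "yield_kg_ha", factors = fac_y)
    tab$response <- "wheat_yield"
    tab$error_df <- attr(tab, "error_df")
    tab$error_ms <- attr(tab, "error_ms")
    anova_rows[["wheat_yield"]] <- tab
  }
  anova_tab <- bind_rows(anova_rows)[, c("response", "term", "df", "sum_sq",
                                         "mean_sq", "F", "p", "error_df",
                                         "error_ms")]
  readr::write_csv(anova_tab, art("anova.csv"), progress = FALSE)
  files <- c(files, "anova.csv")
  note("stage=stats anova=", if (multi_year) "three-way" else "two-way",
       " alpha=", cfg$stats$alpha)

  letter_rows <- list()
  for (resp in LETTER_RESPONSES) {
    for (yr in unique(samples$year)) {
      for (top in sort(unique(samples$top_cm))) {
        sub <- samples[samples$year == yr & samples$top_cm == top, ]
        led <- lsd_letters(sub[[resp]], sub$treatment, cfg$stats$alpha)
        led$response <- resp; led$year <- yr; led$top_cm <- top
        letter_rows[[length(letter_rows) + 1]] <- led
      }
    }
  }
  if (cfg$esm$aggregation == "per-replicate") {
    deepest <- max(stocks$level)
    for (yr in unique(stocks$year)) {
      sub <- stocks[stocks$year == yr & stocks$level == deepest, ]
      led <- lsd_letters(sub$storage_Mg_ha, sub$treatment, cfg$stats$alpha)
      led$response <- "soc_storage"; led$year <- yr; led$top_cm <- NA_integer_
      letter_rows[[length(letter_rows) + 1]] <- led
    }
  }
  if (!is.null(d$yields)) {
    for (yr in unique(d$yields$year)) {
      sub <- d$yields[d$yields$year == yr, ]
      led <- lsd_letters(sub$yield_kg_ha,
                         treatment_label(sub$wheat_tillage,
                                         sub$maize_tillage),
                         cfg$stats$alpha)
      led$response <- "wheat_yield"; led$year <- yr
      led$top_cm <- NA_integer_
      letter_rows[[length(letter_rows) + 1]] <- led
    }
  }
  letters_tab <- bind_rows(letter_rows)[, c("response", "year", "top_cm",
                                            "group", "n", "mean", "letters")]
  readr::write_csv(letters_tab, art("letters.csv"), progress = FALSE)
  files <- c(files, "letters.csv")

  corr <- layer_correlations(samples, CORR_VARS)
  readr::write_csv(corr, art("correlations.csv"), progress = FALSE)
  files <- c(files, "correlations.csv")

  imp <- rf_importance(samples, RF_PREDICTORS, "emf",
                       n_trees = cfg$stats$rf_trees,
                       n_permutations = cfg$stats$rf_permutations,
                       seed = derive_seed(cfg$seed, "pipeline_rf"))
  imp_out <- imp
  imp_out$var_explained_pct <- attr(imp, "var_explained_pct")
  readr::write_csv(imp_out, art("importance.csv"), progress = FALSE)
  files <- c(files, "importance.csv")
  note("stage=stats rf_trees=", cfg$stats$rf_trees, " rf_permutations=",
       cfg$stats$rf_permutations)

  reg <- emf_sqi_regression(samples$emf, samples$sqi)
  readr::write_csv(reg, art("regression.csv"), progress = FALSE)
  files <- c(files, "regression.csv")

  writeLines(log_lines, art("run.log"))
  files <- c(files, "run.log")

  checksums <- tools::md5sum(file.path(cfg$output_dir, sort(files)))
  names(checksums) <- sort(files)
  manifest <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(art("config.yaml"))),
    files = as.list(checksums)
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
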