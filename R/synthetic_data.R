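# Synthetic split-plot trial generator.
#
# Emulates the statistical structure of a two-year, 2 (wheat-season) x 3
# (maize-season) split-plot tillage trial with 3 replicates, five 10 cm
# depth layers, monotone depth profiles (bulk density increasing, carbon
# fractions and enzyme activities decreasing with depth) and treatment
# effects entering as multipliers on depth bands.

BANDS <- c("0-20", "20-40", "40-50")

band_of <- function(top_cm) {
  ifelse(top_cm < 20, "0-20", ifelse(top_cm < 40, "20-40", "40-50"))
}

#' Per-variable generator parameters
#'
#' The generated value for variable `v`, plot `p`, layer `i` is
#' `surface_mean * depth_decay^(i-1) * multiplier(treatment, band) *
#' year_factor * exp(plot_effect_p) * (1 + eps)` with
#' `eps ~ N(0, residual_cv)` drawn per observation and
#' `plot_effect_p ~ N(0, plot_sd)` drawn once per plot, shared across
#' layers and years (this is what induces the split-plot within-plot
#' correlation). Noise is multiplicative so strictly positive variables
#' stay positive and the coefficient of variation is depth-stable.
#'
#' @param surface_mean expected value in the 0-10 cm layer (variable's own
#'   units), before treatment and plot effects.
#' @param depth_decay multiplicative change per 10 cm layer step; `>= 1`
#'   for bulk density (which increases with depth), `<= 1` otherwise.
#' @param plot_sd standard deviation of the lognormal plot effect.
#' @param residual_cv residual coefficient of variation, in `[0, 0.5)`.
#' @param multipliers optional 6 x 3 matrix (treatment x depth band) of
#'   multiplicative treatment effects; defaults to all 1 (no effect).
#' @param year_factors optional named multiplicative year effects,
#'   default 1 for every year.
#' @return a list of class `variable_param`.
#' @export
variable_param <- function(surface_mean, depth_decay, plot_sd = 0.04,
                           residual_cv = 0.08, multipliers = NULL,
                           year_factors = NULL) {
  structure(
    list(surface_mean = surface_mean, depth_decay = depth_decay,
         plot_sd = plot_sd, residual_cv = residual_cv,
         multipliers = multipliers, year_factors = year_factors),
    class = "variable_param"
  )
}

# Mean levels chosen to land in the printed ranges of comparable
# fluvo-aquic tillage trials: BD ~1.45-1.70 g cm^-3, SOC ~7-16 g kg^-1,
# DOC ~30-61 mg kg^-1, MBC ~50-190 mg kg^-1, enzyme activities a few to
# ~30 mg g^-1 24h^-1. Noise levels are anchored to the error mean squares
# such trials print (residual SDs of a few percent of the mean; e.g. an
# SOC error mean square of 0.05 (g kg^-1)^2 at mean ~11 g kg^-1 is a
# residual CV near 2%), so residual CVs default to 2-5% with a smaller
# plot-level component.
default_variable_params <- function() {
  list(
    bd_g_cm3    = variable_param(1.45, 1.04, plot_sd = 0.01, residual_cv = 0.02),
    soc_g_kg    = variable_param(16.0, 0.82, plot_sd = 0.02, residual_cv = 0.04),
    doc_mg_kg   = variable_param(58.0, 0.85, plot_sd = 0.02, residual_cv = 0.04),
    mbc_mg_kg   = variable_param(185.0, 0.72, plot_sd = 0.03, residual_cv = 0.05),
    invertase   = variable_param(30.0, 0.75, plot_sd = 0.03, residual_cv = 0.05),
    urease      = variable_param(24.0, 0.70, plot_sd = 0.03, residual_cv = 0.05),
    phosphatase = variable_param(5.5, 0.60, plot_sd = 0.03, residual_cv = 0.05)
  )
}

fill_param <- function(param, years) {
  if (is.null(param$multipliers)) {
    param$multipliers <- matrix(
      1, nrow = 6, ncol = length(BANDS),
      dimnames = list(treatment_levels(), BANDS)
    )
  }
  if (is.null(param$year_factors)) {
    param$year_factors <- setNames(rep(1, length(years)), as.character(years))
  }
  param
}

check_param <- function(param, name, bd_like = FALSE, ratio = FALSE) {
  if (param$surface_mean <= 0) stop(name, ": surface_mean must be > 0")
  if (param$residual_cv < 0 || param$residual_cv >= 0.5) {
    stop(name, ": residual_cv must lie in [0, 0.5)")
  }
  if (param$plot_sd < 0) stop(name, ": plot_sd must be >= 0")
  if (any(param$multipliers <= 0)) stop(name, ": multipliers must be > 0")
  if (!ratio) {
    if (bd_like && param$depth_decay < 1) {
      stop(name, ": bulk density must not decrease with depth (depth_decay >= 1)")
    }
    if (!bd_like && param$depth_decay > 1) {
      stop(name, ": depth_decay must be <= 1 (decreases with depth)")
    }
  }
  invisible(param)
}

#' Parameterize the synthetic trial
#'
#' Captures the full design: factor levels, replication, depth layering,
#' seed, and per-variable response surfaces (see [variable_param()]).
#' Labile organic carbon is not generated directly: a labile *fraction*
#' of SOC is generated (clamped to (0, 0.35]) and LOC = SOC x fraction,
#' so `loc <= soc` holds by construction. Wheat yield is generated per
#' plot from the same multiplicative framework, without a depth dimension.
#'
#' @param years integer years, default `c(2018, 2019)`.
#' @param treatments tibble as [all_treatments()] (a subset is allowed).
#' @param replicates number of replicate blocks, default 3.
#' @param layers tibble of depth layers, default [default_layers()].
#' @param seed integer seed; every draw is reproducible from it.
#'   Per-variable substreams are derived by hashing the variable name, so
#'   adding a variable does not shift the draws of the others.
#' @param variables named list of [variable_param()] for `bd_g_cm3`,
#'   `soc_g_kg`, `doc_mg_kg`, `mbc_mg_kg`, `invertase`, `urease`,
#'   `phosphatase`.
#' @param loc_fraction [variable_param()] for the LOC/SOC ratio
#'   (default mean 0.28, clamped to (0.01, 0.35]).
#' @param yield list with `mean` (kg ha^-1, default 6000), `plot_sd`,
#'   `residual_cv`, optional per-treatment `multipliers` (named vector)
#'   and `year_factors`.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(years = c(2018L, 2019L),
                        treatments = all_treatments(),
                        replicates = 3L,
                        layers = default_layers(),
                        seed = 1L,
                        variables = default_variable_params(),
                        loc_fraction = variable_param(0.28, 1, plot_sd = 0,
                                                      residual_cv = 0.04),
                        yield = list(mean = 6000, plot_sd = 0.02,
                                     residual_cv = 0.03)) {
  stopifnot(replicates >= 1, nrow(treatments) >= 1, nrow(layers) >= 1)
  if (any(layers$bottom_cm <= layers$top_cm)) stop("malformed layers")
  variables <- lapply(variables, fill_param, years = years)
  loc_fraction <- fill_param(loc_fraction, years)
  if (loc_fraction$surface_mean > 0.35) {
    stop("loc_fraction surface_mean must lie in (0, 0.35]")
  }
  for (nm in names(variables)) {
    check_param(variables[[nm]], nm, bd_like = nm == "bd_g_cm3")
  }
  check_param(loc_fraction, "loc_fraction", ratio = TRUE)
  if (is.null(yield$multipliers)) {
    yield$multipliers <- setNames(rep(1, 6), treatment_levels())
  }
  if (is.null(yield$year_factors)) {
    yield$year_factors <- setNames(rep(1, length(years)), as.character(years))
  }
  if (yield$mean <= 0 || any(yield$multipliers <= 0)) {
    stop("yield mean and multipliers must be > 0")
  }
  structure(
    list(years = as.integer(years), treatments = treatments,
         replicates = as.integer(replicates), layers = layers,
         seed = as.integer(seed), variables = variables,
         loc_fraction = loc_fraction, yield = yield),
    class = "design_spec"
  )
}

#' A structure-free design for calibration studies
#'
#' All depth decays are 1, all treatment multipliers are 1, year factors
#' are 1 and plot effects are 0: every observation is pure multiplicative
#' noise around a constant mean. Under this design every term of the
#' factorial ANOVA is null, which is what type-I-error calibration needs.
#'
#' @inheritParams design_spec
#' @param residual_cv shared residual coefficient of variation.
#' @return a `design_spec`.
#' @export
null_design_spec <- function(seed = 1L, residual_cv = 0.08) {
  vars <- default_variable_params()
  for (nm in names(vars)) {
    vars[[nm]]$depth_decay <- 1
    vars[[nm]]$plot_sd <- 0
    vars[[nm]]$residual_cv <- residual_cv
  }
  design_spec(seed = seed, variables = vars,
              loc_fraction = variable_param(0.28, 1, plot_sd = 0,
                                            residual_cv = residual_cv),
              yield = list(mean = 6000, plot_sd = 0,
                           residual_cv = residual_cv))
}

#' A demonstration design with qualitative tillage effects planted
#'
#' Starts from the neutral defaults and plants effects with the
#' qualitative shape reported for subsoiling systems: lower bulk density
#' under subsoiling in the 0-40 cm band; higher SOC, labile pools and
#' enzyme activities under rotary tillage + subsoiling near the surface
#' and under deep tillage + subsoiling in the 20-40 cm band; higher wheat
#' yield under subsoiling.
#'
#' @inheritParams design_spec
#' @return a `design_spec`.
#' @export
demo_design_spec <- function(seed = 1L) {
  spec <- design_spec(seed = seed)
  subsoil <- c("RT-SBR", "RT-SIR", "DT-SBR", "DT-SIR")
  rt_sub <- c("RT-SBR", "RT-SIR")
  dt_sub <- c("DT-SBR", "DT-SIR")
  spec <- planted_effect_spec(spec, "bd_g_cm3", c("0-20", "20-40"), -0.03,
                              subsoil)
  for (v in c("soc_g_kg", "doc_mg_kg", "mbc_mg_kg")) {
    spec <- planted_effect_spec(spec, v, "0-20", 0.08, rt_sub)
    spec <- planted_effect_spec(spec, v, "20-40", 0.10, dt_sub)
  }
  for (v in c("invertase", "urease", "phosphatase")) {
    spec <- planted_effect_spec(spec, v, "0-20", 0.12, rt_sub)
    spec <- planted_effect_spec(spec, v, "20-40", 0.12, dt_sub)
  }
  spec$yield$multipliers[subsoil] <- 1.05
  spec$yield$multipliers["DT-SIR"] <- 1.08
  spec
}

#' Plant a localized multiplicative effect
#'
#' Returns a copy of `base` whose treatment multipliers for `variable`
#' are scaled by `1 + delta` in the named depth band(s) and treatments;
#' every other cell is untouched.
#'
#' @param base a `design_spec`.
#' @param variable one of the generated variable names, `"loc_fraction"`,
#'   or `"yield"` (for which `band` is ignored).
#' @param band subset of `"0-20"`, `"20-40"`, `"40-50"`.
#' @param delta fractional effect, `> -1` (e.g. `0.10` = +10%).
#' @param treatments character vector of treatment labels.
#' @return a modified `design_spec`.
#' @export
planted_effect_spec <- function(base, variable, band, delta, treatments) {
  stopifnot(inherits(base, "design_spec"), delta > -1)
  if (!all(treatments %in% treatment_levels())) {
    stop("unknown treatment label(s): ",
         paste(setdiff(treatments, treatment_levels()), collapse = ", "))
  }
  spec <- base
  if (identical(variable, "yield")) {
    spec$yield$multipliers[treatments] <-
      spec$yield$multipliers[treatments] * (1 + delta)
    return(spec)
  }
  if (!all(band %in% BANDS)) {
    stop("unknown depth band(s): ",
         paste(setdiff(band, BANDS), collapse = ", "))
  }
  if (identical(variable, "loc_fraction")) {
    spec$loc_fraction$multipliers[treatments, band] <-
      spec$loc_fraction$multipliers[treatments, band] * (1 + delta)
    return(spec)
  }
  if (!variable %in% names(spec$variables)) {
    stop("unknown variable: ", variable)
  }
  spec$variables[[variable]]$multipliers[treatments, band] <-
    spec$variables[[variable]]$multipliers[treatments, band] * (1 + delta)
  spec
}

# Draw one variable over the profile grid under its own substream.
gen_values <- function(design, name, param, grid, n_plots, max_retry = 100) {
  mult <- param$multipliers[cbind(grid$trt_idx, match(grid$band, BANDS))]
  mu <- param$surface_mean * param$depth_decay^(grid$layer_idx - 1) *
    mult * unname(param$year_factors[as.character(grid$year)])
  with_seed(derive_seed(design$seed, name), {
    plot_eff <- rnorm(n_plots, 0, param$plot_sd)
    base <- mu * exp(plot_eff[grid$plot_idx])
    val <- base * (1 + rnorm(nrow(grid), 0, param$residual_cv))
    tries <- 0
    while (any(val <= 0)) {
      tries <- tries + 1
      if (tries > max_retry) {
        stop("could not generate strictly positive values for ", name)
      }
      bad <- which(val <= 0)
      val[bad] <- base[bad] * (1 + rnorm(length(bad), 0, param$residual_cv))
    }
    val
  })
}

#' Generate a synthetic trial dataset
#'
#' Fully reproducible from `design$seed`; the record ordering is the
#' canonical (year, treatment, replicate, top_cm) sort and does not depend
#' on the seed. Generated datasets always pass [soil_dataset()] validation.
#'
#' @param design a [design_spec()].
#' @return a [soil_dataset()] with profiles and yields; `provenance`
#'   records the seed.
#' @export
#' @examples
#' d <- generate_dataset(design_spec(seed = 42))
#' d
generate_dataset <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  trt <- design$treatments
  n_trt <- nrow(trt)
  n_rep <- design$replicates
  n_lay <- nrow(design$layers)
  n_plots <- n_trt * n_rep
  # canonical grid: year, treatment, replicate, layer
  grid <- expand.grid(
    layer_idx = seq_len(n_lay), rep = seq_len(n_rep),
    trt_idx = seq_len(n_trt), year = design$years,
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[order(grid$year, grid$trt_idx, grid$rep, grid$layer_idx), ]
  grid$plot_idx <- (grid$trt_idx - 1) * n_rep + grid$rep
  grid$top_cm <- design$layers$top_cm[grid$layer_idx]
  grid$band <- band_of(grid$top_cm)

  vals <- lapply(names(design$variables), function(nm) {
    gen_values(design, nm, design$variables[[nm]], grid, n_plots)
  })
  names(vals) <- names(design$variables)
  frac <- gen_values(design, "loc_fraction", design$loc_fraction, grid,
                     n_plots)
  frac <- pmin(pmax(frac, 0.01), 0.35)
  profiles <- tibble(
    year = as.integer(grid$year),
    wheat_tillage = trt$wheat_tillage[grid$trt_idx],
    maize_tillage = trt$maize_tillage[grid$trt_idx],
    replicate = as.integer(grid$rep),
    top_cm = as.integer(grid$top_cm),
    bottom_cm = as.integer(design$layers$bottom_cm[grid$layer_idx]),
    bd_g_cm3 = vals$bd_g_cm3,
    soc_g_kg = vals$soc_g_kg,
    loc_g_kg = vals$soc_g_kg * frac,
    doc_mg_kg = vals$doc_mg_kg,
    mbc_mg_kg = vals$mbc_mg_kg,
    invertase = vals$invertase,
    urease = vals$urease,
    phosphatase = vals$phosphatase
  )

  ygrid <- expand.grid(
    rep = seq_len(n_rep), trt_idx = seq_len(n_trt), year = design$years,
    KEEP.OUT.ATTRS = FALSE
  )
  ygrid <- ygrid[order(ygrid$year, ygrid$trt_idx, ygrid$rep), ]
  ygrid$plot_idx <- (ygrid$trt_idx - 1) * n_rep + ygrid$rep
  yp <- design$yield
  label <- treatment_label(trt$wheat_tillage, trt$maize_tillage)
  mu_y <- yp$mean * unname(yp$multipliers[label[ygrid$trt_idx]]) *
    unname(yp$year_factors[as.character(ygrid$year)])
  yield_vals <- with_seed(derive_seed(design$seed, "yield"), {
    plot_eff <- rnorm(n_plots, 0, yp$plot_sd)
    base <- mu_y * exp(plot_eff[ygrid$plot_idx])
    val <- base * (1 + rnorm(nrow(ygrid), 0, yp$residual_cv))
    tries <- 0
    while (any(val <= 0)) {
      tries <- tries + 1
      if (tries > 100) stop("could not generate strictly positive yields")
      bad <- which(val <= 0)
      val[bad] <- base[bad] * (1 + rnorm(length(bad), 0, yp$residual_cv))
    }
    val
  })
  yields <- tibble(
    year = as.integer(ygrid$year),
    wheat_tillage = trt$wheat_tillage[ygrid$trt_idx],
    maize_tillage = trt$maize_tillage[ygrid$trt_idx],
    replicate = as.integer(ygrid$rep),
    yield_kg_ha = yield_vals
  )
  soil_dataset(profiles, yields,
               provenance = paste0("synthetic (seed ", design$seed, ")"))
}
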