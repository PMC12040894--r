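# Equivalent-soil-mass (ESM) soil organic carbon storage.
#
# Fixed-depth carbon stocks confound treatment effects with bulk density
# differences: a loosened soil holds less mass in 0-40 cm, so comparing
# stocks over a fixed depth compares different amounts of soil. The ESM
# method fixes the comparison mass instead: at each cumulative level j a
# reference mass M_j (the maximum cumulative soil mass over the stacks in
# scope) is used, and any mass a profile lacks relative to M_j is topped
# up with soil of concentration C_extra. Storage at level j is
#   [ sum_{i<=j} M_soil,i * C_i + (M_j - sum_{i<=j} M_soil,i) * C_extra ] * 0.001
# in Mg ha^-1, with M_soil,i = bd_i * thickness_m * 10000 (Mg ha^-1) and
# carbon concentrations in kg Mg^-1 (numerically equal to g kg^-1).

#' Soil mass of one layer
#'
#' `bd * thickness_m * 10000`, i.e. bulk density read as Mg m^-3 times
#' layer thickness in metres times 10 000 m^2 per hectare, giving
#' Mg ha^-1.
#'
#' @param bd bulk density, g cm^-3 (numerically Mg m^-3), `> 0`.
#' @param top_cm,bottom_cm layer bounds in cm.
#' @return layer soil mass, Mg ha^-1.
#' @export
#' @examples
#' layer_soil_mass(1.5, 0, 10)   # 1500
#' layer_soil_mass(1.49, 0, 10)  # 1490
layer_soil_mass <- function(bd, top_cm, bottom_cm) {
  if (any(bd <= 0)) stop("bulk density must be > 0")
  bd * (bottom_cm - top_cm) / 100 * 10000
}

#' Build a layer stack for ESM arithmetic
#'
#' Takes the layers of one plot (or one treatment mean) and returns the
#' ordered stack of soil masses and carbon concentrations down to
#' `max_depth_cm`. Layers may be supplied in any order; sorting by
#' `top_cm` is canonical. The profile must cover `0..max_depth_cm`
#' contiguously.
#'
#' @param layers data frame with columns `top_cm`, `bottom_cm`,
#'   `bd_g_cm3`, `soc_g_kg` (one row per layer of a single profile).
#' @param max_depth_cm bottom of the stack; default 40 (four cumulative
#'   levels even when five layers were sampled).
#' @return tibble with columns `level`, `top_cm`, `bottom_cm`,
#'   `soil_mass` (Mg ha^-1), `carbon_conc` (kg Mg^-1), `cum_mass`.
#' @export
build_stack <- function(layers, max_depth_cm = 40) {
  layers <- as.data.frame(layers)[order(layers$top_cm), , drop = FALSE]
  layers <- layers[layers$top_cm < max_depth_cm, , drop = FALSE]
  if (nrow(layers) == 0 || max(layers$bottom_cm) < max_depth_cm) {
    stop("max_depth_cm exceeds available profile depth")
  }
  if (layers$top_cm[1] != 0 ||
      any(layers$top_cm[-1] != layers$bottom_cm[-nrow(layers)])) {
    stop("non-contiguous profile: layers must tile 0..max_depth_cm")
  }
  mass <- layer_soil_mass(layers$bd_g_cm3, layers$top_cm, layers$bottom_cm)
  tibble(
    level = seq_len(nrow(layers)),
    top_cm = layers$top_cm,
    bottom_cm = layers$bottom_cm,
    soil_mass = mass,
    carbon_conc = layers$soc_g_kg,
    cum_mass = cumsum(mass)
  )
}

#' Reference masses for a comparison scope
#'
#' At each cumulative level j the reference mass is the maximum cumulative
#' soil mass over all stacks in scope, so every stack's deficit relative
#' to the reference is non-negative.
#'
#' @param stacks list of stacks from [build_stack()], sharing layering.
#' @param scope free-text descriptor recorded with the result.
#' @return numeric vector `M_j`, one per level, with attribute `scope`.
#' @export
reference_masses <- function(stacks, scope = "") {
  if (length(stacks) == 0) stop("empty scope: no stacks supplied")
  n <- nrow(stacks[[1]])
  for (s in stacks) {
    if (nrow(s) != n || any(s$top_cm != stacks[[1]]$top_cm)) {
      stop("all stacks in a scope must share the same layering")
    }
  }
  refs <- do.call(pmax, lapply(stacks, function(s) s$cum_mass))
  structure(refs, scope = scope)
}

#' ESM storage for one stack
#'
#' Applies the cumulative reference-mass correction at every level of the
#' stack. The mass deficit `M_j - cum_mass_j` is topped up with soil of
#' concentration `C_extra`; the default `"next-layer"` policy uses the
#' concentration of the layer immediately below the cumulative level (the
#' soil that would physically be included to reach the reference mass),
#' falling back to the deepest layer's own concentration at the profile
#' bottom. `"same-layer"` uses the concentration of layer j itself.
#'
#' @param stack a [build_stack()] result.
#' @param refs reference masses from [reference_masses()] computed on a
#'   scope containing this stack.
#' @param c_extra top-up concentration policy, `"next-layer"` (default)
#'   or `"same-layer"`.
#' @return tibble with `level`, `cum_depth_cm`, `storage_Mg_ha`,
#'   `deficit_Mg_ha`, `c_extra_kg_Mg`.
#' @export
#' @examples
#' stack <- build_stack(data.frame(
#'   top_cm = c(0, 10), bottom_cm = c(10, 20),
#'   bd_g_cm3 = c(1.4, 1.5), soc_g_kg = c(10, 8)
#' ), max_depth_cm = 20)
#' esm_storage(stack, c(1500, 3100))  # storage 14.8, 27.6 Mg ha^-1
esm_storage <- function(stack, refs,
                        c_extra = c("next-layer", "same-layer")) {
  c_extra <- match.arg(c_extra)
  n <- nrow(stack)
  if (length(refs) != n) stop("refs must have one mass per stack level")
  deficit <- as.numeric(refs) - stack$cum_mass
  if (any(deficit < -1e-9 * as.numeric(refs))) {
    stop("stack heavier than reference mass: scope mismatch, not truncating")
  }
  deficit <- pmax(deficit, 0)
  cx <- switch(c_extra,
    "next-layer" = stack$carbon_conc[pmin(stack$level + 1L, n)],
    "same-layer" = stack$carbon_conc
  )
  tibble(
    level = stack$level,
    cum_depth_cm = stack$bottom_cm,
    storage_Mg_ha = (cumsum(stack$soil_mass * stack$carbon_conc) +
                       deficit * cx) * 0.001,
    deficit_Mg_ha = deficit,
    c_extra_kg_Mg = cx
  )
}

#' ESM storage table for a whole dataset
#'
#' Groups the dataset by the reference scope, builds stacks, computes
#' reference masses within scope, and applies the ESM correction. With
#' `aggregation = "per-replicate"` (the default) each plot gets its own
#' stack — reference masses are then maxima over plots in scope — so the
#' replicate spread of storage is preserved for downstream ANOVA and LSD
#' letters. `"replicate-mean-first"` averages bulk density and SOC over
#' replicates per treatment before stacking, and reference masses are
#' maxima over treatment means.
#'
#' @param d a [soil_dataset()].
#' @param scope `"year"` (reference masses computed within each year,
#'   across treatments; the default, since bulk density shifts between
#'   years) or `"pooled"` (one set of reference masses overall).
#' @param aggregation `"per-replicate"` or `"replicate-mean-first"`.
#' @param max_depth_cm bottom of the cumulative computation, default 40.
#' @param c_extra top-up policy, see [esm_storage()].
#' @return tidy tibble: `year`, `treatment`, `replicate` (`NA` under
#'   `"replicate-mean-first"`), `level`, `cum_depth_cm`,
#'   `storage_Mg_ha`, `deficit_Mg_ha`, `c_extra_kg_Mg`; the policy and
#'   scope are recorded as attributes.
#' @export
esm_table <- function(d, scope = c("year", "pooled"),
                      aggregation = c("per-replicate",
                                      "replicate-mean-first"),
                      max_depth_cm = 40,
                      c_extra = c("next-layer", "same-layer")) {
  stopifnot(inherits(d, "soil_dataset"))
  scope <- match.arg(scope)
  aggregation <- match.arg(aggregation)
  c_extra <- match.arg(c_extra)
  p <- d$profiles
  p$treatment <- treatment_label(p$wheat_tillage, p$maize_tillage)
  if (aggregation == "replicate-mean-first") {
    p <- p |>
      group_by(.data$year, .data$treatment, .data$top_cm, .data$bottom_cm) |>
      summarise(bd_g_cm3 = mean(.data$bd_g_cm3),
                soc_g_kg = mean(.data$soc_g_kg), .groups = "drop")
    p$replicate <- NA_integer_
  }
  p$scope_key <- if (scope == "year") as.character(p$year) else "all"
  p$stack_key <- paste(p$year, p$treatment, p$replicate)
  out <- list()
  for (sk in unique(p$scope_key)) {
    ps <- p[p$scope_key == sk, , drop = FALSE]
    keys <- unique(ps[, c("year", "treatment", "replicate", "stack_key")])
    stacks <- lapply(keys$stack_key, function(k) {
      build_stack(ps[ps$stack_key == k, , drop = FALSE], max_depth_cm)
    })
    refs <- reference_masses(stacks, scope = paste0("scope=", sk))
    res <- lapply(seq_along(stacks), function(i) {
      r <- esm_storage(stacks[[i]], refs, c_extra = c_extra)
      r$year <- keys$year[i]
      r$treatment <- keys$treatment[i]
      r$replicate <- keys$replicate[i]
      r
    })
    out[[sk]] <- bind_rows(res)
  }
  res <- bind_rows(out)[, c("year", "treatment", "replicate", "level",
                            "cum_depth_cm", "storage_Mg_ha",
                            "deficit_Mg_ha", "c_extra_kg_Mg")]
  res <- res[order(res$year, match(res$treatment, treatment_levels()),
                   res$replicate, res$level), ]
  attr(res, "scope") <- scope
  attr(res, "aggregation") <- aggregation
  attr(res, "c_extra") <- c_extra
  res
}
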