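# Soil quality index (radar-area variant) and ecosystem multifunctionality.

ENZYME_COLS <- c("invertase", "urease", "phosphatase")

#' Scoring configuration for SQI and EMF
#'
#' @param indicators ordered character vector of profile columns entering
#'   the SQI; the default set is SOC, LOC, NLOC, DOC, MBC, the three
#'   enzymes (all more-is-better) and bulk density (less-is-better),
#'   n = 9 indicators.
#' @param directions named character vector over `indicators`, values
#'   `"more"` or `"less"`.
#' @param normalization_scope grouping over which the min-max bounds of
#'   each indicator are taken: `"year"` (default; pooled across
#'   treatments, replicates and depths within a year, so that depth
#'   gradients survive scoring) or `"all"`.
#' @param standardization_scope pool for the enzyme z-scores feeding the
#'   EMF, `"year"` (default) or `"all"`.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @param sqi_method `"sum-of-squares"` (default) or `"polygon"`, see
#'   [sqi_area()].
#' @return a list of class `scoring_config`.
#' @export
scoring_config <- function(indicators = c("soc_g_kg", "loc_g_kg", "nloc_g_kg",
                                          "doc_mg_kg", "mbc_mg_kg",
                                          "invertase", "urease", "phosphatase",
                                          "bd_g_cm3"),
                           directions = NULL,
                           normalization_scope = c("year", "all"),
                           standardization_scope = c("year", "all"),
                           sd_convention = c("sample", "population"),
                           sqi_method = c("sum-of-squares", "polygon")) {
  if (length(indicators) == 0) stop("indicator set must be non-empty")
  if (is.null(directions)) {
    directions <- setNames(
      ifelse(indicators == "bd_g_cm3", "less", "more"), indicators
    )
  }
  if (!all(indicators %in% names(directions)) ||
      !all(directions %in% c("more", "less"))) {
    stop("directions must name every indicator as 'more' or 'less'")
  }
  structure(
    list(indicators = indicators, directions = directions[indicators],
         normalization_scope = match.arg(normalization_scope),
         standardization_scope = match.arg(standardization_scope),
         sd_convention = match.arg(sd_convention),
         sqi_method = match.arg(sqi_method)),
    class = "scoring_config"
  )
}

#' Min-max linear score of one indicator
#'
#' More-is-better indicators are scored `x / x_max`; less-is-better
#' indicators are scored `x_min / x` (the standard decreasing ratio
#' score), so every score lies in `[0, 1]` with 1 at the favourable end.
#'
#' @param x analyzed value(s), within `[x_min, x_max]`.
#' @param direction `"more"` or `"less"`.
#' @param x_min,x_max scope minimum and maximum of the indicator.
#' @return score(s) in `[0, 1]`.
#' @export
#' @examples
#' linear_score(5, "more", 1, 10)  # 0.5
#' linear_score(2, "less", 2, 8)   # 1
linear_score <- function(x, direction = c("more", "less"), x_min, x_max) {
  direction <- match.arg(direction)
  if (any(x < x_min | x > x_max)) {
    stop("x outside [x_min, x_max]: scoring scope mismatch")
  }
  if (direction == "more") {
    if (x_max == 0) stop("x_max must be non-zero for more-is-better scoring")
    x / x_max
  } else {
    if (x_min <= 0) stop("x_min must be > 0 for less-is-better scoring")
    x_min / x
  }
}

#' Radar-area soil quality index
#'
#' Combines `n >= 3` linear scores into a single index,
#' `0.5 * sum(s_i^2) * sin(2*pi/n)` — the sum over indicators of the
#' area of an isosceles triangle with equal sides `s_i` and apex angle
#' `2*pi/n`. Note this formula has no cross terms, so it is invariant to
#' the ordering of indicators; the literal area of the radar polygon
#' (adjacent-product form `0.5 * sin(2*pi/n) * sum(s_i * s_{i+1})`,
#' cyclic), which does depend on ordering, is available as
#' `method = "polygon"`.
#'
#' @param scores numeric vector of component scores (each in `[0, 1]`),
#'   length `>= 3`.
#' @param method `"sum-of-squares"` (default) or `"polygon"`.
#' @return the index; bounded by `0.5 * n * sin(2*pi/n)`, attained iff
#'   all scores are 1.
#' @export
#' @examples
#' sqi_area(rep(1, 4))  # 2
#' sqi_area(rep(1, 9))  # 4.5 * sin(2*pi/9) ~ 2.89
sqi_area <- function(scores, method = c("sum-of-squares", "polygon")) {
  method <- match.arg(method)
  n <- length(scores)
  if (n < 3) stop("radar area needs at least 3 indicators")
  if (method == "sum-of-squares") {
    0.5 * sum(scores^2) * sin(2 * pi / n)
  } else {
    0.5 * sin(2 * pi / n) * sum(scores * scores[c(2:n, 1)])
  }
}

scope_groups <- function(p, scope) {
  if (scope == "year") as.character(p$year) else rep("all", nrow(p))
}

#' Per-sample soil quality index over a dataset
#'
#' Computes min-max bounds for every indicator within the normalization
#' scope, scores each sample (plot x layer x year), and combines the
#' scores with [sqi_area()]. A degenerate indicator (constant within
#' scope) scores 1 for every sample, with a warning.
#'
#' @param d a [soil_dataset()].
#' @param cfg a [scoring_config()].
#' @return tibble with the sample keys, one `score_<indicator>` column
#'   per indicator, and `sqi`.
#' @export
sqi_pipeline <- function(d, cfg = scoring_config()) {
  stopifnot(inherits(d, "soil_dataset"), inherits(cfg, "scoring_config"))
  p <- sample_table(d)
  missing_ind <- setdiff(cfg$indicators, names(p))
  if (length(missing_ind) > 0) {
    stop("indicator(s) absent from dataset: ",
         paste(missing_ind, collapse = ", "))
  }
  grp <- scope_groups(p, cfg$normalization_scope)
  score_mat <- matrix(NA_real_, nrow(p), length(cfg$indicators),
                      dimnames = list(NULL, cfg$indicators))
  for (g in unique(grp)) {
    idx <- grp == g
    for (ind in cfg$indicators) {
      x <- p[[ind]][idx]
      lo <- min(x); hi <- max(x)
      if (lo == hi) {
        warning("indicator '", ind, "' is constant within scope '", g,
                "'; scored 1")
        score_mat[idx, ind] <- 1
      } else {
        score_mat[idx, ind] <- linear_score(x, cfg$directions[[ind]], lo, hi)
      }
    }
  }
  out <- p[, c("year", "wheat_tillage", "maize_tillage", "treatment",
               "replicate", "top_cm", "bottom_cm")]
  for (ind in cfg$indicators) {
    out[[paste0("score_", ind)]] <- score_mat[, ind]
  }
  out$sqi <- apply(score_mat, 1, sqi_area, method = cfg$sqi_method)
  out
}

#' Z-score standardization
#'
#' `(x - mean(x)) / SD(x)` over a pool of at least two values.
#'
#' @param x numeric pool.
#' @param sd_convention `"sample"` (n-1) or `"population"` (n).
#' @return z-scores with pool mean 0 and (by the chosen convention) SD 1.
#' @export
#' @examples
#' zscore(c(1, 2, 3))  # -1 0 1
zscore <- function(x, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (length(x) < 2) stop("z-score pool must have at least 2 values")
  s <- if (sd_convention == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("constant pool: SD is zero")
  (x - mean(x)) / s
}

#' Per-sample ecosystem multifunctionality index over a dataset
#'
#' Each of the three enzyme activities (invertase, urease, neutral
#' phosphatase) is z-scored over the standardization scope; the EMF of a
#' sample is the mean of its three enzyme z-scores. Surface samples of a
#' profile with decreasing enzyme activity therefore come out positive
#' and deep samples negative.
#'
#' @inheritParams sqi_pipeline
#' @return tibble with the sample keys, `z_<enzyme>` columns, and `emf`.
#' @export
emf_pipeline <- function(d, cfg = scoring_config()) {
  stopifnot(inherits(d, "soil_dataset"), inherits(cfg, "scoring_config"))
  p <- sample_table(d)
  grp <- scope_groups(p, cfg$standardization_scope)
  zs <- matrix(NA_real_, nrow(p), length(ENZYME_COLS),
               dimnames = list(NULL, ENZYME_COLS))
  for (g in unique(grp)) {
    idx <- grp == g
    for (enz in ENZYME_COLS) {
      zs[idx, enz] <- zscore(p[[enz]][idx], cfg$sd_convention)
    }
  }
  out <- p[, c("year", "wheat_tillage", "maize_tillage", "treatment",
               "replicate", "top_cm", "bottom_cm")]
  for (enz in ENZYME_COLS) out[[paste0("z_", enz)]] <- zs[, enz]
  out$emf <- rowMeans(zs)
  out
}

#' Combined per-sample index table
#'
#' Joins [sqi_pipeline()] and [emf_pipeline()] on the sample keys; the
#' result is the per-sample input for the trial statistics (correlations,
#' random-forest importance, EMF~SQI regression).
#'
#' @inheritParams sqi_pipeline
#' @return tibble with sample keys, per-component scores and z-scores,
#'   `sqi` and `emf`.
#' @export
indices_table <- function(d, cfg = scoring_config()) {
  keys <- c("year", "wheat_tillage", "maize_tillage", "treatment",
            "replicate", "top_cm", "bottom_cm")
  left_join(sqi_pipeline(d, cfg), emf_pipeline(d, cfg), by = keys)
}
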