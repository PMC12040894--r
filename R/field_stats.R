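# Trial statistics: factorial ANOVA, Fisher LSD compact letter displays,
# per-layer correlations, random-forest permutation importance, and the
# EMF ~ SQI regression.

#' Factorial fixed-effects ANOVA
#'
#' Three-way (year x depth x tillage, all interactions) or two-way
#' (year x tillage, for responses without a depth dimension) ANOVA on a
#' balanced complete layout, with the pooled residual as the single error
#' term. Depth is treated as a categorical factor.
#'
#' @param data data frame holding the response and factor columns.
#' @param response name of the response column.
#' @param factors subset of `c("year", "depth", "treatment")`; `"depth"`
#'   is looked up in a `depth` column, else `top_cm`, else `level`;
#'   `"treatment"` in a `treatment` column, else composed from
#'   `wheat_tillage`/`maize_tillage`.
#' @return tibble with one row per term (`Y`, `D`, `T` and their
#'   interactions): `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`;
#'   attributes `error_df` and `error_ms` carry the residual stratum.
#' @export
factorial_anova <- function(data, response,
                            factors = c("year", "depth", "treatment")) {
  stopifnot(all(factors %in% c("year", "depth", "treatment")),
            response %in% names(data))
  y <- data[[response]]
  if (any(is.na(y))) stop("response contains missing values")
  if (var(y) == 0) stop("zero residual variance: response is constant")
  fac <- list()
  if ("year" %in% factors) fac$Y <- factor(data$year)
  if ("depth" %in% factors) {
    depth_col <- intersect(c("depth", "top_cm", "level"), names(data))[1]
    if (is.na(depth_col)) stop("no depth column found")
    fac$D <- factor(data[[depth_col]])
  }
  if ("treatment" %in% factors) {
    fac$T <- factor(
      if ("treatment" %in% names(data)) data$treatment
      else treatment_label(data$wheat_tillage, data$maize_tillage),
      levels = intersect(treatment_levels(),
                         unique(if ("treatment" %in% names(data))
                           data$treatment
                           else treatment_label(data$wheat_tillage,
                                                data$maize_tillage)))
    )
  }
  counts <- table(do.call(interaction, fac))
  if (length(unique(counts)) != 1 || min(counts) < 2) {
    census <- paste(names(counts), counts, sep = ":", collapse = ", ")
    stop("layout must be balanced with >= 2 replicates per cell; cells: ",
         census)
  }
  df <- data.frame(fac)
  df$.y <- y
  form <- stats::as.formula(paste(".y ~", paste(names(fac), collapse = "*")))
  fit <- aov(form, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  res_i <- which(terms == "Residuals")
  error_ms <- tab[res_i, "Mean Sq"]
  if (error_ms <= 0 || !is.finite(error_ms)) {
    stop("zero residual variance: response is degenerate")
  }
  out <- tibble(
    term = gsub(":", "×", terms[-res_i]),
    df = tab[-res_i, "Df"],
    sum_sq = tab[-res_i, "Sum Sq"],
    mean_sq = tab[-res_i, "Mean Sq"],
    F = tab[-res_i, "F value"],
    p = tab[-res_i, "Pr(>F)"]
  )
  attr(out, "error_df") <- tab[res_i, "Df"]
  attr(out, "error_ms") <- error_ms
  attr(out, "error_ss") <- tab[res_i, "Sum Sq"]
  out
}

# Pairwise significance under Fisher's LSD with a pooled error mean
# square. Returns a logical k x k matrix (TRUE = significantly different).
lsd_significance <- function(means, ns, mse, df_err, alpha) {
  k <- length(means)
  sig <- matrix(FALSE, k, k)
  tcrit <- if (mse > 0) qt(1 - alpha / 2, df_err) else NA_real_
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (mse > 0) {
        lsd <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
        sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd
      } else {
        # zero pooled MSE: any difference in means is exact
        sig[i, j] <- sig[j, i] <- means[i] != means[j]
      }
    }
  }
  sig
}

# Insert-and-absorb compact letter display. Columns (letters) start as
# the full treatment set; every significant pair splits each column
# containing both; columns that are subsets of another are absorbed.
# Sharing a letter is then exactly equivalent to pairwise
# non-significance.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  absorb <- function(cols) {
    cols <- cols[lengths(cols) > 0]
    keys <- vapply(cols, function(col) paste(sort(col), collapse = ","),
                   character(1))
    cols <- cols[!duplicated(keys)]
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[b] && length(cols[[a]]) < length(cols[[b]]) &&
            all(cols[[a]] %in% cols[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    cols[keep]
  }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      newcols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          newcols <- c(newcols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      cols <- absorb(newcols)
    }
  }
  cols
}

#' Fisher LSD compact letter display
#'
#' One-way comparison of group means using Fisher's least significant
#' difference with the pooled within-group mean square, summarized as a
#' compact letter display: two groups share a letter if and only if their
#' difference is not significant at `alpha`. Letters are assigned over
#' groups sorted by descending mean.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), `>= 2` groups with
#'   `>= 2` replicates each.
#' @param alpha significance level, default 0.05.
#' @return tibble `group`, `n`, `mean`, `letters`, sorted by descending
#'   mean; attributes `mse`, `df_error`, `alpha`.
#' @export
lsd_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- tabulate(groups, nbins = k)
  if (any(ns < 2)) stop("every group needs >= 2 replicates")
  means <- tapply(values, groups, mean)
  df_err <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df_err
  ord <- order(-means)
  sig <- lsd_significance(means[ord], ns[ord], mse, df_err, alpha)
  cols <- cld_insert_absorb(sig)
  # letter order: by the highest-mean member of each column
  col_rank <- vapply(cols, min, integer(1))
  cols <- cols[order(col_rank)]
  letter_of <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  out <- tibble(
    group = levels(groups)[ord],
    n = ns[ord],
    mean = as.numeric(means[ord]),
    letters = letter_of
  )
  attr(out, "mse") <- mse
  attr(out, "df_error") <- df_err
  attr(out, "alpha") <- alpha
  out
}

#' Per-layer correlation screen
#'
#' Pearson correlations with two-sided p-values among a set of variables,
#' computed within each grouping cell (default year x depth layer), with
#' treatments and replicates pooled. A constant variable yields `NA`
#' correlations with an explanatory note instead of an error; no
#' multiple-testing adjustment is applied (raw p-values, as is customary
#' for trial correlation heatmaps).
#'
#' @param data sample-level data frame (e.g. profiles joined with
#'   indices).
#' @param variables character vector of numeric columns to correlate.
#' @param by grouping columns, default `c("year", "top_cm")`.
#' @return tidy tibble with the grouping keys, `var1`, `var2`, `r`, `p`,
#'   `n`, `note`; all ordered pairs are emitted, so the matrix form is
#'   symmetric with unit diagonal.
#' @export
layer_correlations <- function(data, variables,
                               by = c("year", "top_cm")) {
  stopifnot(all(variables %in% names(data)), all(by %in% names(data)))
  key <- do.call(paste, c(data[by], sep = "\r"))
  out <- list()
  for (g in unique(key)) {
    sub <- data[key == g, , drop = FALSE]
    for (a in variables) {
      for (b in variables) {
        x <- sub[[a]]; y <- sub[[b]]
        ok <- stats::complete.cases(x, y)
        n_ok <- sum(ok)
        row <- sub[1, by, drop = FALSE]
        if (a == b) {
          r <- 1; p <- NA_real_; note <- NA_character_
        } else if (n_ok < 3) {
          r <- NA_real_; p <- NA_real_; note <- "insufficient observations"
        } else if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
          r <- NA_real_; p <- NA_real_; note <- "constant variable"
        } else {
          ct <- cor.test(x[ok], y[ok], method = "pearson")
          r <- unname(ct$estimate); p <- ct$p.value; note <- NA_character_
        }
        out[[length(out) + 1]] <- tibble(
          row, var1 = a, var2 = b, r = r, p = p, n = n_ok, note = note
        )
      }
    }
  }
  bind_rows(out)
}

#' Random-forest permutation importance
#'
#' Fits a regression random forest of the response on the predictors and
#' reports each predictor's permutation importance (mean increase in MSE
#' when the predictor is permuted out-of-bag). Significance is assessed
#' against a null distribution obtained by refitting the forest
#' `n_permutations` times with the response permuted and recording the
#' importance each predictor attains by chance:
#' `p = (1 + #(null >= observed)) / (n_permutations + 1)`.
#' Deterministic under a fixed seed.
#'
#' @param data complete-case data frame.
#' @param predictors character vector of predictor columns (e.g. MBC,
#'   LOC, SOC, DOC, NLOC, BD).
#' @param response response column (e.g. `emf`).
#' @param n_trees trees per forest, default 500.
#' @param n_permutations response permutations for the null, default 100.
#' @param seed integer seed.
#' @return tibble `predictor`, `importance` (increase in MSE),
#'   `p_value`, sorted by descending importance; attribute
#'   `var_explained_pct` is the forest's out-of-bag variance explained.
#' @export
rf_importance <- function(data, predictors, response,
                          n_trees = 500, n_permutations = 100, seed = 1) {
  stopifnot(all(c(predictors, response) %in% names(data)))
  df <- data[stats::complete.cases(data[c(predictors, response)]),
             c(predictors, response), drop = FALSE]
  if (nrow(df) < 10) stop("need at least 10 complete samples")
  x <- as.data.frame(df[predictors])
  y <- df[[response]]
  with_seed(derive_seed(seed, "rf_importance"), {
    fit <- randomForest::randomForest(x, y, ntree = n_trees,
                                      importance = TRUE)
    obs <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    null_ge <- rep(0L, length(obs))
    for (k in seq_len(n_permutations)) {
      perm_fit <- randomForest::randomForest(x, sample(y), ntree = n_trees,
                                             importance = TRUE)
      null_imp <- randomForest::importance(perm_fit, type = 1,
                                           scale = FALSE)[, 1]
      null_ge <- null_ge + as.integer(null_imp >= obs)
    }
    out <- tibble(
      predictor = names(obs),
      importance = as.numeric(obs),
      p_value = (1 + null_ge) / (n_permutations + 1)
    )
    out <- out[order(-out$importance), ]
    attr(out, "var_explained_pct") <- 100 * fit$rsq[n_trees]
    attr(out, "n_trees") <- n_trees
    attr(out, "n_permutations") <- n_permutations
    attr(out, "seed") <- seed
    out
  })
}

#' Linear regression of EMF on SQI
#'
#' Ordinary least squares with the slope t-test and coefficient of
#' determination.
#'
#' @param emf,sqi paired numeric vectors, `>= 3` pairs.
#' @return one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
emf_sqi_regression <- function(emf, sqi) {
  if (length(emf) != length(sqi) || length(emf) < 3) {
    stop("need >= 3 paired observations")
  }
  if (sd(sqi) == 0) stop("constant sqi: regression undefined")
  fit <- lm(emf ~ sqi)
  sm <- summary(fit)
  tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["sqi", "Pr(>|t|)"],
    n = length(emf)
  )
}
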