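# Shared builders for the test suite. Everything is generated in code;
# no fixture files.

# A design with every noise component switched off: the generated values
# are exactly the deterministic response surface.
noise_free_spec <- function(seed = 1, bd_cv = 0, ...) {
  vars <- agrisoc:::default_variable_params()
  for (nm in names(vars)) {
    vars[[nm]]$plot_sd <- 0
    vars[[nm]]$residual_cv <- 0
  }
  vars$bd_g_cm3$residual_cv <- bd_cv
  design_spec(seed = seed, variables = vars,
              loc_fraction = variable_param(0.28, 1, plot_sd = 0,
                                            residual_cv = 0),
              yield = list(mean = 6000, plot_sd = 0, residual_cv = 0),
              ...)
}

# Sample-level table with SQI and EMF joined on, as the stats stage uses.
samples_with_indices <- function(d, cfg = scoring_config()) {
  idx <- indices_table(d, cfg)
  dplyr::left_join(
    agrisoc:::sample_table(d),
    idx[, c("year", "treatment", "replicate", "top_cm", "sqi", "emf")],
    by = c("year", "treatment", "replicate", "top_cm")
  )
}

# Independent loop-based reimplementation of the cumulative
# reference-mass storage formula; shares no code with esm_storage().
brute_force_esm <- function(bd, soc, thick_m, refs, policy = "next-layer") {
  n <- length(bd)
  mass <- numeric(n)
  for (i in 1:n) mass[i] <- bd[i] * thick_m[i] * 10000
  out <- numeric(n)
  for (j in 1:n) {
    stock <- 0
    cum <- 0
    for (i in 1:j) {
      stock <- stock + mass[i] * soc[i]
      cum <- cum + mass[i]
    }
    cx <- if (policy == "next-layer") soc[min(j + 1, n)] else soc[j]
    out[j] <- (stock + (refs[j] - cum) * cx) * 0.001
  }
  out
}

# Letter-sharing relation implied by a compact letter display.
sharing_matrix <- function(letters_tab) {
  chars <- strsplit(letters_tab$letters, "")
  k <- length(chars)
  share <- matrix(FALSE, k, k, dimnames = list(letters_tab$group,
                                               letters_tab$group))
  for (i in 1:k) {
    for (j in 1:k) share[i, j] <- length(intersect(chars[[i]], chars[[j]])) > 0
  }
  share
}

# Brute-force all-pairs Fisher LSD non-significance relation.
brute_force_lsd_relation <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups, nbins = k)
  df_err <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df_err
  nonsig <- matrix(TRUE, k, k, dimnames = list(levels(groups),
                                               levels(groups)))
  for (i in 1:k) {
    for (j in 1:k) {
      if (i != j) {
        if (mse > 0) {
          tstat <- abs(means[i] - means[j]) /
            sqrt(mse * (1 / ns[i] + 1 / ns[j]))
          nonsig[i, j] <- 2 * stats::pt(-tstat, df_err) >= alpha
        } else {
          nonsig[i, j] <- means[i] == means[j]
        }
      }
    }
  }
  nonsig
}
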