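test_that("generation is deterministic in the seed and canonically ordered", {
  d1 <- generate_dataset(design_spec(seed = 11))
  d2 <- generate_dataset(design_spec(seed = 11))
  d3 <- generate_dataset(design_spec(seed = 12))
  expect_identical(d1$profiles, d2$profiles)
  expect_identical(d1$yields, d2$yields)
  expect_false(isTRUE(all.equal(d1$profiles$soc_g_kg, d3$profiles$soc_g_kg)))
  # record ordering is the canonical sort, independent of the seed
  keys <- c("year", "wheat_tillage", "maize_tillage", "replicate", "top_cm")
  expect_identical(d1$profiles[keys], d3$profiles[keys])
})

test_that("the noise-free limit reproduces the response surface exactly", {
  d <- generate_dataset(noise_free_spec(seed = 1))
  p <- d$profiles
  # every replicate identical
  spread <- tapply(p$soc_g_kg,
                   paste(p$year, p$wheat_tillage, p$maize_tillage, p$top_cm),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  vars <- agrisoc:::default_variable_params()
  layer_idx <- p$top_cm / 10 + 1
  for (nm in c("bd_g_cm3", "soc_g_kg", "mbc_mg_kg", "phosphatase")) {
    expect_equal(
      p[[nm]],
      vars[[nm]]$surface_mean * vars[[nm]]$depth_decay^(layer_idx - 1),
      tolerance = 1e-12
    )
  }
  expect_equal(p$loc_g_kg, p$soc_g_kg * 0.28, tolerance = 1e-12)
  expect_true(all(d$yields$yield_kg_ha == 6000))
})

test_that("planted effects are local and scale expectations exactly", {
  base <- design_spec(seed = 2)
  expect_identical(planted_effect_spec(base, "soc_g_kg", "20-40", 0,
                                       c("DT-SBR", "DT-SIR")),
                   base)
  spec <- planted_effect_spec(base, "soc_g_kg", "20-40", 0.10,
                              c("DT-SBR", "DT-SIR"))
  m0 <- base$variables$soc_g_kg$multipliers
  m1 <- spec$variables$soc_g_kg$multipliers
  expect_equal(sum(m1 != m0), 2)  # two treatment rows x one band
  expect_equal(m1[c("DT-SBR", "DT-SIR"), "20-40"],
               m0[c("DT-SBR", "DT-SIR"), "20-40"] * 1.10)
  expect_error(planted_effect_spec(base, "soc_g_kg", "15-25", 0.1, "DT-SBR"),
               "band")
  expect_error(planted_effect_spec(base, "nope", "20-40", 0.1, "DT-SBR"),
               "variable")
  # -5% BD under subsoiling: noise-free expectation ratio is exactly 0.95
  nf <- noise_free_spec(seed = 2)
  nf_bd <- planted_effect_spec(nf, "bd_g_cm3", c("0-20", "20-40"), -0.05,
                               c("RT-SBR", "RT-SIR", "DT-SBR", "DT-SIR"))
  p0 <- generate_dataset(nf)$profiles
  p1 <- generate_dataset(nf_bd)$profiles
  sub <- p0$maize_tillage %in% c("SBR", "SIR") & p0$top_cm < 40
  expect_equal(p1$bd_g_cm3[sub] / p0$bd_g_cm3[sub],
               rep(0.95, sum(sub)), tolerance = 1e-12)
  expect_equal(p1$bd_g_cm3[!sub], p0$bd_g_cm3[!sub])
})

test_that("generated datasets always satisfy the data-model invariants", {
  for (seed in c(1, 77, 2024)) {
    d <- generate_dataset(design_spec(seed = seed))
    expect_equal(nrow(d$validation), 0)
    expect_equal(nrow(d$profiles), 2 * 6 * 3 * 5)
    expect_true(all(d$profiles$loc_g_kg / d$profiles$soc_g_kg <= 0.35))
  }
})

test_that("sample means match the closed-form lognormal expectation", {
  # E[value] = surface_mean * decay^(i-1) * exp(plot_sd^2 / 2) under
  # multiplicative noise; checked per cell over replicate datasets.
  spec <- design_spec(seed = 0)
  n_rep <- 400
  cells <- expand.grid(top = c(0, 30), trt = c("RT-NT", "DT-SIR"))
  sums <- matrix(0, nrow(cells), 2)  # running sum and sum of squares
  for (k in seq_len(n_rep)) {
    spec$seed <- k
    p <- generate_dataset(spec)$profiles
    trt <- paste0(p$wheat_tillage, "-", p$maize_tillage)
    for (c_i in seq_len(nrow(cells))) {
      v <- mean(p$soc_g_kg[p$top_cm == cells$top[c_i] &
                             trt == cells$trt[c_i] & p$year == 2018])
      sums[c_i, 1] <- sums[c_i, 1] + v
      sums[c_i, 2] <- sums[c_i, 2] + v^2
    }
  }
  par <- spec$variables$soc_g_kg
  for (c_i in seq_len(nrow(cells))) {
    expected <- par$surface_mean * par$depth_decay^(cells$top[c_i] / 10) *
      exp(par$plot_sd^2 / 2)
    m <- sums[c_i, 1] / n_rep
    se <- sqrt((sums[c_i, 2] / n_rep - m^2) / n_rep)
    expect_lt(abs(m - expected), 3 * se + 1e-12)
  }
})

test_that("plot effects induce positive within-plot correlation across layers", {
  vars <- agrisoc:::default_variable_params()
  vars$soc_g_kg$plot_sd <- 0.2
  vars$soc_g_kg$residual_cv <- 0.05
  spec <- design_spec(seed = 0, variables = vars)
  top_vals <- mid_vals <- numeric(150)
  for (k in seq_len(150)) {
    spec$seed <- k
    p <- generate_dataset(spec)$profiles
    sel <- p$year == 2018 & p$wheat_tillage == "RT" &
      p$maize_tillage == "NT" & p$replicate == 1
    top_vals[k] <- p$soc_g_kg[sel & p$top_cm == 0]
    mid_vals[k] <- p$soc_g_kg[sel & p$top_cm == 20]
  }
  expect_gt(stats::cor(top_vals, mid_vals), 0.3)
})

test_that("design invariants are enforced at construction", {
  vars <- agrisoc:::default_variable_params()
  vars$soc_g_kg$residual_cv <- 0.6
  expect_error(design_spec(variables = vars), "residual_cv")
  vars <- agrisoc:::default_variable_params()
  vars$bd_g_cm3$depth_decay <- 0.9
  expect_error(design_spec(variables = vars), "bulk density")
  vars <- agrisoc:::default_variable_params()
  vars$mbc_mg_kg$depth_decay <- 1.2
  expect_error(design_spec(variables = vars), "depth_decay")
  vars <- agrisoc:::default_variable_params()
  vars$soc_g_kg$surface_mean <- -1
  expect_error(design_spec(variables = vars), "surface_mean")
})
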