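test_that("layer mass is bulk density times thickness times 10^4", {
  expect_equal(layer_soil_mass(1.5, 0, 10), 1500)
  expect_equal(layer_soil_mass(1.0, 0, 10), 1000)
  expect_equal(layer_soil_mass(1.49, 0, 10), 1490)
  expect_error(layer_soil_mass(0, 0, 10), "bulk density")
})

test_that("stacks are canonical, contiguous and cumulative", {
  layers <- data.frame(
    top_cm = c(0, 10, 20, 30), bottom_cm = c(10, 20, 30, 40),
    bd_g_cm3 = 1.5, soc_g_kg = c(10, 9, 8, 7)
  )
  st <- build_stack(layers, 40)
  expect_equal(st$soil_mass, rep(1500, 4))
  expect_equal(st$cum_mass, c(1500, 3000, 4500, 6000))
  shuffled <- layers[c(3, 1, 4, 2), ]
  expect_identical(build_stack(shuffled, 40), st)
  expect_error(build_stack(layers[-3, ], 40), "non-contiguous")
  expect_error(build_stack(layers, 50), "exceeds available")
})

test_that("reference masses are per-level maxima over the scope", {
  mk <- function(bd) build_stack(data.frame(
    top_cm = c(0, 10), bottom_cm = c(10, 20), bd_g_cm3 = bd, soc_g_kg = 10
  ), 20)
  a <- mk(c(1.4, 1.5))  # cum 1400, 2900
  b <- mk(c(1.5, 1.6))  # cum 1500, 3100
  expect_equal(as.numeric(reference_masses(list(a, b))), c(1500, 3100))
  expect_equal(as.numeric(reference_masses(list(a))), a$cum_mass)
  expect_error(reference_masses(list()), "empty scope")
  # brute-force maximum over 10 random stacks
  set.seed(42)
  stacks <- lapply(1:10, function(i) mk(stats::runif(2, 1.0, 1.9)))
  refs <- as.numeric(reference_masses(stacks))
  for (j in 1:2) {
    expect_equal(refs[j], max(vapply(stacks, function(s) s$cum_mass[j], 0)))
  }
})

test_that("the reference-mass correction matches the hand-worked case", {
  stack <- build_stack(data.frame(
    top_cm = c(0, 10), bottom_cm = c(10, 20),
    bd_g_cm3 = c(1.4, 1.5), soc_g_kg = c(10, 8)
  ), 20)
  res <- esm_storage(stack, c(1500, 3100))
  expect_equal(res$storage_Mg_ha, c(14.8, 27.6))
  expect_equal(res$deficit_Mg_ha, c(100, 200))
  expect_equal(res$c_extra_kg_Mg, c(8, 8))
  # deficit zero at every level collapses to the fixed-depth stock
  res0 <- esm_storage(stack, stack$cum_mass, c_extra = "same-layer")
  expect_equal(res0$storage_Mg_ha,
               cumsum(stack$soil_mass * stack$carbon_conc) * 0.001)
  # uniform one-layer sanity: bd 1.5, C 10 over 0-10 cm is 15 Mg/ha
  one <- build_stack(data.frame(top_cm = 0, bottom_cm = 10,
                                bd_g_cm3 = 1.5, soc_g_kg = 10), 10)
  expect_equal(esm_storage(one, 1500)$storage_Mg_ha, 15)
  # a stack heavier than its reference is a scope bug, never truncated
  expect_error(esm_storage(stack, c(1300, 3100)), "heavier")
})

test_that("storage responds to layer mass with slope C_i - C_extra", {
  stack <- build_stack(data.frame(
    top_cm = c(0, 10, 20), bottom_cm = c(10, 20, 30),
    bd_g_cm3 = c(1.3, 1.5, 1.6), soc_g_kg = c(12, 8, 5)
  ), 30)
  refs <- stack$cum_mass + c(200, 150, 100)
  base <- esm_storage(stack, refs)
  h <- 1  # Mg/ha perturbation of layer 1 mass, refs held fixed
  bumped <- stack
  bumped$soil_mass[1] <- bumped$soil_mass[1] + h
  bumped$cum_mass <- cumsum(bumped$soil_mass)
  pert <- esm_storage(bumped, refs)
  for (j in 1:3) {
    slope <- (pert$storage_Mg_ha[j] - base$storage_Mg_ha[j]) / h * 1000
    expect_equal(slope,
                 stack$carbon_conc[1] - base$c_extra_kg_Mg[j],
                 tolerance = 1e-9)
  }
})

test_that("identical soil masses make the ESM correction a no-op", {
  d <- generate_dataset(noise_free_spec(seed = 9))
  st <- esm_table(d)
  expect_true(all(st$deficit_Mg_ha == 0))
  p <- d$profiles
  fixed <- p[p$top_cm < 40, ] |>
    dplyr::group_by(.data$year, .data$wheat_tillage, .data$maize_tillage,
                    .data$replicate) |>
    dplyr::arrange(.data$top_cm, .by_group = TRUE) |>
    dplyr::summarise(storage = list(cumsum(
      .data$bd_g_cm3 * (.data$bottom_cm - .data$top_cm) / 100 *
        .data$soc_g_kg * 10
    )), .groups = "drop")
  got <- st |>
    dplyr::group_by(.data$year, .data$treatment, .data$replicate) |>
    dplyr::summarise(storage = list(.data$storage_Mg_ha), .groups = "drop")
  for (i in seq_len(nrow(got))) {
    ref_row <- which(
      fixed$year == got$year[i] &
        paste0(fixed$wheat_tillage, "-", fixed$maize_tillage) ==
          got$treatment[i] &
        fixed$replicate == got$replicate[i]
    )
    expect_equal(got$storage[[i]], fixed$storage[[ref_row]],
                 tolerance = 1e-12)
  }
})

test_that("aggregation modes agree on noise-free data and the table matches brute force", {
  d <- generate_dataset(noise_free_spec(seed = 10))
  per_rep <- esm_table(d, aggregation = "per-replicate")
  mean_first <- esm_table(d, aggregation = "replicate-mean-first")
  avg <- per_rep |>
    dplyr::group_by(.data$year, .data$treatment, .data$level) |>
    dplyr::summarise(storage = mean(.data$storage_Mg_ha), .groups = "drop")
  joined <- dplyr::left_join(
    avg, mean_first[, c("year", "treatment", "level", "storage_Mg_ha")],
    by = c("year", "treatment", "level")
  )
  expect_equal(joined$storage, joined$storage_Mg_ha, tolerance = 1e-12)

  # random noisy dataset against the independent loop oracle
  d2 <- generate_dataset(design_spec(seed = 123))
  tab <- esm_table(d2, aggregation = "per-replicate", c_extra = "next-layer")
  p <- d2$profiles
  p$treatment <- paste0(p$wheat_tillage, "-", p$maize_tillage)
  for (yr in unique(p$year)) {
    py <- p[p$year == yr & p$top_cm < 40, ]
    key <- paste(py$treatment, py$replicate)
    refs <- rep(0, 4)
    for (k in unique(key)) {
      q <- py[key == k, ][order(py$top_cm[key == k]), ]
      refs <- pmax(refs, cumsum(q$bd_g_cm3 * 0.1 * 10000))
    }
    for (k in unique(key)) {
      q <- py[key == k, ][order(py$top_cm[key == k]), ]
      want <- brute_force_esm(q$bd_g_cm3, q$soc_g_kg, rep(0.1, 4), refs)
      got <- tab$storage_Mg_ha[tab$year == yr &
                                 tab$treatment == q$treatment[1] &
                                 tab$replicate == q$replicate[1]]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("storage is non-decreasing with depth on realistic profiles", {
  for (seed in c(5, 31)) {
    tab <- esm_table(generate_dataset(design_spec(seed = seed)))
    by_stack <- split(tab$storage_Mg_ha,
                      paste(tab$year, tab$treatment, tab$replicate))
    expect_true(all(vapply(by_stack,
                           function(v) all(diff(v) > 0), logical(1))))
  }
})
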