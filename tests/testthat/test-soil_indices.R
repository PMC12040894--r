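test_that("linear scores hit the endpoints and ratios exactly", {
  expect_equal(linear_score(10, "more", 2, 10), 1)
  expect_equal(linear_score(2, "less", 2, 10), 1)
  expect_equal(linear_score(5, "more", 1, 10), 0.5)
  expect_equal(linear_score(4, "less", 2, 10), 0.5)
  expect_error(linear_score(11, "more", 2, 10), "scope")
  expect_error(linear_score(5, "less", 0, 10), "x_min")
})

test_that("the radar-area index matches its closed form and bound", {
  expect_equal(sqi_area(rep(1, 4)), 2)
  expect_equal(sqi_area(rep(0, 5)), 0)
  expect_equal(sqi_area(rep(1, 9)), 4.5 * sin(2 * pi / 9))
  expect_error(sqi_area(c(1, 1)), "at least 3")
  # order invariance of the printed (no cross terms) form ...
  s <- c(0.2, 0.9, 0.5, 0.7, 1.0)
  expect_equal(sqi_area(s), sqi_area(rev(s)))
  expect_equal(sqi_area(s), sqi_area(sample(s)))
  # ... while the true polygon area is order-dependent
  expect_false(isTRUE(all.equal(sqi_area(s, method = "polygon"),
                                sqi_area(s[c(1, 3, 5, 2, 4)],
                                         method = "polygon"))))
})

test_that("SQI scoring is scale invariant and ranks a dominant treatment first", {
  d <- generate_dataset(design_spec(seed = 21))
  cfg <- scoring_config()
  base <- sqi_pipeline(d, cfg)
  # common rescaling of any indicator within scope leaves SQI unchanged
  p2 <- d$profiles
  p2$mbc_mg_kg <- p2$mbc_mg_kg * 2
  p2$bd_g_cm3 <- p2$bd_g_cm3 * 1.05
  doubled <- sqi_pipeline(soil_dataset(p2, d$yields), cfg)
  expect_equal(doubled$sqi, base$sqi, tolerance = 1e-12)
  # a treatment boosted in every indicator holds the scope maximum
  spec <- design_spec(seed = 22)
  for (v in names(spec$variables)) {
    delta <- if (v == "bd_g_cm3") -0.15 else 0.25
    spec <- planted_effect_spec(spec, v, c("0-20", "20-40", "40-50"),
                                delta, "DT-SIR")
  }
  db <- generate_dataset(spec)
  res <- sqi_pipeline(db, cfg)
  top_layer <- res[res$top_cm == 0 & res$year == 2018, ]
  best <- top_layer$treatment[which.max(top_layer$sqi)]
  expect_equal(best, "DT-SIR")
})

test_that("SQI pipeline equals a from-scratch recomputation", {
  d <- generate_dataset(design_spec(seed = 23))
  cfg <- scoring_config()
  res <- sqi_pipeline(d, cfg)
  p <- agrisoc:::sample_table(d)
  n <- length(cfg$indicators)
  for (i in c(1, 50, 180)) {
    pool <- p[p$year == p$year[i], ]
    total <- 0
    for (ind in cfg$indicators) {
      x <- p[[ind]][i]
      s <- if (cfg$directions[[ind]] == "more") x / max(pool[[ind]])
           else min(pool[[ind]]) / x
      total <- total + s^2
    }
    expect_equal(res$sqi[i], 0.5 * total * sin(2 * pi / n),
                 tolerance = 1e-12)
  }
})

test_that("a degenerate indicator scores 1 with a warning", {
  d <- generate_dataset(design_spec(seed = 24))
  p <- d$profiles
  p$doc_mg_kg <- 40
  w <- capture_warnings(res <- sqi_pipeline(soil_dataset(p, d$yields)))
  expect_true(any(grepl("constant within scope", w)))
  expect_true(all(res$score_doc_mg_kg == 1))
})

test_that("z-scores normalize exactly under both SD conventions", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- stats::rnorm(40, 5, 2)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  zp <- zscore(x, "population")
  expect_equal(sqrt(mean((zp - mean(zp))^2)), 1, tolerance = 1e-12)
  expect_equal(zscore(c(2, 4, 6))[2], 0)
  expect_error(zscore(rep(3, 5)), "constant pool")
  expect_error(zscore(3), "at least 2")
})

test_that("EMF is the mean enzyme z-score and decreases with depth", {
  d <- generate_dataset(design_spec(seed = 25))
  res <- emf_pipeline(d)
  expect_equal(res$emf,
               rowMeans(res[, c("z_invertase", "z_urease", "z_phosphatase")]))
  # z-scored within year, the pool mean of EMF is zero
  for (yr in unique(res$year)) {
    expect_equal(mean(res$emf[res$year == yr]), 0, tolerance = 1e-12)
  }
  # enzymes decrease with depth, so mean EMF must too (pooled scoping)
  prof <- tapply(res$emf, res$top_cm, mean)
  expect_true(all(diff(prof[order(as.numeric(names(prof)))]) < 0))
})

test_that("EMF is invariant to affine transforms of any single enzyme", {
  d <- generate_dataset(design_spec(seed = 26))
  base <- emf_pipeline(d)
  p <- d$profiles
  p$urease <- 3.7 * p$urease + 11
  shifted <- emf_pipeline(soil_dataset(p, d$yields))
  expect_equal(shifted$emf, base$emf, tolerance = 1e-12)
})
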