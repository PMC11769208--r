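test_that("weight coefficients normalize integer scores under each rounding mode", {
  # six-criterion region: five unit scores plus a double-weight exposure term
  expect_equal(compute_weight_coefficients(c(1, 1, 1, 1, 1, 2)),
               c(1, 1, 1, 1, 1, 2) / 7)
  expect_equal(compute_weight_coefficients(c(1, 1, 1, 1, 1, 2), "display3"),
               c(0.143, 0.143, 0.143, 0.143, 0.143, 0.286))
  # the sum-to-one adjustment lands on the last largest coefficient
  expect_equal(compute_weight_coefficients(c(1, 1, 1, 1, 1, 2), "table_match"),
               c(0.143, 0.143, 0.143, 0.143, 0.143, 0.285))
  expect_equal(compute_weight_coefficients(c(1, 1, 1, 2, 1, 1, 2), "display3"),
               c(0.111, 0.111, 0.111, 0.222, 0.111, 0.111, 0.222))
  expect_equal(compute_weight_coefficients(c(1, 1, 1, 2, 1, 1, 2), "table_match"),
               c(0.111, 0.111, 0.111, 0.222, 0.111, 0.111, 0.223))
  expect_equal(compute_weight_coefficients(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(compute_weight_coefficients(5), 1)

  expect_error(compute_weight_coefficients(numeric()), class = "msdrisk_invalid_input")
  expect_error(compute_weight_coefficients(c(1, 0)), class = "msdrisk_invalid_input")
  expect_error(compute_weight_coefficients(c(1, 1.5)), class = "msdrisk_invalid_input")
})

test_that("exact-mode coefficients sum to 1 for random score vectors", {
  for (seed in 1:50) {
    set.seed(seed)
    scores <- sample(1:9, sample(1:8, 1), replace = TRUE)
    q <- compute_weight_coefficients(scores)
    expect_equal(sum(q), 1, tolerance = 1e-15)
    expect_true(all(q > 0))
  }
})

test_that("element factors reproduce printed table cells", {
  # neck: a = 1.120 (male), unit-score q of B = (1,1,1,1,1,2)
  q_neck <- compute_weight_coefficients(c(1, 1, 1, 1, 1, 2))[1]
  expect_equal(round(element_factor(1.120, q_neck), 3), 0.160)
  expect_equal(round(element_factor(0.161, q_neck), 3), 0.023)
  # shoulder/elbow: B = (1,1,1,2,1,1,2)
  q_sym <- compute_weight_coefficients(c(1, 1, 1, 2, 1, 1, 2))[4]
  expect_equal(round(element_factor(1.009, q_sym), 3), 0.224)
  expect_equal(round(element_factor(1.005, q_sym), 3), 0.223)
  expect_equal(round(element_factor(0.976, 1 / 9), 3), 0.108)
  # identical under displayed coefficients
  expect_equal(element_factor(1.120, 0.143, "display3"), 0.160)
  expect_equal(element_factor(1.009, 0.222, "display3"), 0.224)
  # unit likelihood returns the weight
  expect_equal(element_factor(1, 0.5), 0.5)
  expect_error(element_factor(-1, 0.5), class = "msdrisk_invalid_input")
  expect_error(element_factor(1, 0), class = "msdrisk_invalid_input")
  expect_error(element_factor(1, 1.2), class = "msdrisk_invalid_input")
})

test_that("likelihood blending is a share-weighted mean bounded by its inputs", {
  expect_equal(blend_likelihoods(c(0.919, 1.041), c(0.5, 0.5)), 0.980)
  expect_equal(blend_likelihoods(c(0.7, 1.3), c(1, 0)), 0.7)
  expect_equal(blend_likelihoods(c(1, 1), c(0.3, 0.7)), 1)
  for (seed in 1:25) {
    set.seed(seed)
    a <- runif(2, 0.5, 1.5)
    c1 <- runif(1)
    b <- blend_likelihoods(a, c(c1, 1 - c1))
    expect_gte(b, min(a))
    expect_lte(b, max(a))
  }
  expect_error(blend_likelihoods(c(1, 1), c(0.6, 0.6)), class = "msdrisk_invalid_input")
  expect_error(blend_likelihoods(c(1, 1), c(-0.1, 1.1)), class = "msdrisk_invalid_input")
})

test_that("scenario probability scales the baseline by the factor sum and clips", {
  # all likelihoods 1 with any valid weights: p equals the baseline
  q <- compute_weight_coefficients(c(2, 3, 1))
  sp <- scenario_probability(0.37, element_factor(rep(1, 3), q))
  expect_equal(sp$probability, 0.37)
  expect_false(sp$clipped)

  # worked shift example: Q = 0.5 with a neutral factor sum stays 0.5
  expect_equal(scenario_probability(0.5, 1)$probability, 0.5)

  # neck baseline at age 43 times the hand-summed printed factor chain
  q43 <- evaluate_baseline(msd_baseline_curves("neck"), 43)
  expect_equal(q43, 0.4653283, tolerance = 1e-7)
  expect_equal(round(scenario_probability(q43, 1.013)$probability, 4), 0.4714)

  expect_warning(sp2 <- scenario_probability(0.9, c(0.8, 0.7)),
                 class = "msdrisk_clip_warning")
  expect_equal(sp2$probability, 1)
  expect_true(sp2$clipped)

  tb <- tiny_table()
  factors <- data.frame(criterion = c("sex", "load"), value = c(0.55, 0.4))
  expect_equal(scenario_probability(0.5, factors, tb)$factor_sum, 0.95)
  bad <- data.frame(criterion = c("sex", "other"), value = c(0.55, 0.4))
  expect_error(scenario_probability(0.5, bad, tb), class = "msdrisk_invalid_input")
  expect_error(scenario_probability(1.5, 1), class = "msdrisk_invalid_input")
})

test_that("scenario probability is linear in baseline and in each likelihood before clipping", {
  q <- compute_weight_coefficients(c(1, 2, 1, 3))
  a <- c(0.9, 1.1, 1.0, 0.8)
  base <- scenario_probability(0.2, element_factor(a, q))$probability
  expect_equal(scenario_probability(0.4, element_factor(a, q))$probability,
               2 * base, tolerance = 1e-12)
  # doubling one likelihood adds exactly q_i * a_i * Q
  a2 <- a; a2[2] <- 2 * a[2]
  expect_equal(scenario_probability(0.2, element_factor(a2, q))$probability - base,
               0.2 * q[2] * a[2], tolerance = 1e-12)
})

test_that("scenario probability matches a term-by-term rational-weight oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:7, 1)
    scores <- sample(1:5, n, replace = TRUE)
    a <- runif(n, 0.5, 1.5)
    Q <- runif(1, 0.05, 0.6)
    # oracle: sum B_i * a_i computed term by term, divided once by sum B
    oracle <- Q * sum(vapply(seq_len(n), function(i) scores[i] * a[i], 0)) / sum(scores)
    got <- quiet(scenario_probability(
      Q, element_factor(a, compute_weight_coefficients(scores))
    ))$probability
    expect_equal(got, min(1, oracle), tolerance = 1e-12)
  }
})

test_that("normalization verification reports exact and display residuals", {
  for (tb in msd_default_criteria()) {
    chk <- verify_normalization(tb, "exact")
    expect_true(chk$ok)
    expect_equal(chk$residual, 0, tolerance = 1e-15)
  }
  # elbow displayed weights sum to 0.999: residual reported, still ok at
  # display tolerance
  chk <- verify_normalization(msd_default_criteria("elbow"), "display3")
  expect_true(chk$ok)
  expect_equal(chk$residual, 0.001)
  # table_match repairs the displayed sum exactly
  chk2 <- verify_normalization(msd_default_criteria("elbow"), "table_match")
  expect_equal(chk2$residual, 0)

  # constructed violation: a manually edited weight set summing to 0.9
  q_bad <- c(0.4, 0.5)
  expect_false(abs(1 - sum(q_bad)) <= 1e-12)
})

test_that("criterion and table constructors enforce their invariants", {
  expect_error(criterion_def("x", 0), class = "msdrisk_invalid_input")
  expect_error(criterion_def("x", 1, "categorical", c(a = -1)),
               class = "msdrisk_invalid_input")
  expect_error(criterion_def("x", 1, "proportional", c(a = 1, b = 1, c = 1)),
               class = "msdrisk_invalid_input")
  expect_error(criterion_def("x", 1, "parametric", c(a = 1)),
               class = "msdrisk_invalid_input")
  expect_error(
    criteria_table("neck", list(criterion_def("x", 1, "parametric"),
                                criterion_def("x", 2, "parametric"))),
    class = "msdrisk_invalid_input"
  )
  # single-criterion table is legal with q = 1
  single <- criteria_table("neck", list(criterion_def("only", 3, "parametric")))
  expect_equal(unname(weight_coefficients(single)), 1)
})

test_that("criteria tables round-trip losslessly through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  tables <- msd_default_criteria()
  write_criteria(tables, path)
  back <- read_criteria(path)
  expect_equal(back, tables)

  # packaged JSON matches the in-code defaults
  packaged <- read_criteria(system.file("extdata", "criteria_tables.json",
                                        package = "msdrisk"))
  expect_equal(packaged, tables)
  # the packaged neck table flags its outlier likelihood
  expect_match(packaged$neck$notes, "0.161")
})
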