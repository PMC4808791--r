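pts <- function(x, y) tibble::tibble(mutation_rate = x, optimal_mismatch_rate = y)

test_that("fit_mismatch_model matches hand-computed OLS", {
  m <- fit_mismatch_model(pts(c(0, 1, 2, 3), c(1, 3, 5, 7)))  # y = 2x + 1
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$rmse, 0, tolerance = 1e-10)

  two <- fit_mismatch_model(pts(c(1, 4), c(2, 11)))  # interpolating line
  expect_equal(two$r2, 1)
  expect_equal(two$slope, 3)

  m <- fit_mismatch_model(pts(c(1, 2, 3), c(2, 2, 4)))
  expect_equal(m$slope, 1, tolerance = 1e-12)          # normal equations by hand
  expect_equal(m$intercept, 2 / 3, tolerance = 1e-12)
  expect_equal(m$r2, 0.75, tolerance = 1e-12)

  expect_error(fit_mismatch_model(pts(c(2, 2), c(1, 3))), "equal")
  expect_error(fit_mismatch_model(pts(1, 1)), "two")
})

test_that("fit_mismatch_model agrees with closed-form normal equations on random sets", {
  withr::local_seed(33)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    x <- runif(n, 0, 0.2)
    y <- 150 * x + rnorm(n)
    m <- fit_mismatch_model(pts(x, y))
    o <- oracle_ols(x, y)
    expect_equal(m$slope, o$slope, tolerance = 1e-10)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(m$r2, o$r2, tolerance = 1e-10)
    expect_equal(m$rmse, o$rmse, tolerance = 1e-10)
  }
  # noiseless recovery at machine precision
  m <- fit_mismatch_model(pts(seq(0.01, 0.15, 0.01), 140 * seq(0.01, 0.15, 0.01) + 2))
  expect_equal(m$slope, 140, tolerance = 1e-9)
  expect_equal(m$intercept, 2, tolerance = 1e-9)
})

test_that("tidy and glance expose the broom-style views", {
  m <- fit_mismatch_model(pts(c(0.01, 0.05, 0.1), c(2, 8, 15)))
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "mutation_rate"))
  expect_equal(td$estimate, c(m$intercept, m$slope))
  gl <- glance(m)
  expect_equal(gl$r.squared, m$r2)
  expect_equal(gl$nobs, 3L)
})

test_that("predict_mismatch applies the line, clamps and flags extrapolation", {
  m <- fit_mismatch_model(pts(c(0, 1), c(1, 3)))  # y = 2x + 1
  expect_equal(predict_mismatch(m, 0)$predicted_mismatch_rate, 1)
  expect_equal(predict_mismatch(m, 0.5, read_length = 100)$predicted_N, 2L)

  down <- fit_mismatch_model(pts(c(0, 1), c(0.25, -0.75)))  # y = -x + 0.25
  expect_equal(predict_mismatch(down, 0.75)$predicted_mismatch_rate, 0)  # clamped

  expect_warning(predict_mismatch(m, 2), "extrapolation")
  expect_error(predict_mismatch(m, -0.1), "non-negative")
})

test_that("holdout_rmse measures out-of-sample error", {
  train <- pts(c(0, 1, 2), c(1, 3, 5))
  expect_equal(holdout_rmse(train, pts(c(0.5, 1.5), c(2, 4))), 0)
  expect_equal(holdout_rmse(train, pts(1, 6)), 3)  # prediction 3, observation 6
  expect_error(holdout_rmse(train, pts(numeric(), numeric())), "test")
})

test_that("model JSON round trip reproduces the fit from its points", {
  m <- fit_mismatch_model(pts(c(0.01, 0.05, 0.09, 0.13), c(3, 9, 14, 22)))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$slope, m$slope, tolerance = 1e-12)
  expect_equal(back$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(back$r2, m$r2, tolerance = 1e-12)
})

test_that("decide_strategy follows the decision flow", {
  model <- fit_mismatch_model(pts(c(0, 0.2), c(0, 20)))  # rate = 100 * d
  expect_equal(decide_strategy(ref_available = TRUE)$strategy, "REFERENCE_BASED")

  pra <- decide_strategy(distances = c(ortholog = 0.045), model = model)
  expect_equal(pra$strategy, "PRA")
  expect_equal(pra$predicted_mismatch_rate, 4.5)
  expect_equal(pra$predicted_N, 4L)

  dn <- decide_strategy(distances = c(ortholog = 0.15), model = model)
  expect_equal(dn$strategy, "DE_NOVO")
  expect_true(is.na(dn$predicted_mismatch_rate))

  # marker preference order: ortholog beats 16s beats dloop
  d <- decide_strategy(distances = c(dloop = 0.3, ortholog = 0.05, `16s` = 0.15),
                       model = model)
  expect_equal(d$marker, "ortholog")
  d <- decide_strategy(distances = c(dloop = 0.3, `16s` = 0.10), model = model)
  expect_equal(d$marker, "16s")
  expect_equal(d$strategy, "PRA")  # 0.10 <= 0.189 and 10% <= 14.44%
  expect_error(decide_strategy(), "cannot decide")
  expect_error(decide_strategy(distances = c(unknown = 0.1)), "cannot decide")
})

test_that("the predicted-rate bound can veto an in-threshold distance", {
  steep <- fit_mismatch_model(pts(c(0, 0.2), c(0, 40)))  # rate = 200 * d
  d <- decide_strategy(distances = c(ortholog = 0.09), model = steep)
  expect_equal(d$strategy, "DE_NOVO")  # 18% predicted > 14.44% bound
})

test_that("decide_strategy is monotone in distance", {
  model <- fit_mismatch_model(pts(c(0, 0.2), c(0, 20)))
  strategies <- vapply(
    seq(0.01, 0.4, by = 0.01),
    function(d) decide_strategy(distances = c(ortholog = d), model = model)$strategy,
    character(1)
  )
  first_denovo <- match("DE_NOVO", strategies)
  expect_false(is.na(first_denovo))
  expect_true(all(strategies[first_denovo:length(strategies)] == "DE_NOVO"))
})

test_that("high ambiguous-base fractions attach the outlier warning", {
  model <- fit_mismatch_model(pts(c(0, 0.2), c(0, 20)))
  noisy <- decide_strategy(distances = c(ortholog = 0.05), model = model,
                           read_ambiguous_fraction = 0.10)
  expect_match(noisy$warnings, "ambiguous", all = FALSE)
  clean <- decide_strategy(distances = c(ortholog = 0.05), model = model,
                           read_ambiguous_fraction = 0.01)
  expect_length(clean$warnings, 0)
})
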