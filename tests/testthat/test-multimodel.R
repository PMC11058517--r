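# Shared small synthetic dataset with a real effect of one composite.
make_toy_data <- function(n = 250, seed = 7, slope = 1.5) {
  set.seed(seed)
  data.frame(
    society_id = sprintf("S%03d", 1:n),
    language_family = sample(sprintf("F%02d", 1:8), n, replace = TRUE),
    temperature_harshness = rnorm(n),
    xeric_harshness = rnorm(n),
    mountain_dwelling = rnorm(n),
    ground_plan = NA,
    stringsAsFactors = FALSE
  ) -> d
  eta <- -0.3 + slope * d$temperature_harshness
  d$ground_plan <- ifelse(runif(n) < plogis(eta), "angular", "rounded")
  d
}

test_that("model enumeration is the hierarchy-respecting powerset", {
  full <- model_spec("ground_plan",
                     c("temperature_harshness", "xeric_harshness",
                       "mountain_dwelling"),
                     random_effect = "none")
  specs <- enumerate_models(full)
  expect_length(specs, 8)
  sizes <- sort(sapply(specs, function(s) length(s$predictors)))
  expect_equal(sizes, c(0, 1, 1, 1, 2, 2, 2, 3))
  keys <- sapply(specs, function(s)
    paste(sort(s$predictors), collapse = "+"))
  expect_equal(anyDuplicated(keys), 0)

  # interaction present only with both mains; random effect doubles the set
  full2 <- model_spec(
    "ground_plan",
    c("temperature_harshness", "political_complexity",
      "temp_harshness_x_political_complexity"),
    random_effect = "language_family")
  specs2 <- enumerate_models(full2)
  expect_length(specs2, (4 + 1) * 2)
  for (s in specs2) {
    if ("temp_harshness_x_political_complexity" %in% s$predictors) {
      expect_true(all(c("temperature_harshness", "political_complexity")
                      %in% s$predictors))
    }
  }
  expect_error(
    model_spec("ground_plan", "temp_harshness_x_political_complexity"),
    "hierarchy")
})

test_that("akaike weights match the closed form", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w[1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(w[2], exp(-1) / (1 + exp(-1)), tolerance = 1e-12)
  # symmetry, normalisation, order equivariance
  expect_equal(akaike_weights(rep(7, 5)), rep(0.2, 5))
  set.seed(3)
  a <- runif(10, 100, 120)
  w2 <- akaike_weights(a)
  expect_equal(sum(w2), 1, tolerance = 1e-12)
  perm <- sample(10)
  expect_equal(akaike_weights(a[perm]), w2[perm], tolerance = 1e-14)
  expect_error(akaike_weights(numeric(0)), "empty")
  expect_error(akaike_weights(c(1, Inf)), "non-finite")
})

test_that("candidates share one complete-case dataset and flag failures", {
  d <- make_toy_data()
  d$temperature_harshness[1:10] <- NA
  full <- model_spec("ground_plan",
                     c("temperature_harshness", "xeric_harshness"),
                     random_effect = "none")
  cand <- fit_candidates(enumerate_models(full), d)
  expect_equal(cand$n, 240)
  ns <- sapply(cand$fits, `[[`, "n")
  expect_true(all(ns == 240))
  expect_length(cand$fits, 4)
  expect_true(all(cand$converged))

  # a constant predictor makes its models non-converged, others unaffected
  d2 <- make_toy_data()
  d2$xeric_harshness <- 0
  cand2 <- fit_candidates(enumerate_models(full), d2)
  has_xeric <- sapply(cand2$specs, function(s)
    "xeric_harshness" %in% s$predictors)
  expect_true(all(!cand2$converged[has_xeric]))
  expect_true(all(cand2$converged[!has_xeric]))
})

test_that("averaging is exact on degenerate and hand-computed sets", {
  d <- make_toy_data()
  # single model: the average equals it exactly
  one <- fit_candidates(list(model_spec("ground_plan",
                                        "temperature_harshness",
                                        random_effect = "none")), d)
  avg1 <- average_model(one)
  f1 <- one$fits[[1]]
  expect_equal(avg1$weights, 1)
  expect_equal(avg1$avg_coef[, f1$terms], f1$coef[1, ],
               tolerance = 1e-12)
  expect_equal(avg1$uncond_se[, f1$terms], f1$se[1, ], tolerance = 1e-12)
  expect_equal(avg1$avg_prob, f1$fitted_prob, tolerance = 1e-12)

  # hand-built three-model set: spreadsheet-style weighted sums
  full <- model_spec("ground_plan",
                     c("temperature_harshness", "xeric_harshness"),
                     random_effect = "none")
  cand <- fit_candidates(enumerate_models(full), d)
  avg <- average_model(cand)
  fits <- cand$fits[cand$converged]
  w <- akaike_weights(sapply(fits, `[[`, "aicc"))
  term <- "temperature_harshness"
  beta_i <- sapply(fits, function(f)
    if (term %in% f$terms) f$coef[1, term] else 0)
  se_i <- sapply(fits, function(f)
    if (term %in% f$terms) f$se[1, term] else 0)
  bbar <- sum(w * beta_i)
  use <- sqrt(sum(w * (se_i^2 + (beta_i - bbar)^2)))
  expect_equal(unname(avg$avg_coef[1, term]), bbar, tolerance = 1e-10)
  expect_equal(unname(avg$uncond_se[1, term]), use, tolerance = 1e-10)

  # identical coefficients across models: spread term vanishes
  b <- c(1.2, 1.2); se <- c(0.3, 0.4); wts <- c(0.6, 0.4)
  spread_se <- sqrt(sum(wts * (se^2 + (b - sum(wts * b))^2)))
  expect_equal(spread_se, sqrt(sum(wts * se^2)))
})

test_that("averaging is invariant to candidate order", {
  d <- make_toy_data(n = 180)
  full <- model_spec("ground_plan",
                     c("temperature_harshness", "xeric_harshness"),
                     random_effect = "none")
  specs <- enumerate_models(full)
  a1 <- average_model(fit_candidates(specs, d))
  a2 <- average_model(fit_candidates(rev(specs), d))
  expect_equal(a2$avg_coef[, colnames(a1$avg_coef), drop = FALSE],
               a1$avg_coef, tolerance = 1e-10)
  expect_equal(sort(a2$importance), sort(a1$importance),
               tolerance = 1e-10)
  expect_equal(a2$accuracy, a1$accuracy)
})

test_that("relative importance sums the weights of containing models", {
  s1 <- model_spec("ground_plan", character(), random_effect = "none")
  s2 <- model_spec("ground_plan", "temperature_harshness",
                   random_effect = "none")
  imp <- relative_importance(list(s1, s2), c(0.5, 0.5))
  expect_equal(unname(imp["temperature_harshness"]), 0.5)
  s3 <- model_spec("ground_plan", "temperature_harshness",
                   random_effect = "language_family")
  imp2 <- relative_importance(list(s2, s3), c(0.3, 0.7))
  expect_equal(unname(imp2["temperature_harshness"]), 1)  # in every model
  expect_equal(unname(imp2["language_family"]), 0.7)
  imp3 <- relative_importance(list(s1, s1), c(0.4, 0.6))
  expect_length(imp3, 0)                                  # in no model
})

test_that("importance separates true from decoy predictors", {
  d <- make_toy_data(n = 300, seed = 11, slope = 1.2)
  full <- model_spec("ground_plan",
                     c("temperature_harshness", "xeric_harshness"),
                     random_effect = "none")
  avg <- average_model(fit_candidates(enumerate_models(full), d))
  expect_gt(avg$importance["temperature_harshness"],
            avg$importance["xeric_harshness"])
  expect_gt(avg$importance["temperature_harshness"], 0.9)
})

test_that("effect profiles are coherent probability curves", {
  d <- make_toy_data(n = 400, seed = 13, slope = 1.5)
  full <- model_spec("ground_plan", "temperature_harshness",
                     random_effect = "none")
  avg <- average_model(fit_candidates(enumerate_models(full), d))
  prof <- effect_profile(avg, "temperature_harshness",
                         grid = seq(-2, 2, length.out = 21))
  p <- as.matrix(prof[, c("rounded", "angular")])
  expect_equal(rowSums(p), rep(1, 21), tolerance = 1e-10)
  # single positive slope: angular probability strictly increasing
  expect_true(all(diff(prof$angular) > 0))
  expect_error(effect_profile(avg, "mountain_dwelling"), "unknown")
})

test_that("profiles stratified by complexity expose the interaction", {
  set.seed(17)
  n <- 600
  d <- data.frame(
    society_id = sprintf("S%03d", 1:n),
    language_family = "F01",
    temperature_harshness = rnorm(n),
    political_complexity = sample(c(1, 5), n, replace = TRUE)
  )
  # slope of harshness flips sign with complexity by construction
  eta <- 0.8 * d$temperature_harshness *
    ifelse(d$political_complexity == 5, 1, -1)
  d$ground_plan <- ifelse(runif(n) < plogis(eta), "angular", "rounded")
  full <- model_spec(
    "ground_plan",
    c("temperature_harshness", "political_complexity",
      "temp_harshness_x_political_complexity"),
    random_effect = "none")
  avg <- average_model(fit_candidates(enumerate_models(full), d))
  prof <- effect_profile(avg, "temperature_harshness",
                         grid = c(-1.5, 1.5), by_complexity = c(1, 5))
  slope_at <- function(pc) {
    sub <- prof[prof$political_complexity == pc, ]
    diff(sub$angular)
  }
  expect_lt(slope_at(1), 0)
  expect_gt(slope_at(5), 0)
})

test_that("cross-tab percentages match hand tallies", {
  a <- c("mono", "poly", "poly", "mono", "poly", "mono", NA)
  b <- c("round", "round", "angular", "angular", "round", NA, "round")
  ct <- crosstab_percent(a, b)
  expect_equal(rowSums(ct$percent), c(mono = 100, poly = 100),
               tolerance = 1e-9)
  expect_equal(unname(ct$counts["poly", "round"]), 2)
  expect_equal(unname(ct$percent["poly", "round"]), 200 / 3)
  expect_equal(unname(ct$percent["mono", "angular"]), 50)
  # a category absent in b is retained as a zero cell
  ct2 <- crosstab_percent(c("x", "x", "y"), c("u", "u", "u"))
  expect_equal(unname(ct2$percent["y", "u"]), 100)
  expect_error(crosstab_percent(c(NA, NA), c("a", "b")), "no complete")
})
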