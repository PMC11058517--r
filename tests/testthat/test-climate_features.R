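test_that("discretisation is a deterministic per-cell tally", {
  # every January exactly 5 degrees -> one January cell holds all years
  m <- matrix(rnorm(120, 15, 8), 10, 12)
  m[, 1] <- 5
  sm <- discretize_series(m, n_states = 6)
  expect_s3_class(sm, "state_matrix")
  expect_equal(sum(sm[1, ] > 0), 1)
  expect_equal(max(sm[1, ]), 10)

  # conservation: every row sums to n_years
  expect_true(all(rowSums(sm) == 10))

  # sinusoidal series vs independent per-cell counting oracle
  yrs <- 8
  sine <- outer(rep(1, yrs), sin(2 * pi * (1:12) / 12) * 10) +
    matrix(rnorm(yrs * 12, 0, 2), yrs, 12)
  sm4 <- discretize_series(sine, n_states = 4)
  breaks <- seq(min(sine), max(sine), length.out = 5)
  expect_equal(unclass(sm4)[, ], oracle_state_matrix(sine, breaks),
               ignore_attr = TRUE)
})

test_that("discretisation validates its inputs", {
  m <- matrix(rnorm(24), 2, 12)
  expect_error(discretize_series(m, n_states = 1), "n_states")
  expect_error(discretize_series(m[1, , drop = FALSE], 4), "2 years")
  m[1, 1] <- NA
  expect_error(discretize_series(m, 4), "missing")
  # constant series is valid: single occupied state
  cm <- discretize_series(matrix(20, 5, 12), 4)
  expect_true(all(cm[, 1] == 5) && all(cm[, -1] == 0))
})

test_that("colwell hits its analytic bounds", {
  # uniform table: H(XY) = H(X) + log s so P = C = M = 0
  uni <- colwell(matrix(10L, 12, 4))
  expect_equal(uni$P, 0, tolerance = 1e-12)
  expect_equal(uni$C, 0, tolerance = 1e-12)
  expect_equal(uni$M, 0, tolerance = 1e-12)

  # strict periodicity: each month always in a fixed state -> P = 1
  per <- matrix(0L, 12, 3)
  per[cbind(1:12, rep(1:3, 4))] <- 10L
  res <- colwell(per)
  expect_equal(res$P, 1, tolerance = 1e-12)
  expect_equal(res$C + res$M, 1, tolerance = 1e-12)
})

test_that("colwell matches the direct entropy evaluation on examples", {
  sm <- matrix(c(10, 5, 0, 5), 2, 2)   # rows [[10,0],[5,5]]
  got <- colwell(sm)
  want <- oracle_colwell(sm)
  expect_equal(got$P, want$P, tolerance = 1e-12)
  expect_equal(got$C, want$C, tolerance = 1e-12)
  expect_equal(got$M, want$M, tolerance = 1e-12)
  expect_error(colwell(matrix(1, 12, 1)), "degenerate")
  expect_error(colwell(matrix(0, 12, 4)), "positive")
})

test_that("colwell properties hold on random matrices", {
  set.seed(101)
  for (i in 1:200) {
    sm <- random_state_matrix(t = sample(2:12, 1), s = sample(2:6, 1))
    if (sum(sm) == 0) sm[1, 1] <- 1
    got <- colwell(sm)
    want <- oracle_colwell(sm)
    expect_equal(got$P, want$P, tolerance = 1e-10)
    expect_equal(got$C, want$C, tolerance = 1e-10)
    expect_equal(got$M, want$M, tolerance = 1e-10)
    # P = C + M; label-permutation and count-scaling invariance
    expect_equal(got$P, got$C + got$M, tolerance = 1e-9)
    expect_equal(colwell(sm[, sample(ncol(sm))])$P, got$P,
                 tolerance = 1e-10)
    expect_equal(colwell(sm * 7L)$P, got$P, tolerance = 1e-10)
    expect_true(all(unlist(got) >= 0 & unlist(got) <= 1 + 1e-12))
  }
})

test_that("colwell P ordering is robust to the state count", {
  set.seed(77)
  p8 <- p12 <- numeric(30)
  for (i in 1:30) {
    noise <- runif(1, 0, 6)
    m <- outer(rep(1, 6), sin(2 * pi * (1:12) / 12) * 8) +
      matrix(rnorm(72, 0, noise), 6, 12)
    p8[i] <- colwell(discretize_series(m, 8))$P
    p12[i] <- colwell(discretize_series(m, 12))$P
  }
  expect_gt(cor(p8, p12, method = "spearman"), 0.9)
})

test_that("climate summaries agree with direct moments and Colwell cases", {
  df <- data.frame(society_id = c("A", "B"), lon = c(0, 10),
                   lat = c(0, 10), language_family = "F",
                   elevation_m = c(100, 200), slope_deg = c(1, 2))
  set.seed(5)
  temp_b <- matrix(rnorm(60, 12, 6), 5, 12)
  precip_b <- matrix(rexp(60, 1 / 80), 5, 12)
  tbl <- structure(list(
    societies = df,
    climate = list(
      A = list(temp = matrix(20, 5, 12),
               precip = matrix(rep(1:12 * 10, each = 5), 5, 12)),
      B = list(temp = temp_b, precip = precip_b)
    )
  ), class = "society_table")
  s <- summarize_climate(tbl, n_states = 5)
  # constant series: mean 20, zero variance, full constancy
  expect_equal(s$temp_mean[1], 20)
  expect_equal(s$temp_var[1], 0)
  expect_equal(s$temp_C[1], 1)
  expect_equal(s$temp_P[1], 1)
  # exact repeating seasonal cycle: P = 1
  expect_equal(s$precip_P[1], 1)
  # stochastic series: moments equal a direct two-pass computation
  expect_equal(s$temp_mean[2], mean(temp_b), tolerance = 1e-12)
  expect_equal(s$temp_var[2], var(as.vector(temp_b)), tolerance = 1e-12)
  expect_equal(s$precip_mean[2], mean(precip_b), tolerance = 1e-12)
  expect_equal(s$elevation_m, df$elevation_m)
})

test_that("repeating annual patterns are fully predictable under any scheme", {
  base <- abs(sin(2 * pi * (1:12) / 12)) * 50 + 5
  m <- matrix(rep(base, 7), 7, 12, byrow = TRUE)
  for (ns in c(2, 5, 10)) {
    for (sch in c("equal_width", "log_equal_width")) {
      expect_equal(colwell(discretize_series(m, ns, sch))$P, 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("box-cox lambda recovery and edge handling", {
  # lambda = 1: transform is x - 1, shape preserved
  x <- c(2, 4, 9, 1.5, 3)
  y1 <- (x^1 - 1) / 1
  expect_equal(y1, x - 1)

  # log-normal data: lambda near 0
  set.seed(11)
  xl <- exp(rnorm(5000, 1, 0.6))
  bc <- box_cox_normalize(xl)
  expect_lt(abs(bc$lambda), 0.15)
  expect_equal(bc$shift, 0)

  # shift policy and errors
  expect_error(box_cox_normalize(c(0, 1, 2), shift = FALSE),
               "non-positive")
  sh <- box_cox_normalize(c(0, 1, 2))
  expect_equal(sh$shift, 1)
  expect_error(box_cox_normalize(rep(3, 10)), "no variance")
})

test_that("box-cox profile likelihood matches the MASS oracle", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- rgamma(400, shape = 2, rate = 0.5)
  bc <- box_cox_normalize(x)
  prof <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  lam_mass <- prof$x[which.max(prof$y)]
  expect_equal(bc$lambda, lam_mass, tolerance = 0.02)
})

test_that("varimax composites preserve variance and find block structure", {
  set.seed(31)
  n <- 400
  # three independent latent blocks
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  X <- data.frame(
    society_id = sprintf("S%03d", 1:n),
    temp_mean = -z1 + rnorm(n, 0, 0.3) + 10,
    temp_var = exp(z1 + rnorm(n, 0, 0.3)),
    temp_P = plogis(-z1 + rnorm(n, 0, 0.3)),
    precip_mean = exp(-z3 + rnorm(n, 0, 0.3) + 4),
    precip_var = exp(-2 * z3 + rnorm(n, 0, 0.5) + 6),
    precip_P = plogis(-z3 + rnorm(n, 0, 0.3)),
    elevation_m = exp(z2 * 0.8 + rnorm(n, 0, 0.2) + 6),
    slope_deg = exp(z2 * 0.7 + rnorm(n, 0, 0.3))
  )
  comp <- env_composites(X)
  L <- comp$loadings
  # each block loads dominantly on its own component
  expect_gt(abs(L["temp_var", "temperature_harshness"]), 0.7)
  expect_gt(abs(L["elevation_m", "mountain_dwelling"]), 0.7)
  expect_gt(abs(L["precip_var", "xeric_harshness"]), 0.7)
  # orientation: harsh = cold, mountainous = high, xeric = dry
  expect_lt(L["temp_mean", "temperature_harshness"], 0)
  expect_gt(L["elevation_m", "mountain_dwelling"], 0)
  expect_lt(L["precip_mean", "xeric_harshness"], 0)
  expect_gt(cor(comp$scores$temperature_harshness, -X$temp_mean), 0.7)
  # scores standardised
  for (cn in colnames(L)) {
    expect_lt(abs(mean(comp$scores[[cn]])), 1e-6)
    expect_equal(sd(comp$scores[[cn]]), 1, tolerance = 1e-6)
  }
  expect_error(env_composites(X, variables = c("temp_mean", "temp_var")),
               "p < k|at least k")
})

test_that("varimax rotation is orthonormal and preserves communalities", {
  set.seed(41)
  n <- 300
  Xs <- scale(matrix(rnorm(n * 6), n, 6) %*%
                matrix(runif(36, -1, 1), 6, 6))
  pc <- prcomp(Xs)
  L <- pc$rotation[, 1:3] %*% diag(pc$sdev[1:3])
  rot <- varimax(L, normalize = TRUE)
  R <- rot$rotmat
  expect_equal(crossprod(R), diag(3), tolerance = 1e-8)
  expect_equal(rowSums((L %*% R)^2), rowSums(L^2), tolerance = 1e-8)
})
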