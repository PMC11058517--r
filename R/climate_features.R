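# Climate summaries: within-year predictability (Colwell's P = C + M),
# moments, Box-Cox normalisation and varimax-rotated environmental composites.

#' Discretise a monthly series into a time-class by state frequency table
#'
#' Builds the frequency table underlying Colwell's predictability index:
#' rows are the 12 months (time classes), columns are discrete states, and
#' cell (m, k) counts the years in which month m fell in state k.
#'
#' @param monthly A years-by-12 numeric matrix with no missing cells.
#' @param n_states Number of discrete states (>= 2).
#' @param scheme Binning scheme: `"equal_width"` (equal-width bins over the
#'   observed range) or `"log_equal_width"` (equal-width on `log1p`, for
#'   right-skewed non-negative variables such as precipitation).
#' @return A `state_matrix`: integer 12-by-`n_states` count matrix with
#'   attribute `n_years`.
#' @export
discretize_series <- function(monthly, n_states = 10,
                              scheme = c("equal_width", "log_equal_width")) {
  scheme <- match.arg(scheme)
  monthly <- as.matrix(monthly)
  if (ncol(monthly) != 12) stop("monthly matrix must have 12 columns")
  if (nrow(monthly) < 2) stop("need at least 2 years")
  if (anyNA(monthly)) stop("missing cells; impute or drop years upstream")
  if (n_states < 2) stop("n_states must be >= 2")
  x <- monthly
  if (scheme == "log_equal_width") {
    if (any(x < 0)) stop("log_equal_width requires non-negative values")
    x <- log1p(x)
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    # constant series: everything in the first state
    state <- matrix(1L, nrow(x), ncol(x))
  } else {
    width <- (rng[2] - rng[1]) / n_states
    state <- pmin(floor((x - rng[1]) / width) + 1L, n_states)
    state <- matrix(as.integer(state), nrow(x), ncol(x))
  }
  counts <- matrix(0L, nrow = 12, ncol = n_states)
  for (m in 1:12) {
    tab <- tabulate(state[, m], nbins = n_states)
    counts[m, ] <- as.integer(tab)
  }
  structure(counts, n_years = nrow(monthly), class = "state_matrix")
}

#' Colwell's predictability, constancy and contingency
#'
#' Information-theoretic decomposition of a time-class by state frequency
#' table with row totals X, column totals Y and grand total N:
#' \deqn{H(X) = -\sum_m (X_m/N)\log(X_m/N)}
#' and likewise H(Y) over states and H(XY) over cells. Then, with s states,
#' constancy \eqn{C = 1 - H(Y)/\log s}, contingency
#' \eqn{M = (H(X) + H(Y) - H(XY))/\log s} and predictability
#' \eqn{P = C + M = 1 - (H(XY) - H(X))/\log s}. P ranges from 0 (completely
#' unpredictable) to 1 (fully predictable); the convention 0 log 0 = 0
#' applies throughout.
#'
#' @param sm A non-negative count matrix (time classes by states), e.g. from
#'   [discretize_series()]. A single occupied column is fine; a single state
#'   *column* (s = 1) is a degenerate state space and errors.
#' @return List with components `P`, `C`, `M`, each in \[0, 1\].
#' @export
colwell <- function(sm) {
  sm <- unclass(as.matrix(sm))
  if (any(sm < 0)) stop("negative counts")
  s <- ncol(sm)
  if (s < 2) stop("degenerate state space (s = 1)")
  N <- sum(sm)
  if (N <= 0) stop("grand total must be positive")
  plogp <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hx <- plogp(rowSums(sm) / N)
  hy <- plogp(colSums(sm) / N)
  hxy <- plogp(sm / N)
  C <- 1 - hy / log(s)
  M <- (hx + hy - hxy) / log(s)
  P <- 1 - (hxy - hx) / log(s)
  clip <- function(v) {
    if (v < 0 && v > -1e-12) 0 else v
  }
  list(P = clip(P), C = clip(C), M = clip(M))
}

#' Per-society climate summary
#'
#' Computes, for each society with monthly series, the mean and variance of
#' temperature and precipitation over all year-month cells, plus Colwell's
#' P, C and M per variable (temperature binned equal-width, precipitation
#' equal-width on log1p by default), and carries elevation and slope through.
#'
#' @param tbl A `society_table` with monthly climate attached.
#' @param n_states Number of Colwell states (default 10).
#' @param temp_scheme,precip_scheme Binning schemes passed to
#'   [discretize_series()].
#' @return Data frame, one row per society: `society_id`, `temp_mean`,
#'   `temp_var`, `temp_P`, `temp_C`, `temp_M`, `precip_mean`, `precip_var`,
#'   `precip_P`, `precip_C`, `precip_M`, `elevation_m`, `slope_deg`.
#'   Societies without climate series get `NA` summaries (and are dropped
#'   later from any model needing composites).
#' @export
summarize_climate <- function(tbl, n_states = 10,
                              temp_scheme = "equal_width",
                              precip_scheme = "log_equal_width") {
  stopifnot(inherits(tbl, "society_table"))
  df <- tbl$societies
  one <- function(id) {
    cm <- tbl$climate[[id]]
    row <- data.frame(
      society_id = id, temp_mean = NA_real_, temp_var = NA_real_,
      temp_P = NA_real_, temp_C = NA_real_, temp_M = NA_real_,
      precip_mean = NA_real_, precip_var = NA_real_,
      precip_P = NA_real_, precip_C = NA_real_, precip_M = NA_real_,
      stringsAsFactors = FALSE
    )
    if (is.null(cm) || anyNA(cm$temp) || anyNA(cm$precip)) return(row)
    row$temp_mean <- mean(cm$temp)
    row$temp_var <- stats::var(as.vector(cm$temp))
    row$precip_mean <- mean(cm$precip)
    row$precip_var <- stats::var(as.vector(cm$precip))
    ct <- colwell(discretize_series(cm$temp, n_states, temp_scheme))
    cp <- colwell(discretize_series(cm$precip, n_states, precip_scheme))
    row[c("temp_P", "temp_C", "temp_M")] <- ct[c("P", "C", "M")]
    row[c("precip_P", "precip_C", "precip_M")] <- cp[c("P", "C", "M")]
    row
  }
  out <- do.call(rbind, lapply(df$society_id, one))
  out$elevation_m <- df$elevation_m
  out$slope_deg <- df$slope_deg
  rownames(out) <- NULL
  out
}

#' Box-Cox normalisation with profile-likelihood lambda
#'
#' Finds the power-transform exponent maximising the Box-Cox profile
#' log-likelihood on a grid over \[-5, 5\] followed by local refinement, and
#' returns the transformed vector \eqn{y = (x^\lambda - 1)/\lambda} (or
#' \eqn{\log x} at \eqn{\lambda = 0}).
#'
#' @param x Numeric vector. Must be strictly positive after the shift.
#' @param shift If `TRUE` (default) and `min(x) <= 0`, add `1 - min(x)`
#'   before transforming; the shift used is recorded in the result.
#' @return List with `y` (transformed values), `lambda`, and `shift`.
#' @export
box_cox_normalize <- function(x, shift = TRUE) {
  if (anyNA(x)) stop("missing values not allowed")
  if (stats::var(x) == 0) stop("no variance")
  sh <- 0
  if (min(x) <= 0) {
    if (!shift) stop("non-positive values with shift disabled")
    sh <- 1 - min(x)
  }
  xs <- x + sh
  n <- length(xs)
  slx <- sum(log(xs))
  profile_ll <- function(lam) {
    y <- if (abs(lam) < 1e-8) log(xs) else (xs^lam - 1) / lam
    v <- stats::var(y) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * slx
  }
  grid <- seq(-5, 5, by = 0.1)
  ll <- vapply(grid, profile_ll, numeric(1))
  best <- grid[which.max(ll)]
  opt <- stats::optimize(profile_ll, lower = max(-5, best - 0.2),
                         upper = min(5, best + 0.2), maximum = TRUE,
                         tol = 1e-6)
  lam <- opt$maximum
  y <- if (abs(lam) < 1e-8) log(xs) else (xs^lam - 1) / lam
  list(y = y, lambda = lam, shift = sh)
}

# Default PCA input variables (quantities computed by summarize_climate).
.default_pca_variables <- c(
  "temp_mean", "temp_var", "temp_P",
  "precip_mean", "precip_var", "precip_P",
  "elevation_m", "slope_deg"
)

#' Varimax-rotated environmental composites
#'
#' Box-Cox-normalises, centres and scales each environmental variable, takes
#' the top-k principal axes, applies a normalised varimax rotation, and
#' re-standardises the rotated scores. The three components are identified
#' and oriented by their loadings: "temperature harshness" (largest absolute
#' loading on temperature variables, oriented so the mean-temperature loading
#' is negative — harsh sites are cold, variable and unpredictable), "mountain
#' dwelling" (largest on elevation/slope, oriented positive on elevation) and
#' "xeric harshness" (the remainder, oriented so the precipitation-mean
#' loading is negative — xeric sites are dry with unpredictable rain).
#'
#' @param env Data frame of environmental variables (e.g. from
#'   [summarize_climate()]); rows with any missing value among `variables`
#'   are dropped (ids retained in the result).
#' @param variables Character vector of columns to use (default: temperature
#'   mean/variance/P, precipitation mean/variance/P, elevation, slope).
#' @param k Number of components (default 3).
#' @return An `env_composite` object: list with `scores` (data.frame:
#'   `society_id`, `temperature_harshness`, `mountain_dwelling`,
#'   `xeric_harshness`), `loadings` (p-by-k), `variance_explained`,
#'   `boxcox_lambdas`, `dropped` (ids without complete data).
#' @export
env_composites <- function(env, variables = .default_pca_variables, k = 3) {
  if (length(variables) < k) stop("need at least k variables (p < k)")
  miss <- setdiff(variables, names(env))
  if (length(miss)) stop("variable not found: ", miss[[1]])
  ids <- if ("society_id" %in% names(env)) env$society_id
         else as.character(seq_len(nrow(env)))
  X <- as.matrix(env[, variables, drop = FALSE])
  keep <- stats::complete.cases(X)
  Xc <- X[keep, , drop = FALSE]
  if (nrow(Xc) <= length(variables)) stop("too few complete rows for PCA")
  lambdas <- numeric(length(variables))
  names(lambdas) <- variables
  for (j in seq_along(variables)) {
    bc <- box_cox_normalize(Xc[, j])
    Xc[, j] <- bc$y
    lambdas[j] <- bc$lambda
  }
  Xs <- scale(Xc)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  L <- pc$rotation[, 1:k, drop = FALSE] %*%
    diag(pc$sdev[1:k], k, k)                       # loadings = corr scale
  rot <- stats::varimax(L, normalize = TRUE)
  Lr <- L %*% rot$rotmat
  # deterministic sign convention before orientation
  for (j in 1:k) if (Lr[which.max(abs(Lr[, j])), j] < 0) Lr[, j] <- -Lr[, j]
  ident <- .identify_components(Lr, variables)
  Lr <- Lr[, ident$order, drop = FALSE] %*% diag(ident$sign, k, k)
  colnames(Lr) <- ident$names
  # scores: project standardised data on the rotated axes, re-standardise
  raw_scores <- Xs %*% Lr
  sc <- scale(raw_scores)
  scores <- data.frame(society_id = ids[keep], sc, stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(
    scores = scores,
    loadings = Lr,
    variance_explained = colSums(Lr^2) / length(variables),
    boxcox_lambdas = lambdas,
    dropped = ids[!keep]
  ), class = "env_composite")
}

# Assign rotated components to the named composites and fix orientation.
.identify_components <- function(L, variables) {
  k <- ncol(L)
  temp_vars <- grep("^temp", variables)
  terr_vars <- which(variables %in% c("elevation_m", "slope_deg"))
  precip_vars <- grep("^precip", variables)
  strength <- function(rows) apply(abs(L[rows, , drop = FALSE]), 2, max)
  ord <- integer(k)
  avail <- 1:k
  pick <- function(rows) {
    st <- strength(rows)
    st[-avail] <- -Inf
    which.max(st)
  }
  temp_c <- pick(temp_vars); avail <- setdiff(avail, temp_c)
  terr_c <- pick(terr_vars); avail <- setdiff(avail, terr_c)
  xeric_c <- avail[1]
  ord <- c(temp_c, terr_c, xeric_c)
  sgn <- c(
    if (L[variables == "temp_mean", temp_c] > 0) -1 else 1,
    if (L[variables == "elevation_m", terr_c] < 0) -1 else 1,
    if (length(precip_vars) &&
        L[variables == "precip_mean", xeric_c] > 0) -1 else 1
  )
  list(order = ord, sign = sgn,
       names = c("temperature_harshness", "mountain_dwelling",
                 "xeric_harshness"))
}

#' @export
print.env_composite <- function(x, ...) {
  cat("env_composite:", nrow(x$scores), "societies,",
      ncol(x$loadings), "varimax components\n")
  cat("variance explained:",
      paste(sprintf("%.2f", x$variance_explained), collapse = ", "), "\n")
  print(round(x$loadings, 2))
  invisible(x)
}
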