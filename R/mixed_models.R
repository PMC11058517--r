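# Binary / multinomial logistic regression with optional language-family
# random intercepts. Baseline-category logit, fitted by Newton-Raphson; the
# mixed model adds one Normal(0, sigma_j^2) intercept per non-reference
# category and group, independent across categories (diagonal covariance),
# estimated by joint penalised Newton over (beta, u) inside a Laplace
# approximation to the marginal likelihood maximised over log sigma.

.sep_threshold <- 15   # |coef| beyond this flags (quasi-)separation

# Softmax probabilities for baseline-category logit.
# eta: n x (J-1) linear predictors for non-reference categories.
# Returns n x J with the reference category FIRST.
.bcl_prob <- function(eta) {
  ex <- exp(cbind(0, eta))
  ex / rowSums(ex)
}

# Multinomial log-likelihood given n x J probabilities and integer category
# index (1 = reference).
.bcl_loglik <- function(prob, yi) {
  sum(log(pmax(prob[cbind(seq_along(yi), yi)], 1e-300)))
}

# Score and negative Hessian of the baseline-category log-likelihood in the
# stacked parameterisation theta = c(vec of coef columns per category) for
# design C (n x p). Y is n x (J-1) indicators for non-reference categories,
# P is n x (J-1) fitted probabilities of those categories.
.bcl_score_hess <- function(C, Y, P) {
  p <- ncol(C)
  Jm1 <- ncol(Y)
  score <- as.vector(crossprod(C, Y - P))
  H <- matrix(0, p * Jm1, p * Jm1)
  for (j in seq_len(Jm1)) {
    for (l in j:Jm1) {
      w <- if (j == l) P[, j] * (1 - P[, j]) else -P[, j] * P[, l]
      blk <- crossprod(C * w, C)
      rj <- (j - 1) * p + seq_len(p)
      rl <- (l - 1) * p + seq_len(p)
      H[rj, rl] <- blk
      if (l != j) H[rl, rj] <- t(blk)
    }
  }
  list(score = score, hess = H)
}

#' Fit a fixed-effects multinomial (baseline-category) logistic regression
#'
#' Maximum-likelihood baseline-category logit fitted by Newton-Raphson with
#' step halving. A binary response is the J = 2 special case. Convergence is
#' declared when the maximum absolute score falls below 1e-6 (within 200
#' iterations); any coefficient exceeding 15 in absolute value during
#' fitting flags (quasi-)separation and the fit is marked non-converged but
#' retained.
#'
#' @param X Numeric design matrix (no intercept column; one is added).
#'   Column names become coefficient names.
#' @param y Response: factor or character. At least two observed categories.
#' @param ref Reference category (default: first level).
#' @return A `cmm_fit`: list with `coef` ((J-1) x q matrix, rows = non-
#'   reference categories), `se`, `re_var` (zeros here), `loglik`, `K`, `n`,
#'   `aicc`, `converged`, `fitted_prob` (n x J, columns in declared category
#'   order with the reference first), `categories`, `ref`, `terms`.
#' @export
fit_multinomial <- function(X, y, ref = NULL) {
  prep <- .prep_categorical(X, y, ref)
  C <- prep$C
  fit <- .bcl_newton(C, prep$Y)
  n <- nrow(C)
  Jm1 <- ncol(prep$Y)
  K <- Jm1 * ncol(C)
  prob <- .bcl_prob(C %*% fit$B)
  colnames(prob) <- prep$categories
  se <- .safe_se(fit$H, ncol(C), Jm1)
  .new_cmm_fit(
    coef = t(fit$B), se = se, re_var = rep(0, Jm1),
    loglik = .bcl_loglik(prob, prep$yi), K = K, n = n,
    converged = fit$converged, fitted_prob = prob,
    categories = prep$categories, ref = prep$categories[1],
    terms = colnames(C), groups = NULL
  )
}

.prep_categorical <- function(X, y, ref) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.character(y)
  if (anyNA(y) || anyNA(X)) stop("complete cases only")
  cats <- sort(unique(y))
  if (length(cats) < 2) stop("response has a single observed category")
  if (!is.null(ref)) {
    if (!ref %in% cats) stop("reference category not observed")
    cats <- c(ref, setdiff(cats, ref))
  }
  C <- cbind(`(Intercept)` = 1, X)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("design matrix is rank deficient (collinear)")
  yi <- match(y, cats)
  Y <- matrix(0, nrow(C), length(cats) - 1)
  for (j in 2:length(cats)) Y[, j - 1] <- as.numeric(yi == j)
  colnames(Y) <- cats[-1]
  list(C = C, Y = Y, yi = yi, categories = cats)
}

.bcl_newton <- function(C, Y, penalty = NULL, B0 = NULL,
                        tol = 1e-6, max_iter = 200) {
  p <- ncol(C)
  Jm1 <- ncol(Y)
  B <- if (is.null(B0)) matrix(0, p, Jm1) else B0
  pen_d <- if (is.null(penalty)) rep(0, p * Jm1) else penalty
  obj <- function(B) {
    prob <- .bcl_prob(C %*% B)
    ll <- sum(Y * log(pmax(prob[, -1, drop = FALSE], 1e-300))) +
      sum((1 - rowSums(Y)) * log(pmax(prob[, 1], 1e-300)))
    ll - sum(pen_d * as.vector(B)^2) / 2
  }
  converged <- FALSE
  separated <- FALSE
  f <- obj(B)
  for (it in seq_len(max_iter)) {
    P <- .bcl_prob(C %*% B)[, -1, drop = FALSE]
    sh <- .bcl_score_hess(C, Y, P)
    g <- sh$score - pen_d * as.vector(B)
    H <- sh$hess + diag(pen_d, length(pen_d))
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    # step halving on the (penalised) log-likelihood
    alpha <- 1
    repeat {
      Bn <- B + matrix(alpha * step, p, Jm1)
      fn <- obj(Bn)
      if (is.finite(fn) && fn >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { Bn <- B; fn <- f; break }
    }
    B <- Bn; f <- fn
    if (max(abs(B)) > .sep_threshold) separated <- TRUE
  }
  P <- .bcl_prob(C %*% B)[, -1, drop = FALSE]
  sh <- .bcl_score_hess(C, Y, P)
  H <- sh$hess + diag(pen_d, length(pen_d))
  list(B = B, H = H, converged = converged && !separated,
       separated = separated)
}

.safe_se <- function(H, p, Jm1) {
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(matrix(NA_real_, Jm1, p))
  d <- diag(V)
  d[d < 0] <- NA_real_
  matrix(sqrt(d), nrow = Jm1, ncol = p, byrow = TRUE)
}

.new_cmm_fit <- function(coef, se, re_var, loglik, K, n, converged,
                         fitted_prob, categories, ref, terms, groups,
                         re_intercepts = NULL) {
  rownames(coef) <- categories[-1]
  colnames(coef) <- terms
  dimnames(se) <- dimnames(coef)
  aicc_val <- if (n > K + 1) aicc(loglik, K, n) else NA_real_
  structure(list(
    coef = coef, se = se, re_var = re_var, loglik = loglik, K = K, n = n,
    aicc = aicc_val, converged = converged, fitted_prob = fitted_prob,
    categories = categories, ref = ref, terms = terms, groups = groups,
    re_intercepts = re_intercepts
  ), class = "cmm_fit")
}

#' @export
print.cmm_fit <- function(x, ...) {
  J <- length(x$categories)
  kind <- if (is.null(x$groups)) "fixed-effects" else "mixed"
  cat(sprintf("%s %s logit: %d categories (ref = %s), n = %d\n",
              kind, if (J == 2) "binary" else "multinomial",
              J, x$ref, x$n))
  cat(sprintf("  logLik = %.3f, K = %d, AICc = %.3f, converged = %s\n",
              x$loglik, x$K, x$aicc, x$converged))
  if (!is.null(x$groups))
    cat("  random-intercept variance(s):",
        paste(sprintf("%.3f", x$re_var), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a mixed multinomial logit with group random intercepts
#'
#' Baseline-category logit with, for each non-reference category j, a group
#' (language family) random intercept u_gj ~ Normal(0, sigma_j^2),
#' independent across categories and groups. For fixed variances, (beta, u)
#' are maximised jointly by penalised Newton; the variances maximise the
#' Laplace approximation to the marginal log-likelihood
#' \deqn{\ell(y | \hat\beta, \hat u) - \tfrac12 \hat u' D^{-1} \hat u
#'   - \tfrac12 \log\det(I + D^{1/2} H_{uu} D^{1/2})}
#' over log sigma. Boundary estimates (sigma near 0) are allowed and
#' flagged.
#'
#' @inheritParams fit_multinomial
#' @param groups Group labels aligned with rows of `X`. A single observed
#'   group falls back to the fixed fit (with a warning) and `re_var = 0`.
#' @param fix_sigma Optional vector of random-intercept SDs (recycled to
#'   J-1) to hold fixed instead of estimating; `0` collapses to the
#'   fixed-effects likelihood exactly.
#' @return A `cmm_fit` (see [fit_multinomial()]); `K` additionally counts
#'   one variance parameter per non-reference category, `re_var` holds the
#'   estimated variances, `groups` the group levels and `re_intercepts` the
#'   predicted (conditional-mode) random intercepts (G x (J-1)).
#' @export
fit_mixed_multinomial <- function(X, y, groups, ref = NULL,
                                  fix_sigma = NULL) {
  groups <- as.character(groups)
  if (anyNA(groups)) stop("missing group labels")
  glev <- sort(unique(groups))
  if (length(glev) < 2) {
    warning("single group; falling back to fixed-effects fit")
    fit <- fit_multinomial(X, y, ref)
    fit$groups <- glev
    return(fit)
  }
  prep <- .prep_categorical(X, y, ref)
  C <- prep$C
  Y <- prep$Y
  n <- nrow(C)
  p <- ncol(C)
  G <- length(glev)
  Jm1 <- ncol(Y)
  Z <- matrix(0, n, G)
  Z[cbind(seq_len(n), match(groups, glev))] <- 1
  CZ <- cbind(C, Z)
  u_idx <- as.vector(vapply(seq_len(Jm1), function(j)
    (j - 1) * (p + G) + p + seq_len(G), numeric(G)))

  eval_sigma <- function(log_sig, B0 = NULL) {
    sig2 <- exp(2 * log_sig)
    pen <- rep(0, (p + G) * Jm1)
    pen[u_idx] <- rep(1 / sig2, each = G)
    fit <- .bcl_newton(CZ, Y, penalty = pen, B0 = B0)
    theta <- as.vector(fit$B)
    prob <- .bcl_prob(CZ %*% fit$B)
    ll <- .bcl_loglik(prob, prep$yi)
    u <- theta[u_idx]
    quad <- sum(u^2 * rep(1 / sig2, each = G))
    # log det(I + D^{1/2} H_uu D^{1/2}); H_uu = data Hessian in u block
    Huu <- (fit$H - diag(pen, length(pen)))[u_idx, u_idx]
    Dh <- rep(sqrt(sig2), each = G)
    Mat <- diag(1, G * Jm1) + (Dh %o% Dh) * Huu
    ld <- determinant(Mat, logarithm = TRUE)$modulus[1]
    list(lmarg = ll - quad / 2 - ld / 2, fit = fit, cond_ll = ll)
  }

  if (!is.null(fix_sigma)) {
    sig <- rep_len(fix_sigma, Jm1)
    if (all(sig == 0)) {
      # exact fixed-effects likelihood, u pinned at 0
      fx <- fit_multinomial(X, y, ref)
      fx$K <- fx$K + Jm1
      fx$aicc <- if (fx$n > fx$K + 1) aicc(fx$loglik, fx$K, fx$n)
                 else NA_real_
      fx$re_var <- rep(0, Jm1)
      fx$groups <- glev
      fx$re_intercepts <- matrix(0, G, Jm1,
                                 dimnames = list(glev,
                                                 fx$categories[-1]))
      fx$boundary <- rep(TRUE, Jm1)
      return(fx)
    }
    log_par <- log(sig)
    ev <- eval_sigma(log_par)
    opt <- list(par = log_par, objective = -ev$lmarg, convergence = 0)
  } else {
    # outer optimisation over log sigma_j
    warm <- NULL
    neg <- function(ls) {
      ev <- eval_sigma(ls, B0 = warm)
      warm <<- ev$fit$B
      -ev$lmarg
    }
    start <- rep(log(0.5), Jm1)
    opt <- stats::nlminb(start, neg, lower = rep(-5, Jm1),
                         upper = rep(3, Jm1),
                         control = list(rel.tol = 1e-7, iter.max = 100))
    ev <- eval_sigma(opt$par, B0 = warm)
  }
  fit <- ev$fit
  sig2 <- exp(2 * opt$par)
  boundary <- opt$par <= -4.99
  sig2[boundary] <- 0

  K <- Jm1 * p + Jm1
  B <- fit$B
  beta <- B[seq_len(p), , drop = FALSE]
  U <- matrix(as.vector(B)[u_idx], nrow = G, ncol = Jm1,
              dimnames = list(glev, prep$categories[-1]))
  prob <- .bcl_prob(CZ %*% B)
  colnames(prob) <- prep$categories
  se_full <- .safe_se(fit$H, p + G, Jm1)
  se <- se_full[, seq_len(p), drop = FALSE]
  out <- .new_cmm_fit(
    coef = t(beta), se = se, re_var = sig2,
    loglik = -opt$objective, K = K, n = n,
    converged = fit$converged && opt$convergence %in% c(0, 1),
    fitted_prob = prob, categories = prep$categories,
    ref = prep$categories[1], terms = colnames(C), groups = glev,
    re_intercepts = U
  )
  out$boundary <- boundary
  out$conditional_loglik <- ev$cond_ll
  out
}

#' Finite-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2K + \frac{2K(K+1)}{n - K - 1}}
#'
#' @param loglik Maximised log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Number of observations (societies); must exceed K + 1.
#' @return AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop("AICc undefined (n <= K + 1)")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Predicted category probabilities from a fitted model
#'
#' Softmax over the category linear predictors. For mixed fits, groups seen
#' in fitting use their predicted intercepts; unseen (or `NULL`) groups use
#' u = 0, i.e. population-level prediction.
#'
#' @param fit A `cmm_fit`.
#' @param Xnew New design matrix with the fit's non-intercept columns.
#' @param groups Optional group labels for mixed fits.
#' @return n x J probability matrix (reference category first).
#' @export
predict_prob <- function(fit, Xnew, groups = NULL) {
  Xnew <- as.matrix(Xnew)
  want <- setdiff(fit$terms, "(Intercept)")
  if (length(want)) {
    if (is.null(colnames(Xnew)) && ncol(Xnew) == length(want))
      colnames(Xnew) <- want
    miss <- setdiff(want, colnames(Xnew))
    if (length(miss)) stop("design column missing: ", miss[[1]])
    Xnew <- Xnew[, want, drop = FALSE]
  } else {
    Xnew <- Xnew[, 0, drop = FALSE]
  }
  C <- cbind(1, Xnew)
  eta <- C %*% t(fit$coef)
  if (!is.null(fit$re_intercepts) && !is.null(groups)) {
    groups <- as.character(groups)
    hit <- match(groups, rownames(fit$re_intercepts))
    add <- fit$re_intercepts[ifelse(is.na(hit), 1L, hit), , drop = FALSE]
    add[is.na(hit), ] <- 0
    eta <- eta + add
  }
  prob <- .bcl_prob(eta)
  colnames(prob) <- fit$categories
  prob
}

#' Accuracy of categorical predictions against baselines
#'
#' Accuracy is the share of rows whose most probable category (ties going to
#' the first category in declared order) equals the observation; chance is
#' 1/J (one over the number of response categories); the modal baseline is
#' the relative abundance of the most common observed category.
#'
#' @param prob n x J probability matrix with category column names.
#' @param y Observed categories, no missing values.
#' @return List with `accuracy`, `chance`, `modal`.
#' @export
classification_metrics <- function(prob, y) {
  y <- as.character(y)
  if (anyNA(y)) stop("missing responses")
  if (nrow(prob) != length(y)) stop("prob rows not aligned with y")
  J <- ncol(prob)
  pred <- colnames(prob)[apply(prob, 1, which.max)]
  list(
    accuracy = mean(pred == y),
    chance = 1 / J,
    modal = max(table(y)) / length(y)
  )
}
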