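# Independent oracle implementations used to cross-check package code.
# These are deliberately written from the definitions, not by calling the
# functions they verify.

# Colwell's decomposition straight from the entropy definitions.
oracle_colwell <- function(counts) {
  counts <- as.matrix(unclass(counts))
  N <- sum(counts)
  s <- ncol(counts)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hx <- ent(rowSums(counts) / N)
  hy <- ent(colSums(counts) / N)
  hxy <- ent(as.vector(counts) / N)
  list(P = 1 - (hxy - hx) / log(s),
       C = 1 - hy / log(s),
       M = (hx + hy - hxy) / log(s))
}

# Per-cell tally of a discretised monthly series (brute force).
oracle_state_matrix <- function(monthly, breaks) {
  t_classes <- ncol(monthly)
  counts <- matrix(0L, t_classes, length(breaks) - 1)
  for (m in seq_len(t_classes)) {
    for (yr in seq_len(nrow(monthly))) {
      v <- monthly[yr, m]
      k <- findInterval(v, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
      counts[m, k] <- counts[m, k] + 1L
    }
  }
  counts
}

# Spherical law of cosines distance (alternative great-circle formula).
oracle_sloc_km <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  to_rad <- pi / 180
  d <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) *
    cos((lon2 - lon1) * to_rad)
  R * acos(pmin(1, pmax(-1, d)))
}

# O(n^2) brute-force k nearest neighbours with the package's tie rule.
oracle_knn <- function(df, k) {
  n <- nrow(df)
  out <- vector("list", n)
  names(out) <- df$society_id
  for (i in seq_len(n)) {
    d <- vernarch::haversine_km(df$lon[i], df$lat[i], df$lon[-i],
                                df$lat[-i])
    oth <- df$society_id[-i]
    ord <- order(d, oth)
    out[[i]] <- oth[ord[seq_len(k)]]
  }
  out
}

# Binary logistic regression by hand-rolled IRLS (no glm call).
oracle_irls_logistic <- function(X, y01, tol = 1e-10, max_iter = 100) {
  C <- cbind(1, X)
  b <- rep(0, ncol(C))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(C %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y01 - mu) / w
    bn <- solve(crossprod(C * w, C), crossprod(C * w, z))
    if (max(abs(bn - b)) < tol) {
      b <- bn
      break
    }
    b <- bn
  }
  as.vector(b)
}

# Borrowing fraction by an explicit per-society loop.
oracle_borrowing <- function(trait, nb_ids) {
  ids <- rownames(nb_ids)
  out <- setNames(rep(NA_real_, length(ids)), ids)
  for (i in seq_along(ids)) {
    f <- trait[[ids[i]]]
    if (is.na(f)) next
    nb <- trait[nb_ids[i, ]]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    out[i] <- sum(nb == f) / length(nb)
  }
  out
}

# Small random state matrix for property loops.
random_state_matrix <- function(t = 12, s = 4) {
  matrix(rpois(t * s, lambda = 3), t, s)
}

# Small society data frame scattered on the sphere.
random_society_df <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    society_id = sprintf("S%03d", seq_len(n)),
    lon = runif(n, -180, 180),
    lat = asin(runif(n, -1, 1)) * 180 / pi,
    stringsAsFactors = FALSE
  )
}
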