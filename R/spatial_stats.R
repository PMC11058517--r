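# Great-circle geometry, nearest-neighbour tables, the neighbour-borrowing
# statistic (horizontal-transmission proxy) and Moran's I correlograms.

.earth_radius_km <- 6371.0088

#' Great-circle (haversine) distance in kilometres
#'
#' Distance on a sphere of radius 6371.0088 km. Vectorised over both points.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 180), all(abs(lon2) <= 180))
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * .earth_radius_km * asin(pmin(1, sqrt(a)))
}

# Full pairwise haversine matrix (km) for a society data frame. Uses the
# haversine form (not the chord/acos shortcut) so that equal separations
# produce bit-identical distances and id tie-breaking is exact.
.pairwise_km <- function(df) {
  n <- nrow(df)
  to_rad <- pi / 180
  sdlat <- sin(outer(df$lat, df$lat, "-") * to_rad / 2)
  sdlon <- sin(outer(df$lon, df$lon, "-") * to_rad / 2)
  coslat <- cos(df$lat * to_rad)
  a <- sdlat^2 + outer(coslat, coslat) * sdlon^2
  d <- matrix(2 * .earth_radius_km * asin(pmin(1, sqrt(a))), n, n)
  diag(d) <- 0
  dimnames(d) <- list(df$society_id, df$society_id)
  d
}

#' k-nearest-neighbour table on the sphere
#'
#' For every society, the `k` nearest other societies by great-circle
#' distance. Ties are broken by society id in lexicographic order, so the
#' table is deterministic given coordinates and ids.
#'
#' @param df Data frame with `society_id`, `lon`, `lat` (all non-missing).
#' @param k Number of neighbours (default 10, the first layer of neighbours
#'   plus some of their neighbours).
#' @return A `neighbor_table`: list with `ids` (n-by-k character matrix,
#'   row names = focal ids), `dist_km` (n-by-k numeric), and `k`.
#' @export
nearest_neighbors <- function(df, k = 10) {
  n <- nrow(df)
  if (n < 2) stop("need at least 2 societies")
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k must be < n")
  if (anyNA(df$lon) || anyNA(df$lat)) stop("missing coordinates")
  d <- .pairwise_km(df)
  ids <- df$society_id
  nb_id <- matrix(NA_character_, n, k, dimnames = list(ids, NULL))
  nb_d <- matrix(NA_real_, n, k, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    di <- d[i, -i]
    oth <- ids[-i]
    ord <- order(di, oth)          # distance, then id lexicographic
    take <- ord[seq_len(k)]
    nb_id[i, ] <- oth[take]
    nb_d[i, ] <- di[take]
  }
  structure(list(ids = nb_id, dist_km = nb_d, k = k),
            class = "neighbor_table")
}

#' @export
print.neighbor_table <- function(x, ...) {
  cat("neighbor_table:", nrow(x$ids), "societies, k =", x$k, "\n")
  invisible(x)
}

#' Neighbour-borrowing fraction of a categorical trait
#'
#' For each focal society with a non-missing trait, the fraction of its
#' nearest neighbours with a non-missing trait that share the focal
#' society's category — a proxy for horizontal cultural transmission. The
#' denominator counts only neighbours with non-missing traits; a missing
#' focal trait or zero usable neighbours yields `NA`. Setting
#' `missing_as_mismatch = TRUE` instead keeps all neighbours in the
#' denominator and counts missing ones as non-matches.
#'
#' @param trait Named (by society id) or positionally aligned categorical
#'   vector.
#' @param nbrs A `neighbor_table` from [nearest_neighbors()].
#' @param missing_as_mismatch Denominator policy (default `FALSE`).
#' @return Numeric vector in \[0, 1\] (or `NA`), named by society id.
#' @export
borrowing_fraction <- function(trait, nbrs, missing_as_mismatch = FALSE) {
  stopifnot(inherits(nbrs, "neighbor_table"))
  ids <- rownames(nbrs$ids)
  if (is.null(names(trait))) {
    if (length(trait) != length(ids)) stop("trait not aligned with table")
    names(trait) <- ids
  }
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (i in seq_along(ids)) {
    focal <- trait[[ids[i]]]
    if (is.na(focal)) next
    nb <- trait[nbrs$ids[i, ]]
    if (missing_as_mismatch) {
      out[i] <- sum(!is.na(nb) & nb == focal) / length(nb)
    } else {
      usable <- !is.na(nb)
      if (!any(usable)) next
      out[i] <- sum(nb[usable] == focal) / sum(usable)
    }
  }
  out
}

#' Moran's I spatial autocorrelogram
#'
#' Moran's I of a numeric vector computed in equal-width great-circle
#' distance classes spanning (0, max pairwise distance\]. Within class c the
#' binary weight matrix has w_ij = 1 for pairs whose distance falls in the
#' class, and
#' \deqn{I_c = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with z the centred values. Under no autocorrelation E\[I\] = -1/(n-1).
#'
#' @param values Non-constant numeric vector aligned with `df` rows.
#' @param df Data frame with `lon`, `lat`.
#' @param n_classes Number of distance classes (default 12).
#' @param n_perm If > 0, permutation envelopes per class from this many
#'   random relabellings (seeded; default 0 = none).
#' @param seed Seed for the permutations.
#' @return A `moran_correlogram`: data.frame with `class`, `lower_km`,
#'   `upper_km`, `midpoint_km`, `I`, `n_pairs`, `reliable` (>= 30 pairs) and,
#'   with permutations, `lo`/`hi` (2.5/97.5 percentiles of the null); plus
#'   attributes `expected_I` and `n`.
#' @export
morans_correlogram <- function(values, df, n_classes = 12, n_perm = 0,
                               seed = 1L) {
  n <- length(values)
  if (n < 10) stop("need n >= 10")
  if (nrow(df) != n) stop("values not aligned with df")
  if (anyNA(values)) stop("missing values")
  if (stats::var(values) == 0) stop("zero variance")
  d <- .pairwise_km(df)
  maxd <- max(d)
  edges <- seq(0, maxd, length.out = n_classes + 1)
  cls <- matrix(0L, n, n)
  up <- upper.tri(d)
  cls[up] <- pmin(pmax(ceiling(d[up] / (maxd / n_classes)), 1L), n_classes)
  moran_by_class <- function(v) {
    z <- v - mean(v)
    denom <- sum(z^2)
    zz <- tcrossprod(z)
    vapply(seq_len(n_classes), function(c) {
      w <- cls == c
      s0 <- 2 * sum(w)            # symmetric pairs
      if (s0 == 0) return(NA_real_)
      (n / s0) * (2 * sum(zz[w])) / denom
    }, numeric(1))
  }
  I <- moran_by_class(values)
  n_pairs <- vapply(seq_len(n_classes), function(c) sum(cls == c), integer(1))
  out <- data.frame(
    class = seq_len(n_classes),
    lower_km = edges[-(n_classes + 1)],
    upper_km = edges[-1],
    midpoint_km = (edges[-1] + edges[-(n_classes + 1)]) / 2,
    I = I, n_pairs = n_pairs, reliable = n_pairs >= 30
  )
  if (n_perm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    perm <- replicate(n_perm, moran_by_class(sample(values)))
    out$lo <- apply(perm, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
    out$hi <- apply(perm, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
  }
  structure(out, expected_I = -1 / (n - 1), n = n,
            class = c("moran_correlogram", "data.frame"))
}

# Save/restore the RNG state so diagnostics do not disturb caller streams.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pearson residuals of the observed-category indicator
#'
#' For a categorical response with fitted probabilities, the Pearson residual
#' of the indicator of category `j` is
#' \eqn{(1\{y_i = j\} - \hat p_{ij}) / \sqrt{\hat p_{ij}(1 - \hat p_{ij})}}.
#' These per-category residual vectors are what the residual correlogram
#' screens (by maximum |I|) for a multinomial fit.
#'
#' @param prob n-by-J probability matrix with category column names.
#' @param y Observed categories (character/factor), no missing.
#' @return n-by-J matrix of residuals.
#' @export
category_residuals <- function(prob, y) {
  y <- as.character(y)
  if (is.null(colnames(prob))) stop("prob needs category column names")
  J <- ncol(prob)
  res <- matrix(NA_real_, nrow(prob), J, dimnames = dimnames(prob))
  for (j in seq_len(J)) {
    p <- pmin(pmax(prob[, j], 1e-12), 1 - 1e-12)
    res[, j] <- ((y == colnames(prob)[j]) - p) / sqrt(p * (1 - p))
  }
  res
}
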