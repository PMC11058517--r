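# Synthetic-world generator: societies on a sphere with spatially clustered
# language families, spatially autocorrelated seasonal climate with a
# tunable predictability knob, social traits, and house traits produced by a
# multinomial-logit model with family random intercepts (vertical
# transmission) plus an optional neighbour-contagion process (horizontal
# transmission). All randomness flows from a single integer seed through
# fixed per-stage substreams.

.substream <- c(geography = 11L, climate = 23L, social = 37L, traits = 53L)

#' World configuration for the synthetic generator
#'
#' @param n_societies Number of societies.
#' @param n_families Number of language families (<= n_societies).
#' @param family_clustering Dispersion of societies around their family seed
#'   point, in km (smaller = tighter spatial clustering of families).
#' @param gradient_strength Latitudinal temperature gradient strength
#'   (degrees C from equator to pole; default 40, roughly the observed
#'   equator-to-subarctic span of annual means).
#' @param spatial_range_km Range of the spatial correlation kernel for site
#'   climate effects (default 2000 km).
#' @param seasonal_amplitude Peak seasonal temperature half-range at the
#'   poles, degrees C (default 15).
#' @param predictability_knob In \[0, 1\]: 1 = every year repeats the annual
#'   cycle exactly (Colwell P = 1); 0 = maximal interannual noise.
#' @param n_years Years of monthly climate (default 50, matching a
#'   half-century observational window).
#' @param social_prevalences Named list of category probabilities for
#'   `polygyny`, `settlement` and `political_complexity`.
#' @param house_model Named list, per response, with elements `coef` (matrix
#'   of slopes on named columns for each non-reference category),
#'   `family_sigma`, `contagion_eta`, `contagion_rounds`. See
#'   [default_house_model()].
#' @param seed Mandatory integer seed.
#' @return A `world_config` list.
#' @export
world_config <- function(n_societies = 120, n_families = 12,
                         family_clustering = 500,
                         gradient_strength = 40, spatial_range_km = 2000,
                         seasonal_amplitude = 15,
                         predictability_knob = 0.8, n_years = 50,
                         social_prevalences = NULL, house_model = NULL,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_families > n_societies) stop("n_families > n_societies")
  stopifnot(predictability_knob >= 0, predictability_knob <= 1,
            family_clustering > 0, spatial_range_km > 0, n_years >= 5)
  if (is.null(social_prevalences)) {
    social_prevalences <- list(
      polygyny = c(none = 0.25, occasional = 0.3, frequent = 0.45),
      settlement = c(sedentary = 0.75, nomadic = 0.25),
      political_complexity = c(0.45, 0.25, 0.15, 0.1, 0.05)
    )
  }
  if (is.null(house_model)) house_model <- default_house_model()
  structure(list(
    n_societies = n_societies, n_families = n_families,
    family_clustering = family_clustering,
    gradient_strength = gradient_strength,
    spatial_range_km = spatial_range_km,
    seasonal_amplitude = seasonal_amplitude,
    predictability_knob = predictability_knob, n_years = n_years,
    social_prevalences = social_prevalences, house_model = house_model,
    seed = as.integer(seed)
  ), class = "world_config")
}

#' Default generative house-trait model
#'
#' Moderate climate effects in the directions the comparative literature
#' predicts (elevated floors in warm/wet sites, subterranean in harsh cold,
#' thick walls in harsh cold/dry, flat roofs in dry sites, angular ground
#' plans in politically complex societies), family_sigma = 1 and a mild
#' neighbour contagion.
#'
#' @param slope Overall effect scale multiplier (default 1).
#' @param family_sigma Random-intercept SD shared by all responses.
#' @param contagion_eta Neighbour-share contagion coefficient.
#' @param contagion_rounds Sequential contagion passes.
#' @return Named list usable as `house_model` in [world_config()].
#' @export
default_house_model <- function(slope = 1, family_sigma = 1,
                                contagion_eta = 1, contagion_rounds = 2) {
  m <- function(...) {
    x <- rbind(...)
    colnames(x) <- c("temperature_harshness", "xeric_harshness",
                     "mountain_dwelling", "political_complexity",
                     "settlement_nomadic")
    x * slope
  }
  list(
    ground_plan = list(   # ref rounded; angular with complexity/sedentism
      coef = m(angular = c(0.3, 0, 0, 0.8, -1.2)),
      intercept = c(angular = -1),
      family_sigma = family_sigma, contagion_eta = contagion_eta,
      contagion_rounds = contagion_rounds
    ),
    floor_level = list(   # ref ground
      coef = m(subterranean = c(1.2, 0.5, 0, 0, 0),
               elevated = c(-1.5, -0.8, 0, 0, 0)),
      intercept = c(subterranean = -2, elevated = -1.5),
      family_sigma = family_sigma, contagion_eta = contagion_eta,
      contagion_rounds = contagion_rounds
    ),
    wall_material = list( # ref thick (cold/dry); others displace it
      coef = m(wood_bamboo = c(-1.2, -0.8, 0, 0, 0),
               fabric_skins = c(0.6, 0.5, 0, 0, 1.5),
               thatch = c(-1.5, -1, 0, 0, 0)),
      intercept = c(wood_bamboo = 0.5, fabric_skins = -2, thatch = -0.5),
      family_sigma = family_sigma, contagion_eta = contagion_eta,
      contagion_rounds = contagion_rounds
    ),
    roof_shape = list(    # ref sloped (warm/wet)
      coef = m(rounded_domed = c(0.8, 0.6, 0, 0, 0.8),
               flat = c(0.4, 1.2, 0, 0, 0)),
      intercept = c(rounded_domed = -1, flat = -1.5),
      family_sigma = family_sigma, contagion_eta = contagion_eta,
      contagion_rounds = contagion_rounds
    )
  )
}

#' Generate geography: clustered coordinates, family labels, terrain
#'
#' Family seed points are uniform on the sphere; societies scatter around
#' their family's seed with tangent-plane Gaussian dispersion of scale
#' `family_clustering` km. Elevation is a smooth random surface (kernel-
#' weighted mixture of spherical bumps) plus noise, slope derived from the
#' same surface.
#'
#' @param cfg A `world_config`.
#' @return Data frame: `society_id`, `lon`, `lat`, `language_family`,
#'   `elevation_m`, `slope_deg`.
#' @export
generate_geography <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + .substream[["geography"]])
  n <- cfg$n_societies
  G <- cfg$n_families
  # uniform points on the sphere for family seeds
  seed_lat <- asin(stats::runif(G, -1, 1)) * 180 / pi
  seed_lon <- stats::runif(G, -180, 180)
  fam <- sort(rep_len(seq_len(G), n))
  ang <- cfg$family_clustering / .earth_radius_km   # radians of dispersion
  dlat <- stats::rnorm(n, 0, ang) * 180 / pi
  dlon <- stats::rnorm(n, 0, ang) * 180 / pi /
    pmax(cos(seed_lat[fam] * pi / 180), 0.2)
  lat <- pmin(pmax(seed_lat[fam] + dlat, -89.9), 89.9)
  lon <- ((seed_lon[fam] + dlon + 180) %% 360) - 180
  # smooth elevation surface: spherical Gaussian bumps
  nb <- 25
  b_lat <- asin(stats::runif(nb, -1, 1)); b_lon <- stats::runif(nb, -pi, pi)
  bx <- cos(b_lat) * cos(b_lon); by <- cos(b_lat) * sin(b_lon)
  bz <- sin(b_lat)
  amp <- stats::rnorm(nb, 0, 800)
  p_lat <- lat * pi / 180; p_lon <- lon * pi / 180
  px <- cos(p_lat) * cos(p_lon); py <- cos(p_lat) * sin(p_lon)
  pz <- sin(p_lat)
  gc <- matrix(acos(pmin(1, pmax(-1, cbind(px, py, pz) %*%
                                   rbind(bx, by, bz)))), n, nb)
  K <- exp(-(gc * .earth_radius_km / 1500)^2)
  surf <- as.vector(K %*% amp)
  elevation <- pmax(0, 300 + surf + stats::rnorm(n, 0, 100))
  slope <- pmax(0, abs(surf) / 200 + stats::rnorm(n, 0, 1.5))
  data.frame(
    society_id = sprintf("S%04d", seq_len(n)),
    lon = lon, lat = lat,
    language_family = sprintf("F%02d", fam),
    elevation_m = elevation, slope_deg = pmin(slope, 45),
    stringsAsFactors = FALSE
  )
}

#' Simulate spatially autocorrelated monthly climate
#'
#' Temperature = latitudinal gradient + spatially correlated site effect +
#' latitude-scaled seasonal sine + interannual noise scaled by
#' (1 - predictability_knob). Precipitation is the exponentiated analogue
#' (log-scale field), so it is positive and right-skewed. With
#' `predictability_knob = 1` every year repeats the annual cycle exactly.
#'
#' @param cfg A `world_config`.
#' @param geo Data frame from [generate_geography()].
#' @return Named list (by society id) of lists with `temp` and `precip`
#'   years-by-12 matrices.
#' @export
simulate_monthly_climate <- function(cfg, geo) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + .substream[["climate"]])
  n <- nrow(geo)
  noise_sd <- 3 * (1 - cfg$predictability_knob)
  # spatially correlated site effects by kernel mixing of iid noise
  d <- .pairwise_km(geo)
  K <- exp(-(d / cfg$spatial_range_km)^2)
  Kw <- K / rowSums(K)
  site_t <- as.vector(Kw %*% stats::rnorm(n, 0, 6)) * sqrt(n / sum(Kw^2))
  site_t <- site_t / max(stats::sd(site_t), 1e-9) * 4
  site_p <- as.vector(Kw %*% stats::rnorm(n, 0, 1))
  site_p <- site_p / max(stats::sd(site_p), 1e-9) * 0.8
  months <- 1:12
  out <- vector("list", n)
  names(out) <- geo$society_id
  for (i in seq_len(n)) {
    absl <- abs(geo$lat[i]) / 90
    mean_t <- 27 - cfg$gradient_strength * absl + site_t[i] -
      geo$elevation_m[i] * 0.0065
    amp_t <- cfg$seasonal_amplitude * absl
    season <- sin(2 * pi * (months - 4) / 12) * amp_t
    base_t <- mean_t + season
    temp <- matrix(rep(base_t, cfg$n_years), ncol = 12, byrow = TRUE)
    if (noise_sd > 0)
      temp <- temp + matrix(stats::rnorm(cfg$n_years * 12, 0, noise_sd),
                            ncol = 12)
    log_p <- log(60) + 1.2 * (1 - absl) + site_p[i] +
      0.6 * sin(2 * pi * (months - 6) / 12) * (0.3 + absl)
    precip <- matrix(rep(exp(log_p), cfg$n_years), ncol = 12, byrow = TRUE)
    if (noise_sd > 0)
      precip <- precip * exp(matrix(
        stats::rnorm(cfg$n_years * 12, 0, noise_sd / 6), ncol = 12))
    rownames(temp) <- rownames(precip) <- seq_len(cfg$n_years)
    out[[i]] <- list(temp = temp, precip = precip)
  }
  out
}

# Social traits drawn independently from configured prevalences.
.simulate_social <- function(cfg, n) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + .substream[["social"]])
  pv <- cfg$social_prevalences
  draw <- function(p) sample(seq_along(p), n, replace = TRUE, prob = p)
  # raw EA codes so the generated table exercises the recode layer
  polyg <- c(none = 1L, occasional = 2L, frequent = 4L)[
    names(pv$polygyny)[draw(pv$polygyny)]]
  settl <- c(sedentary = 5L, nomadic = 1L)[
    names(pv$settlement)[draw(pv$settlement)]]
  pc <- draw(pv$political_complexity)
  data.frame(ea009 = unname(polyg), ea030 = unname(settl),
             ea033 = as.integer(pc))
}

# Reverse maps: analysis category -> a representative raw EA code.
.category_to_code <- list(
  ground_plan = c(rounded = 2L, angular = 5L),
  floor_level = c(subterranean = 1L, ground = 2L, elevated = 3L),
  wall_material = c(thick = 1L, wood_bamboo = 6L, fabric_skins = 10L,
                    thatch = 8L),
  roof_shape = c(rounded_domed = 3L, sloped = 6L, flat = 7L)
)
.response_ea <- c(ground_plan = "ea079", floor_level = "ea080",
                  wall_material = "ea081", roof_shape = "ea082")

#' Simulate house traits under vertical and horizontal transmission
#'
#' Initial categories are drawn from a multinomial logit whose linear
#' predictor combines the configured slopes on the (true) environmental
#' composites and social covariates with a family random intercept
#' Normal(0, family_sigma^2) per non-reference category. Then
#' `contagion_rounds` sequential passes redraw each society with an added
#' term `contagion_eta` times the current neighbour share of each category,
#' approximating an autologistic neighbourhood field.
#'
#' @param cfg A `world_config`.
#' @param covariates Data frame with the generative covariate columns
#'   (`temperature_harshness`, `xeric_harshness`, `mountain_dwelling`,
#'   `political_complexity`, `settlement_nomadic`) plus `language_family`.
#' @param nbrs A `neighbor_table` for the contagion passes.
#' @return List with `traits` (data.frame of category labels per response),
#'   `family_intercepts` (per response, G x (J-1) matrix of realised
#'   intercepts).
#' @export
simulate_house_traits <- function(cfg, covariates, nbrs) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + .substream[["traits"]])
  n <- nrow(covariates)
  fams <- sort(unique(covariates$language_family))
  traits <- data.frame(row.names = seq_len(n))
  fam_ints <- list()
  for (resp in names(cfg$house_model)) {
    hm <- cfg$house_model[[resp]]
    cats_nr <- rownames(hm$coef)
    ref <- setdiff(.trait_levels[[resp]], cats_nr)[1]
    cats <- c(ref, cats_nr)
    Xg <- as.matrix(covariates[, colnames(hm$coef), drop = FALSE])
    U <- matrix(stats::rnorm(length(fams) * length(cats_nr), 0,
                             hm$family_sigma),
                nrow = length(fams),
                dimnames = list(fams, cats_nr))
    fi <- match(covariates$language_family, fams)
    eta <- Xg %*% t(hm$coef) +
      matrix(hm$intercept, n, length(cats_nr), byrow = TRUE) +
      U[fi, , drop = FALSE]
    draw_from <- function(eta_extra) {
      pr <- .bcl_prob(eta + eta_extra)
      idx <- vapply(seq_len(n), function(i)
        sample.int(length(cats), 1, prob = pr[i, ]), integer(1))
      cats[idx]
    }
    cur <- draw_from(matrix(0, n, length(cats_nr)))
    if (hm$contagion_eta != 0 && hm$contagion_rounds > 0) {
      for (r in seq_len(hm$contagion_rounds)) {
        share <- matrix(0, n, length(cats_nr))
        for (j in seq_along(cats_nr)) {
          ind <- stats::setNames(as.numeric(cur == cats_nr[j]),
                                 covariates$society_id)
          share[, j] <- vapply(seq_len(n), function(i)
            mean(ind[nbrs$ids[i, ]]), numeric(1))
        }
        cur <- draw_from(hm$contagion_eta * share)
      }
    }
    traits[[resp]] <- cur
    fam_ints[[resp]] <- U
  }
  list(traits = traits, family_intercepts = fam_ints)
}

#' Generate a full synthetic world
#'
#' Runs geography, climate, social and house-trait generation and assembles
#' a `society_table` whose EA code columns will recode back to the generated
#' categories, together with the ground truth needed for recovery tests.
#'
#' @param cfg A `world_config`.
#' @return A `synthetic_world`: list with `table` (a `society_table`),
#'   `truth` (config, true composite covariates, family intercepts,
#'   neighbour table used for contagion).
#' @export
generate_world <- function(cfg) {
  geo <- generate_geography(cfg)
  climate <- simulate_monthly_climate(cfg, geo)
  social <- .simulate_social(cfg, nrow(geo))
  # "true" composites for the generative model: standardised constructs of
  # the same quantities the analysis pipeline later estimates
  absl <- abs(geo$lat) / 90
  mean_t <- 27 - cfg$gradient_strength * absl - geo$elevation_m * 0.0065
  covariates <- data.frame(
    society_id = geo$society_id,
    language_family = geo$language_family,
    temperature_harshness = as.numeric(scale(-mean_t)),
    xeric_harshness = as.numeric(scale(-vapply(climate, function(cm)
      mean(cm$precip), numeric(1)))),
    mountain_dwelling = as.numeric(scale(geo$elevation_m +
                                           100 * geo$slope_deg)),
    political_complexity = social$ea033,
    settlement_nomadic = as.numeric(social$ea030 <= 2),
    stringsAsFactors = FALSE
  )
  nbrs <- nearest_neighbors(geo, k = min(10, nrow(geo) - 1))
  ht <- simulate_house_traits(cfg, covariates, nbrs)
  df <- geo
  df[c("ea009", "ea030", "ea033")] <- social
  for (resp in names(ht$traits)) {
    code <- .category_to_code[[resp]][ht$traits[[resp]]]
    df[[.response_ea[[resp]]]] <- unname(code)
  }
  df <- df[, intersect(.society_columns, names(df))]
  for (col in setdiff(.society_columns, names(df))) {
    df[[col]] <- NA_integer_
  }
  df <- df[, .society_columns]
  tbl <- structure(list(societies = df, climate = climate),
                   class = "society_table")
  structure(list(
    table = tbl,
    truth = list(config = cfg, covariates = covariates,
                 family_intercepts = ht$family_intercepts,
                 neighbors = nbrs)
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", nrow(x$table$societies), "societies, seed",
      x$truth$config$seed, "\n")
  invisible(x)
}

#' Parameter-recovery report for a pipeline run on a synthetic world
#'
#' Compares fitted full-model slopes to the generative truth per response:
#' bias and RMSE of matched coefficients, sign-agreement rate among non-zero
#' true slopes, estimated random-intercept SD against `family_sigma`, and
#' the relative importance of true (non-zero slope) vs decoy predictors.
#'
#' @param world A `synthetic_world`.
#' @param results A pipeline result (from [run_pipeline()]) computed on
#'   `world$table`.
#' @return Data frame, one row per response, with recovery metrics.
#' @export
recovery_report <- function(world, results) {
  stopifnot(inherits(world, "synthetic_world"))
  rows <- list()
  for (resp in names(results$analyses)) {
    an <- results$analyses[[resp]]
    hm <- world$truth$config$house_model[[resp]]
    if (is.null(hm) || is.null(an)) next
    full <- an$full_fit
    true_coef <- hm$coef
    est <- full$coef
    common_terms <- intersect(colnames(true_coef), colnames(est))
    common_cats <- intersect(rownames(true_coef), rownames(est))
    if (!length(common_terms) || !length(common_cats)) next
    tm <- true_coef[common_cats, common_terms, drop = FALSE]
    em <- est[common_cats, common_terms, drop = FALSE]
    diff <- em - tm
    nz <- tm != 0
    rows[[resp]] <- data.frame(
      response = resp,
      bias = mean(diff), rmse = sqrt(mean(diff^2)),
      sign_agreement = if (any(nz))
        mean(sign(em[nz]) == sign(tm[nz])) else NA_real_,
      sigma_hat = sqrt(mean(full$re_var)),
      sigma_true = hm$family_sigma,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
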