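# End-to-end orchestration: read or generate a society table, recode traits,
# summarise climate, build composites, neighbours and borrowing, fit the
# full and all nested models per house feature, average by AICc, check
# residual spatial autocorrelation, and write a reproducible report bundle.

#' Build a run configuration
#'
#' Exactly one of `input` (paths to society/climate CSVs) or `world`
#' (a `world_config` for the synthetic generator) must be given. Defaults
#' follow the analysis constants: k = 10 nearest neighbours, 12 Moran
#' distance classes, 3 varimax components, 10 Colwell states.
#'
#' @param input Optional list with `society_csv` and `climate_csv` paths.
#' @param world Optional `world_config`.
#' @param k_neighbors Neighbour count for the borrowing statistic.
#' @param n_states Colwell state count.
#' @param n_moran_classes Moran correlogram distance classes.
#' @param pca_variables Environmental variables entering the composite PCA.
#' @param responses House features to analyse.
#' @param predictors Toggleable full-model terms (default: the three
#'   composites, polygyny, settlement, political complexity and the
#'   temperature-harshness-by-complexity interaction; the borrowing term and
#'   the language-family random effect are always toggled in as well).
#' @param include_interaction Keep the harshness-by-complexity interaction
#'   in the full model.
#' @param include_random_effect Toggle the language-family random effect.
#' @param output_dir Optional directory for the CSV/JSON report bundle.
#' @param seed Seed recorded in the manifest (and used for any permutation
#'   diagnostics); the synthetic world carries its own seed.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, world = NULL, k_neighbors = 10,
                       n_states = 10, n_moran_classes = 12,
                       pca_variables = .default_pca_variables,
                       responses = c("ground_plan", "floor_level",
                                     "wall_material", "roof_shape"),
                       predictors = c(.composite_terms, .social_terms),
                       include_interaction = TRUE,
                       include_random_effect = TRUE,
                       output_dir = NULL, seed = 1L) {
  if (is.null(input) == is.null(world))
    stop("exactly one of 'input' or 'world' must be given")
  structure(list(
    input = input, world = world, k_neighbors = k_neighbors,
    n_states = n_states, n_moran_classes = n_moran_classes,
    pca_variables = pca_variables, responses = responses,
    predictors = predictors, include_interaction = include_interaction,
    include_random_effect = include_random_effect,
    output_dir = output_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full comparative analysis pipeline
#'
#' Stages: read/generate -> recode -> climate summaries -> varimax
#' composites -> neighbour table + per-response borrowing fraction -> per
#' response: full mixed fit, Moran residual correlogram, nested-model
#' enumeration and fitting, AICc averaging, relative importance and accuracy
#' baselines. The whole pass is deterministic given config + seed.
#'
#' @param cfg A `run_config`.
#' @param verbose Print stage progress.
#' @return A `pipeline_result`: list with `data` (analysis data frame),
#'   `composites`, `neighbors`, `analyses` (per response: `full_fit`,
#'   `moran`, `averaged`, `candidates_n`, `converged_n`, `n`), `crosstab`
#'   (polygyny x ground plan row percentages), `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (!is.null(cfg$world)) {
    say("stage generate: %d societies", cfg$world$n_societies)
    world <- generate_world(cfg$world)
    tbl <- world$table
  } else {
    say("stage read: %s", cfg$input$society_csv)
    tbl <- read_society_table(cfg$input$society_csv,
                              climate_path = cfg$input$climate_csv)
    world <- NULL
  }
  df <- recode_traits(tbl$societies)
  say("stage recode: %d societies", nrow(df))

  clim <- summarize_climate(tbl, n_states = cfg$n_states)
  comp <- env_composites(clim, variables = cfg$pca_variables)
  say("stage composites: %d societies scored", nrow(comp$scores))
  df <- merge(df, comp$scores, by = "society_id", all.x = TRUE, sort = FALSE)
  df <- df[order(df$society_id), ]
  rownames(df) <- NULL

  located <- !is.na(df$lon) & !is.na(df$lat)
  nbrs <- nearest_neighbors(df[located, ], k = cfg$k_neighbors)
  say("stage neighbors: k = %d over %d societies", cfg$k_neighbors,
      sum(located))

  analyses <- list()
  for (resp in cfg$responses) {
    say("stage response: %s", resp)
    trait <- stats::setNames(df[[resp]], df$society_id)
    trait[trait == "excluded"] <- NA
    bf <- borrowing_fraction(trait[rownames(nbrs$ids)], nbrs)
    dat <- df
    dat$borrowing <- unname(bf[match(dat$society_id, names(bf))])
    pr <- c(cfg$predictors,
            if (cfg$include_interaction &&
                all(c("temperature_harshness", "political_complexity")
                    %in% cfg$predictors)) .interaction_term,
            "borrowing")
    full <- model_spec(resp, pr,
                       if (cfg$include_random_effect) "language_family"
                       else "none")
    specs <- enumerate_models(full)
    cand <- fit_candidates(specs, dat)
    # full model = last spec (all terms, random effect if enabled)
    full_idx <- length(specs)
    full_fit <- cand$fits[[full_idx]]
    if (is.null(full_fit)) full_fit <- cand$fits[[which(cand$converged)[
      which.max(vapply(cand$fits[cand$converged], function(f)
        length(f$terms), integer(1)))]]]
    avg <- average_model(cand)
    moran <- .residual_correlogram(full_fit, cand$data, cfg)
    analyses[[resp]] <- list(
      full_fit = full_fit, moran = moran, averaged = avg,
      candidates_n = length(specs), converged_n = sum(cand$converged),
      n = cand$n
    )
    say("  n = %d, %d/%d models converged, accuracy %.3f",
        cand$n, sum(cand$converged), length(specs), avg$accuracy)
  }
  crosstab <- tryCatch(crosstab_percent(df$polygyny, df$ground_plan),
                       error = function(e) NULL)
  manifest <- list(
    seed = cfg$seed,
    k_neighbors = cfg$k_neighbors, n_states = cfg$n_states,
    n_moran_classes = cfg$n_moran_classes,
    pca_variables = cfg$pca_variables,
    responses = cfg$responses, predictors = cfg$predictors,
    include_interaction = cfg$include_interaction,
    include_random_effect = cfg$include_random_effect,
    world_seed = if (!is.null(cfg$world)) cfg$world$seed else NULL,
    n_societies = nrow(df),
    package_version = as.character(utils::packageVersion("vernarch")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  res <- structure(list(
    data = df, composites = comp, neighbors = nbrs, analyses = analyses,
    crosstab = crosstab, manifest = manifest, world = world
  ), class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_report_bundle(res, cfg$output_dir)
  res
}

# Moran correlogram of the Pearson residuals of the full fit, screened by
# the maximum |I| across response categories.
.residual_correlogram <- function(fit, dat, cfg) {
  prob <- fit$fitted_prob
  res <- category_residuals(prob, dat[[.find_response(fit, dat)]])
  best <- NULL
  for (j in seq_len(ncol(res))) {
    if (stats::var(res[, j]) == 0) next
    mc <- morans_correlogram(res[, j], dat,
                             n_classes = cfg$n_moran_classes)
    if (is.null(best) ||
        max(abs(mc$I), na.rm = TRUE) > max(abs(best$I), na.rm = TRUE))
      best <- mc
  }
  best
}

.find_response <- function(fit, dat) {
  for (resp in names(.trait_levels)) {
    if (resp %in% names(dat) &&
        all(fit$categories %in% .trait_levels[[resp]])) return(resp)
  }
  stop("cannot identify response column")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$manifest$n_societies, "societies\n")
  for (resp in names(x$analyses)) {
    an <- x$analyses[[resp]]
    cat(sprintf(
      "  %-14s n = %4d  models %3d (%3d converged)  acc %.3f (modal %.3f, chance %.3f)\n",
      resp, an$n, an$candidates_n, an$converged_n,
      an$averaged$accuracy, an$averaged$modal, an$averaged$chance))
  }
  invisible(x)
}

#' Write the report bundle (CSVs + JSON manifest) for a pipeline result
#'
#' Per response: full-model coefficient table, averaged-model table
#' (averaged coefficient, unconditional SE), Moran correlogram data; plus an
#' importance/accuracy summary across responses, the polygyny-by-ground-plan
#' cross-tab, effect-profile data for each composite, and `manifest.json`.
#' Output is plain text and byte-stable for a fixed config + seed.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `invisible(res)`.
#' @export
write_report_bundle <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, name) {
    for (col in names(d)) if (is.numeric(d[[col]]))
      d[[col]] <- formatC(d[[col]], digits = 12, format = "g")
    utils::write.csv(d, file.path(dir, name), row.names = FALSE)
  }
  summary_rows <- list()
  for (resp in names(res$analyses)) {
    an <- res$analyses[[resp]]
    fit <- an$full_fit
    co <- as.data.frame(as.table(fit$coef), stringsAsFactors = FALSE)
    names(co) <- c("category", "term", "estimate")
    co$se <- as.vector(fit$se)
    co$z <- co$estimate / co$se
    wcsv(co, paste0("full_model_", resp, ".csv"))
    avg <- an$averaged
    am <- as.data.frame(as.table(avg$avg_coef), stringsAsFactors = FALSE)
    names(am) <- c("category", "term", "avg_estimate")
    am$uncond_se <- as.vector(avg$uncond_se)
    wcsv(am, paste0("averaged_model_", resp, ".csv"))
    wcsv(as.data.frame(an$moran), paste0("moran_", resp, ".csv"))
    imp <- avg$importance
    summary_rows[[resp]] <- data.frame(
      response = resp, n = an$n,
      chance = avg$chance, modal = avg$modal, accuracy = avg$accuracy,
      t(as.data.frame(imp)), stringsAsFactors = FALSE
    )
    for (comp in intersect(.composite_terms, names(imp))) {
      prof <- effect_profile(avg, comp)
      wcsv(prof, paste0("profile_", resp, "_", comp, ".csv"))
    }
  }
  smry <- do.call(rbind, summary_rows)
  rownames(smry) <- NULL
  wcsv(smry, "summary_importance_accuracy.csv")
  if (!is.null(res$crosstab)) {
    ct <- as.data.frame.matrix(res$crosstab$percent)
    ct <- cbind(category = rownames(ct), ct)
    wcsv(ct, "crosstab_polygyny_ground_plan.csv")
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Write a small fixture world to CSV files
#'
#' The 120-society world used by the test suite, emitted in the same CSV
#' formats [read_society_table()] reads.
#'
#' @param dir Output directory.
#' @param seed Generator seed (default 42).
#' @param n_years Years of monthly climate (default 10 to keep files small).
#' @return Paths of the two files written, invisibly.
#' @export
write_fixture_world <- function(dir, seed = 42, n_years = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- world_config(n_societies = 120, n_families = 12,
                      n_years = n_years, seed = seed)
  w <- generate_world(cfg)
  paths <- c(file.path(dir, "societies.csv"), file.path(dir, "climate.csv"))
  write_society_table(w$table, paths[1], paths[2])
  invisible(paths)
}
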