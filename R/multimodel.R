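# Multimodel inference: enumerate all nested models of a full specification,
# fit them on a common complete-case dataset, weight by AICc, and derive
# model-averaged coefficients, unconditional SEs, relative variable
# importance, averaged predictions and accuracy baselines.

.composite_terms <- c("temperature_harshness", "mountain_dwelling",
                      "xeric_harshness")
.social_terms <- c("polygyny", "settlement", "political_complexity")
.interaction_term <- "temp_harshness_x_political_complexity"
.default_refs <- c(ground_plan = "rounded", floor_level = "ground",
                   wall_material = "thick", roof_shape = "sloped")

#' Construct a model specification
#'
#' @param response One of `"ground_plan"`, `"floor_level"`,
#'   `"wall_material"`, `"roof_shape"` (or any categorical column name).
#' @param predictors Character vector of predictor terms among the
#'   environmental composites, social traits, the
#'   temperature-harshness-by-political-complexity interaction, and
#'   `"borrowing"`.
#' @param random_effect `"language_family"` or `"none"`.
#' @param ref Reference category for the response (default per trait:
#'   rounded / ground / thick / sloped).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, predictors = character(),
                       random_effect = c("language_family", "none"),
                       ref = NULL) {
  random_effect <- match.arg(random_effect)
  predictors <- unique(predictors)
  if (.interaction_term %in% predictors &&
      !all(c("temperature_harshness", "political_complexity") %in%
           predictors)) {
    stop("interaction requires both main effects (hierarchy rule)")
  }
  if (is.null(ref) && response %in% names(.default_refs))
    ref <- .default_refs[[response]]
  structure(list(response = response, predictors = predictors,
                 random_effect = random_effect, ref = ref),
            class = "model_spec")
}

#' Enumerate all nested models of a full specification
#'
#' All subsets of the full model's toggleable terms, with the intercept
#' always included and the interaction only appearing together with both of
#' its main effects. The random effect and the borrowing term are toggled
#' like any other predictor (so their relative importance is defined).
#' Enumeration order is deterministic and duplicate-free.
#'
#' @param full A `model_spec` for the fully parameterised model.
#' @return List of `model_spec`, from intercept-only to the full model.
#' @export
enumerate_models <- function(full) {
  stopifnot(inherits(full, "model_spec"))
  mains <- setdiff(full$predictors, .interaction_term)
  has_int <- .interaction_term %in% full$predictors
  toggles <- mains
  specs <- list()
  n_main <- length(toggles)
  for (mask in 0:(2^n_main - 1)) {
    subset <- toggles[bitwAnd(mask, 2^(seq_len(n_main) - 1)) > 0]
    int_opts <- if (has_int &&
                    all(c("temperature_harshness", "political_complexity")
                        %in% subset)) c(FALSE, TRUE) else FALSE
    for (with_int in int_opts) {
      pr <- c(subset, if (with_int) .interaction_term)
      re_opts <- if (full$random_effect == "language_family")
        c("none", "language_family") else "none"
      for (re in re_opts) {
        specs[[length(specs) + 1]] <-
          model_spec(full$response, pr, re, ref = full$ref)
      }
    }
  }
  specs
}

# Build the numeric design matrix for a spec's predictors from a recoded,
# composite-augmented analysis data frame. Categorical social traits enter
# as treatment dummies (reference: first declared level), political
# complexity as numeric 1-5, composites and borrowing as numeric scores.
.build_design <- function(data, predictors) {
  cols <- list()
  for (term in predictors) {
    if (term == .interaction_term) {
      cols[[term]] <- data$temperature_harshness * data$political_complexity
    } else if (term %in% names(.trait_levels)) {
      lev <- .trait_levels[[term]]
      v <- factor(data[[term]], levels = lev)
      for (l in lev[-1]) {
        cols[[paste0(term, "_", l)]] <- as.numeric(v == l)
      }
    } else {
      cols[[term]] <- as.numeric(data[[term]])
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  do.call(cbind, cols)
}

# Columns of `data` that a spec needs (for complete-case filtering).
.spec_columns <- function(spec) {
  pr <- setdiff(spec$predictors, .interaction_term)
  cols <- c(spec$response, pr)
  if (.interaction_term %in% spec$predictors)
    cols <- union(cols, c("temperature_harshness", "political_complexity"))
  if (spec$random_effect == "language_family")
    cols <- union(cols, "language_family")
  cols
}

#' Fit every candidate specification on a common complete-case dataset
#'
#' Societies missing any variable of the *full* model (the union of all
#' candidate columns) are dropped first, so every candidate is fitted on the
#' same n. Fits that error or hit separation are flagged non-converged and
#' retained; at least one converged fit is required.
#'
#' @param specs List of `model_spec` (e.g. from [enumerate_models()]).
#' @param data Analysis data frame with recoded traits, composite scores,
#'   `borrowing` and `language_family` columns as needed.
#' @return List with `fits` (list of `cmm_fit` or `NULL` for errors),
#'   `specs`, `data` (the common complete-case subset), `n`.
#' @export
fit_candidates <- function(specs, data) {
  all_cols <- Reduce(union, lapply(specs, .spec_columns))
  all_cols <- intersect(all_cols, names(data))
  keep <- stats::complete.cases(data[, all_cols, drop = FALSE])
  if ("wall_material" %in% all_cols)
    keep <- keep & data$wall_material != "excluded"
  dat <- data[keep, , drop = FALSE]
  if (!nrow(dat)) stop("no complete cases")
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    X <- .build_design(dat, sp$predictors)
    y <- dat[[sp$response]]
    fits[i] <- list(tryCatch({
      if (sp$random_effect == "language_family") {
        fit_mixed_multinomial(X, y, dat$language_family, ref = sp$ref)
      } else {
        fit_multinomial(X, y, ref = sp$ref)
      }
    }, error = function(e) NULL))
  }
  conv <- vapply(fits, function(f)
    !is.null(f) && isTRUE(f$converged) && is.finite(f$aicc), logical(1))
  if (!any(conv)) stop("zero converged candidate models")
  list(fits = fits, specs = specs, data = dat, n = nrow(dat),
       converged = conv)
}

#' Akaike weights from AICc values
#'
#' \eqn{\Delta_i = AICc_i - \min_j AICc_j};
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param aiccs Finite numeric vector of AICc values.
#' @return Weights summing to 1, aligned with the input.
#' @export
akaike_weights <- function(aiccs) {
  if (!length(aiccs)) stop("empty AICc vector")
  if (any(!is.finite(aiccs))) stop("non-finite AICc")
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' AICc-weighted average model
#'
#' Zero-method (shrinkage) averaging over the converged candidates: a
#' coefficient absent from a model contributes zero with that model's
#' weight, so
#' \eqn{\bar\beta = \sum_i w_i \hat\beta_i} and the unconditional standard
#' error is
#' \eqn{\sqrt{\sum_i w_i (SE_i^2 + (\hat\beta_i - \bar\beta)^2)}}.
#' Averaged predicted probabilities are the weight-averaged fitted
#' probability matrices, and accuracy baselines come from
#' [classification_metrics()] on those.
#'
#' @param cand Result of [fit_candidates()].
#' @return An `averaged_model`: list with `weights` (over converged fits,
#'   summing to 1), `avg_coef` ((J-1) x full term set), `uncond_se`,
#'   `importance` (named vector over predictors + random effect),
#'   `avg_prob`, `accuracy`, `chance`, `modal`, `best` (index of the
#'   minimum-AICc fit), `n`.
#' @export
average_model <- function(cand) {
  conv <- cand$converged
  fits <- cand$fits[conv]
  specs <- cand$specs[conv]
  if (!length(fits)) stop("no converged fits to average")
  w <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  # full coefficient layout: union of term columns over candidates
  terms_all <- Reduce(union, lapply(fits, function(f) f$terms))
  cats <- fits[[which.max(vapply(fits, function(f)
    length(f$categories), integer(1)))]]$categories
  Jm1 <- length(cats) - 1
  avg <- matrix(0, Jm1, length(terms_all),
                dimnames = list(cats[-1], terms_all))
  m2 <- avg   # running sum of w * (se^2 + beta^2), for the spread term
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    cj <- match(f$terms, terms_all)
    rj <- match(rownames(f$coef), cats[-1])
    avg[rj, cj] <- avg[rj, cj] + w[i] * f$coef
    m2[rj, cj] <- m2[rj, cj] + w[i] * (f$se^2 + f$coef^2)
  }
  uncond <- sqrt(pmax(m2 - avg^2, 0))   # sum w (se^2 + (b - avg)^2)
  probs <- lapply(fits, function(f) f$fitted_prob[, cats, drop = FALSE])
  avg_prob <- Reduce(`+`, Map(function(p, wi) p * wi, probs, as.list(w)))
  y <- cand$data[[specs[[1]]$response]]
  metrics <- classification_metrics(avg_prob, y)
  structure(list(
    weights = w, avg_coef = avg, uncond_se = uncond,
    importance = relative_importance(specs, w),
    avg_prob = avg_prob, accuracy = metrics$accuracy,
    chance = metrics$chance, modal = metrics$modal,
    best = which(conv)[which.max(w)], n = cand$n,
    response = specs[[1]]$response, categories = cats,
    specs = specs, fits = fits
  ), class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("averaged_model for '%s': %d converged models, n = %d\n",
              x$response, length(x$weights), x$n))
  cat(sprintf("  accuracy = %.3f (chance %.3f, modal %.3f)\n",
              x$accuracy, x$chance, x$modal))
  cat("  relative importance:\n")
  imp <- sort(x$importance, decreasing = TRUE)
  for (nm in names(imp)) cat(sprintf("    %-42s %.3f\n", nm, imp[nm]))
  invisible(x)
}

#' Relative variable importance
#'
#' For each predictor (including the borrowing term and the language-family
#' random effect), the sum of Akaike weights of the models containing it —
#' a scale from 0 (no contribution) to 1 (needed for the stated predictive
#' accuracy).
#'
#' @param specs List of `model_spec` for the (converged) candidates.
#' @param weights Akaike weights aligned with `specs` (renormalised over the
#'   converged set).
#' @return Named numeric vector in \[0, 1\].
#' @export
relative_importance <- function(specs, weights) {
  stopifnot(length(specs) == length(weights))
  terms <- Reduce(union, lapply(specs, function(s) s$predictors))
  has_re <- any(vapply(specs, function(s)
    s$random_effect != "none", logical(1)))
  out <- stats::setNames(numeric(length(terms)), terms)
  for (i in seq_along(specs)) {
    for (t in specs[[i]]$predictors) out[t] <- out[t] + weights[i]
  }
  if (has_re) {
    re_w <- sum(weights[vapply(specs, function(s)
      s$random_effect != "none", logical(1))])
    out <- c(out, language_family = re_w)
  }
  out
}

#' Averaged-probability curves along an environmental composite
#'
#' Predicted category probabilities from the averaged model along a grid of
#' one composite, all other covariates held at a fixed profile (defaults:
#' composites 0, modal social categories in the analysis data, borrowing at
#' its mean). Optionally stratified by political complexity (e.g. 1 =
#' acephalous vs 5 = large state) to display the
#' harshness-by-complexity interaction.
#'
#' @param avg An `averaged_model`.
#' @param composite Composite to profile (must be a predictor somewhere in
#'   the candidate set).
#' @param grid Numeric grid of composite values (default -2.5..2.5).
#' @param fixed Named list overriding profile values.
#' @param by_complexity Optional numeric vector of political-complexity
#'   levels to stratify by.
#' @return Data frame: `composite`, value, optional `political_complexity`,
#'   one probability column per category (rows sum to 1).
#' @export
effect_profile <- function(avg, composite,
                           grid = seq(-2.5, 2.5, length.out = 41),
                           fixed = list(), by_complexity = NULL) {
  stopifnot(inherits(avg, "averaged_model"))
  all_terms <- Reduce(union, lapply(avg$specs, function(s) s$predictors))
  if (!composite %in% all_terms) stop("unknown composite: ", composite)
  data <- NULL
  strata <- if (is.null(by_complexity)) NA else by_complexity
  rows <- list()
  for (pc in strata) {
    prof <- .default_profile(avg, fixed)
    if (!is.na(pc)) prof$political_complexity <- pc
    newdata <- prof[rep(1, length(grid)), , drop = FALSE]
    newdata[[composite]] <- grid
    prob <- .predict_avg(avg, newdata)
    block <- data.frame(composite = composite, value = grid)
    if (!is.na(pc)) block$political_complexity <- pc
    rows[[length(rows) + 1]] <- cbind(block, as.data.frame(prob))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.default_profile <- function(avg, fixed = list()) {
  all_terms <- Reduce(union, lapply(avg$specs, function(s) s$predictors))
  dat <- NULL
  prof <- list()
  for (t in setdiff(all_terms, .interaction_term)) {
    if (t %in% names(fixed)) {
      prof[[t]] <- fixed[[t]]
    } else if (t %in% .composite_terms) {
      prof[[t]] <- 0
    } else if (t == "political_complexity") {
      prof[[t]] <- 1
    } else if (t %in% names(.trait_levels)) {
      prof[[t]] <- .trait_levels[[t]][1]
    } else {
      prof[[t]] <- 0.5   # borrowing-like fractions
    }
  }
  as.data.frame(prof, stringsAsFactors = FALSE)
}

# Averaged population-level prediction at new covariate values.
.predict_avg <- function(avg, newdata) {
  probs <- Map(function(f, s) {
    X <- .build_design(newdata, s$predictors)
    predict_prob(f, X)[, avg$categories, drop = FALSE]
  }, avg$fits, avg$specs)
  Reduce(`+`, Map(function(p, wi) p * wi, probs, as.list(avg$weights)))
}

#' Row-percentage cross-tabulation of two categorical vectors
#'
#' Pairwise-complete cross-tab with row percentages (each row sums to 100)
#' and the raw counts.
#'
#' @param a Row variable (e.g. polygyny category).
#' @param b Column variable (e.g. ground plan).
#' @return List with `percent` (row percentages) and `counts` matrices.
#' @export
crosstab_percent <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no complete pairs")
  counts <- table(as.character(a)[keep], as.character(b)[keep],
                  dnn = NULL)
  pct <- 100 * sweep(counts, 1, rowSums(counts), "/")
  list(percent = unclass(pct), counts = unclass(counts))
}
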