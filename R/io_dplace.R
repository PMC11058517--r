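# Canonical column names of a society table. Raw exports use varying headers;
# `col_map` translates them (names = canonical, values = header in the file).
.society_columns <- c(
  "society_id", "lon", "lat", "language_family",
  "ea079", "ea080", "ea081", "ea082", "ea009", "ea030", "ea033",
  "elevation_m", "slope_deg"
)
.mandatory_columns <- c("society_id", "lon", "lat")
.ea_columns <- c("ea079", "ea080", "ea081", "ea082", "ea009", "ea030", "ea033")

#' Read a D-PLACE-style society table
#'
#' Reads a CSV with one row per society (id, coordinates, language family,
#' Ethnographic Atlas integer codes, terrain) and, optionally, a long-format
#' companion CSV of monthly climate series (`society_id, year, month, temp_c,
#' precip_mm`).
#'
#' @param path Path to the society CSV (UTF-8, header, "." decimal separator).
#' @param climate_path Optional path to the long-format monthly climate CSV.
#' @param col_map Optional named character vector mapping canonical column
#'   names (e.g. `"lon"`) to the header used in the file. Unmapped canonical
#'   names are looked up verbatim (case-insensitive).
#' @return A `society_table`: a list with `$societies` (data.frame, one row per
#'   society) and `$climate` (named list; per society a list with `temp` and
#'   `precip` years-by-12 matrices, or `NULL`).
#' @details Unparseable numeric cells become `NA` with a warning; the row count
#'   of the input is preserved. Missing mandatory columns (id, lon, lat) are a
#'   hard error naming the first missing column.
#' @export
read_society_table <- function(path, climate_path = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", ""))
  nm <- names(raw)
  resolve <- function(canon) {
    if (!is.null(col_map) && canon %in% names(col_map)) {
      hit <- match(col_map[[canon]], nm)
    } else {
      hit <- match(tolower(canon), tolower(nm))
    }
    hit
  }
  for (canon in .mandatory_columns) {
    if (is.na(resolve(canon))) {
      stop("mandatory column missing: '", canon, "'")
    }
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in .society_columns) {
    hit <- resolve(canon)
    if (is.na(hit)) {
      out[[canon]] <- if (canon %in% c("society_id", "language_family"))
        NA_character_ else NA_real_
      next
    }
    col <- raw[[hit]]
    if (canon %in% c("society_id", "language_family")) {
      out[[canon]] <- as.character(col)
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & is.na(num)
      if (any(bad)) {
        warning(sum(bad), " unparseable value(s) in column '", canon,
                "' set to missing")
      }
      out[[canon]] <- num
    }
  }
  for (ea in .ea_columns) out[[ea]] <- as.integer(out[[ea]])
  validate_societies(out)

  climate <- stats::setNames(vector("list", nrow(out)), out$society_id)
  if (!is.null(climate_path)) {
    cl <- utils::read.csv(climate_path, stringsAsFactors = FALSE)
    need <- c("society_id", "year", "month", "temp_c", "precip_mm")
    miss <- setdiff(need, names(cl))
    if (length(miss)) stop("climate file missing column: '", miss[[1]], "'")
    for (id in intersect(unique(cl$society_id), out$society_id)) {
      sub <- cl[cl$society_id == id, ]
      climate[[id]] <- list(
        temp = .long_to_matrix(sub, "temp_c"),
        precip = .long_to_matrix(sub, "precip_mm")
      )
    }
  }
  structure(list(societies = out, climate = climate), class = "society_table")
}

.long_to_matrix <- function(sub, value_col) {
  years <- sort(unique(sub$year))
  m <- matrix(NA_real_, nrow = length(years), ncol = 12,
              dimnames = list(years, NULL))
  m[cbind(match(sub$year, years), sub$month)] <- sub[[value_col]]
  m
}

#' Write a society table (and optional climate companion) to CSV
#'
#' Inverse of [read_society_table()]: numbers are written at full precision so
#' a write/read round trip reproduces all non-missing fields exactly.
#'
#' @param tbl A `society_table`.
#' @param path Output CSV path for the society table.
#' @param climate_path Optional output path for the long-format climate CSV.
#' @return `invisible(tbl)`.
#' @export
write_society_table <- function(tbl, path, climate_path = NULL) {
  stopifnot(inherits(tbl, "society_table"))
  df <- tbl$societies
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17), character(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(climate_path)) {
    rows <- list()
    for (id in names(tbl$climate)) {
      cm <- tbl$climate[[id]]
      if (is.null(cm)) next
      yrs <- as.integer(rownames(cm$temp))
      if (is.null(yrs) || anyNA(yrs)) yrs <- seq_len(nrow(cm$temp))
      grid <- expand.grid(month = 1:12, year = yrs)
      rows[[id]] <- data.frame(
        society_id = id, year = grid$year, month = grid$month,
        temp_c = vapply(seq_len(nrow(grid)), function(i)
          format(cm$temp[match(grid$year[i], yrs), grid$month[i]],
                 digits = 17), character(1)),
        precip_mm = vapply(seq_len(nrow(grid)), function(i)
          format(cm$precip[match(grid$year[i], yrs), grid$month[i]],
                 digits = 17), character(1)),
        stringsAsFactors = FALSE
      )
    }
    long <- do.call(rbind, rows)
    utils::write.csv(long, climate_path, row.names = FALSE, na = "")
  }
  invisible(tbl)
}

validate_societies <- function(df) {
  bad_lon <- which(!is.na(df$lon) & (df$lon < -180 | df$lon > 180))
  if (length(bad_lon)) stop("longitude out of [-180, 180] at row ", bad_lon[1])
  bad_lat <- which(!is.na(df$lat) & (df$lat < -90 | df$lat > 90))
  if (length(bad_lat)) stop("latitude out of [-90, 90] at row ", bad_lat[1])
  for (ea in intersect(.ea_columns, names(df))) {
    bad <- which(!is.na(df[[ea]]) & df[[ea]] < 0)
    if (length(bad)) stop("negative code in ", ea, " at row ", bad[1])
  }
  invisible(df)
}

#' @export
print.society_table <- function(x, ...) {
  n <- nrow(x$societies)
  n_clim <- sum(!vapply(x$climate, is.null, logical(1)))
  cat("society_table:", n, "societies,", n_clim, "with monthly climate\n")
  cat("  language families:",
      length(unique(stats::na.omit(x$societies$language_family))), "\n")
  invisible(x)
}

# Recode maps: raw Ethnographic Atlas integer code -> analysis category.
# Codes outside the mapped sets fall to "excluded" (wall material, reflecting
# the exclusion of rare ice/snow walls) or to missing.
.recode_map <- list(
  ground_plan = c(`1` = "rounded", `2` = "rounded", `3` = "rounded",
                  `4` = "angular", `5` = "angular", `6` = "angular"),
  floor_level = c(`1` = "subterranean", `2` = "ground",
                  `3` = "elevated", `4` = "elevated"),
  wall_material = c(`1` = "thick", `2` = "thick", `9` = "thick",
                    `5` = "wood_bamboo", `6` = "wood_bamboo",
                    `7` = "wood_bamboo", `10` = "fabric_skins",
                    `8` = "thatch"),
  roof_shape = c(`1` = "rounded_domed", `2` = "rounded_domed",
                 `3` = "rounded_domed", `4` = "rounded_domed",
                 `5` = "rounded_domed", `6` = "sloped", `8` = "sloped",
                 `9` = "sloped", `7` = "flat"),
  polygyny = c(`1` = "none", `7` = "none", `2` = "occasional",
               `3` = "frequent", `4` = "frequent", `5` = "frequent",
               `6` = "frequent"),
  settlement = c(`1` = "nomadic", `2` = "nomadic", `3` = "sedentary",
                 `4` = "sedentary", `5` = "sedentary", `6` = "sedentary",
                 `7` = "sedentary", `8` = "sedentary")
)

.trait_levels <- list(
  ground_plan = c("rounded", "angular"),
  floor_level = c("ground", "subterranean", "elevated"),
  wall_material = c("thick", "wood_bamboo", "fabric_skins", "thatch"),
  roof_shape = c("sloped", "rounded_domed", "flat"),
  polygyny = c("none", "occasional", "frequent"),
  settlement = c("sedentary", "nomadic")
)

.recode_one <- function(codes, map, excluded_for_unmapped = FALSE) {
  out <- unname(map[as.character(codes)])
  if (excluded_for_unmapped) {
    unmapped <- is.na(out) & !is.na(codes)
    out[unmapped] <- "excluded"
  }
  out
}

#' Recode raw house-feature codes into analysis categories
#'
#' Maps Ethnographic Atlas integer codes to the four house-feature response
#' variables: ground plan (EA079: 1-3 rounded, 4-6 angular), floor level
#' (EA080: 1 subterranean, 2 ground, 3-4 elevated), wall material (EA081:
#' 1, 2, 9 thick; 5-7 wood/bamboo; 10 fabric/skins; 8 thatch; anything else,
#' e.g. rare ice/snow walls, "excluded") and roof shape (EA082: 1-5
#' rounded/domed, 6, 8, 9 sloped, 7 flat). Unmapped or missing codes become
#' `NA`; "excluded" wall codes are treated as missing by all models.
#'
#' @param df Data frame with columns `ea079`, `ea080`, `ea081`, `ea082`
#'   (a `society_table$societies`), or a `society_table`.
#' @return The data frame with character columns `ground_plan`, `floor_level`,
#'   `wall_material`, `roof_shape` appended.
#' @export
recode_house_traits <- function(df) {
  if (inherits(df, "society_table")) df <- df$societies
  df$ground_plan <- .recode_one(df$ea079, .recode_map$ground_plan)
  df$floor_level <- .recode_one(df$ea080, .recode_map$floor_level)
  df$wall_material <- .recode_one(df$ea081, .recode_map$wall_material,
                                  excluded_for_unmapped = TRUE)
  df$roof_shape <- .recode_one(df$ea082, .recode_map$roof_shape)
  df
}

#' Recode raw social-trait codes into analysis categories
#'
#' Polygyny (EA009: 1, 7 none; 2 occasional; 3-6 frequent), settlement
#' (EA030: 1, 2 nomadic; 3-8 sedentary) and political complexity (EA033,
#' levels of jurisdictional hierarchy beyond the local community, kept as an
#' ordinal 1-5 where 1 = acephalous and 5 = large state).
#'
#' @inheritParams recode_house_traits
#' @return The data frame with `polygyny`, `settlement` (character) and
#'   `political_complexity` (integer 1-5 or `NA`) appended.
#' @export
recode_social_traits <- function(df) {
  if (inherits(df, "society_table")) df <- df$societies
  df$polygyny <- .recode_one(df$ea009, .recode_map$polygyny)
  df$settlement <- .recode_one(df$ea030, .recode_map$settlement)
  pc <- df$ea033
  pc[!is.na(pc) & (pc < 1 | pc > 5)] <- NA_integer_
  df$political_complexity <- as.integer(pc)
  df
}

#' Recode all traits (house + social) in one pass
#'
#' @inheritParams recode_house_traits
#' @return Data frame with all seven recoded trait columns appended.
#' @export
recode_traits <- function(df) {
  recode_social_traits(recode_house_traits(df))
}
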