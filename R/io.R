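# Validated CSV readers and writers for the three core tables:
# observations, sites, species traits.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_row <- function(row, field, msg) {
  stop(sprintf("row %d, field '%s': %s", row, field, msg), call. = FALSE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read transect observations
#'
#' Reads a long-format CSV of butterfly detections, one row per detection
#' event (or per fractional apportioned count). Required columns:
#' `site_id, year, day_of_year, survey_round, taxon_code, species_level,
#' distance_m, count, under_canopy`. Records identified only to a higher
#' taxon (family or genus) carry `species_level = FALSE`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of validated observations with columns
#'   `site_id`, `year`, `day_of_year`, `survey_round`, `taxon_code`,
#'   `resolved_to_species` (logical), `distance_m`, `count`, `under_canopy`.
#' @seealso [write_observations()], [read_sites()], [read_species_traits()]
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "year", "day_of_year", "survey_round",
                      "taxon_code", "species_level", "distance_m", "count",
                      "under_canopy"), "observations")
  out <- data.frame(
    site_id = as.character(df$site_id),
    year = as.integer(df$year),
    day_of_year = as.integer(df$day_of_year),
    survey_round = as.integer(df$survey_round),
    taxon_code = as.character(df$taxon_code),
    resolved_to_species = as.logical(df$species_level),
    distance_m = as.numeric(df$distance_m),
    count = as.numeric(df$count),
    under_canopy = as.logical(df$under_canopy),
    stringsAsFactors = FALSE
  )
  validate_observations(out)
  out
}

validate_observations <- function(obs) {
  for (i in seq_len(nrow(obs))) {
    if (is.na(obs$distance_m[i]) || obs$distance_m[i] < 0) {
      stop_row(i, "distance_m", "perpendicular distance must be >= 0")
    }
    if (is.na(obs$count[i]) || obs$count[i] <= 0) {
      stop_row(i, "count", "count must be > 0")
    }
    if (is.na(obs$day_of_year[i]) || obs$day_of_year[i] < 1L ||
        obs$day_of_year[i] > 366L) {
      stop_row(i, "day_of_year", "day of year must lie in [1, 366]")
    }
    if (is.na(obs$resolved_to_species[i])) {
      stop_row(i, "species_level", "must be TRUE or FALSE")
    }
  }
  invisible(obs)
}

#' Write transect observations
#'
#' Inverse of [read_observations()]: writes the documented CSV schema so
#' that reading the result back reproduces the input field-for-field.
#'
#' @param obs Observations data.frame as returned by [read_observations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  out <- data.frame(
    site_id = obs$site_id,
    year = obs$year,
    day_of_year = obs$day_of_year,
    survey_round = obs$survey_round,
    taxon_code = obs$taxon_code,
    species_level = obs$resolved_to_species,
    distance_m = obs$distance_m,
    count = obs$count,
    under_canopy = obs$under_canopy,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site attributes
#'
#' Reads the site table: coordinates, transect length, canopy cover,
#' habitat class (one of open, savanna, woodland, scrub, forest) and the
#' site-level covariates consumed by downstream models.
#'
#' @param path Path to a CSV file with columns `site_id, x_m, y_m,
#'   transect_length_m, canopy_cover_pct, habitat, fire2, fire15, veg_short,
#'   veg_tall, litter, habitat_diversity, developed_pct, agriculture_pct`.
#' @return A validated data.frame, one row per site.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "x_m", "y_m", "transect_length_m",
                      "canopy_cover_pct", "habitat", "fire2", "fire15",
                      "veg_short", "veg_tall", "litter", "habitat_diversity",
                      "developed_pct", "agriculture_pct"), "sites")
  df$site_id <- as.character(df$site_id)
  validate_sites(df)
  df
}

validate_sites <- function(sites) {
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(sites))) {
    if (is.na(sites$transect_length_m[i]) || sites$transect_length_m[i] <= 0) {
      stop_row(i, "transect_length_m", "transect length must be > 0")
    }
    cc <- sites$canopy_cover_pct[i]
    if (is.na(cc) || cc < 0 || cc > 100) {
      stop_row(i, "canopy_cover_pct", "canopy cover must lie in [0, 100]")
    }
    if (!sites$habitat[i] %in% HABITAT_LEVELS) {
      stop_row(i, "habitat", paste0("unknown habitat class '",
                                    sites$habitat[i], "'"))
    }
  }
  invisible(sites)
}

#' Write site attributes
#' @param sites Site data.frame as returned by [read_sites()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read species traits
#'
#' Reads the species trait table (taxonomy plus raw NatureServe rank
#' string). The numeric reversed rank used by the conservation value index
#' is computed on demand by [reversed_rank()].
#'
#' @param path Path to a CSV file with columns
#'   `species_code, family, natureserve_rank`.
#' @return A validated data.frame, one row per species.
#' @export
read_species_traits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("species_code", "family", "natureserve_rank"),
                "species traits")
  df$species_code <- as.character(df$species_code)
  df$family <- as.character(df$family)
  df$natureserve_rank <- as.character(df$natureserve_rank)
  if (anyDuplicated(df$species_code)) {
    stop("duplicate species_code in trait table", call. = FALSE)
  }
  # fail fast on unparsable rank strings
  for (i in seq_len(nrow(df))) {
    tryCatch(reversed_rank(df$natureserve_rank[i]),
             error = function(e) stop_row(i, "natureserve_rank",
                                          conditionMessage(e)))
  }
  df
}

#' Write species traits
#' @param traits Trait data.frame as returned by [read_species_traits()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_traits <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
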