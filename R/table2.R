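# Packaged replica of the published density table: 61 species with mean
# per-survey densities (ha^-1), raw counts, max-group indicator habitat and
# fitted effective strip widths from the original field study.

#' Load the packaged 61-species density table
#'
#' Returns the package's read-only replica of the published table of
#' estimated butterfly densities across 25 northwest-Indiana sites:
#' per species, the family, common and scientific name, mean density
#' (ha^-1) with its standard error and rank, the raw count, the habitat
#' with the highest indicator value (`max_group`, with its significance
#' flag), and the effective strip width in metres (`esw`; `esw_pooled`
#' marks values shared across a taxonomically pooled detection group).
#'
#' @return A data.frame with 61 rows and columns `family`, `common_name`,
#'   `species_name`, `mean_density`, `density_se`, `density_rank`, `counts`,
#'   `max_group`, `max_group_significance`, `esw`, `esw_pooled`.
#' @examples
#' t2 <- load_table2_fixture()
#' sum(t2$counts)        # total butterflies counted
#' range(t2$esw)         # spread of effective strip widths (m)
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_fixture.csv", package = "canopyfly")
  if (path == "") stop("packaged density table not found", call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(
                   family = "character", common_name = "character",
                   species_name = "character", mean_density = "numeric",
                   density_se = "numeric", density_rank = "integer",
                   counts = "integer", max_group = "character",
                   max_group_significance = "character", esw = "numeric",
                   esw_pooled = "logical"))
  df$max_group_significance[is.na(df$max_group_significance)] <- ""
  validate_table2(df)
  df
}

# Structural integrity check; any failure means the shipped file was altered.
validate_table2 <- function(df) {
  ok <- nrow(df) == 61L &&
    !anyNA(df$counts) && all(df$counts >= 1L) &&
    !anyNA(df$esw) && all(df$esw > 0) &&
    !anyNA(df$mean_density) && all(df$mean_density > 0) &&
    all(tolower(df$max_group) %in% HABITAT_LEVELS) &&
    !anyDuplicated(df$species_name)
  if (!ok) {
    stop("packaged density table failed its integrity check (corrupted fixture?)",
         call. = FALSE)
  }
  invisible(df)
}

#' Load packaged NatureServe ranks for the 61 observed species
#'
#' Species trait table (family and raw NatureServe G/T rank string) for the
#' species of [load_table2_fixture()], as reported for 2017: all species
#' G5 (secure) except a small set of vulnerable or imperiled taxa.
#'
#' @return A data.frame with columns `species_code`, `family`,
#'   `natureserve_rank`, suitable for [read_species_traits()] consumers.
#' @export
load_natureserve_ranks <- function() {
  path <- system.file("extdata", "natureserve_ranks.csv",
                      package = "canopyfly")
  if (path == "") stop("packaged rank table not found", call. = FALSE)
  read_species_traits(path)
}
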