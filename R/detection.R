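# Distance-sampling engine: taxonomic pooling of sparse species,
# half-normal detection fits, effective strip widths, apportionment of
# records identified only to higher taxa, and the surveys x species
# density table.

genus_of <- function(species_code) {
  vapply(strsplit(species_code, "[ _]"), `[`, character(1), 1)
}

#' Pool species into detection groups
#'
#' Species with at least `min_detections` species-level distance records
#' (and no sparse congeners) stand alone. Sparser species climb a
#' taxonomic ladder: all members of a genus containing a sparse species
#' form one genus group if the genus's pooled detections reach the
#' threshold; otherwise the leftover species of a family pool together,
#' and failing that a single global pool absorbs the rest. The result is a
#' true partition: every species belongs to exactly one group, and a
#' group's members share one detection fit (hence one effective strip
#' width).
#'
#' @param obs Observations (only `resolved_to_species` rows are counted).
#' @param traits Trait table giving `family` for every `species_code`;
#'   genus is taken as the first word of the species code.
#' @param min_detections Minimum detections for a stand-alone fit
#'   (default 30).
#' @return Data.frame with columns `species_code`, `group_id`,
#'   `n_detections` (per species).
#' @export
pool_species <- function(obs, traits, min_detections = 30) {
  sp_obs <- obs[obs$resolved_to_species, , drop = FALSE]
  species <- unique(sp_obs$taxon_code)
  missing <- setdiff(species, traits$species_code)
  if (length(missing) > 0L) {
    stop("species absent from trait table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(sp_obs$taxon_code, levels = species))
  fam <- traits$family[match(species, traits$species_code)]
  gen <- genus_of(species)
  n <- as.integer(counts)
  group <- rep(NA_character_, length(species))

  sparse <- n < min_detections
  # genus groups: any genus containing a sparse member pools whole if the
  # pooled total reaches the threshold
  for (g in unique(gen)) {
    idx <- which(gen == g)
    if (any(sparse[idx]) && sum(n[idx]) >= min_detections &&
        length(idx) > 1L) {
      group[idx] <- paste0("genus:", g)
    }
  }
  # adequate species not absorbed above stand alone
  solo <- is.na(group) & !sparse
  group[solo] <- paste0("species:", species[solo])
  # family groups for the remaining sparse species
  for (f in unique(fam)) {
    idx <- which(fam == f & is.na(group))
    if (length(idx) > 0L && sum(n[idx]) >= min_detections) {
      group[idx] <- paste0("family:", f)
    }
  }
  # everything still unassigned joins one global pool
  group[is.na(group)] <- "global"
  data.frame(species_code = species, group_id = group, n_detections = n,
             stringsAsFactors = FALSE)
}

#' Fit a half-normal detection function
#'
#' Maximum-likelihood fit of the half-normal detection function
#' g(x) = exp(-x^2 / (2 sigma^2)) to perpendicular distances, optionally
#' truncated at `w`. Untruncated (w = Inf) the MLE has the closed form
#' sigma = sqrt(sum(x^2)/n); truncated fits maximize the likelihood
#' numerically.
#'
#' @param distances Perpendicular distances in metres, all in `[0, w]`.
#' @param truncation Truncation distance w (default `Inf`).
#' @param min_detections Minimum sample size to attempt a fit.
#' @return An object of class `"halfnormal_fit"`: list with `sigma`,
#'   `truncation`, `esw` (effective strip width, m), `n_detections`,
#'   `log_likelihood`.
#' @export
fit_halfnormal <- function(distances, truncation = Inf, min_detections = 1) {
  x <- distances
  if (length(x) < min_detections) {
    stop("too few detections for a detection fit", call. = FALSE)
  }
  if (any(x < 0) || any(x > truncation)) {
    stop("distances must lie in [0, truncation]", call. = FALSE)
  }
  if (all(x == 0)) {
    stop("degenerate fit: all distances are zero", call. = FALSE)
  }
  w <- truncation
  if (is.infinite(w)) {
    sigma <- sqrt(sum(x^2) / length(x))
  } else {
    nll <- function(log_sigma) {
      s <- exp(log_sigma)
      length(x) * log(hn_integral(s, w)) + sum(x^2) / (2 * s^2)
    }
    s0 <- sqrt(sum(x^2) / length(x))
    opt <- optimize(nll, interval = log(c(s0 / 50, max(s0 * 50, w))))
    sigma <- exp(opt$minimum)
  }
  ll <- -(length(x) * log(hn_integral(sigma, w)) + sum(x^2) / (2 * sigma^2))
  fit <- structure(list(sigma = sigma, truncation = w,
                        n_detections = length(x), log_likelihood = ll),
                   class = "halfnormal_fit")
  fit$esw <- effective_strip_width(fit)
  fit
}

# integral of exp(-x^2/(2 s^2)) from 0 to w
hn_integral <- function(sigma, w) {
  if (is.infinite(w)) sigma * sqrt(pi / 2)
  else sigma * sqrt(2 * pi) * (pnorm(w / sigma) - 0.5)
}

#' Effective strip width of a detection fit
#'
#' ESW = integral of the detection function g(x) from 0 to the truncation
#' distance: the strip half-width at which the expected number of
#' individuals detected beyond it equals the number missed within it.
#' For the half-normal, ESW = sigma * sqrt(pi/2) untruncated, and
#' approaches w as detection becomes perfect out to the truncation.
#'
#' @param fit A `"halfnormal_fit"` object.
#' @return ESW in metres.
#' @export
effective_strip_width <- function(fit) {
  hn_integral(fit$sigma, fit$truncation)
}

#' @export
print.halfnormal_fit <- function(x, ...) {
  cat(sprintf(
    "Half-normal detection fit: sigma = %.3f m, ESW = %.3f m (n = %d%s)\n",
    x$sigma, x$esw, x$n_detections,
    if (is.finite(x$truncation)) sprintf(", w = %g m", x$truncation) else ""))
  invisible(x)
}

#' @export
coef.halfnormal_fit <- function(object, ...) c(sigma = object$sigma)

#' @export
logLik.halfnormal_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 1L, nobs = object$n_detections,
            class = "logLik")
}

#' Fit detection functions for all pooled groups
#'
#' Convenience wrapper: partitions species with [pool_species()] and fits
#' one half-normal per group from the pooled species-level distances.
#'
#' @inheritParams pool_species
#' @param truncation Truncation distance (default `Inf`).
#' @return List with `groups` (the pooling table, plus each species' `esw`)
#'   and `fits` (named list of `"halfnormal_fit"` objects by `group_id`).
#' @export
fit_detection <- function(obs, traits, min_detections = 30,
                          truncation = Inf) {
  pools <- pool_species(obs, traits, min_detections)
  sp_obs <- obs[obs$resolved_to_species, , drop = FALSE]
  grp <- pools$group_id[match(sp_obs$taxon_code, pools$species_code)]
  fits <- lapply(split(sp_obs$distance_m, grp), fit_halfnormal,
                 truncation = truncation)
  pools$esw <- vapply(pools$group_id, function(g) fits[[g]]$esw, numeric(1))
  list(groups = pools, fits = fits)
}

#' Apportion records identified only to a higher taxon
#'
#' Splits the count of each family- or genus-level record among the
#' species of that taxon identified at the same site on the same day,
#' proportionally to their identified counts (fractional counts result).
#' Records with no same-site-same-day identified candidate are dropped;
#' the dropped rows are attached as attribute `"dropped"` (with a
#' `drop_reason` column) so that total counts are conserved:
#' input total = output total + dropped total.
#'
#' @param obs Observations data.frame; rows with
#'   `resolved_to_species = FALSE` carry a family name (or genus) in
#'   `taxon_code`.
#' @param traits Trait table used to resolve which species belong to a
#'   higher taxon (family match first, then genus).
#' @return Observations with all rows at species level; apportioned rows
#'   keep the donor's site/day/distance and gain fractional counts.
#' @export
apportion_unidentified <- function(obs, traits) {
  unid <- which(!obs$resolved_to_species)
  if (length(unid) == 0L) return(obs)
  id_rows <- obs[obs$resolved_to_species, , drop = FALSE]
  out <- list(id_rows)
  dropped <- list()
  for (i in unid) {
    code <- obs$taxon_code[i]
    members <- traits$species_code[traits$family == code]
    if (length(members) == 0L) {
      members <- traits$species_code[genus_of(traits$species_code) == code]
    }
    if (length(members) == 0L) {
      stop(sprintf("higher taxon '%s' has no candidate species", code),
           call. = FALSE)
    }
    cand <- id_rows[id_rows$site_id == obs$site_id[i] &
                      id_rows$year == obs$year[i] &
                      id_rows$day_of_year == obs$day_of_year[i] &
                      id_rows$taxon_code %in% members, , drop = FALSE]
    if (nrow(cand) == 0L) {
      row <- obs[i, , drop = FALSE]
      row$drop_reason <- "no same-site-same-day identified candidates"
      dropped[[length(dropped) + 1L]] <- row
      next
    }
    by_sp <- tapply(cand$count, cand$taxon_code, sum)
    share <- obs$count[i] * by_sp / sum(by_sp)
    add <- obs[rep(i, length(share)), , drop = FALSE]
    add$taxon_code <- names(share)
    add$count <- as.numeric(share)
    add$resolved_to_species <- TRUE
    out[[length(out) + 1L]] <- add
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- if (length(dropped) > 0L) {
    dr <- do.call(rbind, dropped)
    rownames(dr) <- NULL
    dr
  } else NULL
  res
}

#' Per-survey density table
#'
#' Converts apportioned counts to densities with the distance-sampling
#' estimator D = 10^4 * n / (2 L ESW) (n the possibly fractional count per
#' survey and species, L the transect length in m, ESW in m, D in
#' individuals per hectare). Every site x survey-round combination gets a
#' row; species not observed in a survey get density 0.
#'
#' @param obs Species-level observations (run [apportion_unidentified()]
#'   first if needed).
#' @param sites Site table with `site_id` and `transect_length_m`.
#' @param detection Result of [fit_detection()] (or a list with a `groups`
#'   data.frame carrying `species_code` and `esw`).
#' @return A data.frame of class `"density_table"`: metadata columns
#'   `site_id`, `survey_round`, `year`, `day_of_year`, then one numeric
#'   density column per species.
#' @export
estimate_densities <- function(obs, sites, detection) {
  if (any(!obs$resolved_to_species)) {
    stop("observations still contain higher-taxon records; apportion first",
         call. = FALSE)
  }
  esw_map <- setNames(detection$groups$esw, detection$groups$species_code)
  species <- sort(unique(obs$taxon_code))
  no_fit <- setdiff(species, names(esw_map))
  if (length(no_fit) > 0L) {
    stop("no detection fit for observed species: ",
         paste(no_fit, collapse = ", "), call. = FALSE)
  }
  L <- setNames(sites$transect_length_m, sites$site_id)
  rounds <- sort(unique(obs$survey_round))
  # survey calendar: one (year, day) per round, taken from the observations
  cal <- unique(obs[, c("survey_round", "year", "day_of_year")])
  cal <- cal[!duplicated(cal$survey_round), , drop = FALSE]
  grid <- expand.grid(site_id = sites$site_id, survey_round = rounds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$year <- cal$year[match(grid$survey_round, cal$survey_round)]
  grid$day_of_year <- cal$day_of_year[match(grid$survey_round,
                                            cal$survey_round)]
  dens <- matrix(0, nrow = nrow(grid), ncol = length(species),
                 dimnames = list(NULL, species))
  key_grid <- paste(grid$site_id, grid$survey_round)
  key_obs <- paste(obs$site_id, obs$survey_round)
  n_tab <- tapply(obs$count, list(key_obs, obs$taxon_code), sum)
  hit <- match(rownames(n_tab), key_grid)
  for (j in seq_along(species)) {
    nj <- n_tab[, species[j]]
    nj[is.na(nj)] <- 0
    dens[hit, j] <- nj
  }
  site_L <- L[grid$site_id]
  dens <- dens * 1e4 / (2 * site_L)
  dens <- sweep(dens, 2, esw_map[species], "/")
  out <- cbind(grid, as.data.frame(dens, check.names = FALSE))
  class(out) <- c("density_table", "data.frame")
  out
}

#' Species density columns of a density table
#' @param dt A `"density_table"`.
#' @return Numeric matrix (surveys x species).
#' @export
density_matrix <- function(dt) {
  meta <- c("site_id", "survey_round", "year", "day_of_year")
  as.matrix(as.data.frame(dt)[, setdiff(names(dt), meta), drop = FALSE])
}

#' Per-survey and per-site community metrics from a density table
#'
#' Per survey: richness (species with nonzero density), total density
#' (ha^-1), and CVI (if `traits` supplies NatureServe ranks). Per site:
#' the mean of each per-survey metric across rounds, plus ACE richness
#' from raw integer counts when `obs` is supplied.
#'
#' @param dt A `"density_table"` from [estimate_densities()].
#' @param traits Optional trait table with `natureserve_rank` for the CVI.
#' @param obs Optional species-level observations for site-level ACE.
#' @param sites Optional site table; adds `canopy_cover_pct` and `habitat`
#'   to the site summary.
#' @return List with data.frames `survey` and `site`.
#' @export
community_metrics <- function(dt, traits = NULL, obs = NULL, sites = NULL) {
  m <- density_matrix(dt)
  survey <- data.frame(site_id = dt$site_id, survey_round = dt$survey_round,
                       year = dt$year, day_of_year = dt$day_of_year,
                       richness = rowSums(m > 0),
                       total_density = rowSums(m),
                       stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    rk <- reversed_rank(
      traits$natureserve_rank[match(colnames(m), traits$species_code)])
    if (anyNA(rk)) {
      stop("species missing from trait table for CVI", call. = FALSE)
    }
    survey$cvi <- apply(m, 1, conservation_value_index, ranks = rk)
  }
  site <- aggregate(survey[, setdiff(names(survey),
                                     c("site_id", "survey_round", "year",
                                       "day_of_year")), drop = FALSE],
                    by = list(site_id = survey$site_id), FUN = mean)
  names(site)[-1] <- paste0("mean_", names(site)[-1])
  if (!is.null(obs)) {
    ace <- vapply(site$site_id, function(s) {
      ab <- tapply(obs$count[obs$site_id == s],
                   obs$taxon_code[obs$site_id == s], sum)
      ace_richness(round(as.numeric(ab)))
    }, numeric(1))
    site$ace_richness <- ace
  }
  if (!is.null(sites)) {
    site$canopy_cover_pct <-
      sites$canopy_cover_pct[match(site$site_id, sites$site_id)]
    site$habitat <- sites$habitat[match(site$site_id, sites$site_id)]
  }
  list(survey = survey, site = site)
}
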