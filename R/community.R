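# Community metrics: reversed NatureServe ranks, the conservation value
# index (CVI), ACE richness, species accumulation curves, under-canopy
# percentages, and inverse-distance plot averaging.

#' Reversed numeric NatureServe rank
#'
#' Parses a NatureServe G/T rank string and returns the reversed numeric
#' rank used as a conservation weight: the native scale runs G1 (critically
#' imperiled) to G5 (secure); after reversal scores run 1 (secure) to
#' 5 (critically imperiled). Grammar: plain `"Gk"` gives k; a range
#' `"GjGk"` gives the midpoint (j + k)/2; an infraspecific `"GkTm"` gives
#' m (the T rank describes the surveyed population and overrides the
#' species-level G rank). The reversed rank is 6 minus the numeric rank.
#'
#' @param rank_raw Character vector of rank strings, e.g. `"G5"`, `"G3G4"`,
#'   `"G5T2"`.
#' @return Numeric vector of reversed ranks in `[1, 5]`.
#' @examples
#' reversed_rank(c("G5", "G3G4", "G5T2", "G4T1"))  # 1, 2.5, 4, 5
#' @export
reversed_rank <- function(rank_raw) {
  vapply(rank_raw, function(r) {
    if (is.na(r)) stop("missing NatureServe rank", call. = FALSE)
    r <- gsub("\\s", "", r)
    if (grepl("^G[1-5]T[1-5]$", r)) {
      num <- as.numeric(substr(r, 4, 4))        # T overrides G
    } else if (grepl("^G[1-5]G[1-5]$", r)) {
      num <- (as.numeric(substr(r, 2, 2)) + as.numeric(substr(r, 4, 4))) / 2
    } else if (grepl("^G[1-5]$", r)) {
      num <- as.numeric(substr(r, 2, 2))
    } else {
      stop(sprintf("unparsable NatureServe rank '%s'", r), call. = FALSE)
    }
    6 - num
  }, numeric(1), USE.NAMES = FALSE)
}

#' Conservation value index (CVI)
#'
#' Density-weighted sum of reversed NatureServe ranks over the imperiled
#' part of the community: CVI = sum over species with reversed rank r > 2
#' (vulnerable, imperiled or critically imperiled) of r times that
#' species' density. Species at or below r = 2 contribute nothing.
#'
#' @param densities Named or unnamed numeric vector of species densities
#'   (ha^-1) for one survey.
#' @param ranks Numeric vector of reversed ranks, aligned with `densities`.
#' @return The CVI, a nonnegative scalar.
#' @examples
#' conservation_value_index(c(2, 1, 10), c(3, 5, 2))  # 3*2 + 5*1 = 11
#' @export
conservation_value_index <- function(densities, ranks) {
  if (length(densities) != length(ranks)) {
    stop("densities and ranks must align species-for-species", call. = FALSE)
  }
  if (anyNA(ranks)) stop("species missing a reversed rank", call. = FALSE)
  keep <- ranks > 2
  sum(ranks[keep] * densities[keep])
}

#' ACE estimate of asymptotic species richness
#'
#' Abundance-based Coverage Estimator. With rare species defined as those
#' of abundance at most `rare_cutoff`, sample coverage C = 1 - F1/N_rare
#' (F1 singletons, N_rare individuals in rare species),
#' S_ACE = S_abund + S_rare/C + (F1/C) * gamma^2, where gamma^2 is the
#' estimated squared coefficient of variation of the rare-species
#' abundances, floored at zero.
#'
#' @param abundances Nonnegative integer abundances, one per species
#'   (zeros are ignored).
#' @param rare_cutoff Abundance at or below which a species counts as rare
#'   (classical convention: 10).
#' @return Estimated richness (at least the observed richness).
#' @examples
#' ace_richness(c(1, 1, 2, 3, 12, 20))  # about 7.79
#' @export
ace_richness <- function(abundances, rare_cutoff = 10) {
  if (any(abundances < 0) || any(abundances != round(abundances))) {
    stop("abundances must be nonnegative integers", call. = FALSE)
  }
  n <- abundances[abundances > 0]
  rare <- n[n <= rare_cutoff]
  abund <- n[n > rare_cutoff]
  if (length(rare) == 0L) return(length(abund))
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  C <- 1 - F1 / N_rare
  if (C <= 0) {
    stop("ACE undefined: all rare individuals are singletons (coverage 0)",
         call. = FALSE)
  }
  Fi <- tabulate(rare, nbins = rare_cutoff)
  ss <- sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * Fi)
  gamma2 <- max(length(rare) / C * ss / (N_rare * (N_rare - 1)) - 1, 0)
  length(abund) + length(rare) / C + F1 / C * gamma2
}

#' Species accumulation curve
#'
#' Mean and variance of the number of species accumulated as sampling
#' effort grows, over random orderings. Two effort currencies:
#' `mode = "sites"` accumulates whole sites in random order (species
#' density); `mode = "individuals"` draws individuals without replacement
#' from the pooled abundances (rarefaction-style species richness).
#' When the number of site orderings is small enough
#' (factorial(n sites) <= `n_randomizations`) the site mode enumerates all
#' orderings exactly instead of sampling.
#'
#' @param x For `"sites"`: a sites x species abundance (or incidence)
#'   matrix. For `"individuals"`: either such a matrix (columns are summed)
#'   or a named abundance vector.
#' @param mode `"sites"` or `"individuals"`.
#' @param effort Integer vector of efforts at which to evaluate the curve;
#'   defaults to every site count, or 25 equally spaced individual counts.
#' @param n_randomizations Number of random orderings (default 200).
#' @param seed Optional integer seed for reproducible orderings.
#' @return An object of class `"accumulation_curve"`: a list with `mode`,
#'   `effort`, `mean`, `var`, `n_randomizations`.
#' @export
accumulation_curve <- function(x, mode = c("sites", "individuals"),
                               effort = NULL, n_randomizations = 200,
                               seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "sites") {
    m <- as.matrix(x)
    n_sites <- nrow(m)
    if (is.null(effort)) effort <- seq_len(n_sites)
    if (any(effort < 1) || any(effort > n_sites)) {
      stop("effort outside the available number of sites", call. = FALSE)
    }
    orderings <- if (factorial(n_sites) <= n_randomizations) {
      all_permutations(n_sites)
    } else {
      lapply(seq_len(n_randomizations), function(i) sample.int(n_sites))
    }
    acc <- vapply(orderings, function(ord) {
      cum <- matrixStats_cum_species(m[ord, , drop = FALSE])
      cum[effort]
    }, numeric(length(effort)))
  } else {
    ab <- if (is.matrix(x) || is.data.frame(x)) colSums(as.matrix(x)) else x
    ab <- round(ab)
    total <- sum(ab)
    if (is.null(effort)) {
      effort <- unique(round(seq(1, total, length.out = min(25, total))))
    }
    if (any(effort < 1) || any(effort > total)) {
      stop("effort outside the available number of individuals",
           call. = FALSE)
    }
    ids <- rep.int(seq_along(ab), ab)
    acc <- vapply(seq_len(n_randomizations), function(i) {
      perm <- sample(ids)
      first_seen <- !duplicated(perm)
      cum <- cumsum(first_seen)
      cum[effort]
    }, numeric(length(effort)))
  }
  acc <- matrix(acc, nrow = length(effort))
  structure(list(mode = mode, effort = effort,
                 mean = rowMeans(acc),
                 var = if (ncol(acc) > 1L) apply(acc, 1, var)
                       else rep(0, nrow(acc)),
                 n_randomizations = ncol(acc)),
            class = "accumulation_curve")
}

# species accumulated after 1..n sites of a fixed ordering
matrixStats_cum_species <- function(m) {
  present <- m > 0
  seen <- rep(FALSE, ncol(m))
  out <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    seen <- seen | present[i, ]
    out[i] <- sum(seen)
  }
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Species accumulation curve (%s mode, %d randomizations)\n",
              x$mode, x$n_randomizations))
  cat(sprintf("  effort %d..%d; species %.2f..%.2f\n",
              min(x$effort), max(x$effort), min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.accumulation_curve <- function(x, ...) {
  ci <- 1.96 * sqrt(x$var)
  plot(x$effort, x$mean, type = "l", xlab = x$mode, ylab = "species",
       ylim = range(c(x$mean - ci, x$mean + ci)), ...)
  graphics::lines(x$effort, x$mean + ci, lty = 2)
  graphics::lines(x$effort, x$mean - ci, lty = 2)
  invisible(x)
}

curve_at_effort <- function(curve, effort) {
  i <- match(effort, curve$effort)
  if (is.na(i)) stop("curve not evaluated at that effort", call. = FALSE)
  c(mean = curve$mean[i], var = curve$var[i])
}

#' z-test comparison of two accumulation curves at a common effort
#'
#' Compares mean accumulated species between two curves at the same effort
#' with z = (meanA - meanB) / sqrt(varA + varB) and a two-sided normal p.
#'
#' @param curveA,curveB Objects from [accumulation_curve()], evaluated at
#'   `effort`.
#' @param effort Common effort at which to compare.
#' @return List with `z` and `p`.
#' @seealso [compare_richness_pairwise()] for the all-pairs battery with
#'   Benjamini-Hochberg adjustment.
#' @export
compare_richness_at_effort <- function(curveA, curveB, effort) {
  a <- curve_at_effort(curveA, effort)
  b <- curve_at_effort(curveB, effort)
  v <- a[["var"]] + b[["var"]]
  if (v <= 0) stop("zero combined variance at this effort", call. = FALSE)
  z <- (a[["mean"]] - b[["mean"]]) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pairwise accumulation-curve comparisons with B-H adjustment
#'
#' @param curves Named list of accumulation curves (e.g. one per habitat).
#' @param effort Common effort at which to compare all pairs.
#' @return Data.frame with one row per unordered pair: `groupA`, `groupB`,
#'   `z`, `p_raw`, `p_adj` (Benjamini-Hochberg across pairs).
#' @export
compare_richness_pairwise <- function(curves, effort) {
  nm <- names(curves)
  pairs <- utils::combn(nm, 2)
  res <- apply(pairs, 2, function(pr) {
    cmp <- compare_richness_at_effort(curves[[pr[1]]], curves[[pr[2]]],
                                      effort)
    c(z = cmp$z, p = cmp$p)
  })
  out <- data.frame(groupA = pairs[1, ], groupB = pairs[2, ],
                    z = res["z", ], p_raw = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- benjamini_hochberg(out$p_raw)
  out
}

#' Under-canopy observation percentages by family
#'
#' For each family: the overall percentage of observations made directly
#' below tree or shrub canopy (all observations pooled), and the unweighted
#' mean (with SE) of per-species percentages over species with more than
#' `min_obs` observations.
#'
#' @param obs Observations data.frame (needs `taxon_code`, `under_canopy`,
#'   `count`, `resolved_to_species`).
#' @param traits Species trait table mapping `species_code` to `family`.
#' @param min_obs Species enter the species-mean only with more than this
#'   many observations (default 20).
#' @return Data.frame with one row per family: `family`, `overall_pct`,
#'   `n_overall`, `species_mean_pct`, `species_se_pct`, `n_species`.
#' @export
under_canopy_summary <- function(obs, traits, min_obs = 20) {
  obs <- obs[obs$resolved_to_species, , drop = FALSE]
  fam <- traits$family[match(obs$taxon_code, traits$species_code)]
  if (anyNA(fam)) {
    stop("species absent from trait table: ",
         paste(unique(obs$taxon_code[is.na(fam)]), collapse = ", "),
         call. = FALSE)
  }
  w <- obs$count
  res <- lapply(split(seq_len(nrow(obs)), fam), function(idx) {
    n_overall <- sum(w[idx])
    overall <- 100 * sum(w[idx] * obs$under_canopy[idx]) / n_overall
    per_sp <- vapply(split(idx, obs$taxon_code[idx]), function(j) {
      c(n = sum(w[j]), pct = 100 * sum(w[j] * obs$under_canopy[j]) / sum(w[j]))
    }, numeric(2))
    keep <- per_sp["n", ] > min_obs
    pcts <- per_sp["pct", keep]
    data.frame(overall_pct = overall, n_overall = n_overall,
               species_mean_pct = if (any(keep)) mean(pcts) else NA_real_,
               species_se_pct = if (sum(keep) > 1) sd(pcts) / sqrt(sum(keep))
                                else NA_real_,
               n_species = sum(keep))
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(family = names(res), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Inverse-distance-weighted site average
#'
#' Averages plot-level measurements across a site with weights proportional
#' to the inverse of each plot's distance from the transect centre
#' (exponent 1): sum(v/d) / sum(1/d).
#'
#' @param values Numeric plot measurements.
#' @param distances Positive distances (m) of each plot from the transect
#'   centre.
#' @return The weighted mean.
#' @examples
#' idw_site_average(c(0, 10), c(1, 2))  # 10/3
#' @export
idw_site_average <- function(values, distances) {
  if (length(values) != length(distances)) {
    stop("values and distances must have equal length", call. = FALSE)
  }
  if (any(distances <= 0)) stop("all distances must be > 0", call. = FALSE)
  sum(values / distances) / sum(1 / distances)
}
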