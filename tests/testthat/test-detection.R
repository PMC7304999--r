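test_that("untruncated half-normal MLE matches the closed form", {
  fit <- fit_halfnormal(c(1, 2, 2, 3))
  expect_equal(fit$sigma, sqrt(4.5), tolerance = 1e-10)
  expect_equal(fit$sigma, 2.1213, tolerance = 1e-4)
  # cross-check against direct numeric likelihood maximization
  nll <- function(s) {
    length(c(1, 2, 2, 3)) * log(s * sqrt(pi / 2)) +
      sum(c(1, 2, 2, 3)^2) / (2 * s^2)
  }
  opt <- optimize(nll, c(0.1, 20))
  expect_equal(fit$sigma, opt$minimum, tolerance = 1e-4)
})

test_that("degenerate distance sets are refused", {
  expect_error(fit_halfnormal(c(0, 0, 0)), "degenerate")
  expect_error(fit_halfnormal(c(1, 2), min_detections = 5), "too few")
  expect_error(fit_halfnormal(c(1, 9), truncation = 5), "truncation")
})

test_that("fitted sigma recovers the generating sigma", {
  set.seed(17)
  x <- abs(rnorm(500, 0, 3))
  fit <- fit_halfnormal(x)
  expect_lt(abs(fit$sigma - 3) / 3, 0.1)
  # truncated fit agrees
  xt <- x[x <= 8]
  fit_t <- fit_halfnormal(xt, truncation = 8)
  expect_lt(abs(fit_t$sigma - 3) / 3, 0.1)
})

test_that("effective strip width matches quadrature and its limits", {
  fit <- fit_halfnormal(c(1, 2, 2, 3))
  expect_equal(fit$esw, 2.659, tolerance = 1e-3)
  expect_equal(fit$esw, fit$sigma * sqrt(pi / 2), tolerance = 1e-10)
  # quadrature oracle for a truncated fit
  fit_t <- list(sigma = 2.5, truncation = 4)
  esw_t <- effective_strip_width(fit_t)
  quad <- integrate(function(x) exp(-x^2 / (2 * 2.5^2)), 0, 4)$value
  expect_equal(esw_t, quad, tolerance = 1e-8)
  # near-perfect detection out to the truncation distance
  expect_equal(effective_strip_width(list(sigma = 1e6, truncation = 5)), 5,
               tolerance = 1e-6)
  # esw <= sigma * sqrt(pi/2) always, and monotone in sigma and w
  sig <- seq(0.5, 8, by = 0.5)
  esws <- vapply(sig, function(s)
    effective_strip_width(list(sigma = s, truncation = 6)), numeric(1))
  expect_true(all(diff(esws) > 0))
  expect_true(all(esws <= sig * sqrt(pi / 2) + 1e-12))
  ws <- c(1, 2, 4, 8, Inf)
  esww <- vapply(ws, function(w)
    effective_strip_width(list(sigma = 3, truncation = w)), numeric(1))
  expect_true(all(diff(esww) > 0))
})

make_pool_obs <- function(counts) {
  # counts: named vector species -> number of detections
  do.call(rbind, lapply(names(counts), function(sp) {
    n <- counts[[sp]]
    data.frame(site_id = "A", year = 1998L, day_of_year = 150L,
               survey_round = 1L, taxon_code = sp,
               resolved_to_species = TRUE,
               distance_m = seq(0.5, 3, length.out = n),
               count = 1, under_canopy = FALSE, stringsAsFactors = FALSE)
  }))
}

test_that("pooling climbs the genus-family-global ladder", {
  traits <- data.frame(
    species_code = c("Colias eurytheme", "Colias philodice",
                     "Pieris rapae", "Papilio glaucus", "Papilio troilus"),
    family = c("Pieridae", "Pieridae", "Pieridae", "Papilionidae",
               "Papilionidae"),
    natureserve_rank = "G5", stringsAsFactors = FALSE)

  # abundant loner stands alone
  obs <- make_pool_obs(c("Pieris rapae" = 100))
  p <- pool_species(obs, traits, min_detections = 30)
  expect_equal(p$group_id, "species:Pieris rapae")

  # sparse species pools with its abundant congener
  obs <- make_pool_obs(c("Colias eurytheme" = 60, "Colias philodice" = 5,
                         "Pieris rapae" = 100))
  p <- pool_species(obs, traits, min_detections = 30)
  expect_equal(p$group_id[p$species_code == "Colias philodice"],
               p$group_id[p$species_code == "Colias eurytheme"])
  expect_equal(p$group_id[p$species_code == "Pieris rapae"],
               "species:Pieris rapae")

  # sparse genus falls through to family, then to the global pool
  obs <- make_pool_obs(c("Colias philodice" = 5, "Pieris rapae" = 40,
                         "Papilio glaucus" = 3))
  p <- pool_species(obs, traits, min_detections = 30)
  expect_equal(p$group_id[p$species_code == "Colias philodice"], "global")
  expect_equal(p$group_id[p$species_code == "Papilio glaucus"], "global")

  # every species in exactly one group (partition)
  expect_equal(anyDuplicated(p$species_code), 0L)
  expect_true(all(!is.na(p$group_id)))

  expect_error(pool_species(make_pool_obs(c("Unknownia sp" = 5)), traits),
               "absent from trait table")
})

test_that("pooled groups expose one shared ESW across members", {
  traits <- data.frame(
    species_code = c("Colias eurytheme", "Colias philodice"),
    family = "Pieridae", natureserve_rank = "G5", stringsAsFactors = FALSE)
  obs <- make_pool_obs(c("Colias eurytheme" = 60, "Colias philodice" = 5))
  det <- fit_detection(obs, traits, min_detections = 30)
  expect_equal(length(unique(det$groups$esw)), 1L)
  expect_equal(length(det$fits), 1L)
  expect_equal(det$fits[[1]]$n_detections, 65L)
})

test_that("apportionment splits counts proportionally and conserves totals", {
  traits <- toy_traits()
  obs <- data.frame(
    site_id = "A", year = 1998L, day_of_year = 150L, survey_round = 1L,
    taxon_code = c("Pieris rapae", "Colias eurytheme", "Pieridae"),
    resolved_to_species = c(TRUE, TRUE, FALSE),
    distance_m = c(1, 1, 2), count = c(6, 2, 4), under_canopy = FALSE,
    stringsAsFactors = FALSE)
  out <- apportion_unidentified(obs, traits)
  expect_true(all(out$resolved_to_species))
  tot <- tapply(out$count, out$taxon_code, sum)
  expect_equal(tot[["Pieris rapae"]], 9)      # 6 + 3
  expect_equal(tot[["Colias eurytheme"]], 3)  # 2 + 1
  expect_equal(sum(out$count), sum(obs$count))
})

test_that("records with no same-site-same-day candidates are dropped and logged", {
  traits <- toy_traits()
  obs <- data.frame(
    site_id = c("A", "B"), year = 1998L, day_of_year = 150L,
    survey_round = 1L,
    taxon_code = c("Pieris rapae", "Pieridae"),
    resolved_to_species = c(TRUE, FALSE),
    distance_m = 1, count = c(2, 4), under_canopy = FALSE,
    stringsAsFactors = FALSE)
  out <- apportion_unidentified(obs, traits)
  dropped <- attr(out, "dropped")
  expect_equal(nrow(dropped), 1L)
  expect_match(dropped$drop_reason, "no same-site-same-day")
  # conservation: input total = output total + dropped total
  expect_equal(sum(obs$count), sum(out$count) + sum(dropped$count))

  obs$taxon_code[2] <- "Sphingidae"
  expect_error(apportion_unidentified(obs, traits), "no candidate species")
})

test_that("density follows D = 1e4 n / (2 L ESW) with zeros for absences", {
  sites <- toy_sites(2)
  sites$transect_length_m <- 500
  obs <- data.frame(
    site_id = rep("S01", 10), year = 1998L, day_of_year = 150L,
    survey_round = 1L, taxon_code = "Pieris rapae",
    resolved_to_species = TRUE, distance_m = 1, count = 1,
    under_canopy = FALSE, stringsAsFactors = FALSE)
  det <- list(groups = data.frame(species_code = "Pieris rapae",
                                  group_id = "g", n_detections = 10L,
                                  esw = 2, stringsAsFactors = FALSE))
  dt <- estimate_densities(obs, sites, det)
  expect_s3_class(dt, "density_table")
  expect_equal(dt[dt$site_id == "S01", "Pieris rapae"], 50)
  expect_equal(dt[dt$site_id == "S02", "Pieris rapae"], 0)

  # doubling ESW halves the density
  det2 <- det; det2$groups$esw <- 4
  dt2 <- estimate_densities(obs, sites, det2)
  expect_equal(dt2[dt2$site_id == "S01", "Pieris rapae"], 25)

  det$groups$species_code <- "Somebody else"
  expect_error(estimate_densities(obs, sites, det), "no detection fit")
})

test_that("density estimator is consistent on simulated surveys", {
  # single well-detected species; compare estimated site-level mean
  # density to the analytic expectation
  rel_err <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_sites_per_habitat = 1, n_survey_rounds = 3,
                             unidentified_rate = 0,
                             species = one_species(A = 80, tau = 1e6,
                                                   psd = 1e6, sigma = 3),
                             rng_seed = 1000 + s)
    sim <- simulate_dataset(cfg)
    det <- fit_detection(sim$observations, sim$traits, min_detections = 30)
    dt <- estimate_densities(sim$observations, sim$sites, det)
    est <- mean(density_matrix(dt))
    truth <- mean(sim$ground_truth$lambda$lambda)
    (est - truth) / truth
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.05)
})

test_that("per-survey richness equals nonzero density cells", {
  cfg <- simulation_config(n_sites_per_habitat = 1, n_survey_rounds = 5,
                           unidentified_rate = 0,
                           species = make_species_pool(10, seed = 4),
                           rng_seed = 12)
  sim <- simulate_dataset(cfg)
  det <- fit_detection(sim$observations, sim$traits, min_detections = 20)
  dt <- estimate_densities(sim$observations, sim$sites, det)
  met <- community_metrics(dt, sim$traits)
  expect_equal(met$survey$richness, rowSums(density_matrix(dt) > 0))
  expect_true(all(met$survey$cvi >= 0))
})
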