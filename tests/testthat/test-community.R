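test_that("NatureServe rank strings map to reversed numeric ranks", {
  expect_equal(reversed_rank("G5"), 1)
  expect_equal(reversed_rank("G1"), 5)
  expect_equal(reversed_rank("G3G4"), 2.5)
  expect_equal(reversed_rank("G4G5"), 1.5)
  expect_equal(reversed_rank("G5T2"), 4)  # T overrides G
  expect_equal(reversed_rank("G4T1"), 5)
  expect_error(reversed_rank("Q2"), "unparsable")
  expect_error(reversed_rank("G6"), "unparsable")
})

test_that("CVI sums rank-weighted densities over imperiled species only", {
  # all secure: empty inclusion set
  expect_equal(conservation_value_index(c(3, 7, 1), c(1, 1, 1)), 0)
  # worked three-species example; the r = 2 species is excluded
  expect_equal(conservation_value_index(c(2, 1, 10), c(3, 5, 2)), 11)
  expect_error(conservation_value_index(c(1, 2), c(3, NA)), "missing")
  expect_error(conservation_value_index(c(1, 2), 3), "align")
  # linearity in densities
  d <- c(0.5, 2, 4); r <- c(3, 1, 4)
  expect_equal(conservation_value_index(3 * d, r),
               3 * conservation_value_index(d, r))
})

test_that("CVI inclusion set for the observed community is the four imperiled taxa", {
  rk <- load_natureserve_ranks()
  rr <- reversed_rank(rk$natureserve_rank)
  expect_setequal(rk$species_code[rr > 2],
                  c("Problema byssus", "Erynnis martialis",
                    "Lycaeides melissa samuelis", "Danaus plexippus"))
})

test_that("ACE matches the hand-worked example and vegan's estimator", {
  expect_equal(ace_richness(c(1, 1, 2, 3, 12, 20)), 7.786667,
               tolerance = 1e-6)
  # independent implementation cross-check
  ab <- c(1, 1, 1, 2, 2, 4, 5, 8, 15, 30, 42)
  expect_equal(ace_richness(ab),
               unname(vegan::estimateR(ab)["S.ACE"]), tolerance = 1e-8)
  # no rare species: observed richness
  expect_equal(ace_richness(c(12, 20, 50)), 3)
  # adding an abundant species adds exactly one
  expect_equal(ace_richness(c(1, 1, 2, 3, 12, 20, 99)),
               ace_richness(c(1, 1, 2, 3, 12, 20)) + 1)
  # ACE >= observed richness whenever defined
  set.seed(2)
  for (i in 1:20) {
    ab <- rpois(15, 4) + 1
    expect_gte(ace_richness(ab), sum(ab > 0))
  }
  expect_error(ace_richness(c(1, 1, 1)), "undefined")
  expect_error(ace_richness(c(1.5, 2)), "integer")
})

test_that("site-mode accumulation matches exhaustive enumeration", {
  m <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 0, 1, 1))
  cur <- accumulation_curve(m, mode = "sites", n_randomizations = 200)
  # brute-force oracle over all 3! orderings
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  acc <- sapply(perms, function(p) {
    seen <- rep(FALSE, 4)
    vapply(p, function(i) {
      seen <<- seen | (m[i, ] > 0); sum(seen)
    }, numeric(1))
  })
  expect_equal(cur$mean, rowMeans(acc))
  expect_equal(cur$var, apply(acc, 1, var))
  expect_equal(cur$n_randomizations, 6L)
})

test_that("accumulation curves are nondecreasing and exhaust the pool", {
  set.seed(4)
  m <- matrix(rpois(8 * 12, 1.2), 8, 12)
  cs <- accumulation_curve(m, mode = "sites", n_randomizations = 100,
                           seed = 1)
  expect_true(all(diff(cs$mean) >= 0))
  expect_equal(cs$mean[length(cs$mean)], sum(colSums(m) > 0))
  expect_equal(cs$var[length(cs$var)], 0)

  ci <- accumulation_curve(m, mode = "individuals",
                           n_randomizations = 1000, seed = 1)
  expect_true(all(diff(ci$mean) >= 0))
  expect_true(all(ci$var >= 0))
  expect_equal(ci$mean[length(ci$mean)], sum(colSums(m) > 0))
  # concavity of the mean curve, up to Monte-Carlo noise
  expect_true(all(diff(diff(ci$mean)) <= 0.25))

  expect_error(accumulation_curve(m, mode = "sites", effort = 9),
               "outside")
  # single site: a one-point curve at its own richness
  c1 <- accumulation_curve(m[1, , drop = FALSE], mode = "sites")
  expect_equal(c1$mean, sum(m[1, ] > 0))
})

test_that("richness comparison z-test matches hand arithmetic", {
  ca <- structure(list(mode = "individuals", effort = 1400, mean = 10,
                       var = 1, n_randomizations = 200),
                  class = "accumulation_curve")
  cb <- structure(list(mode = "individuals", effort = 1400, mean = 13,
                       var = 1.25, n_randomizations = 200),
                  class = "accumulation_curve")
  cmp <- compare_richness_at_effort(ca, cb, 1400)
  expect_equal(cmp$z, -2)
  expect_equal(cmp$p, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(cmp$p, 0.0455, tolerance = 1e-3)
  # identical curves: z = 0, p = 1
  cmp0 <- compare_richness_at_effort(ca, ca, 1400)
  expect_equal(cmp0$z, 0)
  expect_equal(cmp0$p, 1)

  curves <- list(a = ca, b = cb, c = ca)
  pw <- compare_richness_pairwise(curves, 1400)
  expect_true(all(pw$p_adj >= pw$p_raw))
})

test_that("under-canopy summary pools overall and averages species", {
  traits <- data.frame(
    species_code = c("sp1", "sp2", "sp3"), family = "Nymphalidae",
    natureserve_rank = "G5", stringsAsFactors = FALSE)
  mk <- function(sp, n, n_under) {
    data.frame(site_id = "A", year = 1998L, day_of_year = 150L,
               survey_round = 1L, taxon_code = sp,
               resolved_to_species = TRUE, distance_m = 1, count = 1,
               under_canopy = rep(c(TRUE, FALSE), c(n_under, n - n_under)),
               stringsAsFactors = FALSE)
  }
  obs <- rbind(mk("sp1", 30, 12),   # 40 %
               mk("sp2", 25, 5),    # 20 %
               mk("sp3", 10, 10))   # under threshold
  s <- under_canopy_summary(obs, traits, min_obs = 20)
  expect_equal(s$species_mean_pct, 30)
  expect_equal(s$n_species, 2L)
  expect_equal(s$overall_pct, 100 * (12 + 5 + 10) / 65)
  # all flags true
  obs2 <- mk("sp1", 25, 25)
  expect_equal(under_canopy_summary(obs2, traits)$overall_pct, 100)
})

test_that("inverse-distance averaging weights by 1/d", {
  expect_equal(idw_site_average(c(0, 10), c(1, 2)), 10 / 3, tolerance = 1e-9)
  expect_equal(idw_site_average(c(3, 9, 6), c(5, 5, 5)), 6)
  expect_equal(idw_site_average(7, 2), 7)
  expect_error(idw_site_average(c(1, 2), c(1, 0)), "> 0")
})
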