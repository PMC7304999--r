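# Small in-code fixtures shared across tests.

toy_observations <- function() {
  data.frame(
    site_id = c("A", "A", "B"),
    year = 1998L,
    day_of_year = c(150L, 150L, 151L),
    survey_round = c(3L, 3L, 3L),
    taxon_code = c("Pieris rapae", "Colias eurytheme", "Pieris rapae"),
    resolved_to_species = TRUE,
    distance_m = c(1.5, 0, 2.25),
    count = c(1, 2, 1),
    under_canopy = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

toy_traits <- function() {
  data.frame(
    species_code = c("Pieris rapae", "Colias eurytheme", "Colias philodice",
                     "Papilio glaucus"),
    family = c("Pieridae", "Pieridae", "Pieridae", "Papilionidae"),
    natureserve_rank = c("G5", "G5", "G5", "G5"),
    stringsAsFactors = FALSE
  )
}

toy_sites <- function(n = 25) {
  habs <- rep(c("open", "savanna", "woodland", "scrub", "forest"),
              length.out = n)
  data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    x_m = seq_len(n) * 1000, y_m = 0,
    transect_length_m = 500,
    canopy_cover_pct = seq(0, 100, length.out = n),
    habitat = habs,
    fire2 = 0.2, fire15 = 2, veg_short = 50, veg_tall = 40, litter = 30,
    habitat_diversity = 1.2, developed_pct = 10, agriculture_pct = 20,
    stringsAsFactors = FALSE
  )
}

# one-row species spec for the generator
one_species <- function(mu = 50, tau = 20, A = 10, peak = 180, psd = 30,
                        sigma = 3, rank = "G5", code = "Gen_sp1",
                        family = "Nymphalidae") {
  data.frame(species_code = code, family = family, mu = mu, tau = tau,
             A = A, phenology_peak = peak, phenology_sd = psd,
             sigma = sigma, natureserve_rank = rank,
             stringsAsFactors = FALSE)
}

# Gaussian-niche community matrix along a known gradient (Poisson noise)
niche_community <- function(n_samples = 40, n_species = 15, seed = 1) {
  set.seed(seed)
  grad <- seq(0, 100, length.out = n_samples)
  mu <- runif(n_species, 0, 100)
  tau <- runif(n_species, 12, 25)
  A <- runif(n_species, 5, 30)
  lam <- sapply(seq_len(n_species),
                function(j) A[j] * exp(-(grad - mu[j])^2 / (2 * tau[j]^2)))
  list(m = matrix(rpois(n_samples * n_species, lam), n_samples, n_species),
       gradient = grad, lambda = lam)
}
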