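# Canopy-response curve fitting and peak extraction, the rank-averaged
# conservation composite, and Moran spatial eigenvector construction.

aicc <- function(fit, n) {
  k <- attr(logLik(fit), "df")
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

cubic_peak_x <- function(beta, lo, hi) {
  # argmax of b0 + b1 x + b2 x^2 + b3 x^3 over [lo, hi]
  cand <- c(lo, hi)
  dcoef <- c(beta[2], 2 * beta[3], 3 * beta[4])  # derivative coefficients
  if (abs(dcoef[3]) > 0) {
    disc <- dcoef[2]^2 - 4 * dcoef[3] * dcoef[1]
    if (disc >= 0) {
      roots <- (-dcoef[2] + c(-1, 1) * sqrt(disc)) / (2 * dcoef[3])
      cand <- c(cand, roots[roots >= lo & roots <= hi])
    }
  } else if (abs(dcoef[2]) > 0) {
    root <- -dcoef[1] / dcoef[2]
    if (root >= lo && root <= hi) cand <- c(cand, root)
  }
  vals <- beta[1] + beta[2] * cand + beta[3] * cand^2 + beta[4] * cand^3
  cand[which.max(vals)]
}

#' Fit a canopy-response peak curve
#'
#' Least-squares fits of a cubic polynomial
#' y = b0 + b1 x + b2 x^2 + b3 x^3 and a 3-parameter Gaussian peak
#' y = a exp(-0.5 ((x - x0)/b)^2) (initialized at a = max(y),
#' x0 = argmax(y), b = range(x)/4) to a response along the canopy-cover
#' gradient. The winner is the model with the lower AICc; the reported
#' peak is the argmax of the winning curve restricted to the observed
#' canopy range (extrapolated maxima are refused).
#'
#' @param x Canopy cover percent in `[0, 100]`, length >= 5.
#' @param y Response (richness, density, CVI, composite rank, ...).
#' @return Object of class `"peak_fit"`: list with `model` (`"cubic"` or
#'   `"gaussian_peak"`), `parameters`, `r_squared`, `aicc` (named vector,
#'   both models), `peak_x`, `peak_y`, `fitted_curve` (function of x),
#'   `n`.
#' @export
fit_peak_model <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 5L) stop("need at least 5 points", call. = FALSE)
  if (any(x < 0 | x > 100)) stop("x must be canopy cover in [0, 100]",
                                 call. = FALSE)
  n <- length(x)
  lo <- min(x); hi <- max(x)

  cub <- lm(y ~ x + I(x^2) + I(x^3))
  aicc_cub <- aicc(cub, n)

  gau <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-0.5 * ((x - x0) / b)^2),
                      start = list(a = max(y), x0 = x[which.max(y)],
                                   b = diff(range(x)) / 4),
                      lower = c(a = -Inf, x0 = -Inf, b = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  aicc_gau <- if (is.null(gau)) Inf else aicc(gau, n)

  if (is.null(gau) && is.na(coef(cub)[4])) {
    stop("neither peak model could be fitted", call. = FALSE)
  }
  use_gau <- aicc_gau < aicc_cub
  if (use_gau) {
    prm <- coef(gau)
    fitted_curve <- function(z) prm[["a"]] *
      exp(-0.5 * ((z - prm[["x0"]]) / prm[["b"]])^2)
    peak_x <- if (prm[["a"]] >= 0) min(max(prm[["x0"]], lo), hi) else {
      # inverted bell: maximum sits at the range end farther from x0
      if (abs(lo - prm[["x0"]]) > abs(hi - prm[["x0"]])) lo else hi
    }
    res <- y - fitted_curve(x)
  } else {
    beta <- coef(cub)
    beta[is.na(beta)] <- 0
    fitted_curve <- function(z) beta[1] + beta[2] * z + beta[3] * z^2 +
      beta[4] * z^3
    peak_x <- cubic_peak_x(beta, lo, hi)
    res <- y - fitted_curve(x)
    prm <- beta
  }
  structure(list(model = if (use_gau) "gaussian_peak" else "cubic",
                 parameters = prm,
                 r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
                 aicc = c(cubic = aicc_cub, gaussian_peak = aicc_gau),
                 peak_x = unname(peak_x),
                 peak_y = unname(fitted_curve(peak_x)),
                 fitted_curve = fitted_curve, n = n),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf(
    "Canopy-response peak fit: %s model, peak at %.1f%% canopy (R^2 = %.3f, n = %d)\n",
    x$model, x$peak_x, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) object$parameters

#' @export
predict.peak_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stop("supply newdata (canopy cover values)",
                             call. = FALSE)
  z <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  object$fitted_curve(z)
}

#' @export
plot.peak_fit <- function(x, ...) {
  z <- seq(0, 100, length.out = 200)
  plot(z, x$fitted_curve(z), type = "l", xlab = "canopy cover (%)",
       ylab = "fitted response", ...)
  graphics::abline(v = x$peak_x, lty = 2)
  invisible(x)
}

#' Rank-averaged conservation composite
#'
#' Ranks sites on each of richness, density and CVI from 1 (least
#' desirable: lowest value) to n (most desirable), with midranks for
#' ties, and averages the three ranks per site.
#'
#' @param site_table Data.frame with one row per site and columns
#'   `richness`, `density`, `cvi` (plus an optional `site_id`).
#' @return Data.frame with `site_id` (if present), `rank_richness`,
#'   `rank_density`, `rank_cvi`, `average_rank`.
#' @export
rank_composite <- function(site_table) {
  need <- c("richness", "density", "cvi")
  missing <- setdiff(need, names(site_table))
  if (length(missing) > 0L) {
    stop("missing metric column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(site_table[, need])) stop("missing metric values", call. = FALSE)
  out <- data.frame(rank_richness = rank(site_table$richness),
                    rank_density = rank(site_table$density),
                    rank_cvi = rank(site_table$cvi))
  out$average_rank <- rowMeans(out)
  if ("site_id" %in% names(site_table)) {
    out <- cbind(site_id = site_table$site_id, out)
  }
  out
}

#' Moran spatial eigenvectors (SEVM)
#'
#' Builds synthetic spatial predictors from site coordinates: the pairwise
#' distance matrix is truncated at the longest minimum-spanning-tree edge
#' to give a binary connectivity matrix, which is doubly centred; the
#' eigenvectors with positive eigenvalues, in decreasing eigenvalue order,
#' are spatial filters from broad to fine scale. Which eigenvectors enter
#' a downstream model is the caller's choice (the first is the broadest
#' trend).
#'
#' @param xy Two-column matrix or data.frame of planar site coordinates
#'   (m), >= 3 distinct sites.
#' @return List with `vectors` (sites x k matrix, zero-mean orthogonal
#'   columns), `values` (positive eigenvalues, decreasing), `threshold`
#'   (the truncation distance used).
#' @export
spatial_eigenvectors <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) stop("need at least 3 sites", call. = FALSE)
  d <- as.matrix(dist(xy))
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate coordinates collapse the connectivity graph",
         call. = FALSE)
  }
  mst <- vegan::spantree(as.dist(d))
  threshold <- max(mst$dist)
  W <- (d <= threshold) * 1
  diag(W) <- 0
  n <- nrow(W)
  H <- diag(n) - matrix(1 / n, n, n)
  E <- eigen(H %*% W %*% H, symmetric = TRUE)
  pos <- E$values > sqrt(.Machine$double.eps) * max(abs(E$values))
  list(vectors = E$vectors[, pos, drop = FALSE],
       values = E$values[pos],
       threshold = threshold)
}

#' Canopy-peak report for a site-level summary
#'
#' Chains the gradient analysis end-to-end: given per-site richness,
#' density, CVI and canopy cover, fits a peak curve ([fit_peak_model()])
#' to each metric and to the rank-averaged composite
#' ([rank_composite()]), and reports the canopy cover at each peak.
#'
#' @param site_table Data.frame with columns `canopy_cover_pct`,
#'   `richness`, `density`, `cvi` (and optionally `site_id`).
#' @return List of class `"gradient_report"`: `peaks` (named list of peak
#'   canopy covers for richness, density, cvi, composite) and `fits`
#'   (the corresponding `"peak_fit"` objects).
#' @export
gradient_report <- function(site_table) {
  need <- c("canopy_cover_pct", "richness", "density", "cvi")
  missing <- setdiff(need, names(site_table))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  comp <- rank_composite(site_table)
  x <- site_table$canopy_cover_pct
  fits <- list(richness = fit_peak_model(x, site_table$richness),
               density = fit_peak_model(x, site_table$density),
               cvi = fit_peak_model(x, site_table$cvi),
               composite = fit_peak_model(x, comp$average_rank))
  structure(list(peaks = lapply(fits, `[[`, "peak_x"), fits = fits),
            class = "gradient_report")
}

#' @export
print.gradient_report <- function(x, ...) {
  cat("Canopy cover (%) at peak response:\n")
  for (nm in names(x$peaks)) {
    cat(sprintf("  %-9s %.1f  (%s model)\n", nm, x$peaks[[nm]],
                x$fits[[nm]]$model))
  }
  invisible(x)
}
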