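# Composition analytics: one-dimensional principal-curve ordination,
# indicator value (IndVal) analysis with permutation nulls, and predictive
# co-correspondence analysis (CoCA).

apply_transform <- function(m, transform) {
  if (is.function(transform)) return(transform(m))
  switch(transform,
         none = m,
         sqrt = sqrt(m),
         log_half = log(m + 0.5),
         stop("unknown transform '", transform, "'", call. = FALSE))
}

# first correspondence-analysis axis of a nonnegative matrix (row scores)
ca_axis1 <- function(m) {
  if (any(m < 0)) stop("correspondence analysis needs nonnegative entries",
                       call. = FALSE)
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0)) stop("matrix has an all-zero row", call. = FALSE)
  cs_pos <- cs > 0
  m <- m[, cs_pos, drop = FALSE]
  cs <- cs[cs_pos]
  tot <- sum(m)
  P <- m / tot
  r <- rs / tot
  c <- cs / tot
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(S, nu = 1, nv = 0)
  sv$u[, 1] / sqrt(r)  # trivial axis already removed by the centring
}

project_to_polyline <- function(Y, C) {
  n <- nrow(Y)
  G <- nrow(C)
  seg_len <- sqrt(rowSums((C[-1, , drop = FALSE] -
                             C[-G, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  for (k in seq_len(G - 1L)) {
    a <- C[k, ]
    d <- C[k + 1L, ] - a
    len2 <- sum(d^2)
    diff <- sweep(Y, 2, a)
    tt <- if (len2 > 0) pmin(pmax(as.numeric(diff %*% d) / len2, 0), 1)
          else rep(0, n)
    resid <- diff - outer(tt, d)
    d2 <- rowSums(resid^2)
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_s[hit] <- arc[k] + tt[hit] * seg_len[k]
  }
  list(s = best_s, d2 = best_d2)
}

#' One-dimensional principal-curve ordination
#'
#' Fits a smooth one-dimensional curve through the samples in species
#' space and scores each sample by its arc-length position along the
#' curve, rescaled to `[0, 1]`. Sample scores are initialized from the
#' first correspondence-analysis axis; each iteration smooths every
#' species' (transformed) abundance against the current scores with a
#' cubic smoothing spline of fixed effective degrees of freedom, projects
#' each sample to the nearest point of the resulting multivariate curve,
#' and re-parameterizes by arc length, until the total residual sum of
#' squares changes by less than `tol` (relative) or `max_iter` iterations.
#'
#' @param m Samples x species abundance matrix (>= 3 samples; 2 samples
#'   are a degenerate exact fit).
#' @param transform `"none"`, `"sqrt"`, `"log_half"` (ln(x + 0.5)) or a
#'   function applied to the matrix before fitting.
#' @param df Effective degrees of freedom of the per-species spline
#'   smoother (default 4).
#' @param canopy Optional numeric gradient (e.g. site canopy cover) used
#'   only to orient the scores (positive correlation); orientation is
#'   otherwise resolved against the initializing axis.
#' @param tol Relative tolerance on the residual sum of squares (1e-6).
#' @param max_iter Maximum iterations (50).
#' @param n_grid Number of curve evaluation points (100).
#' @return Object of class `"principal_curve_ord"`: list with `scores`
#'   (in `[0, 1]`), `variance_explained`, `curve` (grid x species fitted
#'   curve), `n_iterations`, `converged`.
#' @export
principal_curve_ordination <- function(m, transform = "none", df = 4,
                                       canopy = NULL, tol = 1e-6,
                                       max_iter = 50, n_grid = 100) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  Y <- apply_transform(m, transform)
  ss_tot <- sum(sweep(Y, 2, colMeans(Y))^2)
  if (ss_tot == 0) stop("constant matrix: no compositional variation",
                        call. = FALSE)
  orient <- function(scores) {
    ref <- if (!is.null(canopy)) canopy else init
    if (cor(scores, ref) < 0) 1 - scores else scores
  }
  if (n == 2L) {
    init <- c(0, 1)
    scores <- orient(c(0, 1))
    return(structure(list(scores = scores, variance_explained = 1,
                          curve = Y, n_iterations = 0L, converged = TRUE),
                     class = "principal_curve_ord"))
  }
  init <- ca_axis1(m)
  s <- init - min(init)
  if (max(s) > 0) s <- s / max(s)
  df_eff <- min(df, n - 1)
  ss_prev <- Inf
  converged <- FALSE
  iter <- 0L
  curve <- NULL
  for (iter in seq_len(max_iter)) {
    grid <- seq(min(s), max(s), length.out = n_grid)
    curve <- matrix(0, n_grid, ncol(Y), dimnames = list(NULL, colnames(Y)))
    for (j in seq_len(ncol(Y))) {
      if (length(unique(s)) >= 4) {
        fit <- smooth.spline(s, Y[, j], df = df_eff)
        curve[, j] <- predict(fit, grid)$y
      } else {
        fit <- lm(Y[, j] ~ s)
        curve[, j] <- predict(fit, data.frame(s = grid))
      }
    }
    pr <- project_to_polyline(Y, curve)
    ss_res <- sum(pr$d2)
    s_new <- pr$s
    rng <- max(s_new) - min(s_new)
    if (rng == 0) {  # collapsed curve: keep previous parameterization
      break
    }
    s <- (s_new - min(s_new)) / rng
    if (is.finite(ss_prev) &&
        abs(ss_prev - ss_res) <= tol * max(ss_prev, .Machine$double.eps)) {
      converged <- TRUE
      ss_prev <- ss_res
      break
    }
    ss_prev <- ss_res
  }
  if (!converged) {
    warning("principal-curve ordination did not converge in ", max_iter,
            " iterations; returning current state", call. = FALSE)
  }
  scores <- orient(s)
  structure(list(scores = scores,
                 variance_explained = max(0, min(1, 1 - ss_prev / ss_tot)),
                 curve = curve, n_iterations = iter, converged = converged),
            class = "principal_curve_ord")
}

#' @export
print.principal_curve_ord <- function(x, ...) {
  cat(sprintf(
    "Principal-curve ordination: %d samples, %.1f%% variance explained (%s, %d iterations)\n",
    length(x$scores), 100 * x$variance_explained,
    if (x$converged) "converged" else "not converged", x$n_iterations))
  invisible(x)
}

indval_matrix <- function(m, groups, group_levels) {
  pres <- m > 0
  A <- matrix(0, ncol(m), length(group_levels),
              dimnames = list(colnames(m), group_levels))
  B <- A
  for (g in group_levels) {
    idx <- groups == g
    A[, g] <- colMeans(m[idx, , drop = FALSE])
    B[, g] <- colMeans(pres[idx, , drop = FALSE])
  }
  denom <- rowSums(A)
  A <- A / ifelse(denom > 0, denom, 1)
  100 * A * B
}

#' Indicator value (IndVal) analysis
#'
#' Dufrene-Legendre indicator values: for species s and group g,
#' specificity A = (mean abundance of s in g) / (sum over groups of its
#' mean abundances), fidelity B = fraction of g's sites holding s, and
#' IndVal = 100 A B. Each species' indicator habitat is the group with the
#' maximal IndVal (ties broken by the canonical habitat order
#' open, savanna, woodland, scrub, forest, or the factor level order);
#' significance comes from permuting sites across groups (group sizes
#' preserved) with p = (1 + #{permutation max-IndVal >= observed}) /
#' (n_perm + 1), Benjamini-Hochberg adjusted across species.
#'
#' @param m Sites x species abundance matrix.
#' @param groups Group (habitat) labels, one per site.
#' @param n_perm Number of permutations (default 4999).
#' @param seed Optional integer seed.
#' @return Object of class `"indval"`: list with `indval` (species x
#'   group matrix in `[0, 100]`), and `summary`, a data.frame with
#'   `species`, `max_group`, `indval`, `p_raw`, `p_adj`.
#' @export
indicator_values <- function(m, groups, n_perm = 4999, seed = NULL) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  groups <- as.character(groups)
  lev <- intersect(HABITAT_LEVELS, unique(groups))
  lev <- c(lev, setdiff(unique(groups), lev))
  if (length(lev) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  iv <- indval_matrix(m, groups, lev)
  obs_max <- apply(iv, 1, max)
  max_grp <- lev[apply(iv, 1, which.max)]
  exceed <- rep(0L, ncol(m))
  for (b in seq_len(n_perm)) {
    ivp <- indval_matrix(m, sample(groups), lev)
    exceed <- exceed + (apply(ivp, 1, max) >= obs_max)
  }
  p_raw <- (1 + exceed) / (n_perm + 1)
  structure(list(indval = iv,
                 summary = data.frame(species = colnames(m),
                                      max_group = max_grp,
                                      indval = obs_max,
                                      p_raw = p_raw,
                                      p_adj = benjamini_hochberg(p_raw),
                                      stringsAsFactors = FALSE,
                                      row.names = NULL),
                 n_perm = n_perm),
            class = "indval")
}

#' @export
print.indval <- function(x, ...) {
  cat(sprintf("Indicator value analysis (%d species, %d permutations)\n",
              nrow(x$summary), x$n_perm))
  print(format(head(x$summary[order(x$summary$p_raw), ], 10), digits = 3),
        row.names = FALSE)
  invisible(x)
}

# chi-square standardization of a community matrix: weighted, centred
# row profiles. Row weights r default to the matrix's own row masses.
chi_standardize <- function(m, r = NULL) {
  rs <- rowSums(m)
  if (any(rs == 0)) stop("matrix has an all-zero row", call. = FALSE)
  Q <- m / rs
  if (is.null(r)) r <- rs / sum(rs)
  cm <- as.numeric(crossprod(r, Q))  # weighted mean profile
  keep <- cm > 0
  Z <- sweep(Q[, keep, drop = FALSE], 2, cm[keep])
  Z <- sweep(Z, 2, sqrt(cm[keep]), "/")
  Z <- Z * sqrt(r)
  list(Z = Z, r = r, cm = cm, keep = keep)
}

# standardize new raw rows with a training standardization
chi_apply <- function(std, m_new, r_new) {
  rs <- rowSums(m_new)
  Q <- m_new / rs
  Z <- sweep(Q[, std$keep, drop = FALSE], 2, std$cm[std$keep])
  Z <- sweep(Z, 2, sqrt(std$cm[std$keep]), "/")
  Z * sqrt(r_new)
}

pls_fit <- function(X, Y, k) {
  comps <- vector("list", k)
  Xd <- X
  for (a in seq_len(k)) {
    M <- crossprod(Xd, Y)
    sv <- svd(M, nu = 1, nv = 0)
    u <- sv$u[, 1]
    t_a <- as.numeric(Xd %*% u)
    tt <- sum(t_a^2)
    if (tt < .Machine$double.eps) {
      comps <- comps[seq_len(a - 1L)]
      break
    }
    p_a <- as.numeric(crossprod(Xd, t_a)) / tt
    q_a <- as.numeric(crossprod(Y, t_a)) / tt
    Xd <- Xd - outer(t_a, p_a)
    comps[[a]] <- list(u = u, p = p_a, q = q_a, t = t_a,
                       sv = sv$d[1])
  }
  comps
}

pls_predict <- function(comps, Xnew, k) {
  Yhat <- matrix(0, nrow(Xnew), length(comps[[1]]$q))
  Xd <- Xnew
  for (a in seq_len(k)) {
    cp <- comps[[a]]
    t_new <- as.numeric(Xd %*% cp$u)
    Yhat <- Yhat + outer(t_new, cp$q)
    Xd <- Xd - outer(t_new, cp$p)
  }
  Yhat
}

#' Predictive co-correspondence analysis
#'
#' Relates two community matrices sampled at the same sites, extracting
#' axes that maximize the ability of the predictor community `X` to
#' predict the response community `Y`. Both matrices are converted to
#' chi-square standardized row profiles with shared site weights (the row
#' totals of `Y`); axes are extracted sequentially as weighted-averaging
#' partial-least-squares components (each site-score axis orthogonal to
#' the previous ones). Predictive power is summarized by the
#' leave-one-out cross-validated fit for k axes, 100 * (1 - PRESS /
#' total weighted SS of Y), which can be negative when `X` carries no
#' information about `Y`; axis significance can be tested by permuting the
#' sample rows of `X`.
#'
#' @param Y Response community matrix (samples x species, nonnegative, no
#'   all-zero rows).
#' @param X Predictor community matrix on the same samples.
#' @param max_axes Number of axes to extract.
#' @param n_perm Permutations for the axis significance test (0 = skip).
#' @param seed Optional integer seed.
#' @return Object of class `"coca"`: list with `cv_fit` (cumulative
#'   leave-one-out fit %, per axis count), `variance_explained`
#'   (cumulative % of the weighted SS of Y), `site_scores` (samples x
#'   axes), `axis_p` (if permuted), `n_axes`.
#' @export
predictive_coca <- function(Y, X, max_axes = 4, n_perm = 0, seed = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must share the same samples",
                               call. = FALSE)
  if (any(Y < 0) || any(X < 0)) stop("entries must be nonnegative",
                                     call. = FALSE)
  if (any(rowSums(Y) == 0) || any(rowSums(X) == 0)) {
    stop("all-zero sample row", call. = FALSE)
  }
  n <- nrow(Y)
  k <- min(max_axes, n - 2L)
  if (!is.null(seed)) set.seed(seed)
  r <- rowSums(Y) / sum(Y)
  stdY <- chi_standardize(Y, r)
  stdX <- chi_standardize(X, r)
  comps <- pls_fit(stdX$Z, stdY$Z, k)
  k <- length(comps)
  ss_tot <- sum(stdY$Z^2)
  ve <- vapply(seq_len(k), function(a) {
    100 * sum(pls_predict(comps, stdX$Z, a)^2) / ss_tot
  }, numeric(1))
  scores <- vapply(comps, `[[`, numeric(n), "t")

  # leave-one-out: refit margins and components on n-1 sites, predict the
  # held-out chi-square profile, accumulate weighted squared error
  press <- matrix(0, n, k)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    r_tr <- rowSums(Y[tr, , drop = FALSE]) / sum(Y[tr, , drop = FALSE])
    sY <- chi_standardize(Y[tr, , drop = FALSE], r_tr)
    sX <- chi_standardize(X[tr, , drop = FALSE], r_tr)
    cmp <- pls_fit(sX$Z, sY$Z, k)
    zx <- chi_apply(sX, X[i, , drop = FALSE], r[i])
    zy <- chi_apply(sY, Y[i, , drop = FALSE], r[i])
    for (a in seq_len(min(k, length(cmp)))) {
      err <- pls_predict(cmp, zx, a) - zy
      press[i, a] <- sum(err^2)
    }
    if (length(cmp) < k) {
      press[i, seq(length(cmp) + 1L, k)] <- press[i, length(cmp)]
    }
  }
  cv_fit <- 100 * (1 - colSums(press) / ss_tot)

  axis_p <- NULL
  if (n_perm > 0) {
    sv_obs <- vapply(comps, `[[`, numeric(1), "sv")
    ge <- rep(0L, k)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      sXp <- chi_standardize(X[perm, , drop = FALSE], r)
      cmpp <- pls_fit(sXp$Z, stdY$Z, k)
      svp <- vapply(cmpp, `[[`, numeric(1), "sv")
      length(svp) <- k
      svp[is.na(svp)] <- 0
      ge <- ge + (svp >= sv_obs)
    }
    axis_p <- (1 + ge) / (n_perm + 1)
  }
  structure(list(cv_fit = cv_fit, variance_explained = ve,
                 site_scores = matrix(scores, nrow = n,
                                      dimnames = list(rownames(Y),
                                                      paste0("axis",
                                                             seq_len(k)))),
                 axis_p = axis_p, n_axes = k),
            class = "coca")
}

#' @export
print.coca <- function(x, ...) {
  cat(sprintf("Predictive co-correspondence analysis (%d axes)\n", x$n_axes))
  tab <- data.frame(axes = seq_len(x$n_axes),
                    cv_fit_pct = round(x$cv_fit, 2),
                    cum_var_pct = round(x$variance_explained, 2))
  if (!is.null(x$axis_p)) tab$p <- signif(x$axis_p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
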