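# Permutation and rank-based inference: PERMANOVA with pairwise
# comparisons, Kruskal-Wallis with Dunn's test, Spearman correlation,
# Benjamini-Hochberg adjustment.

#' Community dissimilarity matrix
#'
#' Thin wrapper over [vegan::vegdist()] exposing the metrics used here:
#' `"sorensen"` is the quantitative Sorensen (= Bray-Curtis) dissimilarity
#' on abundances, `"sorensen_binary"` its presence/absence form,
#' `"euclidean"` the Euclidean distance.
#'
#' @param x Samples x species matrix.
#' @param metric One of `"sorensen"`, `"sorensen_binary"`, `"euclidean"`.
#' @return A `"dist"` object.
#' @export
community_distance <- function(x, metric = c("sorensen", "sorensen_binary",
                                             "euclidean")) {
  metric <- match.arg(metric)
  switch(metric,
         sorensen = vegan::vegdist(x, method = "bray"),
         sorensen_binary = vegan::vegdist(x, method = "bray", binary = TRUE),
         euclidean = dist(x))
}

permanova_ss <- function(d2, groups) {
  N <- nrow(d2)
  ss_t <- sum(d2[upper.tri(d2)]) / N
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(ss_t = ss_t, ss_w = ss_w)
}

permanova_F <- function(d2, groups) {
  a <- length(unique(groups))
  N <- nrow(d2)
  ss <- permanova_ss(d2, groups)
  ss_a <- ss[["ss_t"]] - ss[["ss_w"]]
  (ss_a / (a - 1)) / (ss[["ss_w"]] / (N - a))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions squared inter-sample dissimilarities among groups and tests
#' the pseudo-F by permuting group labels. With a univariate response and
#' Euclidean distance the pseudo-F is exactly the classical one-way
#' ANOVA F. Pairwise comparisons rerun the same statistic on each group
#' pair (permuting only within the pair) and report t = sqrt(F) with
#' Benjamini-Hochberg-adjusted p values.
#'
#' @param x Samples x species matrix, or a ready-made `"dist"` object
#'   (then `metric` is ignored).
#' @param groups Group labels, one per sample; every group needs >= 2
#'   samples.
#' @param metric Dissimilarity passed to [community_distance()].
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Optional integer seed.
#' @param pairwise Run all pairwise comparisons as well?
#' @return An object of class `"permanova"`: list with `pseudo_F`,
#'   `df_among`, `df_within`, `p`, `n_perm`, and (if requested) `pairwise`,
#'   a data.frame with `groupA`, `groupB`, `t`, `p_raw`, `p_adj`.
#' @export
permanova <- function(x, groups, metric = "sorensen", n_perm = 9999,
                      seed = NULL, pairwise = TRUE) {
  d <- if (inherits(x, "dist")) x else community_distance(x, metric)
  d2 <- as.matrix(d)^2
  groups <- as.character(groups)
  N <- nrow(d2)
  if (length(groups) != N) stop("one group label per sample", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs at least two samples",
                          call. = FALSE)
  if (permanova_ss(d2, groups)[["ss_t"]] <= 0) {
    stop("no variation among samples (all pairwise distances zero)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  f_obs <- permanova_F(d2, groups)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    permanova_F(d2, sample(groups))
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  res <- structure(list(pseudo_F = f_obs,
                        df_among = length(tab) - 1L,
                        df_within = N - length(tab),
                        p = p, n_perm = n_perm),
                   class = "permanova")
  if (pairwise && length(tab) > 2L) {
    nm <- names(tab)
    prs <- utils::combn(nm, 2)
    rows <- apply(prs, 2, function(pr) {
      idx <- which(groups %in% pr)
      sub <- d2[idx, idx, drop = FALSE]
      g <- groups[idx]
      f0 <- permanova_F(sub, g)
      fp <- vapply(seq_len(n_perm), function(i) permanova_F(sub, sample(g)),
                   numeric(1))
      c(t = sqrt(f0), p = (1 + sum(fp >= f0)) / (n_perm + 1))
    })
    pw <- data.frame(groupA = prs[1, ], groupB = prs[2, ],
                     t = rows["t", ], p_raw = rows["p", ],
                     stringsAsFactors = FALSE)
    pw$p_adj <- benjamini_hochberg(pw$p_raw)
    res$pairwise <- pw
  }
  res
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.3f, p = %.4g (%d permutations)\n",
              x$df_among, x$df_within, x$pseudo_F, x$p, x$n_perm))
  if (!is.null(x$pairwise)) {
    cat("Pairwise comparisons (t = sqrt(F), B-H adjusted p):\n")
    print(format(x$pairwise, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) followed by
#' Dunn's z for every group pair,
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with tie
#' term T = sum(t^3 - t) / (12 (N - 1)), two-sided normal p values,
#' Benjamini-Hochberg adjusted across pairs.
#'
#' @param values Numeric response.
#' @param groups Group labels, one per value.
#' @return List with `H`, `df`, `p`, and `pairwise` (data.frame with
#'   `groupA`, `groupB`, `z`, `p_raw`, `p_adj`).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab == 0L)) {
    stop("need at least two nonempty groups", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    # complete ties carry no rank information
    kw <- list(statistic = 0, parameter = length(tab) - 1L, p.value = 1)
  } else {
    kw <- kruskal.test(values, factor(groups))
  }
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  nm <- names(tab)
  prs <- utils::combn(nm, 2)
  z <- apply(prs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / tab[[pr[1]]] + 1 / tab[[pr[2]]]))
    dif <- rbar[[pr[1]]] - rbar[[pr[2]]]
    if (se > 0) dif / se else 0  # complete ties: no evidence either way
  })
  pw <- data.frame(groupA = prs[1, ], groupB = prs[2, ], z = z,
                   p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  pw$p_adj <- benjamini_hochberg(pw$p_raw)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the t approximation for the
#' p value (handles ties).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p` (two-sided).
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1);
#' delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of raw p values in (0, 1].
#' @return Adjusted p values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
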