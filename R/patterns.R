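#' Binarize a biomass field
#'
#' Mask convention is `field >= threshold`. The published thresholds are
#' 500 g m^-2 for vascular plants and 200 g m^-2 for Sphagnum; regime
#' thresholds and critical exponents are insensitive to these over wide
#' ranges, but filling factors are not.
#'
#' @param field numeric matrix.
#' @param threshold biomass threshold, g m^-2 (> 0).
#' @param species optional tag, `"vascular"` or `"sphagnum"`.
#' @return list of class `binary_pattern`: `mask` (logical matrix),
#'   `threshold`, `species`.
#' @export
binarize <- function(field, threshold, species = NULL) {
  if (threshold <= 0)
    peat_stop("threshold must be > 0", "peat_invalid_parameter")
  structure(list(mask = field >= threshold, threshold = threshold,
                 species = species),
            class = c("binary_pattern", "list"))
}

as_mask <- function(pattern) {
  if (inherits(pattern, "binary_pattern")) pattern$mask
  else if (is.matrix(pattern)) pattern != 0
  else peat_stop("expected a binary_pattern or matrix", "peat_validation_error")
}

#' Label connected components on the torus
#'
#' Connected-component labelling with wrap-around adjacency. Each cluster
#' carries winding flags: following its internal adjacencies around the
#' torus, a net nonzero displacement in x (or y) marks the cluster as
#' percolating — it covers a full turn around the torus — which is the
#' appropriate notion of percolation under periodic boundaries (touching two
#' opposite index edges is neither necessary nor sufficient).
#'
#' @param pattern [binarize()] output, or a logical/0-1 matrix.
#' @param connectivity 4 or 8 (default 8, matching the usual
#'   connected-component convention for these patterns; classical
#'   site-percolation results use 4).
#' @param dx cell size in metres used for areas in m^2.
#' @return list of class `cluster_set`: `labels` (integer matrix, 0 =
#'   background, clusters 1..K in scan order), `area_cells`, `area_m2`,
#'   `wraps_x`, `wraps_y`, `percolating` (either flag), `connectivity`, `dx`.
#' @export
label_clusters_torus <- function(pattern, connectivity = 8, dx = 1) {
  if (!connectivity %in% c(4, 8))
    peat_stop("connectivity must be 4 or 8", "peat_invalid_parameter")
  mask <- as_mask(pattern)
  out <- cpp_label_torus(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                         as.integer(connectivity))
  structure(list(labels = out$labels,
                 area_cells = out$area_cells,
                 area_m2 = out$area_cells * dx^2,
                 wraps_x = out$wraps_x, wraps_y = out$wraps_y,
                 percolating = out$wraps_x | out$wraps_y,
                 connectivity = connectivity, dx = dx),
            class = c("cluster_set", "list"))
}

#' Number of clusters in a cluster set
#' @param clusters [label_clusters_torus()] output.
#' @export
n_clusters <- function(clusters) length(clusters$area_cells)

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d percolating (connectivity %d)\n",
              n_clusters(x), sum(x$percolating), x$connectivity))
  invisible(x)
}

#' Filling factor
#'
#' Fraction of the grid covered by the mask.
#'
#' @param pattern [binarize()] output or logical matrix.
#' @return fraction in `[0, 1]`.
#' @export
filling_factor <- function(pattern) {
  mask <- as_mask(pattern)
  sum(mask) / length(mask)
}

#' Mean finite-cluster area
#'
#' Arithmetic mean area (m^2) over the non-percolating clusters, the
#' statistic fitted against the filling factor near the percolation
#' transition of the vegetation patterns.
#'
#' @param clusters [label_clusters_torus()] output.
#' @return mean area in m^2.
#' @export
mean_finite_cluster_area <- function(clusters) {
  fin <- !clusters$percolating
  if (!any(fin))
    peat_stop("no finite (non-percolating) cluster", "peat_undefined_value")
  mean(clusters$area_m2[fin])
}

#' Size-weighted mean finite-cluster size
#'
#' The second-moment mean cluster size of percolation theory,
#' `S = sum(s^2 n_s) / sum(s n_s)` over non-percolating clusters — the
#' expected size of the cluster containing a randomly chosen occupied cell.
#' For two-dimensional uncorrelated site percolation this statistic diverges
#' at the threshold with the classical exponent gamma = 43/18; the plain
#' arithmetic mean ([mean_finite_cluster_area()]) does not.
#'
#' @param clusters [label_clusters_torus()] output.
#' @param units `"cells"` (default) or `"m2"`.
#' @return size-weighted mean cluster size.
#' @export
mean_finite_cluster_size <- function(clusters, units = c("cells", "m2")) {
  units <- match.arg(units)
  fin <- !clusters$percolating
  if (!any(fin))
    peat_stop("no finite (non-percolating) cluster", "peat_undefined_value")
  s <- clusters$area_cells[fin]
  out <- sum(as.numeric(s)^2) / sum(as.numeric(s))
  if (units == "m2") out * clusters$dx^2 else out
}

#' Classify the pattern regime (1-6)
#'
#' Decision table over the two species' cluster sets, in order:
#' \enumerate{
#'   \item vascular filling factor `< eps` -> regime 1 (full Sphagnum cover);
#'   \item Sphagnum filling factor `< eps` -> regime 6 (full vascular cover);
#'   \item both species percolating -> ambiguous-regime error (carries both
#'     flag sets);
#'   \item Sphagnum percolates only: regime 2 (sparse vascular spots) when no
#'     finite Sphagnum cluster exists, else regime 3 (vascular lines/spots in
#'     a percolating Sphagnum network);
#'   \item vascular percolates only: regime 4 (percolating vascular network
#'     with extra finite vascular clusters) when finite vascular clusters
#'     exist, else regime 5 (vascular dominance, isolated Sphagnum spots);
#'   \item neither percolating (not produced by the model's steady patterns
#'     but possible on arbitrary masks): the denser species is treated as the
#'     matrix phase (regime 3 when Sphagnum is denser, else 4), with a
#'     warning.
#' }
#'
#' @param B_clusters,S_clusters [label_clusters_torus()] of the vascular and
#'   Sphagnum masks (same grid).
#' @param B_fill,S_fill filling factors of the two masks.
#' @param eps emptiness tolerance on the filling factors (default 1e-3).
#' @return integer regime in 1..6.
#' @export
classify_regime <- function(B_clusters, S_clusters, B_fill, S_fill,
                            eps = 1e-3) {
  if (B_fill < eps) return(1L)
  if (S_fill < eps) return(6L)
  B_perc <- any(B_clusters$percolating)
  S_perc <- any(S_clusters$percolating)
  if (B_perc && S_perc)
    peat_stop("both species percolate: regime ambiguous",
              "peat_ambiguous_regime",
              B_wraps = cbind(x = B_clusters$wraps_x, y = B_clusters$wraps_y),
              S_wraps = cbind(x = S_clusters$wraps_x, y = S_clusters$wraps_y))
  if (S_perc) {
    finite_S <- any(!S_clusters$percolating)
    return(if (finite_S) 3L else 2L)
  }
  if (B_perc) {
    finite_B <- any(!B_clusters$percolating)
    return(if (finite_B) 4L else 5L)
  }
  warning("neither species percolates; classifying by dominant cover")
  if (S_fill >= B_fill) 3L else 4L
}

#' Fit a Gaussian peak to cluster counts along the nutrient ladder
#'
#' Least-squares Gaussian `a * exp(-(x - center)^2 / (2 w^2)) + offset`
#' fitted to cluster counts as a function of nutrient input; the peak centre
#' defines the transition from approximately circular to elongated clusters.
#' Both fit variants (free or zero baseline offset) are available.
#'
#' @param x nutrient-input values (>= 5 points).
#' @param counts cluster counts at each `x`.
#' @param offset include a free baseline offset (default `TRUE`).
#' @return list of class `peak_fit`: `center`, `width`, `amplitude`,
#'   `offset`, `se_center`, `fit` (the `nls` object). A centre within half a
#'   ladder step of the range boundary triggers a boundary-centre warning.
#' @export
fit_transition_peak <- function(x, counts, offset = TRUE) {
  if (length(x) < 5 || length(counts) != length(x))
    peat_stop("need >= 5 (x, count) points", "peat_validation_error")
  if (all(counts == 0))
    peat_stop("all counts are zero: no peak to fit", "peat_fit_failure")
  w <- pmax(counts - min(counts), 0)
  c0 <- if (sum(w) > 0) sum(x * w) / sum(w) else mean(x)
  w0 <- if (sum(w) > 0) sqrt(sum(w * (x - c0)^2) / sum(w)) else diff(range(x)) / 4
  w0 <- max(w0, diff(range(x)) / 20)
  start <- list(a = max(counts) - min(counts), center = c0, width = w0)
  if (offset) start$o <- min(counts)
  form <- if (offset) counts ~ a * exp(-(x - center)^2 / (2 * width^2)) + o
          else counts ~ a * exp(-(x - center)^2 / (2 * width^2))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = x, counts = counts),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      peat_stop(paste0("Gaussian fit did not converge: ", conditionMessage(e)),
                "peat_fit_failure"))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["center", "Std. Error"],
                 error = function(e) NA_real_)
  step <- if (length(x) > 1) min(diff(sort(unique(x)))) else 0
  if (est[["center"]] <= min(x) + step / 2 || est[["center"]] >= max(x) - step / 2)
    warning("fitted peak centre lies at the ladder boundary")
  structure(list(center = unname(est[["center"]]),
                 width = abs(unname(est[["width"]])),
                 amplitude = unname(est[["a"]]),
                 offset = if (offset) unname(est[["o"]]) else 0,
                 se_center = se, fit = fit),
            class = c("peak_fit", "list"))
}

#' Fit the percolation critical exponent
#'
#' Near the percolation transition the mean cluster area diverges as a power
#' law of the distance of the filling factor `p` from its critical value:
#' `A ~ |p - p_c|^(-gamma)`. The exponent is estimated by linear regression
#' of `log(A)` on `log|p - p_c|` over the fit window; `gamma = -slope` with
#' its regression standard error.
#'
#' @param p filling factors (none equal to `p_c`).
#' @param area mean cluster areas at each `p`.
#' @param p_c critical filling factor.
#' @param window half-width of the fit window on `|p - p_c|` (default 0.15;
#'   scaling holds only near criticality). The number of points retained is
#'   reported so window sensitivity can be assessed.
#' @return list of class `percolation_fit`: `gamma`, `se`, `p_c`, `window`,
#'   `n_points`, `fit` (the `lm` object).
#' @export
fit_percolation_exponent <- function(p, area, p_c, window = 0.15) {
  if (any(p == p_c))
    peat_stop("points with p == p_c are not allowed", "peat_domain_error")
  keep <- abs(p - p_c) <= window & is.finite(area) & area > 0
  if (sum(keep) < 4)
    peat_stop("need >= 4 usable points inside the fit window",
              "peat_validation_error")
  lx <- log(abs(p[keep] - p_c))
  ly <- log(area[keep])
  fit <- lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))$coefficients # exact data: se ~ 0
  structure(list(gamma = -unname(coef(fit)[2]),
                 se = unname(sm["lx", "Std. Error"]),
                 p_c = p_c, window = window, n_points = sum(keep), fit = fit),
            class = c("percolation_fit", "list"))
}

#' @export
print.percolation_fit <- function(x, ...) {
  cat(sprintf("<percolation_fit> gamma = %.3f +/- %.3f (p_c = %.3f, %d points, window %.2f)\n",
              x$gamma, x$se, x$p_c, x$n_points, x$window))
  invisible(x)
}

#' Estimate the critical filling factor by bracketing
#'
#' `p_c` is the midpoint between the largest non-percolating and the
#' smallest percolating filling factor observed for the species —
#' assumption-free, no functional form imposed.
#'
#' @param fill filling factors across a series of patterns.
#' @param percolating logical percolation state of each pattern.
#' @return list: `p_c`, `bracket` (the two bracketing filling factors).
#' @export
estimate_critical_filling <- function(fill, percolating) {
  if (length(fill) != length(percolating))
    peat_stop("fill and percolating must have equal length",
              "peat_validation_error")
  if (!any(percolating) || all(percolating))
    peat_stop("series does not bracket the percolation switch",
              "peat_not_bracketed")
  lo <- max(fill[!percolating])
  hi <- min(fill[percolating])
  list(p_c = (lo + hi) / 2, bracket = c(non_percolating = lo, percolating = hi))
}
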