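test_that("binarization follows the >= threshold convention", {
  expect_equal(sum(binarize(matrix(0, 8, 8), 500)$mask), 0)
  expect_true(all(binarize(matrix(500, 8, 8), 500)$mask))
  f <- matrix(c(0, 600), 4, 4)
  expect_identical(binarize(f, 500)$mask, f == 600)
  expect_error(binarize(f, 0), class = "peat_invalid_parameter")
})

test_that("filling factor counts mask cells", {
  expect_equal(filling_factor(matrix(FALSE, 4, 4)), 0)
  expect_equal(filling_factor(matrix(TRUE, 4, 4)), 1)
  m <- matrix(FALSE, 128, 128)
  m[seq_len(4096)] <- TRUE
  expect_equal(filling_factor(m), 0.25)
})

test_that("toroidal labelling handles wrap merges and winding", {
  # a full row winds around x
  m <- matrix(FALSE, 6, 6); m[3, ] <- TRUE
  cl <- label_clusters_torus(m, 4)
  expect_equal(n_clusters(cl), 1)
  expect_true(cl$wraps_x); expect_false(cl$wraps_y)

  # two disjoint 2x2 blocks: no percolation
  m <- matrix(FALSE, 8, 8)
  m[1:2, 1:2] <- TRUE; m[5:6, 5:6] <- TRUE
  cl <- label_clusters_torus(m, 4, dx = 2)
  expect_equal(n_clusters(cl), 2)
  expect_equal(sort(cl$area_cells), c(4, 4))
  expect_equal(sort(cl$area_m2), c(16, 16))
  expect_false(any(cl$percolating))

  # a 2x2 block straddling the x boundary merges across the seam
  m <- matrix(FALSE, 8, 8)
  m[3:4, c(1, 8)] <- TRUE
  cl <- label_clusters_torus(m, 4)
  expect_equal(n_clusters(cl), 1)
  expect_equal(cl$area_cells, 4)
  expect_false(any(cl$percolating))

  # full column winds around y
  m <- matrix(FALSE, 5, 7); m[, 2] <- TRUE
  cl <- label_clusters_torus(m, 4)
  expect_true(cl$wraps_y); expect_false(cl$wraps_x)

  # full grid winds both ways
  cl <- label_clusters_torus(matrix(TRUE, 6, 6), 4)
  expect_true(cl$wraps_x && cl$wraps_y)
})

test_that("labelling matches the flood-fill + doubled-torus oracle exhaustively on 4x4", {
  # all 2^16 masks, 4-connectivity: counts, area multisets, winding flags and
  # the label partition itself must agree with the independent oracle
  for (code in 0:65535) {
    m <- matrix(bitwAnd(bitwShiftR(code, 0:15), 1L) == 1L, 4, 4)
    cl <- label_clusters_torus(m, 4)
    or <- oracle_cluster_set(m, 4)
    if (length(or$areas) != n_clusters(cl) ||
        !identical(sort(cl$area_cells), sort(or$areas)) ||
        !identical(canonical_labels(cl$labels), canonical_labels(or$labels)) ||
        !identical(cl$wraps_x, or$wraps_x) ||
        !identical(cl$wraps_y, or$wraps_y)) {
      fail(sprintf("mismatch with oracle at mask code %d", code))
    }
  }
  succeed()
})

test_that("labelling matches the oracle on random 16x16 masks at both connectivities", {
  set.seed(99)
  for (p_occ in c(0.3, 0.5, 0.7)) {
    for (rep in 1:34) {
      m <- matrix(runif(256) < p_occ, 16, 16)
      for (conn in c(4, 8)) {
        cl <- label_clusters_torus(m, conn)
        or <- oracle_cluster_set(m, conn)
        expect_identical(sort(cl$area_cells), sort(or$areas))
        expect_identical(canonical_labels(cl$labels), canonical_labels(or$labels))
        expect_identical(cl$wraps_x, or$wraps_x)
        expect_identical(cl$wraps_y, or$wraps_y)
      }
    }
  }
})

test_that("cluster statistics are invariant under torus shifts and rotations", {
  set.seed(5)
  m <- matrix(runif(20 * 20) < 0.5, 20, 20)
  base <- label_clusters_torus(m, 8)
  sig <- function(cl) list(sort(cl$area_cells), sum(cl$wraps_x), sum(cl$wraps_y))
  shift2 <- function(mm, dy, dx) {
    ny <- nrow(mm); nx <- ncol(mm)
    mm[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
  }
  for (sh in list(c(1, 0), c(0, 7), c(9, 13))) {
    cl <- label_clusters_torus(shift2(m, sh[1], sh[2]), 8)
    expect_identical(sig(cl), sig(base))
  }
  rot <- label_clusters_torus(t(m[nrow(m):1, ]), 8) # 90 degree rotation
  expect_identical(sort(rot$area_cells), sort(base$area_cells))
  expect_equal(sum(rot$wraps_x) + sum(rot$wraps_y),
               sum(base$wraps_x) + sum(base$wraps_y))
})

test_that("mean finite-cluster statistics exclude percolating clusters", {
  m <- matrix(FALSE, 8, 8)
  m[1:2, 1:2] <- TRUE; m[5:6, 5:6] <- TRUE
  cl <- label_clusters_torus(m, 4, dx = 2)
  expect_equal(mean_finite_cluster_area(cl), 16) # 4 cells x 4 m2
  m[4, ] <- TRUE # add a percolating stripe
  cl <- label_clusters_torus(m, 4, dx = 1)
  expect_equal(mean_finite_cluster_area(cl), 4)
  # size-weighted mean: (16+16)/(4+4) = 4 cells here (equal sizes)
  expect_equal(mean_finite_cluster_size(cl), 4)
  # unequal sizes weight the big cluster: {1, 3} -> 10/4
  m2 <- matrix(FALSE, 8, 8)
  m2[1, 1] <- TRUE; m2[4, 2:4] <- TRUE
  cl2 <- label_clusters_torus(m2, 4)
  expect_equal(mean_finite_cluster_area(cl2), 2)
  expect_equal(mean_finite_cluster_size(cl2), 10 / 4)
  # all-percolating mask has no finite cluster
  cl3 <- label_clusters_torus(matrix(TRUE, 4, 4), 4)
  expect_error(mean_finite_cluster_area(cl3), class = "peat_undefined_value")
  # oracle cross-check on a random mask
  set.seed(31)
  m4 <- matrix(runif(144) < 0.4, 12, 12)
  cl4 <- label_clusters_torus(m4, 4, dx = 2)
  or <- oracle_cluster_set(m4, 4)
  fin <- !(or$wraps_x | or$wraps_y)
  expect_equal(mean_finite_cluster_area(cl4), mean(or$areas[fin]) * 4)
})

test_that("regime classifier follows the decision table", {
  g <- 16
  full <- matrix(TRUE, g, g); empty <- matrix(FALSE, g, g)
  cs <- function(m) label_clusters_torus(m, 8)
  # full Sphagnum, no vascular -> regime 1
  expect_equal(classify_regime(cs(empty), cs(full), 0, 1), 1L)
  # full vascular, no Sphagnum -> regime 6
  expect_equal(classify_regime(cs(full), cs(empty), 1, 0), 6L)
  # disjoint vascular spots in a percolating Sphagnum sea -> regime 2
  B <- matrix(FALSE, g, g)
  B[2:4, 2:4] <- TRUE; B[9:11, 9:11] <- TRUE
  S <- !B
  expect_equal(classify_regime(cs(B), cs(S), filling_factor(B),
                               filling_factor(S)), 2L)
  # Sphagnum percolates AND has finite fragments -> regime 3
  S3 <- matrix(FALSE, g, g); S3[1:3, ] <- TRUE; S3[8, 8] <- TRUE
  B3 <- matrix(FALSE, g, g); B3[5:6, 3:6] <- TRUE
  expect_equal(classify_regime(cs(B3), cs(S3), filling_factor(B3),
                               filling_factor(S3)), 3L)
  # vascular percolates with extra finite vascular clusters -> regime 4
  B4 <- matrix(FALSE, g, g); B4[1:3, ] <- TRUE; B4[8, 8] <- TRUE
  S4 <- matrix(FALSE, g, g); S4[5:6, 3:6] <- TRUE
  expect_equal(classify_regime(cs(B4), cs(S4), filling_factor(B4),
                               filling_factor(S4)), 4L)
  # single percolating vascular mass, isolated Sphagnum spots -> regime 5
  B5 <- matrix(TRUE, g, g); B5[5:6, 5:6] <- FALSE
  S5 <- !B5
  expect_equal(classify_regime(cs(B5), cs(S5), filling_factor(B5),
                               filling_factor(S5)), 5L)
  # both percolating -> ambiguous signal
  Bx <- matrix(FALSE, g, g); Bx[4, ] <- TRUE
  Sx <- matrix(FALSE, g, g); Sx[, 7] <- TRUE
  expect_error(classify_regime(cs(Bx), cs(Sx), filling_factor(Bx),
                               filling_factor(Sx)),
               class = "peat_ambiguous_regime")
})

test_that("Gaussian peak fitter recovers centres, noisy or exact", {
  x <- seq(0.5, 4, by = 0.25)
  y <- 40 * exp(-(x - 2)^2 / (2 * 0.5^2)) + 3
  fit <- fit_transition_peak(x, y)
  expect_equal(fit$center, 2, tolerance = 1e-6)
  expect_equal(fit$width, 0.5, tolerance = 1e-6)
  expect_equal(fit$offset, 3, tolerance = 1e-5)
  # 5% noise, 20 points: centre within 0.1
  set.seed(12)
  yn <- y * (1 + rnorm(length(y), 0, 0.05))
  expect_lt(abs(fit_transition_peak(x, yn)$center - 2), 0.1)
  # zero-offset variant on offset-free data
  y0 <- 40 * exp(-(x - 2)^2 / (2 * 0.5^2))
  expect_equal(fit_transition_peak(x, y0, offset = FALSE)$center, 2,
               tolerance = 1e-6)
  # degenerate inputs
  expect_error(fit_transition_peak(x, rep(0, length(x))),
               class = "peat_fit_failure")
  expect_error(fit_transition_peak(1:4, 1:4), class = "peat_validation_error")
  # a monotone ramp has no interior peak: either the fit fails outright or
  # the centre lands on the ladder boundary with a warning
  ramp <- tryCatch(
    { fit_transition_peak(x, 10 * x); "silent" },
    peat_fit_failure = function(e) "signalled",
    warning = function(w)
      if (grepl("boundary", conditionMessage(w))) "signalled" else "silent")
  expect_equal(ramp, "signalled")
})

test_that("percolation exponent fit is exact on exact power-law data", {
  pts <- power_law_cluster_samples(0.83, 0.37, seq(0.1, 0.3, by = 0.02))
  fit <- fit_percolation_exponent(pts$p, pts$area, 0.37, window = 0.4)
  expect_equal(fit$gamma, 0.83, tolerance = 1e-9)
  expect_lt(fit$se, 1e-9)
  # 10% lognormal noise, 12 points: recovery within 2 standard errors
  set.seed(77)
  pts <- power_law_cluster_samples(0.83, 0.37, seq(0.39, 0.50, by = 0.01),
                                   noise_sd = 0.1, seed = 42)
  fit <- fit_percolation_exponent(pts$p, pts$area, 0.37, window = 0.2)
  expect_lt(abs(fit$gamma - 0.83), 2 * fit$se)
  expect_error(fit_percolation_exponent(c(0.37, 0.4, 0.45, 0.5), rep(1, 4), 0.37),
               class = "peat_domain_error")
})

test_that("critical filling factor is bracketed by the percolation switch", {
  est <- estimate_critical_filling(c(0.2, 0.3, 0.36, 0.38, 0.45),
                                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(est$p_c, 0.37)
  expect_equal(unname(est$bracket), c(0.36, 0.38))
  expect_error(estimate_critical_filling(c(0.1, 0.2), c(FALSE, FALSE)),
               class = "peat_not_bracketed")
  # Monte-Carlo: random site percolation at 128^2 brackets the literature
  # threshold 0.5927 within a few hundredths
  g <- sim_grid(128, 128, 1)
  probs <- seq(0.52, 0.67, by = 0.01)
  fills <- perc <- numeric(length(probs))
  for (i in seq_along(probs)) {
    fld <- uncorrelated_binary_field(g, probs[i], seed = 1000 + i)
    cl <- label_clusters_torus(fld, 4)
    fills[i] <- filling_factor(fld)
    perc[i] <- any(cl$percolating)
  }
  est <- estimate_critical_filling(fills, as.logical(perc))
  expect_lt(abs(est$p_c - 0.5927), 0.04)
})
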