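# Independent oracles used across the suite.
#
# oracle_label(): plain stack-based flood fill with a precomputed neighbour
# table — no offset tracking. Winding (torus percolation) is detected by a
# structurally different route than the package's labeller: the mask is tiled
# twice along one axis and a cluster winds in that direction iff a cell and
# its translated image end up in the same component of the doubled torus.

oracle_nbr_cache <- new.env(parent = emptyenv())

oracle_neighbors <- function(ny, nx, connectivity) {
  key <- paste(ny, nx, connectivity, sep = "_")
  if (!is.null(oracle_nbr_cache[[key]])) return(oracle_nbr_cache[[key]])
  offs <- if (connectivity == 8)
    cbind(dy = c(-1, 1, 0, 0, -1, -1, 1, 1), dx = c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  n <- ny * nx
  idx <- seq_len(n) - 1L
  y <- idx %% ny
  x <- idx %/% ny
  nbr <- matrix(0L, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    y2 <- (y + offs[k, 1]) %% ny
    x2 <- (x + offs[k, 2]) %% nx
    nbr[, k] <- y2 + ny * x2 + 1L
  }
  oracle_nbr_cache[[key]] <- nbr
  nbr
}

oracle_label <- function(mask, connectivity = 4) {
  ny <- nrow(mask); nx <- ncol(mask); n <- ny * nx
  nbr <- oracle_neighbors(ny, nx, connectivity)
  occ <- as.logical(mask)
  labels <- integer(n)
  areas <- integer(0)
  comp <- 0L
  for (i0 in which(occ)) {
    if (labels[i0] > 0L) next
    comp <- comp + 1L
    labels[i0] <- comp
    stack <- i0
    area <- 0L
    while (length(stack) > 0) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      area <- area + 1L
      for (j in nbr[i, ]) {
        if (occ[j] && labels[j] == 0L) {
          labels[j] <- comp
          stack <- c(stack, j)
        }
      }
    }
    areas[comp] <- area
  }
  list(labels = matrix(labels, ny, nx), areas = areas, n = comp)
}

# winding via the doubled-torus image test
oracle_cluster_set <- function(mask, connectivity = 4) {
  ny <- nrow(mask); nx <- ncol(mask)
  base <- oracle_label(mask, connectivity)
  k <- base$n
  wraps_x <- logical(k)
  wraps_y <- logical(k)
  if (k > 0) {
    dlx <- oracle_label(cbind(mask, mask), connectivity)$labels
    dly <- oracle_label(rbind(mask, mask), connectivity)$labels
    for (comp in seq_len(k)) {
      i <- which(base$labels == comp)[1]
      y <- (i - 1L) %% ny + 1L
      x <- (i - 1L) %/% ny + 1L
      wraps_x[comp] <- dlx[y, x] == dlx[y, x + nx]
      wraps_y[comp] <- dly[y, x] == dly[y + ny, x]
    }
  }
  list(labels = base$labels, areas = base$areas,
       wraps_x = wraps_x, wraps_y = wraps_y)
}

# canonical form of a labelling: relabel in first-occurrence (column-major)
# order so two labellings can be compared directly
canonical_labels <- function(labels) {
  v <- as.vector(labels)
  seen <- unique(v[v > 0])
  out <- v
  out[v > 0] <- match(v[v > 0], seen)
  out
}

# scalar reference Euler step: explicit double loop over cells, neighbour
# indexing written out by hand; mirrors the model equations independently of
# the package's vectorised/compiled paths
reference_step <- function(state, params, grid, dt, forcing = NULL) {
  p <- params
  fo <- list(p = p$p, e = p$e, t_v = p$t_v)
  if (!is.null(forcing)) fo[names(forcing)] <- forcing
  ny <- grid$ny; nx <- grid$nx; dx <- grid$dx
  B <- state$B; S <- state$S; H <- state$H; N <- state$N
  Nc <- N / (H * p$theta)
  Bn <- B; Sn <- S; Hn <- H; Nn <- N
  wrap <- function(i, n) ((i - 1) %% n) + 1
  for (y in 1:ny) for (x in 1:nx) {
    nb <- list(c(wrap(y - 1, ny), x), c(wrap(y + 1, ny), x),
               c(y, wrap(x - 1, nx)), c(y, wrap(x + 1, nx)))
    f <- min(max((H[y, x] - p$z - p$h2) / (p$h1 - p$h2), 0), 1)
    lapB <- 0; lapS <- 0; darcy <- 0; ndif <- 0; nadv <- 0
    for (q in nb) {
      yq <- q[1]; xq <- q[2]
      lapB <- lapB + (B[yq, xq] - B[y, x])
      lapS <- lapS + (S[yq, xq] - S[y, x])
      darcy <- darcy + 0.5 * (H[y, x] + H[yq, xq]) * (H[yq, xq] - H[y, x])
      ndif <- ndif + 0.5 * (H[y, x] + H[yq, xq]) * (Nc[yq, xq] - Nc[y, x])
      nadv <- nadv + 0.5 * (H[y, x] * Nc[y, x] + H[yq, xq] * Nc[yq, xq]) *
        (H[yq, xq] - H[y, x])
    }
    dB <- p$r_B * Nc[y, x] * B[y, x] * f - (p$d + p$b) * B[y, x] -
      p$c_BS * S[y, x] - p$k_BS * S[y, x] * B[y, x] / (p$H_B + B[y, x]) +
      p$D_B * lapB / dx^2
    dS <- p$r_S * S[y, x] * (1 - S[y, x] / p$S_max) -
      p$k_SB * S[y, x] * B[y, x] / (p$H_S + S[y, x]) + p$D_S * lapS / dx^2
    dH <- (fo$p - fo$e * f - fo$t_v * f * B[y, x]) / p$theta +
      (p$k / p$theta) * darcy / dx^2
    dN <- p$N_in - p$u * Nc[y, x] * B[y, x] * f +
      (p$d * p$u / p$g_conv) * B[y, x] - p$r * N[y, x] +
      p$theta * p$D_N * ndif / dx^2 + p$k * nadv / dx^2
    Bn[y, x] <- max(B[y, x] + dt * dB, 0)
    Sn[y, x] <- max(S[y, x] + dt * dS, 0)
    Hn[y, x] <- max(H[y, x] + dt * dH, 1e-6)
    Nn[y, x] <- max(N[y, x] + dt * dN, 0)
  }
  field_state(Bn, Sn, Hn, Nn, time = state$time + dt)
}

# small valid state for quick tests
tiny_state <- function(ny = 4, nx = 4, params = peat_params(), seed = 1) {
  set.seed(seed)
  field_state(B = matrix(runif(ny * nx, 0, 600), ny, nx),
              S = matrix(runif(ny * nx, 0, 600), ny, nx),
              H = matrix(runif(ny * nx, 0.4, 1.8), ny, nx),
              N = matrix(runif(ny * nx, 0, 10), ny, nx))
}
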