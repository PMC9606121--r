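# Independent brute-force oracles used across test files.

# Plain-R per-step transport loop consuming the same RNG stream and dense
# stopping grid as the compiled transport, for per-voxel agreement checks.
oracle_transport_kernel <- function(nuclide, model, n_events, voxel_um,
                                    half_extent_um, seed) {
  g <- stopping_dense_grid(model)
  nd <- 2L * as.integer(floor(half_extent_um / voxel_um)) + 1L
  half <- (nd - 1) / 2
  step <- min(voxel_um / 5, 0.2)
  cutoff <- min(model$energy_MeV)
  inv_v <- 1 / voxel_um
  counts <- branch_allocation(nuclide$branch_fractions, n_events)
  acc <- array(0, c(nd, nd, nd))
  nS <- length(g$S)
  lookup <- function(E) {
    f <- (E - g$E0) / g$dE
    i <- min(max(floor(f), 0), nS - 2)
    w <- f - i
    g$S[i + 1] + w * (g$S[i + 2] - g$S[i + 1])
  }
  set.seed(seed)
  for (b in seq_along(counts)) {
    for (ev in seq_len(counts[b])) {
      mu <- 2 * runif(1) - 1
      phi <- 2 * pi * runif(1)
      st <- sqrt(max(0, 1 - mu^2))
      dir <- c(st * cos(phi), st * sin(phi), mu)
      E <- nuclide$alpha_energies_MeV[b]
      pos <- c(0, 0, 0)
      alive <- TRUE
      while (alive) {
        S <- lookup(E)
        dep <- S * step
        if (E - dep <= cutoff) {
          dep <- E
          mid <- pos
          alive <- FALSE
        } else {
          mid <- pos + 0.5 * step * dir
          pos <- pos + step * dir
          E <- E - dep
        }
        f <- mid * inv_v + 0.5 + half
        if (all(f >= 0 & f < nd)) {
          ii <- floor(f) + 1
          acc[ii[1], ii[2], ii[3]] <- acc[ii[1], ii[2], ii[3]] + dep
        }
      }
    }
  }
  acc / n_events
}

# Exhaustive group-by-distance radial average.
oracle_radial_average <- function(values) {
  d <- dim(values)
  half <- (d - 1) / 2
  r2 <- outer(outer((((seq_len(d[1]) - 1) - half[1]))^2,
                    (((seq_len(d[2]) - 1) - half[2]))^2, "+"),
              (((seq_len(d[3]) - 1) - half[3]))^2, "+")
  out <- values
  for (u in unique(as.vector(r2))) {
    sel <- r2 == u
    out[sel] <- mean(values[sel])
  }
  out
}

# Direct triple-loop cross-correlation oracle: out[r] = sum_o A[r+o] K[o].
oracle_convolve <- function(A, K) {
  da <- dim(A); dk <- dim(K)
  ck <- (dk + 1) / 2
  out <- array(0, da)
  for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) for (g in seq_len(dk[3])) {
    w <- K[a, b, g]
    if (w == 0) next
    o <- c(a, b, g) - ck
    src_lo <- pmax(1, 1 + o); src_hi <- pmin(da, da + o)
    if (any(src_lo > src_hi)) next
    dst_lo <- src_lo - o; dst_hi <- src_hi - o
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] +
      w * A[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  out
}

# Exhaustive Otsu scan: threshold maximizing between-class variance over
# all 256-bin histogram cut points.
oracle_otsu <- function(x, levels = 256) {
  x <- as.vector(x)
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), levels),
                levels)
  mids <- (br[-1] + br[-(levels + 1)]) / 2
  best <- -Inf; thr <- mids[1]
  for (t in seq_len(levels - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- br[t + 1] }
  }
  thr
}

# Brute-force connected components (8-connectivity) + intensity-weighted
# centroids, by repeated neighbourhood dilation.
oracle_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask != 0, arr.ind = TRUE)
  remaining <- rep(TRUE, nrow(idx))
  key <- paste(idx[, 1], idx[, 2])
  while (any(remaining)) {
    cur <- cur + 1L
    seed <- which(remaining)[1]
    comp <- seed
    grew <- TRUE
    while (grew) {
      grew <- FALSE
      for (cand in which(remaining)) {
        if (cand %in% comp) next
        dr <- abs(idx[cand, 1] - idx[comp, 1])
        dc <- abs(idx[cand, 2] - idx[comp, 2])
        if (any(dr <= 1 & dc <= 1)) { comp <- c(comp, cand); grew <- TRUE }
      }
    }
    lab[idx[comp, , drop = FALSE]] <- cur
    remaining[comp] <- FALSE
  }
  lab
}

# Blob image helpers for registration/fusion tests: smooth asymmetric blobs.
make_blob_image <- function(n = 96, seed = 1, k = 4) {
  set.seed(seed)
  img <- matrix(0, n, n)
  cx <- runif(k, n * 0.3, n * 0.7)
  cy <- runif(k, n * 0.3, n * 0.7)
  s <- runif(k, n / 20, n / 8)
  a <- runif(k, 0.5, 2)
  xs <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)  # column coordinate (x)
  ys <- matrix(seq_len(n) - 1, n, n)                # row coordinate (y)
  for (i in seq_len(k))
    img <- img + a[i] * exp(-((xs - cx[i])^2 + (ys - cy[i])^2) / (2 * s[i]^2))
  img
}
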