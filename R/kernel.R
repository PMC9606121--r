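#' Generate the At-211-chain alpha energy-deposition kernel
#'
#' Simplified Monte Carlo: for each emission a decay pathway is sampled from
#' the branch fractions, an isotropic direction is drawn, and a straight
#' CSDA track is transported from the centre of the central voxel,
#' depositing S(E) * step per sub-voxel step and the residual energy at the
#' track endpoint. Per-track energy conservation is exact, so the kernel
#' total equals the branch-weighted mean initial alpha energy. Per-voxel
#' relative standard errors are tracked from per-event sums of squares.
#'
#' @param nuclide a [nuclide_at211()]-style object.
#' @param model a [stopping_power_model()].
#' @param n_events number of source alpha emissions (>= 1).
#' @param voxel_um cubic voxel edge (um), default 1.
#' @param half_extent_um grid half-extent (um); the default 75 gives the
#'   151^3 grid at 1 um. Must cover the maximum CSDA range unless
#'   `truncate = TRUE`.
#' @param seed RNG seed; the same seed reproduces the kernel bitwise.
#' @param truncate allow a grid smaller than the alpha range (deposition
#'   outside the grid is then lost).
#' @param step_um sub-voxel step; default `min(voxel_um / 5, 0.2)`.
#' @return A `dose_kernel`: fields `values` (3D array, MeV per source
#'   emission per voxel), `voxel_xyz_um`, `n_events`, `rel_uncertainty`
#'   (relative standard errors), `total_MeV`, `provenance`.
#' @export
generate_kernel <- function(nuclide, model, n_events, voxel_um = 1,
                            half_extent_um = 75, seed = 1L,
                            truncate = FALSE, step_um = NULL) {
  if (n_events < 1) stop("n_events must be >= 1")
  if (voxel_um <= 0) stop("voxel_um must be positive")
  max_range <- max(csda_range(nuclide$alpha_energies_MeV, model))
  if (!truncate && half_extent_um < max_range)
    stop("half_extent_um (", half_extent_um, ") below max CSDA range (",
         round(max_range, 1), " um); pass truncate = TRUE to allow")
  if (is.null(step_um)) step_um <- min(voxel_um / 5, 0.2)
  dim <- 2L * as.integer(floor(half_extent_um / voxel_um)) + 1L
  g <- stopping_dense_grid(model)
  counts <- branch_allocation(nuclide$branch_fractions, n_events)
  set.seed(seed)
  res <- cpp_transport_kernel(dim, voxel_um, counts,
                              nuclide$alpha_energies_MeV,
                              g$E0, g$dE, g$S,
                              step_um, min(model$energy_MeV))
  values <- array(res$sum / n_events, c(dim, dim, dim))
  rel <- array(0, c(dim, dim, dim))
  if (n_events > 1) {
    vars <- (res$sumsq - res$sum^2 / n_events) / (n_events - 1)
    se <- sqrt(pmax(vars, 0) / n_events)
    nz <- res$sum > 0
    rel[nz] <- se[nz] / values[nz]
  }
  new_dose_kernel(values, rep(voxel_um, 3), n_events, rel,
                  provenance = list(nuclide = nuclide$name,
                                    branch_fractions = nuclide$branch_fractions,
                                    alpha_energies_MeV = nuclide$alpha_energies_MeV,
                                    stopping_power_id = model$id,
                                    step_um = step_um, seed = seed,
                                    radially_averaged = FALSE))
}

#' Deterministic per-branch event allocation
#'
#' Events are apportioned to decay pathways by cumulative rounding of the
#' branch fractions (largest-remainder style), so the simulated branch mix
#' is exact and the kernel total equals the branch-weighted mean initial
#' energy rather than fluctuating with branch sampling.
#'
#' @param fractions branch fractions summing to 1.
#' @param n_events total emissions.
#' @return Integer-valued vector of per-branch counts summing to `n_events`.
#' @export
branch_allocation <- function(fractions, n_events)
  diff(c(0, round(cumsum(fractions) * n_events)))

new_dose_kernel <- function(values, voxel_xyz_um, n_events, rel_uncertainty,
                            provenance = list()) {
  structure(list(values = values, voxel_xyz_um = as.numeric(voxel_xyz_um),
                 n_events = n_events, rel_uncertainty = rel_uncertainty,
                 total_MeV = sum(values), provenance = provenance),
            class = "dose_kernel")
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat("<dose_kernel> ", paste(dim(x$values), collapse = "x"),
      " voxels of ", paste(signif(x$voxel_xyz_um, 4), collapse = "x"),
      " um; total ", signif(x$total_MeV, 6), " MeV/emission; ",
      format(x$n_events, big.mark = ","), " events\n", sep = "")
  invisible(x)
}

#' Radially average a cubic kernel
#'
#' Voxels are grouped by the Euclidean distance of their centres from the
#' source voxel centre and each voxel's value is replaced by its group mean.
#' By default groups are the exact-distance classes of the cubic lattice
#' (so the result is exactly invariant under the octahedral symmetries of
#' the grid); `bin_width_vox` pools instead into fixed-width half-open
#' radial bins. Group means preserve the kernel total; uncertainties are
#' propagated as bin-pooled standard errors.
#'
#' @param kernel a cubic-voxel `dose_kernel`.
#' @param bin_width_vox optional radial bin width in voxel units; `NULL`
#'   (default) groups by exact voxel-centre distance.
#' @return A `dose_kernel` with averaged values.
#' @export
radial_average <- function(kernel, bin_width_vox = NULL) {
  v <- kernel$voxel_xyz_um
  if (max(abs(v - v[1])) > 1e-9 * v[1])
    stop("radial averaging requires cubic voxels; average before rebinning")
  d <- dim(kernel$values)
  half <- (d - 1) / 2
  i2 <- ((seq_len(d[1]) - 1) - half[1])^2
  j2 <- ((seq_len(d[2]) - 1) - half[2])^2
  k2 <- ((seq_len(d[3]) - 1) - half[3])^2
  r2 <- outer(outer(i2, j2, "+"), k2, "+")
  key <- if (is.null(bin_width_vox)) as.integer(round(r2 * 4)) else
    as.integer(floor(sqrt(r2) / bin_width_vox))  # exact classes vs bins
  key <- key + 1L
  nk <- max(key)
  cnt <- tabulate(key, nk)
  val <- as.vector(kernel$values)
  sums <- numeric(nk)
  tmp <- rowsum(val, key)
  sums[as.integer(rownames(tmp))] <- tmp
  m <- sums / pmax(cnt, 1)
  out <- array(m[key], d)
  se2 <- as.vector((kernel$rel_uncertainty * kernel$values)^2)
  s2 <- numeric(nk)
  tmp <- rowsum(se2, key)
  s2[as.integer(rownames(tmp))] <- tmp
  pooled_se <- sqrt(s2) / pmax(cnt, 1)
  rel <- pooled_se[key] / ifelse(m[key] > 0, m[key], Inf)
  prov <- kernel$provenance
  prov$radially_averaged <- TRUE
  new_dose_kernel(out, v, kernel$n_events, array(rel, d), prov)
}

block_sum_axis <- function(arr, f, axis) {
  if (f == 1) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dm <- dim(x)
  grp <- rep(seq_len(dm[1] / f), each = f)
  x <- rowsum(matrix(x, nrow = dm[1]), grp)
  dim(x) <- c(dm[1] / f, dm[2], dm[3])
  aperm(x, order(perm))
}

#' Rebin a kernel to coarser voxels by block summation
#'
#' Energy is extensive, so output voxels are sums of their constituent fine
#' voxels and the kernel total is preserved. The output grid has odd
#' dimensions with the source voxel inside the central output voxel (for
#' even rebin factors the source centre sits half a fine voxel off the
#' coarse-voxel centre, the closest achievable alignment). The fine grid is
#' zero-padded outward to complete the edge blocks.
#'
#' @param kernel a `dose_kernel`.
#' @param target_xy_um,target_z_um target voxel sizes; must be integer
#'   multiples of the corresponding source voxel size.
#' @return A `dose_kernel` on the coarser grid.
#' @export
rebin_kernel <- function(kernel, target_xy_um, target_z_um = target_xy_um) {
  src <- kernel$voxel_xyz_um
  tgt <- c(target_xy_um, target_xy_um, target_z_um)
  f <- tgt / src
  if (any(abs(f - round(f)) > 1e-9))
    stop("target voxel sizes must be integer multiples of source sizes")
  f <- as.integer(round(f))
  d <- dim(kernel$values)
  half <- (d - 1L) %/% 2L
  ctr_in_block <- (f - 1L) %/% 2L
  H <- as.integer(ceiling((half - ctr_in_block) / f))
  newd <- f * (2L * H + 1L)
  pad_lo <- H * f + ctr_in_block - half
  pad_hi <- newd - d - pad_lo
  stopifnot(all(pad_lo >= 0), all(pad_hi >= 0))
  padded <- array(0, newd)
  se2 <- array(0, newd)
  idx <- lapply(1:3, function(a) seq_len(d[a]) + pad_lo[a])
  padded[idx[[1]], idx[[2]], idx[[3]]] <- kernel$values
  se2[idx[[1]], idx[[2]], idx[[3]]] <-
    (kernel$rel_uncertainty * kernel$values)^2
  for (a in 1:3) {
    padded <- block_sum_axis(padded, f[a], a)
    se2 <- block_sum_axis(se2, f[a], a)
  }
  rel <- sqrt(se2) / ifelse(padded > 0, padded, Inf)
  new_dose_kernel(padded, tgt, kernel$n_events, rel, kernel$provenance)
}

#' Mean statistical uncertainty of the kernel
#'
#' Mean relative standard error over voxels with nonzero value, as a
#' percentage.
#'
#' @param kernel a `dose_kernel` carrying `rel_uncertainty`.
#' @return Percentage.
#' @export
kernel_uncertainty_summary <- function(kernel) {
  nz <- kernel$values > 0
  if (!any(nz)) stop("all-zero kernel: uncertainty summary undefined")
  100 * mean(kernel$rel_uncertainty[nz])
}

#' Radial profile of a cubic kernel
#'
#' Mean energy per voxel as a function of voxel-centre distance, for
#' profile plots and support checks.
#'
#' @param kernel a cubic `dose_kernel`.
#' @param bin_um radial bin width (um).
#' @return Tibble with `r_um` (bin centre), `mean_MeV`, `n_voxels`.
#' @export
kernel_radial_profile <- function(kernel, bin_um = 1) {
  v <- kernel$voxel_xyz_um[1]
  d <- dim(kernel$values)
  half <- (d - 1) / 2
  r <- sqrt(outer(outer((((seq_len(d[1]) - 1) - half[1]) * v)^2,
                        (((seq_len(d[2]) - 1) - half[2]) * v)^2, "+"),
                  (((seq_len(d[3]) - 1) - half[3]) * v)^2, "+"))
  b <- factor(floor(as.vector(r) / bin_um))
  m <- as.vector(rowsum(as.vector(kernel$values), b)) / tabulate(b)
  tibble::tibble(r_um = (as.numeric(levels(b)) + 0.5) * bin_um,
                 mean_MeV = m, n_voxels = tabulate(b))
}
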