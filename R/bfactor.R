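#' Convert Q-scores to atomic B factors
#'
#' The linear map `B = f * (1 - Q)`: a perfectly resolved atom (Q = 1)
#' gets B = 0, and lower resolvability gives proportionally larger
#' displacement parameters. Values are clamped at 0.
#'
#' @param q Per-atom Q-scores.
#' @param f Non-negative scaling factor (A^2 per unit of 1 - Q).
#' @return Per-atom B factors (A^2).
#' @export
q_to_bfactor <- function(q, f) {
  stopifnot(f >= 0)
  pmax(0, f * (1 - q))
}

#' Render a model map from coordinates and B factors
#'
#' Each non-hydrogen atom contributes an isotropic 3D Gaussian of variance
#' `sigma0^2 + B / (8 * pi^2)` (the standard isotropic-displacement
#' convention), with equal integral per atom scaled by occupancy; no
#' element-specific scattering factors are applied (a documented
#' simplification -- Q-scores are affine-invariant, and CC-mean nearly so).
#' Contributions are truncated at `cutoff_sigma` standard deviations.
#'
#' @param model An `atomic_model`.
#' @param b_atoms B factors (A^2): scalar, one per atom, or one per
#'   non-hydrogen atom (in model order).
#' @param grid Either a [density_map] whose geometry is reused, or `NULL`
#'   to build a grid covering the model with margin `pad`.
#' @param voxel Voxel size (A) when `grid` is `NULL`.
#' @param pad Margin (A) when `grid` is `NULL`.
#' @param sigma0 Base Gaussian width at B = 0 (A); defaults to the
#'   Q-score reference width 0.6 A.
#' @param cutoff_sigma Truncation radius in standard deviations.
#' @return A [density_map].
#' @export
render_model_map <- function(model, b_atoms = 0, grid = NULL, voxel = 0.5,
                             pad = 5, sigma0 = 0.6, cutoff_sigma = 4) {
  heavy <- which(!model$is_h)
  xyz <- model_xyz(model)[heavy, , drop = FALSE]
  occ <- model$occupancy[heavy]
  b <- expand_b(b_atoms, model, heavy)
  if (any(b < 0)) stop("B factors must be non-negative")
  if (is.null(grid)) {
    lo <- apply(xyz, 2L, min) - pad
    hi <- apply(xyz, 2L, max) + pad
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
    vox <- rep(voxel, 3L)
    orig <- lo
  } else {
    stopifnot(inherits(grid, "density_map"))
    dims <- dim(grid$values)
    vox <- grid$voxel_size
    orig <- grid$origin
  }
  vals <- array(0, dim = dims)
  sig <- sqrt(sigma0^2 + b / (8 * pi^2))
  amp <- occ / ((2 * pi)^1.5 * sig^3)
  truncated <- FALSE
  for (a in seq_along(occ)) {
    ctr <- (xyz[a, ] - orig) / vox          # fractional 0-based index
    rad <- cutoff_sigma * sig[a] / vox
    if (any(ctr < 0) || any(ctr > dims - 1L)) truncated <- TRUE
    i0 <- pmax(0L, as.integer(ceiling(ctr - rad)))
    i1 <- pmin(dims - 1L, as.integer(floor(ctr + rad)))
    if (any(i0 > i1)) next
    gx <- exp(-0.5 * ((i0[1]:i1[1] - ctr[1]) * vox[1] / sig[a])^2)
    gy <- exp(-0.5 * ((i0[2]:i1[2] - ctr[2]) * vox[2] / sig[a])^2)
    gz <- exp(-0.5 * ((i0[3]:i1[3] - ctr[3]) * vox[3] / sig[a])^2)
    block <- amp[a] * outer(outer(gx, gy), gz)
    ix <- (i0[1]:i1[1]) + 1L; iy <- (i0[2]:i1[2]) + 1L; iz <- (i0[3]:i1[3]) + 1L
    vals[ix, iy, iz] <- vals[ix, iy, iz] + block
  }
  if (truncated)
    warning("some atoms fall outside the grid; contributions truncated")
  density_map(vals, vox, orig)
}

expand_b <- function(b_atoms, model, heavy) {
  if (length(b_atoms) == 1L) rep(b_atoms, length(heavy))
  else if (length(b_atoms) == nrow(model)) as.numeric(b_atoms[heavy])
  else if (length(b_atoms) == length(heavy)) as.numeric(b_atoms)
  else stop("length(b_atoms) must be 1, n_atoms or n_heavy_atoms")
}

#' CC-mean between two maps
#'
#' Pearson correlation about the mean over (optionally masked) voxels of
#' two maps on identical grids.
#'
#' @param map_a,map_b [density_map]s with identical dimensions.
#' @param mask Optional logical array selecting voxels (e.g. from
#'   [model_mask]); `NULL` uses all voxels.
#' @return Scalar correlation, or `NA` if a side has zero variance.
#' @export
cc_maps <- function(map_a, map_b, mask = NULL) {
  stopifnot(identical(dim(map_a$values), dim(map_b$values)))
  a <- map_a$values; b <- map_b$values
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(a)))
    a <- a[mask]; b <- b[mask]
  }
  if (length(a) < 2L) stop("need at least 2 voxels for a correlation")
  cc_about_mean(as.numeric(a), as.numeric(b))
}

#' Mask of voxels near model atoms
#'
#' Marks voxels whose center lies within `radius` of any non-hydrogen
#' atom; used to restrict CC-mean to the molecular envelope so empty
#' background does not dominate the correlation.
#'
#' @param map A [density_map] supplying the grid.
#' @param model An `atomic_model`.
#' @param radius Angstrom radius, default 3.
#' @return Logical array with the map's dimensions.
#' @export
model_mask <- function(map, model, radius = 3) {
  dims <- dim(map$values)
  mask <- array(FALSE, dims)
  xyz <- model_xyz(model)[!model$is_h, , drop = FALSE]
  vox <- map$voxel_size
  for (a in seq_len(nrow(xyz))) {
    ctr <- (xyz[a, ] - map$origin) / vox
    rad <- radius / vox
    i0 <- pmax(0L, as.integer(ceiling(ctr - rad)))
    i1 <- pmin(dims - 1L, as.integer(floor(ctr + rad)))
    if (any(i0 > i1)) next
    dx2 <- ((i0[1]:i1[1] - ctr[1]) * vox[1])^2
    dy2 <- ((i0[2]:i1[2] - ctr[2]) * vox[2])^2
    dz2 <- ((i0[3]:i1[3] - ctr[3]) * vox[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    ix <- (i0[1]:i1[1]) + 1L; iy <- (i0[2]:i1[2]) + 1L; iz <- (i0[3]:i1[3]) + 1L
    mask[ix, iy, iz] <- mask[ix, iy, iz] | inside
  }
  mask
}

#' Optimize the Q-to-B scaling factor against the experimental map
#'
#' For each candidate scaling factor `f`, converts the measured Q-scores
#' to B factors (`B = f * (1 - Q)`, or a user transform), renders a model
#' map on the experimental grid and computes the masked CC-mean against
#' the experimental map. The optimum is the `f` with the highest CC-mean
#' (ties toward the smallest `f`).
#'
#' @param map Experimental [density_map].
#' @param model An `atomic_model`.
#' @param q A `qscore_result` from [qscore] for this map/model pair.
#' @param scan Candidate scaling factors; default `seq(0, 300, by = 10)`.
#' @param mask `"model"` (default, 3 A envelope via [model_mask]),
#'   `"none"`, or a logical array.
#' @param sigma0 Base rendering width (A).
#' @param transform Function `(q, f) -> B` mapping Q-scores to B factors;
#'   default [q_to_bfactor].
#' @return A `bfactor_fit`: list with `f_opt`, `cc_curve` (data frame
#'   `f`, `cc`), `b_atoms` (per scorable atom at `f_opt`), `scan`.
#' @export
optimize_bfactor_scale <- function(map, model, q, scan = seq(0, 300, by = 10),
                                   mask = "model", sigma0 = 0.6,
                                   transform = q_to_bfactor) {
  stopifnot(inherits(q, "qscore_result"))
  if (identical(mask, "model")) mask <- model_mask(map, model)
  else if (identical(mask, "none")) mask <- NULL
  heavy <- which(!model$is_h)
  qa <- q$atoms$q[match(model$serial[heavy], q$atoms$serial)]
  qa[is.na(qa)] <- mean(q$atoms$q, na.rm = TRUE)   # unscored atoms: model mean
  cc <- vapply(scan, function(f) {
    rendered <- render_model_map(model, transform(qa, f), grid = map,
                                 sigma0 = sigma0)
    cc_maps(map, rendered, mask)
  }, numeric(1))
  if (all(is.na(cc))) stop("CC-mean undefined for every scan value")
  f_opt <- scan[which.max(cc)]
  structure(list(f_opt = f_opt,
                 cc_curve = data.frame(f = scan, cc = cc),
                 b_atoms = transform(qa, f_opt), scan = scan),
            class = "bfactor_fit")
}

#' @export
print.bfactor_fit <- function(x, ...) {
  cat(sprintf("bfactor_fit: f_opt = %g (CC-mean %.4f over scan %g-%g)\n",
              x$f_opt, max(x$cc_curve$cc, na.rm = TRUE),
              min(x$scan), max(x$scan)))
  invisible(x)
}

#' @export
plot.bfactor_fit <- function(x, ...) {
  cols <- ifelse(x$cc_curve$f == x$f_opt, "orange", "grey40")
  graphics::barplot(x$cc_curve$cc, names.arg = x$cc_curve$f, col = cols,
                    xlab = "scaling factor f", ylab = "CC-mean", ...)
  invisible(x)
}
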