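#' Construct a density map object
#'
#' A `density_map` holds a 3D scalar grid together with its physical
#' geometry: the voxel size in Angstrom along each axis and the Angstrom
#' position of the *center* of voxel `[1, 1, 1]` (0-based index origin).
#' The Angstrom position of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * voxel_size`.
#'
#' @param values 3D numeric array of map values.
#' @param voxel_size Voxel size in Angstrom; length 1 (isotropic) or 3.
#' @param origin Angstrom coordinates of the first voxel center (length 3).
#' @return An object of class `density_map` with fields `values`,
#'   `voxel_size`, `origin`, `mean` and `rmsd` (population standard
#'   deviation of all voxels).
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!all(is.finite(values)))
    stop("map values must all be finite")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive finite values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values")
  m <- mean(values)
  structure(
    list(values = values, voxel_size = voxel_size, origin = origin,
         mean = m, rmsd = sqrt(mean((values - m)^2))),
    class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, voxel %.4g x %.4g x %.4g A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (A): %.3f %.3f %.3f\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  mean %.5g, rmsd %.5g, range [%.5g, %.5g]\n",
              x$mean, x$rmsd, min(x$values), max(x$values)))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Reads MRC2014-style volumes (mode 2, 32-bit float; mode 0/1 integer data
#' is also accepted and converted). Axis order must be the canonical
#' `mapc,mapr,maps = 1,2,3`; permuted volumes are rejected rather than
#' silently normalized. The grid origin is taken from the `ORIGIN` header
#' fields when any is nonzero, otherwise from `nxstart/nystart/nzstart`
#' times the voxel size -- the two dialects found in the wild. Use `origin`
#' to override both.
#'
#' @param path Path to a `.mrc`/`.map` file.
#' @param origin Optional length-3 numeric overriding the header origin (A).
#' @return A [density_map].
#' @export
read_map <- function(path, origin = NULL) {
  if (!file.exists(path)) stop("map file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  seek(con, 0L)
  hdr_dbl <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")
  magic <- writeBin(hdr_int[53L], raw(), size = 4L, endian = "little")
  if (!identical(magic[1:3], charToRaw("MAP")))
    stop("not an MRC/CCP4 map (missing 'MAP ' magic): ", path)
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4L]
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_dbl[11:13]
  axes <- hdr_int[17:19]
  if (any(nxyz <= 0L)) stop("invalid MRC header: non-positive dimensions")
  if (!identical(axes, 1:3))
    stop("MRC axis order ", paste(axes, collapse = ","),
         " not supported (expect 1,2,3)")
  if (any(mxyz <= 0L) || any(!is.finite(cella)) || any(cella <= 0))
    stop("invalid MRC header: zero or negative cell/sampling")
  voxel <- cella / mxyz
  nsymbt <- hdr_int[24L]
  hdr_origin <- hdr_dbl[50:52]
  seek(con, 1024L + nsymbt)
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L, endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    stop("unsupported MRC mode ", mode, " (expect 0, 1 or 2)"))
  if (length(vals) != n) stop("truncated MRC data section: ", path)
  if (is.null(origin)) {
    origin <- if (any(hdr_origin != 0)) hdr_origin else nstart * voxel
  }
  density_map(array(vals, dim = nxyz), voxel_size = voxel, origin = origin)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' The origin is written to both the `ORIGIN` float fields and (rounded to
#' the nearest voxel) the `nxstart` fields, so either reader dialect
#' recovers it.
#'
#' @param map A [density_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                              # nx ny nz
  wi(2L)                             # mode 2 = float32
  wi(round(map$origin / map$voxel_size))  # nstart
  wi(d)                              # mx my mz
  wf(d * map$voxel_size)             # cella
  wf(c(90, 90, 90))                  # cellb
  wi(1:3)                            # mapc mapr maps
  wf(c(min(map$values), max(map$values), map$mean))
  wi(1L)                             # ispg
  wi(0L)                             # nsymbt
  wi(integer(25L))                   # extra
  wf(map$origin)                     # origin x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(map$rmsd)
  wi(0L)                             # nlabl
  writeBin(raw(800L), con)           # labels
  writeBin(as.numeric(map$values), con, size = 4L, endian = "little")
  invisible(path)
}

#' Map between Angstrom positions and voxel indices
#'
#' `xyz_to_index` returns fractional 0-based voxel indices for Angstrom
#' positions; `index_to_xyz` is its inverse. Both are vectorized over rows.
#'
#' @param map A [density_map].
#' @param xyz n x 3 matrix (or length-3 vector) of Angstrom positions.
#' @param idx n x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return n x 3 numeric matrix.
#' @export
xyz_to_index <- function(map, xyz) {
  xyz <- rbind2mat(xyz)
  sweep(sweep(xyz, 2L, map$origin, "-"), 2L, map$voxel_size, "/")
}

#' @rdname xyz_to_index
#' @export
index_to_xyz <- function(map, idx) {
  idx <- rbind2mat(idx)
  sweep(sweep(idx, 2L, map$voxel_size, "*"), 2L, map$origin, "+")
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  stopifnot(ncol(x) == 3L)
  x
}

#' Trilinear interpolation of map values
#'
#' Interpolates the 8 voxels surrounding each query point. Points outside
#' the hull of voxel centers get `NA`.
#'
#' @param map A [density_map].
#' @param xyz n x 3 matrix of Angstrom positions.
#' @return Numeric vector of length n; `NA` for out-of-grid points.
#' @export
interpolate_map <- function(map, xyz) {
  f <- xyz_to_index(map, xyz)
  d <- dim(map$values)
  i0 <- floor(f)
  t <- f - i0
  inside <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= d[1] - 2L + (t[, 1] == 0) &
    i0[, 2] <= d[2] - 2L + (t[, 2] == 0) &
    i0[, 3] <= d[3] - 2L + (t[, 3] == 0)
  out <- rep(NA_real_, nrow(f))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  t <- t[inside, , drop = FALSE]
  # clamp the +1 corner for points sitting exactly on the far face
  i1 <- pmin(i0 + 1, matrix(d - 1L, nrow(i0), 3L, byrow = TRUE))
  v <- map$values
  lin <- function(ix, iy, iz) v[1L + ix + d[1] * (iy + d[2] * iz)]
  tx <- t[, 1]; ty <- t[, 2]; tz <- t[, 3]
  out[inside] <-
    lin(i0[, 1], i0[, 2], i0[, 3]) * (1 - tx) * (1 - ty) * (1 - tz) +
    lin(i1[, 1], i0[, 2], i0[, 3]) * tx       * (1 - ty) * (1 - tz) +
    lin(i0[, 1], i1[, 2], i0[, 3]) * (1 - tx) * ty       * (1 - tz) +
    lin(i1[, 1], i1[, 2], i0[, 3]) * tx       * ty       * (1 - tz) +
    lin(i0[, 1], i0[, 2], i1[, 3]) * (1 - tx) * (1 - ty) * tz +
    lin(i1[, 1], i0[, 2], i1[, 3]) * tx       * (1 - ty) * tz +
    lin(i0[, 1], i1[, 2], i1[, 3]) * (1 - tx) * ty       * tz +
    lin(i1[, 1], i1[, 2], i1[, 3]) * tx       * ty       * tz
  out
}
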