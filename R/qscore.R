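#' Radial sampling protocol for Q-scores
#'
#' Controls how map values are sampled around each atom. The reference
#' profile is a Gaussian of width `sigma_ref`; shells of radius
#' `r_step, 2 r_step, ..., r_max` each carry up to `pts_per_shell` points
#' placed quasi-uniformly on the sphere (golden-spiral design, rotated per
#' shell by a seeded rotation). A candidate point strictly closer to a
#' neighboring atom than to the target atom is rejected (the ownership
#' rule); up to `max_attempts` rotations are tried per shell and the one
#' with the most accepted points is kept.
#'
#' @param sigma_ref Width of the reference Gaussian (A). The default 0.6 A
#'   makes Q = 1 for an atom rendered as a 0.6 A Gaussian, the sharpest
#'   peak observed in the best-resolved single-particle maps.
#' @param r_max Outermost shell radius (A).
#' @param r_step Shell spacing (A).
#' @param pts_per_shell Points per shell.
#' @param max_attempts Shell rotations tried when neighbors reject points.
#' @param seed Integer seed for the per-shell rotations.
#' @return A `sampling_protocol` list.
#' @export
sampling_protocol <- function(sigma_ref = 0.6, r_max = 2.0, r_step = 0.1,
                              pts_per_shell = 8L, max_attempts = 8L,
                              seed = 1L) {
  stopifnot(sigma_ref > 0, r_step > 0, r_step <= r_max, pts_per_shell >= 1)
  structure(list(sigma_ref = sigma_ref, r_max = r_max, r_step = r_step,
                 pts_per_shell = as.integer(pts_per_shell),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "sampling_protocol")
}

#' Reference Gaussian profile
#'
#' The profile the sampled map values are correlated against:
#' `v(r) = exp(-(r / sigma_ref)^2 / 2)`. Amplitude and offset are fixed at
#' (1, 0): Pearson correlation is invariant to a positive affine rescaling
#' of either argument, so they are immaterial.
#'
#' @param radii Non-negative radii (A).
#' @param protocol A [sampling_protocol].
#' @return Numeric vector of profile values.
#' @export
reference_profile <- function(radii, protocol = sampling_protocol()) {
  stopifnot(all(radii >= 0))
  exp(-0.5 * (radii / protocol$sigma_ref)^2)
}

#' Pearson correlation about the mean
#'
#' The CC-mean used both per atom (Q-score) and between maps. Returns `NA`
#' when either argument has zero variance (undefined correlation).
#'
#' @param u,v Equal-length numeric vectors (length >= 2).
#' @return Scalar in `[-1, 1]`, or `NA` if undefined.
#' @export
cc_about_mean <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2L)
  # relative tolerance: constant inputs reach here with rounding-level spread
  su <- stats::sd(u); sv <- stats::sd(v)
  if (su <= 1e-12 * max(1, abs(mean(u))) ||
      sv <= 1e-12 * max(1, abs(mean(v)))) return(NA_real_)
  stats::cor(u, v)
}

# Golden-spiral quasi-uniform direction set on the unit sphere.
golden_spiral <- function(n) {
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Deterministic uniforms in [0,1) from integer keys; avoids touching the
# global RNG so per-atom sampling is reproducible regardless of call order.
hash_unif <- function(...) {
  h <- sum(c(...) * c(12.9898, 78.2330, 37.7190, 4.8989)[seq_along(c(...))])
  x <- sin(h + c(1, 2, 3)) * 43758.5453123
  x - floor(x)
}

# Rotation matrix from three uniforms (axis from area-uniform sphere point,
# angle uniform on [0, 2*pi)).
rotation_from_unifs <- function(u) {
  z <- 2 * u[1] - 1
  phi <- 2 * pi * u[2]
  axis <- c(sqrt(max(0, 1 - z^2)) * cos(phi), sqrt(max(0, 1 - z^2)) * sin(phi), z)
  ang <- 2 * pi * u[3]
  c_ <- cos(ang); s <- sin(ang); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; zz <- axis[3]
  matrix(c(x * x * C + c_, x * y * C - zz * s, x * zz * C + y * s,
           y * x * C + zz * s, y * y * C + c_, y * zz * C - x * s,
           zz * x * C - y * s, zz * y * C + x * s, zz * zz * C + c_),
         3L, 3L, byrow = TRUE)
}

#' Generate ownership-filtered shell points around an atom
#'
#' Returns the atom center (radius 0) plus, for each shell radius, the
#' accepted points of the best of `max_attempts` seeded rotations of the
#' golden-spiral design. A point is accepted only if no neighbor atom is
#' strictly closer to it than the target atom is (ownership rule), so the
#' correlation only sees density attributable to the target atom.
#'
#' @param atom_xyz Length-3 Angstrom position of the target atom.
#' @param neighbors_xyz m x 3 matrix of neighboring atom positions
#'   (excluding the target atom); may have zero rows.
#' @param protocol A [sampling_protocol].
#' @param atom_key Integer mixed into the rotation seed so different atoms
#'   get different rotations.
#' @return List with `points` (n x 3), `radii` (length n), `n_nominal` and
#'   `n_rejected`.
#' @export
shell_points <- function(atom_xyz, neighbors_xyz = NULL,
                         protocol = sampling_protocol(), atom_key = 0L) {
  radii <- seq(protocol$r_step, protocol$r_max, by = protocol$r_step)
  base <- golden_spiral(protocol$pts_per_shell)
  if (!is.null(neighbors_xyz) && length(neighbors_xyz) > 0) {
    neighbors_xyz <- rbind2mat(neighbors_xyz)
  } else neighbors_xyz <- matrix(numeric(0), 0L, 3L)
  pts <- matrix(atom_xyz, 1L, 3L)
  out_r <- 0
  n_rej <- 0L
  for (si in seq_along(radii)) {
    r <- radii[si]
    best <- NULL
    best_n <- -1L
    for (att in seq_len(protocol$max_attempts)) {
      rot <- rotation_from_unifs(hash_unif(protocol$seed, atom_key, si, att))
      cand <- sweep((base %*% rot) * r, 2L, atom_xyz, "+")
      if (nrow(neighbors_xyz) > 0L) {
        ok <- vapply(seq_len(nrow(cand)), function(i) {
          d2 <- colSums((t(neighbors_xyz) - cand[i, ])^2)
          r * r <= min(d2)
        }, logical(1L))
      } else ok <- rep(TRUE, nrow(cand))
      if (sum(ok) > best_n) {
        best <- cand[ok, , drop = FALSE]
        best_n <- sum(ok)
      }
      if (best_n == nrow(cand)) break
    }
    n_rej <- n_rej + (protocol$pts_per_shell - best_n)
    if (best_n > 0L) {
      pts <- rbind(pts, best)
      out_r <- c(out_r, rep(r, best_n))
    }
  }
  list(points = pts, radii = out_r,
       n_nominal = 1L + length(radii) * protocol$pts_per_shell,
       n_rejected = n_rej)
}

#' Q-score of a single atom
#'
#' Samples the map radially around the atom ([shell_points] then trilinear
#' interpolation) and correlates the sampled values with the reference
#' Gaussian profile at the same radii. Out-of-grid sample points are
#' discarded; the atom is flagged `low_support` if fewer than half of the
#' nominal points survive, and unscored (`NA`) if fewer than two distinct
#' radii remain or the sampled values have zero variance.
#'
#' @param map A [density_map].
#' @param atom_xyz Length-3 Angstrom position.
#' @param neighbors_xyz m x 3 matrix of neighbor positions.
#' @param protocol A [sampling_protocol].
#' @param atom_key Integer identifying the atom (rotation seed component).
#' @return List with `q` (scalar or `NA`), `n_points`, `n_rejected`,
#'   `low_support`, `boundary` flags.
#' @export
qscore_atom <- function(map, atom_xyz, neighbors_xyz = NULL,
                        protocol = sampling_protocol(), atom_key = 0L) {
  sp <- shell_points(atom_xyz, neighbors_xyz, protocol, atom_key)
  u <- interpolate_map(map, sp$points)
  ok <- !is.na(u)
  boundary <- any(!ok)
  u <- u[ok]
  radii <- sp$radii[ok]
  low_support <- length(u) < 0.5 * sp$n_nominal
  if (length(unique(radii)) < 2L) {
    return(list(q = NA_real_, n_points = length(u), n_rejected = sp$n_rejected,
                low_support = TRUE, boundary = boundary))
  }
  v <- reference_profile(radii, protocol)
  list(q = cc_about_mean(u, v), n_points = length(u),
       n_rejected = sp$n_rejected, low_support = low_support,
       boundary = boundary)
}

#' Q-scores for a whole model
#'
#' Scores every non-hydrogen atom with positive occupancy. Neighbor sets
#' for the ownership rule are all other scorable atoms within
#' `2 * r_max` of the target. The model Q-score is the unweighted mean
#' over scored atoms; unscored atoms (flagged `NA`) are excluded from the
#' mean and listed.
#'
#' @param map A [density_map].
#' @param model An `atomic_model`.
#' @param protocol A [sampling_protocol].
#' @return A `qscore_result`: list with `atoms` (per-atom data frame
#'   carrying `serial`, `chain`, `res_seq`, `res_name`, `name`, `q` and
#'   flags), `model_q`, `n_scored`, `n_unscored`, `protocol`.
#' @export
qscore <- function(map, model, protocol = sampling_protocol()) {
  stopifnot(inherits(map, "density_map"), inherits(model, "atomic_model"))
  scorable <- which(!model$is_h & model$occupancy > 0)
  if (length(scorable) == 0L) stop("model has no scorable atoms")
  xyz <- model_xyz(model)[scorable, , drop = FALSE]
  cutoff2 <- (2 * protocol$r_max)^2
  n <- nrow(xyz)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- xyz[d2 > 0 & d2 <= cutoff2, , drop = FALSE]
    res[[i]] <- qscore_atom(map, xyz[i, ], nb, protocol,
                            atom_key = model$serial[scorable[i]])
  }
  atoms <- data.frame(
    serial = model$serial[scorable], chain = model$chain[scorable],
    res_seq = model$res_seq[scorable], res_name = model$res_name[scorable],
    name = model$name[scorable], element = model$element[scorable],
    q = vapply(res, `[[`, numeric(1), "q"),
    n_points = vapply(res, `[[`, integer(1), "n_points"),
    low_support = vapply(res, `[[`, logical(1), "low_support"),
    boundary = vapply(res, `[[`, logical(1), "boundary"),
    stringsAsFactors = FALSE)
  scored <- !is.na(atoms$q)
  structure(list(
    atoms = atoms,
    model_q = mean(atoms$q[scored]),
    n_scored = sum(scored), n_unscored = sum(!scored),
    unscored_serials = atoms$serial[!scored],
    protocol = protocol, entry_id = attr(model, "entry_id")),
    class = "qscore_result")
}

#' @export
print.qscore_result <- function(x, ...) {
  cat(sprintf("Q-scores for '%s': model Q = %.4f over %d atoms (%d unscored)\n",
              x$entry_id, x$model_q, x$n_scored, x$n_unscored))
  q <- x$atoms$q[!is.na(x$atoms$q)]
  cat(sprintf("  per-atom Q: min %.3f, median %.3f, max %.3f\n",
              min(q), stats::median(q), max(q)))
  invisible(x)
}
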