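# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy atomic model
#'
#' Builds small chemically labeled models with canonical atom names so
#' the group-classification rules apply, at plausible bonded spacings
#' (~1.5 A). Kinds: `"helix"` / `"strand"` trace alternating ALA/LEU
#' residues along an alpha-helical or extended backbone; `"rna"` builds G
#' nucleotides with full phosphate/ribose/base atom sets; `"ligand"`
#' places NAG (N-acetylglucosamine) units. Geometry is idealized, not
#' stereochemically refined. Deterministic per seed (a small coordinate
#' jitter breaks exact lattice alignment).
#'
#' @param n_residues Number of residues / nucleotides / ligand copies.
#' @param kind `"helix"`, `"strand"`, `"rna"` or `"ligand"`.
#' @param seed Integer seed.
#' @param chain Chain identifier.
#' @return An `atomic_model`.
#' @export
make_toy_model <- function(n_residues, kind = c("helix", "strand", "rna",
                                                "ligand"),
                           seed = 1L, chain = "A") {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 1)
  with_seed(seed, {
    rows <- lapply(seq_len(n_residues), function(i) {
      jit <- function(m) m + matrix(stats::runif(length(m), -0.05, 0.05),
                                    nrow(m), 3L)
      if (kind %in% c("helix", "strand")) {
        ca <- if (kind == "helix") {
          th <- i * 100 * pi / 180
          c(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
        } else c(0.5 * (-1)^i, 0, 3.3 * i)
        res <- if (i %% 2L == 1L) "ALA" else "LEU"
        nm <- c("N", "CA", "C", "O",
                if (res == "ALA") "CB" else c("CB", "CG", "CD1", "CD2"))
        el <- substr(nm, 1L, 1L)
        off <- rbind(c(-1.46, 0, -0.4), c(0, 0, 0), c(1.52, 0, 0.4),
                     c(1.9, 1.0, 1.0), c(-0.5, 1.4, 0),
                     c(-0.9, 2.3, 1.1), c(-1.8, 3.3, 0.6), c(0.2, 3.0, 1.9))
        xyz <- jit(sweep(off[seq_along(nm), , drop = FALSE], 2L, ca, "+"))
      } else if (kind == "rna") {
        base0 <- c(8 * cos(i * 0.6), 8 * sin(i * 0.6), 4.5 * i)
        nm <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6",
                "O6", "N1", "C2", "N2", "N3", "C4")
        el <- substr(nm, 1L, 1L)
        off <- rbind(c(0, 0, 0), c(-0.8, 1.2, 0), c(1.2, 0.8, -0.4),
                     c(0.3, -1.0, 1.0), c(1.1, -1.9, 1.6), c(2.0, -1.2, 2.5),
                     c(3.2, -1.0, 1.8), c(2.3, -2.2, 3.6), c(2.0, -1.8, 4.9),
                     c(3.7, -2.6, 3.3), c(4.0, -4.0, 3.4), c(4.3, -1.7, 2.5),
                     c(5.5, -2.2, 1.9), c(5.7, -3.3, 1.2), c(7.0, -3.4, 0.8),
                     c(7.7, -2.3, 1.3), c(9.1, -1.9, 1.2), c(10.0, -2.6, 0.7),
                     c(9.4, -0.7, 1.8), c(8.5, 0.1, 2.4), c(9.0, 1.3, 2.9),
                     c(7.2, -0.2, 2.5), c(6.6, -1.4, 2.0))
        res <- "G"
        xyz <- jit(sweep(off, 2L, base0, "+"))
      } else {
        ctr <- c(8 * i, 0, 0)
        nm <- c("C1", "C2", "C3", "C4", "C5", "O5", "C6", "O6", "O3", "O4",
                "N2", "C7", "O7", "C8")
        el <- substr(nm, 1L, 1L)
        th <- (0:5) * pi / 3
        ring <- cbind(1.45 * cos(th), 1.45 * sin(th),
                      0.25 * (-1)^(0:5))
        off <- rbind(ring, c(2.4, 1.6, 1.0), c(3.3, 2.4, 0.4),
                     c(-1.2, -2.4, 0.9), c(-2.6, -0.9, -1.0),
                     c(1.6, -2.4, -0.8), c(2.2, -3.5, -0.1),
                     c(2.0, -4.1, 1.0), c(3.4, -4.1, -0.9))
        res <- "NAG"
        xyz <- jit(sweep(off, 2L, ctr, "+"))
      }
      data.frame(name = nm, element = el, res_name = res, res_seq = i,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    atomic_model(serial = seq_len(nrow(df)), name = df$name,
                 element = df$element, chain = chain,
                 res_name = df$res_name, res_seq = df$res_seq,
                 x = df$x, y = df$y, z = df$z,
                 entry_id = sprintf("toy_%s_%d", kind, n_residues))
  })
}

#' Simulate an experimental-style map for a model
#'
#' Renders the model with the given per-atom B factors and adds
#' independent Gaussian white noise of standard deviation
#' `noise_rms * sd(signal)`. With `noise_rms = 0` the output is exactly
#' the rendered map.
#'
#' @param model An `atomic_model`.
#' @param b_atoms B factors passed to [render_model_map].
#' @param voxel Voxel size (A); keep at or below 1 A for scoring tests.
#' @param noise_rms Noise level as a fraction of the signal RMS.
#' @param seed Integer seed for the noise draw.
#' @param pad Grid margin (A).
#' @param sigma0 Base rendering width (A).
#' @return A [density_map] with attribute `b_true` (per heavy atom).
#' @export
simulate_map <- function(model, b_atoms = 0, voxel = 0.5, noise_rms = 0,
                         seed = 1L, pad = 5, sigma0 = 0.6) {
  map <- render_model_map(model, b_atoms, voxel = voxel, pad = pad,
                          sigma0 = sigma0)
  if (noise_rms > 0) {
    sd_sig <- stats::sd(as.numeric(map$values))
    noise <- with_seed(seed, stats::rnorm(length(map$values),
                                          sd = noise_rms * sd_sig))
    map <- density_map(map$values + array(noise, dim(map$values)),
                       map$voxel_size, map$origin)
  }
  attr(map, "b_true") <- expand_b(b_atoms, model, which(!model$is_h))
  map
}

#' Default synthetic mean curve for archive simulation
#'
#' The cubic through the qualitative archive anchors Q(1 A) = 0.95,
#' Q(3 A) = 0.52, Q(5 A) = 0.30, Q(10 A) = 0.10: a fast decrease over
#' 1-5 A and a slow tail over 5-10 A. This is a synthetic calibration for
#' testing, not a fit to archive data.
#'
#' @return Length-4 numeric: coefficients in ascending powers of d.
#' @export
default_mean_curve <- function() {
  anchors_d <- c(1, 3, 5, 10)
  anchors_q <- c(0.95, 0.52, 0.30, 0.10)
  unname(solve(outer(anchors_d, 0:3, "^"), anchors_q))
}

#' Simulate an archive table of (resolution, Q) pairs
#'
#' Draws resolutions from a unimodal distribution over `d_range` (scaled
#' Beta, mode near 3.7 A, emulating the archive's resolution histogram)
#' and Q-scores as a decreasing cubic mean curve plus skewed residuals.
#' Residuals are mirrored-Gumbel: mean zero, long tail toward low
#' Q-scores, as archive residuals show (models that are poorly fitted can
#' only lose Q). A warning (not clipping) is raised if any simulated Q
#' leaves `[-0.1, 1.05]`.
#'
#' @param n Number of rows (>= 100 recommended for statistics tests).
#' @param d_range Resolution range (A), default `c(1, 10)`.
#' @param mean_curve Cubic coefficients (ascending powers); default
#'   [default_mean_curve].
#' @param noise_scale Gumbel scale of the residuals; the default 0.05
#'   gives residual SD ~0.064, comparable to the archive scatter.
#' @param d_shape Beta shape parameters for the resolution distribution.
#' @param seed Integer seed.
#' @return An `archive_table` with attributes `mean_curve` and
#'   `noise_scale`.
#' @export
simulate_archive <- function(n = 10000L, d_range = c(1, 10),
                             mean_curve = default_mean_curve(),
                             noise_scale = 0.05, d_shape = c(2.5, 4.5),
                             seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    d <- d_range[1] + diff(d_range) * stats::rbeta(n, d_shape[1], d_shape[2])
    r <- rgumbel_mirrored(n, noise_scale)
    q <- polyval(mean_curve, d) + r
  })
  if (any(q < -0.1 | q > 1.05))
    warning(sum(q < -0.1 | q > 1.05),
            " simulated Q value(s) outside [-0.1, 1.05]; not clipped")
  t <- archive_table(sprintf("synthetic%06d", seq_len(n)), d, q)
  attr(t, "mean_curve") <- mean_curve
  attr(t, "noise_scale") <- noise_scale
  t
}

# Mirrored Gumbel residuals: negative of a Gumbel(0, beta) draw, centered
# to mean zero. Skewness -1.14, long lower tail.
rgumbel_mirrored <- function(n, beta) {
  g <- -beta * log(-log(stats::runif(n)))
  -(g - beta * 0.57721566490153286)
}
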