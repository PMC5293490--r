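#' Specification for a simulated embryo
#'
#' Describes one synthetic S3/S4-like spherical embryo: labeled cells live
#' in a spherical shell (the embryonic wall) whose polar angle relative to
#' the pharynx follows the damped-sine density with ground-truth
#' `theta_prime`; mitotic labels are i.i.d. Bernoulli and independent of
#' position (matching the observed absence of regional bias in mitoses);
#' fiduciary beads are uniform decoy points in the bounding box.
#'
#' Defaults model an embryo on the ~100 µm scale with the wall at radii
#' 100-140 µm; only the polar angle enters the downstream analysis, so the
#' shell geometry is a free choice. The default mitotic rate of 3% is a
#' typical low-single-digit mitotic index for cycling cells.
#'
#' @param n_cells number of labeled cells (non-negative integer).
#' @param theta_prime ground-truth dampening parameter (radians, \eqn{\ge
#'   0}).
#' @param shell_inner_um,shell_outer_um wall radii in µm, inner < outer.
#' @param mitotic_rate probability a labeled cell is mitotic, in
#'   \eqn{[0, 1]}.
#' @param n_beads number of decoy bead spots.
#' @param center embryo center position (µm).
#' @param seed integer seed; simulation is deterministic given the seed.
#' @return An object of class `"embryo_sim_spec"`.
#' @export
embryo_sim_spec <- function(n_cells, theta_prime, shell_inner_um = 100,
                            shell_outer_um = 140, mitotic_rate = 0.03,
                            n_beads = 25, center = c(0, 0, 0), seed = 1) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || is.na(n_cells) ||
      n_cells < 0 || n_cells != floor(n_cells)) {
    stop("invalid 'n_cells': must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(theta_prime) || length(theta_prime) != 1L ||
      is.na(theta_prime) || theta_prime < 0) {
    stop("invalid 'theta_prime': must be a non-negative real", call. = FALSE)
  }
  if (!is.numeric(shell_inner_um) || !is.numeric(shell_outer_um) ||
      shell_inner_um <= 0 || shell_outer_um <= 0 ||
      shell_inner_um >= shell_outer_um) {
    stop("invalid shell radii: need 0 < 'shell_inner_um' < 'shell_outer_um'",
         call. = FALSE)
  }
  if (!is.numeric(mitotic_rate) || length(mitotic_rate) != 1L ||
      is.na(mitotic_rate) || mitotic_rate < 0 || mitotic_rate > 1) {
    stop("invalid 'mitotic_rate': must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_beads) || length(n_beads) != 1L || is.na(n_beads) ||
      n_beads < 0 || n_beads != floor(n_beads)) {
    stop("invalid 'n_beads': must be a non-negative integer", call. = FALSE)
  }
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center)) {
    stop("invalid 'center': must be a numeric length-3 vector", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), theta_prime = theta_prime,
                 shell_inner_um = shell_inner_um,
                 shell_outer_um = shell_outer_um,
                 mitotic_rate = mitotic_rate, n_beads = as.integer(n_beads),
                 center = center, seed = as.integer(seed)),
            class = "embryo_sim_spec")
}

#' Simulate one embryo's spot cloud
#'
#' Generates an [embryo_frame()] realizing the specification: cell radius
#' uniform in the wall, azimuth uniform on \eqn{[0, 2\pi)}, polar angle from
#' the damped-sine sampler [rdsine()] at the spec's ground-truth
#' `theta_prime`. The pharynx landmark sits on the oral pole (+z from the
#' center at mid-wall radius); bead decoys are uniform in the bounding box
#' of the outer shell.
#'
#' @param spec an [embryo_sim_spec()].
#' @param embryo_id identifier for the generated frame.
#' @return An `"embryo_frame"`. Deterministic given `spec$seed`.
#' @examples
#' fr <- simulate_embryo(embryo_sim_spec(200, theta_prime = 0.45, seed = 3))
#' fr
#' @export
simulate_embryo <- function(spec, embryo_id = "sim1") {
  stopifnot(inherits(spec, "embryo_sim_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_cells
  theta <- rdsine(n, spec$theta_prime)
  r <- stats::runif(n, spec$shell_inner_um, spec$shell_outer_um)
  phi <- stats::runif(n, 0, 2 * pi)
  # oral pole = +z from the center
  x <- spec$center[1] + r * sin(theta) * cos(phi)
  y <- spec$center[2] + r * sin(theta) * sin(phi)
  z <- spec$center[3] + r * cos(theta)
  cls <- ifelse(stats::runif(n) < spec$mitotic_rate, "mitotic", "piwi1")
  cells <- data.frame(
    spot_id = if (n) sprintf("c%04d", seq_len(n)) else character(),
    class = if (n) cls else character(),
    x_um = x, y_um = y, z_um = z)
  if (spec$n_beads > 0) {
    R <- spec$shell_outer_um
    beads <- data.frame(
      spot_id = sprintf("b%04d", seq_len(spec$n_beads)),
      class = "bead",
      x_um = stats::runif(spec$n_beads, spec$center[1] - R, spec$center[1] + R),
      y_um = stats::runif(spec$n_beads, spec$center[2] - R, spec$center[2] + R),
      z_um = stats::runif(spec$n_beads, spec$center[3] - R, spec$center[3] + R))
    cells <- rbind(cells, beads)
  }
  pharynx <- spec$center +
    c(0, 0, (spec$shell_inner_um + spec$shell_outer_um) / 2)
  embryo_frame(embryo_id, cells, center = spec$center, pharynx = pharynx)
}

#' Simulate a cohort of embryos
#'
#' Repeats [simulate_embryo()] with per-embryo child seeds and optional
#' Gaussian jitter of the ground-truth dampening parameter across embryos
#' (truncated at 0). Embryo-to-embryo variability in the true parameter is
#' not quantified by any measurement we know of, so the jitter defaults to
#' 0.
#'
#' @param n_embryos number of embryos.
#' @param spec the base [embryo_sim_spec()]; its `seed` drives the cohort.
#' @param cells_per_embryo optional integer vector (length 1 or
#'   `n_embryos`) overriding `spec$n_cells` per embryo.
#' @param theta_jitter_sd SD of per-embryo jitter on `theta_prime`.
#' @return A list of `"embryo_frame"` objects named by embryo id.
#' @export
simulate_embryo_cohort <- function(n_embryos, spec, cells_per_embryo = NULL,
                                   theta_jitter_sd = 0) {
  stopifnot(inherits(spec, "embryo_sim_spec"), n_embryos >= 1)
  if (is.null(cells_per_embryo)) cells_per_embryo <- spec$n_cells
  cells_per_embryo <- rep_len(as.integer(cells_per_embryo), n_embryos)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  tp <- pmax(0, stats::rnorm(n_embryos, spec$theta_prime, theta_jitter_sd))
  frames <- lapply(seq_len(n_embryos), function(i) {
    s <- spec
    s$n_cells <- cells_per_embryo[i]
    s$theta_prime <- tp[i]
    s$seed <- child_seed(spec$seed, i)
    simulate_embryo(s, embryo_id = sprintf("emb%03d", i))
  })
  names(frames) <- vapply(frames, `[[`, character(1), "embryo_id")
  frames
}
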