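#' Spot classes recognized in embryo frames
#'
#' `piwi1` and `mitotic` are labeled cells (mitotic cells are piwi-1+,
#' H3S10p+); `bead` marks fiduciary beads from the imaging prep, which are
#' decoys for the analysis and excluded by default everywhere.
#' @export
SPOT_CLASSES <- c("piwi1", "mitotic", "bead")

#' Construct an embryo frame
#'
#' An embryo frame is one embryo's spot cloud plus two landmarks, all in
#' micrometers: the embryo center and the temporary embryonic pharynx, which
#' marks the oral pole of the oral-aboral axis.
#'
#' @param embryo_id character scalar.
#' @param cells data frame with columns `spot_id`, `class` (one of
#'   [SPOT_CLASSES]), `x_um`, `y_um`, `z_um`. May have zero rows.
#' @param center,pharynx numeric length-3 landmark positions (µm). The
#'   pharynx must not coincide with the center.
#' @param center_source `"landmark"` when the center came from an exported
#'   landmark row, `"centroid"` when it was back-filled as the centroid of
#'   non-bead spots.
#' @return An object of class `"embryo_frame"`.
#' @export
embryo_frame <- function(embryo_id, cells, center, pharynx,
                         center_source = "landmark") {
  if (!is.character(embryo_id) || length(embryo_id) != 1L) {
    stop("'embryo_id' must be a single string", call. = FALSE)
  }
  if (is.null(cells)) {
    cells <- data.frame(spot_id = character(), class = character(),
                        x_um = numeric(), y_um = numeric(), z_um = numeric())
  }
  need <- c("spot_id", "class", "x_um", "y_um", "z_um")
  if (!all(need %in% names(cells))) {
    stop("'cells' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(cells$class), SPOT_CLASSES)
  if (length(bad)) {
    stop("unknown spot class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  center <- as.numeric(center)
  pharynx <- as.numeric(pharynx)
  if (length(center) != 3L || length(pharynx) != 3L ||
      anyNA(center) || anyNA(pharynx)) {
    stop("'center' and 'pharynx' must be numeric length-3 vectors",
         call. = FALSE)
  }
  if (sqrt(sum((pharynx - center)^2)) == 0) {
    stop("pharynx landmark coincides with the embryo center; the oral-aboral axis is undefined",
         call. = FALSE)
  }
  structure(list(embryo_id = embryo_id,
                 cells = cells[, need],
                 center = center,
                 pharynx = pharynx,
                 center_source = center_source),
            class = "embryo_frame")
}

#' @export
print.embryo_frame <- function(x, ...) {
  tab <- table(factor(x$cells$class, levels = SPOT_CLASSES))
  cat(sprintf("Embryo frame '%s': %d spots (%s); center [%s] (%s), pharynx [%s]\n",
              x$embryo_id, nrow(x$cells),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              paste(format(x$center, digits = 4), collapse = ", "),
              x$center_source,
              paste(format(x$pharynx, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Construct a sample of oral-aboral polar angles
#'
#' @param angles numeric vector in \eqn{[0, \pi]} (radians), measured from
#'   the oral (pharynx) pole.
#' @param source_ids optional data frame with columns `embryo_id`,
#'   `spot_id` parallel to `angles`.
#' @return An object of class `"theta_sample"` with fields `angles`, `n`,
#'   `source_ids`.
#' @export
theta_sample <- function(angles = numeric(), source_ids = NULL) {
  angles <- check_theta_domain(angles)
  if (!is.null(source_ids)) {
    stopifnot(is.data.frame(source_ids),
              all(c("embryo_id", "spot_id") %in% names(source_ids)),
              nrow(source_ids) == length(angles))
  }
  structure(list(angles = angles, n = length(angles),
                 source_ids = source_ids),
            class = "theta_sample")
}

#' @export
print.theta_sample <- function(x, ...) {
  cat(sprintf("Theta sample: n = %d angles in [0, pi]", x$n))
  if (x$n) {
    cat(sprintf("; mean %.3f rad", mean(x$angles)))
  }
  cat("\n")
  invisible(x)
}

#' Oral-aboral polar angles of an embryo's cells
#'
#' For each retained cell the angle is \eqn{\theta = \arccos(\hat{u} \cdot
#' \hat{p})}, where \eqn{\hat{u}} is the unit vector from the embryo center
#' to the cell and \eqn{\hat{p}} the unit vector from the center to the
#' pharynx; \eqn{\theta = 0} at the oral pole. Equivalent to rotating the
#' cloud so the pharynx sits on the +z axis and reading off the spherical
#' polar angle, without the matrix work. The arccos argument is clamped to
#' \eqn{[-1, 1]} so rounding can never produce NaN at the poles.
#'
#' @param frame an [embryo_frame()].
#' @param include_classes spot classes to retain; beads are never included
#'   unless requested explicitly.
#' @return A [theta_sample()]. Cells at zero distance from the center are
#'   dropped with a warning. An empty retained set yields an empty sample,
#'   not an error.
#' @export
oral_aboral_angles <- function(frame,
                               include_classes = c("piwi1", "mitotic")) {
  stopifnot(inherits(frame, "embryo_frame"))
  if (length(include_classes) == 0) {
    stop("'include_classes' must name at least one spot class", call. = FALSE)
  }
  cells <- frame$cells[frame$cells$class %in% include_classes, , drop = FALSE]
  if (nrow(cells) == 0L) return(theta_sample())
  p <- frame$pharynx - frame$center
  p <- p / sqrt(sum(p^2))
  u <- cbind(cells$x_um - frame$center[1],
             cells$y_um - frame$center[2],
             cells$z_um - frame$center[3])
  len <- sqrt(rowSums(u^2))
  if (any(len == 0)) {
    warning(sum(len == 0),
            " spot(s) at zero distance from the embryo center dropped",
            call. = FALSE)
    cells <- cells[len > 0, , drop = FALSE]
    u <- u[len > 0, , drop = FALSE]
    len <- len[len > 0]
    if (nrow(cells) == 0L) return(theta_sample())
  }
  cosang <- as.numeric(u %*% p) / len
  theta <- acos(pmin(pmax(cosang, -1), 1))
  theta_sample(theta,
               data.frame(embryo_id = frame$embryo_id,
                          spot_id = cells$spot_id))
}

# Rodrigues rotation matrix taking unit vector 'from' onto unit vector 'to'.
rotation_between <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-14) {
    if (c_ > 0) return(diag(3))
    # anti-aligned: 180 degrees about any axis perpendicular to 'from'
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * from) * from
    perp <- perp / sqrt(sum(perp^2))
    return(2 * outer(perp, perp) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Align an embryo frame to the oral-aboral axis
#'
#' Returns a rigidly moved copy of the frame whose center is at the origin
#' and whose pharynx lies on the +z axis, via the rotation taking the
#' center-to-pharynx direction onto (0, 0, 1). Identity when already
#' aligned; a 180-degree rotation about a perpendicular axis when
#' anti-aligned. Being an isometry, it preserves [oral_aboral_angles()] and
#' all distances from the center.
#'
#' @param frame an [embryo_frame()].
#' @return An aligned `"embryo_frame"`.
#' @export
align_to_axis <- function(frame) {
  stopifnot(inherits(frame, "embryo_frame"))
  p <- frame$pharynx - frame$center
  p <- p / sqrt(sum(p^2))
  R <- rotation_between(p, c(0, 0, 1))
  cells <- frame$cells
  if (nrow(cells)) {
    pos <- cbind(cells$x_um - frame$center[1],
                 cells$y_um - frame$center[2],
                 cells$z_um - frame$center[3]) %*% t(R)
    cells$x_um <- pos[, 1]
    cells$y_um <- pos[, 2]
    cells$z_um <- pos[, 3]
  }
  embryo_frame(frame$embryo_id, cells,
               center = c(0, 0, 0),
               pharynx = as.numeric(R %*% (frame$pharynx - frame$center)),
               center_source = frame$center_source)
}

#' Pool angle samples across embryos
#'
#' Concatenates samples (e.g., per-embryo angle sets across a cohort of
#' stage S3 and S4 embryos), preserving source identifiers; `n` is the sum
#' of the pooled counts.
#'
#' @param samples a list of [theta_sample()] objects (a single sample is
#'   also accepted).
#' @return A pooled [theta_sample()].
#' @export
pool_theta <- function(samples) {
  if (inherits(samples, "theta_sample")) samples <- list(samples)
  stopifnot(all(vapply(samples, inherits, logical(1), "theta_sample")))
  angles <- unlist(lapply(samples, `[[`, "angles"), use.names = FALSE)
  if (is.null(angles)) angles <- numeric()
  ids <- lapply(samples, `[[`, "source_ids")
  src <- if (all(vapply(ids, is.null, logical(1)))) {
    NULL
  } else {
    do.call(rbind, lapply(seq_along(samples), function(i) {
      if (is.null(ids[[i]])) {
        data.frame(embryo_id = rep(NA_character_, samples[[i]]$n),
                   spot_id = rep(NA_character_, samples[[i]]$n))
      } else {
        ids[[i]][, c("embryo_id", "spot_id")]
      }
    }))
  }
  theta_sample(angles, src)
}
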