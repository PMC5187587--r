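#' C--H vector in the molecular frame
#'
#' @param r internuclear distance in Angstrom (> 0).
#' @param orientation numeric length-3 direction in the molecular frame;
#'   normalized to unit length.
#' @return object of class `ch_vector` with fields `r` and `orientation`
#'   (unit norm).
#' @export
ch_vector <- function(r = 1.09, orientation = c(0, 0, 1)) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("invalid geometry: C-H distance must be a positive number",
         call. = FALSE)
  if (!is.numeric(orientation) || length(orientation) != 3L ||
      any(!is.finite(orientation)))
    stop("invalid geometry: orientation must be a finite length-3 vector",
         call. = FALSE)
  nrm <- sqrt(sum(orientation^2))
  if (nrm < 1e-12)
    stop("invalid geometry: orientation vector has zero length", call. = FALSE)
  structure(list(r = r, orientation = orientation / nrm),
            class = "ch_vector")
}

#' Spin-system geometry (CH or CH2)
#'
#' A CH geometry carries one C--H vector; a CH2 geometry carries two, with the
#' H--C--H angle recorded and checked against the vectors to within 1e-9
#' degrees.
#'
#' @param ch_vectors list of one or two [ch_vector()] objects.
#' @param hch_angle H--C--H angle in degrees (CH2 only).
#' @return object of class `spin_geometry`.
#' @export
spin_geometry <- function(ch_vectors, hch_angle = NULL) {
  if (!is.list(ch_vectors) || !length(ch_vectors) %in% c(1L, 2L) ||
      !all(vapply(ch_vectors, inherits, logical(1), "ch_vector")))
    stop("invalid geometry: ch_vectors must be a list of 1 or 2 ch_vector objects",
         call. = FALSE)
  if (length(ch_vectors) == 2L) {
    if (is.null(hch_angle))
      stop("invalid geometry: CH2 requires hch_angle", call. = FALSE)
    u <- ch_vectors[[1L]]$orientation
    v <- ch_vectors[[2L]]$orientation
    ang <- acos(max(-1, min(1, sum(u * v)))) * 180 / pi
    if (abs(ang - hch_angle) > 1e-9)
      stop(sprintf(
        "invalid geometry: angle between C-H vectors (%.9f deg) differs from hch_angle (%.9f deg)",
        ang, hch_angle), call. = FALSE)
  }
  structure(list(ch_vectors = ch_vectors, hch_angle = hch_angle),
            class = "spin_geometry")
}

#' @rdname spin_geometry
#' @param r C--H distance in Angstrom.
#' @export
spin_geometry_ch <- function(r = 1.09) {
  spin_geometry(list(ch_vector(r)))
}

#' @rdname spin_geometry
#' @param r2 distance of the second C--H bond (defaults to `r`).
#' @export
spin_geometry_ch2 <- function(r = 1.09, hch_angle = 109.47, r2 = r) {
  half <- hch_angle / 2 * pi / 180
  v1 <- c(sin(half), 0, cos(half))
  v2 <- c(-sin(half), 0, cos(half))
  spin_geometry(list(ch_vector(r, v1), ch_vector(r2, v2)),
                hch_angle = hch_angle)
}

n_protons <- function(geometry) length(geometry$ch_vectors)

#' @export
print.spin_geometry <- function(x, ...) {
  kind <- if (n_protons(x) == 1L) "CH" else "CH2"
  cat(sprintf("<spin_geometry: %s>\n", kind))
  for (v in x$ch_vectors)
    cat(sprintf("  r = %.3f A, orientation = (%.4f, %.4f, %.4f)\n",
                v$r, v$orientation[1], v$orientation[2], v$orientation[3]))
  if (!is.null(x$hch_angle))
    cat(sprintf("  H-C-H angle = %.2f deg\n", x$hch_angle))
  invisible(x)
}
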