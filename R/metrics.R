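#' Circumferential cyclic strain of a vessel wall
#'
#' Computes the Green-Lagrange circumferential strain from the time course
#' of either the vessel cross-sectional area A(t) or the wall radius r(t),
#' relative to the reference frame (t = 0):
#' \deqn{E_{\theta\theta}(t) = \frac{1}{2}\left[\left(\frac{r(t)}{r(0)}\right)^2 - 1\right]
#'   = \frac{A(t)/A(0) - 1}{2}}
#' The two forms are algebraically identical for a circular cross-section
#' (A = pi r^2); when both inputs are given, both are computed and their
#' maximum absolute disagreement reported.
#'
#' @param time timepoints (ms); the reference is the entry with
#'   \code{time == 0} if present, else the first entry.
#' @param area cross-sectional areas A(t) (any area unit), all positive.
#' @param radius wall radii r(t) (any length unit), all positive.
#' @return data.frame with \code{time} and strain column(s)
#'   (\code{strain_area} and/or \code{strain_radius}); when both are
#'   given, attribute \code{max_discrepancy} holds their maximum absolute
#'   difference.
#' @examples
#' circumferential_strain(time = c(0, 50), area = c(1, 1.2))
#' @export
circumferential_strain <- function(time, area = NULL, radius = NULL) {
  if (is.null(area) && is.null(radius)) {
    stop("supply 'area' and/or 'radius'", call. = FALSE)
  }
  ref_i <- if (any(time == 0)) which(time == 0)[1L] else 1L
  out <- data.frame(time = time)
  if (!is.null(area)) {
    stopifnot(length(area) == length(time))
    if (any(area <= 0) || area[ref_i] <= 0) {
      stop("areas must be positive", call. = FALSE)
    }
    out$strain_area <- (area / area[ref_i] - 1) / 2
  }
  if (!is.null(radius)) {
    stopifnot(length(radius) == length(time))
    if (any(radius <= 0) || radius[ref_i] <= 0) {
      stop("radii must be positive", call. = FALSE)
    }
    out$strain_radius <- ((radius / radius[ref_i])^2 - 1) / 2
  }
  if (!is.null(area) && !is.null(radius)) {
    attr(out, "max_discrepancy") <-
      max(abs(out$strain_area - out$strain_radius))
  }
  out
}

#' Percentage of cell contraction from an impedance trace
#'
#' Normalizes the cell index (CI) to 1 at the time of agonist addition
#' and returns (1 - CI_min) x 100, where CI_min is the minimum normalized
#' CI within the post-agonist window (half-open: (t_agonist, t_agonist +
#' window]).  Negative values (relaxation) are returned unclamped.
#'
#' @param time timepoints (minutes).
#' @param ci cell-index values.
#' @param agonist_time time of agonist addition (must lie within the
#'   trace); the normalizing CI is the value at the latest timepoint <=
#'   \code{agonist_time}.
#' @param window window length after agonist addition (default 30 min).
#' @return contraction percentage (scalar).
#' @examples
#' contraction_percent(time = 0:40, ci = c(rep(2, 11), rep(1.6, 30)),
#'                     agonist_time = 10) # 20
#' @export
contraction_percent <- function(time, ci, agonist_time, window = 30) {
  stopifnot(length(time) == length(ci), length(ci) > 0)
  if (agonist_time < min(time) || agonist_time > max(time)) {
    stop("agonist_time must lie within the trace", call. = FALSE)
  }
  at <- max(which(time <= agonist_time))
  ci0 <- ci[at]
  if (ci0 == 0) stop("CI at agonist time is 0; cannot normalize",
                     call. = FALSE)
  norm <- ci / ci0
  in_window <- time > agonist_time & time <= agonist_time + window
  if (!any(in_window)) stop("post-agonist window is empty", call. = FALSE)
  (1 - min(norm[in_window])) * 100
}
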