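#' Extracellular stimulus field: K+ hotspot and glutamate bolus
#'
#' Prescribed (not diffusion-solved) extracellular fields: a spherical K+
#' elevation (default 2.5 -> 5 mM over a 20 um diameter sphere for 1 s) and a
#' brief glutamate bolus (default 0.1 mM for 1 ms in a 3 um sphere at 0.9 s
#' after K+ onset). Concentrations are homogeneous inside each sphere; an
#' optional exponential skirt approximates diffusion beyond the sphere edge.
#'
#' @param k_center K-sphere centre (um, length-3).
#' @param k_diameter K-sphere diameter (um), default 20.
#' @param k_amplitude K+ inside the sphere during the bolus (mM), default 5.
#' @param k_baseline Baseline K+ (mM), default 2.5.
#' @param k_onset,k_duration K-bolus timing (ms), default 0 and 1000.
#' @param glu_center Glu-sphere centre (um); `NULL` (default) lets the
#'   simulator place it on the compartment nearest 4 um from the soma inside
#'   the K sphere.
#' @param glu_diameter Glu-sphere diameter (um), default 3.
#' @param glu_peak Glutamate during the bolus (mM), default 0.1.
#' @param glu_onset,glu_duration Glu-bolus timing (ms), default 900 and 1
#'   (the 2 ms variant is selectable).
#' @param skirt_lambda Optional length constant (um) of an exponential
#'   concentration skirt outside the spheres; `NULL` (default) disables it.
#' @param glu_ambient `"reversal"` (ambient glutamate pinned to the
#'   transporter zero-current concentration for the local K+) or `"zero"`.
#'
#' @return A list of class `"stimulus_field"`.
#' @export
stimulus_field <- function(k_center = c(0, 0, 0), k_diameter = 20,
                           k_amplitude = 5, k_baseline = 2.5,
                           k_onset = 0, k_duration = 1000,
                           glu_center = NULL, glu_diameter = 3,
                           glu_peak = 0.1, glu_onset = 900, glu_duration = 1,
                           skirt_lambda = NULL,
                           glu_ambient = c("reversal", "zero")) {
  glu_ambient <- match.arg(glu_ambient)
  stopifnot(length(k_center) == 3,
            is.null(glu_center) || length(glu_center) == 3,
            k_diameter > 0, glu_diameter > 0, k_duration > 0,
            glu_duration > 0, glu_peak >= 0)
  if (k_amplitude < k_baseline) {
    stop("stimulus_field: k_amplitude must be >= k_baseline", call. = FALSE)
  }
  if (!is.null(glu_center)) {
    d <- sqrt(sum((glu_center - k_center)^2))
    if (k_amplitude > k_baseline &&
        d + glu_diameter / 2 > k_diameter / 2 + 1e-9) {
      warning("stimulus_field: glutamate sphere is not fully inside the K+ ",
              "sphere; the paired-condition geometry expects it to be")
    }
  }
  structure(list(k_center = k_center, k_diameter = k_diameter,
                 k_amplitude = k_amplitude, k_baseline = k_baseline,
                 k_onset = k_onset, k_duration = k_duration,
                 glu_center = glu_center, glu_diameter = glu_diameter,
                 glu_peak = glu_peak, glu_onset = glu_onset,
                 glu_duration = glu_duration,
                 skirt_lambda = skirt_lambda, glu_ambient = glu_ambient,
                 ambient_values = NULL),
            class = "stimulus_field")
}

sphere_weight <- function(pos, centre, radius, lambda) {
  d <- sqrt((pos[, 1] - centre[1])^2 + (pos[, 2] - centre[2])^2 +
              (pos[, 3] - centre[3])^2)
  w <- as.numeric(d <= radius)
  if (!is.null(lambda)) {
    out <- d > radius
    w[out] <- exp(-(d[out] - radius) / lambda)
  }
  w
}

#' Sample the extracellular field at positions and a time
#'
#' @param field A [stimulus_field()].
#' @param position Length-3 vector or n x 3 matrix of positions (um).
#' @param t Time (ms), `>= 0`, relative to the K-bolus onset convention of
#'   the field.
#' @param ambient Ambient glutamate values `c(baseline, elevated)` (mM) used
#'   outside the bolus; defaults to the values attached by the simulator, or
#'   0 when none are attached.
#'
#' @return A tibble with one row per position: `K_out`, `Glu_out` (mM).
#' @examples
#' f <- stimulus_field()
#' sample_extracellular(f, c(0, 0, 0), t = 500)    # inside K sphere
#' sample_extracellular(f, c(4, 0, 0), t = 900.5)  # during the Glu bolus
#' @export
sample_extracellular <- function(field, position, t, ambient = NULL) {
  stopifnot(inherits(field, "stimulus_field"), t >= 0)
  if (is.null(field$glu_center)) {
    stop("sample_extracellular: glu_center is unresolved; set it or let ",
         "simulate_coupled() place it on the morphology", call. = FALSE)
  }
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  if (is.null(ambient)) {
    ambient <- field$ambient_values %||% c(baseline = 0, elevated = 0)
  }
  k_on <- t >= field$k_onset && t < field$k_onset + field$k_duration
  wk <- sphere_weight(pos, field$k_center, field$k_diameter / 2,
                      field$skirt_lambda)
  K <- field$k_baseline +
    (if (k_on) (field$k_amplitude - field$k_baseline) * wk else 0)
  glu_on <- t >= field$glu_onset && t < field$glu_onset + field$glu_duration
  wg <- sphere_weight(pos, field$glu_center, field$glu_diameter / 2,
                      field$skirt_lambda)
  amb <- ambient[[1]] + (if (k_on) (ambient[[2]] - ambient[[1]]) * wk else 0)
  Glu <- amb
  if (glu_on) Glu <- pmax(amb, field$glu_peak * wg)
  tibble::tibble(K_out = K, Glu_out = Glu)
}
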