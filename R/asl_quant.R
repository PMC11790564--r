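#' ASL quantification constants
#'
#' Consensus single-compartment pulsed-ASL constants: longitudinal
#' relaxation time of arterial blood (ms), labeling efficiency, and
#' blood-brain partition coefficient (ml/g).
#'
#' @param t1_blood_ms T1 of arterial blood in ms (default 1650).
#' @param alpha labeling efficiency in (0, 1] (default 0.98).
#' @param lambda blood-brain partition coefficient, ml/g (default 0.9).
#' @return list of class `quant_params`.
#' @export
quant_params <- function(t1_blood_ms = 1650, alpha = 0.98, lambda = 0.9) {
  stopifnot(t1_blood_ms > 0, alpha > 0, alpha <= 1, lambda > 0)
  structure(list(t1_blood_ms = t1_blood_ms, alpha = alpha, lambda = lambda),
            class = "quant_params")
}

#' Perfusion-weighted difference from a control/label series
#'
#' Forms the mean perfusion-weighted signal \eqn{\Delta M} from an alternating
#' control/label time series. The default `pairwise` scheme subtracts each
#' label volume from its paired control before averaging. The `surround`
#' scheme subtracts, at each interior control, the mean of the two adjacent
#' label volumes, which cancels a linear temporal drift to first order.
#'
#' @param series 4D array, time along the 4th dimension, volumes alternating
#'   control, label, control, label, ... (control first by default).
#' @param scheme `"pairwise"` or `"surround"`.
#' @param control_first logical; if `FALSE` the series starts with a label
#'   volume.
#' @return 3D array, the mean difference signal.
#' @export
surround_subtract <- function(series, scheme = c("pairwise", "surround"),
                              control_first = TRUE) {
  scheme <- match.arg(scheme)
  if (is.null(dim(series)) || length(dim(series)) != 4L)
    stop("'series' must be a 4D array (x, y, z, time)", call. = FALSE)
  nt <- dim(series)[4]
  if (nt < 2L || nt %% 2L != 0L)
    stop("'series' must hold an equal number of control and label volumes",
         call. = FALSE)
  ctrl_idx <- seq(if (control_first) 1L else 2L, nt, by = 2L)
  lab_idx <- seq(if (control_first) 2L else 1L, nt, by = 2L)
  ctrl <- series[, , , ctrl_idx, drop = FALSE]
  lab <- series[, , , lab_idx, drop = FALSE]
  npair <- length(ctrl_idx)
  if (scheme == "pairwise" || npair < 2L) {
    dm <- ctrl - lab
  } else {
    # surround: control_k minus the mean of the labels flanking it in time;
    # at the series ends only one flanking label exists
    dm <- array(0, dim = dim(ctrl))
    for (k in seq_len(npair)) {
      if (control_first) {
        # labels at positions k-1 and k flank control k
        lo <- max(1L, k - 1L); hi <- k
      } else {
        lo <- k; hi <- min(npair, k + 1L)
      }
      dm[, , , k] <- ctrl[, , , k] - (lab[, , , lo] + lab[, , , hi]) / 2
    }
  }
  apply(dm, 1:3, mean)
}

#' Cerebral blood flow from the single-compartment pulsed-ASL model
#'
#' Closed-form QUIPSS II quantification:
#' \deqn{CBF = \frac{6000 \,\lambda\, \Delta M \, e^{TI/T_{1b}}}{2\,\alpha\, TI_1 \, M_0}}
#' with \eqn{TI_1} in seconds, yielding ml/100g/min. Voxels whose `m0` falls
#' at or below `m0_threshold` times the robust maximum of `m0` are masked to
#' `NA` to guard against division blow-ups.
#'
#' @param deltam 3D perfusion-weighted difference volume.
#' @param m0 3D equilibrium magnetization volume, same grid.
#' @param params a [quant_params()] object.
#' @param ti_ms inversion time in ms (default 1800).
#' @param ti1_ms bolus duration in ms (default 1650).
#' @param m0_threshold fraction of the robust (99th percentile) maximum of
#'   `m0` below which voxels are masked (default 0.1).
#' @return 3D CBF array in ml/100g/min, `NA` at masked voxels. The count of
#'   masked voxels is attached as attribute `n_masked`.
#' @export
pasl_cbf <- function(deltam, m0, params = quant_params(),
                     ti_ms = 1800, ti1_ms = 1650, m0_threshold = 0.1) {
  check_same_grid(deltam, m0, "deltam", "m0")
  stopifnot(inherits(params, "quant_params"), ti_ms > 0, ti1_ms > 0)
  robust_max <- quantile(m0[is.finite(m0)], 0.99, names = FALSE)
  bad <- !is.finite(m0) | m0 <= m0_threshold * robust_max
  cbf <- 6000 * params$lambda * deltam * exp(ti_ms / params$t1_blood_ms) /
    (2 * params$alpha * (ti1_ms / 1000) * m0)
  cbf[bad] <- NA_real_
  attr(cbf, "n_masked") <- sum(bad)
  cbf
}

#' Normalize CBF to the subject's total-brain mean
#'
#' Divides a CBF volume by its mean over the whole brain mask (gray matter,
#' white matter and CSF/ventricular compartments together), yielding
#' dimensionless relative CBF (rCBF) whose brain-mask mean is exactly 1.
#'
#' @param cbf 3D CBF volume.
#' @param brain_mask 3D mask of all brain voxels.
#' @return 3D rCBF array with the normalizer (ml/100g/min) attached as
#'   attribute `normalizer`.
#' @export
relative_cbf <- function(cbf, brain_mask) {
  m <- as_mask(brain_mask, "brain_mask")
  check_same_grid(cbf, m, "cbf", "brain_mask")
  if (!any(m)) stop("brain mask is empty", call. = FALSE)
  normalizer <- mean(cbf[m], na.rm = TRUE)
  if (!is.finite(normalizer) || normalizer <= 0)
    stop("total-brain mean CBF is not positive; cannot normalize",
         call. = FALSE)
  out <- cbf / normalizer
  attr(out, "normalizer") <- normalizer
  attr(out, "n_masked") <- NULL
  out
}
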