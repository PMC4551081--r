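#' Double-gamma hemodynamic response function kernel
#'
#' The canonical HRF approximation: the difference of two gamma
#' densities, a positive response peaking a few seconds after the event
#' and a delayed undershoot scaled by \code{ratio}.  The kernel is
#' sampled at the repetition time and normalized to unit peak.
#'
#' Default parameters follow the conventional double-gamma
#' parameterization: peak delay 6 s, undershoot delay 16 s, dispersions
#' 1 s, peak/undershoot ratio 1/6, onset 0 s.
#'
#' @param tr_seconds sampling interval in seconds (> 0).
#' @param duration_seconds kernel support in seconds (>= 2 TRs).
#' @param parameters optional named overrides of any of
#'   \code{peak_delay}, \code{undershoot_delay}, \code{peak_dispersion},
#'   \code{undershoot_dispersion}, \code{ratio}, \code{onset}.
#' @return object of class \code{"hrf_kernel"}: \code{samples} (first
#'   sample at time 0), \code{tr_seconds}, \code{duration_seconds},
#'   \code{parameters}, \code{kernel_id}.
#' @export
#' @examples
#' k <- hrf_double_gamma(2)
#' plot(seq_along(k$samples) * 2 - 2, k$samples, type = "l")
hrf_double_gamma <- function(tr_seconds, duration_seconds = 32,
                             parameters = list()) {
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (duration_seconds < 2 * tr_seconds)
    stop("duration_seconds must be at least two sampling intervals")
  par <- modifyList(list(peak_delay = 6, undershoot_delay = 16,
                         peak_dispersion = 1, undershoot_dispersion = 1,
                         ratio = 1 / 6, onset = 0), parameters)
  t <- seq(0, by = tr_seconds, length.out = ceiling(duration_seconds / tr_seconds))
  h <- .hrf_eval(t, par)
  peak <- max(h)
  if (peak <= 0) stop("degenerate HRF: non-positive peak")
  structure(list(samples = h / peak,
                 tr_seconds = tr_seconds,
                 duration_seconds = duration_seconds,
                 parameters = par,
                 kernel_id = paste0("double-gamma:",
                                    paste(signif(unlist(par), 4), collapse = ","))),
            class = "hrf_kernel")
}

.hrf_eval <- function(t, par) {
  ts <- t - par$onset
  shape1 <- par$peak_delay / par$peak_dispersion
  shape2 <- par$undershoot_delay / par$undershoot_dispersion
  g1 <- stats::dgamma(ts, shape = shape1, scale = par$peak_dispersion)
  g2 <- stats::dgamma(ts, shape = shape2, scale = par$undershoot_dispersion)
  g1 - par$ratio * g2
}

#' Task input container
#'
#' Holds one or more external (task-condition) input vectors aligned to
#' an ROI time series, before and after HRF convolution.
#'
#' @param raw numeric vector or n_u x T matrix of raw input (e.g. a 0/1
#'   boxcar of task presence).
#' @return object of class \code{"input_series"}.
#' @export
input_series <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  if (!all(is.finite(raw))) stop("non-finite input values")
  structure(list(raw = raw, convolved = NULL, kernel_id = NA_character_),
            class = "input_series")
}

#' @export
print.input_series <- function(x, ...) {
  cat("task input:", nrow(x$raw), "vector(s) of length", ncol(x$raw),
      if (!is.null(x$convolved)) paste0("(convolved: ", x$kernel_id, ")") else
        "(not convolved)", "\n")
  invisible(x)
}

#' Convolve task input with an HRF kernel
#'
#' Causal discrete convolution of each raw input vector with the kernel
#' samples, truncated to the input length.  The raw input is preserved.
#'
#' @param u an \code{\link{input_series}} (or numeric vector/matrix).
#' @param kernel an \code{\link{hrf_kernel}}.
#' @return the \code{input_series} with its \code{convolved} field set.
#' @export
convolve_input <- function(u, kernel) {
  if (!inherits(u, "input_series")) u <- input_series(u)
  h <- kernel$samples
  T <- ncol(u$raw)
  conv <- t(apply(u$raw, 1, function(x) {
    stats::convolve(x, rev(h), type = "open")[seq_len(T)]
  }))
  if (nrow(u$raw) == 1) conv <- matrix(conv, nrow = 1)
  u$convolved <- conv
  u$kernel_id <- kernel$kernel_id
  u
}
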