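#' Preprocessing configuration
#'
#' Parameters for the three-stage spectral clean-up: Savitzky--Golay
#' smoothing, airPLS baseline removal and per-spectrum min--max scaling.
#' Window 11 / order 3 suits spectra sampled at roughly 2 cm^-1; lambda 1e5
#' gives a baseline stiff enough to ride under serum fluorescence without
#' absorbing Raman peaks. All values are tunable.
#'
#' @param sg_window Savitzky--Golay window length in points (odd,
#'   > \code{sg_order}).
#' @param sg_order Savitzky--Golay polynomial degree.
#' @param airpls_lambda Smoothness penalty lambda (> 0); larger values give
#'   stiffer baselines.
#' @param airpls_ratio Termination ratio in (0, 1): iteration stops when the
#'   mass of points below the baseline falls under this fraction of the
#'   total signal mass.
#' @param airpls_maxiter Iteration cap (>= 1).
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(sg_window = 11, sg_order = 3,
                              airpls_lambda = 1e5, airpls_ratio = 1e-3,
                              airpls_maxiter = 30) {
  sg_window <- as.integer(sg_window)
  sg_order <- as.integer(sg_order)
  if (is.na(sg_window) || sg_window %% 2 == 0)
    stop("'sg_window' must be odd")
  if (is.na(sg_order) || sg_order < 0 || sg_order >= sg_window)
    stop("'sg_order' must be non-negative and smaller than 'sg_window'")
  if (!is.finite(airpls_lambda) || airpls_lambda <= 0)
    stop("'airpls_lambda' must be > 0")
  if (!is.finite(airpls_ratio) || airpls_ratio <= 0 || airpls_ratio >= 1)
    stop("'airpls_ratio' must be in (0, 1)")
  airpls_maxiter <- as.integer(airpls_maxiter)
  if (is.na(airpls_maxiter) || airpls_maxiter < 1)
    stop("'airpls_maxiter' must be >= 1")
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 airpls_lambda = airpls_lambda, airpls_ratio = airpls_ratio,
                 airpls_maxiter = airpls_maxiter),
            class = "preprocess_config")
}

#' Savitzky--Golay smoothing
#'
#' Local least-squares polynomial smoothing: within each sliding window a
#' polynomial of the given degree is fitted and evaluated at the window
#' centre, which removes high-frequency noise while preserving peak width
#' and shape. Exact on any signal that is itself a polynomial of degree at
#' most \code{order}.
#'
#' @param intensity Numeric vector, length >= \code{window}.
#' @param window Window length in points (odd, > \code{order}).
#' @param order Polynomial degree.
#' @return Smoothed vector of the same length.
#' @export
savitzky_golay <- function(intensity, window = 11, order = 3) {
  window <- as.integer(window)
  order <- as.integer(order)
  if (is.na(window) || window %% 2 == 0) stop("'window' must be odd")
  if (is.na(order) || order < 0 || order >= window)
    stop("'order' must be non-negative and smaller than 'window'")
  if (!is.numeric(intensity) || length(intensity) < window)
    stop("'intensity' must be numeric with length >= 'window'")
  if (any(!is.finite(intensity))) stop("'intensity' contains non-finite values")
  as.numeric(signal::sgolayfilt(intensity, p = order, n = window))
}

#' airPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares. At iteration t
#' the baseline z solves the weighted Whittaker system
#' \deqn{(W_t + \lambda D^T D)\, z = W_t\, y}
#' with D the second-difference operator, so z is smooth where the penalty
#' dominates and tracks y where the weights are large. The residual
#' d = y - z then drives the reweighting: points at or above the baseline
#' (Raman peaks) get weight 0, while points below it get
#' w_i = exp(t |d_i| / |d^-|) where |d^-| is the total mass of negative
#' residuals. Iteration stops when |d^-| < ratio * ||y||_1 (or the negative
#' mass vanishes), or at \code{maxiter}. The system is pentadiagonal and is
#' solved sparsely in O(L) memory.
#'
#' @param intensity Numeric vector of length >= 4.
#' @param lambda Smoothness penalty (> 0).
#' @param ratio Termination ratio in (0, 1).
#' @param maxiter Iteration cap.
#' @return An object of class \code{airpls_result}: list with
#'   \code{baseline}, \code{corrected} (\code{intensity - baseline}),
#'   \code{n_iterations} and \code{converged}.
#' @examples
#' x <- seq(0, 1, length.out = 200)
#' y <- 2 + x + exp(-((x - 0.5) / 0.02)^2)  # line + one peak
#' res <- airpls(y, lambda = 1e4)
#' max(abs(res$corrected[abs(x - 0.5) > 0.2]))  # ~0 off-peak
#' @export
airpls <- function(intensity, lambda = 1e5, ratio = 1e-3, maxiter = 30) {
  y <- as.numeric(intensity)
  L <- length(y)
  if (L < 4) stop("'intensity' must have length >= 4")
  if (any(!is.finite(y))) stop("'intensity' contains non-finite values")
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  D <- Matrix::bandSparse(L - 2, L, k = 0:2,
                          diagonals = list(rep(1, L - 2), rep(-2, L - 2),
                                           rep(1, L - 2)))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, L)
  y_l1 <- sum(abs(y))
  converged <- FALSE
  z <- y
  for (t in seq_len(maxiter)) {
    W <- Matrix::Diagonal(L, w)
    z <- as.numeric(Matrix::solve(W + lambda * DtD, w * y))
    d <- y - z
    neg <- d < 0
    dneg <- sum(abs(d[neg]))
    if (dneg == 0 || dneg < ratio * y_l1) {
      converged <- TRUE
      break
    }
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dneg)
  }
  structure(list(baseline = z, corrected = y - z,
                 n_iterations = t, converged = converged),
            class = "airpls_result")
}

#' @export
#' @method print airpls_result
print.airpls_result <- function(x, ...) {
  cat(sprintf("<airpls_result> L=%d, %d iteration(s), %s\n",
              length(x$baseline), x$n_iterations,
              if (x$converged) "converged" else "reached maxiter"))
  invisible(x)
}

#' Min--max scaling
#'
#' Rescales a spectrum affinely to \code{[0, 1]} so classifiers see relative
#' rather than absolute Raman intensity.
#'
#' @param intensity Non-constant numeric vector.
#' @return \code{(y - min) / (max - min)}; minimum exactly 0, maximum
#'   exactly 1.
#' @export
minmax_scale <- function(intensity) {
  if (any(!is.finite(intensity))) stop("'intensity' contains non-finite values")
  r <- range(intensity)
  if (r[1] == r[2])
    stop("constant spectrum: min-max scaling is undefined")
  (intensity - r[1]) / (r[2] - r[1])
}

#' Preprocess every spectrum in a set
#'
#' Applies, independently per spectrum and in this fixed order: Savitzky--
#' Golay smoothing, airPLS baseline subtraction, min--max scaling. Labels
#' and sample identifiers are preserved. Stage errors are annotated with the
#' offending sample's identifier.
#'
#' @param set A \code{\link{spectrum_set}}.
#' @param cfg A \code{\link{preprocess_config}}.
#' @return A \code{\link{spectrum_set}} of cleaned spectra, each with
#'   minimum 0 and maximum 1.
#' @export
preprocess_set <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectrum_set"), inherits(cfg, "preprocess_config"))
  n <- nrow(set$intensities)
  out <- set$intensities
  for (i in seq_len(n)) {
    y <- tryCatch({
      s <- savitzky_golay(set$intensities[i, ], cfg$sg_window, cfg$sg_order)
      b <- airpls(s, cfg$airpls_lambda, cfg$airpls_ratio, cfg$airpls_maxiter)
      minmax_scale(b$corrected)
    }, error = function(e)
      stop(sprintf("sample '%s': %s", set$sample_ids[i], conditionMessage(e)),
           call. = FALSE))
    stopifnot(min(y) == 0, max(y) == 1)
    out[i, ] <- y
  }
  spectrum_set(set$axis, out, set$labels, set$sample_ids,
               class_order = if (is.null(set$labels)) NULL else levels(set$labels))
}
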