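#' Diagnostic class vocabulary
#'
#' The three diagnostic groups handled by the pipeline, in canonical order:
#' healthy controls (HC), breast cancer (BC) and ductal carcinoma in situ
#' (DCIS).
#'
#' @return Character vector \code{c("HC", "BC", "DCIS")}.
#' @export
raman_classes <- function() c("HC", "BC", "DCIS")

#' Build an evenly spaced wavenumber axis
#'
#' Creates the Raman-shift axis shared by all spectra in a dataset. The
#' default covers 400--4000 cm^-1 with 1698 points, the shape serum spectra
#' are recorded on by a dispersive spectrometer in this pipeline.
#'
#' @param start First Raman shift in cm^-1 (must be >= 0).
#' @param stop Last Raman shift in cm^-1 (must exceed \code{start}).
#' @param n_points Number of points (>= 8).
#' @return Numeric vector of length \code{n_points}, strictly increasing,
#'   with endpoints exactly \code{start} and \code{stop}.
#' @examples
#' ax <- make_axis(400, 4000, 1698)
#' length(ax); range(ax)
#' @export
make_axis <- function(start = 400, stop = 4000, n_points = 1698) {
  if (!is.numeric(start) || !is.numeric(stop) || length(start) != 1 ||
      length(stop) != 1 || !is.finite(start) || !is.finite(stop))
    stop("'start' and 'stop' must be finite scalars")
  if (stop <= start) stop("'stop' must be greater than 'start'")
  if (start < 0) stop("'start' must be non-negative (Raman shift in cm^-1)")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 8)
    stop("'n_points' must be at least 8")
  seq(start, stop, length.out = n_points)
}

check_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 8)
    stop("axis must be a numeric vector of length >= 8")
  if (any(!is.finite(axis))) stop("axis contains non-finite values")
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  if (axis[1] < 0) stop("axis must start at a non-negative wavenumber")
  invisible(axis)
}

#' Construct a set of aligned spectra
#'
#' A \code{spectrum_set} holds N spectra sharing one wavenumber axis, with
#' an optional diagnostic label and an identifier per spectrum. It is the
#' dataset object consumed by preprocessing, splitting and model fitting.
#'
#' @param axis Shared wavenumber axis (see \code{\link{make_axis}}).
#' @param intensities N x L numeric matrix, one spectrum per row.
#' @param labels Character or factor of length N with values from
#'   \code{class_order} (may be \code{NULL} for unlabelled data).
#' @param sample_ids Character vector of length N; generated as
#'   \code{"S1"..."SN"} when omitted.
#' @param class_order Label vocabulary and its order; defaults to
#'   \code{\link{raman_classes}()} restricted to the labels present.
#' @return An object of class \code{spectrum_set}: a list with elements
#'   \code{axis}, \code{intensities}, \code{labels} (factor or \code{NULL})
#'   and \code{sample_ids}.
#' @export
spectrum_set <- function(axis, intensities, labels = NULL, sample_ids = NULL,
                         class_order = NULL) {
  check_axis(axis)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) > 0 && ncol(intensities) != length(axis))
    stop("ncol(intensities) must equal length(axis)")
  if (nrow(intensities) > 0 && any(!is.finite(intensities)))
    stop("intensities contain non-finite values")
  n <- nrow(intensities)
  if (!is.null(labels)) {
    if (length(labels) != n) stop("length(labels) must equal nrow(intensities)")
    if (is.null(class_order)) {
      known <- raman_classes()
      class_order <- if (all(as.character(labels) %in% known))
        known[known %in% as.character(labels)] else sort(unique(as.character(labels)))
    }
    bad <- setdiff(unique(as.character(labels)), class_order)
    if (length(bad))
      stop("unknown label(s): ", paste(bad, collapse = ", "))
    labels <- factor(as.character(labels), levels = class_order)
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (n > 0) paste0("S", seq_len(n)) else character(0)
  }
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal nrow(intensities)")
  dimnames(intensities) <- NULL
  structure(list(axis = axis, intensities = intensities,
                 labels = labels, sample_ids = as.character(sample_ids)),
            class = "spectrum_set")
}

#' @export
#' @method print spectrum_set
print.spectrum_set <- function(x, ...) {
  n <- nrow(x$intensities)
  cat(sprintf("<spectrum_set> %d spectra x %d points, %.1f-%.1f cm^-1\n",
              n, length(x$axis), min(x$axis), max(x$axis)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) nrow(x$intensities)

#' Subset a spectrum set by sample index
#'
#' @param x A \code{spectrum_set}.
#' @param i Integer or logical index over samples (rows).
#' @param ... Ignored.
#' @return A \code{spectrum_set} with the selected spectra; the label
#'   vocabulary (factor levels) is preserved.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  structure(list(axis = x$axis,
                 intensities = x$intensities[i, , drop = FALSE],
                 labels = if (is.null(x$labels)) NULL else x$labels[i],
                 sample_ids = x$sample_ids[i]),
            class = "spectrum_set")
}

#' Plot class-mean spectra
#'
#' Draws the mean spectrum of each diagnostic class (or the overall mean for
#' unlabelled data) against the wavenumber axis.
#'
#' @param x A \code{spectrum_set}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.spectrum_set <- function(x, ...) {
  if (nrow(x$intensities) == 0) stop("empty spectrum_set")
  if (is.null(x$labels)) {
    m <- matrix(colMeans(x$intensities), ncol = 1)
    lab <- "mean"
  } else {
    lev <- levels(droplevels(x$labels))
    m <- sapply(lev, function(l)
      colMeans(x$intensities[x$labels == l, , drop = FALSE]))
    lab <- lev
  }
  graphics::matplot(x$axis, m, type = "l", lty = 1,
                    xlab = expression(paste("Raman shift (", cm^-1, ")")),
                    ylab = "Intensity (a.u.)", ...)
  graphics::legend("topright", legend = lab, lty = 1,
                   col = seq_along(lab), bty = "n")
  invisible(x)
}
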