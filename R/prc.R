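#' Tabulated infinitesimal phase-resetting curve
#'
#' A PRC tabulated at phase-bin centers, in units of cycles per pA·ms
#' (phase advance per unit injected charge). The continuous curve is the
#' piecewise-linear interpolant through the bin centers with the endpoints
#' pinned to zero: Z(0) = Z(1) = 0.
#'
#' @param bin_centers Phases in (0, 1), strictly increasing.
#' @param values PRC values at the bin centers, cycles/(pA·ms).
#' @param se Optional standard errors (same units, one per bin).
#' @param r_squared Optional R² of the regression the table came from.
#' @return An object of class `"prc"`.
#' @examples
#' z <- tabulated_prc(c(0.25, 0.5, 0.75), c(1, 2, 1) * 1e-3)
#' prc_interpolate(z, c(0, 0.375, 1))
#' sensitivity(z)
#' centroid(z)
#' @export
tabulated_prc <- function(bin_centers, values, se = NULL, r_squared = NULL) {
  bin_centers <- as.numeric(bin_centers)
  values <- as.numeric(values)
  if (length(bin_centers) != length(values))
    stop("bin_centers and values must have equal length")
  if (any(bin_centers <= 0) || any(bin_centers >= 1))
    stop("bin centers must lie strictly inside (0, 1)")
  if (is.unsorted(bin_centers, strictly = TRUE))
    stop("bin centers must be strictly increasing")
  if (!all(is.finite(values))) stop("PRC values must be finite")
  if (!is.null(se) && length(se) != length(values))
    stop("se must have one entry per bin")
  structure(list(bin_centers = bin_centers, values = values,
                 se = se, r_squared = r_squared),
            class = "prc")
}

#' @export
print.prc <- function(x, ...) {
  cat(sprintf("<prc: %d bins, peak %.4g cycles/(pA ms) at phase %.3f",
              length(x$values), max(x$values),
              x$bin_centers[which.max(x$values)]))
  if (!is.null(x$r_squared)) cat(sprintf(", fit R^2 = %.3f", x$r_squared))
  cat(">\n")
  cat(sprintf("  sensitivity (int Z^2): %.4g cycles^2/(pA^2 ms^2)\n", sensitivity(x)))
  if (abs(sum(x$values)) > 0)
    cat(sprintf("  centroid             : %.4f\n", centroid(x)))
  invisible(x)
}

#' @export
plot.prc <- function(x, se_band = TRUE, ...) {
  knots <- .prc_knots(x)
  graphics::plot(knots$x, knots$y, type = "l", xlab = "phase (cycles)",
                 ylab = "Z (cycles / pA ms)", ...)
  graphics::points(x$bin_centers, x$values, pch = 16, cex = 0.6)
  if (se_band && !is.null(x$se))
    graphics::arrows(x$bin_centers, x$values - 2 * x$se,
                     x$bin_centers, x$values + 2 * x$se,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  invisible(x)
}

# knots of the pinned-endpoint interpolant
.prc_knots <- function(prc) {
  list(x = c(0, prc$bin_centers, 1), y = c(0, prc$values, 0))
}

#' Evaluate the interpolated PRC
#'
#' Piecewise-linear interpolation between bin centers with pinned zero
#' endpoints. Phases past the firing point (`phi > 1`) return 0: charge
#' delivered after the crossing cannot reset the interval that produced it.
#'
#' @param prc A [tabulated_prc()].
#' @param phi Phase(s) in `[0, 1]` (values above 1 allowed, returning 0).
#' @return Numeric vector of Z values, cycles/(pA·ms).
#' @export
prc_interpolate <- function(prc, phi) {
  stopifnot(inherits(prc, "prc"))
  phi <- as.numeric(phi)
  if (any(phi < 0)) stop("phase must be >= 0")
  k <- .prc_knots(prc)
  out <- numeric(length(phi))
  inside <- phi <= 1
  if (any(inside))
    out[inside] <- stats::approx(k$x, k$y, xout = phi[inside], rule = 2)$y
  out
}

#' PRC sensitivity: the integral of the squared PRC
#'
#' Computes S = ∫₀¹ Z(φ)² dφ on the pinned-endpoint piecewise-linear
#' interpolant. The square of a linear segment is quadratic, so the segment
#' integral has the exact closed form (v₁² + v₁v₂ + v₂²)/3 × width, which is
#' used here (a triangular PRC of height h integrates to h²/3 exactly).
#'
#' @param prc A [tabulated_prc()].
#' @return Sensitivity in cycles²/(pA²·ms²). This scalar controls how strongly
#'   zero-mean current noise inflates spike-time variance.
#' @export
sensitivity <- function(prc) {
  stopifnot(inherits(prc, "prc"))
  k <- .prc_knots(prc)
  v1 <- k$y[-length(k$y)]; v2 <- k$y[-1]
  w <- diff(k$x)
  sum(w * (v1^2 + v1 * v2 + v2^2) / 3)
}

#' PRC centroid (first moment)
#'
#' The sum of the products of the tabulated PRC values and their phases,
#' divided by the sum of the PRC values. Summarizes whether noise sensitivity
#' peaks early or late in the firing cycle.
#'
#' @param prc A [tabulated_prc()].
#' @return Centroid phase in (0, 1).
#' @export
centroid <- function(prc) {
  stopifnot(inherits(prc, "prc"))
  s <- sum(prc$values)
  if (s == 0) stop("centroid undefined: PRC values sum to zero")
  sum(prc$bin_centers * prc$values) / s
}

#' Parametric type-1 PRC fixtures
#'
#' Generates nonnegative (type-1) PRC shapes tabulated at bin centers, used
#' as ground truth in synthetic experiments:
#' * `raised_cosine`: Z(φ) = A·(1 − cos 2πφ)/2, symmetric about φ = 0.5;
#' * `beta`: Z(φ) = A·φᵖ(1 − φ)ᑫ / max, skewed early (p < q) or late (p > q).
#'
#' The amplitude may be given directly or calibrated so that [sensitivity()]
#' of the continuous shape equals a target value (for the raised cosine the
#' unit-amplitude integral is exactly 3/8; the beta shape is integrated
#' numerically).
#'
#' @param family Shape family.
#' @param amplitude Peak value A in cycles/(pA·ms); ignored if
#'   `sensitivity_target` is given.
#' @param sensitivity_target Desired ∫Z² in cycles²/(pA²·ms²).
#' @param p,q Beta-family exponents (> 0).
#' @param n_bins Number of tabulation bins; centers at (i − ½)/n_bins.
#' @return A [tabulated_prc()].
#' @examples
#' z <- make_type1_prc(sensitivity_target = 4e-7)
#' sensitivity(z)
#' @export
make_type1_prc <- function(family = c("raised_cosine", "beta"),
                           amplitude = NULL, sensitivity_target = NULL,
                           p = 2, q = 2, n_bins = 50) {
  family <- match.arg(family)
  shape <- switch(family,
    raised_cosine = function(phi) (1 - cos(2 * pi * phi)) / 2,
    beta = {
      if (p <= 0 || q <= 0) stop("beta exponents p, q must be > 0")
      pk <- p / (p + q)
      mx <- pk^p * (1 - pk)^q
      function(phi) phi^p * (1 - phi)^q / mx
    })
  if (is.null(amplitude)) {
    if (is.null(sensitivity_target))
      stop("supply either amplitude or sensitivity_target")
    s_unit <- if (family == "raised_cosine") 3 / 8 else
      stats::integrate(function(u) shape(u)^2, 0, 1, rel.tol = 1e-10)$value
    amplitude <- sqrt(sensitivity_target / s_unit)
  }
  if (amplitude < 0) stop("amplitude must be nonnegative")
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  tabulated_prc(centers, amplitude * shape(centers))
}

#' Read/write PRC tables as delimited text
#'
#' Columns: bin center, value, and optionally standard error; an optional
#' `# r_squared = ...` header carries the fit R².
#'
#' @param path File path.
#' @return [read_prc()] returns a [tabulated_prc()]; [write_prc()] returns
#'   `path` invisibly.
#' @export
read_prc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- .parse_header(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(.split_fields(body), as.numeric))
  if (anyNA(m)) stop("non-numeric entry in PRC table ", path)
  tabulated_prc(m[, 1], m[, 2],
                se = if (ncol(m) >= 3) m[, 3] else NULL,
                r_squared = if (!is.null(hdr$r_squared))
                  as.numeric(hdr$r_squared) else NULL)
}

#' @rdname read_prc
#' @param x A [tabulated_prc()].
#' @export
write_prc <- function(x, path) {
  stopifnot(inherits(x, "prc"))
  hdr <- "# bin_center value"
  if (!is.null(x$se)) hdr <- paste(hdr, "se")
  out <- hdr
  if (!is.null(x$r_squared))
    out <- c(sprintf("# r_squared = %.17g", x$r_squared), out)
  rows <- if (is.null(x$se))
    sprintf("%.17g\t%.17g", x$bin_centers, x$values)
  else
    sprintf("%.17g\t%.17g\t%.17g", x$bin_centers, x$values, x$se)
  writeLines(c(out, rows), path)
  invisible(path)
}
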