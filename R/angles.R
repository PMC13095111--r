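#' Wrap an angle to the canonical range [0, 360)
#'
#' All angles in this package are azimuths in degrees with canonical range
#' \eqn{[0, 360)}; positive rotation is counter-clockwise.
#'
#' @param a Numeric vector of angles in degrees. Must be finite.
#' @return Numeric vector of the same length, each value in `[0, 360)` and
#'   congruent to the input modulo 360.
#' @examples
#' wrap_angle(360) # 0
#' wrap_angle(-90) # 270
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) {
    abort("`a` must be a finite numeric vector of angles in degrees.")
  }
  ((a %% 360) + 360) %% 360
}

#' Wrapped angular difference in [-180, 180)
#'
#' Computes `a - b` wrapped to the half-open interval \eqn{[-180, 180)},
#' the signed shortest rotation from `b` to `a`.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled to a common
#'   length). `b` defaults to 0, so `wrap_diff(a)` wraps a single angle.
#' @return Numeric vector of wrapped differences in degrees.
#' @examples
#' wrap_diff(350, 10) # -20
#' wrap_diff(180) # -180
#' @export
wrap_diff <- function(a, b = 0) {
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("`a` and `b` must be finite numeric vectors of angles in degrees.")
  }
  (((a - b + 180) %% 360) + 360) %% 360 - 180
}

#' Signed angle from one direction to another
#'
#' Returns the signed angle by which the unit vector at `u_dir` must rotate
#' (counter-clockwise positive) to reach the unit vector at `v_dir`, computed
#' as `atan2(u_perp . v, u . v)` where `u_perp` is the counter-clockwise
#' orthogonal of `u`.
#'
#' @param u_dir,v_dir Numeric vectors of angles in degrees (recycled).
#' @return Signed angles in degrees, in the range \eqn{(-180, 180]}.
#' @examples
#' signed_angle(0, 90) # +90
#' signed_angle(0, 270) # -90
#' @export
signed_angle <- function(u_dir, v_dir) {
  if (any(!is.finite(u_dir)) || any(!is.finite(v_dir))) {
    abort("`u_dir` and `v_dir` must be finite numeric angles in degrees.")
  }
  ur <- deg2rad(u_dir)
  vr <- deg2rad(v_dir)
  u <- cos(ur) * cos(vr) + sin(ur) * sin(vr)
  # u_perp = (-sin(u), cos(u)): counter-clockwise orthogonal
  v <- -sin(ur) * cos(vr) + cos(ur) * sin(vr)
  rad2deg(atan2(v, u))
}

#' Root-mean-square angular error between two angle traces
#'
#' Element-wise differences are wrapped to \eqn{[-180, 180)} before squaring,
#' so a constant 180-degree offset yields exactly 180.
#'
#' @param trace_a,trace_b Numeric vectors of angles in degrees, equal length,
#'   length at least 1.
#' @return A single non-negative number (degrees).
#' @examples
#' angular_rmse(c(0, 10), c(0, 10)) # 0
#' angular_rmse(c(0, 90), c(180, 270)) # 180
#' @export
angular_rmse <- function(trace_a, trace_b) {
  if (length(trace_a) != length(trace_b)) {
    abort("`trace_a` and `trace_b` must have equal length.")
  }
  if (length(trace_a) < 1) {
    abort("traces must contain at least one sample.")
  }
  sqrt(mean(wrap_diff(trace_a, trace_b)^2))
}

#' Decode an angle from population activity (population vector average)
#'
#' Decodes the represented angle as the complex argument of the rate-weighted
#' sum of preferred-direction unit vectors.
#'
#' @param rates Non-negative firing rates, one per neuron; at least one must
#'   be positive.
#' @param dirs Preferred directions in degrees, same length as `rates`.
#' @return Decoded angle in degrees, wrapped to `[0, 360)`.
#' @examples
#' pva_decode(c(1, 1, 0), c(0, 120, 240)) # 60
#' @export
pva_decode <- function(rates, dirs) {
  if (length(rates) != length(dirs)) {
    abort("`rates` and `dirs` must have equal length.")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("`rates` must be finite and non-negative.")
  }
  if (!any(rates > 0)) {
    abort("all rates are zero: decoded direction is undefined.")
  }
  z <- sum(rates * unit_complex(wrap_angle(dirs)))
  if (Mod(z) < 1e-12 * sum(rates)) {
    abort("population vector resultant has zero norm: direction undefined.")
  }
  wrap_angle(rad2deg(Arg(z)))
}

#' Test whether a set of directions forms a positive basis
#'
#' A set of unit vectors forms a positive basis of the plane when the origin
#' lies strictly inside their convex hull; equivalently, when every inner
#' angle between circularly adjacent vectors is strictly less than 180
#' degrees (the inner angles always sum to 360 for distinct directions).
#'
#' @param dirs Numeric vector of at least 2 directions in degrees.
#' @param tol Numeric tolerance used to collapse duplicate directions.
#' @return An object of class `positive_basis_report`: a list with elements
#'   `is_positive_basis`, `adjacent_gaps` (inner angles between sorted
#'   distinct directions, degrees), `max_gap`, `gap_sum`, `directions`
#'   (distinct, sorted), `multiplicity` (count of inputs collapsed into each
#'   distinct direction), and `degenerate` (`TRUE` when all inputs are
#'   identical).  A gap of exactly 180 degrees is classified as *not* a
#'   positive basis (the strict inequality governs).
#' @examples
#' is_positive_basis(c(0, 120, 240))$is_positive_basis # TRUE
#' is_positive_basis(c(0, 60, 120))$is_positive_basis # FALSE
#' @export
is_positive_basis <- function(dirs, tol = 1e-9) {
  if (length(dirs) < 2) {
    abort("need at least 2 directions to assess a positive basis.")
  }
  w <- wrap_angle(dirs)
  s <- sort(w)
  # collapse duplicates (within tolerance, including the 0/360 seam)
  keep <- c(TRUE, diff(s) > tol)
  if (sum(keep) > 1 && (360 - (s[length(s)] - s[1])) <= tol) {
    # last value duplicates the first across the wrap seam
    keep[length(keep)] <- keep[length(keep)] & FALSE
  }
  uniq <- s[keep]
  multiplicity <- vapply(
    uniq,
    function(u) sum(abs(wrap_diff(w, u)) <= tol),
    integer(1) + 0
  )
  degenerate <- length(uniq) < 2
  if (degenerate) {
    gaps <- 360
    names(gaps) <- as.character(round(uniq[1], 6))
  } else {
    gaps <- c(diff(uniq), 360 - (uniq[length(uniq)] - uniq[1]))
    names(gaps) <- as.character(round(uniq, 6))
  }
  report <- list(
    is_positive_basis = !degenerate && length(uniq) >= 3 && max(gaps) < 180,
    adjacent_gaps = gaps,
    max_gap = max(gaps),
    gap_sum = sum(gaps),
    directions = uniq,
    multiplicity = multiplicity,
    degenerate = degenerate
  )
  class(report) <- "positive_basis_report"
  report
}

#' @export
print.positive_basis_report <- function(x, ...) {
  cat(
    "Positive-basis report:",
    if (x$is_positive_basis) "positive basis" else "NOT a positive basis",
    "\n"
  )
  cat(
    "  distinct directions:",
    paste(round(x$directions, 3), collapse = ", "),
    "\n"
  )
  cat(
    "  adjacent gaps:", paste(round(x$adjacent_gaps, 3), collapse = ", "),
    " (max", round(x$max_gap, 3), ", sum", round(x$gap_sum, 6), ")\n"
  )
  if (x$degenerate) cat("  degenerate: all directions identical\n")
  invisible(x)
}

#' @describeIn is_positive_basis Tidy the report into a tibble with one row
#'   per distinct direction and its gap to the next direction.
#' @param x A `positive_basis_report`.
#' @param ... Unused.
#' @method tidy positive_basis_report
#' @export
tidy.positive_basis_report <- function(x, ...) {
  tibble(
    direction_deg = x$directions,
    multiplicity = x$multiplicity,
    gap_to_next_deg = as.numeric(x$adjacent_gaps)
  )
}
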