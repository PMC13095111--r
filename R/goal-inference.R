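# Internal: complex steering-direction vectors (one per steering neuron) as
# weighted sums of compass unit vectors, normalised to unit length.
steering_direction_complex <- function(w, compass_pfds, side) {
  z <- as.numeric(w %*% Re(unit_complex(compass_pfds))) +
    1i * as.numeric(w %*% Im(unit_complex(compass_pfds)))
  bad <- which(Mod(z) < 1e-9)
  if (length(bad) > 0) {
    abort(paste0(
      "degenerate steering direction: ", side, " steering neuron(s) ",
      paste(bad, collapse = ", "),
      " have zero-norm compass-weighted direction sums."
    ))
  }
  z / Mod(z)
}

#' Steering-neuron associated directions
#'
#' Each steering neuron inherits a direction equal to the weighted complex
#' sum of the preferred directions of the compass neurons it samples,
#' normalised to unit length.  A zero-norm sum is an error (the neuron has no
#' defined direction).
#'
#' @param spec A [circuit_spec()].
#' @return A tibble with one row per steering neuron: `side` ("L"/"R"),
#'   `neuron` (index within side), `direction_deg`.
#' @examples
#' steering_directions(build_uniform(3))
#' @export
steering_directions <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  zl <- steering_direction_complex(spec$w_cs_l, spec$compass_pfds, "left")
  zr <- steering_direction_complex(spec$w_cs_r, spec$compass_pfds, "right")
  tibble(
    side = c(rep("L", length(zl)), rep("R", length(zr))),
    neuron = c(seq_along(zl), seq_along(zr)),
    direction_deg = wrap_angle(rad2deg(Arg(c(zl, zr))))
  )
}

# Internal inference core shared by infer_goal_directions() and the fitting
# objective.  Returns NULL when a combined direction is degenerate (instead
# of erroring) so the optimiser can penalise such parameter vectors.
infer_eta_core <- function(compass_pfds, w_cs_l, w_cs_r, w_gs_l, w_gs_r,
                           balance) {
  c_ <- unit_complex(compass_pfds)
  zl <- w_cs_l %*% c_
  zr <- w_cs_r %*% c_
  if (any(Mod(zl) < 1e-9) || any(Mod(zr) < 1e-9)) {
    return(NULL)
  }
  zl <- zl / Mod(zl)
  zr <- zr / Mod(zr)
  gl <- t(w_gs_l) %*% zl
  gr <- t(w_gs_r) %*% zr
  if (any(Mod(gl) < 1e-9) || any(Mod(gr) < 1e-9)) {
    return(NULL)
  }
  gl <- as.complex(gl / Mod(gl))
  gr <- as.complex(gr / Mod(gr))
  u <- Re(gl) * Re(gr) + Im(gl) * Im(gr)
  # counter-clockwise orthogonal of gl is i*gl = (-Im(gl), Re(gl))
  v <- Re(gl) * Im(gr) - Im(gl) * Re(gr)
  ang <- rad2deg(atan2(v, u))
  gl_deg <- rad2deg(Arg(gl))
  eta <- ifelse(
    ang > 0,
    gl_deg + balance * ang,
    gl_deg - (180 - (1 - balance) * ang)
  )
  list(
    gl_deg = wrap_angle(gl_deg),
    gr_deg = wrap_angle(rad2deg(Arg(gr))),
    u = u, v = v,
    signed_angle_deg = ang,
    eta_deg = wrap_angle(eta)
  )
}

#' Infer goal-neuron associated directions from wiring
#'
#' For each goal neuron, the combined left (right) component is the weighted
#' complex sum, over the left (right) steering neurons it innervates, of
#' those neurons' associated directions, normalised to unit length.  The
#' inferred direction is then a weighted directed midpoint of the two
#' components: with the signed angle `ang` from the left to the right
#' component (counter-clockwise orthogonal convention), the direction is
#' `arg(gL) + balance * ang` when `ang > 0` and otherwise `arg(gL) - (180 -
#' (1 - balance) * ang)` (the outer-angle midpoint, respecting the turn
#' directionality of the two steering sets).  The boundary case `ang == 0`
#' falls in the second branch, giving the antipode for exactly aligned
#' components.
#'
#' Every goal neuron must innervate at least one left and one right steering
#' neuron, and no combined component may have zero norm.
#'
#' @param spec A [circuit_spec()].
#' @return A tibble of class `goal_inference` with one row per goal neuron:
#'   `goal_neuron`, `gl_deg`, `gr_deg` (component directions), `u`, `v`
#'   (projections of the right component on the left component and its
#'   counter-clockwise orthogonal), `signed_angle_deg` in `(-180, 180]`, and
#'   `eta_deg` (the inferred direction).
#' @examples
#' infer_goal_directions(build_uniform(3))$eta_deg # 60, 180, 300
#' @export
infer_goal_directions <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  no_l <- which(colSums(spec$w_gs_l) <= 0)
  no_r <- which(colSums(spec$w_gs_r) <= 0)
  if (length(no_l) > 0 || length(no_r) > 0) {
    abort(paste0(
      "goal neuron(s) ", paste(union(no_l, no_r), collapse = ", "),
      " do not innervate both a left and a right steering neuron; ",
      "their associated direction is undefined."
    ))
  }
  res <- infer_eta_core(
    spec$compass_pfds, spec$w_cs_l, spec$w_cs_r,
    spec$w_gs_l, spec$w_gs_r, spec$balance
  )
  if (is.null(res)) {
    # re-run the steering-direction path for a precise error message
    steering_directions(spec)
    abort("degenerate combined goal-component direction (zero norm).")
  }
  out <- tibble(
    goal_neuron = seq_along(res$eta_deg),
    gl_deg = res$gl_deg,
    gr_deg = res$gr_deg,
    u = res$u,
    v = res$v,
    signed_angle_deg = res$signed_angle_deg,
    eta_deg = res$eta_deg
  )
  class(out) <- c("goal_inference", class(out))
  attr(out, "balance") <- spec$balance
  out
}

#' Set a circuit's goal directions from its wiring
#'
#' Convenience wrapper: runs [infer_goal_directions()] and returns the spec
#' with `goal_dirs` replaced by the inferred directions (source flagged
#' `"inferred"`).
#'
#' @param spec A [circuit_spec()].
#' @return The updated spec.
#' @export
set_inferred_goal_dirs <- function(spec) {
  gi <- infer_goal_directions(spec)
  spec$goal_dirs <- gi$eta_deg
  spec$goal_dirs_source <- "inferred"
  spec
}
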