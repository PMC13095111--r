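# Internal: steering-command matrix over heading x goal grids (headings in
# rows, goals in columns).  `rc` optionally supplies a precomputed compass
# rate matrix (n_heading x n_compass) so optimisation loops can reuse it.
surface_command_matrix <- function(spec, headings, goals, rc = NULL) {
  n_h <- length(headings)
  n_g <- length(goals)
  if (spec$flavor == "fly-softplus") {
    fly <- spec$fly
    sp <- function(x) {
      fly_softplus(
        x, fly$softplus_scale, fly$softplus_slope, fly$softplus_shift
      )
    }
    side_sum <- function(pfl3) {
      total <- matrix(0, n_h, n_g)
      for (j in 1:12) {
        hj <- cos(deg2rad(headings - pfl3[j]))
        gj <- fly$goal_input_weight * cos(deg2rad(goals - fly$fc2_dirs[j]))
        total <- total + sp(outer(hj, gj, "+"))
      }
      total
    }
    sum_l <- side_sum(fly$pfl3_left_dirs)
    sum_r <- side_sum(fly$pfl3_right_dirs)
  } else {
    act <- spec$activation
    if (is.null(spec$goal_dirs)) {
      abort("`spec$goal_dirs` is unset; infer directions first.")
    }
    if (is.null(rc)) {
      rc <- sigmoid_rate(
        cos(deg2rad(outer(headings, spec$compass_pfds, "-"))),
        act$slope, act$bias
      )
    }
    rg <- sigmoid_rate(
      cos(deg2rad(outer(goals, spec$goal_dirs, "-"))),
      act$slope, act$bias
    )
    side_sum <- function(w_cs, w_gs) {
      a <- rc %*% t(w_cs) # n_h x n_steer
      b <- rg %*% t(w_gs) # n_g x n_steer
      total <- matrix(0, n_h, n_g)
      for (s in seq_len(ncol(a))) {
        total <- total +
          sigmoid_rate(outer(a[, s], b[, s], "+"), act$slope, act$bias)
      }
      total
    }
    sum_l <- side_sum(spec$w_cs_l, spec$w_gs_l)
    sum_r <- side_sum(spec$w_cs_r, spec$w_gs_r)
  }
  spec$k * ((1 - spec$balance) * sum_l - spec$balance * sum_r)
}

#' Steering surface over a heading x goal grid
#'
#' Evaluates the steering command at every combination of `grid_n` headings
#' and `grid_n` goals linearly sampled over `[0, 360)`.
#'
#' @param spec A [circuit_spec()].
#' @param grid_n Grid resolution per axis (at least 8; default 72, i.e.
#'   5-degree steps).
#' @return A tibble of class `steering_surface` with columns `heading_deg`,
#'   `goal_deg`, `command` (heading varies fastest), and attributes
#'   `headings`, `goals`, `grid_n`.
#' @examples
#' s <- steering_surface(build_uniform(3), grid_n = 24)
#' @export
steering_surface <- function(spec, grid_n = 72) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (!is.numeric(grid_n) || grid_n < 8) {
    abort("`grid_n` must be at least 8.")
  }
  grid_n <- as.integer(grid_n)
  ang <- seq(0, 360, length.out = grid_n + 1)[seq_len(grid_n)]
  m <- surface_command_matrix(spec, ang, ang)
  if (any(!is.finite(m))) {
    abort("steering surface contains non-finite commands.")
  }
  out <- tibble(
    heading_deg = rep(ang, times = grid_n),
    goal_deg = rep(ang, each = grid_n),
    command = as.vector(m)
  )
  class(out) <- c("steering_surface", class(out))
  attr(out, "headings") <- ang
  attr(out, "goals") <- ang
  attr(out, "grid_n") <- grid_n
  attr(out, "builder") <- spec$builder
  out
}

#' Root-mean-square difference between two steering surfaces
#'
#' Plain (not angular) RMSE over all grid cells; commands are rates, not
#' angles.  The two surfaces must share the same grid.
#'
#' @param a,b Two [steering_surface()] objects on identical grids.
#' @return A single non-negative number.
#' @export
surface_rmse <- function(a, b) {
  stopifnot(inherits(a, "steering_surface"), inherits(b, "steering_surface"))
  ha <- attr(a, "headings")
  hb <- attr(b, "headings")
  if (length(ha) != length(hb) || max(abs(ha - hb)) > 1e-9 ||
    max(abs(attr(a, "goals") - attr(b, "goals"))) > 1e-9) {
    abort("surfaces are on different grids.")
  }
  sqrt(mean((a$command - b$command)^2))
}

#' Rotational-invariance score of a steering surface
#'
#' A steering circuit is rotationally invariant when its command depends only
#' on the wrapped difference between heading and goal, i.e. the surface is
#' constant along diagonals.  The score is the mean over diagonals of the
#' per-diagonal variance of the command; 0 means perfectly invariant.
#'
#' @param s A [steering_surface()] on a square grid.
#' @return A single non-negative number.
#' @export
rotational_invariance_score <- function(s) {
  stopifnot(inherits(s, "steering_surface"))
  n <- attr(s, "grid_n")
  m <- matrix(s$command, n, n)
  diag_id <- (row(m) - col(m)) %% n
  vals <- tapply(as.vector(m), as.vector(diag_id), var)
  mean(vals)
}

#' @describeIn steering_surface Heatmap of the steering surface.
#' @param object A `steering_surface`.
#' @param ... Unused.
#' @method autoplot steering_surface
#' @export
autoplot.steering_surface <- function(object, ...) {
  ggplot(object, aes(.data$heading_deg, .data$goal_deg, fill = .data$command)) +
    geom_raster() +
    scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac", midpoint = 0
    ) +
    coord_equal() +
    labs(
      x = "heading (deg)", y = "goal (deg)", fill = "command\n(deg/s)",
      title = paste0("Steering surface (", attr(object, "builder"), ")")
    ) +
    theme_minimal()
}

#' @describeIn steering_surface Print the heatmap.
#' @param s A `steering_surface`.
#' @export
plot_surface <- function(s, ...) print(autoplot(s, ...))
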