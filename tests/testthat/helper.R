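# Independent convex-hull oracle for the positive-basis test: a set of unit
# vectors is a positive basis of the plane iff the origin lies strictly
# inside their convex hull.
hull_contains_origin <- function(dirs_deg) {
  r <- pi * dirs_deg / 180
  p <- cbind(cos(r), sin(r))
  idx <- grDevices::chull(p)
  poly <- p[idx, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) {
    return(FALSE)
  }
  s <- vapply(seq_len(n), function(i) {
    a <- poly[i, ]
    b <- poly[(i %% n) + 1, ]
    (b[1] - a[1]) * (0 - a[2]) - (b[2] - a[2]) * (0 - a[1])
  }, numeric(1))
  all(s > 1e-12) || all(s < -1e-12)
}

# The differential-evolution fit used by the acceptance tests is computed
# once and shared (seed fixed at 42 before any acceptance run).
acceptance_cache <- new.env(parent = emptyenv())

acceptance_fit <- function() {
  if (is.null(acceptance_cache$fit)) {
    acceptance_cache$fit <- suppressWarnings(
      fit_unintuitive(config = fit_config(seed = 42))
    )
  }
  acceptance_cache$fit
}

# Tuned circuits are likewise cached across acceptance blocks.
tuned <- function(name, builder) {
  if (is.null(acceptance_cache[[name]])) {
    acceptance_cache[[name]] <- tune_gain(builder)
  }
  acceptance_cache[[name]]
}
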