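#' Check a circuit against the prescriptive steering rules
#'
#' Evaluates the five construction rules:
#' \describe{
#'   \item{Rule 1 (prescriptive)}{Compass preferred directions must form a
#'     positive basis.}
#'   \item{Rule 2 (descriptive)}{Each steering neuron's direction is the
#'     weighted sum of the compass directions it samples (reported, never
#'     pass/fail).}
#'   \item{Rule 3 (descriptive)}{Each goal neuron's innervation of left and
#'     right steering neurons defines its functional steering pair(s)
#'     (reported, never pass/fail).}
#'   \item{Rule 4 (prescriptive)}{Declared goal directions must agree with
#'     the wiring-implied (inferred) directions, within `rule4_tol`.}
#'   \item{Rule 5 (prescriptive)}{Inferred goal directions must form a
#'     positive basis.}
#' }
#'
#' @param spec A [circuit_spec()].
#' @param rule4_tol Tolerance (degrees) for the declared-vs-inferred
#'   comparison.  Default 20: wide enough to absorb label/wiring offsets in
#'   anatomically labelled circuits (the fly circuit's FC2 labels sit up to
#'   15 degrees from the wiring-implied directions because duplicated
#'   steering tunings serve neighbouring goal neurons) while far below the
#'   180-degree displacement of the rule-4-breaking circuit.
#' @return An object of class `rule_check_report`: a list with
#'   `rule1`/`rule5` ([is_positive_basis()] reports on compass and inferred
#'   goal directions), `rule2_directions` (tibble from
#'   [steering_directions()]), `rule3_pairs` (tibble mapping each goal neuron
#'   to its left and right steering sets), `rule4_consistency` (tibble of
#'   declared vs inferred directions and wrapped differences), `passes`
#'   (named logical for rules 1, 4, 5), and `rule4_tol`.
#' @examples
#' rule_check(build_uniform(3))$passes # all TRUE
#' @export
rule_check <- function(spec, rule4_tol = 20) {
  stopifnot(inherits(spec, "circuit_spec"))
  rule1 <- is_positive_basis(spec$compass_pfds)
  dirs <- steering_directions(spec)
  gi <- infer_goal_directions(spec)
  rule5 <- is_positive_basis(gi$eta_deg)

  rule3 <- tibble(
    goal_neuron = seq_len(n_goal(spec)),
    left_neurons = map(
      seq_len(n_goal(spec)),
      function(j) which(spec$w_gs_l[, j] > 0)
    ),
    right_neurons = map(
      seq_len(n_goal(spec)),
      function(j) which(spec$w_gs_r[, j] > 0)
    )
  )

  declared <- spec$goal_dirs %||% gi$eta_deg
  rule4 <- tibble(
    goal_neuron = gi$goal_neuron,
    declared_deg = declared,
    inferred_deg = gi$eta_deg,
    abs_diff_deg = abs(wrap_diff(declared, gi$eta_deg))
  )

  report <- list(
    rule1 = rule1,
    rule2_directions = dirs,
    rule3_pairs = rule3,
    rule4_consistency = rule4,
    rule5 = rule5,
    inference = gi,
    passes = c(
      rule1 = rule1$is_positive_basis,
      rule4 = all(rule4$abs_diff_deg <= rule4_tol),
      rule5 = rule5$is_positive_basis
    ),
    rule4_tol = rule4_tol,
    builder = spec$builder
  )
  class(report) <- "rule_check_report"
  report
}

#' @export
print.rule_check_report <- function(x, ...) {
  cat("Rule-check report (circuit:", x$builder, ")\n")
  status <- function(p) if (p) "PASS" else "FAIL"
  cat(
    "  rule 1 (compass positive basis):     ", status(x$passes["rule1"]),
    " (max gap ", round(x$rule1$max_gap, 2), " deg)\n",
    sep = ""
  )
  cat(
    "  rule 2 (steering directions):        described, ",
    nrow(x$rule2_directions), " steering neurons\n",
    sep = ""
  )
  cat(
    "  rule 3 (goal-steering innervation):  described, ",
    nrow(x$rule3_pairs), " goal neurons\n",
    sep = ""
  )
  cat(
    "  rule 4 (declared vs inferred dirs):  ", status(x$passes["rule4"]),
    " (max |diff| ", round(max(x$rule4_consistency$abs_diff_deg), 2),
    " deg, tol ", x$rule4_tol, ")\n",
    sep = ""
  )
  cat(
    "  rule 5 (goal-dir positive basis):    ", status(x$passes["rule5"]),
    " (max gap ", round(x$rule5$max_gap, 2), " deg)\n",
    sep = ""
  )
  cat(
    "  inferred goal directions:",
    paste(round(x$inference$eta_deg, 2), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @describeIn rule_check Tidy the report: one row per rule with
#'   pass/fail status (`NA` for the descriptive rules 2 and 3) and a short
#'   detail string.
#' @param x A `rule_check_report`.
#' @param ... Unused.
#' @method tidy rule_check_report
#' @export
tidy.rule_check_report <- function(x, ...) {
  tibble(
    rule = paste0("rule", 1:5),
    prescriptive = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    pass = c(
      x$passes[["rule1"]], NA, NA,
      x$passes[["rule4"]], x$passes[["rule5"]]
    ),
    detail = c(
      paste0("compass max gap ", round(x$rule1$max_gap, 3), " deg"),
      paste0(nrow(x$rule2_directions), " steering-neuron directions"),
      paste0(nrow(x$rule3_pairs), " goal-neuron innervation sets"),
      paste0(
        "max declared-inferred |diff| ",
        round(max(x$rule4_consistency$abs_diff_deg), 3),
        " deg (tol ", x$rule4_tol, ")"
      ),
      paste0("goal-dir max gap ", round(x$rule5$max_gap, 3), " deg")
    )
  )
}

#' @describeIn rule_check One-row summary of the prescriptive rules.
#' @method glance rule_check_report
#' @export
glance.rule_check_report <- function(x, ...) {
  tibble(
    rule1_pass = x$passes[["rule1"]],
    rule4_pass = x$passes[["rule4"]],
    rule5_pass = x$passes[["rule5"]],
    all_pass = all(x$passes),
    compass_max_gap_deg = x$rule1$max_gap,
    goal_dir_max_gap_deg = x$rule5$max_gap,
    rule4_max_diff_deg = max(x$rule4_consistency$abs_diff_deg)
  )
}
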