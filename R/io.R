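spec_schema_version <- 1L

#' Write a circuit specification to JSON
#'
#' Serialises a [circuit_spec()] to a human-diffable JSON file (schema
#' version 1): angle lists in degrees, dense row-major weight matrices (row =
#' postsynaptic steering neuron) including explicit sparsity zeros, scalar
#' parameters, and a provenance block with the builder name and parameters.
#' The write/read round trip reproduces the spec.
#'
#' @param spec A [circuit_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_spec()]
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "circuit_spec"))
  payload <- list(
    schema_version = spec_schema_version,
    flavor = spec$flavor,
    compass_pfds = spec$compass_pfds,
    goal_dirs = spec$goal_dirs,
    goal_dirs_source = spec$goal_dirs_source,
    weights = list(
      compass_to_left = spec$w_cs_l,
      compass_to_right = spec$w_cs_r,
      goal_to_left = spec$w_gs_l,
      goal_to_right = spec$w_gs_r
    ),
    gain_k = spec$k,
    balance = spec$balance,
    activation = spec$activation,
    fly = spec$fly,
    provenance = list(
      builder = spec$builder,
      builder_params = spec$builder_params
    )
  )
  write_json(
    payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

as_weight_matrix <- function(x, name) {
  if (is.null(x)) {
    abort(paste0("weights$", name, ": missing weight matrix."))
  }
  m <- if (is.matrix(x)) x else matrix(unlist(x), nrow = length(x), byrow = TRUE)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    abort(paste0("weights$", name, ": non-finite entries."))
  }
  if (any(m < 0)) {
    abort(paste0(
      "weights$", name, ": negative weight found; ",
      "connections must be excitatory (weights >= 0)."
    ))
  }
  m
}

#' Read a circuit specification from JSON
#'
#' Validates and deserialises a file written by [write_spec()].  Unknown
#' schema versions are rejected; negative weights are rejected (connections
#' are excitatory); a file without `goal_dirs` has its directions recomputed
#' from the wiring and flagged `"inferred"`.
#'
#' @param path Path to a circuit-spec JSON file.
#' @return A [circuit_spec()].
#' @export
read_spec <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("circuit-spec file not found: ", path))
  }
  raw <- read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version)) {
    abort("schema_version: missing.")
  }
  if (raw$schema_version != spec_schema_version) {
    abort(paste0(
      "schema_version: unknown version ", raw$schema_version,
      " (this package reads version ", spec_schema_version, ")."
    ))
  }
  if (is.null(raw$flavor) ||
    !raw$flavor %in% c("sigmoid-rate", "fly-softplus")) {
    abort("flavor: must be 'sigmoid-rate' or 'fly-softplus'.")
  }
  if (is.null(raw$compass_pfds)) {
    abort("compass_pfds: missing.")
  }
  fly <- NULL
  if (!is.null(raw$fly) && length(raw$fly) > 0) {
    fly <- as.list(raw$fly)
  }
  goal_dirs <- raw$goal_dirs
  source <- raw$goal_dirs_source %||% "inferred"
  spec <- circuit_spec(
    compass_pfds = as.numeric(raw$compass_pfds),
    w_cs_l = as_weight_matrix(raw$weights$compass_to_left, "compass_to_left"),
    w_cs_r = as_weight_matrix(raw$weights$compass_to_right, "compass_to_right"),
    w_gs_l = as_weight_matrix(raw$weights$goal_to_left, "goal_to_left"),
    w_gs_r = as_weight_matrix(raw$weights$goal_to_right, "goal_to_right"),
    k = raw$gain_k %||% 1,
    balance = raw$balance %||% 0.5,
    activation = as.list(raw$activation %||% list(slope = 2, bias = 0.6)),
    goal_dirs = if (is.null(goal_dirs)) NULL else as.numeric(goal_dirs),
    goal_dirs_source = source,
    flavor = raw$flavor,
    fly = fly,
    builder = raw$provenance$builder %||% "file",
    builder_params = as.list(raw$provenance$builder_params %||% list())
  )
  if (is.null(spec$goal_dirs)) {
    spec <- set_inferred_goal_dirs(spec)
  }
  spec
}
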