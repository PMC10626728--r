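#' Write a two-arm model configuration to JSON
#'
#' Serializes both arms, the shared cohort/settings and the sensitivity
#' ranges to a single JSON document with sections `model` (settings +
#' cohort), `arms` (`ch`, `dt`) and `ranges`. Numbers are written at full
#' precision so that [read_model_config()] round-trips every numeric field
#' bit-exactly.
#'
#' @param model list with elements `ch`, `dt` (each an `hf_model`) and
#'   `ranges` (data frame), as returned by [hf_paper_model()] or
#'   [random_model_instance()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  arm_block <- function(m) list(
    arm = m$arm,
    transition = unname(unclass(m$transition)),
    hosp = list(monthly_prob = m$hosp$monthly_prob,
                risk_ratio = m$hosp$risk_ratio),
    costs = m$costs[c("direct_medical_per_admission",
                      "direct_nonmedical_annual", "indirect_annual",
                      "dtx_annual")],
    utilities = list(mean = m$utilities$mean,
                     variance = m$utilities$variance))
  s <- model$ch$settings
  doc <- list(
    model = list(settings = unclass(s),
                 cohort = list(initial_counts =
                                 unname(model$ch$cohort$initial_counts))),
    arms = list(ch = arm_block(model$ch), dt = arm_block(model$dt)),
    ranges = model$ranges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a two-arm model configuration from JSON
#'
#' Parses a document written by [write_model_config()] (or hand-authored to
#' the same schema), rebuilds both `hf_model` arms and the ranges table, and
#' surfaces content violations (negative costs, out-of-range probabilities
#' or utilities) as errors. Transition rows that do not sum exactly to one
#' are accepted — printed matrices carry rounding defects that the engine
#' repairs at evaluation time.
#'
#' @param path path to the JSON document.
#' @return List with elements `ch`, `dt`, `ranges`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (sec in c("model", "arms"))
    if (is.null(doc[[sec]]))
      stop(sprintf("config error: missing section '%s'", sec))
  for (arm in c("ch", "dt"))
    if (is.null(doc$arms[[arm]]))
      stop(sprintf("config error: missing arm '%s'", arm))

  ss <- doc$model$settings
  settings <- economic_settings(
    annual_discount_rate = ss$annual_discount_rate, cycles = ss$cycles,
    cycles_per_year = ss$cycles_per_year, horizon_years = ss$horizon_years,
    wtp = ss$wtp, annualization = ss$annualization,
    half_cycle = isTRUE(ss$half_cycle))
  init <- doc$model$cohort$initial_counts
  if (length(init) != 5L)
    stop("config error: model.cohort.initial_counts must have 5 entries")
  cohort <- cohort_spec(init)

  build_arm <- function(b, name) {
    for (f in c("transition", "hosp", "costs", "utilities"))
      if (is.null(b[[f]]))
        stop(sprintf("config error: arms.%s missing field '%s'", name, f))
    tm <- as.matrix(b$transition)
    if (!identical(dim(tm), c(5L, 5L)))
      stop(sprintf("config error: arms.%s.transition must be 5x5 (a state row is missing or malformed)", name))
    model_instance(
      arm = if (is.null(b$arm)) toupper(name) else b$arm,
      transition = transition_matrix(tm),
      hosp = hosp_profile(b$hosp$monthly_prob, b$hosp$risk_ratio),
      costs = cost_profile(b$costs$direct_medical_per_admission,
                           b$costs$direct_nonmedical_annual,
                           b$costs$indirect_annual, b$costs$dtx_annual),
      utilities = utility_profile(b$utilities$mean, b$utilities$variance),
      cohort = cohort, settings = settings)
  }
  ch <- build_arm(doc$arms$ch, "ch")
  dt <- build_arm(doc$arms$dt, "dt")

  for (m in list(ch, dt)) {
    rep <- validate_model(m, row_sum_tolerance = Inf)
    if (!is_valid(rep))
      stop(sprintf("config validation error (arm %s): %s", m$arm,
                   paste(rep$message, collapse = "; ")))
  }

  ranges <- if (!is.null(doc$ranges)) as.data.frame(doc$ranges) else NULL
  list(ch = ch, dt = dt, ranges = ranges)
}
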