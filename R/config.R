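#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline receives a seed derived
#' deterministically from the global seed and the stage name, so one global
#' seed reproduces the full run while stages stay independent.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name (character).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * (31 ^ (seq_along(utf8ToInt(stage)) %% 7)))
  as.integer((as.numeric(global_seed) * 2654435761 + h) %% (2^31 - 1))
}

#' Serialize / restore a fertility model
#'
#' Round-trips a [fertility_model()] through YAML or JSON (keys:
#' \code{base}, \code{decay}, \code{rounding}, \code{max_clutch}).
#'
#' @param model A [fertility_model()].
#' @param path File path; the extension (\code{.yaml}/\code{.yml} or
#'   \code{.json}) picks the format.
#' @return \code{read_fertility_model}: the restored model.
#' @export
write_fertility_model <- function(model, path) {
  stopifnot(inherits(model, "fertility_model"))
  x <- unclass(model)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_fertility_model
#' @export
read_fertility_model <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("base", "decay", "rounding", "max_clutch")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("fertility model config missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  fertility_model(base = x$base, decay = x$decay, rounding = x$rounding,
                  max_clutch = x$max_clutch)
}

#' Write a scenario-comparison summary as JSON
#'
#' @param comparison Result of [compare_scenarios()].
#' @param path Output path.
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(
    list(groups = comparison$groups,
         percent_diff = comparison$percent_diff),
    path, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  invisible(path)
}

#' Run manifest for a simulated dataset
#'
#' Records seeds, parameter echo and package version next to a generated
#' CSV, for provenance.
#'
#' @param spec A [scenario_spec()].
#' @param params A [generator_params()].
#' @param seed The seed used.
#' @param path Output JSON path.
#' @export
write_manifest <- function(spec, params, seed, path) {
  pf <- params$p_parasitize
  manifest <- list(
    package = "twogenfit",
    version = as.character(utils::packageVersion("twogenfit")),
    scenario = spec$name,
    n_founders = spec$n_founders,
    hosts_offered = spec$hosts_offered,
    seed = seed,
    params = list(
      p_parasitize = pf,
      p_female = params$p_female,
      dish_sd = params$dish_sd,
      egg_budget = params$egg_budget,
      p_host_emerge_parasitized_fict = params$p_host_emerge_parasitized_fict,
      p_host_emerge_control_fict = params$p_host_emerge_control_fict,
      max_clutch = params$max_clutch
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Simulate all built-in study scenarios
#'
#' One call reproducing the full factorial design suite: the three
#' no-choice arms, the choice test, and the fictitious-host experiment
#' arms, each seeded via [derive_seed()] from one global seed.
#'
#' @param params A [generator_params()].
#' @param global_seed Integer global seed.
#' @param scenarios Scenario names (default: all built-ins).
#' @return Named list of host-egg tables.
#' @export
simulate_study <- function(params = generator_params(), global_seed = 1,
                           scenarios = names(builtin_scenarios())) {
  stats::setNames(lapply(scenarios, function(nm) {
    generate_trials(scenario_spec(nm), params,
                    seed = derive_seed(global_seed, nm))
  }), scenarios)
}
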