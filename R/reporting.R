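# End-to-end orchestration: evidence -> PSA -> CEAC/frontier/ICER ->
# EVPI/EVPPI -> population scaling, with CSV outputs and a run manifest.

#' Build a run configuration
#'
#' A fully serializable description of one analysis run; a completed run's
#' config plus master seed reproduces all outputs bit-for-bit.
#'
#' @param evidence_source `"generate"` (synthetic evidence from
#'   `generator_config`) or a path to an evidence JSON file.
#' @param generator_config Settings for [generate_evidence()] when
#'   generating.
#' @param analysis `"ALL_NYHA"` or `"NYHA4"` (the latter starts the cohort
#'   in NYHA class IV and scales the population by `nyha4_fraction`).
#' @param n_psa_draws PSA size.
#' @param lambda_max,lambda_step Willingness-to-pay grid spec, EUR/QALY.
#' @param evppi_groups,evppi_step,evppi_caps EVPPI groups and escalation
#'   budgets (named caps; unnamed groups default to 1,000).
#' @param evppi_lambdas Optional explicit EVPPI threshold grid.
#' @param settings Model settings from [model_settings()].
#' @param population List with `base`, `increment`, `years`, `start_year`,
#'   `discount_rate`, `nyha4_fraction`.
#' @param out_dir Output directory.
#' @param seed Master seed; every random stream is derived from it.
#' @param plots Emit PNG plots (requires ggplot2; default `FALSE`).
#' @return A list of class `hfvoi_config`.
#' @export
run_config <- function(evidence_source = "generate",
                       generator_config = default_generator_config(),
                       analysis = c("ALL_NYHA", "NYHA4"),
                       n_psa_draws = 2500L,
                       lambda_max = 100000, lambda_step = 1000,
                       evppi_groups = HF_GROUPS,
                       evppi_step = 500L,
                       evppi_caps = c(TRANSITIONS = 2500L),
                       evppi_lambdas = NULL,
                       settings = model_settings(),
                       population = list(base = 160000, increment = 5000,
                                         years = 20L, start_year = 2018L,
                                         discount_rate = 0.04,
                                         nyha4_fraction = 0.0732),
                       out_dir = tempfile("hfvoi_run_"),
                       seed = 1L, plots = FALSE) {
  structure(list(
    evidence_source = evidence_source,
    generator_config = generator_config,
    analysis = match.arg(analysis),
    n_psa_draws = as.integer(n_psa_draws),
    lambda_max = lambda_max, lambda_step = lambda_step,
    evppi_groups = evppi_groups, evppi_step = as.integer(evppi_step),
    evppi_caps = evppi_caps, evppi_lambdas = evppi_lambdas,
    settings = settings, population = population,
    out_dir = out_dir, seed = as.integer(seed), plots = isTRUE(plots)
  ), class = "hfvoi_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults. Nested keys `settings` and `population` are merged with their
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `hfvoi_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$generator_config)) {
    args$generator_config <- do.call(default_generator_config,
                                     raw$generator_config)
  }
  if (!is.null(raw$settings)) {
    args$settings <- do.call(model_settings, raw$settings)
  }
  if (!is.null(raw$population)) {
    dflt <- formals(run_config)$population
    args$population <- modifyList(eval(dflt), raw$population)
  }
  if (!is.null(raw$evppi_caps)) args$evppi_caps <- unlist(raw$evppi_caps)
  do.call(run_config, args)
}

write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full decision-analytic pipeline
#'
#' Executes evidence construction, the PSA, acceptability curves, frontier,
#' ICER table, EVPI/EVPPI curves and population scaling for the configured
#' analysis, writing canonical CSV outputs and a manifest with content
#' checksums. The NYHA IV analysis restricts the initial distribution to
#' NYHA class IV and scales the effective population by the configured
#' subgroup fraction.
#'
#' @param config From [run_config()] or [read_run_config()].
#' @return A list of class `hfvoi_bundle`: `files` (named paths),
#'   `manifest`, and the in-memory results (`psa`, `voi`, `population`).
#' @export
run_full_analysis <- function(config = run_config()) {
  if (!inherits(config, "hfvoi_config")) {
    stop("config must be an hfvoi_config (see run_config())", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  evidence <- if (identical(config$evidence_source, "generate")) {
    generate_evidence(config$generator_config, seed = config$seed)
  } else {
    read_evidence(config$evidence_source)
  }
  if (config$analysis == "NYHA4") evidence <- restrict_to_nyha4(evidence)

  lambdas <- wtp_grid(0, config$lambda_max, config$lambda_step)
  voi <- voi_curves(evidence, lambdas = lambdas,
                    evppi_lambdas = config$evppi_lambdas,
                    n_psa = config$n_psa_draws,
                    groups = config$evppi_groups,
                    caps = config$evppi_caps, step = config$evppi_step,
                    seed = config$seed, settings = config$settings)
  psa <- voi$psa

  pp <- config$population
  proj <- incidence_projection(pp$base, pp$increment, pp$years,
                               pp$start_year)
  pop <- effective_population(proj, pp$discount_rate)
  n_eff <- if (config$analysis == "NYHA4") {
    subgroup_population(pop, pp$nyha4_fraction)
  } else {
    pop$effective
  }

  pop_voi <- rbind(
    data.frame(analysis = config$analysis, quantity = "EVPI",
               lambda = voi$evpi$lambda, per_patient = voi$evpi$evpi,
               effective_population = n_eff,
               population_value = population_voi(voi$evpi$evpi, n_eff)),
    data.frame(analysis = config$analysis,
               quantity = paste0("EVPPI:", voi$evppi$group),
               lambda = voi$evppi$lambda, per_patient = voi$evppi$value,
               effective_population = n_eff,
               population_value = population_voi(voi$evppi$value, n_eff))
  )

  files <- c(
    evidence = {
      p <- file.path(config$out_dir, "evidence.json")
      write_evidence(evidence, p)
      p
    },
    psa = write_csv_out(
      data.frame(draw = rep(seq_len(psa$n_draws), times = 3L),
                 arm = rep(HF_ARMS, each = psa$n_draws),
                 cost = as.numeric(psa$costs),
                 qalys = as.numeric(psa$effects)),
      config$out_dir, "psa.csv"),
    ceac = write_csv_out(ceac(psa, lambdas), config$out_dir, "ceac.csv"),
    frontier = write_csv_out(frontier(psa, lambdas), config$out_dir,
                             "frontier.csv"),
    icer = write_csv_out(icer_table(psa), config$out_dir, "icer.csv"),
    evpi = write_csv_out(voi$evpi, config$out_dir, "evpi.csv"),
    evppi = write_csv_out(voi$evppi, config$out_dir, "evppi.csv"),
    population_voi = write_csv_out(pop_voi, config$out_dir,
                                   "population_voi.csv")
  )

  if (config$plots && requireNamespace("ggplot2", quietly = TRUE)) {
    p1 <- file.path(config$out_dir, "ceac.png")
    ggplot2::ggsave(p1, plot_ceac(ceac(psa, lambdas)), width = 7,
                    height = 4.5, dpi = 150)
    p2 <- file.path(config$out_dir, "evpi.png")
    ggplot2::ggsave(p2, plot_evpi(voi$evpi), width = 7, height = 4.5,
                    dpi = 150)
    files <- c(files, ceac_plot = p1, evpi_plot = p2)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hfvoi")),
    analysis = config$analysis, seed = config$seed,
    n_psa_draws = config$n_psa_draws,
    effective_population = n_eff,
    files = lapply(files, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest = manifest_path)

  structure(list(files = files, manifest = manifest, psa = psa, voi = voi,
                 population = pop, effective_population = n_eff,
                 config = config),
            class = "hfvoi_bundle")
}

#' @export
print.hfvoi_bundle <- function(x, ...) {
  cat("<hfvoi_bundle>", x$config$analysis, "analysis,",
      length(x$files), "files in", x$config$out_dir, "\n")
  invisible(x)
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ceac_df From [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(ceac_df,
                  ggplot2::aes(x = .data$lambda, y = .data$probability,
                               colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability most cost-effective", colour = "Arm") +
    ggplot2::theme_minimal()
}

#' Plot a per-patient EVPI curve
#'
#' @param evpi_df Data frame with columns `lambda`, `evpi`.
#' @return A ggplot object.
#' @export
plot_evpi <- function(evpi_df) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(evpi_df, ggplot2::aes(x = .data$lambda, y = .data$evpi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Per-patient EVPI (EUR)") +
    ggplot2::theme_minimal()
}
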