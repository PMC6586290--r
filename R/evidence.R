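# Evidence-base data model, synthetic generator and JSON serialization.
#
# The evidence base is the prior information from which every parameter
# distribution in the probabilistic analysis is constructed: transition
# counts (Dirichlet), utility moments (beta), resource-use and unit-cost
# moments (gamma), uniform fee bounds, and initial NYHA state counts.

#' Default settings for the synthetic evidence generator
#'
#' Returns the full list of generator settings with their defaults. The
#' defaults describe a chronic heart failure cohort whose statistical
#' structure mirrors the telehealth trial inputs the model was originally
#' built from: an initial NYHA distribution of 19/44/29/8 percent, 4-month
#' transition rows with appreciable mortality in the severe classes, mildly
#' protective telehealth arms (relative reduction of transitions to worse
#' states and to death versus usual care), state-dependent utilities and
#' resource use shared across arms, and positive telehealth fees. All
#' monetary values are synthetic EUR magnitudes, not trial estimates.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of generator settings.
#' @details Settings:
#' \describe{
#'   \item{n_trial_phases}{Number of trial phases with distinct transition
#'     matrices (4-month cycles; default 3, i.e. one year of follow-up).}
#'   \item{pseudo_n}{Pseudo-sample size per transition row, phase and arm;
#'     controls Dirichlet uncertainty (default 100).}
#'   \item{base_rows}{4x5 matrix of usual-care transition probabilities from
#'     each living state to the five states.}
#'   \item{effect_nts, effect_htm}{Relative reduction of transition mass to
#'     worse states and death versus usual care (defaults 0.12 and 0.20).}
#'   \item{arm_shared_transitions}{If TRUE one set of transition matrices is
#'     drawn per realization and shared by all arms (requires identical
#'     counts across arms, i.e. zero treatment effects); used for
#'     null-effect symmetry analyses (default FALSE).}
#'   \item{initial_fractions}{Initial NYHA occupancy fractions (sum 1).}
#'   \item{initial_pseudo_n}{Pseudo-sample size behind the initial
#'     distribution counts (default 400).}
#'   \item{utility_mean, utility_sd}{Per-state utility moments; DEAD is
#'     fixed at utility 0.}
#'   \item{utility_distribution}{"beta" (default) or "gamma".}
#'   \item{hosp_er_means, contact_means}{Mean resource counts per 4-month
#'     cycle, per living state (matrices state x type).}
#'   \item{resource_cv, unit_cost_cv}{Coefficients of variation for the
#'     gamma resource-use and unit-cost distributions.}
#'   \item{unit_cost_means}{EUR per resource unit.}
#'   \item{treatment_specific_resource_use}{If TRUE resource-use evidence is
#'     stored per arm (default FALSE: state-dependent only).}
#'   \item{htm_install_fee_bounds, htm_service_fee_bounds}{Uniform bounds,
#'     EUR; install fee recurs at every equipment replacement, service fee
#'     accrues per cycle.}
#'   \item{nts_cost_per_cycle}{Fixed EUR per cycle for nurse telephone
#'     support.}
#'   \item{replacement_interval_years}{Telemonitoring equipment replacement
#'     interval (default 5 years).}
#'   \item{fix_intervention_fees}{If TRUE the fees are held at their
#'     midpoints instead of being sampled.}
#'   \item{row_jitter_sd}{Optional lognormal jitter applied to transition
#'     counts (default 0: generator fully deterministic given the config).}
#' }
#' @export
#' @examples
#' cfg <- default_generator_config(effect_htm = 0.25)
#' cfg$effect_htm
default_generator_config <- function(...) {
  base_rows <- matrix(c(
    # to: NYHA1  NYHA2  NYHA3  NYHA4  DEAD
    0.75, 0.15, 0.05, 0.02, 0.03, # from NYHA1
    0.10, 0.65, 0.15, 0.05, 0.05, # from NYHA2
    0.03, 0.12, 0.60, 0.15, 0.10, # from NYHA3
    0.01, 0.04, 0.15, 0.55, 0.25  # from NYHA4
  ), nrow = 4, byrow = TRUE, dimnames = list(HF_LIVING, HF_STATES))

  cfg <- list(
    n_trial_phases = 3L,
    pseudo_n = 100,
    base_rows = base_rows,
    effect_nts = 0.12,
    effect_htm = 0.20,
    arm_shared_transitions = FALSE,
    initial_fractions = c(NYHA1 = 0.19, NYHA2 = 0.44, NYHA3 = 0.29,
                          NYHA4 = 0.08),
    initial_pseudo_n = 400,
    utility_mean = c(NYHA1 = 0.85, NYHA2 = 0.75, NYHA3 = 0.60, NYHA4 = 0.45),
    utility_sd = c(NYHA1 = 0.04, NYHA2 = 0.05, NYHA3 = 0.06, NYHA4 = 0.08),
    utility_distribution = "beta",
    hosp_er_means = matrix(
      c(0.8, 1.5, 3.0, 6.0,    # hospital days per cycle
        0.05, 0.10, 0.20, 0.40 # ER visits per cycle
      ), nrow = 4, dimnames = list(HF_LIVING, HF_HOSP_ER)),
    contact_means = matrix(
      c(0.5, 1.0, 2.0, 4.0,   # nurse visits
        1.0, 1.5, 2.0, 3.0,   # GP visits
        0.5, 1.0, 1.5, 2.5,   # specialist visits
        0.1, 0.3, 0.6, 1.2,   # hospitalist contacts
        0.5, 1.0, 1.5, 2.5    # telephone calls
      ), nrow = 4, dimnames = list(HF_LIVING, HF_CONTACTS)),
    resource_cv = 0.2,
    unit_cost_means = c(hospital_day = 500, er_visit = 250, nurse_visit = 35,
                        gp_visit = 35, specialist_visit = 95,
                        hospitalist_visit = 120, telephone_call = 15),
    unit_cost_cv = 0.1,
    treatment_specific_resource_use = FALSE,
    htm_install_fee_bounds = c(1500, 2500),
    htm_service_fee_bounds = c(300, 500),
    nts_cost_per_cycle = 150,
    replacement_interval_years = 5,
    fix_intervention_fees = FALSE,
    row_jitter_sd = 0
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown generator settings: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- modifyList(cfg, overrides)
  }
  cfg
}

# Apply a relative-risk-style protective effect to one usual-care row:
# transition mass to strictly worse living states and to death is reduced by
# `effect` and the removed mass is added to staying in the current state.
apply_protective_effect <- function(row, from_index, effect) {
  worse <- c(
    if (from_index < 4) (from_index + 1):4 else integer(0),
    5L
  )
  shifted <- row
  removed <- sum(row[worse]) * effect
  shifted[worse] <- row[worse] * (1 - effect)
  shifted[from_index] <- shifted[from_index] + removed
  shifted
}

#' Generate a synthetic evidence base
#'
#' Builds an [`hfvoi_evidence`] object emulating the structure of the trial
#' evidence behind the heart failure telehealth decision model: per-arm,
#' per-phase transition count matrices among NYHA I-IV and death; beta (or
#' gamma) utility evidence per living state; gamma resource-use and
#' unit-cost evidence split into a hospitalization/ER block and a
#' professional-contacts block; uniform telemonitoring fee bounds; and
#' initial NYHA state counts.
#'
#' The generator is deterministic given `config`: transition counts are the
#' target transition probabilities scaled by the pseudo-sample size, so that
#' the Dirichlet means equal the targets exactly and a zero treatment effect
#' yields identical counts in all three arms. The `seed` is recorded in the
#' metadata and is consumed only when `row_jitter_sd > 0`.
#'
#' @param config Generator settings from [default_generator_config()].
#' @param seed Integer seed recorded in metadata (and used for optional
#'   count jitter).
#' @param label Free-text label stored in metadata.
#' @return An object of class `hfvoi_evidence`.
#' @export
#' @examples
#' ev <- generate_evidence(seed = 1)
#' ev$initial$counts / sum(ev$initial$counts)
generate_evidence <- function(config = default_generator_config(),
                              seed = 1L, label = "synthetic") {
  cfg <- modifyList(default_generator_config(), config)
  if (cfg$pseudo_n <= 0) stop("pseudo_n must be positive", call. = FALSE)
  if (cfg$initial_pseudo_n <= 0) {
    stop("initial_pseudo_n must be positive", call. = FALSE)
  }
  n_phases <- as.integer(cfg$n_trial_phases)
  stopifnot(n_phases >= 1L)

  effects <- c(UC = 0, NTS = cfg$effect_nts, HTM = cfg$effect_htm)
  if (any(effects < 0 | effects >= 1)) {
    stop("treatment effects must lie in [0, 1)", call. = FALSE)
  }

  counts <- array(
    0, dim = c(3L, n_phases, 4L, 5L),
    dimnames = list(arm = HF_ARMS, phase = paste0("phase", seq_len(n_phases)),
                    from = HF_LIVING, to = HF_STATES)
  )
  for (a in seq_along(HF_ARMS)) {
    for (s in 1:4) {
      row <- apply_protective_effect(cfg$base_rows[s, ], s, effects[a])
      for (p in seq_len(n_phases)) counts[a, p, s, ] <- row * cfg$pseudo_n
    }
  }
  if (cfg$row_jitter_sd > 0) {
    set.seed(derive_seed(seed, "evidence-jitter"))
    counts[] <- counts * exp(rnorm(length(counts), 0, cfg$row_jitter_sd))
  }
  if (any(apply(counts, c(1, 2, 3), sum) <= 0)) {
    stop("every transition row must have a positive total count",
         call. = FALSE)
  }

  ut <- beta_from_moments(cfg$utility_mean, cfg$utility_sd, "utility")

  n_res_arms <- if (isTRUE(cfg$treatment_specific_resource_use)) 3L else 1L
  res_block <- function(means, types, path) {
    mean_arr <- array(
      rep(t(means), each = n_res_arms),
      dim = c(n_res_arms, 4L, length(types)),
      dimnames = list(arm = if (n_res_arms == 3L) HF_ARMS else "shared",
                      state = HF_LIVING, type = types)
    )
    gp <- gamma_from_mean_cv(as.numeric(mean_arr), cfg$resource_cv, path)
    list(mean = mean_arr,
         shape = array(gp$shape, dim = dim(mean_arr),
                       dimnames = dimnames(mean_arr)),
         rate = array(gp$rate, dim = dim(mean_arr),
                      dimnames = dimnames(mean_arr)))
  }
  uc <- gamma_from_mean_cv(cfg$unit_cost_means, cfg$unit_cost_cv,
                           "resource.unit_costs")

  ev <- structure(list(
    schema_version = 1L,
    metadata = list(label = label, seed = as.integer(seed), config = cfg),
    transition = list(counts = counts, n_trial_phases = n_phases,
                      arm_shared = isTRUE(cfg$arm_shared_transitions)),
    utility = list(
      distribution = cfg$utility_distribution,
      mean = cfg$utility_mean, sd = cfg$utility_sd,
      alpha = ut$alpha, beta = ut$beta
    ),
    resource = list(
      treatment_specific = isTRUE(cfg$treatment_specific_resource_use),
      hosp_er = res_block(cfg$hosp_er_means, HF_HOSP_ER, "resource.hosp_er"),
      contacts = res_block(cfg$contact_means, HF_CONTACTS,
                           "resource.contacts"),
      unit_costs = list(mean = cfg$unit_cost_means,
                        shape = setNames(uc$shape, HF_RESOURCES),
                        rate = setNames(uc$rate, HF_RESOURCES))
    ),
    intervention = list(
      htm_install_fee = c(lower = cfg$htm_install_fee_bounds[1],
                          upper = cfg$htm_install_fee_bounds[2]),
      htm_service_fee = c(lower = cfg$htm_service_fee_bounds[1],
                          upper = cfg$htm_service_fee_bounds[2]),
      nts_cost_per_cycle = cfg$nts_cost_per_cycle,
      replacement_interval_years = cfg$replacement_interval_years,
      fix_fees = isTRUE(cfg$fix_intervention_fees)
    ),
    initial = list(counts = cfg$initial_fractions * cfg$initial_pseudo_n)
  ), class = "hfvoi_evidence")
  validate_evidence(ev)
  ev
}

#' Validate an evidence base against its schema invariants
#'
#' Checks every structural invariant (positive row totals, utility means in
#' (0,1), positive gamma shapes/rates, ordered fee bounds, positive initial
#' total). Errors name the offending field path.
#'
#' @param evidence An `hfvoi_evidence` object (or a plain list conforming to
#'   the schema).
#' @return The validated object, invisibly.
#' @export
validate_evidence <- function(evidence) {
  need <- c("schema_version", "metadata", "transition", "utility",
            "resource", "intervention", "initial")
  for (blk in need) {
    if (is.null(evidence[[blk]])) fail_field(blk, "missing block")
  }
  tc <- evidence$transition$counts
  if (!is.array(tc) || length(dim(tc)) != 4L ||
      !all(dim(tc)[c(1, 3, 4)] == c(3L, 4L, 5L))) {
    fail_field("transition.counts", "must be an arm x phase x 4 x 5 array")
  }
  if (any(tc < 0)) {
    idx <- which(tc < 0, arr.ind = TRUE)[1, ]
    fail_field(sprintf("transition.counts[%s]",
                       paste(idx, collapse = ",")),
               "negative count")
  }
  if (any(apply(tc, c(1, 2, 3), sum) <= 0)) {
    fail_field("transition.counts", "a from-state row has zero total count")
  }
  np <- evidence$transition$n_trial_phases
  if (!is.numeric(np) || np < 1 || np != dim(tc)[2]) {
    fail_field("transition.n_trial_phases",
               "must match the phase dimension of counts")
  }
  if (isTRUE(evidence$transition$arm_shared) &&
      !(identical(unname(tc[1, , , ]), unname(tc[2, , , ])) &&
        identical(unname(tc[1, , , ]), unname(tc[3, , , ])))) {
    fail_field("transition.arm_shared",
               "shared-arm sampling requires identical counts in all arms")
  }
  u <- evidence$utility
  if (any(u$mean <= 0 | u$mean >= 1)) {
    fail_field("utility.mean", "means must lie strictly inside (0, 1)")
  }
  if (identical(u$distribution, "beta") &&
      (any(u$alpha <= 0) || any(u$beta <= 0))) {
    fail_field("utility.alpha/beta", "beta parameters must be positive")
  }
  for (blk in c("hosp_er", "contacts")) {
    b <- evidence$resource[[blk]]
    if (any(b$shape <= 0) || any(b$rate <= 0)) {
      fail_field(paste0("resource.", blk),
                 "gamma shapes and rates must be strictly positive")
    }
    if (any(!is.finite(b$mean)) || any(b$mean < 0)) {
      fail_field(paste0("resource.", blk),
                 "means must be finite and non-negative")
    }
  }
  ucst <- evidence$resource$unit_costs
  if (any(ucst$shape <= 0) || any(ucst$rate <= 0)) {
    fail_field("resource.unit_costs", "gamma parameters must be positive")
  }
  iv <- evidence$intervention
  for (fee in c("htm_install_fee", "htm_service_fee")) {
    b <- iv[[fee]]
    if (b[["lower"]] > b[["upper"]]) {
      fail_field(paste0("intervention.", fee), "lower bound exceeds upper")
    }
    if (any(b < 0)) fail_field(paste0("intervention.", fee), "negative fee")
  }
  if (iv$nts_cost_per_cycle < 0) {
    fail_field("intervention.nts_cost_per_cycle", "negative cost")
  }
  if (iv$replacement_interval_years <= 0) {
    fail_field("intervention.replacement_interval_years", "must be positive")
  }
  ic <- evidence$initial$counts
  if (length(ic) != 4L || any(ic < 0) || sum(ic) <= 0) {
    fail_field("initial.counts",
               "needs 4 non-negative counts with positive total")
  }
  invisible(evidence)
}

#' Restrict an evidence base to the NYHA IV subgroup
#'
#' Returns a copy whose initial distribution places all mass on NYHA IV;
#' every other evidence block is untouched. Used for the severe-subgroup
#' analysis, which starts the whole cohort in NYHA class IV.
#'
#' @param evidence An `hfvoi_evidence` object.
#' @return The restricted `hfvoi_evidence`.
#' @export
restrict_to_nyha4 <- function(evidence) {
  validate_evidence(evidence)
  total <- sum(evidence$initial$counts)
  evidence$initial$counts <- setNames(c(0, 0, 0, total), HF_LIVING)
  evidence
}

# ---- serialization ---------------------------------------------------------

# Arrays are stored as {dim, dimnames, values} so the JSON round-trip is
# exact and layout-unambiguous.
pack_array <- function(x) {
  list(dim = dim(x), dimnames = dimnames(x), values = as.numeric(x))
}

unpack_array <- function(x, path) {
  if (is.null(x$values) || is.null(x$dim)) {
    fail_field(path, "malformed array (needs dim and values)")
  }
  arr <- array(as.numeric(x$values), dim = as.integer(x$dim))
  if (!is.null(x$dimnames)) dimnames(arr) <- lapply(x$dimnames, as.character)
  arr
}

named_vec <- function(x) as.list(x)

unpack_named <- function(x) {
  v <- unlist(x, use.names = TRUE)
  setNames(as.numeric(v), names(v))
}

#' Write an evidence base to JSON
#'
#' The schema is versioned (`schema_version` field); arrays are stored with
#' explicit dimensions so that [read_evidence()] reproduces the object
#' field-for-field.
#'
#' @param evidence An `hfvoi_evidence` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  validate_evidence(evidence)
  cfg <- evidence$metadata$config
  cfg$base_rows <- pack_array(cfg$base_rows)
  cfg$hosp_er_means <- pack_array(cfg$hosp_er_means)
  cfg$contact_means <- pack_array(cfg$contact_means)
  # named vectors as JSON objects so names survive the round trip
  for (f in names(cfg)) {
    if (is.numeric(cfg[[f]]) && !is.null(names(cfg[[f]]))) {
      cfg[[f]] <- as.list(cfg[[f]])
    }
  }
  doc <- list(
    schema_version = evidence$schema_version,
    metadata = list(label = evidence$metadata$label,
                    seed = evidence$metadata$seed, config = cfg),
    transition = list(counts = pack_array(evidence$transition$counts),
                      n_trial_phases = evidence$transition$n_trial_phases,
                      arm_shared = isTRUE(evidence$transition$arm_shared)),
    utility = list(distribution = evidence$utility$distribution,
                   mean = named_vec(evidence$utility$mean),
                   sd = named_vec(evidence$utility$sd),
                   alpha = named_vec(evidence$utility$alpha),
                   beta = named_vec(evidence$utility$beta)),
    resource = list(
      treatment_specific = evidence$resource$treatment_specific,
      hosp_er = lapply(evidence$resource$hosp_er, pack_array),
      contacts = lapply(evidence$resource$contacts, pack_array),
      unit_costs = lapply(evidence$resource$unit_costs, named_vec)
    ),
    intervention = list(
      htm_install_fee = named_vec(evidence$intervention$htm_install_fee),
      htm_service_fee = named_vec(evidence$intervention$htm_service_fee),
      nts_cost_per_cycle = evidence$intervention$nts_cost_per_cycle,
      replacement_interval_years =
        evidence$intervention$replacement_interval_years,
      fix_fees = evidence$intervention$fix_fees
    ),
    initial = list(counts = named_vec(evidence$initial$counts))
  )
  # 17 significant digits: doubles round-trip bit-exactly through JSON
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read an evidence base from JSON
#'
#' Parses and validates a file produced by [write_evidence()] (or any file
#' conforming to the documented schema). Schema violations are reported with
#' the offending field path.
#'
#' @param path Path to an evidence JSON file.
#' @return An `hfvoi_evidence` object.
#' @export
read_evidence <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (blk in c("transition", "utility", "resource", "intervention",
                "initial")) {
    if (is.null(doc[[blk]])) fail_field(blk, "missing block")
  }
  cfg <- doc$metadata$config
  if (!is.null(cfg)) {
    for (f in c("base_rows", "hosp_er_means", "contact_means")) {
      if (!is.null(cfg[[f]])) {
        cfg[[f]] <- unpack_array(cfg[[f]], paste0("metadata.config.", f))
      }
    }
    for (f in names(cfg)) {
      if (is.list(cfg[[f]]) && !is.array(cfg[[f]])) {
        cfg[[f]] <- unpack_named(cfg[[f]])
      }
    }
  }
  res_block <- function(x, path) {
    list(mean = unpack_array(x$mean, paste0(path, ".mean")),
         shape = unpack_array(x$shape, paste0(path, ".shape")),
         rate = unpack_array(x$rate, paste0(path, ".rate")))
  }
  ev <- structure(list(
    schema_version = as.integer(doc$schema_version),
    metadata = list(label = doc$metadata$label,
                    seed = as.integer(doc$metadata$seed), config = cfg),
    transition = list(
      counts = unpack_array(doc$transition$counts, "transition.counts"),
      n_trial_phases = as.integer(doc$transition$n_trial_phases),
      arm_shared = isTRUE(doc$transition$arm_shared)
    ),
    utility = list(distribution = doc$utility$distribution,
                   mean = unpack_named(doc$utility$mean),
                   sd = unpack_named(doc$utility$sd),
                   alpha = unpack_named(doc$utility$alpha),
                   beta = unpack_named(doc$utility$beta)),
    resource = list(
      treatment_specific = isTRUE(doc$resource$treatment_specific),
      hosp_er = res_block(doc$resource$hosp_er, "resource.hosp_er"),
      contacts = res_block(doc$resource$contacts, "resource.contacts"),
      unit_costs = lapply(doc$resource$unit_costs, unpack_named)
    ),
    intervention = list(
      htm_install_fee = unpack_named(doc$intervention$htm_install_fee),
      htm_service_fee = unpack_named(doc$intervention$htm_service_fee),
      nts_cost_per_cycle = as.numeric(doc$intervention$nts_cost_per_cycle),
      replacement_interval_years =
        as.numeric(doc$intervention$replacement_interval_years),
      fix_fees = isTRUE(doc$intervention$fix_fees)
    ),
    initial = list(counts = unpack_named(doc$initial$counts))
  ), class = "hfvoi_evidence")
  validate_evidence(ev)
  ev
}

#' @export
print.hfvoi_evidence <- function(x, ...) {
  cat("<hfvoi_evidence>", x$metadata$label, "\n")
  cat("  arms:", paste(HF_ARMS, collapse = ", "), "|",
      x$transition$n_trial_phases, "trial phases\n")
  frac <- x$initial$counts / sum(x$initial$counts)
  cat("  initial NYHA distribution:",
      paste(sprintf("%s=%.3f", HF_LIVING, frac), collapse = " "), "\n")
  cat("  utilities (", x$utility$distribution, "): ",
      paste(sprintf("%.2f", x$utility$mean), collapse = " "), "\n", sep = "")
  cat("  resource use:",
      if (x$resource$treatment_specific) "treatment-specific" else
        "shared across arms", "\n")
  invisible(x)
}
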