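# Parameter sampling: joint draws from the evidence-base distributions and
# conditional draws that hold one EVPPI parameter group fixed.
#
# Internally draws are held in batches (arrays with the draw index last) so
# the nested EVPPI loops can sample thousands of joint realizations with a
# handful of vectorized RNG calls. `sample_draw()` is the single-draw surface.

# Fields owned by each parameter group. "FEES" is a pseudo-group used only
# in diagnostic full-conditioning; it is not EVPPI-eligible.
group_fields <- function(group) {
  map <- list(
    TRANSITIONS = "transitions",
    UTILITIES = "utilities",
    HOSP_ER = "hosp_er",
    CONTACTS_COSTS = c("contacts", "unit_costs"),
    INITIAL_DIST = "initial",
    FEES = c("install_fee", "service_fee")
  )
  bad <- setdiff(group, names(map))
  if (length(bad)) {
    stop("unknown parameter group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unique(unlist(map[group], use.names = FALSE))
}

# Sample a batch of n joint parameter draws. All randomness comes from the
# current RNG state unless `seed` is given. Sampling order is fixed:
# transitions, utilities, hosp/ER use, contacts, unit costs, fees, initial.
sample_draws <- function(evidence, n, seed = NULL) {
  validate_evidence(evidence)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  stopifnot(n >= 1L)

  counts <- evidence$transition$counts # (arm, phase, from, to)
  np <- dim(counts)[2]
  arm_shared <- isTRUE(evidence$transition$arm_shared)
  n_tr_arms <- if (arm_shared) 1L else 3L
  if (arm_shared) counts <- counts[1L, , , , drop = FALSE]
  alpha <- as.numeric(counts)
  g <- numeric(length(alpha) * n)
  pos <- rep(alpha > 0, times = n)
  g[pos] <- rgamma(sum(pos), shape = rep(alpha, times = n)[pos], rate = 1)
  ga <- array(g, dim = c(n_tr_arms, np, 4L, 5L, n))
  # normalize each (arm, phase, from, draw) row over `to`
  perm <- aperm(ga, c(1, 2, 3, 5, 4))
  dim(perm) <- c(n_tr_arms * np * 4L * n, 5L)
  perm <- perm / rowSums(perm)
  dim(perm) <- c(n_tr_arms, np, 4L, n, 5L)
  transitions <- aperm(perm, c(3, 5, 2, 1, 4)) # (from, to, phase, arm, draw)
  if (arm_shared) {
    # replicate the single drawn set across the three arms (array() recycles
    # the arm-last layout along its final dimension)
    transitions <- aperm(array(aperm(transitions, c(1, 2, 3, 5, 4)),
                               dim = c(4L, 5L, np, n, 3L)),
                         c(1, 2, 3, 5, 4))
  }

  u <- evidence$utility
  utilities <- if (identical(u$distribution, "gamma")) {
    shape <- u$mean^2 / u$sd^2
    rate <- u$mean / u$sd^2
    matrix(rgamma(4L * n, shape = rep(shape, times = n),
                  rate = rep(rate, times = n)), 4L, n)
  } else {
    matrix(rbeta(4L * n, shape1 = rep(u$alpha, times = n),
                 shape2 = rep(u$beta, times = n)), 4L, n)
  }

  res_draw <- function(block) {
    sh <- as.numeric(block$shape)
    ra <- as.numeric(block$rate)
    fin <- rep(is.finite(ra), times = n) # rate Inf marks a mean-zero cell
    out <- numeric(length(sh) * n)
    out[fin] <- rgamma(sum(fin), shape = rep(sh, times = n)[fin],
                       rate = rep(ra, times = n)[fin])
    array(out, dim = c(dim(block$shape), n))
  }
  hosp_er <- res_draw(evidence$resource$hosp_er)
  contacts <- res_draw(evidence$resource$contacts)

  ucst <- evidence$resource$unit_costs
  unit_costs <- matrix(
    rgamma(7L * n, shape = rep(ucst$shape, times = n),
           rate = rep(ucst$rate, times = n)), 7L, n,
    dimnames = list(HF_RESOURCES, NULL)
  )

  iv <- evidence$intervention
  if (isTRUE(iv$fix_fees)) {
    install_fee <- rep(mean(iv$htm_install_fee), n)
    service_fee <- rep(mean(iv$htm_service_fee), n)
  } else {
    install_fee <- runif(n, iv$htm_install_fee[["lower"]],
                         iv$htm_install_fee[["upper"]])
    service_fee <- runif(n, iv$htm_service_fee[["lower"]],
                         iv$htm_service_fee[["upper"]])
  }

  initial <- t(rdirichlet_rows(n, evidence$initial$counts))

  structure(list(
    n = n, n_phases = np,
    treatment_specific = evidence$resource$treatment_specific,
    transitions = transitions, utilities = utilities,
    hosp_er = hosp_er, contacts = contacts, unit_costs = unit_costs,
    install_fee = install_fee, service_fee = service_fee,
    nts_cost = iv$nts_cost_per_cycle,
    replacement_interval_years = iv$replacement_interval_years,
    initial = initial
  ), class = "hfvoi_draws")
}

# Extract draw i of a batch as a single hfvoi_draw.
draws_slice <- function(batch, i = 1L) {
  structure(list(
    n_phases = batch$n_phases,
    treatment_specific = batch$treatment_specific,
    transitions = array(batch$transitions[, , , , i],
                        dim = dim(batch$transitions)[1:4],
                        dimnames = list(from = HF_LIVING, to = HF_STATES,
                                        phase = NULL, arm = HF_ARMS)),
    utilities = setNames(c(batch$utilities[, i], 0), HF_STATES),
    hosp_er = array(batch$hosp_er[, , , i], dim = dim(batch$hosp_er)[1:3]),
    contacts = array(batch$contacts[, , , i],
                     dim = dim(batch$contacts)[1:3]),
    unit_costs = batch$unit_costs[, i],
    install_fee = batch$install_fee[i],
    service_fee = batch$service_fee[i],
    nts_cost = batch$nts_cost,
    replacement_interval_years = batch$replacement_interval_years,
    initial = setNames(batch$initial[, i], HF_LIVING)
  ), class = "hfvoi_draw")
}

# Rebuild a size-1 batch from a single draw (used by arm_outcomes()).
draw_to_batch <- function(draw) {
  structure(list(
    n = 1L, n_phases = draw$n_phases,
    treatment_specific = draw$treatment_specific,
    transitions = array(draw$transitions, c(dim(draw$transitions), 1L)),
    utilities = matrix(draw$utilities[HF_LIVING], 4L, 1L),
    hosp_er = array(draw$hosp_er, c(dim(draw$hosp_er), 1L)),
    contacts = array(draw$contacts, c(dim(draw$contacts), 1L)),
    unit_costs = matrix(draw$unit_costs, 7L, 1L),
    install_fee = draw$install_fee, service_fee = draw$service_fee,
    nts_cost = draw$nts_cost,
    replacement_interval_years = draw$replacement_interval_years,
    initial = matrix(draw$initial, 4L, 1L)
  ), class = "hfvoi_draws")
}

#' Draw one joint parameter realization from an evidence base
#'
#' Each transition row is drawn from a Dirichlet distribution with the
#' evidence counts as concentration parameters; utilities from beta (or
#' gamma) distributions; resource-use counts and unit costs from gamma
#' distributions; telemonitoring fees from uniform distributions within
#' their bounds; and the initial NYHA distribution from a Dirichlet over the
#' initial counts. All parameters are sampled independently.
#'
#' @param evidence An `hfvoi_evidence` object.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return An object of class `hfvoi_draw` with elements `transitions`
#'   (from x to x phase x arm array of probabilities), `utilities` (per
#'   state, `DEAD` = 0), `hosp_er` and `contacts` (resource counts per
#'   cycle), `unit_costs` (EUR), fees, and `initial` (probability vector
#'   over living states).
#' @export
#' @examples
#' ev <- generate_evidence(seed = 1)
#' draw <- sample_draw(ev, seed = 42)
#' rowSums(draw$transitions[, , 1, "UC"]) # each row sums to 1
sample_draw <- function(evidence, seed = NULL) {
  draws_slice(sample_draws(evidence, 1L, seed = seed), 1L)
}

#' Extract the fields owned by one EVPPI parameter group
#'
#' The five groups (`r paste(HF_GROUPS, collapse = ", ")`) partition the
#' EVPPI-eligible parameters; unit costs travel with the professional
#' contacts group; the pseudo-group `"FEES"` (intervention fees) is
#' available for diagnostic full conditioning only.
#'
#' @param draw An `hfvoi_draw`.
#' @param group Character vector of group labels.
#' @return A named list of the group's fields, class `hfvoi_group_values`,
#'   with the groups recorded in the `"groups"` attribute.
#' @export
extract_group <- function(draw, group) {
  fields <- group_fields(group)
  structure(draw[fields], class = "hfvoi_group_values", groups = group)
}

# Validate fixed group values before conditioning.
validate_group_values <- function(fixed) {
  if (!is.null(fixed$utilities)) {
    u <- fixed$utilities
    if (any(u < 0 | u > 1)) {
      stop("fixed utilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(fixed$transitions)) {
    tr <- fixed$transitions
    if (any(tr < 0)) stop("fixed transition probabilities must be non-negative",
                          call. = FALSE)
    dims <- dim(tr)
    rows <- matrix(aperm(tr, c(1, 3, 4, 2)), ncol = 5L)
    if (any(abs(rowSums(rows) - 1) > 1e-12)) {
      stop("fixed transition rows must sum to 1", call. = FALSE)
    }
  }
  if (!is.null(fixed$initial)) {
    if (any(fixed$initial < 0) || abs(sum(fixed$initial) - 1) > 1e-12) {
      stop("fixed initial distribution must be a probability vector",
           call. = FALSE)
    }
  }
  for (f in c("hosp_er", "contacts", "unit_costs", "install_fee",
              "service_fee")) {
    if (!is.null(fixed[[f]]) && any(fixed[[f]] < 0)) {
      stop("fixed ", f, " values must be non-negative", call. = FALSE)
    }
  }
  invisible(fixed)
}

# Batch conditional sampling: a fresh joint batch whose fixed fields are
# overwritten verbatim (replicated across draws). Because all parameters are
# sampled independently, the conditional distribution of the complement
# equals its marginal.
sample_conditional_draws <- function(evidence, fixed, n, seed = NULL) {
  validate_group_values(fixed)
  batch <- sample_draws(evidence, n, seed = seed)
  for (f in intersect(names(fixed),
                      c("transitions", "utilities", "hosp_er", "contacts",
                        "unit_costs", "initial"))) {
    v <- fixed[[f]]
    if (f == "utilities") v <- v[seq_len(4L)] # living states only
    batch[[f]][] <- as.numeric(v) # draw index last, so recycling replicates
  }
  if (!is.null(fixed$install_fee)) batch$install_fee[] <- fixed$install_fee
  if (!is.null(fixed$service_fee)) batch$service_fee[] <- fixed$service_fee
  batch
}

#' Draw parameters conditionally on fixed group values
#'
#' Returns a joint draw whose group fields equal `fixed` verbatim while the
#' remaining fields are freshly sampled as in [sample_draw()]. Under the
#' model's independence assumption the conditional distribution of the
#' complement is its marginal distribution.
#'
#' @param evidence An `hfvoi_evidence` object.
#' @param fixed Group values from [extract_group()].
#' @param seed Optional integer seed.
#' @return An `hfvoi_draw`.
#' @export
sample_conditional <- function(evidence, fixed, seed = NULL) {
  draws_slice(sample_conditional_draws(evidence, fixed, 1L, seed = seed), 1L)
}
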