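#' Inoculate a treatment
#'
#' Turns a treatment specification into per-species initial CFU counts:
#' residents share `resident_total` equally, invaders (the focal species
#' plus any co-invaders) share `invader_total` equally, and species absent
#' from the treatment get 0.
#'
#' @param treatment One row of an [design_co_invasion()]-style design table
#'   (columns `focal`, `residents`, `co_invaders`, `invasion_type`).
#' @param scheme An [inoculation_scheme()].
#' @param pool The species pool.
#' @return Named numeric vector of CFU counts over the pool.
#' @examples
#' d <- design_co_invasion()
#' inoculate(d[1, ], inoculation_scheme(), species_pool())
#' @export
inoculate <- function(treatment, scheme = inoculation_scheme(),
                      pool = species_pool()) {
  pool <- as_pool(pool)
  residents <- split_set(treatment$residents, pool)
  invaders <- c(treatment$focal, split_set(treatment$co_invaders, pool))
  if (treatment$invasion_type == "co" && length(residents) == 0L) {
    stop("invalid treatment '", treatment$treatment_id,
         "': a co-invasion needs a non-empty resident community", call. = FALSE)
  }
  extra <- setdiff(c(residents, invaders), pool)
  if (length(extra)) {
    stop("treatment species not in pool: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  inoc <- stats::setNames(numeric(length(pool)), pool)
  if (length(residents)) inoc[residents] <- scheme$resident_total / length(residents)
  inoc[invaders] <- scheme$invader_total / length(invaders)
  inoc
}

## Internal abundance scale for the integrator: state is N / 1e6 CFU, which
## keeps a 5-species batch culture O(1)-conditioned; atol 1e-10 in scaled
## units is 1e-4 CFU, far below one cell.
.sim_scale <- 1e6
.sim_rtol <- 1e-10
.sim_atol <- 1e-10
.sim_blowup <- 1e12   # scaled units; ~1e18 CFU, far beyond any batch culture

#' Simulate one batch culture
#'
#' Integrates the gLV dynamics `dN_i/dt = N_i (r_i + sum_j alpha_ij N_j)`
#' from the inoculum to `assay_days` with `deSolve::ode` (lsoda, adaptive
#' step). Abundances are scaled internally to units of 1e6 CFU; species
#' inoculated at exactly 0 stay at 0; the run is deterministic.
#'
#' @param params A [community_params()] object.
#' @param inoculum Named (or pool-ordered) non-negative CFU vector; at
#'   least one species must be positive.
#' @param trajectory If `TRUE`, also return the dense trajectory (201 time
#'   points) as attribute `"trajectory"` (a matrix, CFU units).
#' @return Named numeric vector of final CFU counts.
#' @examples
#' p <- community_params("X", r = 1, alpha = matrix(-1e-7, 1, 1), assay_days = 21)
#' simulate_batch(p, c(X = 1e3))  # approaches K = 1e7
#' @export
simulate_batch <- function(params, inoculum, trajectory = FALSE) {
  stopifnot(inherits(params, "community_params"))
  n <- length(params$labels)
  if (length(inoculum) != n) {
    stop("inoculum must have one entry per species", call. = FALSE)
  }
  if (!is.null(names(inoculum))) inoculum <- inoculum[params$labels]
  if (anyNA(inoculum) || any(inoculum < 0)) {
    stop("inoculum must be non-negative", call. = FALSE)
  }
  if (all(inoculum == 0)) stop("at least one species must be inoculated", call. = FALSE)

  x0 <- inoculum / .sim_scale
  r <- unname(params$r)
  a_scaled <- params$alpha * .sim_scale
  rhs <- function(t, x, p) {
    x <- pmax(x, 0)
    list(x * (r + as.vector(a_scaled %*% x)))
  }
  times <- if (trajectory) seq(0, params$assay_days, length.out = 201L) else c(0, params$assay_days)
  # divergent systems make lsoda warn and return early; the non-finite /
  # blow-up check below turns that into the dynamics-divergence error
  sol <- suppressWarnings(
    deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                 method = "lsoda", rtol = .sim_rtol, atol = .sim_atol))
  states <- sol[, -1, drop = FALSE]
  if (anyNA(states) || any(!is.finite(states)) || any(states > .sim_blowup)) {
    stop("dynamics diverged: non-finite or unbounded trajectory for r = (",
         paste(signif(params$r, 4), collapse = ", "),
         "), alpha range [", signif(min(params$alpha), 4), ", ",
         signif(max(params$alpha), 4), "]", call. = FALSE)
  }
  final <- pmax(states[nrow(states), ], 0) * .sim_scale
  final[inoculum == 0] <- 0
  names(final) <- params$labels
  if (trajectory) {
    traj <- pmax(states, 0) * .sim_scale
    colnames(traj) <- params$labels
    attr(final, "trajectory") <- cbind(time = sol[, 1], traj)
  }
  final
}

#' Observe final abundances through the plate-count model
#'
#' With Poisson noise, the observed whole-culture abundance is
#' `rpois(final x f) / f` where `f` is the effective sampling fraction;
#' with `noise = "none"` the observation is the true final. Any observation
#' below the detection limit is recorded as 0 with `below_detection = TRUE`.
#' Reproducible given `seed`.
#'
#' @param final Named non-negative CFU vector.
#' @param model An [observation_model()].
#' @param seed Integer seed for the Poisson draws.
#' @return A list with `observed` (numeric vector) and `below_detection`
#'   (logical vector).
#' @export
observe <- function(final, model = observation_model(), seed = 1L) {
  stopifnot(inherits(model, "observation_model"))
  if (anyNA(final) || any(final < 0)) stop("final abundances must be non-negative", call. = FALSE)
  if (model$noise == "poisson") {
    set.seed(as.integer(seed))
    f <- model$sampling_fraction
    observed <- stats::rpois(length(final), lambda = final * f) / f
  } else {
    observed <- as.numeric(final)
  }
  below <- observed < model$detection_limit | observed == 0
  observed[below] <- 0
  names(observed) <- names(final)
  names(below) <- names(final)
  list(observed = observed, below_detection = below)
}

#' Derive a replicate-level seed
#'
#' Deterministic, insertion-order-independent seed for one replicate of one
#' treatment: the treatment id is folded into a 31-bit polynomial hash
#' (base 31, modulus 2^31 - 1), then combined linearly with the master seed
#' and the replicate number, modulo 2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param treatment_id Treatment identifier string.
#' @param replicate Replicate number (1-based).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
replicate_seed <- function(master_seed, treatment_id, replicate) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(treatment_id)) h <- (h * 31 + b) %% m
  as.integer((h + (abs(as.numeric(master_seed)) %% m) * 65539 +
                as.numeric(replicate) * 7919) %% m)
}

#' Generate a synthetic invasion-assay dataset
#'
#' Runs the full generative model over a design table: each treatment is
#' inoculated, its (deterministic) batch dynamics are integrated once, and
#' each replicate is an independent plate-count observation of the final
#' state, seeded by [replicate_seed()] so the output is byte-identical
#' across runs and independent of treatment order.
#'
#' @param design An `"invasion_design"` data frame.
#' @param params A [community_params()] object (or preset name).
#' @param scheme An [inoculation_scheme()].
#' @param model An [observation_model()].
#' @param master_seed Integer master seed.
#' @return A CFU-count data frame with one row per treatment x replicate x
#'   inoculated species: columns `treatment_id`, `replicate`, `species`,
#'   `role` (`"resident"`/`"invader"`), `N0`, `N1`, `below_detection`,
#'   `assay_days`.
#' @examples
#' d <- design_co_invasion(species_pool(), c(2, 2), replicates = 2)
#' counts <- simulate_dataset(d[1:2, ], community_preset("stabilized"),
#'                            master_seed = 42)
#' head(counts)
#' @export
simulate_dataset <- function(design,
                             params = community_preset("stabilized"),
                             scheme = inoculation_scheme(),
                             model = observation_model(),
                             master_seed = 1L) {
  if (is.character(params)) params <- community_preset(params)
  stopifnot(inherits(params, "community_params"))
  if (nrow(design) == 0L) stop("design is empty", call. = FALSE)
  pool <- species_pool(params$labels)
  cache <- new.env(parent = emptyenv())   # finals are deterministic per inoculum
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    inoc <- tryCatch(inoculate(tr, scheme, pool), error = function(e) {
      stop("treatment '", tr$treatment_id, "': ", conditionMessage(e), call. = FALSE)
    })
    key <- paste(inoc, collapse = ",")
    final <- if (!is.null(cache[[key]])) cache[[key]] else {
      cache[[key]] <- tryCatch(simulate_batch(params, inoc), error = function(e) {
        stop("treatment '", tr$treatment_id, "': ", conditionMessage(e), call. = FALSE)
      })
      cache[[key]]
    }
    present <- names(inoc)[inoc > 0]
    invaders <- c(tr$focal, split_set(tr$co_invaders, pool))
    reps <- vector("list", tr$replicates)
    for (rep_i in seq_len(tr$replicates)) {
      obs <- observe(final[present], model,
                     seed = replicate_seed(master_seed, tr$treatment_id, rep_i))
      reps[[rep_i]] <- data.frame(
        treatment_id = tr$treatment_id,
        replicate = rep_i,
        species = present,
        role = ifelse(present %in% invaders, "invader", "resident"),
        N0 = unname(inoc[present]),
        N1 = unname(obs$observed),
        below_detection = unname(obs$below_detection),
        assay_days = params$assay_days,
        stringsAsFactors = FALSE
      )
    }
    out[[i]] <- do.call(rbind, reps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
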