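#' Malthusian parameter
#'
#' Realized per-capita exponential growth rate over an assay,
#' `m = ln(N1/N0)/t`. Negative when the population declined. The unit of
#' `m` is the inverse of the unit of `t` (this package reports per-week
#' rates for the standard 1-week assay).
#'
#' @param N0 Starting density (CFU), strictly positive.
#' @param N1 Final density (CFU), non-negative; `N1 = 0` returns `-Inf`
#'   (extinction at the observed resolution) — below-detection handling
#'   belongs to the imputation policy upstream, not here.
#' @param t Assay time, positive.
#' @return Numeric rate (vectorized).
#' @examples
#' malthusian(1e3, 1e6, 1)   # ln(1000) = 6.9078
#' @export
malthusian <- function(N0, N1, t) {
  if (any(!is.finite(N0)) || any(N0 <= 0)) {
    stop("invalid input: N0 must be strictly positive", call. = FALSE)
  }
  if (any(is.na(N1)) || any(N1 < 0)) {
    stop("invalid input: N1 must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("invalid input: t must be positive", call. = FALSE)
  }
  log(N1 / N0) / t
}

#' Pooled community Malthusian parameter
#'
#' The community growth rate is the density change of all non-focal
#' populations combined — residents and co-invaders pooled by SUMMED
#' densities, not by averaging per-species rates:
#' `m_community = ln(sum(N1)/sum(N0))/t`.
#'
#' @param N0,N1 Vectors of per-species starting/final densities for the
#'   non-focal populations of one replicate.
#' @param t Assay time.
#' @return A single rate; `-Inf` if every population fell to zero.
#' @examples
#' pooled_malthusian(c(100, 100), c(400, 100), 1)  # ln(500/200)
#' @export
pooled_malthusian <- function(N0, N1, t) {
  if (length(N0) == 0L || length(N0) != length(N1)) {
    stop("invalid input: need matching non-empty N0/N1 vectors", call. = FALSE)
  }
  s0 <- sum(N0)
  s1 <- sum(N1)
  if (!is.finite(s0) || s0 <= 0) {
    stop("undefined community growth: pooled starting density is not positive",
         call. = FALSE)
  }
  malthusian(s0, s1, t)
}

#' Below-detection imputation policy
#'
#' What to do when the focal invader's final density falls below the
#' detection limit (recorded as 0). The species may not be extinct — a
#' plate count simply cannot see it — so the replicate is kept by default
#' with the final density imputed at the detection limit, which yields a
#' strongly negative focal growth rate and a conservative (low) relative
#' growth rate. All affected estimates are flagged.
#'
#' @param method `"impute_at_limit"` (default; `N1 <- detection_limit`),
#'   `"impute_half_limit"` (`N1 <- detection_limit/2`), or
#'   `"drop_replicate"` (estimate recorded as missing).
#' @param detection_limit Whole-culture CFU detection limit used for
#'   imputation (default `1e3`, matching [observation_model()]).
#' @return A list of class `"imputation_policy"`.
#' @export
imputation_policy <- function(method = c("impute_at_limit", "drop_replicate",
                                         "impute_half_limit"),
                              detection_limit = 1e3) {
  method <- match.arg(method)
  if (detection_limit <= 0) stop("detection_limit must be positive", call. = FALSE)
  structure(list(method = method, detection_limit = detection_limit),
            class = "imputation_policy")
}

rgr_flags <- function(...) {
  f <- c(...)
  if (length(f)) paste(f, collapse = ",") else ""
}

#' Relative invader growth rate for one replicate
#'
#' Computes the focal invader's Malthusian parameter, the pooled community
#' parameter over every other population (residents AND co-invaders), and
#' their ratio `rgr = m_focal / m_community`. An RGR above 1 means the rare
#' invader outgrew the community: negative frequency dependence, the
#' invasion-criterion signature of stability.
#'
#' If the pooled community did not grow (`m_community <= 0`) the ratio is
#' not interpretable as frequency dependence and `rgr` is recorded as `NA`
#' with flag `community_decline`. A below-detection focal final is handled
#' by the [imputation_policy()] and flagged.
#'
#' @param obs Data frame of all observations of one treatment x replicate
#'   (columns `species`, `role`, `N0`, `N1`, `below_detection`).
#' @param focal Focal species label; must be present with role
#'   `"invader"`.
#' @param t Assay time (weeks, for per-week rates).
#' @param policy An [imputation_policy()].
#' @return One-row data frame: `focal`, `m_focal`, `m_community`, `rgr`,
#'   `flags` (comma-separated, possibly empty).
#' @examples
#' obs <- data.frame(species = c("V", "A", "P"),
#'                   role = c("invader", "resident", "resident"),
#'                   N0 = c(10, 100, 100), N1 = c(40, 400, 100),
#'                   below_detection = FALSE)
#' rgr_replicate(obs, "V", t = 1)   # ln(4)/ln(2.5) = 1.513
#' @export
rgr_replicate <- function(obs, focal, t, policy = imputation_policy()) {
  i <- which(obs$species == focal & obs$role == "invader")
  if (length(i) != 1L) {
    stop("invalid input: focal species '", focal,
         "' must appear exactly once with role 'invader'", call. = FALSE)
  }
  others <- obs[-i, , drop = FALSE]
  if (nrow(others) == 0L) {
    stop("invalid input: no non-focal populations to pool", call. = FALSE)
  }
  flags <- character(0)
  N1_focal <- obs$N1[i]
  below <- isTRUE(obs$below_detection[i]) || N1_focal == 0
  if (below) {
    flags <- c(flags, "focal_below_detection")
    if (policy$method == "drop_replicate") {
      return(data.frame(focal = focal, m_focal = NA_real_,
                        m_community = NA_real_, rgr = NA_real_,
                        flags = rgr_flags(flags, "dropped"),
                        stringsAsFactors = FALSE))
    }
    N1_focal <- switch(policy$method,
                       impute_at_limit = policy$detection_limit,
                       impute_half_limit = policy$detection_limit / 2)
    flags <- c(flags, "imputed")
  }
  m_focal <- malthusian(obs$N0[i], N1_focal, t)
  m_community <- pooled_malthusian(others$N0, others$N1, t)
  if (!is.finite(m_community) || m_community <= 0) {
    flags <- c(flags, "community_decline")
    rgr <- NA_real_
  } else {
    rgr <- m_focal / m_community
  }
  data.frame(focal = focal, m_focal = m_focal, m_community = m_community,
             rgr = rgr, flags = rgr_flags(flags), stringsAsFactors = FALSE)
}

#' Relative invader growth rates for a whole dataset
#'
#' Computes one [rgr_replicate()] estimate per design row x replicate: the
#' design row names the focal invader, and every other population in that
#' replicate (residents and co-invaders alike) forms the pooled community.
#' Treatments that share a culture but differ in focal species are separate
#' design rows, so a co-invasion treatment with k invaders contributes k
#' estimates per replicate across its k design rows.
#'
#' @param counts CFU-count data frame ([simulate_dataset()] schema; real
#'   plate-count exports with the same columns work identically).
#' @param design An `"invasion_design"` data frame.
#' @param policy An [imputation_policy()].
#' @return Data frame of class `"rgr_table"`: `treatment_id`, `replicate`,
#'   `focal`, `residents`, `co_invaders`, `invasion_type`, `m_focal`,
#'   `m_community`, `rgr`, `flags`. Rates are per week
#'   (`t = assay_days/7`).
#' @export
rgr_table <- function(counts, design, policy = imputation_policy()) {
  needed <- c("treatment_id", "replicate", "species", "role", "N0", "N1", "assay_days")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols)) {
    stop("counts table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"below_detection" %in% names(counts)) counts$below_detection <- counts$N1 == 0
  problems <- character(0)
  extra <- setdiff(unique(counts$treatment_id), design$treatment_id)
  if (length(extra)) {
    problems <- c(problems, paste0("counts contain unknown treatment_id(s): ",
                                   paste(utils::head(extra, 5), collapse = ", ")))
  }
  absent <- setdiff(design$treatment_id, unique(counts$treatment_id))
  if (length(absent)) {
    problems <- c(problems, paste0("design treatment(s) missing from counts: ",
                                   paste(utils::head(absent, 5), collapse = ", ")))
  }
  if (length(problems)) {
    stop("counts/design reconciliation failed: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  by_treatment <- split(counts, counts$treatment_id)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    tc <- by_treatment[[tr$treatment_id]]
    reps <- sort(unique(tc$replicate))
    rows <- vector("list", length(reps))
    for (j in seq_along(reps)) {
      obs <- tc[tc$replicate == reps[j], , drop = FALSE]
      t_weeks <- unique(obs$assay_days) / 7
      if (length(t_weeks) != 1L) {
        stop("counts/design reconciliation failed: mixed assay_days within ",
             tr$treatment_id, " replicate ", reps[j], call. = FALSE)
      }
      est <- rgr_replicate(obs, tr$focal, t_weeks, policy)
      rows[[j]] <- cbind(
        data.frame(treatment_id = tr$treatment_id, replicate = reps[j],
                   stringsAsFactors = FALSE),
        est,
        data.frame(residents = tr$residents, co_invaders = tr$co_invaders,
                   invasion_type = tr$invasion_type, stringsAsFactors = FALSE)
      )
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res <- res[, c("treatment_id", "replicate", "focal", "residents", "co_invaders",
                 "invasion_type", "m_focal", "m_community", "rgr", "flags")]
  rownames(res) <- NULL
  structure(res, class = c("rgr_table", "data.frame"))
}

#' @export
print.rgr_table <- function(x, ...) {
  defined <- sum(is.finite(x$rgr))
  cat("Relative invader growth rates: ", nrow(x), " focal-replicate estimates (",
      defined, " defined), ", length(unique(x$treatment_id)), " treatments\n",
      sep = "")
  flagged <- sum(nzchar(x$flags))
  if (flagged) cat("  flagged estimates: ", flagged, "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
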