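#' Generalized Lotka-Volterra community parameters
#'
#' Bundles the parameters of the batch-culture dynamics
#' \deqn{dN_i/dt = N_i (r_i + \sum_j \alpha_{ij} N_j)}
#' where `r` is the intrinsic per-capita growth rate (per day) and
#' `alpha[i, j]` the per-capita effect of species j on species i's growth,
#' in units of 1/(CFU day). Negative diagonal entries encode
#' self-limitation; a single species with `r > 0` and `alpha[i, i] < 0` is
#' logistic with carrying capacity `K = -r/alpha[i, i]`.
#'
#' @param labels Species labels (canonical order).
#' @param r Numeric vector of intrinsic growth rates, per day.
#' @param alpha Square interaction matrix, dimension `length(labels)`.
#' @param assay_days Assay duration in days (default 7, one week of static
#'   batch growth).
#' @return A list of class `"community_params"`.
#' @seealso [community_preset()] for bundled parameter sets.
#' @export
community_params <- function(labels, r, alpha, assay_days = 7) {
  labels <- as.character(labels)
  n <- length(labels)
  if (anyDuplicated(labels) || n < 1L) stop("labels must be unique and non-empty", call. = FALSE)
  r <- as.numeric(r)
  alpha <- as.matrix(alpha)
  if (length(r) != n) stop("r must have one entry per species", call. = FALSE)
  if (!all(dim(alpha) == c(n, n))) {
    stop("alpha must be a square matrix of dimension ", n, call. = FALSE)
  }
  if (anyNA(r) || anyNA(alpha) || !all(is.finite(r)) || !all(is.finite(alpha))) {
    stop("r and alpha must be finite", call. = FALSE)
  }
  if (!is.numeric(assay_days) || length(assay_days) != 1L || assay_days <= 0) {
    stop("assay_days must be a positive number", call. = FALSE)
  }
  dimnames(alpha) <- list(labels, labels)
  names(r) <- labels
  structure(list(labels = labels, r = r, alpha = alpha,
                 assay_days = as.numeric(assay_days)),
            class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat("gLV community parameters: ", length(x$labels), " species (",
      paste(x$labels, collapse = ", "), "), assay ", x$assay_days, " days\n",
      sep = "")
  cat("r (per day):\n")
  print(x$r)
  cat("alpha (per CFU per day):\n")
  print(x$alpha)
  invisible(x)
}

## Documented preset constants. Magnitudes are in absolute CFU units for a
## 6 ml batch culture: self-limitation -1e-8 per (CFU day) puts a
## single-species carrying capacity near 1e8 CFU for r ~ 1/day (a dilute
## medium at ~2e7 CFU/ml), and the neutral coupling -2e-9 puts the
## whole-community capacity (r/|alpha|, 5e8 CFU) far above the 1.616e7 CFU
## total inoculum, so every inoculated community grows over the assay the
## way a batch culture does.
.preset_r_neutral <- rep(1.0, 5)
.preset_r_varied  <- c(A = 1.2, O = 1.0, P = 1.3, S = 0.9, V = 1.1)
.preset_alpha_self  <- -1e-8
.preset_alpha_cross <- -2e-9
.preset_alpha_neutral <- -2e-9
.preset_alpha_facil <- 8e-10

#' Bundled community parameter presets
#'
#' Three deterministic parameter sets for the default five-species pool
#' (A, O, P, S, V):
#' \describe{
#'   \item{`neutral`}{All species identical: equal `r` (1/day) and a flat
#'     interaction matrix (`alpha[i, j] = alpha[i, i]` for all j, -2e-9).
#'     Every species' per-capita growth rate is identical at all times, so
#'     every relative invader growth rate is exactly 1: no stabilization.}
#'   \item{`stabilized`}{Species-specific `r` (1.2, 1.0, 1.3, 0.9, 1.1 per
#'     day for A, O, P, S, V) with intraspecific limitation dominating
#'     interspecific (-1e-8 diagonal vs -2e-9 off-diagonal). Rare invaders
#'     escape most competition: mutual invasibility expected.}
#'   \item{`paper_like`}{As `stabilized`, but Variovorax (V) gains a growth
#'     benefit from Pseudomonas, Ochrobactrum and Achromobacter
#'     (`alpha[V, P] = alpha[V, O] = alpha[V, A] = +8e-10`) and is unaffected
#'     by Stenotrophomonas (`alpha[V, S] = 0`); every other off-diagonal
#'     entry is competitive. Mirrors the reported interaction signs of the
#'     five-species soil community.}
#' }
#' All magnitudes are fixed documented constants, so presets are fully
#' deterministic.
#'
#' @param name One of `"neutral"`, `"stabilized"`, `"paper_like"`.
#' @param assay_days Assay duration in days (default 7).
#' @return A [community_params()] object for the five-species pool.
#' @examples
#' community_preset("paper_like")$alpha["V", ]
#' @export
community_preset <- function(name = c("neutral", "stabilized", "paper_like"),
                             assay_days = 7) {
  name <- match.arg(name)
  labels <- c("A", "O", "P", "S", "V")
  if (name == "neutral") {
    alpha <- matrix(.preset_alpha_neutral, 5, 5)
    return(community_params(labels, .preset_r_neutral, alpha, assay_days))
  }
  alpha <- matrix(.preset_alpha_cross, 5, 5)
  diag(alpha) <- .preset_alpha_self
  if (name == "paper_like") {
    dimnames(alpha) <- list(labels, labels)
    alpha["V", c("A", "O", "P")] <- .preset_alpha_facil
    alpha["V", "S"] <- 0
  }
  community_params(labels, .preset_r_varied, alpha, assay_days)
}

#' Inoculation scheme
#'
#' Describes how total inocula are split between the resident and invading
#' groups. Defaults follow the standard assay: residents 16e6 CFU total,
#' invaders 16e4 CFU total (a 100-fold lower density), each group's total
#' divided equally among its members.
#'
#' @param resident_total Total resident inoculum, CFU (default `16e6`).
#' @param invader_total Total invader inoculum, CFU (default `16e4`).
#' @return A list of class `"inoculation_scheme"` with a computed
#'   `fold_ratio = resident_total/invader_total`.
#' @export
inoculation_scheme <- function(resident_total = 16e6, invader_total = 16e4) {
  if (resident_total <= 0 || invader_total <= 0) {
    stop("inoculum totals must be positive", call. = FALSE)
  }
  structure(list(resident_total = resident_total,
                 invader_total = invader_total,
                 fold_ratio = resident_total / invader_total),
            class = "inoculation_scheme")
}

#' Plate-count observation model
#'
#' Observed abundances emulate colony counting at a plating dilution: the
#' counted colonies are a Poisson draw with mean `final x
#' sampling_fraction`, scaled back to whole-culture CFU. Observations below
#' the detection limit are recorded as 0 and flagged below-detection.
#'
#' @param noise `"poisson"` (default) or `"none"` (observed = true final).
#' @param sampling_fraction Fraction of culture CFUs represented by counted
#'   colonies, in (0, 1]. Default `1e-4` (a typical plating dilution).
#' @param detection_limit Whole-culture CFU below which a species is
#'   recorded as undetected. Default `1e3` (roughly one colony at the
#'   default dilution).
#' @return A list of class `"observation_model"`.
#' @export
observation_model <- function(noise = c("poisson", "none"),
                              sampling_fraction = 1e-4,
                              detection_limit = 1e3) {
  noise <- match.arg(noise)
  if (!is.numeric(sampling_fraction) || length(sampling_fraction) != 1L ||
      sampling_fraction <= 0 || sampling_fraction > 1) {
    stop("sampling_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (detection_limit < 0) stop("detection_limit must be non-negative", call. = FALSE)
  structure(list(noise = noise, sampling_fraction = sampling_fraction,
                 detection_limit = detection_limit),
            class = "observation_model")
}
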