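#' Pipeline run configuration
#'
#' A fully serializable description of one end-to-end analysis run: design
#' options, simulator parameters (or paths to real count tables), the
#' observation model, analysis options and the master seed. The config is
#' written verbatim (YAML) into the output directory so a run can be
#' reproduced exactly.
#'
#' @param pool Species labels.
#' @param invader_richness Co-invasion invader richness range, `c(min, max)`.
#' @param resident_richness Single-invasion resident richness range.
#' @param replicates Replicates per treatment.
#' @param preset Simulator preset name (see [community_preset()]); ignored
#'   when `params` or count files are supplied.
#' @param params Optional explicit [community_params()].
#' @param resident_total,invader_total Inoculum totals, CFU.
#' @param noise,sampling_fraction,detection_limit Observation model (see
#'   [observation_model()]).
#' @param policy_method Below-detection policy (see [imputation_policy()]).
#' @param alpha,adjust Stability-testing options (see
#'   [classify_stability()]).
#' @param seed Master seed (integer).
#' @param counts_co,counts_single Optional paths to CFU-count CSVs; when
#'   given, the simulator stage is skipped and the files are ingested
#'   instead (same schema as [simulate_dataset()]).
#' @param out_dir Optional output directory; when non-`NULL`,
#'   [run_pipeline()] writes every stage table, the config and a run log
#'   there.
#' @return A list of class `"run_config"`.
#' @export
pipeline_config <- function(pool = c("A", "O", "P", "S", "V"),
                            invader_richness = c(2, 4),
                            resident_richness = c(1, 4),
                            replicates = 6,
                            preset = "stabilized",
                            params = NULL,
                            resident_total = 16e6,
                            invader_total = 16e4,
                            noise = "poisson",
                            sampling_fraction = 1e-4,
                            detection_limit = 1e3,
                            policy_method = "impute_at_limit",
                            alpha = 0.05,
                            adjust = "fdr",
                            seed = 1L,
                            counts_co = NULL,
                            counts_single = NULL,
                            out_dir = NULL) {
  cfg <- list(pool = as.character(pool),
              invader_richness = as.integer(invader_richness),
              resident_richness = as.integer(resident_richness),
              replicates = as.integer(replicates),
              preset = preset, params = params,
              resident_total = resident_total, invader_total = invader_total,
              noise = noise, sampling_fraction = sampling_fraction,
              detection_limit = detection_limit,
              policy_method = policy_method,
              alpha = alpha, adjust = adjust, seed = as.integer(seed),
              counts_co = counts_co, counts_single = counts_single,
              out_dir = out_dir)
  species_pool(cfg$pool)
  observation_model(cfg$noise, cfg$sampling_fraction, cfg$detection_limit)
  imputation_policy(cfg$policy_method, max(cfg$detection_limit, .Machine$double.eps))
  structure(cfg, class = "run_config")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A `"run_config"` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

## CSVs are written with numerics formatted to 10 significant digits so a
## rerun under the same config and seed is byte-identical.
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full invasion-stability pipeline
#'
#' Executes design enumeration, data generation (or ingestion of real
#' count tables), relative-growth-rate computation and the full stability
#' analysis, returning (and optionally writing) every stage output plus a
#' summary. Deterministic given the config and its seed.
#'
#' Stages: (1) enumerate the co- and single-invasion designs; (2) simulate
#' CFU counts under the configured gLV preset and observation model, or
#' read them from `counts_co`/`counts_single`; (3) compute RGR tables;
#' (4) classify stability per treatment within each invasion type;
#' (5) pair treatments on (focal, residents), compute per-treatment mean
#' RGRs, per-species rank correlations and the species-by-slope linear
#' model; (6) within-treatment invasion-type contrasts.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return A list of class `"invasion_run"` with elements `config`,
#'   `design_co`, `design_single`, `counts_co`, `counts_single`, `rgr_co`,
#'   `rgr_single`, `calls_co`, `calls_single`, `pairs`, `paired_means`,
#'   `correlations`, `comparison`, `contrasts`, `summary`.
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(replicates = 3, seed = 7))
#' run$summary$n_stable
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  pool <- species_pool(config$pool)

  design_co <- stage("design", design_co_invasion(pool, config$invader_richness,
                                                  config$replicates))
  design_single <- stage("design", design_single_invasion(pool, config$resident_richness,
                                                          config$replicates))
  params <- if (!is.null(config$params)) config$params else
    community_preset(config$preset)
  scheme <- inoculation_scheme(config$resident_total, config$invader_total)
  model <- observation_model(config$noise, config$sampling_fraction,
                             config$detection_limit)
  policy <- imputation_policy(config$policy_method, config$detection_limit)

  simulated <- is.null(config$counts_co)
  counts_co <- stage("simulate", if (simulated) {
    simulate_dataset(design_co, params, scheme, model, config$seed)
  } else {
    utils::read.csv(config$counts_co, stringsAsFactors = FALSE)
  })
  counts_single <- stage("simulate", if (is.null(config$counts_single)) {
    simulate_dataset(design_single, params, scheme, model, config$seed + 1L)
  } else {
    utils::read.csv(config$counts_single, stringsAsFactors = FALSE)
  })

  rgr_co <- stage("rgr", rgr_table(counts_co, design_co, policy))
  rgr_single <- stage("rgr", rgr_table(counts_single, design_single, policy))

  calls_co <- stage("analyze", classify_stability(rgr_co, config$alpha, config$adjust))
  calls_single <- stage("analyze", classify_stability(rgr_single, config$alpha,
                                                      config$adjust))
  pairs <- stage("analyze", pair_by_residents(design_co, design_single))
  paired_means <- stage("analyze", paired_mean_rgr(rgr_co, rgr_single))
  correlations <- stage("analyze", correlate_by_species(paired_means))
  comparison <- stage("analyze", fit_rgr_comparison(paired_means))
  paired_keys <- paste(pairs$focal[pairs$paired], pairs$residents[pairs$paired], sep = "|")
  both <- rbind(as.data.frame(rgr_co), as.data.frame(rgr_single))
  both <- both[paste(both$focal, both$residents, sep = "|") %in% paired_keys, ]
  contrasts <- stage("analyze", within_treatment_contrasts(both, alpha = config$alpha))

  summary <- list(
    n_treatments_co = nrow(design_co),
    n_treatments_single = nrow(design_single),
    n_paired = sum(pairs$paired),
    n_stable = sum(calls_co$stable),
    n_unstable = sum(!calls_co$stable & !calls_co$untestable),
    n_untestable = sum(calls_co$untestable),
    by_focal = summarize_by_focal(calls_co),
    correlations = correlations,
    common_slope = comparison$common_slope,
    n_significant_contrasts = sum(contrasts$significant)
  )

  run <- structure(list(config = config, design_co = design_co,
                        design_single = design_single, counts_co = counts_co,
                        counts_single = counts_single, rgr_co = rgr_co,
                        rgr_single = rgr_single, calls_co = calls_co,
                        calls_single = calls_single, pairs = pairs,
                        paired_means = paired_means, correlations = correlations,
                        comparison = comparison, contrasts = contrasts,
                        summary = summary),
                   class = "invasion_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_design(run$design_co, p("design_co.csv"))
  write_design(run$design_single, p("design_single.csv"))
  write_table_csv(run$counts_co, p("counts_co.csv"))
  write_table_csv(run$counts_single, p("counts_single.csv"))
  write_table_csv(run$rgr_co, p("rgr_co.csv"))
  write_table_csv(run$rgr_single, p("rgr_single.csv"))
  write_table_csv(run$calls_co, p("stability_calls.csv"))
  write_table_csv(run$correlations, p("species_correlations.csv"))
  write_table_csv(run$comparison$terms, p("model_terms.csv"))
  write_table_csv(run$contrasts, p("contrasts.csv"))
  cfg <- run$config
  cfg$params <- NULL   # explicit matrices do not round-trip through YAML
  cfg$out_dir <- NULL  # implied by the file's own location
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  log_lines <- c(
    paste0("alpha: ", cfg$alpha),
    paste0("adjustment: ", cfg$adjust),
    paste0("imputation policy: ", cfg$policy_method,
           " (detection limit ", cfg$detection_limit, " CFU)"),
    paste0("master seed: ", cfg$seed),
    paste0("stability-test family size (co): ", attr(run$calls_co, "family_size")),
    paste0("stability-test family size (single): ", attr(run$calls_single, "family_size")),
    paste0("correlation family size: ", sum(!is.na(run$correlations$p_raw))),
    paste0("contrast family size: ", nrow(run$contrasts))
  )
  writeLines(log_lines, p("run_log.txt"))
  invisible(out_dir)
}

#' Summarize stability calls per focal species
#'
#' Per-species bookkeeping of the stability verdicts: how many treatments
#' each species invaded, how many could be tested, how many were called
#' stable and how many were untestable. Denominators always equal the
#' species' treatment count in the design (14 per species in the default
#' five-species co-invasion design).
#'
#' @param calls A [classify_stability()] result.
#' @return Data frame: `focal`, `n_total`, `n_tested`, `n_stable`,
#'   `n_untestable`.
#' @export
summarize_by_focal <- function(calls) {
  if (nrow(calls) == 0L) stop("no stability calls to summarize", call. = FALSE)
  sp <- unique(calls$focal)
  out <- data.frame(
    focal = sp,
    n_total = vapply(sp, function(s) sum(calls$focal == s), 0L),
    n_tested = vapply(sp, function(s) sum(calls$focal == s & !calls$untestable), 0L),
    n_stable = vapply(sp, function(s) sum(calls$focal == s & calls$stable), 0L),
    n_untestable = vapply(sp, function(s) sum(calls$focal == s & calls$untestable), 0L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
print.invasion_run <- function(x, ...) {
  s <- x$summary
  cat("Invasion-stability pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  co-invasion design: ", s$n_treatments_co, " treatments; single-invasion: ",
      s$n_treatments_single, " (", s$n_paired, " paired)\n", sep = "")
  cat("  stability calls (co-invasion): ", s$n_stable, " stable, ",
      s$n_unstable, " unstable, ", s$n_untestable, " untestable\n", sep = "")
  bf <- s$by_focal
  for (i in seq_len(nrow(bf))) {
    cat("    ", bf$focal[i], ": ", bf$n_stable[i], " out of ", bf$n_total[i],
        " stable\n", sep = "")
  }
  cat("  common single-vs-co slope: ", signif(s$common_slope, 4), "\n", sep = "")
  cat("  significant within-treatment contrasts: ", s$n_significant_contrasts,
      " of ", nrow(x$contrasts), "\n", sep = "")
  invisible(x)
}
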