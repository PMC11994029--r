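#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1, returned in the input
#' order). Thin validated front-end to `stats::p.adjust(method = "BH")`.
#' Note BH is not idempotent in general; it is monotone (adjusted values
#' preserve the order of raw values).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA`s pass through).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.002, 0.01, 0.03, 0.04))  # 0.008 0.020 0.040 0.040
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("invalid input: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify community stability per treatment
#'
#' For each treatment group (one focal species x resident community x
#' invasion type), tests whether the mean relative invader growth rate
#' differs from 1 with a two-sided one-sample t-test, adjusts the resulting
#' p-values across all groups in the run by the false discovery rate
#' method, and calls a group *stable* when the mean RGR exceeds 1 AND the
#' adjusted p-value falls below `alpha`. Direction is read from the mean,
#' as is conventional: a significantly low mean is an unstable (failed)
#' invasion, not a stable one.
#'
#' Groups with fewer than 2 defined RGR values, or with zero within-group
#' variance, cannot be tested; they are reported as `untestable` (with the
#' mean shown) rather than dropped, so output rows always match the design.
#'
#' @param rgr An [rgr_table()] (or data frame with columns `treatment_id`,
#'   `focal`, `residents`, `invasion_type`, `rgr`).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"fdr"` (Benjamini-Hochberg, default) or `"none"`.
#' @return Data frame of class `"stability_calls"`, one row per group:
#'   `treatment_id`, `focal`, `residents`, `invasion_type`,
#'   `n_replicates` (defined RGR values used), `mean_rgr`, `t_statistic`,
#'   `df`, `p_raw`, `p_adjusted`, `stable`, `untestable`. Attributes
#'   `alpha`, `adjust` and `family_size` (number of tests adjusted
#'   together) record the testing family.
#' @examples
#' rgr <- data.frame(treatment_id = rep(c("t1", "t2"), each = 3),
#'                   focal = "A", residents = c("O"), invasion_type = "co",
#'                   rgr = c(1.1, 1.2, 1.3, 0.95, 1.0, 1.05))
#' classify_stability(rgr)
#' @export
classify_stability <- function(rgr, alpha = 0.05, adjust = c("fdr", "none")) {
  adjust <- match.arg(adjust)
  needed <- c("treatment_id", "focal", "residents", "invasion_type", "rgr")
  if (!all(needed %in% names(rgr))) {
    stop("rgr table needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  groups <- split(rgr, rgr$treatment_id)
  groups <- groups[unique(rgr$treatment_id)]   # keep input order
  rows <- lapply(groups, function(g) {
    vals <- g$rgr[is.finite(g$rgr)]
    n <- length(vals)
    mean_rgr <- if (n) mean(vals) else NA_real_
    testable <- n >= 2L && stats::sd(vals) > 0
    if (testable) {
      tt <- stats::t.test(vals, mu = 1, alternative = "two.sided")
      data.frame(treatment_id = g$treatment_id[1], focal = g$focal[1],
                 residents = g$residents[1], invasion_type = g$invasion_type[1],
                 n_replicates = n, mean_rgr = mean_rgr,
                 t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, untestable = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(treatment_id = g$treatment_id[1], focal = g$focal[1],
                 residents = g$residents[1], invasion_type = g$invasion_type[1],
                 n_replicates = n, mean_rgr = mean_rgr,
                 t_statistic = NA_real_, df = NA_real_, p_raw = NA_real_,
                 untestable = TRUE, stringsAsFactors = FALSE)
    }
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  calls$p_adjusted <- if (adjust == "fdr") bh_fdr(calls$p_raw) else calls$p_raw
  calls$stable <- !calls$untestable & !is.na(calls$mean_rgr) &
    calls$mean_rgr > 1 & !is.na(calls$p_adjusted) & calls$p_adjusted < alpha
  calls <- calls[, c("treatment_id", "focal", "residents", "invasion_type",
                     "n_replicates", "mean_rgr", "t_statistic", "df",
                     "p_raw", "p_adjusted", "stable", "untestable")]
  structure(calls, alpha = alpha, adjust = adjust,
            family_size = sum(!is.na(calls$p_raw)),
            class = c("stability_calls", "data.frame"))
}

#' @export
print.stability_calls <- function(x, ...) {
  cat("Stability calls: ", nrow(x), " groups (alpha = ", attr(x, "alpha"),
      ", adjustment = ", attr(x, "adjust"),
      ", family of ", attr(x, "family_size"), " tests)\n", sep = "")
  cat("  stable: ", sum(x$stable), "   unstable: ",
      sum(!x$stable & !x$untestable), "   untestable: ", sum(x$untestable),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.stability_calls <- function(object, ...) {
  out <- summarize_by_focal(object)
  cat("Stability calls by focal species:\n")
  print.data.frame(out, row.names = FALSE)
  invisible(out)
}

#' Mean RGR per treatment, paired across invasion types
#'
#' Averages defined replicate-level RGR values within each (focal, resident
#' community) for both datasets and joins them on the pairing of
#' [pair_by_residents()], giving the per-treatment means used by
#' [correlate_by_species()] and [fit_rgr_comparison()].
#'
#' @param rgr_co,rgr_single [rgr_table()]s for the co- and single-invasion
#'   assays.
#' @return Data frame: `species` (focal), `residents`, `mean_rgr_single`,
#'   `mean_rgr_co`, `n_single`, `n_co` (defined replicates per mean).
#'   Unpaired treatments are omitted.
#' @export
paired_mean_rgr <- function(rgr_co, rgr_single) {
  mean_by_group <- function(tab) {
    key <- paste(tab$focal, tab$residents, sep = "|")
    defined <- is.finite(tab$rgr)
    m <- tapply(tab$rgr[defined], key[defined], mean)
    n <- tapply(tab$rgr[defined], key[defined], length)
    data.frame(key = names(m), mean_rgr = as.numeric(m),
               n = as.integer(n), stringsAsFactors = FALSE)
  }
  co <- mean_by_group(rgr_co)
  single <- mean_by_group(rgr_single)
  hit <- match(co$key, single$key)
  keep <- !is.na(hit)
  parts <- strsplit(co$key[keep], "|", fixed = TRUE)
  data.frame(
    species = vapply(parts, `[`, "", 1L),
    residents = vapply(parts, `[`, "", 2L),
    mean_rgr_single = single$mean_rgr[hit[keep]],
    mean_rgr_co = co$mean_rgr[keep],
    n_single = single$n[hit[keep]],
    n_co = co$n[keep],
    stringsAsFactors = FALSE
  )
}

#' Per-species rank correlation of single- vs co-invasion growth rates
#'
#' For each species, Spearman's rank correlation between the treatment mean
#' RGR under single invasion and under co-invasion, with average ranks on
#' ties and the asymptotic t-approximation for the p-value (the null is
#' independence, i.e. rho = 0; `stats::cor.test(method = "spearman",
#' exact = FALSE)`). P-values are FDR-adjusted across species.
#'
#' @param paired_means Output of [paired_mean_rgr()] (columns `species`,
#'   `mean_rgr_single`, `mean_rgr_co`).
#' @return Data frame: `species`, `n_pairs`, `rho`, `p_raw`, `p_adjusted`,
#'   `note` (`"ok"`, `"too_few_pairs"` or `"constant_input"`).
#' @export
correlate_by_species <- function(paired_means) {
  sp <- unique(paired_means$species)
  rows <- lapply(sp, function(s) {
    d <- paired_means[paired_means$species == s, ]
    x <- d$mean_rgr_single
    y <- d$mean_rgr_co
    if (nrow(d) < 3L) {
      return(data.frame(species = s, n_pairs = nrow(d), rho = NA_real_,
                        p_raw = NA_real_, note = "too_few_pairs",
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(species = s, n_pairs = nrow(d), rho = NA_real_,
                        p_raw = NA_real_, note = "constant_input",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(species = s, n_pairs = nrow(d), rho = unname(ct$estimate),
               p_raw = ct$p.value, note = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_raw)
  out[, c("species", "n_pairs", "rho", "p_raw", "p_adjusted", "note")]
}

#' Linear model of co-invasion on single-invasion growth rates
#'
#' Fits ordinary least squares of the co-invasion treatment mean RGR on the
#' single-invasion mean crossed with species identity, and tests terms by
#' nested-model comparisons: the single:species interaction against the
#' additive model, then (from the additive model) the common slope and the
#' species intercepts. For Gaussian OLS the residual-sum-of-squares F-test
#' is the exact small-sample form of the likelihood-ratio comparison; the
#' chi-squared LRT is available as an option. A common slope of 1 with
#' zero species offsets is the 1-1 line expected if single invasions
#' predicted co-invasion growth rates exactly.
#'
#' @param paired_means Output of [paired_mean_rgr()]; needs at least 2
#'   species with at least 3 paired points each.
#' @param test `"F"` (default, nested F on residual sums of squares) or
#'   `"LRT"` (chi-squared likelihood ratio).
#' @return Object of class `"rgr_comparison"`: list with `terms` (one row
#'   per tested term: df pair, statistic, p), `common_slope`, `intercepts`
#'   (per species, from the additive model), the fitted `lm` objects
#'   (`full`, `additive`) and `data`. Methods: `print`, `summary`, `coef`,
#'   `plot`.
#' @export
fit_rgr_comparison <- function(paired_means, test = c("F", "LRT")) {
  test <- match.arg(test)
  d <- data.frame(
    y = paired_means$mean_rgr_co,
    x = paired_means$mean_rgr_single,
    species = factor(paired_means$species)
  )
  if (nlevels(d$species) < 2L) stop("need at least 2 species", call. = FALSE)
  if (any(table(d$species) < 3L)) {
    stop("need at least 3 paired points per species", call. = FALSE)
  }
  full <- stats::lm(y ~ x * species, data = d)
  if (anyNA(stats::coef(full))) {
    aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("collinear design: aliased term(s) ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  additive <- stats::lm(y ~ x + species, data = d)
  no_slope <- stats::lm(y ~ species, data = d)
  no_species <- stats::lm(y ~ x, data = d)
  cmp <- function(small, big, label) {
    if (test == "F") {
      a <- stats::anova(small, big)
      data.frame(term = label, df1 = a$Df[2], df2 = a$Res.Df[2],
                 statistic = a$F[2], p = a$`Pr(>F)`[2],
                 stringsAsFactors = FALSE)
    } else {
      df1 <- length(stats::coef(big)) - length(stats::coef(small))
      lr <- 2 * (as.numeric(stats::logLik(big)) - as.numeric(stats::logLik(small)))
      data.frame(term = label, df1 = df1, df2 = NA_real_, statistic = lr,
                 p = stats::pchisq(lr, df1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }
  }
  terms <- rbind(
    cmp(additive, full, "single:species interaction"),
    cmp(no_slope, additive, "single-invasion slope"),
    cmp(no_species, additive, "species intercepts")
  )
  cf <- stats::coef(additive)
  base <- cf["(Intercept)"]
  lev <- levels(d$species)
  intercepts <- stats::setNames(
    base + c(0, cf[paste0("species", lev[-1])]), lev)
  structure(list(terms = terms, common_slope = unname(cf["x"]),
                 intercepts = intercepts, full = full, additive = additive,
                 test = test, data = d),
            class = "rgr_comparison")
}

#' @export
print.rgr_comparison <- function(x, ...) {
  cat("Single- vs co-invasion growth-rate comparison (", nrow(x$data),
      " paired treatment means, ", nlevels(x$data$species), " species)\n",
      sep = "")
  cat("  common slope (additive model): ", signif(x$common_slope, 4),
      "   [1 would be the 1-1 line]\n", sep = "")
  cat("  term tests (", if (x$test == "F") "nested F" else "chi-squared LRT",
      "):\n", sep = "")
  tt <- x$terms
  for (i in seq_len(nrow(tt))) {
    dfs <- if (is.na(tt$df2[i])) paste0("df = ", tt$df1[i]) else
      paste0("df = ", tt$df1[i], ",", tt$df2[i])
    cat(sprintf("    %-28s %s  stat = %.4g  p = %.4g\n",
                tt$term[i], dfs, tt$statistic[i], tt$p[i]))
  }
  invisible(x)
}

#' @export
coef.rgr_comparison <- function(object, ...) {
  c(slope = object$common_slope, object$intercepts)
}

#' @export
summary.rgr_comparison <- function(object, ...) {
  print(object)
  cat("  per-species intercepts:\n")
  print(signif(object$intercepts, 4))
  invisible(object)
}

#' Within-treatment single- vs co-invasion contrasts
#'
#' Fits the replicate-level factorial model `rgr ~ treatment x
#' invasion_type` (treatment = focal species x resident community) by least
#' squares, reports the global interaction F-statistic, and computes one
#' invasion-type contrast (co minus single cell mean) per paired treatment
#' from the factorial model's pooled residual variance, with
#' Benjamini-Hochberg adjustment across contrasts by default (Bonferroni
#' optional).
#'
#' @param rgr Replicate-level RGR data frame for the paired treatments:
#'   columns `focal`, `residents`, `invasion_type` (`"single"`/`"co"`) and
#'   `rgr`. Treatments lacking both invasion types with at least 2 defined
#'   replicates each are excluded with a warning.
#' @param adjust `"fdr"` (default) or `"bonferroni"`.
#' @param alpha Significance level for the `significant` column.
#' @return Data frame of class `"contrast_table"`, one row per paired
#'   treatment: `focal`, `residents`, `mean_single`, `mean_co`,
#'   `difference` (co - single), `se`, `t_statistic`, `df`, `p_raw`,
#'   `p_adjusted`, `significant`. Attribute `interaction` holds the global
#'   treatment x invasion-type test (`F`, `df1`, `df2`, `p`).
#' @export
within_treatment_contrasts <- function(rgr, adjust = c("fdr", "bonferroni"),
                                       alpha = 0.05) {
  adjust <- match.arg(adjust)
  needed <- c("focal", "residents", "invasion_type", "rgr")
  if (!all(needed %in% names(rgr))) {
    stop("rgr table needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  d <- rgr[is.finite(rgr$rgr), needed]
  d$key <- paste(d$focal, d$residents, sep = "|")
  tab <- table(d$key, d$invasion_type)
  ok <- if (!all(c("co", "single") %in% colnames(tab))) character(0) else
    rownames(tab)[tab[, "co"] >= 2 & tab[, "single"] >= 2]
  dropped <- setdiff(unique(d$key), ok)
  if (length(dropped)) {
    warning("excluding unpaired/under-replicated treatment(s): ",
            paste(dropped, collapse = "; "), call. = FALSE)
  }
  if (!length(ok)) stop("no fully paired treatments to contrast", call. = FALSE)
  d <- d[d$key %in% ok, ]
  d$key <- factor(d$key, levels = ok)
  d$invasion_type <- factor(d$invasion_type, levels = c("single", "co"))
  full <- stats::lm(rgr ~ key * invasion_type, data = d)
  additive <- stats::lm(rgr ~ key + invasion_type, data = d)
  a <- stats::anova(additive, full)
  interaction <- list(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
                      p = a$`Pr(>F)`[2])
  s2 <- sum(stats::residuals(full)^2) / stats::df.residual(full)
  dfr <- stats::df.residual(full)
  rows <- lapply(ok, function(k) {
    dk <- d[d$key == k, ]
    m_co <- mean(dk$rgr[dk$invasion_type == "co"])
    m_single <- mean(dk$rgr[dk$invasion_type == "single"])
    n_co <- sum(dk$invasion_type == "co")
    n_single <- sum(dk$invasion_type == "single")
    se <- sqrt(s2 * (1 / n_co + 1 / n_single))
    tstat <- (m_co - m_single) / se
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(focal = parts[1], residents = parts[2],
               mean_single = m_single, mean_co = m_co,
               difference = m_co - m_single, se = se, t_statistic = tstat,
               df = dfr, p_raw = 2 * stats::pt(-abs(tstat), dfr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "fdr") bh_fdr(out$p_raw) else
    pmin(out$p_raw * nrow(out), 1)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  structure(out, interaction = interaction, adjust = adjust, alpha = alpha,
            class = c("contrast_table", "data.frame"))
}

#' @export
print.contrast_table <- function(x, ...) {
  it <- attr(x, "interaction")
  cat("Within-treatment invasion-type contrasts: ", nrow(x), " paired treatments\n",
      sep = "")
  cat(sprintf("  global treatment x invasion-type interaction: F(%d, %d) = %.4g, p = %.4g\n",
              it$df1, it$df2, it$F, it$p))
  cat("  significant contrasts (", attr(x, "adjust"), ", alpha = ",
      attr(x, "alpha"), "): ", sum(x$significant), "\n", sep = "")
  invisible(x)
}
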