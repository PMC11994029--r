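test_that("BH adjustment matches the hand-executed step-up", {
  expect_equal(bh_fdr(c(0.002, 0.01, 0.03, 0.04)), c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.03), 0.03)                 # m = 1: unchanged
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))   # all equal: monotone cap
  expect_error(bh_fdr(c(0.5, 1.2)), "invalid input")
  expect_error(bh_fdr(c(-0.1, 0.5)), "invalid input")
})

test_that("BH equals the brute-force step-up on random vectors and is monotone", {
  set.seed(2024)
  for (i in 1:2000) {
    m <- sample(1:40, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))  # rounding induces ties
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # monotone: adjusted values preserve the order of raw values
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("one-sample t matches the closed form to 1e-12", {
  set.seed(7)
  for (i in 1:1000) {
    x <- rnorm(sample(3:30, 1), mean = runif(1, 0.5, 2), sd = runif(1, 0.01, 1))
    tt <- t.test(x, mu = 1)
    orc <- oracle_t(x, 1)
    expect_equal(unname(tt$statistic), orc$statistic, tolerance = 1e-12)
    expect_equal(tt$p.value, orc$p, tolerance = 1e-12)
  }
})

test_that("stability calls test each group once against 1 with FDR control", {
  set.seed(31)
  d <- design_co_invasion(replicates = 6)
  rgr <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    data.frame(treatment_id = d$treatment_id[i], focal = d$focal[i],
               residents = d$residents[i], invasion_type = "co",
               rgr = rnorm(6, mean = 1.6, sd = 0.3), stringsAsFactors = FALSE)
  }))
  calls <- classify_stability(rgr, alpha = 0.05)
  expect_equal(nrow(calls), 70)
  expect_equal(attr(calls, "family_size"), 70)
  expect_equal(calls$p_adjusted, bh_fdr(calls$p_raw))
  expect_true(all(calls$p_adjusted >= calls$p_raw - 1e-15))
  # frozen hand case: values 1.1, 1.2, 1.3 give t = 3.4641 on df = 2
  one <- classify_stability(data.frame(treatment_id = "g", focal = "A",
                                       residents = "O", invasion_type = "co",
                                       rgr = c(1.1, 1.2, 1.3)))
  expect_equal(one$mean_rgr, 1.2)
  expect_equal(one$t_statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(one$df, 2)
})

test_that("stability verdict needs both mean > 1 and adjusted significance", {
  base <- data.frame(treatment_id = rep(c("hi", "lo", "flat"), each = 4),
                     focal = "A", residents = "O", invasion_type = "co",
                     rgr = c(1.5, 1.6, 1.55, 1.45,      # clearly above 1
                             0.5, 0.45, 0.55, 0.5,      # clearly below 1
                             1.0, 1.0, 1.0, 1.0))       # zero variance
  calls <- classify_stability(base)
  expect_true(calls$stable[calls$treatment_id == "hi"])
  expect_false(calls$stable[calls$treatment_id == "lo"])  # significant but mean < 1
  expect_false(calls$p_adjusted[calls$treatment_id == "lo"] > 0.05)
  flat <- calls[calls$treatment_id == "flat", ]
  expect_true(flat$untestable)       # zero variance: untestable, mean reported
  expect_false(flat$stable)
  expect_equal(flat$mean_rgr, 1)
  # all-missing group is untestable, not dropped
  calls2 <- classify_stability(rbind(base, data.frame(
    treatment_id = "gone", focal = "A", residents = "P", invasion_type = "co",
    rgr = c(NA_real_, NA_real_, NA_real_, NA_real_))))
  expect_equal(nrow(calls2), 4)
  expect_true(calls2$untestable[calls2$treatment_id == "gone"])
})

test_that("Spearman correlations match the rank-then-Pearson oracle with ties", {
  set.seed(15)
  for (i in 1:500) {
    n <- sample(4:25, 1)
    x <- round(runif(n), sample(1:3, 1))
    y <- round(x * runif(1, -2, 2) + rnorm(n, 0, 0.3), sample(1:3, 1))
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(unname(ct$estimate), oracle_spearman(x, y), tolerance = 1e-12)
  }
  pm <- data.frame(species = rep(c("up", "down"), each = 3),
                   mean_rgr_single = c(1, 2, 3, 1, 2, 3),
                   mean_rgr_co = c(2, 4, 6, 3, 2, 1))
  res <- correlate_by_species(pm)
  expect_equal(res$rho[res$species == "up"], 1)
  expect_equal(res$rho[res$species == "down"], -1)
  expect_equal(res$p_adjusted, bh_fdr(res$p_raw))
  # constant input is flagged, not an error
  pm2 <- data.frame(species = "flat", mean_rgr_single = c(1, 1, 1),
                    mean_rgr_co = c(1, 2, 3))
  expect_equal(correlate_by_species(pm2)$note, "constant_input")
})

test_that("five species with 14 pairs each give five correlations", {
  set.seed(8)
  pm <- data.frame(species = rep(c("A", "O", "P", "S", "V"), each = 14),
                   mean_rgr_single = runif(70, 0.5, 3),
                   mean_rgr_co = runif(70, 0.5, 3))
  res <- correlate_by_species(pm)
  expect_equal(nrow(res), 5)
  expect_equal(res$n_pairs, rep(14L, 5))
  expect_true(all(res$rho >= -1 & res$rho <= 1))
})

test_that("interaction model recovers exact generative parameters", {
  species <- rep(c("A", "O", "P", "S", "V"), each = 14)
  offsets <- c(A = 0.2, O = -0.1, P = 0.05, S = 0.4, V = -0.3)
  set.seed(3)
  x <- runif(70, 0.5, 3)
  # exact common slope 0.5 with species offsets, no noise
  pm <- data.frame(species = species, mean_rgr_single = x,
                   mean_rgr_co = 0.5 * x + offsets[species])
  fit <- fit_rgr_comparison(pm)
  expect_equal(fit$common_slope, 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$intercepts), unname(offsets), tolerance = 1e-8)
  # the additive model already fits perfectly: the interaction adds nothing
  expect_lt(sum(residuals(fit$additive)^2), 1e-12)
  expect_lte(sum(residuals(fit$additive)^2) - sum(residuals(fit$full)^2), 1e-12)
  # y identical to x: the 1-1 line, slope 1, all offsets 0
  pm2 <- data.frame(species = species, mean_rgr_single = x, mean_rgr_co = x)
  fit2 <- fit_rgr_comparison(pm2)
  expect_equal(fit2$common_slope, 1, tolerance = 1e-10)
  expect_equal(max(abs(fit2$intercepts)), 0, tolerance = 1e-10)
  # coef method exposes slope + intercepts
  expect_equal(unname(coef(fit)["slope"]), 0.5, tolerance = 1e-8)
})

test_that("species-specific slopes are detected by the interaction test", {
  set.seed(41)
  species <- rep(c("A", "O", "P", "S", "V"), each = 14)
  slopes <- c(A = 0.2, O = 0.6, P = 1.0, S = 1.4, V = 1.8)
  x <- runif(70, 0.5, 3)
  pm <- data.frame(species = species, mean_rgr_single = x,
                   mean_rgr_co = slopes[species] * x + rnorm(70, 0, 0.1))
  fit <- fit_rgr_comparison(pm)
  p_int <- fit$terms$p[fit$terms$term == "single:species interaction"]
  expect_lt(p_int, 0.05)
  # the chi-squared LRT variant agrees qualitatively
  fit_lrt <- fit_rgr_comparison(pm, test = "LRT")
  expect_lt(fit_lrt$terms$p[1], 0.05)
})

test_that("nested-F layout reproduces the factorial degrees of freedom", {
  set.seed(5)
  pm <- data.frame(species = rep(c("A", "O", "P", "S", "V"), each = 14),
                   mean_rgr_single = runif(70), mean_rgr_co = runif(70))
  fit <- fit_rgr_comparison(pm)
  tt <- fit$terms
  expect_equal(tt$df1, c(4, 1, 4))
  expect_equal(tt$df2, c(60, 64, 64))   # 70 points, 10- and 6-parameter models
})

test_that("collinear and undersized comparison inputs error informatively", {
  pm <- data.frame(species = rep("A", 5), mean_rgr_single = 1:5,
                   mean_rgr_co = 1:5)
  expect_error(fit_rgr_comparison(pm), "at least 2 species")
  pm2 <- data.frame(species = c("A", "A", "A", "B", "B"),
                    mean_rgr_single = 1:5, mean_rgr_co = 1:5)
  expect_error(fit_rgr_comparison(pm2), "at least 3")
  pm3 <- data.frame(species = rep(c("A", "B"), each = 3),
                    mean_rgr_single = c(1, 1, 1, 2, 2, 2),   # constant within species
                    mean_rgr_co = rnorm(6))
  expect_error(fit_rgr_comparison(pm3), "collinear")
})

test_that("within-treatment contrasts flag exactly a planted effect", {
  set.seed(12)
  d <- design_co_invasion(replicates = 6)
  keys <- paste(d$focal, d$residents)
  make_rows <- function(type) do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    data.frame(focal = d$focal[i], residents = d$residents[i],
               invasion_type = type, rgr = rnorm(6, 1.5, 0.1),
               stringsAsFactors = FALSE)
  }))
  rgr <- rbind(make_rows("co"), make_rows("single"))
  # plant a +10 SD shift in one treatment's co-invasion values
  target <- rgr$focal == "V" & rgr$residents == "AP" & rgr$invasion_type == "co"
  rgr$rgr[target] <- rgr$rgr[target] + 1.0
  ct <- within_treatment_contrasts(rgr)
  expect_equal(nrow(ct), 70)
  hits <- ct[ct$significant, ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$focal, "V")
  expect_equal(hits$residents, "AP")
  expect_gt(hits$difference, 0.8)
  it <- attr(ct, "interaction")
  expect_equal(it$df1, 69)
  expect_equal(it$df2, 840 - 140)   # 70 pairs x 2 types x 6 reps, 140 cells
})

test_that("identical invasion types give zero contrasts and unpaired rows warn", {
  d <- design_co_invasion(species_pool(LETTERS[1:4]), c(2, 2), replicates = 3)
  rows <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    vals <- c(1.2, 1.4, 1.6)
    rbind(data.frame(focal = d$focal[i], residents = d$residents[i],
                     invasion_type = "co", rgr = vals),
          data.frame(focal = d$focal[i], residents = d$residents[i],
                     invasion_type = "single", rgr = vals))
  }))
  ct <- within_treatment_contrasts(rows)
  expect_true(all(ct$difference == 0))
  expect_true(all(!ct$significant))
  # a treatment missing its single arm is excluded with a warning naming it
  rows2 <- rows[!(rows$focal == "A" & rows$residents == "CD" &
                    rows$invasion_type == "single"), ]
  expect_warning(ct2 <- within_treatment_contrasts(rows2), "A\\|CD")
  expect_equal(nrow(ct2), nrow(ct) - 1)
})
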