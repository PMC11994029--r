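test_that("batch dynamics reduce to known closed forms", {
  # no dynamics: r = 0, alpha = 0 leaves the inoculum untouched
  p0 <- community_params(c("X", "Y"), r = c(0, 0), alpha = matrix(0, 2, 2))
  expect_equal(unname(simulate_batch(p0, c(100, 200))), c(100, 200),
               tolerance = 1e-8)
  # single-species logistic: N(t) = K / (1 + (K/N0 - 1) exp(-rt))
  r <- 1.1; a <- -1e-7; K <- -r / a; N0 <- 1e3; days <- 30
  p1 <- community_params("X", r = r, alpha = matrix(a, 1, 1), assay_days = days)
  closed <- K / (1 + (K / N0 - 1) * exp(-r * days))
  expect_equal(unname(simulate_batch(p1, N0)), closed, tolerance = 1e-6)
  expect_lt(abs(simulate_batch(p1, N0) - K) / K, 0.01)  # long assay reaches K
  # exchangeability: identical species with equal inocula finish equal
  p2 <- community_params(c("X", "Y"), r = c(1, 1),
                         alpha = matrix(c(-1e-7, -3e-8, -3e-8, -1e-7), 2, 2),
                         assay_days = 7)
  fin <- simulate_batch(p2, c(5e4, 5e4))
  expect_equal(fin[["X"]], fin[["Y"]], tolerance = 1e-9)
})

test_that("trajectories stay non-negative and absent species stay absent", {
  p <- community_preset("paper_like")
  inoc <- c(A = 4e6, O = 4e6, P = 4e6, S = 0, V = 16e4)
  fin <- simulate_batch(p, inoc, trajectory = TRUE)
  traj <- attr(fin, "trajectory")
  expect_true(all(traj[, -1] >= 0))           # dense output, all species
  expect_true(all(traj[, "S"] == 0))          # zero inoculum stays at zero
  expect_equal(fin[["S"]], 0)
  expect_true(all(fin[c("A", "O", "P", "V")] > 0))
})

test_that("ill-posed interactions raise a divergence error naming parameters", {
  p <- community_params(c("X", "Y"), r = c(2, 2),
                        alpha = matrix(c(1e-5, 1e-5, 1e-5, 1e-5), 2, 2),
                        assay_days = 7)
  expect_error(simulate_batch(p, c(1e4, 1e4)), "dynamics diverged.*alpha")
})

test_that("inoculation splits group totals equally at the configured ratio", {
  scheme <- inoculation_scheme()
  expect_equal(scheme$fold_ratio, 100)
  d <- design_co_invasion()
  # 4 residents, 1 invader is not in the co design; build it from the single design
  ds <- design_single_invasion(resident_richness = c(4, 4))
  inoc <- inoculate(ds[ds$focal == "V", ], scheme)
  expect_equal(unname(inoc[c("A", "O", "P", "S")]), rep(4e6, 4))
  expect_equal(inoc[["V"]], 16e4)
  # 2 residents, 3 invaders
  i <- which(d$residents == "AO" & d$focal == "P")
  inoc2 <- inoculate(d[i, ], scheme)
  expect_equal(unname(inoc2[c("A", "O")]), rep(8e6, 2))
  expect_equal(unname(inoc2[c("P", "S", "V")]), rep(16e4 / 3, 3))
  expect_equal(sum(inoc2), 16e6 + 16e4)
  # equal totals, one of each role
  sc <- inoculation_scheme(1e4, 1e4)
  d2 <- design_co_invasion(species_pool(c("X", "Y")), c(1, 1))
  expect_equal(unname(inoculate(d2[1, ], sc, c("X", "Y"))), c(1e4, 1e4))
})

test_that("observation model is the identity without noise and unbiased with it", {
  final <- c(A = 5e6, B = 0)
  m0 <- observation_model("none", detection_limit = 0)
  obs <- observe(final, m0)
  expect_equal(obs$observed, final)
  expect_false(obs$below_detection[["A"]])
  expect_true(obs$below_detection[["B"]])   # true zero is below detection
  expect_equal(obs$observed[["B"]], 0)
  # Poisson draws recover the true mean within 3 standard errors
  f <- 1e-3; N <- 2e6; n_seeds <- 400
  mp <- observation_model("poisson", sampling_fraction = f, detection_limit = 0)
  draws <- vapply(seq_len(n_seeds),
                  function(s) observe(c(X = N), mp, seed = s)$observed[["X"]], 0)
  se <- sqrt(N / f / n_seeds)   # var(obs) = N/f for Poisson counts
  expect_lt(abs(mean(draws) - N), 3 * se)
  # variance/mean of the counted colonies is ~1 (Poisson), so var(obs)*f/N ~ 1
  expect_lt(abs(var(draws) * f / N - 1), 3 * sqrt(2 / n_seeds))
  expect_error(observation_model(sampling_fraction = 0), "0, 1")
  expect_error(observation_model(sampling_fraction = 2), "0, 1")
})

test_that("dataset generation is deterministic and has design arithmetic shape", {
  d <- design_co_invasion(replicates = 6)
  params <- community_preset("stabilized")
  a <- simulate_dataset(d, params, master_seed = 99)
  expect_equal(nrow(a), 70 * 6 * 5)   # every species present in every co treatment
  b <- simulate_dataset(d[rev(seq_len(nrow(d))), ], params, master_seed = 99)
  b <- b[order(match(b$treatment_id, a$treatment_id), b$replicate, b$species), ]
  rownames(b) <- NULL
  expect_identical(a, b)              # seed derivation is order-independent
  # tiny design: 1 resident + 1 invader -> 2 rows per replicate
  d2 <- design_co_invasion(species_pool(c("X", "Y")), c(1, 1), replicates = 1)
  p2 <- community_params(c("X", "Y"), c(1, 1), matrix(-1e-8, 2, 2))
  expect_equal(nrow(simulate_dataset(d2[1, ], p2, master_seed = 1)), 2)
  expect_error(simulate_dataset(d[0, ], params), "empty")
})

test_that("presets encode the documented interaction structure", {
  n <- community_preset("neutral")
  expect_true(all(n$alpha == n$alpha[1, 1]))          # rows all identical
  s <- community_preset("stabilized")
  off <- s$alpha[row(s$alpha) != col(s$alpha)]
  expect_true(all(abs(diag(s$alpha)) > abs(off)))     # self-limitation dominates
  expect_true(all(off < 0))
  p <- community_preset("paper_like")
  pos <- which(p$alpha > 0, arr.ind = TRUE)
  expect_equal(nrow(pos), 3)                          # exactly 3 facilitative links
  expect_true(all(rownames(p$alpha)[pos[, 1]] == "V"))
  expect_setequal(colnames(p$alpha)[pos[, 2]], c("A", "O", "P"))
  expect_equal(p$alpha["V", "S"], 0)
  expect_error(community_preset("bogus"))
})

test_that("replicate seeds are stable, spread out and within integer range", {
  s1 <- replicate_seed(42, "V_into_AP_with_OS", 3)
  expect_identical(s1, replicate_seed(42, "V_into_AP_with_OS", 3))
  expect_true(s1 >= 0 && s1 < 2^31)
  ids <- design_co_invasion()$treatment_id
  seeds <- vapply(ids, function(id) replicate_seed(1, id, 1), 0L)
  expect_false(anyDuplicated(seeds) > 0)
})
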