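# Independent brute-force oracles. These deliberately share no code with
# the package internals they check.

# BH step-up by the textbook definition: q_(i) = min_{j >= i} p_(j)*m/j,
# capped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / seq(i, m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# One-sample t statistic from the closed form (xbar - mu) / (s / sqrt(n)).
oracle_t <- function(x, mu = 1) {
  n <- length(x)
  tstat <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(statistic = tstat, df = n - 1,
       p = 2 * pt(-abs(tstat), n - 1))
}

# Spearman rho as Pearson correlation of average ranks (handles ties).
oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# Straight-line reimplementation of the RGR computation: for each design
# row and replicate, focal rate from its own row, community rate from the
# summed densities of every other row, ratio of the two.
oracle_rgr <- function(counts, design, detection_limit = 1e3) {
  out <- list()
  for (i in seq_len(nrow(design))) {
    id <- design$treatment_id[i]
    focal <- design$focal[i]
    sub <- counts[counts$treatment_id == id, ]
    for (rep_i in sort(unique(sub$replicate))) {
      obs <- sub[sub$replicate == rep_i, ]
      t <- obs$assay_days[1] / 7
      fr <- obs[obs$species == focal & obs$role == "invader", ]
      n1 <- if (fr$N1 == 0) detection_limit else fr$N1
      m_f <- log(n1 / fr$N0) / t
      rest <- obs[!(obs$species == focal & obs$role == "invader"), ]
      m_c <- log(sum(rest$N1) / sum(rest$N0)) / t
      rgr <- if (is.finite(m_c) && m_c > 0) m_f / m_c else NA_real_
      out[[length(out) + 1]] <- data.frame(treatment_id = id, replicate = rep_i,
                                           rgr = rgr)
    }
  }
  do.call(rbind, out)
}

# Brute-force co-invasion enumeration: loop over all subsets of the pool,
# keep those in the richness window, one treatment per (subset, focal).
oracle_co_count <- function(n, kmin, kmax) {
  count <- 0
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    k <- length(members)
    if (k >= kmin && k <= kmax) count <- count + k
  }
  count
}

# Tiny counts-table builder for hand-computed growth-rate cases.
make_counts <- function(treatment_id, species, role, N0, N1, replicate = 1,
                        assay_days = 7) {
  data.frame(treatment_id = treatment_id, replicate = replicate,
             species = species, role = role, N0 = N0, N1 = N1,
             below_detection = N1 == 0, assay_days = assay_days,
             stringsAsFactors = FALSE)
}

# Random small CFU tables (plus matching designs) for equivalence checks.
random_small_dataset <- function(seed) {
  set.seed(seed)
  pool <- species_pool(LETTERS[1:4])
  design <- design_co_invasion(pool, c(2, 2), replicates = 2)
  design <- design[sample(nrow(design), 3), ]
  counts <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    tr <- design[i, ]
    do.call(rbind, lapply(1:2, function(rep_i) {
      n0 <- round(runif(4, 50, 5000))
      n1 <- round(runif(4, 0, 5e5))
      if (runif(1) < 0.1) n1[1] <- 0   # occasional below-detection focal
      sp <- c(tr$focal, strsplit(tr$co_invaders, "")[[1]],
              strsplit(tr$residents, "")[[1]])
      make_counts(tr$treatment_id, sp,
                  c("invader", "invader", "resident", "resident"),
                  n0, n1, replicate = rep_i)
    }))
  }))
  list(design = design, counts = counts)
}
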