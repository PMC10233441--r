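# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: AUROC by exhaustive pair counting, life-table
# quantities by literal step-by-step arithmetic, and lifetimes by direct
# hazard simulation.

# AUROC as the probability a random positive outranks a random negative
# (ties count 1/2), by exhaustive enumeration of all pairs.
oracle_auroc_pairs <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Spreadsheet-style abridged life-table computation: scalar loop over
# groups, no vectorized shortcuts shared with the package.
oracle_life_table_e0 <- function(mx, start, width, a0 = 0.3, radix = 1e5) {
  k <- length(mx)
  l <- radix
  Ls <- numeric(k)
  for (i in seq_len(k)) {
    if (i < k) {
      n <- width[i]
      a <- if (i == 1 && n == 1) a0 else n / 2
      q <- n * mx[i] / (1 + (n - a) * mx[i])
      d <- l * q
      Ls[i] <- n * (l - d) + a * d
      l <- l - d
    } else {
      Ls[i] <- l / mx[i]
    }
  }
  sum(Ls) / radix
}

# Mean lifetime under a piecewise-constant hazard: each person walks the
# age groups drawing exponential waiting times.
oracle_simulated_e0 <- function(mx, start, width, n = 2e5, seed = 1) {
  set.seed(seed)
  k <- length(mx)
  alive <- rep(TRUE, n)
  lifetime <- numeric(n)
  for (i in seq_len(k)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    t <- rexp(length(idx), rate = mx[i])
    if (is.finite(width[i])) {
      dies <- t < width[i]
      lifetime[idx[dies]] <- start[i] + t[dies]
      alive[idx[dies]] <- FALSE
    } else {
      lifetime[idx] <- start[i] + t
      alive[idx] <- FALSE
    }
  }
  mean(lifetime)
}

# Sullivan's sum written as an explicit loop.
oracle_hly0 <- function(Lx, lx, pi) {
  total <- 0
  for (i in seq_along(Lx)) total <- total + Lx[i] * (1 - pi[i])
  total / lx[1]
}

# Analytic marginal prevalence of one disease under the generator's
# age/sex distribution, by direct numeric summation.
oracle_marginal_prevalence <- function(baseline, age_slope, female_shift,
                                       age_probs, p_female) {
  total <- 0
  for (i in seq_len(nrow(age_probs))) {
    for (female in c(0, 1)) {
      w <- age_probs$prob[i] * (if (female == 1) p_female else 1 - p_female)
      total <- total +
        w * plogis(baseline + age_slope * age_probs$age[i] +
                     female_shift * female)
    }
  }
  total
}

# small default-configuration population for reuse
small_population <- function(n = 2000, seed = 11, ...) {
  generate_population(generator_config(n, seed = seed, ...))
}
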