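toy_scheme <- tibble::tibble(start = c(0, 50, 80), width = c(50, 30, Inf))
toy_mx <- c(0.002, 0.02, 0.1)

test_that("abridged life-table columns satisfy the defining identities", {
  lt <- build_life_table(toy_mx, scheme = toy_scheme)
  expect_equal(lt$lx[1], 1e5)
  expect_true(all(diff(lt$lx) <= 0))
  expect_true(all(lt$dx >= 0))
  expect_equal(lt$dx[-nrow(lt)], -diff(lt$lx))
  expect_equal(lt$Tx, rev(cumsum(rev(lt$Lx))))
  expect_equal(lt$ex, lt$Tx / lt$lx)
  expect_equal(lt$qx[nrow(lt)], 1)
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
})

test_that("toy-table life expectancy matches step-by-step arithmetic", {
  lt <- build_life_table(toy_mx, scheme = toy_scheme)
  expect_equal(lt$ex[1],
               oracle_life_table_e0(toy_mx, toy_scheme$start,
                                    toy_scheme$width))
  # and the default 19-group scheme agrees with the same oracle
  lt2 <- generate_life_table()
  expect_equal(lt2$ex[1],
               oracle_life_table_e0(lt2$mx, lt2$start, lt2$width))
})

test_that("life expectancy matches simulated lifetimes within 0.1 years", {
  # fine (standard abridged) age groups keep the q_x approximation sharp;
  # a higher-mortality population than the default is used here
  lt <- generate_life_table(a = 4e-4, b = 2e-5, c = 0.105)
  sim <- oracle_simulated_e0(lt$mx, lt$start, lt$width, n = 2e5, seed = 2)
  expect_lt(abs(lt$ex[1] - sim), 0.1)
  # on very coarse groups (widths of 30-50 years) the approximation is
  # visibly biased: document the direction rather than pretend precision
  lt3 <- build_life_table(toy_mx, scheme = toy_scheme)
  sim3 <- oracle_simulated_e0(toy_mx, toy_scheme$start, toy_scheme$width,
                              n = 2e5, seed = 2)
  expect_lt(abs(lt3$ex[1] - sim3), 1)
})

test_that("degenerate inputs are rejected", {
  bad <- tibble::tibble(start = c(0, 10, 30), width = c(10, 5, Inf))
  expect_error(build_life_table(c(0.1, 0.1, 0.1), scheme = bad),
               class = "hlyr_schema_error")
  expect_error(build_life_table(c(0.01, 0.01, 0), scheme = toy_scheme),
               class = "hlyr_domain_error")
})

test_that("prevalence schedules aggregate probabilities by age group", {
  df <- tibble::tibble(age = c(2, 3, 7, 90))
  expect_warning(
    sched <- prevalence_schedule(df, values = c(0, 0, 0, 0),
                                 scheme = abridged_scheme()),
    "empty age group")
  expect_true(all(sched$pi == 0))
  expect_equal(sum(sched$n), 4)

  expect_warning(
    sched2 <- prevalence_schedule(df, values = c(0.1, 0.3, 0.5, 0.9)),
    "empty age group")
  expect_equal(sched2$pi[sched2$start == 1], 0.2) # ages 2 and 3
  expect_equal(sched2$pi[sched2$start == 5], 0.5)
  # gaps borrow from the nearest populated group
  expect_equal(sched2$pi[sched2$start == 10], 0.5)
  expect_equal(sched2$pi[sched2$start == 80], 0.9)

  expect_error(prevalence_schedule(df[0, ], values = numeric(0)),
               class = "hlyr_empty_population")
})

test_that("group prevalence of generated labels matches the generator", {
  cfg <- generator_config(40000, seed = 22)
  pop <- generate_population(cfg)
  obs <- suppressWarnings(
    prevalence_schedule(pop, values = pop$activity_limitation,
                        mode = "observed"))
  mod <- suppressWarnings(prevalence_schedule(pop)) # mean true probability
  # within each populated group the label rate is a binomial draw around
  # the mean generative probability; the aggregate z^2 over the k groups
  # should behave like a chi-square(k) variate
  ok <- obs$n >= 200
  z <- (obs$pi - mod$pi) / sqrt(mod$pi * (1 - mod$pi) / obs$n)
  expect_lt(sum(z[ok]^2), qchisq(0.999, sum(ok)))
  expect_true(all(abs(z[ok]) < 4))
})

test_that("Sullivan's method obeys its closed-form identities", {
  lt <- generate_life_table()
  k <- nrow(lt)
  zero <- tibble::tibble(start = lt$start, width = lt$width,
                         pi = rep(0, k), n = 1)
  res <- sullivan_hly(lt, zero)
  expect_equal(attr(res, "hly_0"), lt$ex[1])

  one <- zero; one$pi <- rep(1, k)
  expect_equal(attr(sullivan_hly(lt, one), "hly_0"), 0)

  const <- zero; const$pi <- rep(0.2, k)
  expect_equal(attr(sullivan_hly(lt, const), "hly_0"), 0.8 * lt$ex[1])
  expect_equal(attr(sullivan_hly(lt, const), "gap_0"), 0.2 * lt$ex[1])

  # toy instance against the explicit-loop oracle
  lt3 <- build_life_table(toy_mx, scheme = toy_scheme)
  sched3 <- tibble::tibble(start = toy_scheme$start,
                           width = toy_scheme$width,
                           pi = c(0.05, 0.3, 0.6), n = c(1, 1, 1))
  res3 <- sullivan_hly(lt3, sched3)
  expect_equal(attr(res3, "hly_0"),
               oracle_hly0(lt3$Lx, lt3$lx, sched3$pi))
  expect_true(all(res3$hly <= res3$ex + 1e-12))

  mis <- sched3; mis$start <- mis$start + 5
  expect_error(sullivan_hly(lt3, mis), class = "hlyr_schema_error")
})

test_that("life tables survive a CSV round trip through their rates", {
  lt <- generate_life_table()
  path <- tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_equal(as.data.frame(lt2), as.data.frame(lt))
  bad <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(age_group_start = 0, m_x = 0.1), bad)
  expect_error(read_life_table(bad), regexp = "age_group_width",
               class = "hlyr_schema_error")
})

test_that("healthy life years fall linearly in each group prevalence", {
  lt <- build_life_table(toy_mx, scheme = toy_scheme)
  base <- tibble::tibble(start = toy_scheme$start, width = toy_scheme$width,
                         pi = c(0.1, 0.2, 0.4), n = 1)
  h0 <- attr(sullivan_hly(lt, base), "hly_0")
  for (i in 1:3) {
    bumped <- base
    bumped$pi[i] <- bumped$pi[i] + 0.1
    h1 <- attr(sullivan_hly(lt, bumped), "hly_0")
    expect_lt(h1, h0)
    # slope in pi_x is exactly -L_x / l_0
    expect_equal(h1 - h0, -0.1 * lt$Lx[i] / lt$lx[1])
  }
})
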