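# Counterfactual policy simulation and the HCAL individual index.
#
# A policy scenario sets target prevalence rates for selected diseases.
# The counterfactual population is built by randomly sampling carriers of
# each targeted disease and clearing their flag (or setting it, for an
# increase), leaving population size, age structure and every other field
# untouched — which is what Sullivan's method needs to compare like with
# like. Re-predicting limitation probabilities on the counterfactual and
# re-running Sullivan's method yields the simulated change in healthy
# life years.

#' Define a policy scenario
#'
#' @param targets named numeric vector: disease name -> target prevalence
#'   (a proportion in \[0, 1\]). An empty vector is the do-nothing
#'   scenario.
#' @param n_repeats number of seeded resampling repeats used by
#'   [simulate_policy_hly()].
#' @return an object of class `policy_scenario`.
#' @export
#' @examples
#' policy_scenario(c(back_pain = 0.025))
policy_scenario <- function(targets = numeric(0), n_repeats = 20L) {
  if (length(targets) > 0) {
    unknown <- setdiff(names(targets), disease_names())
    if (length(unknown) > 0) {
      abort(paste0("unknown disease(s) in scenario: ",
                   paste(unknown, collapse = ", ")),
            class = "hlyr_schema_error")
    }
    check_probability(targets, "target prevalence")
  }
  structure(list(targets = targets, n_repeats = as.integer(n_repeats)),
            class = "policy_scenario")
}

#' Apply a scenario to a survey population
#'
#' For each targeted disease with current prevalence `p0` and target `p1 <
#' p0`, a simple random sample of `round((p0 - p1) * N)` carriers has the
#' flag cleared; for `p1 > p0` the flag is set in a sample of
#' non-carriers. All other columns are untouched and the achieved
#' prevalence is within `1/N` of the target. Deterministic given the seed.
#'
#' @param records survey tibble.
#' @param scenario a [policy_scenario()].
#' @param seed integer seed.
#' @return the counterfactual survey tibble.
#' @export
apply_scenario <- function(records, scenario, seed = 1L) {
  stopifnot(inherits(scenario, "policy_scenario"))
  n <- nrow(records)
  out <- records
  with_seed(seed, {
    for (d in names(scenario$targets)) {
      target <- scenario$targets[[d]]
      flag <- out[[d]] == 1
      p0 <- mean(flag)
      k <- round(abs(p0 - target) * n)
      if (k == 0) next
      if (target < p0) {
        if (k > sum(flag)) {
          abort(sprintf(
            "target %.4f for %s not attainable: prevalence can only be reduced to 0 (current %.4f)",
            target, d, p0), class = "hlyr_domain_error")
        }
        out[[d]][sample(which(flag), k)] <- 0L
      } else {
        if (k > sum(!flag)) {
          abort(sprintf(
            "target %.4f for %s not attainable: prevalence can only be raised to 1 (current %.4f)",
            target, d, p0), class = "hlyr_domain_error")
        }
        out[[d]][sample(which(!flag), k)] <- 1L
      }
    }
  })
  out
}

#' Simulate the healthy-life-years effect of a policy scenario
#'
#' Predicts limitation probabilities on the baseline population and on
#' `n_repeats` counterfactual populations drawn with fresh seeds, builds
#' the prevalence schedule for each, runs Sullivan's method against the
#' supplied life table, and reports the distribution of the change in
#' healthy life years at birth.
#'
#' @param records baseline survey tibble.
#' @param model a fitted `limitation_model`.
#' @param scenario a [policy_scenario()].
#' @param life_table a [build_life_table()] result.
#' @param scheme age-group scheme shared by life table and schedules.
#' @param seed integer seed (repeat r uses `seed + r`).
#' @return a list of class `policy_simulation`: `baseline` and
#'   `counterfactual` (`hly_result`s; counterfactual from the first
#'   repeat), `hly_difference` (mean over repeats), `sd_difference`,
#'   `differences` (per repeat) and `n_repeats`.
#' @export
simulate_policy_hly <- function(records, model, scenario,
                                life_table, scheme = abridged_scheme(),
                                seed = 1L) {
  stopifnot(inherits(scenario, "policy_scenario"))
  p_base <- predict_proba(model, records)
  base <- sullivan_hly(
    life_table,
    prevalence_schedule(records, values = p_base, scheme = scheme)
  )
  if (length(scenario$targets) == 0) {
    # do-nothing scenario: the counterfactual is the baseline itself
    return(structure(
      list(baseline = base, counterfactual = base, hly_difference = 0,
           sd_difference = 0, differences = rep(0, scenario$n_repeats),
           n_repeats = scenario$n_repeats),
      class = "policy_simulation"
    ))
  }
  results <- purrr::map(seq_len(scenario$n_repeats), function(r) {
    cf <- apply_scenario(records, scenario, seed = seed + r)
    p_cf <- predict_proba(model, cf)
    sullivan_hly(
      life_table,
      prevalence_schedule(cf, values = p_cf, scheme = scheme)
    )
  })
  diffs <- vapply(results, function(res) attr(res, "hly_0"), numeric(1)) -
    attr(base, "hly_0")
  structure(
    list(baseline = base, counterfactual = results[[1]],
         hly_difference = mean(diffs),
         sd_difference = if (length(diffs) > 1) sd(diffs) else 0,
         differences = diffs, n_repeats = scenario$n_repeats),
    class = "policy_simulation"
  )
}

#' @export
print.policy_simulation <- function(x, ...) {
  cat("<policy_simulation>\n")
  cat(sprintf("  baseline HLY at birth: %.2f years\n",
              attr(x$baseline, "hly_0")))
  cat(sprintf("  change in HLY: %+.3f years (SD %.3f over %d repeats)\n",
              x$hly_difference, x$sd_difference, x$n_repeats))
  invisible(x)
}

#' @export
glance.policy_simulation <- function(x, ...) {
  tibble::tibble(
    baseline_hly_0 = attr(x$baseline, "hly_0"),
    counterfactual_hly_0 = attr(x$baseline, "hly_0") + x$hly_difference,
    hly_difference = x$hly_difference,
    sd_difference = x$sd_difference,
    n_repeats = x$n_repeats
  )
}

#' HCAL: health condition without activity limitation index
#'
#' An individual 0-100 score: 100 minus the predicted probability of
#' activity limitation expressed as a percentage.
#'
#' @param probability predicted probabilities in \[0, 1\].
#' @return numeric HCAL values in \[0, 100\].
#' @export
#' @examples
#' hcal_index(c(0, 0.25, 1))
hcal_index <- function(probability) {
  check_probability(probability)
  100 - 100 * probability
}

#' HCAL age curve with cubic fit
#'
#' Per integer age: mean HCAL over respondents of that age with a
#' normal-approximation 95% confidence interval, plus a third-order
#' polynomial least-squares fit of mean HCAL on age.
#'
#' @param model a fitted `limitation_model`, or `NULL` if `values` are
#'   supplied directly.
#' @param records survey tibble covering at least 4 distinct ages.
#' @param values optional per-record HCAL values (bypasses the model).
#' @param conf_level confidence level of the per-age interval.
#' @return a tibble of class `hcal_curve` with columns `age`, `mean_hcal`,
#'   `ci_low`, `ci_high`, `n`, `fitted`; the cubic coefficients (intercept
#'   first) are in attribute `coefficients`.
#' @export
hcal_age_curve <- function(model, records, values = NULL,
                           conf_level = 0.95) {
  if (is.null(values)) {
    values <- hcal_index(predict_proba(model, records))
  }
  stopifnot(length(values) == nrow(records))
  if (length(unique(records$age)) < 4) {
    abort("cubic fit needs at least 4 distinct ages",
          class = "hlyr_domain_error")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  per_age <- tibble::tibble(age = records$age, hcal = values) |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(
      mean_hcal = mean(.data$hcal),
      se = ifelse(dplyr::n() > 1, sd(.data$hcal) / sqrt(dplyr::n()), 0),
      n = dplyr::n()
    ) |>
    dplyr::mutate(ci_low = .data$mean_hcal - z * .data$se,
                  ci_high = .data$mean_hcal + z * .data$se) |>
    dplyr::arrange(.data$age)
  fit <- lm(mean_hcal ~ poly(age, 3, raw = TRUE), data = per_age)
  out <- dplyr::select(per_age, "age", "mean_hcal", "ci_low", "ci_high", "n")
  out$fitted <- unname(predict(fit))
  attr(out, "coefficients") <- unname(coef(fit))
  class(out) <- c("hcal_curve", class(out))
  out
}

#' @export
tidy.hcal_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "age", "age^2", "age^3"),
                 estimate = attr(x, "coefficients"))
}
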