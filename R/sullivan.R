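# Abridged life tables and Sullivan's method.
#
# Sullivan's method turns a period life table plus an age-specific
# prevalence schedule of an unhealthy state into health expectancy: the
# person-years column L_x is weighted by (1 - pi_x) before accumulation,
# so healthy life years at age x are sum_{y>=x} L_y (1 - pi_y) / l_x.

#' Standard abridged age-group scheme
#'
#' Ages 0, 1-4, then five-year groups up to an open-ended terminal group
#' (default 85+), the conventional stratification for national abridged
#' life tables and Sullivan-method estimates.
#'
#' @param open_age start of the open-ended last group.
#' @return a tibble with columns `start` and `width` (last width `Inf`).
#' @export
abridged_scheme <- function(open_age = 85) {
  stopifnot(open_age >= 5, open_age %% 5 == 0)
  start <- c(0, 1, seq(5, open_age, by = 5))
  width <- c(diff(start), Inf)
  tibble::tibble(start = start, width = width)
}

check_scheme <- function(scheme) {
  if (!all(c("start", "width") %in% names(scheme))) {
    abort("scheme needs columns start and width", class = "hlyr_schema_error")
  }
  k <- nrow(scheme)
  if (scheme$start[1] != 0 || !is.infinite(scheme$width[k]) ||
      any(!is.finite(scheme$width[-k])) ||
      (k > 1 && any(scheme$start[-1] != scheme$start[-k] + scheme$width[-k]))) {
    abort("age groups must be contiguous from 0 with an open-ended last group",
          class = "hlyr_schema_error")
  }
  invisible(scheme)
}

# map integer ages to scheme group index
age_to_group <- function(age, scheme) {
  idx <- findInterval(age, scheme$start)
  if (any(idx < 1)) {
    abort("ages below the first age group", class = "hlyr_schema_error")
  }
  idx
}

#' Build an abridged life table from central death rates
#'
#' Standard abridged construction: for a closed group of width `n`,
#' `q_x = n m_x / (1 + (n - a_x) m_x)` with `a_x = n/2` (the first group
#' uses `a0` when it is the width-1 infant group); the open last group has
#' `q = 1` and `L = l / m`. Survivors start from a radix `l_0 = 100,000`.
#'
#' @param mx central death rate per person-year, one per age group.
#' @param scheme age-group scheme, see [abridged_scheme()].
#' @param a0 average years lived by those dying in a width-1 first group.
#' @param radix survivors at exact age 0.
#' @return a tibble of class `life_table` with columns `start`, `width`,
#'   `mx`, `ax`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`.
#' @export
#' @examples
#' lt <- build_life_table(c(0.002, 0.02, 0.1),
#'   scheme = tibble::tibble(start = c(0, 50, 80), width = c(50, 30, Inf)))
#' lt$ex[1]
build_life_table <- function(mx, scheme = abridged_scheme(), a0 = 0.3,
                             radix = 1e5) {
  check_scheme(scheme)
  k <- nrow(scheme)
  stopifnot(length(mx) == k, all(mx >= 0))
  if (mx[k] <= 0) {
    abort("the open last group needs a positive death rate to be closed",
          class = "hlyr_domain_error")
  }
  n <- scheme$width
  ax <- n / 2
  if (n[1] == 1) ax[1] <- a0
  qx <- n * mx / (1 + (n - ax) * mx)
  qx[k] <- 1
  ax[k] <- NA_real_
  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- n * (lx - dx) + ax * dx
  Lx[k] <- lx[k] / mx[k]
  Tx <- rev_cumsum(Lx)
  out <- tibble::tibble(
    start = scheme$start, width = n, mx = mx, ax = ax, qx = qx,
    lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = Tx / lx
  )
  class(out) <- c("life_table", class(out))
  out
}

#' Age-stratified prevalence schedule of activity limitation
#'
#' Aggregates per-respondent information into the per-age-group proportion
#' pi_x fed to Sullivan's method. The default (`mode = "probability"`)
#' averages predicted probabilities within each group; `mode = "threshold"`
#' takes the fraction of predictions above `cutoff`; `mode = "observed"`
#' averages a 0/1 outcome vector. Empty groups are filled from the nearest
#' non-empty group, with a warning.
#'
#' @param data a data frame with an `age` column.
#' @param values per-row probabilities (or 0/1 outcomes); defaults to
#'   `data$true_probability` if present, else `data$activity_limitation`.
#' @param scheme age-group scheme, see [abridged_scheme()].
#' @param mode one of "probability", "threshold", "observed".
#' @param cutoff classification threshold for `mode = "threshold"`.
#' @return a tibble of class `prevalence_schedule` with columns `start`,
#'   `width`, `pi` and `n` (respondents per group).
#' @export
prevalence_schedule <- function(data, values = NULL,
                                scheme = abridged_scheme(),
                                mode = c("probability", "threshold",
                                         "observed"),
                                cutoff = 0.5) {
  mode <- match.arg(mode)
  check_scheme(scheme)
  if (nrow(data) == 0) {
    abort("no records to build a prevalence schedule from",
          class = "hlyr_empty_population")
  }
  if (is.null(values)) {
    values <- data$true_probability %||% data$activity_limitation
  }
  stopifnot(length(values) == nrow(data))
  check_probability(values, "values")
  if (mode == "threshold") values <- as.numeric(values >= cutoff)
  grp <- age_to_group(data$age, scheme)
  agg <- tibble::tibble(grp = grp, v = values) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(pi = mean(.data$v), n = dplyr::n())
  pi <- rep(NA_real_, nrow(scheme))
  cnt <- rep(0L, nrow(scheme))
  pi[agg$grp] <- agg$pi
  cnt[agg$grp] <- agg$n
  if (anyNA(pi)) {
    warn(paste0(sum(is.na(pi)),
                " empty age group(s) filled from the nearest populated group"))
    filled <- which(!is.na(pi))
    for (i in which(is.na(pi))) {
      pi[i] <- pi[filled[which.min(abs(filled - i))]]
    }
  }
  out <- tibble::tibble(start = scheme$start, width = scheme$width,
                        pi = pi, n = cnt)
  class(out) <- c("prevalence_schedule", class(out))
  out
}

#' Healthy life years by Sullivan's method
#'
#' Weights each life-table person-years entry by the proportion free of
#' activity limitation: healthy person-years in a group are
#' `L_x * (1 - pi_x)`, and healthy life years at age x are their sum over
#' ages >= x divided by `l_x`.
#'
#' @param life_table a [build_life_table()] result.
#' @param prevalence a [prevalence_schedule()] on the identical age scheme.
#' @return a tibble of class `hly_result` with per-group columns `start`,
#'   `pi`, `ex` and `hly` (healthy life years at the group's start age),
#'   plus attributes `hly_0`, `e_0` and `gap_0 = e_0 - hly_0`.
#' @export
#' @examples
#' lt <- generate_life_table()
#' pi0 <- prevalence_schedule(tibble::tibble(age = c(20, 70)),
#'                            values = c(0.1, 0.4))
#' res <- sullivan_hly(lt, pi0)
#' glance(res)
sullivan_hly <- function(life_table, prevalence) {
  stopifnot(inherits(life_table, "life_table"))
  if (nrow(life_table) != nrow(prevalence) ||
      any(life_table$start != prevalence$start)) {
    abort("life table and prevalence schedule use different age schemes",
          class = "hlyr_schema_error")
  }
  check_probability(prevalence$pi, "pi")
  healthy_L <- life_table$Lx * (1 - prevalence$pi)
  hly <- rev_cumsum(healthy_L) / life_table$lx
  out <- tibble::tibble(
    start = life_table$start, width = life_table$width,
    pi = prevalence$pi, ex = life_table$ex, hly = hly
  )
  attr(out, "hly_0") <- hly[1]
  attr(out, "e_0") <- life_table$ex[1]
  attr(out, "gap_0") <- life_table$ex[1] - hly[1]
  class(out) <- c("hly_result", class(out))
  out
}

#' @export
glance.hly_result <- function(x, ...) {
  tibble::tibble(hly_0 = attr(x, "hly_0"), e_0 = attr(x, "e_0"),
                 gap_0 = attr(x, "gap_0"))
}

#' @export
tidy.hly_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Life-table CSV interchange
#'
#' `write_life_table` stores the rate inputs (`age_group_start`,
#' `age_group_width`, `m_x`); `read_life_table` reads such a file and
#' rebuilds the full table with [build_life_table()], so derived columns
#' are always consistent with the rates.
#'
#' @param life_table a `life_table` tibble.
#' @param path file path.
#' @param ... passed on to [build_life_table()] (e.g. `a0`, `radix`).
#' @return `read_life_table` returns a `life_table`; `write_life_table`
#'   returns `path` invisibly.
#' @export
write_life_table <- function(life_table, path) {
  stopifnot(inherits(life_table, "life_table"))
  readr::write_csv(
    tibble::tibble(age_group_start = life_table$start,
                   age_group_width = life_table$width,
                   m_x = life_table$mx),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path, ...) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("age_group_start", "age_group_width", "m_x")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("life-table file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hlyr_schema_error")
  }
  build_life_table(raw$m_x,
                   scheme = tibble::tibble(start = raw$age_group_start,
                                           width = raw$age_group_width),
                   ...)
}
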