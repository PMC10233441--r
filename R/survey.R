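# Reading, validating and describing survey record tables.

#' Read a survey record table from CSV
#'
#' Validates the file against the survey schema. Rows with a missing
#' `activity_limitation` are dropped (their count is reported with a
#' message); missing values in disease flags are coerced to 0 with a
#' warning. A file lacking a required column raises a schema error naming
#' the column.
#'
#' @param path path to a headered delimited file with the schema columns.
#' @return a validated tibble of survey records; the number of dropped
#'   rows is available as attribute `n_dropped`.
#' @export
read_survey <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(survey_columns(), names(data))
  if (length(missing) > 0) {
    abort(paste0("survey file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hlyr_schema_error")
  }
  data <- data[survey_columns()]
  n_dropped <- sum(is.na(data$activity_limitation))
  if (n_dropped > 0) {
    inform(paste0("dropped ", n_dropped,
                  " row(s) with missing activity_limitation"))
    data <- data[!is.na(data$activity_limitation), ]
  }
  flag_na <- vapply(data[disease_names()], anyNA, logical(1))
  if (any(flag_na)) {
    warn(paste0("missing disease flags coerced to 0 in: ",
                paste(names(flag_na)[flag_na], collapse = ", ")))
    data <- dplyr::mutate(
      data,
      dplyr::across(dplyr::all_of(disease_names()),
                    ~ dplyr::coalesce(as.integer(.x), 0L))
    )
  }
  data <- dplyr::mutate(
    data,
    age = as.integer(.data$age),
    dplyr::across(dplyr::all_of(c(disease_names(), "activity_limitation")),
                  as.integer)
  )
  validate_survey(data)
  attr(data, "n_dropped") <- n_dropped
  data
}

#' Descriptive comparison of the with- and without-limitation groups
#'
#' One row per variable, comparing respondents with and without activity
#' limitation: median (IQR) and a Mann-Whitney U test for age; n (%) and a
#' 2x2 chi-square test (without continuity correction, so the statistic
#' matches the textbook formula exactly) for sex and each disease.
#' Percentages are rounded half-up to one decimal, the convention of
#' printed survey tables.
#'
#' @param records a survey tibble.
#' @param alpha significance level for the `significant` flag (default
#'   0.01, a common choice for very large survey samples).
#' @return a tibble of class `descriptive_table` with columns `variable`,
#'   `type`, summary strings for each group, `statistic`, `test`,
#'   `p_value` and `significant`; group sizes are kept in attributes
#'   `n_without` / `n_with`.
#' @export
describe_groups <- function(records, alpha = 0.01) {
  validate_survey(records)
  lim <- records$activity_limitation == 1
  if (sum(lim) == 0 || sum(!lim) == 0) {
    abort("both limitation groups must be non-empty",
          class = "hlyr_empty_population")
  }
  n0 <- sum(!lim)
  n1 <- sum(lim)

  fmt_pct <- function(n, d) round_half_up(100 * n / d, 1)

  age_row <- {
    a0 <- records$age[!lim]
    a1 <- records$age[lim]
    p <- suppressWarnings(wilcox.test(a1, a0)$p.value)
    q0 <- quantile(a0, c(0.5, 0.25, 0.75), type = 2)
    q1 <- quantile(a1, c(0.5, 0.25, 0.75), type = 2)
    tibble::tibble(
      variable = "age", type = "continuous",
      without = sprintf("%g (%g-%g)", q0[1], q0[2], q0[3]),
      with = sprintf("%g (%g-%g)", q1[1], q1[2], q1[3]),
      n_without = NA_integer_, n_with = NA_integer_,
      pct_without = NA_real_, pct_with = NA_real_,
      statistic = unname(suppressWarnings(wilcox.test(a1, a0)$statistic)),
      test = "mann-whitney", p_value = p
    )
  }

  binary_row <- function(name, x) {
    c1 <- sum(x & lim)
    c0 <- sum(x & !lim)
    tab <- matrix(c(c0, n0 - c0, c1, n1 - c1), nrow = 2)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(
      variable = name, type = "binary",
      without = sprintf("%s (%s)", format(c0, big.mark = ","),
                        fmt_pct(c0, n0)),
      with = sprintf("%s (%s)", format(c1, big.mark = ","),
                     fmt_pct(c1, n1)),
      n_without = c0, n_with = c1,
      pct_without = fmt_pct(c0, n0), pct_with = fmt_pct(c1, n1),
      statistic = unname(ct$statistic), test = "chi-square",
      p_value = ct$p.value
    )
  }

  rows <- dplyr::bind_rows(
    age_row,
    binary_row("sex_female", records$sex == "female"),
    purrr::map(disease_names(),
               function(d) binary_row(d, records[[d]] == 1))
  )
  rows$significant <- rows$p_value < alpha
  attr(rows, "n_without") <- n0
  attr(rows, "n_with") <- n1
  attr(rows, "alpha") <- alpha
  class(rows) <- c("descriptive_table", class(rows))
  rows
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat(sprintf(
    "Characteristics by activity limitation (without n=%s, with n=%s)\n\n",
    format(attr(x, "n_without"), big.mark = ","),
    format(attr(x, "n_with"), big.mark = ",")))
  p_fmt <- ifelse(x$p_value < 0.001, "<.001",
                  sub("^0", "", sprintf("%.3g", x$p_value)))
  body <- data.frame(variable = x$variable, without = x$without,
                     with = x$with, p = p_fmt)
  print(format(body, justify = "left"), row.names = FALSE)
  invisible(x)
}
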