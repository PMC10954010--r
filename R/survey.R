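#' Survey CSV column names for a configuration
#'
#' The required raw columns are: `id`, `area`, `head_sex`, `head_age`,
#' `civil_status`, `hh_size`, one `days_<group>` column per configured food
#' group, `food_spend`, `total_spend`, and one `cs_<item>` column (0/1) per
#' configured coping item.  Derived columns (`fcs`, `fcs_cat`, `pwfe`,
#' `pwfe_cat`, `csi_cat`, `fsi`, `fsi_label`) are appended on output when
#' present.
#'
#' @param config an [indicator_config()].
#' @return Character vector of required column names.
#' @export
survey_columns <- function(config = indicator_config()) {
  c("id", "area", "head_sex", "head_age", "civil_status", "hh_size",
    paste0("days_", config$food_groups$name),
    "food_spend", "total_spend",
    paste0("cs_", config$coping_items$name))
}

DERIVED_COLUMNS <- c("fcs", "fcs_cat", "pwfe", "pwfe_cat", "csi_cat",
                     "fsi", "fsi_label")

#' Read a household survey from CSV
#'
#' Reads the documented survey schema.  Malformed numeric cells become `NA`
#' (they make the household incomplete rather than aborting the read); row
#' order is preserved.  Categorical vocabulary (`area`, `head_sex`,
#' `civil_status`) and the 0-7 range of the food-day columns are validated.
#'
#' @param path a file path or connection.
#' @param config an [indicator_config()].
#' @return A tibble, one row per household, with attribute `"config"`.
#' @export
read_survey <- function(path, config = indicator_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- survey_columns(config)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("survey file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  num_cols <- c("head_age", "hh_size",
                paste0("days_", config$food_groups$name),
                "food_spend", "total_spend",
                paste0("cs_", config$coping_items$name),
                intersect(c("fcs", "pwfe", "fsi"), names(df)))
  for (cl in num_cols) {
    v <- df[[cl]]
    v[!nzchar(trimws(v))] <- NA
    df[[cl]] <- suppressWarnings(as.numeric(v))
  }
  if (anyDuplicated(df$id))
    stop("household ids must be unique", call. = FALSE)
  check_vocab(df$area, c("urban", "non_urban"), "area")
  check_vocab(df$head_sex, c("female", "male"), "head_sex")
  check_vocab(df$civil_status,
              c("married_or_couple", "divorced_or_widowed", "single"),
              "civil_status")
  for (g in config$food_groups$name) {
    v <- df[[paste0("days_", g)]]
    bad <- which(!is.na(v) & (v < 0 | v > 7 | v != floor(v)))
    if (length(bad))
      stop("days_", g, " outside 0-7 for household id(s): ",
           paste(utils::head(df$id[bad], 5), collapse = ", "), call. = FALSE)
  }
  cat_levels <- list(fcs_cat = FCS_LEVELS, pwfe_cat = PWFE_LEVELS,
                     csi_cat = CSI_LEVELS, fsi_label = FSI_LEVELS)
  for (cat_col in intersect(names(cat_levels), names(df))) {
    v <- df[[cat_col]]
    v[!nzchar(trimws(v))] <- NA
    df[[cat_col]] <- factor(v, levels = cat_levels[[cat_col]])
  }
  out <- tibble::as_tibble(df[, c(required,
                                  intersect(DERIVED_COLUMNS, names(df)))])
  attr(out, "config") <- config
  out
}

check_vocab <- function(x, allowed, what) {
  bad <- !is.na(x) & nzchar(trimws(x)) & !(x %in% allowed)
  if (any(bad))
    stop(what, " must be one of {", paste(allowed, collapse = ","),
         "}; found: ", paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Write a household survey to CSV
#'
#' Emits the documented schema, including any derived columns present, in
#' the canonical column order.  A read/write round trip preserves all values
#' (modulo floating-point text formatting).
#'
#' @param survey a survey tibble.
#' @param path destination path or connection.
#' @param config an [indicator_config()].
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path, config = attr(survey, "config")) {
  if (is.null(config)) config <- indicator_config()
  cols <- c(survey_columns(config), intersect(DERIVED_COLUMNS, names(survey)))
  missing_cols <- setdiff(survey_columns(config), names(survey))
  if (length(missing_cols))
    stop("survey is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(as.data.frame(survey)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Identify complete cases for indicator construction
#'
#' A household is complete iff every field needed by the three indicators is
#' present and usable: all configured food-day counts, both spending fields
#' with `total_spend > 0` and `food_spend <= total_spend`, and an answer to
#' every coping item.  (Zero total spending leaves PWFE undefined, so such
#' households are treated as incomplete.)
#'
#' @param survey a survey tibble.
#' @param config an [indicator_config()].
#' @return The complete households, with attributes `"retained"` and
#'   `"dropped"` carrying the counts.
#' @export
complete_cases <- function(survey, config = attr(survey, "config")) {
  if (is.null(config)) config <- indicator_config()
  ok <- is_complete(survey, config)
  out <- survey[ok, , drop = FALSE]
  attr(out, "config") <- config
  attr(out, "retained") <- sum(ok)
  attr(out, "dropped") <- sum(!ok)
  out
}

is_complete <- function(survey, config) {
  day_cols <- paste0("days_", config$food_groups$name)
  cs_cols <- paste0("cs_", config$coping_items$name)
  days_ok <- rowSums(is.na(as.matrix(survey[, day_cols, drop = FALSE]))) == 0
  cs_ok <- rowSums(is.na(as.matrix(survey[, cs_cols, drop = FALSE]))) == 0
  spend_ok <- !is.na(survey$food_spend) & !is.na(survey$total_spend) &
    survey$total_spend > 0 & survey$food_spend >= 0 &
    survey$food_spend <= survey$total_spend
  days_ok & cs_ok & spend_ok
}

#' Socio-demographic summary of a survey
#'
#' Frequencies and percentages for sex of the household head, civil status
#' and household-size bands (<3, 3-6, >6), plus mean and SD of the head's
#' age.  Percentages use non-missing denominators and are rounded to one
#' decimal.
#'
#' @param survey a survey tibble.
#' @return An object of class `survey_describe`: a list with `frequencies`
#'   (tibble: `variable`, `category`, `n`, `pct`) and `head_age`
#'   (list with `mean`, `sd`, `n`).
#' @export
describe <- function(survey) {
  freq_one <- function(x, variable, levels) {
    x <- x[!is.na(x)]
    n <- vapply(levels, function(l) sum(x == l), 0L)
    tibble::tibble(variable = variable, category = levels, n = as.integer(n),
                   pct = round_half_up(100 * n / sum(n), 1))
  }
  size_band <- cut(survey$hh_size, breaks = c(-Inf, 2, 6, Inf),
                   labels = c("<3", "3-6", ">6"))
  freq <- rbind(
    freq_one(survey$head_sex, "head_sex", c("female", "male")),
    freq_one(survey$civil_status, "civil_status",
             c("married_or_couple", "divorced_or_widowed", "single")),
    freq_one(as.character(size_band), "hh_size_band", c("<3", "3-6", ">6")),
    freq_one(survey$area, "area", c("urban", "non_urban")))
  age <- survey$head_age[!is.na(survey$head_age)]
  structure(list(frequencies = freq,
                 head_age = list(mean = mean(age), sd = stats::sd(age),
                                 n = length(age))),
            class = "survey_describe")
}

#' @export
print.survey_describe <- function(x, ...) {
  cat("Socio-demographic summary\n")
  cat(sprintf("  head age: %.1f +/- %.1f (n=%d)\n",
              x$head_age$mean, x$head_age$sd, x$head_age$n))
  f <- x$frequencies
  for (v in unique(f$variable)) {
    cat(" ", v, "\n")
    sub <- f[f$variable == v, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("    %-22s %6d  %5.1f%%\n",
                  sub$category[i], sub$n[i], sub$pct[i]))
  }
  invisible(x)
}
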