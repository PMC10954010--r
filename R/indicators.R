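#' Food consumption score
#'
#' Weighted sum over food groups of the number of days (0-7) each group was
#' eaten in the past week: `sum_g weight(g) * days(g)`.  With the default
#' WFP weights the score ranges over 0-112.
#'
#' @param food_days named numeric vector of 0-7 day counts, one entry per
#'   configured food group.
#' @param groups data frame of food groups and weights
#'   (default [default_food_groups()]).
#' @return The score, a single number.
#' @export
#' @examples
#' days <- setNames(rep(7, 8), default_food_groups()$name)
#' compute_fcs(days)  # 112
compute_fcs <- function(food_days, groups = default_food_groups()) {
  missing_groups <- setdiff(groups$name, names(food_days))
  if (length(missing_groups))
    stop("food_days is missing group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(food_days), groups$name)
  if (length(unknown))
    stop("unknown food group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d <- food_days[groups$name]
  if (any(is.na(d)) || any(d < 0 | d > 7))
    stop("food_days must be in 0..7 with no missing values", call. = FALSE)
  sum(groups$weight * d)
}

#' Categorize a food consumption score
#'
#' Default cut-offs: poor 0-28, borderline 28.5-42, acceptable above 42.
#' With half-point-valued scores the poor/borderline boundary `fcs <= 28`
#' matches both phrasings "0 to 28" and "28.5 to 42".
#'
#' @param fcs numeric vector of scores (>= 0).
#' @param cutoffs `c(poor_max, borderline_max)`.
#' @return Factor with levels poor < borderline < acceptable.
#' @export
categorize_fcs <- function(fcs, cutoffs = c(poor_max = 28, borderline_max = 42)) {
  if (any(!is.na(fcs) & fcs < 0))
    stop("fcs must be nonnegative", call. = FALSE)
  out <- ifelse(is.na(fcs), NA_character_,
                ifelse(fcs <= cutoffs[[1]], "poor",
                       ifelse(fcs <= cutoffs[[2]], "borderline", "acceptable")))
  factor(out, levels = FCS_LEVELS)
}

#' Proportion of wages allocated to food expenses
#'
#' `food_spend / total_spend`, the economic-vulnerability indicator: the
#' larger the share of the household budget that food absorbs, the more
#' vulnerable the household.
#'
#' @param food_spend,total_spend numeric vectors in a common currency.
#' @return Numeric vector in `[0, 1]`.
#' @export
compute_pwfe <- function(food_spend, total_spend) {
  if (any(!is.na(total_spend) & total_spend == 0))
    stop("PWFE undefined: total_spend is zero", call. = FALSE)
  if (any(!is.na(food_spend) & food_spend < 0))
    stop("food_spend must be nonnegative", call. = FALSE)
  bad <- !is.na(food_spend) & !is.na(total_spend) & food_spend > total_spend
  if (any(bad))
    stop("food_spend exceeds total_spend", call. = FALSE)
  food_spend / total_spend
}

#' Categorize a PWFE value
#'
#' Bands: `<50%`, `[50,65)%`, `[65,75]%`, `>75%`.  The boundary convention
#' keeps "more than 75%" strict and closes the lower bounds of the middle
#' bands on the left.
#'
#' @param pwfe numeric vector in `[0, 1]`.
#' @param cutoffs increasing proportions, default `c(0.50, 0.65, 0.75)`.
#' @return Factor with levels lt50 < p50_65 < p65_75 < gt75.
#' @export
categorize_pwfe <- function(pwfe, cutoffs = c(0.50, 0.65, 0.75)) {
  if (any(!is.na(pwfe) & (pwfe < 0 | pwfe > 1)))
    stop("pwfe must be in [0, 1]", call. = FALSE)
  out <- ifelse(is.na(pwfe), NA_character_,
                ifelse(pwfe < cutoffs[1], "lt50",
                       ifelse(pwfe < cutoffs[2], "p50_65",
                              ifelse(pwfe <= cutoffs[3], "p65_75", "gt75"))))
  factor(out, levels = PWFE_LEVELS)
}

#' Classify livelihood coping severity
#'
#' A household is classified by the most severe coping strategy it reports,
#' under the tier order stress < crisis < emergency; households that report
#' none are classified `none`.
#'
#' @param coping_answers named vector (0/1 or logical), one answer per
#'   configured item; every item must be answered.
#' @param items data frame of coping items (default
#'   [default_coping_items()]).
#' @return A factor level among none, stress, crisis, emergency.
#' @export
#' @examples
#' ans <- setNames(rep(0, 10), default_coping_items()$name)
#' ans["spent_savings"] <- 1
#' classify_coping(ans)  # stress
classify_coping <- function(coping_answers, items = default_coping_items()) {
  missing_items <- setdiff(items$name, names(coping_answers))
  if (length(missing_items))
    stop("unanswered coping item(s): ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  ans <- coping_answers[items$name]
  if (any(is.na(ans)))
    stop("unanswered coping item(s): ",
         paste(items$name[is.na(ans)], collapse = ", "), call. = FALSE)
  yes <- as.logical(as.numeric(ans))
  tiers <- items$tier[yes]
  lev <- if (!length(tiers)) "none" else
    CSI_LEVELS[max(match(tiers, CSI_LEVELS))]
  factor(lev, levels = CSI_LEVELS)
}

#' Compute the three component indicators for every household
#'
#' Row-wise application of [compute_fcs()], [compute_pwfe()] and
#' [classify_coping()] plus their categorizers; deterministic and invariant
#' to row order.  The survey should already be complete-cased
#' (see [complete_cases()]).
#'
#' @param survey a survey tibble of complete cases.
#' @param config an [indicator_config()].
#' @return The survey with columns `fcs`, `fcs_cat`, `pwfe`, `pwfe_cat`,
#'   `csi_cat` filled.
#' @export
compute_indicators <- function(survey, config = attr(survey, "config")) {
  if (is.null(config)) config <- indicator_config()
  day_cols <- paste0("days_", config$food_groups$name)
  days_mat <- as.matrix(survey[, day_cols, drop = FALSE])
  if (anyNA(days_mat) || any(days_mat < 0 | days_mat > 7))
    stop("food-day columns contain missing or out-of-range values; ",
         "complete-case the survey first", call. = FALSE)
  survey$fcs <- as.numeric(days_mat %*% config$food_groups$weight)
  survey$fcs_cat <- categorize_fcs(survey$fcs, config$fcs_cutoffs)
  survey$pwfe <- compute_pwfe(survey$food_spend, survey$total_spend)
  survey$pwfe_cat <- categorize_pwfe(survey$pwfe, config$pwfe_cutoffs)

  cs_cols <- paste0("cs_", config$coping_items$name)
  cs_mat <- as.matrix(survey[, cs_cols, drop = FALSE]) > 0
  if (anyNA(cs_mat))
    stop("coping answers contain missing values; complete-case first",
         call. = FALSE)
  tier_idx <- match(config$coping_items$tier, CSI_LEVELS)
  # per row: highest tier index among yes answers, 1 (none) if no yes
  sev <- apply(cs_mat, 1, function(r)
    if (!any(r)) 1L else max(tier_idx[r]))
  survey$csi_cat <- factor(CSI_LEVELS[sev], levels = CSI_LEVELS)
  attr(survey, "config") <- config
  survey
}
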