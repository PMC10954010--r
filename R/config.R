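#' Category levels used throughout the package
#'
#' Severity-ordered factor levels for the three component indicators and the
#' Food Security Index.  The orderings matter: CHAID treats all three
#' predictors as ordinal and only merges adjacent categories.
#'
#' @name cari-levels
#' @keywords internal
NULL

FCS_LEVELS  <- c("poor", "borderline", "acceptable")
PWFE_LEVELS <- c("lt50", "p50_65", "p65_75", "gt75")
CSI_LEVELS  <- c("none", "stress", "crisis", "emergency")
FSI_LEVELS  <- c("FS", "MFS", "MFI", "SFI")

#' Food Security Index level labels
#'
#' @return Character vector `c("FS", "MFS", "MFI", "SFI")`: food secure,
#'   marginally food secure, moderately food insecure, severely food insecure.
#' @export
fsi_levels <- function() FSI_LEVELS

#' Default food groups and FCS weights
#'
#' The standard WFP food consumption score instrument: eight food groups,
#' each weighted by nutritional importance.  Weekly consumption days (0-7)
#' times the weight, summed over groups, gives the FCS with range 0-112.
#'
#' @return A data frame with columns `name` and `weight` (8 rows).
#' @export
#' @examples
#' default_food_groups()
default_food_groups <- function() {
  data.frame(
    name = c("staples", "pulses", "vegetables", "fruits",
             "meat_fish_eggs", "dairy", "sugar", "oil_fat"),
    weight = c(2, 3, 1, 1, 4, 4, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Default livelihood coping strategy items
#'
#' The standard WFP livelihood-coping item set, each item tagged with its
#' severity tier.  Tiers are ordered stress < crisis < emergency; a household
#' is classified by the most severe tier among the strategies it reports.
#'
#' @return A data frame with columns `name` and `tier` (10 rows).
#' @export
default_coping_items <- function() {
  data.frame(
    name = c("spent_savings", "borrowed_money", "sold_household_goods",
             "bought_on_credit",
             "sold_productive_assets", "reduced_health_education_spending",
             "withdrew_children_from_school",
             "sold_house_or_land", "begged", "illegal_income_activities"),
    tier = c(rep("stress", 4), rep("crisis", 3), rep("emergency", 3)),
    stringsAsFactors = FALSE
  )
}

#' Default 4-point score maps for the CARI console
#'
#' Each indicator category maps to a 1-4 console score.  Food consumption
#' uses the CARI convention in which no category maps to 2 (acceptable 1,
#' borderline 3, poor 4); economic vulnerability and coping map their four
#' ordered categories to 1-4 directly.
#'
#' @return A named list with elements `fcs`, `pwfe` and `csi`, each a named
#'   integer vector over that indicator's categories.
#' @export
default_four_point_map <- function() {
  list(
    fcs  = c(acceptable = 1L, borderline = 3L, poor = 4L),
    pwfe = c(lt50 = 1L, p50_65 = 2L, p65_75 = 3L, gt75 = 4L),
    csi  = c(none = 1L, stress = 2L, crisis = 3L, emergency = 4L)
  )
}

#' Indicator configuration
#'
#' Bundles everything needed to score a survey: the food groups and FCS
#' weights, the FCS category cut-offs, the PWFE band cut-offs, the coping
#' item severity map, the per-indicator 4-point score maps, and the
#' significance level used by the association tests and CHAID.
#'
#' Cut-off conventions (all configurable, defaults are the WFP ones):
#' FCS <= `poor_max` is poor, `poor_max` < FCS <= `borderline_max` is
#' borderline, above that acceptable.  PWFE bands are
#' `[0, c1)`, `[c1, c2)`, `[c2, c3]`, `(c3, 1]` so that "more than 75%" is
#' strict.
#'
#' @param food_groups data frame with columns `name`, `weight`.
#' @param fcs_cutoffs numeric `c(poor_max = 28, borderline_max = 42)`.
#' @param pwfe_cutoffs increasing numeric vector of three proportions.
#' @param coping_items data frame with columns `name`,
#'   `tier` in `stress|crisis|emergency`.
#' @param four_point_map list as [default_four_point_map()].
#' @param alpha significance level in (0,1) for chi-square tests.
#' @return An object of class `indicator_config`.
#' @export
#' @examples
#' cfg <- indicator_config()
#' cfg$fcs_cutoffs
indicator_config <- function(food_groups = default_food_groups(),
                             fcs_cutoffs = c(poor_max = 28, borderline_max = 42),
                             pwfe_cutoffs = c(0.50, 0.65, 0.75),
                             coping_items = default_coping_items(),
                             four_point_map = default_four_point_map(),
                             alpha = 0.05) {
  stopifnot(is.data.frame(food_groups),
            all(c("name", "weight") %in% names(food_groups)))
  if (anyDuplicated(food_groups$name))
    stop("food group names must be unique", call. = FALSE)
  if (any(food_groups$weight <= 0))
    stop("food group weights must be strictly positive", call. = FALSE)
  fcs_cutoffs <- as.numeric(fcs_cutoffs)
  if (length(fcs_cutoffs) != 2 || diff(fcs_cutoffs) <= 0)
    stop("fcs_cutoffs must be two strictly increasing values", call. = FALSE)
  names(fcs_cutoffs) <- c("poor_max", "borderline_max")
  pwfe_cutoffs <- as.numeric(pwfe_cutoffs)
  if (length(pwfe_cutoffs) != 3 || any(diff(pwfe_cutoffs) <= 0) ||
      pwfe_cutoffs[1] <= 0 || pwfe_cutoffs[3] >= 1)
    stop("pwfe_cutoffs must be three increasing proportions in (0,1)",
         call. = FALSE)
  stopifnot(is.data.frame(coping_items),
            all(c("name", "tier") %in% names(coping_items)))
  if (!all(coping_items$tier %in% c("stress", "crisis", "emergency")))
    stop("coping item tiers must be stress, crisis or emergency", call. = FALSE)
  if (anyDuplicated(coping_items$name))
    stop("coping item names must be unique", call. = FALSE)
  for (ind in c("fcs", "pwfe", "csi")) {
    m <- four_point_map[[ind]]
    lv <- switch(ind, fcs = FCS_LEVELS, pwfe = PWFE_LEVELS, csi = CSI_LEVELS)
    if (!setequal(names(m), lv) || !all(m %in% 1:4))
      stop("four_point_map$", ind, " must map every ", ind,
           " category to a score in 1..4", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0,1)", call. = FALSE)
  structure(
    list(food_groups = food_groups,
         fcs_cutoffs = fcs_cutoffs,
         pwfe_cutoffs = pwfe_cutoffs,
         coping_items = coping_items,
         four_point_map = four_point_map,
         alpha = alpha),
    class = "indicator_config")
}

#' @export
print.indicator_config <- function(x, ...) {
  cat("<indicator_config>\n")
  cat("  food groups: ", nrow(x$food_groups), " (",
      paste0(x$food_groups$name, collapse = ", "), ")\n", sep = "")
  cat("  FCS cutoffs: poor <=", x$fcs_cutoffs[["poor_max"]],
      "< borderline <=", x$fcs_cutoffs[["borderline_max"]], "< acceptable\n")
  cat("  PWFE cutoffs:", paste(x$pwfe_cutoffs, collapse = ", "), "\n")
  cat("  coping items:", nrow(x$coping_items), "\n")
  cat("  alpha:", x$alpha, "\n")
  invisible(x)
}

#' Read / write an indicator configuration as YAML
#'
#' @param path file path.
#' @param config an `indicator_config`.
#' @return `read_config` returns an `indicator_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  indicator_config(
    food_groups = data.frame(name = vapply(raw$food_groups, `[[`, "", "name"),
                             weight = vapply(raw$food_groups, function(g)
                               as.numeric(g$weight), 0)),
    fcs_cutoffs = unlist(raw$fcs_cutoffs),
    pwfe_cutoffs = unlist(raw$pwfe_cutoffs),
    coping_items = data.frame(name = vapply(raw$coping_items, `[[`, "", "name"),
                              tier = vapply(raw$coping_items, `[[`, "", "tier")),
    four_point_map = lapply(raw$four_point_map, function(m) {
      v <- vapply(m, as.integer, 0L)
      v
    }),
    alpha = raw$alpha)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "indicator_config"))
  out <- list(
    food_groups = lapply(seq_len(nrow(config$food_groups)), function(i)
      list(name = config$food_groups$name[i],
           weight = config$food_groups$weight[i])),
    fcs_cutoffs = as.list(config$fcs_cutoffs),
    pwfe_cutoffs = as.numeric(config$pwfe_cutoffs),
    coping_items = lapply(seq_len(nrow(config$coping_items)), function(i)
      list(name = config$coping_items$name[i],
           tier = config$coping_items$tier[i])),
    four_point_map = lapply(config$four_point_map, as.list),
    alpha = config$alpha)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Round half away from zero
#'
#' Display-style rounding at `digits` decimals with `.5` always rounded up
#' in magnitude; base `round()` rounds half to even, which shifts boundary
#' cases both in percentage tables and in the index combination.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
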