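#' Combine the three indicators into the Food Security Index
#'
#' Follows the CARI console structure: each indicator category maps to a
#' 4-point score; the coping-capacity domain is the mean of the economic
#' vulnerability (PWFE) and livelihood-coping (CSI) scores; the index is the
#' mean of the current-status (FCS) score and the coping-capacity score,
#' rounded to the nearest integer with halves rounded up:
#'
#' `fsi = round_half_up( (fcs_pt + (pwfe_pt + csi_pt)/2) / 2 )`
#'
#' Half-up rounding (not banker's) is required for the index to behave
#' monotonically at the .5 boundaries — e.g. an acceptable-FCS household
#' using emergency coping with PWFE > 75% scores (1 + 4)/2 = 2.5 and must
#' classify as moderately food insecure, not marginally secure.
#'
#' @param fcs_cat,pwfe_cat,csi_cat category vectors (character or factor).
#' @param map 4-point score maps, see [default_four_point_map()].
#' @param rounding `"half_up"` (default) or `"banker"` (IEEE round-half-even;
#'   exposed for sensitivity analysis only).
#' @return A tibble with columns `fcs_pt`, `pwfe_pt`, `csi_pt`,
#'   `coping_capacity`, `fsi` (integer 1-4) and `fsi_label`
#'   (factor FS < MFS < MFI < SFI).
#' @export
#' @examples
#' compute_fsi("acceptable", "gt75", "emergency")$fsi_label  # MFI
compute_fsi <- function(fcs_cat, pwfe_cat, csi_cat,
                        map = default_four_point_map(),
                        rounding = c("half_up", "banker")) {
  rounding <- match.arg(rounding)
  pt <- function(x, m, what) {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% names(m))
    if (any(bad))
      stop("unmapped ", what, " category: ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    as.numeric(m[x])
  }
  fcs_pt <- pt(fcs_cat, map$fcs, "fcs")
  pwfe_pt <- pt(pwfe_cat, map$pwfe, "pwfe")
  csi_pt <- pt(csi_cat, map$csi, "csi")
  coping <- (pwfe_pt + csi_pt) / 2
  raw <- (fcs_pt + coping) / 2
  fsi <- as.integer(if (rounding == "half_up") round_half_up(raw) else round(raw))
  tibble::tibble(
    fcs_pt = as.integer(fcs_pt), pwfe_pt = as.integer(pwfe_pt),
    csi_pt = as.integer(csi_pt), coping_capacity = coping,
    fsi = fsi, fsi_label = factor(FSI_LEVELS[fsi], levels = FSI_LEVELS))
}

#' Classify every household in a scored survey
#'
#' Applies [compute_fsi()] to the indicator categories computed by
#' [compute_indicators()] and appends `fsi` and `fsi_label` columns.
#'
#' @param survey a survey tibble with `fcs_cat`, `pwfe_cat`, `csi_cat`.
#' @param config an [indicator_config()].
#' @return The survey with `fsi` (1-4) and `fsi_label` filled; counts per
#'   level are available via `table(survey$fsi_label)`.
#' @export
classify_dataset <- function(survey, config = attr(survey, "config")) {
  if (is.null(config)) config <- indicator_config()
  if (nrow(survey) == 0) {
    survey$fsi <- integer(0)
    survey$fsi_label <- factor(character(0), levels = FSI_LEVELS)
    return(survey)
  }
  res <- compute_fsi(survey$fcs_cat, survey$pwfe_cat, survey$csi_cat,
                     map = config$four_point_map)
  survey$fsi <- res$fsi
  survey$fsi_label <- res$fsi_label
  attr(survey, "config") <- config
  survey
}

#' Build the CARI reporting console
#'
#' For each component indicator, the distribution of its 4-point score over
#' the four food-security levels (row percentages, integer-rounded), plus
#' the Food Security Index row.  Each indicator row uses its own non-missing
#' `n`; the FSI row uses the number of fully classified households.
#'
#' @param survey a classified survey (see [classify_dataset()]).
#' @param config an [indicator_config()].
#' @return An object of class `cari_console`: a tibble with columns
#'   `domain`, `indicator`, `n`, `FS`, `MFS`, `MFI`, `SFI`.
#' @export
build_console <- function(survey, config = attr(survey, "config")) {
  if (is.null(config)) config <- indicator_config()
  m <- config$four_point_map
  row_of <- function(pts) {
    pts <- pts[!is.na(pts)]
    n <- length(pts)
    pct <- if (n) round_half_up(100 * vapply(1:4, function(k)
      sum(pts == k), 0L) / n) else rep(NA_real_, 4)
    c(n = n, stats::setNames(pct, FSI_LEVELS))
  }
  rows <- rbind(
    row_of(as.integer(m$fcs[as.character(survey$fcs_cat)])),
    row_of(as.integer(m$pwfe[as.character(survey$pwfe_cat)])),
    row_of(as.integer(m$csi[as.character(survey$csi_cat)])),
    row_of(survey$fsi))
  out <- tibble::tibble(
    domain = c("Current status", "Coping capacity", "Coping capacity",
               "Index"),
    indicator = c("Food consumption score (FCS)",
                  "Proportion of wages allocated to food expenses (PWFE)",
                  "Coping strategy index (CSI)",
                  "Food security index"),
    n = as.integer(rows[, "n"]),
    FS = rows[, "FS"], MFS = rows[, "MFS"],
    MFI = rows[, "MFI"], SFI = rows[, "SFI"])
  class(out) <- c("cari_console", class(out))
  out
}

#' @export
print.cari_console <- function(x, ...) {
  cat("CARI reporting console (row %)\n")
  cat(sprintf("  %-55s %6s %4s %4s %4s %4s\n", "Indicator", "n",
              "FS", "MFS", "MFI", "SFI"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-55s %6d %4.0f %4.0f %4.0f %4.0f\n",
                x$indicator[i], x$n[i], x$FS[i], x$MFS[i], x$MFI[i],
                x$SFI[i]))
  invisible(x)
}
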