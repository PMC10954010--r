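#' Labeled contingency table with a Pearson chi-square test
#'
#' Constructs a `contingency_table` from a counts matrix: marginal totals,
#' the Pearson statistic `X^2 = sum (O-E)^2 / E` without continuity
#' correction, its degrees of freedom `(r-1)(c-1)` and p-value.  A warning
#' is issued (but the plain chi-square is kept) when any expected count
#' falls below 5.
#'
#' @param counts integer matrix with row/column dimnames (or labels given
#'   via `row_labels` / `col_labels`).
#' @param row_labels,col_labels optional character vectors of labels.
#' @return An object of class `contingency_table`: list with `counts`,
#'   `row_totals`, `col_totals`, `total`, `expected`, `statistic`, `df`,
#'   `p.value`.
#' @export
#' @examples
#' tab <- contingency_table(matrix(c(10, 0, 0, 10), 2,
#'                          dimnames = list(c("a", "b"), c("x", "y"))))
#' tab$statistic  # 20
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be nonnegative and complete", call. = FALSE)
  # degenerate: a single observed row or column category leaves df = 0
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  eff <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(eff) < 2 || ncol(eff) < 2)
    stop("degenerate table: fewer than two observed categories on a margin ",
         "(df = 0)", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(eff, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count below 5 in ", sum(ht$expected < 5),
            " cell(s); chi-square approximation may be inaccurate",
            call. = FALSE)
  expected <- matrix(NA_real_, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  expected[keep_r, keep_c] <- ht$expected
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 total = sum(counts),
                 expected = expected,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = unname(ht$p.value)),
            class = "contingency_table")
}

#' Cross-tabulate two categorical survey variables
#'
#' Counts of `row_var` by `col_var` with the Pearson chi-square test of
#' independence attached; unused factor levels are kept as zero rows/columns
#' for display but ignored by the test.
#'
#' @param survey a survey tibble.
#' @param row_var,col_var column names of categorical variables.
#' @return A [contingency_table()].
#' @export
crosstab <- function(survey, row_var, col_var) {
  r <- survey[[row_var]]
  co <- survey[[col_var]]
  if (is.null(r) || is.null(co))
    stop("column not found: ", if (is.null(r)) row_var else col_var,
         call. = FALSE)
  counts <- table(r, co, dnn = c(row_var, col_var))
  contingency_table(unclass(counts))
}

#' Percentage views of a contingency table
#'
#' @param tab a [contingency_table()].
#' @param by `"row"`, `"col"` or `"total"` denominator.
#' @param digits decimals (default 1, the cross-tab reporting convention).
#' @return Matrix of percentages with the table's dimnames.
#' @export
percent <- function(tab, by = c("row", "col", "total"), digits = 1) {
  stopifnot(inherits(tab, "contingency_table"))
  by <- match.arg(by)
  denom <- switch(by,
                  row = matrix(tab$row_totals, nrow(tab$counts),
                               ncol(tab$counts)),
                  col = matrix(tab$col_totals, nrow(tab$counts),
                               ncol(tab$counts), byrow = TRUE),
                  total = tab$total)
  round_half_up(100 * tab$counts / denom, digits)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table (", nrow(x$counts), "x", ncol(x$counts), ")\n",
      sep = "")
  tot <- cbind(rbind(x$counts, Total = x$col_totals),
               Total = c(x$row_totals, x$total))
  print(tot)
  cat(sprintf("Pearson X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Association between the FSI and its component indicators
#'
#' Cross-tabulates each component category (FCS, PWFE, CSI) against the
#' Food Security Index with Pearson chi-square tests — the column-percent
#' layout used when reporting how each indicator distributes within each
#' food-security level.
#'
#' @param survey a classified survey (see [classify_dataset()]).
#' @return Named list of three [contingency_table()] objects
#'   (`fcs`, `pwfe`, `csi`), each with a `col_pct` element attached.
#' @export
association_report <- function(survey) {
  out <- lapply(c(fcs = "fcs_cat", pwfe = "pwfe_cat", csi = "csi_cat"),
                function(v) {
                  tab <- crosstab(survey, v, "fsi_label")
                  tab$col_pct <- percent(tab, "col")
                  tab
                })
  out
}

#' Export a contingency table as CSV
#'
#' Writes counts with marginal totals, a percentage view, and the test
#' result as a trailing comment-free block.
#'
#' @param tab a [contingency_table()].
#' @param path destination.
#' @param by percentage denominator passed to [percent()].
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(tab, path, by = "row") {
  counts <- cbind(rbind(tab$counts, Total = tab$col_totals),
                  Total = c(tab$row_totals, tab$total))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# counts", con)
  utils::write.csv(counts, con)
  writeLines(paste0("# percent by ", by), con)
  utils::write.csv(percent(tab, by), con)
  writeLines(sprintf("# chisq,%.6f,df,%d,p,%.6g",
                     tab$statistic, tab$df, tab$p.value), con)
  invisible(path)
}
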