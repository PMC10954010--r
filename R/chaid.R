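#' CHAID growing parameters
#'
#' Stopping and adjustment settings for the CHAID segmentation.
#' Defaults: merge and split significance 0.05, at most three predictor
#' levels, nodes below 100 households are not re-split, children below 50
#' are not created, Bonferroni adjustment on.
#'
#' @param alpha_split significance level a Bonferroni-adjusted split p-value
#'   must reach.
#' @param alpha_merge category pairs whose 2xJ chi-square p-value exceeds
#'   this are merged.
#' @param max_depth maximum number of predictor levels below the root.
#' @param min_parent minimum node size to attempt a split.
#' @param min_child minimum size of every prospective child.
#' @param bonferroni multiply the split p-value by the number of admissible
#'   category reductions (capped at 1)?
#' @param predictor_adjust additionally multiply the selected p-value by the
#'   number of candidate predictors, so the split decision controls the
#'   familywise error of the whole split search at `alpha_split` (the
#'   variable-selection Bonferroni used by conditional-inference trees).
#' @return An object of class `chaid_params`.
#' @export
chaid_params <- function(alpha_split = 0.05, alpha_merge = 0.05,
                         max_depth = 3, min_parent = 100, min_child = 50,
                         bonferroni = TRUE, predictor_adjust = TRUE) {
  stopifnot(alpha_split > 0, alpha_split < 1,
            alpha_merge > 0, alpha_merge < 1,
            max_depth >= 1, min_parent >= 1, min_child >= 1)
  structure(list(alpha_split = alpha_split, alpha_merge = alpha_merge,
                 max_depth = as.integer(max_depth),
                 min_parent = as.integer(min_parent),
                 min_child = as.integer(min_child),
                 bonferroni = isTRUE(bonferroni),
                 predictor_adjust = isTRUE(predictor_adjust)),
            class = "chaid_params")
}

# Pearson chi-square of a counts matrix after dropping zero margins.
# Returns p = 1 (df 0) for tables with fewer than two observed categories
# on either margin -- such comparisons carry no evidence against merging.
chisq_p <- function(counts) {
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2)
    return(list(statistic = 0, df = 0L, p = 1, log_p = 0))
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  # log-scale p survives the underflow that strong splits produce at
  # survey-scale n, keeping candidate comparisons well defined
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value),
       log_p = stats::pchisq(unname(ht$statistic), unname(ht$parameter),
                             lower.tail = FALSE, log.p = TRUE))
}

#' Kass-style category merging
#'
#' The CHAID merge step: starting from one group per observed category,
#' repeatedly find the pair of groups (adjacent groups only, for ordinal
#' predictors) whose 2xJ chi-square against the target has the largest
#' p-value; while that p-value exceeds `alpha_merge`, merge the pair.  Stops
#' when all remaining pairs differ significantly or one group is left.
#'
#' @param x predictor values (factor; unobserved levels are dropped).
#' @param y target values (factor), same length as `x`.
#' @param scale `"ordinal"` (merge adjacent only) or `"nominal"`.
#' @param alpha_merge merge threshold.
#' @return A list of character vectors: the partition of the observed
#'   categories into merged groups, in category order.
#' @export
merge_categories <- function(x, y, scale = c("ordinal", "nominal"),
                             alpha_merge = 0.05) {
  scale <- match.arg(scale)
  x <- droplevels(factor(x))
  y <- factor(y)
  groups <- as.list(levels(x))
  if (length(groups) < 2) return(groups)
  counts_of <- function(g) {
    tabulate(as.integer(y)[x %in% g], nbins = nlevels(y))
  }
  repeat {
    k <- length(groups)
    if (k == 1) break
    pairs <- if (scale == "ordinal")
      lapply(seq_len(k - 1), function(i) c(i, i + 1L))
    else
      unlist(lapply(seq_len(k - 1), function(i)
        lapply((i + 1):k, function(j) c(i, j))), recursive = FALSE)
    pvals <- vapply(pairs, function(pr) {
      tab <- rbind(counts_of(groups[[pr[1]]]), counts_of(groups[[pr[2]]]))
      chisq_p(tab)$p
    }, 0)
    best <- which.max(pvals)
    if (pvals[best] <= alpha_merge) break
    pr <- pairs[[best]]
    merged <- c(groups[[pr[1]]], groups[[pr[2]]])
    groups <- c(groups[-pr], list(merged))
    # restore category order so ordinal adjacency stays meaningful
    groups <- groups[order(vapply(groups, function(g)
      min(match(g, levels(x))), 0))]
  }
  groups
}

#' Bonferroni multiplier for a merged partition
#'
#' Number of ways `c` original categories can be reduced to `r` groups:
#' `choose(c-1, r-1)` for ordinal predictors (contiguous partitions),
#' and the Stirling-type sum
#' `sum_{i=0}^{r-1} (-1)^i (r-i)^c / (i! (r-i)!)` for nominal ones.
#'
#' @param c number of original (observed) categories.
#' @param r number of merged groups, `1 <= r <= c`.
#' @param scale `"ordinal"` or `"nominal"`.
#' @return Integer multiplier.
#' @export
#' @examples
#' bonferroni_multiplier(4, 2, "ordinal")  # 3
#' bonferroni_multiplier(3, 2, "nominal")  # 3
bonferroni_multiplier <- function(c, r, scale = c("ordinal", "nominal")) {
  scale <- match.arg(scale)
  if (r < 1 || r > c) stop("need 1 <= r <= c", call. = FALSE)
  if (scale == "ordinal") return(choose(c - 1, r - 1))
  i <- 0:(r - 1)
  round(sum((-1)^i * (r - i)^c / (factorial(i) * factorial(r - i))))
}

merged_factor <- function(x, partition) {
  labels <- vapply(partition, paste, "", collapse = "+")
  idx <- integer(0)
  map <- stats::setNames(rep(labels, lengths(partition)),
                         unlist(partition))
  factor(map[as.character(x)], levels = labels)
}

# all partitions of 1..c into r contiguous blocks
contiguous_partitions <- function(c, r) {
  if (r == 1) return(list(list(1:c)))
  lapply(utils::combn(c - 1, r - 1, simplify = FALSE), function(ct) {
    bounds <- c(0, ct, c)
    lapply(seq_len(r), function(b) (bounds[b] + 1):bounds[b + 1])
  })
}

#' Select the best CHAID split for a node
#'
#' For each candidate predictor, searches every admissible merged partition
#' of its observed categories exactly.  A partition is admissible when
#'
#' * its groups are contiguous runs of the (ordinal) category order,
#' * it is *merge-stable*: every adjacent pair of groups differs from each
#'   other at `alpha_merge` by the 2xJ chi-square test — the stopping
#'   criterion of the Kass merge step, imposed exactly rather than reached
#'   greedily (see [merge_categories()] for the classic sequential step),
#' * every prospective child holds at least `min_child` households.
#'
#' Each admissible partition is scored by its Pearson chi-square p-value
#' against the target, Bonferroni-multiplied by the number of ways the
#' observed categories can be reduced to that many groups and (with
#' `predictor_adjust`) by the number of candidate predictors, capped at 1.
#' The smallest adjusted p wins if it is at or below `alpha_split`; ties go
#' to the earlier predictor in the given order, then to fewer groups.
#'
#' @param data data frame holding the node's rows.
#' @param target name of the target column (factor).
#' @param predictors character vector of predictor column names, in
#'   priority order; all treated as ordinal under their factor-level order.
#' @param params a [chaid_params()].
#' @return `NULL` if no admissible split, else a list with `predictor`,
#'   `partition`, `p`, `adjusted_p`, `statistic`, `df`.
#' @export
best_split <- function(data, target, predictors, params = chaid_params()) {
  y <- droplevels(factor(data[[target]]))
  if (nrow(data) < params$min_parent || nlevels(y) < 2) return(NULL)
  xs <- lapply(predictors, function(p) droplevels(factor(data[[p]])))
  n_cand <- sum(vapply(xs, nlevels, 0L) >= 2)
  if (n_cand == 0) return(NULL)
  m_pred <- if (params$predictor_adjust) n_cand else 1
  best <- NULL
  for (pi in seq_along(predictors)) {
    x <- xs[[pi]]
    cc <- nlevels(x)
    if (cc < 2) next
    xi <- as.integer(x)
    yi <- as.integer(y)
    for (r in 2:cc) {
      mult <- if (params$bonferroni)
        bonferroni_multiplier(cc, r, "ordinal") else 1
      for (part in contiguous_partitions(cc, r)) {
        gi <- integer(cc)
        for (b in seq_len(r)) gi[part[[b]]] <- b
        xm <- gi[xi]
        sizes <- tabulate(xm, r)
        if (any(sizes < params$min_child)) next
        counts <- matrix(0L, r, nlevels(y))
        for (b in seq_len(r))
          counts[b, ] <- tabulate(yi[xm == b], nbins = nlevels(y))
        stable <- all(vapply(seq_len(r - 1), function(b)
          chisq_p(counts[c(b, b + 1), , drop = FALSE])$p <=
            params$alpha_merge, TRUE))
        if (!stable) next
        ct <- chisq_p(counts)
        log_adj <- min(0, ct$log_p + log(mult * m_pred))
        if (log_adj > log(params$alpha_split)) next
        cand <- list(predictor = predictors[pi],
                     partition = lapply(part, function(ix) levels(x)[ix]),
                     p = ct$p, adjusted_p = exp(log_adj),
                     log_adjusted_p = log_adj,
                     statistic = ct$statistic, df = ct$df)
        # strict <: ties keep the earlier predictor / fewer groups
        if (is.null(best) || cand$log_adjusted_p < best$log_adjusted_p)
          best <- cand
      }
    }
  }
  best
}

#' Grow a CHAID segmentation tree
#'
#' Recursive application of [best_split()] from the root.  Deterministic
#' given the data and parameters: chi-square statistics do not depend on row
#' order and ties are broken by the fixed predictor order.
#'
#' @param data data frame; must contain the target and predictor columns
#'   as factors and be complete on them.
#' @param target target column name (e.g. `"fsi_label"`).
#' @param predictors predictor column names in priority order.
#' @param params a [chaid_params()].
#' @return An object of class `chaid_tree`: list with `nodes` (list of node
#'   records), `target`, `predictors`, `params`, `n`.
#' @export
grow_tree <- function(data, target, predictors, params = chaid_params()) {
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  if (anyNA(data[, c(target, predictors)]))
    stop("target/predictors contain missing values; complete-case first",
         call. = FALSE)
  nodes <- list()
  tlevels <- levels(factor(data[[target]]))
  new_node <- function(rows, depth, parent, path) {
    y <- factor(data[[target]][rows], levels = tlevels)
    comp <- table(y)
    modal <- names(comp)[which.max(comp)]
    list(id = length(nodes) + 1L, depth = depth, parent = parent,
         rows = rows, n = length(rows),
         composition = comp,
         modal_label = modal,
         label_share = max(comp) / length(rows),
         split_predictor = NA_character_, partition = NULL,
         adjusted_p = NA_real_, statistic = NA_real_,
         children = integer(0), path = path)
  }
  grow <- function(node_id) {
    node <- nodes[[node_id]]
    if (node$depth >= params$max_depth) return(invisible())
    sp <- best_split(data[node$rows, , drop = FALSE], target, predictors,
                     params)
    if (is.null(sp)) return(invisible())
    x <- data[[sp$predictor]][node$rows]
    xm <- merged_factor(x, sp$partition)
    kids <- integer(0)
    for (g in seq_along(sp$partition)) {
      rows_g <- node$rows[as.integer(xm) == g]
      pred_path <- c(node$path, paste0(
        sp$predictor, " in {",
        paste(sp$partition[[g]], collapse = ","), "}"))
      child <- new_node(rows_g, node$depth + 1L, node$id, pred_path)
      nodes[[child$id]] <<- child
      kids <- c(kids, child$id)
    }
    node$split_predictor <- sp$predictor
    node$partition <- sp$partition
    node$adjusted_p <- sp$adjusted_p
    node$statistic <- sp$statistic
    node$children <- kids
    nodes[[node_id]] <<- node
    for (k in kids) grow(k)
    invisible()
  }
  root <- new_node(seq_len(nrow(data)), 0L, NA_integer_, character(0))
  nodes[[1L]] <- root
  grow(1L)
  structure(list(nodes = nodes, target = target, predictors = predictors,
                 params = params, n = nrow(data)),
            class = "chaid_tree")
}

#' Terminal-group summary of a CHAID tree
#'
#' One record per leaf: the defining path (one predicate per split level),
#' size, modal target label and its share, and the full target composition.
#' Leaves are numbered in depth-first order, mirroring how segmentation
#' groups are usually labeled.
#'
#' @param tree a [grow_tree()] result.
#' @param data optional: the data the tree was grown on; when it carries a
#'   `pwfe_cat` column, each leaf also gets the within-leaf PWFE
#'   distribution (row-percent style).
#' @return A tibble: `group`, `node_id`, `path`, `n`, `modal_label`,
#'   `label_share`, one `n_<level>` column per target level, and optionally
#'   `pwfe_pct_<band>` columns.
#' @export
terminal_groups <- function(tree, data = NULL) {
  leaves <- Filter(function(nd) length(nd$children) == 0, tree$nodes)
  ord <- order(vapply(leaves, `[[`, 0L, "id"))
  leaves <- leaves[ord]
  comp <- do.call(rbind, lapply(leaves, function(nd)
    as.integer(nd$composition)))
  colnames(comp) <- paste0("n_", names(leaves[[1]]$composition))
  out <- tibble::tibble(
    group = paste0("G", seq_along(leaves)),
    node_id = vapply(leaves, `[[`, 0L, "id"),
    path = vapply(leaves, function(nd)
      if (length(nd$path)) paste(nd$path, collapse = " & ") else "<root>",
      ""),
    n = vapply(leaves, `[[`, 0L, "n"),
    modal_label = vapply(leaves, `[[`, "", "modal_label"),
    label_share = vapply(leaves, `[[`, 0, "label_share"))
  out <- cbind(out, tibble::as_tibble(comp))
  if (!is.null(data) && "pwfe_cat" %in% names(data)) {
    pw <- do.call(rbind, lapply(leaves, function(nd) {
      p <- table(factor(data$pwfe_cat[nd$rows], levels = PWFE_LEVELS))
      round_half_up(100 * as.numeric(p) / nd$n, 1)
    }))
    colnames(pw) <- paste0("pwfe_pct_", PWFE_LEVELS)
    out <- cbind(out, tibble::as_tibble(pw))
  }
  tibble::as_tibble(out)
}

#' @export
print.chaid_tree <- function(x, ...) {
  cat(format_chaid(x), sep = "\n")
  invisible(x)
}

#' Format a CHAID tree as indented text
#'
#' @param tree a [grow_tree()] result.
#' @return Character vector of lines.
#' @export
format_chaid <- function(tree) {
  lines <- character(0)
  emit <- function(id, label) {
    nd <- tree$nodes[[id]]
    indent <- strrep("  ", nd$depth)
    head <- sprintf("%snode %d%s: n=%d, modal=%s (%.1f%%)", indent, nd$id,
                    if (nzchar(label)) paste0(" [", label, "]") else "",
                    nd$n, nd$modal_label, 100 * nd$label_share)
    if (!is.na(nd$split_predictor))
      head <- paste0(head, sprintf(" | split on %s (adj p=%.3g)",
                                   nd$split_predictor, nd$adjusted_p))
    lines <<- c(lines, head)
    for (i in seq_along(nd$children)) {
      g <- paste(nd$partition[[i]], collapse = ",")
      emit(nd$children[i], paste0(nd$split_predictor, ": ", g))
    }
  }
  emit(1L, "")
  lines
}

#' Export a CHAID tree as structured JSON
#'
#' Nested node objects (split predicate, n, adjusted p, modal label,
#' composition), suitable for diffing.
#'
#' @param tree a [grow_tree()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, path) {
  as_list <- function(id) {
    nd <- tree$nodes[[id]]
    out <- list(id = nd$id, n = nd$n, depth = nd$depth,
                modal_label = nd$modal_label,
                label_share = round(nd$label_share, 4),
                composition = as.list(nd$composition),
                path = nd$path)
    if (!is.na(nd$split_predictor)) {
      out$split <- list(
        predictor = nd$split_predictor,
        groups = lapply(nd$partition, identity),
        adjusted_p = nd$adjusted_p)
      out$children <- lapply(nd$children, as_list)
    }
    out
  }
  jsonlite::write_json(as_list(1L), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
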