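# Independent oracles, kept deliberately naive: they never call the
# package's own chi-square or CHAID code paths.

# Pearson X^2 by explicit double loop over cells
oracle_chisq <- function(counts) {
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       log_p = stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE))
}

# all partitions of 1..c into r contiguous blocks (ordinal CHAID merges)
oracle_contiguous_partitions <- function(c, r) {
  cuts <- utils::combn(c - 1, r - 1, simplify = FALSE)
  lapply(cuts, function(ct) {
    bounds <- c(0, ct, c)
    lapply(seq_len(r), function(b) (bounds[b] + 1):bounds[b + 1])
  })
}

# exhaustive search over every admissible merged partition (contiguous,
# merge-stable at alpha_merge, min_child respected) of every predictor,
# scored by the same doubly Bonferroni-adjusted Pearson p-value
oracle_best_split <- function(data, target, predictors,
                              params = cariseg::chaid_params()) {
  y <- droplevels(factor(data[[target]]))
  if (nrow(data) < params$min_parent || nlevels(y) < 2) return(NULL)
  n_cand <- sum(vapply(predictors, function(p)
    nlevels(droplevels(factor(data[[p]]))), 0L) >= 2)
  if (n_cand == 0) return(NULL)
  m_pred <- if (params$predictor_adjust) n_cand else 1
  best <- NULL
  for (pi in seq_along(predictors)) {
    x <- droplevels(factor(data[[predictors[pi]]]))
    cc <- nlevels(x)
    if (cc < 2) next
    for (r in 2:cc) {
      mult <- if (params$bonferroni) choose(cc - 1, r - 1) else 1
      for (part in oracle_contiguous_partitions(cc, r)) {
        gi <- integer(nlevels(x))
        for (b in seq_along(part)) gi[part[[b]]] <- b
        xm <- gi[as.integer(x)]
        if (any(tabulate(xm, r) < params$min_child)) next
        stable <- all(vapply(seq_len(r - 1), function(b) {
          sub <- xm %in% c(b, b + 1)
          tab2 <- table(xm[sub], y[sub])
          tab2 <- tab2[rowSums(tab2) > 0, colSums(tab2) > 0, drop = FALSE]
          if (nrow(tab2) < 2 || ncol(tab2) < 2) return(FALSE)
          oracle_chisq(unclass(tab2))$p <= params$alpha_merge
        }, TRUE))
        if (!stable) next
        tab <- table(xm, y)
        if (nrow(tab) < 2 || sum(colSums(tab) > 0) < 2) next
        lp <- oracle_chisq(unclass(tab))$log_p
        log_adj <- min(0, lp + log(mult * m_pred))
        if (log_adj > log(params$alpha_split)) next
        cand <- list(predictor = predictors[pi], pred_idx = pi,
                     partition = lapply(part, function(ix) levels(x)[ix]),
                     r = r, adjusted_p = exp(log_adj),
                     log_adjusted_p = log_adj)
        if (is.null(best) ||
            cand$log_adjusted_p < best$log_adjusted_p ||
            (cand$log_adjusted_p == best$log_adjusted_p &&
             (cand$pred_idx < best$pred_idx ||
              (cand$pred_idx == best$pred_idx && cand$r < best$r))))
          best <- cand
      }
    }
  }
  best
}

same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(mapply(function(x, y) identical(as.character(x), as.character(y)),
               a, b))
}

# minimal raw survey with controllable categories, built through the
# generator's constructive synthesis path is avoided on purpose here:
# hand-rolled raw rows exercise read/score independently of generate()
make_raw_household <- function(id = "h1",
                               days = rep(7, 8),
                               food_spend = 300, total_spend = 1000,
                               coping_yes = character(0),
                               area = "urban", head_sex = "female",
                               head_age = 40,
                               civil_status = "married_or_couple",
                               hh_size = 4) {
  cfg <- cariseg::indicator_config()
  row <- data.frame(id = id, area = area, head_sex = head_sex,
                    head_age = head_age, civil_status = civil_status,
                    hh_size = hh_size, stringsAsFactors = FALSE)
  dn <- paste0("days_", cfg$food_groups$name)
  for (i in seq_along(dn)) row[[dn[i]]] <- days[i]
  row$food_spend <- food_spend
  row$total_spend <- total_spend
  for (item in cfg$coping_items$name)
    row[[paste0("cs_", item)]] <- as.integer(item %in% coping_yes)
  row
}

make_raw_survey <- function(rows) {
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "config") <- cariseg::indicator_config()
  out
}
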