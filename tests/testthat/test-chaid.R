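small_params <- chaid_params(min_parent = 20, min_child = 5)

test_that("Bonferroni multipliers count admissible category reductions", {
  # ordinal: contiguous partitions, enumerated independently
  for (cc in 2:5) for (r in 1:cc)
    expect_equal(bonferroni_multiplier(cc, r, "ordinal"),
                 length(oracle_contiguous_partitions(cc, r)))
  expect_equal(bonferroni_multiplier(4, 2, "ordinal"), 3)
  expect_equal(bonferroni_multiplier(7, 1, "ordinal"), 1)
  # nominal: set partitions of 3 into 2 blocks = 3; Stirling S(4,2) = 7
  expect_equal(bonferroni_multiplier(3, 2, "nominal"), 3)
  expect_equal(bonferroni_multiplier(4, 2, "nominal"), 7)
  expect_equal(bonferroni_multiplier(5, 1, "nominal"), 1)
  expect_error(bonferroni_multiplier(3, 4), "r <= c")
})

test_that("category merging keeps significantly different categories apart", {
  # a 2-category predictor yields either one or two groups
  set.seed(71)
  x <- factor(rep(c("a", "b"), each = 50))
  y_same <- factor(sample(c("u", "v"), 100, TRUE))
  expect_length(merge_categories(x, y_same, alpha_merge = 0.05), 1)
  y_diff <- factor(rep(c("u", "v"), each = 50))
  expect_length(merge_categories(x, y_diff, alpha_merge = 0.05), 2)

  # predictor identical to the target: no merges at large n
  z <- factor(sample(letters[1:4], 400, TRUE))
  part <- merge_categories(z, z, scale = "ordinal")
  expect_length(part, 4)

  # predictor independent of the target collapses to one group most times
  collapsed <- 0
  for (i in 1:40) {
    x <- factor(sample(letters[1:3], 400, TRUE))
    y <- factor(sample(c("u", "v", "w"), 400, TRUE))
    if (length(merge_categories(x, y)) == 1) collapsed <- collapsed + 1
  }
  expect_gt(collapsed / 40, 0.5)
})

test_that("ordinal merging only joins adjacent categories", {
  set.seed(8)
  for (i in 1:30) {
    x <- factor(sample(c("L", "M", "H"), 60, TRUE), levels = c("L", "M", "H"))
    y <- factor(sample(c("u", "v"), 60, TRUE, prob = c(0.5, 0.5)))
    part <- merge_categories(x, y, scale = "ordinal")
    for (g in part) {
      idx <- sort(match(g, c("L", "M", "H")))
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})

test_that("best_split picks a perfectly predictive predictor over noise", {
  set.seed(19)
  y <- factor(sample(c("u", "v", "w"), 120, TRUE))
  d <- data.frame(y = y,
                  signal = factor(as.character(y), levels = c("u", "v", "w")),
                  noise = factor(sample(c("a", "b", "c"), 120, TRUE)))
  sp <- best_split(d, "y", c("noise", "signal"), small_params)
  expect_equal(sp$predictor, "signal")
  expect_length(sp$partition, 3)
  expect_lt(sp$adjusted_p, 1e-10)

  # below min_parent: no split
  expect_null(best_split(d[1:10, ], "y", c("noise", "signal"), small_params))
  # constant target: no split
  d2 <- d; d2$y <- factor(rep("u", 120))
  expect_null(best_split(d2, "y", c("noise", "signal"), small_params))
})

test_that("best_split agrees with the exhaustive-partition oracle", {
  set.seed(20240901)
  params <- small_params
  for (rep in 1:120) {
    n <- sample(30:60, 1)
    y <- factor(sample(letters[1:3], n, replace = TRUE))
    mk_pred <- function() {
      probs <- matrix(stats::rgamma(9, shape = stats::runif(1, 0.3, 3)), 3, 3)
      probs <- probs / rowSums(probs)
      factor(vapply(as.integer(y), function(k)
        sample(c("L", "M", "H"), 1, prob = probs[k, ]), ""),
        levels = c("L", "M", "H"))
    }
    d <- data.frame(y = y, p1 = mk_pred(), p2 = mk_pred())
    got <- best_split(d, "y", c("p1", "p2"), params)
    want <- oracle_best_split(d, "y", c("p1", "p2"), params)
    expect_equal(is.null(got), is.null(want))
    if (!is.null(got) && !is.null(want)) {
      expect_equal(got$predictor, want$predictor)
      expect_true(same_partition(got$partition, want$partition))
      expect_equal(got$adjusted_p, want$adjusted_p, tolerance = 1e-9)
    }
  }
})

test_that("grown trees partition the data, respect limits and are order-invariant", {
  sv <- generate(generator_params(n = 1200), seed = 55)
  scored <- as.data.frame(classify_dataset(compute_indicators(
    complete_cases(sv))))
  preds <- c("fcs_cat", "csi_cat", "pwfe_cat")
  params <- chaid_params()
  tree <- grow_tree(scored, "fsi_label", preds, params)

  leaves <- Filter(function(nd) length(nd$children) == 0, tree$nodes)
  all_rows <- sort(unlist(lapply(leaves, `[[`, "rows")))
  expect_equal(all_rows, seq_len(nrow(scored)))          # exact partition
  expect_true(all(vapply(tree$nodes, `[[`, 0L, "depth") <= params$max_depth))
  internal <- Filter(function(nd) length(nd$children) > 0, tree$nodes)
  for (nd in internal) {
    expect_gte(nd$n, params$min_parent)
    expect_lte(nd$adjusted_p, params$alpha_split)
    kid_n <- vapply(nd$children, function(k) tree$nodes[[k]]$n, 0L)
    expect_true(all(kid_n >= params$min_child))
    expect_equal(sum(kid_n), nd$n)
  }

  # row order must not matter
  perm <- sample(nrow(scored))
  tree2 <- grow_tree(scored[perm, ], "fsi_label", preds, params)
  expect_equal(format_chaid(tree2)[order(format_chaid(tree2))],
               format_chaid(tree)[order(format_chaid(tree))])
  g1 <- terminal_groups(tree, scored)
  g2 <- terminal_groups(tree2, scored[perm, ])
  expect_equal(g1$path, g2$path)
  expect_equal(g1$n, g2$n)
  expect_equal(g1$modal_label, g2$modal_label)

  expect_error(grow_tree(scored[0, ], "fsi_label", preds), "empty")
})

test_that("constant target yields a single-node tree covering everything", {
  d <- data.frame(y = factor(rep("u", 200)),
                  x = factor(sample(c("a", "b"), 200, TRUE)))
  tree <- grow_tree(d, "y", "x")
  expect_length(tree$nodes, 1)
  tg <- terminal_groups(tree, d)
  expect_equal(nrow(tg), 1)
  expect_equal(tg$n, 200L)
  expect_equal(tg$path, "<root>")
})

test_that("terminal group sizes always sum to the dataset size", {
  set.seed(23)
  for (i in 1:5) {
    sv <- generate(generator_params(n = 600), seed = 100 + i)
    scored <- as.data.frame(classify_dataset(compute_indicators(
      complete_cases(sv))))
    tree <- grow_tree(scored, "fsi_label",
                      c("fcs_cat", "csi_cat", "pwfe_cat"))
    tg <- terminal_groups(tree, scored)
    expect_equal(sum(tg$n), nrow(scored))
    comp_cols <- paste0("n_", fsi_levels())
    expect_equal(sum(as.matrix(tg[, comp_cols])), nrow(scored))
    # modal label consistent with the composition columns
    for (j in seq_len(nrow(tg)))
      expect_equal(tg$modal_label[j],
                   fsi_levels()[which.max(as.matrix(tg[j, comp_cols]))])
  }
})

test_that("tree text and JSON exports carry the split structure", {
  sv <- generate(generator_params(n = 1500), seed = 4)
  scored <- as.data.frame(classify_dataset(compute_indicators(
    complete_cases(sv))))
  tree <- grow_tree(scored, "fsi_label", c("fcs_cat", "csi_cat", "pwfe_cat"))
  txt <- format_chaid(tree)
  expect_match(txt[1], "split on fcs_cat")
  f <- withr::local_tempfile(fileext = ".json")
  export_tree(tree, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$split$predictor, "fcs_cat")
  expect_equal(parsed$n, nrow(scored))
})
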