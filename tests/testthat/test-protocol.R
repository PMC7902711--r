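test_that("stratified splits preserve class proportions", {
  tab <- tibble::tibble(class = rep(letters[1:20], each = 5))
  sp <- stratified_split(tab, train_frac = 0.8, seed = 3)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  # exactly one test sample per class
  expect_true(all(table(tab$class[sp$test]) == 1))
  # disjoint and exhaustive
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(100))
  # same seed reproduces the plan
  expect_identical(sp, stratified_split(tab, train_frac = 0.8, seed = 3))
  # every class keeps at least one sample on each side even with 2 samples
  tiny <- tibble::tibble(class = rep(c("a", "b"), each = 2))
  sp2 <- stratified_split(tiny, train_frac = 0.95, seed = 1)
  expect_true(all(table(tiny$class[sp2$test]) >= 1))
  expect_error(
    stratified_split(tibble::tibble(class = c("a", "a", "b")), seed = 1),
    "fewer than 2"
  )
  expect_error(stratified_split(tab), "seed")
})

test_that("feature masking implements the four truncation methods", {
  d <- build_design()
  tab <- small_table(seed = 2, design = small_design())
  ylb <- tab[tab$tissue == "YLB", ]
  els <- element_cols(ylb)
  X <- as.matrix(dplyr::as_tibble(ylb)[, els])
  cl <- ylb$class
  sc <- autoscale(X)
  # A: identity
  expect_identical(mask_features(X, cl, "A", d, sc$params), X)
  # B: only the deprived element of each deprivation sample changes
  Xb <- mask_features(X, cl, "B", d, sc$params)
  fe_rows <- which(cl == "-Fe")
  ctrl_rows <- which(cl == "control_D22")
  expect_true(all(Xb[fe_rows, "Fe"] == sc$params$mean["Fe"]))
  expect_identical(Xb[fe_rows, setdiff(els, "Fe")], X[fe_rows, setdiff(els, "Fe")])
  expect_identical(Xb[ctrl_rows, ], X[ctrl_rows, ]) # controls untouched
  # C: exactly the six macronutrients keep their values, for every row
  Xc <- mask_features(X, cl, "C", d, sc$params)
  macros <- c("N", "Mg", "P", "S", "K", "Ca")
  expect_identical(Xc[, macros], X[, macros])
  for (el in setdiff(els, macros)) {
    expect_true(all(Xc[, el] == sc$params$mean[el]))
  }
  # D: deprivation rows keep only their element; controls fully neutralized
  Xd <- mask_features(X, cl, "D", d, sc$params)
  expect_identical(Xd[fe_rows, "Fe"], X[fe_rows, "Fe"])
  expect_true(all(Xd[fe_rows, "Zn"] == sc$params$mean["Zn"]))
  expect_true(all(Xd[ctrl_rows, els] ==
    matrix(sc$params$mean[els], length(ctrl_rows), length(els), byrow = TRUE)))
  expect_error(mask_features(X, cl, "E", d, sc$params), "unknown method")
})

test_that("confusion matrices and their class metrics are consistent", {
  true <- c("a", "a", "b", "b", "b", "c")
  pred <- c("a", "b", "b", "b", "a", "c")
  cm <- confusion_matrix(true, pred)
  expect_equal(dim(cm), c(3, 3))
  expect_equal(sum(cm), 6)
  expect_equal(unname(rowSums(cm)), c(2, 3, 1)) # row sums = class counts
  expect_equal(cm_accuracy(cm), 4 / 6)
  m <- class_sensitivity_specificity(cm)
  expect_equal(m$sensitivity[m$class == "a"], 0.5)
  expect_equal(m$sensitivity[m$class == "b"], 2 / 3)
  # a class with 2/5 correct has sensitivity 0.4
  cm2 <- matrix(c(2, 3, 0, 5), 2, 2,
    byrow = TRUE,
    dimnames = list(c("x", "y"), c("x", "y"))
  )
  expect_equal(
    class_sensitivity_specificity(cm2)$sensitivity[1], 0.4
  )
  # binary specificity: TN / (TN + FP)
  cm3 <- matrix(c(5, 0, 10, 90), 2, 2,
    byrow = TRUE,
    dimnames = list(c("pos", "neg"), c("pos", "neg"))
  )
  expect_equal(
    class_sensitivity_specificity(cm3)$specificity[1], 0.9
  )
  # perfect prediction: diagonal, all sensitivities 1
  cmp <- confusion_matrix(true, true)
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
  expect_true(all(class_sensitivity_specificity(cmp)$sensitivity == 1))
  expect_error(confusion_matrix(c("a"), c("a", "b")), "length")
})

test_that("the repeated-split protocol is deterministic and well-formed", {
  d <- small_design()
  tab <- small_table(seed = 5, design = d)
  ylb <- tab[tab$tissue == "YLB", ]
  pr <- suppressWarnings(run_protocol(
    ylb, d,
    n_repetitions = 2, cv_repeats = 2, seed = 31
  ))
  expect_s3_class(pr, "ion_protocol")
  expect_true(all(pr$accuracy$accuracy >= 0 & pr$accuracy$accuracy <= 1))
  expect_setequal(unique(pr$accuracy$method), c("A", "B", "C", "D"))
  # confusion matrix row sums equal test-class counts (1 per class here)
  cm <- pr$confusions[["1"]][["A"]]
  expect_true(all(rowSums(cm) == 1))
  # sens/spec recomputed from stored confusions match the summaries
  recomputed <- purrr::imap_dfr(pr$confusions, function(per_method, rep) {
    purrr::imap_dfr(per_method, function(cm, m) {
      dplyr::mutate(class_sensitivity_specificity(cm), method = m)
    })
  }) |>
    dplyr::group_by(method, class) |>
    dplyr::summarise(
      sensitivity = mean(sensitivity, na.rm = TRUE),
      specificity = mean(specificity, na.rm = TRUE), .groups = "drop"
    )
  expect_equal(
    dplyr::arrange(recomputed, method, class),
    dplyr::arrange(pr$class_metrics, method, class)
  )
  # same seed, same everything
  pr2 <- suppressWarnings(run_protocol(
    ylb, d,
    n_repetitions = 2, cv_repeats = 2, seed = 31
  ))
  expect_identical(pr$accuracy, pr2$accuracy)
  expect_identical(pr$confusions, pr2$confusions)
  # method A results are identical with the masking layer bypassed
  pr_a <- suppressWarnings(run_protocol(
    ylb, d,
    methods = "A", n_repetitions = 2, cv_repeats = 2, seed = 31
  ))
  expect_identical(
    pr_a$accuracy$accuracy,
    pr$accuracy$accuracy[pr$accuracy$method == "A"]
  )
  expect_error(run_protocol(ylb, d, n_repetitions = 1), "seed")
  expect_error(
    suppressWarnings(run_protocol(tab, d, n_repetitions = 1, seed = 1)),
    "stratum"
  )
})

test_that("noiseless separable classes are classified perfectly by method A", {
  d <- small_design()
  # tiny but nonzero noise keeps autoscaling non-degenerate while the class
  # separation stays enormous
  tab <- small_table(seed = 8, noise_sigma = 0.01, design = d)
  ylb <- tab[tab$tissue == "YLB", ]
  pr <- suppressWarnings(run_protocol(
    ylb, d,
    methods = "A", n_repetitions = 2, cv_repeats = 2, seed = 13
  ))
  expect_equal(mean(pr$accuracy$accuracy), 1)
})

test_that("method comparison yields compact letters over repetitions", {
  d <- small_design()
  tab <- small_table(seed = 9, design = d)
  ylb <- tab[tab$tissue == "YLB", ]
  pr <- suppressWarnings(run_protocol(
    ylb, d,
    n_repetitions = 3, cv_repeats = 2, seed = 17
  ))
  cmp <- compare_methods(pr)
  expect_setequal(cmp$method, c("A", "B", "C", "D"))
  expect_true(all(nchar(cmp$letters) >= 1))
  expect_s3_class(attr(cmp, "kw"), "rank_test")
  # constructed accuracy vectors: three clearly separated methods
  fake <- pr
  fake$accuracy <- tibble::tibble(
    repetition = rep(1:6, 3),
    method = rep(c("A", "B", "C"), each = 6),
    accuracy = c(
      0.95, 0.96, 0.94, 0.97, 0.95, 0.96,
      0.60, 0.62, 0.61, 0.63, 0.60, 0.59,
      0.20, 0.22, 0.21, 0.19, 0.23, 0.20
    ),
    ncomp = 5
  )
  letters3 <- compare_methods(fake)$letters
  expect_length(unique(letters3), 3)
  # identical vectors: everyone shares one letter
  same <- pr
  same$accuracy <- tibble::tibble(
    repetition = rep(1:4, 2), method = rep(c("A", "B"), each = 4),
    accuracy = rep(0.8, 8), ncomp = 5
  )
  expect_equal(unique(compare_methods(same)$letters), "a")
  too_few <- pr
  too_few$accuracy <- pr$accuracy[pr$accuracy$repetition <= 2, ]
  expect_error(compare_methods(too_few), "3 repetitions")
})
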