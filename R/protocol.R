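#' Stratified train/test split
#'
#' Per class, `round(n_c * train_frac)` samples go to training (clamped so
#' that each class keeps at least one sample on each side); the remainder form
#' the test set. With 20 classes of 5 replicates at the default 80/20 this is
#' 80 train / 20 test with exactly one test sample per class.
#'
#' @param table Data frame with a `class` column (every class needs >= 2
#'   samples).
#' @param train_frac Fraction assigned to training.
#' @param seed Integer seed (mandatory).
#' @return An `ion_split`: `train`, `test` (row indices), `seed`.
#' @export
stratified_split <- function(table, train_frac = 0.8, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  classes <- as.character(table$class)
  sizes <- table(classes)
  if (any(sizes < 2)) {
    stop(
      "class(es) with fewer than 2 samples cannot be split: ",
      paste(names(sizes)[sizes < 2], collapse = ", "),
      call. = FALSE
    )
  }
  train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(unique(classes), function(k) {
      idx <- which(classes == k)
      n_tr <- round(length(idx) * train_frac)
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  structure(
    list(
      train = sort(train),
      test = setdiff(seq_len(nrow(table)), train),
      seed = as.integer(seed)
    ),
    class = "ion_split"
  )
}

#' Truncate test predictors for methods A-D
#'
#' Implements the four prediction variants on a single trained model by
#' neutralizing predictors: a neutralized cell is set to the training mean of
#' its column, which becomes exactly zero after autoscaling, so the model sees
#' "no information" there while keeping its dimensionality.
#'
#' * `A` — all elements, nothing neutralized.
#' * `B` — for each sample of class `-X`, element X is neutralized; control
#'   samples are untouched.
#' * `C` — only the six macronutrients keep their values, for every sample.
#' * `D` — for class `-X` everything but X is neutralized; control samples
#'   (which have no deprived element) are fully neutralized.
#'
#' @param X_test Raw test matrix (samples x elements).
#' @param true_classes True class labels of the test rows (methods B and D
#'   are defined per true class).
#' @param method One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param design An `ion_design` (element categories).
#' @param scaling Training `ion_scaling` (supplies the neutral means).
#' @return The truncated matrix, same shape as `X_test`.
#' @export
mask_features <- function(X_test, true_classes, method, design, scaling) {
  if (!method %in% c("A", "B", "C", "D")) {
    stop("unknown method: ", method, call. = FALSE)
  }
  X <- as.matrix(X_test)
  if (method == "A") {
    return(X)
  }
  stopifnot(inherits(design, "ion_design"), inherits(scaling, "ion_scaling"))
  els <- colnames(X)
  mu <- scaling$mean[els]
  dep <- deprived_element(as.character(true_classes))
  bad <- setdiff(stats::na.omit(unique(dep)), els)
  if (length(bad) > 0) {
    stop(
      "deprived element(s) absent from the matrix: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (method == "B") {
    for (i in seq_len(nrow(X))) {
      if (!is.na(dep[i])) X[i, dep[i]] <- mu[dep[i]]
    }
    return(X)
  }
  if (method == "C") {
    macros <- design$elements$element[design$elements$category == "macronutrient"]
    drop_cols <- setdiff(els, macros)
    X[, drop_cols] <- rep(mu[drop_cols], each = nrow(X))
    return(X)
  }
  # method D
  for (i in seq_len(nrow(X))) {
    keep <- dep[i]
    drop_cols <- if (is.na(keep)) els else setdiff(els, keep)
    X[i, drop_cols] <- mu[drop_cols]
  }
  X
}

#' Confusion matrix
#'
#' @param true,predicted Aligned label vectors.
#' @return K x K integer matrix, rows = true classes, columns = predicted,
#'   over the sorted union of labels.
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(true), as.character(predicted))))
  table(
    factor(true, levels = lev),
    factor(predicted, levels = lev),
    dnn = c("true", "predicted")
  ) |> unclass()
}

#' Per-class sensitivity and specificity from a confusion matrix
#'
#' Sensitivity of class k is the fraction of its true members predicted as k;
#' specificity is the fraction of true non-members not predicted as k.
#' Classes with no true members get `NA` sensitivity (undefined, not zero).
#'
#' @param cm Square confusion matrix (rows = true).
#' @return A tibble `class`, `n_true`, `sensitivity`, `specificity`.
#' @export
class_sensitivity_specificity <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  row_s <- rowSums(cm)
  col_s <- colSums(cm)
  d <- diag(cm)
  tibble::tibble(
    class = rownames(cm),
    n_true = as.integer(unname(row_s)),
    sensitivity = unname(ifelse(row_s > 0, d / row_s, NA_real_)),
    specificity = unname((total - row_s - col_s + d) / (total - row_s))
  )
}

#' Overall accuracy of a confusion matrix
#' @param cm Square confusion matrix.
#' @return Fraction of the trace over the total.
#' @export
cm_accuracy <- function(cm) {
  sum(diag(as.matrix(cm))) / sum(cm)
}

#' Run the repeated-split PLS-DA evaluation protocol
#'
#' For one species x tissue stratum: the data are split into stratified
#' 80/20 train/test sets `n_repetitions` times; per repetition the number of
#' latent components is chosen by k-fold repeated CV on the training set, a
#' PLS-DA model is fitted, and the test set is predicted under each requested
#' truncation method (A-D). Confusion matrices, accuracies and per-class
#' sensitivity/specificity are collected and averaged over repetitions.
#'
#' @param table An `ion_table` (or compatible tibble).
#' @param design The `ion_design`.
#' @param species,tissue Stratum selectors; each must leave exactly one
#'   stratum (omit if `table` is already a single stratum).
#' @param methods Subset of `c("A","B","C","D")`.
#' @param n_repetitions Number of 80/20 splits.
#' @param train_frac Training fraction per class.
#' @param folds,cv_repeats,max_comp CV controls for component selection.
#' @param distance Prediction metric.
#' @param seed Integer seed (mandatory); repetition seeds are derived from it.
#' @param retrain_per_method Refit the model on the masked training set for
#'   each method instead of reusing the method-A model (non-default
#'   interpretation, provided for comparison).
#' @return An `ion_protocol` with `$accuracy` (per repetition x method),
#'   `$class_metrics` (mean per method x class), `$confusions`, `$ncomp`.
#' @export
run_protocol <- function(table, design,
                         species = NULL, tissue = NULL,
                         methods = c("A", "B", "C", "D"),
                         n_repetitions = 10,
                         train_frac = 0.8,
                         folds = 5, cv_repeats = 50, max_comp = NULL,
                         distance = "mahalanobis",
                         seed,
                         retrain_per_method = FALSE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(design, "ion_design"))
  methods <- match.arg(methods, several.ok = TRUE)
  data <- dplyr::as_tibble(table)
  if (!is.null(species)) data <- dplyr::filter(data, .data$species == !!species)
  if (!is.null(tissue)) data <- dplyr::filter(data, .data$tissue == !!tissue)
  strata <- unique(data[, intersect(c("species", "tissue"), names(data))])
  if (nrow(strata) != 1) {
    stop(
      "the protocol runs on one species x tissue stratum at a time; got ",
      nrow(strata), " strata",
      call. = FALSE
    )
  }
  els <- intersect(design$elements$element, names(data))
  X <- as.matrix(data[, els])
  classes <- as.character(data$class)

  rep_seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, n_repetitions)
  )

  acc_rows <- list()
  metric_rows <- list()
  confusions <- list()
  for (r in seq_len(n_repetitions)) {
    res <- tryCatch(
      protocol_repetition(
        X, classes, design, methods, train_frac, folds, cv_repeats,
        max_comp, distance, rep_seeds[r], retrain_per_method
      ),
      error = function(e) {
        warning("repetition ", r, " failed: ", conditionMessage(e),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(res)) next
    acc_rows[[length(acc_rows) + 1]] <- tibble::tibble(
      repetition = r, method = methods,
      accuracy = vapply(res$per_method, cm_accuracy, numeric(1)),
      ncomp = res$ncomp
    )
    metric_rows[[length(metric_rows) + 1]] <- purrr::imap_dfr(
      res$per_method,
      function(cm, m) {
        dplyr::mutate(class_sensitivity_specificity(cm),
          method = m, repetition = r, .before = 1
        )
      }
    )
    confusions[[as.character(r)]] <- res$per_method
  }
  if (length(acc_rows) == 0) {
    stop("all repetitions failed", call. = FALSE)
  }
  accuracy <- dplyr::bind_rows(acc_rows)
  raw_metrics <- dplyr::bind_rows(metric_rows)
  class_metrics <- raw_metrics |>
    dplyr::group_by(.data$method, .data$class) |>
    dplyr::summarise(
      sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      specificity = mean(.data$specificity, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(
      accuracy = accuracy,
      class_metrics = class_metrics,
      raw_class_metrics = raw_metrics,
      confusions = confusions,
      stratum = strata,
      methods = methods,
      distance = distance,
      seed = as.integer(seed)
    ),
    class = "ion_protocol"
  )
}

protocol_repetition <- function(X, classes, design, methods, train_frac,
                                folds, cv_repeats, max_comp, distance,
                                seed, retrain_per_method) {
  sub_seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, 2)
  )
  split <- stratified_split(
    tibble::tibble(class = classes),
    train_frac = train_frac, seed = sub_seeds[1]
  )
  X_tr <- X[split$train, , drop = FALSE]
  cl_tr <- classes[split$train]
  X_te <- X[split$test, , drop = FALSE]
  cl_te <- classes[split$test]

  cv <- suppressWarnings(select_ncomp_cv(
    X_tr, cl_tr,
    max_comp = max_comp, folds = folds, repeats = cv_repeats,
    distance = distance, seed = sub_seeds[2]
  ))
  sc <- autoscale(X_tr)
  model <- fit_pls2(
    sc$X, one_hot(cl_tr),
    ncomp = cv$selected, scaling = sc$params, classes = cl_tr
  )
  per_method <- lapply(methods, function(m) {
    if (retrain_per_method && m != "A") {
      X_tr_m <- mask_features(X_tr, cl_tr, m, design, sc$params)
      sc_m <- autoscale(X_tr_m)
      model_m <- fit_pls2(
        sc_m$X, one_hot(cl_tr),
        ncomp = min(cv$selected, ncol(sc_m$X)),
        scaling = sc_m$params, classes = cl_tr
      )
      X_te_m <- mask_features(X_te, cl_te, m, design, sc$params)
      pred <- predict_classes(model_m, X_te_m, distance = distance)
    } else {
      X_te_m <- mask_features(X_te, cl_te, m, design, sc$params)
      pred <- predict_classes(model, X_te_m, distance = distance)
    }
    cm <- confusion_matrix(cl_te, pred)
    # restrict rows to true test classes for metric stability
    cm
  })
  names(per_method) <- methods
  list(per_method = per_method, ncomp = cv$selected)
}

#' @export
print.ion_protocol <- function(x, ...) {
  cat("<ion_protocol> stratum:",
    paste(unlist(x$stratum), collapse = " / "), "\n"
  )
  s <- x$accuracy |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd = stats::sd(.data$accuracy), .groups = "drop"
    )
  print(s)
  invisible(x)
}

#' Compare prediction methods by rank tests with compact letters
#'
#' Kruskal-Wallis across the per-repetition accuracy vectors of the methods,
#' Dunn's post hoc pairwise comparisons (Holm-adjusted), and a compact letter
#' display: methods sharing a letter do not differ significantly.
#'
#' @param result An `ion_protocol`.
#' @param alpha Significance level.
#' @return A tibble `method`, `mean_accuracy`, `letters`, with the
#'   Kruskal-Wallis `rank_test` attached as attribute `kw`.
#' @export
compare_methods <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "ion_protocol"))
  acc <- result$accuracy
  reps <- unique(acc$repetition)
  if (length(reps) < 3) {
    stop("need >= 3 repetitions to compare methods", call. = FALSE)
  }
  groups <- split(acc$accuracy, acc$method)
  kw <- kruskal_wallis(unname(groups))
  if (length(groups) >= 3) {
    pw <- dunn_posthoc(groups, adjust = "holm")
    cld <- compact_letters(pw, alpha = alpha)
  } else {
    w <- wilcoxon_rank_sum(groups[[1]], groups[[2]])
    cld <- tibble::tibble(
      group = names(groups),
      letters = if (w$p_value < alpha) c("a", "b") else c("a", "a")
    )
  }
  out <- tibble::tibble(
    method = names(groups),
    mean_accuracy = vapply(groups, mean, numeric(1))
  ) |>
    dplyr::left_join(cld, by = c("method" = "group"))
  attr(out, "kw") <- kw
  out
}
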