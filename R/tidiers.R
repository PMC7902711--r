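#' Tidy a fitted PLS-DA model
#'
#' One row per predictor x component with the weight, loading and rotation
#' entries, plus the predictor's global VIP.
#'
#' @param x An `ion_pls`.
#' @param ... Unused.
#' @return A tibble `term`, `component`, `weight`, `loading`, `rotation`,
#'   `vip`.
#' @export
tidy.ion_pls <- function(x, ...) {
  vip <- vip_scores(x)
  purrr::map_dfr(seq_len(x$ncomp), function(a) {
    tibble::tibble(
      term = x$predictors,
      component = a,
      weight = x$W[, a],
      loading = x$P[, a],
      rotation = x$R[, a],
      vip = unname(vip)
    )
  })
}

#' Model-level summary of a PLS-DA fit
#'
#' @param x An `ion_pls`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_predictors`, `n_classes`, `ncomp`,
#'   `x_variance_explained` (fraction of the scaled X variance captured by
#'   the score space).
#' @export
glance.ion_pls <- function(x, ...) {
  n <- nrow(x$T)
  x_var <- sum(colSums(x$T^2) * colSums(x$P^2)) / ((n - 1) * length(x$predictors))
  tibble::tibble(
    n = n,
    n_predictors = length(x$predictors),
    n_classes = length(x$class_levels),
    ncomp = x$ncomp,
    x_variance_explained = x_var
  )
}

#' Tidy a cross-validation result
#'
#' @param x An `ion_cv`.
#' @param ... Unused.
#' @return The per-candidate tibble `ncomp`, `cer_mean`, `cer_sd` with a
#'   logical `selected` column.
#' @export
tidy.ion_cv <- function(x, ...) {
  dplyr::mutate(x$results, selected = .data$ncomp == x$selected)
}

#' Tidy a protocol result
#'
#' @param x An `ion_protocol`.
#' @param type `"accuracy"` (per repetition x method) or `"class"` (mean
#'   per-class sensitivity/specificity per method).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ion_protocol <- function(x, type = c("accuracy", "class"), ...) {
  type <- match.arg(type)
  if (type == "accuracy") x$accuracy else x$class_metrics
}

#' Method-level summary of a protocol run
#'
#' @param x An `ion_protocol`.
#' @param ... Unused.
#' @return One row per method: mean/sd accuracy, mean selected ncomp,
#'   number of repetitions.
#' @export
glance.ion_protocol <- function(x, ...) {
  x$accuracy |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      mean_ncomp = mean(.data$ncomp),
      n_repetitions = dplyr::n(),
      .groups = "drop"
    )
}

#' Tidy a rank test
#'
#' @param x A `rank_test`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, p-value and method metadata.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    method = x$method,
    exact = x$exact,
    df = x$df,
    tie_correction = x$tie_correction
  )
}

#' Tidy a PCA
#'
#' @param x An `ion_pca`.
#' @param matrix `"scores"` or `"loadings"`.
#' @param ... Unused.
#' @return A long tibble of the requested matrix with the explained-variance
#'   fraction per component.
#' @export
tidy.ion_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  tibble::tibble(
    row = rep(rownames(m) %||% as.character(seq_len(nrow(m))), ncol(m)),
    component = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m),
    explained = rep(x$explained, each = nrow(m))
  )
}
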