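#' Elemental quantity Q = E x DW
#'
#' The quantity of an element in a harvested tissue is its concentration
#' (ppm = ug per g dry weight) times the tissue dry weight (g), giving ug.
#' Given an ionome table, returns the tidy long quantity table; given numeric
#' vectors, returns the vectorized product.
#'
#' @param x An `ion_table` tibble, or a numeric vector of concentrations (ppm).
#' @param dw Numeric dry weights (g); only for the numeric interface.
#' @return For a table: a long tibble with one row per sample x element and
#'   columns `concentration_ppm`, `dw_g`, `quantity_ug`. For numerics: a
#'   numeric vector of quantities (ug).
#' @examples
#' element_quantity(10, 2) # 20 ug
#' @export
element_quantity <- function(x, dw = NULL) {
  if (is.data.frame(x)) {
    if (!"dw_g" %in% names(x)) {
      stop("table must carry a `dw_g` column", call. = FALSE)
    }
    check_dw(x$dw_g, ids = paste0("row ", seq_len(nrow(x))))
    els <- element_cols(x)
    out <- tidyr::pivot_longer(
      dplyr::as_tibble(x),
      cols = dplyr::all_of(els),
      names_to = "element", values_to = "concentration_ppm"
    )
    if (any(out$concentration_ppm < 0)) {
      stop("concentrations must be >= 0", call. = FALSE)
    }
    out$quantity_ug <- out$concentration_ppm * out$dw_g
    return(out)
  }
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  check_dw(dw, ids = paste0("element ", seq_along(dw)))
  x * dw
}

check_dw <- function(dw, ids) {
  bad <- which(!is.finite(dw) | dw <= 0)
  if (length(bad) > 0) {
    stop(
      "dry weight must be > 0; offending sample(s): ",
      paste(ids[bad], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(dw)
}

#' Whole-plant elemental quantity
#'
#' Sums the per-tissue quantities over the species' full tissue set for every
#' (species, class, replicate, day, element). Errors if any sample is missing
#' a tissue, because a partial sum would silently understate the whole-plant
#' quantity.
#'
#' @param quantities Long quantity tibble from [element_quantity()].
#' @param design An `ion_design` giving each species' tissue set.
#' @return A tibble with one row per sample x element and column
#'   `quantity_ug`.
#' @export
whole_plant_quantity <- function(quantities, design) {
  stopifnot(inherits(design, "ion_design"))
  out <- quantities |>
    dplyr::group_by(
      .data$species, .data$class, .data$replicate, .data$day, .data$element
    ) |>
    dplyr::summarise(
      n_tissues = dplyr::n(),
      quantity_ug = sum(.data$quantity_ug),
      .groups = "drop"
    )
  expected <- vapply(out$species, function(sp) length(design$tissues[[sp]]), numeric(1))
  if (any(out$n_tissues != expected)) {
    bad <- out[out$n_tissues != expected, ]
    stop(
      "incomplete tissue sets for ", nrow(bad),
      " sample x element cell(s); first: ",
      paste(bad$species[1], bad$class[1], bad$replicate[1], bad$element[1]),
      call. = FALSE
    )
  }
  dplyr::select(out, -"n_tissues")
}

#' Net uptake over all subtractive replicate combinations
#'
#' Net uptake between two harvests is estimated from every pairwise difference
#' of whole-plant quantities: one replicate at the later harvest minus one at
#' the earlier harvest. With 5 replicates at each harvest this yields 25
#' combinations; their mean equals the difference of the two group means
#' exactly, and the reported SE is the combination multiset's SD divided by
#' the square root of the number of combinations (anti-conservative, since
#' combinations sharing a replicate are not independent).
#'
#' @param q_d22 Numeric whole-plant quantities at the later harvest.
#' @param q_d0 Numeric whole-plant quantities at the earlier harvest.
#' @return A list of class `ion_nu`: `combinations`, `mean`, `se`,
#'   `n_combinations`.
#' @examples
#' nu <- net_uptake(c(5, 6), c(1, 2))
#' nu$combinations # 4 3 5 4
#' nu$mean # 4
#' @export
net_uptake <- function(q_d22, q_d0) {
  if (length(q_d22) == 0 || length(q_d0) == 0) {
    stop("both replicate sets must be non-empty", call. = FALSE)
  }
  combos <- as.vector(outer(q_d22, q_d0, `-`))
  structure(
    list(
      combinations = combos,
      mean = mean(combos),
      se = stats::sd(combos) / sqrt(length(combos)),
      n_combinations = length(combos)
    ),
    class = "ion_nu"
  )
}

#' @export
print.ion_nu <- function(x, ...) {
  cat(
    "net uptake: mean", signif(x$mean, 4), "+/- SE", signif(x$se, 4),
    "over", x$n_combinations, "subtractive combinations\n"
  )
  invisible(x)
}

#' Net uptake table for every class x element
#'
#' Applies [net_uptake()] per (species, class, element), pairing each class's
#' later-harvest replicates with the shared early-harvest baseline replicates.
#'
#' @param wpq_d22 Whole-plant quantity tibble at the later harvest
#'   (deprivation classes and/or controls).
#' @param wpq_d0 Whole-plant quantity tibble at the initial harvest (one
#'   baseline class per species).
#' @return A tibble with columns `species`, `class`, `element`, `nu_mean`,
#'   `nu_se`, `n_combinations`.
#' @export
net_uptake_table <- function(wpq_d22, wpq_d0) {
  if (!setequal(unique(wpq_d22$element), unique(wpq_d0$element))) {
    stop("element panels of the two harvests differ", call. = FALSE)
  }
  base <- wpq_d0 |>
    dplyr::group_by(.data$species, .data$element) |>
    dplyr::summarise(q0 = list(.data$quantity_ug), .groups = "drop")
  wpq_d22 |>
    dplyr::group_by(.data$species, .data$class, .data$element) |>
    dplyr::summarise(q22 = list(.data$quantity_ug), .groups = "drop") |>
    dplyr::inner_join(base, by = c("species", "element")) |>
    dplyr::mutate(nu = purrr::map2(.data$q22, .data$q0, net_uptake)) |>
    dplyr::mutate(
      nu_mean = purrr::map_dbl(.data$nu, "mean"),
      nu_se = purrr::map_dbl(.data$nu, "se"),
      n_combinations = purrr::map_int(.data$nu, "n_combinations")
    ) |>
    dplyr::select(-"q22", -"q0", -"nu")
}

#' Ratio of a deprived metric to its control, with a rank-test p-value
#'
#' The ratio of means (robust to small denominators in individual replicates)
#' accompanied by a two-sample Wilcoxon rank-sum p-value.
#'
#' @param values_deprived,values_control Per-replicate metric values.
#' @return A one-row tibble: `ratio`, `p_value`, `n_deprived`, `n_control`.
#'   When the control mean is not positive the ratio is `NA` and a warning is
#'   raised.
#' @examples
#' relative_to_control(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
relative_to_control <- function(values_deprived, values_control) {
  mc <- mean(values_control)
  if (!is.finite(mc) || mc <= 0) {
    warning("control mean is not positive; ratio undefined", call. = FALSE)
    ratio <- NA_real_
  } else {
    ratio <- mean(values_deprived) / mc
  }
  w <- wilcoxon_rank_sum(values_deprived, values_control)
  tibble::tibble(
    ratio = ratio,
    p_value = w$p_value,
    n_deprived = length(values_deprived),
    n_control = length(values_control)
  )
}

#' Class x element matrix of concentrations relative to control
#'
#' For each species/tissue stratum and element, compares every deprivation
#' class to the control class by [relative_to_control()].
#'
#' @param table An `ion_table`.
#' @param control_class Reference class (default `control_D22`, the harvest
#'   contemporaneous with the deprivations).
#' @param classes Classes to compare (default: all deprivation classes).
#' @return A tibble of class `ion_relmat`: one row per species x tissue x
#'   class x element with `ratio` and `p_value`.
#' @export
relative_concentrations <- function(table, control_class = "control_D22",
                                    classes = NULL) {
  els <- element_cols(table)
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(table),
    cols = dplyr::all_of(els),
    names_to = "element", values_to = "value"
  )
  if (is.null(classes)) {
    classes <- setdiff(unique(long$class), control_class)
    classes <- grep("^-", classes, value = TRUE)
  }
  ctrl <- long |>
    dplyr::filter(.data$class == control_class) |>
    dplyr::group_by(.data$species, .data$tissue, .data$element) |>
    dplyr::summarise(control = list(.data$value), .groups = "drop")
  out <- long |>
    dplyr::filter(.data$class %in% classes) |>
    dplyr::group_by(.data$species, .data$tissue, .data$class, .data$element) |>
    dplyr::summarise(deprived = list(.data$value), .groups = "drop") |>
    dplyr::inner_join(ctrl, by = c("species", "tissue", "element")) |>
    dplyr::mutate(
      res = purrr::map2(.data$deprived, .data$control, relative_to_control)
    ) |>
    dplyr::select(-"deprived", -"control") |>
    tidyr::unnest("res")
  class(out) <- c("ion_relmat", class(out))
  out
}

#' Relative root nutrient content (RRNC)
#'
#' Fraction of a plant's whole content of an element residing in its roots; a
#' proxy for root-to-shoot translocation. Always in [0, 1] and invariant to
#' the element's unit.
#'
#' @param q_root Root quantity.
#' @param q_whole_plant Whole-plant quantity (>= `q_root`).
#' @return Numeric fraction(s) in [0, 1].
#' @examples
#' rrnc(12, 100) # 0.12
#' @export
rrnc <- function(q_root, q_whole_plant) {
  if (any(q_root < 0)) stop("root quantity must be >= 0", call. = FALSE)
  if (any(q_whole_plant <= 0)) {
    stop("whole-plant quantity must be > 0", call. = FALSE)
  }
  if (any(q_root > q_whole_plant)) {
    stop(
      "root quantity exceeds whole-plant quantity: inconsistent aggregation",
      call. = FALSE
    )
  }
  q_root / q_whole_plant
}

#' Per-sample RRNC table with control comparisons
#'
#' Computes each replicate's root fraction per element, then summarises each
#' class relative to control (ratio of mean RRNC, Wilcoxon p).
#'
#' @inheritParams relative_concentrations
#' @param design An `ion_design` (defines the full tissue sets).
#' @return A tibble of class `ion_relmat` with per-class RRNC means, ratios to
#'   control and p-values.
#' @export
rrnc_table <- function(table, design, control_class = "control_D22") {
  q <- element_quantity(table)
  wpq <- whole_plant_quantity(q, design)
  root <- q |>
    dplyr::filter(.data$tissue == "roots") |>
    dplyr::select(
      "species", "class", "replicate", "day", "element",
      root_ug = "quantity_ug"
    )
  frac <- dplyr::inner_join(
    root, wpq,
    by = c("species", "class", "replicate", "day", "element")
  ) |>
    dplyr::mutate(rrnc = rrnc(.data$root_ug, .data$quantity_ug))
  ctrl <- frac |>
    dplyr::filter(.data$class == control_class) |>
    dplyr::group_by(.data$species, .data$element) |>
    dplyr::summarise(control = list(.data$rrnc), .groups = "drop")
  out <- frac |>
    dplyr::filter(grepl("^-", .data$class)) |>
    dplyr::group_by(.data$species, .data$class, .data$element) |>
    dplyr::summarise(
      rrnc_mean = mean(.data$rrnc),
      values = list(.data$rrnc),
      .groups = "drop"
    ) |>
    dplyr::inner_join(ctrl, by = c("species", "element")) |>
    dplyr::mutate(
      res = purrr::map2(.data$values, .data$control, relative_to_control)
    ) |>
    dplyr::select(-"values", -"control") |>
    tidyr::unnest("res")
  class(out) <- c("ion_relmat", class(out))
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` within each sample; `ddCt = dCt_sample -
#' dCt_control`; relative expression is `2^-ddCt`. Several reference genes are
#' combined by the arithmetic mean of their Ct values before the subtraction.
#'
#' @param ct_target_sample,ct_target_control Target-gene Ct values (cycles).
#' @param ct_ref_sample,ct_ref_control Reference-gene Ct values; vectors (or
#'   matrices with one column per gene) are averaged.
#' @return Relative expression fold(s).
#' @examples
#' relative_expression_ddct(20, 10, 22, 10) # 4
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_control, ct_ref_control) {
  avg_ref <- function(x) {
    if (is.matrix(x)) rowMeans(x) else mean(x)
  }
  args <- list(
    ct_target_sample, as.numeric(ct_ref_sample),
    ct_target_control, as.numeric(ct_ref_control)
  )
  if (any(lengths(args) == 0)) {
    stop("target and reference Ct values are all required", call. = FALSE)
  }
  cts <- unlist(args)
  if (!all(is.finite(cts)) || any(cts <= 0)) {
    stop("all Ct values must be finite and > 0", call. = FALSE)
  }
  dct_sample <- ct_target_sample - avg_ref(ct_ref_sample)
  dct_control <- ct_target_control - avg_ref(ct_ref_control)
  2^(-(dct_sample - dct_control))
}

#' Per-class relative expression from a Ct table
#'
#' @param ct_table An `ion_ct` tibble from [generate_qpcr()] (or read from
#'   file with the same columns).
#' @param target Target gene column (defaults to the table's attribute).
#' @param refs Reference gene columns (>= 1 required).
#' @param control_class Class defining fold 1.
#' @return A tibble with per-class mean fold and SE.
#' @export
ddct_table <- function(ct_table, target = NULL, refs = NULL,
                       control_class = "control_D22") {
  target <- target %||% attr(ct_table, "target")
  refs <- refs %||% attr(ct_table, "refs")
  if (is.null(target) || is.null(refs) || length(refs) < 1) {
    stop("target and at least one reference gene column are required",
      call. = FALSE
    )
  }
  ref_ct <- rowMeans(as.matrix(ct_table[, refs, drop = FALSE]))
  dct <- ct_table[[target]] - ref_ct
  ctrl_dct <- mean(dct[ct_table$class == control_class])
  folds <- 2^(-(dct - ctrl_dct))
  tibble::tibble(class = ct_table$class, fold = folds) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      fold_mean = mean(.data$fold),
      fold_se = stats::sd(.data$fold) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Masked, clipped heatmap layer for a relative matrix
#'
#' Adds a `display` column: cells whose p-value is at or above `alpha` are
#' blanked (`NA`), surviving ratios are clipped to the display bounds
#' (default 0.2–5, the conventional blue-to-orange diverging range). Stored
#' ratios are never altered — masking is purely a display layer.
#'
#' @param ratios An `ion_relmat` tibble (columns `ratio`, `p_value`).
#' @param alpha Significance level for masking; 0.05 for concentration and
#'   uptake heatmaps, 0.01 conventionally for RRNC.
#' @param clip Length-2 numeric display bounds.
#' @return The input with an added `display` column, classed `ion_heatmap`.
#' @export
heatmap_matrix <- function(ratios, alpha = 0.05, clip = c(0.2, 5)) {
  stopifnot(
    all(c("ratio", "p_value") %in% names(ratios)),
    length(clip) == 2, clip[1] < clip[2]
  )
  out <- dplyr::mutate(
    ratios,
    display = ifelse(
      .data$p_value < alpha,
      pmin(pmax(.data$ratio, clip[1]), clip[2]),
      NA_real_
    )
  )
  class(out) <- unique(c("ion_heatmap", class(out)))
  attr(out, "alpha") <- alpha
  attr(out, "clip") <- clip
  out
}
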