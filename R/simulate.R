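#' Generate a synthetic ionome table for one species
#'
#' Draws one sample per (tissue, class, replicate) cell of the design. Each
#' concentration is log-normal around its expected value:
#' `log E = log(baseline * fold * day_mult) + Normal(0, noise_sigma)`,
#' where `day_mult` is the developmental-stage multiplier for D10 harvests and
#' 1 otherwise. Dry weights are generated analogously from the tissue dry
#' weight baseline. With `noise_sigma = 0` every concentration equals its
#' expected value exactly, and the same seed always reproduces the same table
#' bit for bit.
#'
#' @param design An `ion_design`.
#' @param effects An `ion_effects` for one of the design's species, as built
#'   by [default_effects()].
#' @param seed Integer seed; mandatory, because downstream analyses must be
#'   reproducible from the run manifest.
#'
#' @return A tibble (class `ion_table`) with metadata columns `species`,
#'   `tissue`, `class`, `replicate`, `day`, the dry weight `dw_g`, and one
#'   concentration column (ppm) per panel element.
#' @examples
#' d <- build_design()
#' tab <- generate_ionome(d, default_effects(d, "rapeseed"), seed = 1)
#' dim(tab)
#' @export
generate_ionome <- function(design, effects, seed) {
  stopifnot(inherits(design, "ion_design"), inherits(effects, "ion_effects"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: synthetic data must be reproducible", call. = FALSE)
  }
  missing_cl <- setdiff(design$classes, effects$classes)
  if (length(missing_cl) > 0) {
    stop(
      "effects do not cover design class(es): ",
      paste(missing_cl, collapse = ", "),
      call. = FALSE
    )
  }
  missing_el <- setdiff(design$elements$element, effects$elements)
  if (length(missing_el) > 0) {
    stop(
      "effects do not cover design element(s): ",
      paste(missing_el, collapse = ", "),
      call. = FALSE
    )
  }
  species <- effects$species
  tissues <- design$tissues[[species]]
  elements <- design$elements$element

  grid <- tidyr::expand_grid(
    tissue = tissues,
    class = design$classes,
    replicate = seq_len(design$n_replicates)
  )
  grid$day <- class_day(grid$class)

  bl <- effects$baseline
  bl_mat <- matrix(
    NA_real_,
    nrow = length(tissues), ncol = length(elements),
    dimnames = list(tissues, elements)
  )
  bl_mat[cbind(bl$tissue, bl$element)] <- bl$baseline

  # expected concentration per row x element; folds are resolved once per
  # (class, tissue) cell, not per replicate
  cells <- unique(grid[, c("class", "tissue")])
  cell_mu <- lapply(seq_len(nrow(cells)), function(j) {
    folds <- vapply(
      elements,
      function(el) fold_lookup(effects, cells$class[j], el, cells$tissue[j]),
      numeric(1)
    )
    day_mult <- if (class_day(cells$class[j]) == "D10") effects$day_effect else 1
    bl_mat[cells$tissue[j], ] * folds * day_mult
  })
  cell_of <- match(
    paste(grid$class, grid$tissue),
    paste(cells$class, cells$tissue)
  )
  mu <- do.call(rbind, cell_mu)[cell_of, , drop = FALSE]
  colnames(mu) <- elements

  dwb <- stats::setNames(effects$dw_baseline$dw, effects$dw_baseline$tissue)
  dwf <- effects$dw_fold
  dw_mu <- dwb[grid$tissue] *
    dwf$fold[match(paste(grid$class, grid$tissue), paste(dwf$class, dwf$tissue))]

  tab <- withr::with_seed(as.integer(seed), {
    noise <- matrix(
      stats::rnorm(length(mu), sd = effects$noise_sigma),
      nrow = nrow(mu)
    )
    # mu * exp(noise) rather than exp(log mu + noise): the noiseless limit
    # is then the exact product baseline * fold
    conc <- mu * exp(noise)
    dw <- dw_mu * exp(stats::rnorm(nrow(grid), sd = effects$dw_sigma))
    dplyr::bind_cols(
      tibble::tibble(
        species = species,
        tissue = grid$tissue,
        class = grid$class,
        replicate = grid$replicate,
        day = grid$day,
        dw_g = unname(dw)
      ),
      tibble::as_tibble(conc)
    )
  })
  class(tab) <- c("ion_table", class(tab))
  attr(tab, "elements") <- elements
  tab
}

# harvest day implied by a class label: control_D10 -> D10, control_D0 -> D0,
# everything else (deprivations, control_D22) -> D22
class_day <- function(class) {
  dplyr::case_when(
    grepl("_D0$", class) ~ "D0",
    grepl("_D10$", class) ~ "D10",
    .default = "D22"
  )
}

#' Simulate a full multi-species ionome trial
#'
#' Convenience wrapper: builds default effects for each species and binds the
#' per-species tables. Per-species seeds are derived deterministically from
#' `seed`.
#'
#' @param design An `ion_design`.
#' @param seed Integer seed.
#' @param species Species to simulate (default: all in the design).
#' @param ... Passed on to [default_effects()] (e.g. `noise_sigma`,
#'   `strength`).
#' @return An `ion_table` tibble covering all requested species.
#' @export
simulate_ionome <- function(design, seed, species = design$species, ...) {
  stopifnot(inherits(design, "ion_design"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required", call. = FALSE)
  }
  sub_seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, length(species))
  )
  tabs <- purrr::map2(
    species, sub_seeds,
    function(sp, s) {
      generate_ionome(design, default_effects(design, sp, ...), seed = s)
    }
  )
  out <- dplyr::bind_rows(tabs)
  class(out) <- c("ion_table", setdiff(class(out), "ion_table"))
  attr(out, "elements") <- design$elements$element
  out
}

#' Element columns of an ionome table
#'
#' @param table An `ion_table` (or any data frame holding an `elements`
#'   attribute or standard metadata columns).
#' @return Character vector of element column names.
#' @export
element_cols <- function(table) {
  els <- attr(table, "elements")
  if (!is.null(els)) {
    return(intersect(els, names(table)))
  }
  meta <- c("species", "tissue", "class", "replicate", "day", "dw_g")
  setdiff(names(table)[vapply(table, is.numeric, logical(1))], meta)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a relative-expression experiment on root samples: reference-gene
#' Ct values are constant across classes up to noise, and the target gene's Ct
#' in class `c` is the control target Ct minus `log2(true_fold[c])` (one PCR
#' cycle less per doubling of expression), so the delta-delta-Ct method
#' recovers `true_fold` exactly in the noiseless limit.
#'
#' @param design An `ion_design`.
#' @param true_fold Named numeric vector of expression fold changes per class
#'   (> 0). Classes not named get fold 1.
#' @param seed Integer seed (mandatory).
#' @param noise_sd SD of Ct noise, in cycles.
#' @param target,refs Gene column names.
#' @param control_class Class whose expression defines fold 1.
#' @param ct_target_control,ct_ref Baseline Ct values (cycles).
#'
#' @return A tibble (class `ion_ct`) with columns `class`, `replicate` and one
#'   Ct column per gene.
#' @export
generate_qpcr <- function(design, true_fold, seed,
                          noise_sd = 0.1,
                          target = "IRT1",
                          refs = c("EF1", "rRNA18S"),
                          control_class = "control_D22",
                          ct_target_control = 25,
                          ct_ref = 18) {
  stopifnot(inherits(design, "ion_design"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required", call. = FALSE)
  }
  if (any(true_fold <= 0)) {
    stop("all expression folds must be > 0", call. = FALSE)
  }
  fold <- stats::setNames(rep(1, length(design$classes)), design$classes)
  fold[names(true_fold)] <- true_fold
  grid <- tidyr::expand_grid(
    class = design$classes,
    replicate = seq_len(design$n_replicates)
  )
  withr::with_seed(as.integer(seed), {
    out <- grid
    out[[target]] <- ct_target_control - log2(fold[grid$class]) +
      stats::rnorm(nrow(grid), sd = noise_sd)
    for (r in refs) {
      out[[r]] <- ct_ref + stats::rnorm(nrow(grid), sd = noise_sd)
    }
    out <- tibble::as_tibble(out)
    class(out) <- c("ion_ct", class(out))
    attr(out, "target") <- target
    attr(out, "refs") <- refs
    out
  })
}
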