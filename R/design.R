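#' The default functional-ionome element panel
#'
#' Twenty elements spanning the six macronutrients, eight micronutrients and
#' four beneficial elements routinely quantified in plant tissue by ICP-MS,
#' plus V and Al, which are measured but never deprived (they enter hydroponic
#' solutions only as trace contaminants).
#'
#' @return A tibble with columns `element`, `category`
#'   (macronutrient/micronutrient/beneficial/other) and `deprivable`.
#' @export
ionome_elements <- function() {
  tibble::tibble(
    element = c(
      "N", "Mg", "P", "S", "K", "Ca",
      "B", "Cl", "Mn", "Fe", "Ni", "Cu", "Zn", "Mo",
      "Na", "Si", "Co", "Se",
      "V", "Al"
    ),
    category = c(
      rep("macronutrient", 6),
      rep("micronutrient", 8),
      rep("beneficial", 4),
      rep("other", 2)
    ),
    deprivable = c(rep(TRUE, 18), rep(FALSE, 2))
  )
}

default_tissues <- function() {
  list(
    rapeseed = c("roots", "OLB", "YLB", "OP", "YP"),
    wheat    = c("roots", "OLB", "YLB")
  )
}

#' Build a deprivation-trial design
#'
#' Describes the layout of a single-nutrient deprivation experiment: the
#' element panel, the treatment classes (two control harvests plus one
#' deprivation class `"-X"` per deprivable element), the species with their
#' tissue sets, and the number of replicates per class.
#'
#' @param elements Element panel as returned by [ionome_elements()]; a tibble
#'   with columns `element`, `category`, `deprivable`.
#' @param classes Character vector of treatment classes. Defaults to
#'   `control_D10`, `control_D22` and one `"-X"` label per deprivable element.
#' @param species Character vector of species labels.
#' @param tissues Named list mapping each species to its tissue set
#'   (roots, old/young leaf blades, old/young petioles).
#' @param n_replicates Biological replicates per class (>= 2).
#'
#' @return An object of class `ion_design`.
#' @examples
#' d <- build_design()
#' nrow(d$elements)       # 20
#' length(d$classes)      # 20
#' @export
build_design <- function(elements = ionome_elements(),
                         classes = NULL,
                         species = c("rapeseed", "wheat"),
                         tissues = default_tissues(),
                         n_replicates = 5) {
  stopifnot(is.data.frame(elements))
  required <- c("element", "category", "deprivable")
  if (!all(required %in% names(elements))) {
    stop("`elements` must have columns element, category, deprivable",
      call. = FALSE
    )
  }
  if (anyDuplicated(elements$element)) {
    stop("duplicate elements in panel", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- c(
      "control_D10", "control_D22",
      paste0("-", elements$element[elements$deprivable])
    )
  }
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    stop("`n_replicates` must be >= 2 (replication is required for every test)",
      call. = FALSE
    )
  }
  if (!all(species %in% names(tissues))) {
    stop("every species needs a tissue set in `tissues`", call. = FALSE)
  }
  deprivations <- grep("^-", classes, value = TRUE)
  bad <- setdiff(sub("^-", "", deprivations), elements$element)
  if (length(bad) > 0) {
    stop(
      "deprivation class(es) name elements absent from the panel: ",
      paste0("-", bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      elements = tibble::as_tibble(elements),
      classes = classes,
      species = species,
      tissues = tissues[species],
      n_replicates = as.integer(n_replicates)
    ),
    class = "ion_design"
  )
}

#' @export
print.ion_design <- function(x, ...) {
  cat("<ion_design>\n")
  cat(
    "  elements:  ", nrow(x$elements), " (",
    sum(x$elements$category == "macronutrient"), " macro, ",
    sum(x$elements$category == "micronutrient"), " micro, ",
    sum(x$elements$category == "beneficial"), " beneficial)\n",
    sep = ""
  )
  cat(
    "  classes:   ", length(x$classes), " (",
    sum(!grepl("^-", x$classes)), " controls + ",
    sum(grepl("^-", x$classes)), " deprivations)\n",
    sep = ""
  )
  for (sp in x$species) {
    cat(
      "  ", sp, ": ", paste(x$tissues[[sp]], collapse = ", "),
      "\n",
      sep = ""
    )
  }
  cat("  replicates:", x$n_replicates, "per class\n")
  invisible(x)
}

#' Deprived element of a treatment class
#'
#' @param classes Character vector of class labels.
#' @return Character vector: the element named by each `"-X"` label, `NA` for
#'   control classes.
#' @export
deprived_element <- function(classes) {
  ifelse(grepl("^-", classes), sub("^-", "", classes), NA_character_)
}

# Order-of-magnitude tissue concentrations (ppm = ug/g DW) typical of
# hydroponically grown rapeseed/wheat; roots are enriched in poorly
# translocated metals.
default_baselines <- function(species) {
  base <- c(
    N = 50000, Mg = 2500, P = 6000, S = 9000, K = 40000, Ca = 15000,
    B = 30, Cl = 5000, Mn = 60, Fe = 100, Ni = 1.5, Cu = 7, Zn = 40,
    Mo = 0.8, Na = 1500, Si = 1000, Co = 0.15, Se = 0.08, V = 0.05, Al = 30
  )
  if (species == "wheat") {
    # wheat is a Si accumulator, a Ca/B excluder relative to brassicas
    base[["Si"]] <- 6000
    base[["Ca"]] <- 5000
    base[["B"]] <- 8
  }
  root_mult <- c(Fe = 4, Al = 5, Ni = 2, Co = 2, V = 3, Na = 2, Cu = 1.5)
  list(base = base, root_mult = root_mult)
}

# Nutrient-crosstalk templates encoded as multiplicative fold changes.
# Core set (the default generative conditions): -Fe induces IRT1-mediated
# co-uptake of Ni/Cu/Zn/Co; -Na raises root Fe/Cu/Zn/Si; -K lets Na
# substitute osmotically; -S de-represses sulfate transporters that also
# carry molybdate and selenate (and Cl accumulates osmotically).
# The extended set adds further documented interactions: Mo accumulation
# under Mn/Zn/Cu deficiency via the MoCo synthesis network, -Zn raising Fe,
# -S raising V (vanadate through sulfate transporters), Si deprivation
# depressing Ni/Co/V/Fe in young tissue, and N/P deprivation depressing Na
# uptake (proton-pump coupling).
default_crosstalks <- function(set = c("core", "extended")) {
  set <- match.arg(set)
  core <- tibble::tribble(
    ~class, ~element, ~tissue, ~fold,
    "-Fe", "Ni", NA_character_, 2.5,
    "-Fe", "Cu", NA_character_, 2.0,
    "-Fe", "Zn", NA_character_, 2.0,
    "-Fe", "Co", NA_character_, 2.5,
    "-Na", "Fe", "roots", 2.5,
    "-Na", "Cu", "roots", 1.8,
    "-Na", "Zn", "roots", 1.8,
    "-Na", "Si", "roots", 1.6,
    "-K", "Na", NA_character_, 2.0,
    "-S", "Mo", NA_character_, 2.5,
    "-S", "Se", NA_character_, 2.0,
    "-S", "Cl", NA_character_, 1.5
  )
  if (set == "core") {
    return(core)
  }
  dplyr::bind_rows(core, tibble::tribble(
    ~class, ~element, ~tissue, ~fold,
    "-S", "V", NA_character_, 1.5,
    "-Mn", "Mo", NA_character_, 1.8,
    "-Zn", "Mo", NA_character_, 1.8,
    "-Zn", "Fe", NA_character_, 1.6,
    "-Cu", "Mo", NA_character_, 1.8,
    "-Si", "Fe", NA_character_, 0.5,
    "-Si", "Ni", NA_character_, 0.5,
    "-Si", "Co", NA_character_, 0.5,
    "-Si", "V", NA_character_, 0.5,
    "-N", "Na", NA_character_, 0.4,
    "-P", "Na", NA_character_, 0.4
  ))
}

#' Default multiplicative effect model for a species
#'
#' Encodes the generative model of the synthetic ionome as fold changes on a
#' per-element baseline: the deprived element of each `"-X"` class is strongly
#' depleted (default fold 0.05 — a small residual is retained because trace
#' contamination of water and salts never yields a true zero), documented
#' crosstalk elements are raised 1.5–3-fold, and every other element carries a
#' species-wide direction bias (rapeseed ionomes tend to decrease under
#' deprivation, wheat ionomes to increase). Control classes have fold 1 for
#' every element; harvest-day structure is carried by a separate
#' developmental-stage multiplier applied to D10 harvests (younger plants are
#' more concentrated, so the two control harvests remain distinguishable).
#'
#' @param design An `ion_design`.
#' @param species One of `design$species`.
#' @param noise_sigma SD of log-concentration measurement noise (default 0.15,
#'   i.e. ~15% CV, typical of ICP-MS on biological replicates).
#' @param deprived_fold Fold change of the deprived element (default 0.05).
#' @param strength Scales every log fold change (and the day effect); the
#'   class-separability knob. 1 = default magnitudes, 0 = no class signal.
#' @param dw_sigma SD of log dry-weight noise.
#' @param b_root_dw Apply the optional template in which B deprivation reduces
#'   rapeseed root dry weight (fold 0.6)?
#' @param day_effect Multiplier applied to all element concentrations of
#'   D10-harvested samples.
#' @param crosstalks Which crosstalk template set to apply: `"core"` (the
#'   default generative conditions) or `"extended"` (adds further documented
#'   interactions; see [default_crosstalks()]).
#'
#' @return An object of class `ion_effects`.
#' @examples
#' d <- build_design()
#' eff <- default_effects(d, "rapeseed")
#' fold_lookup(eff, "-Fe", "Fe", "YLB") # 0.05
#' @export
default_effects <- function(design, species,
                            noise_sigma = 0.15,
                            deprived_fold = 0.05,
                            strength = 1,
                            dw_sigma = 0.08,
                            b_root_dw = FALSE,
                            day_effect = 1.3,
                            crosstalks = c("core", "extended")) {
  stopifnot(inherits(design, "ion_design"))
  if (!species %in% design$species) {
    stop("unknown species: ", species, call. = FALSE)
  }
  if (noise_sigma < 0 || dw_sigma < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (deprived_fold <= 0 || deprived_fold > 0.2) {
    stop("`deprived_fold` must be in (0, 0.2] (strong depletion)", call. = FALSE)
  }
  elements <- design$elements$element
  tissues <- design$tissues[[species]]
  bl <- default_baselines(species)
  root_mult_of <- function(el) {
    m <- bl$root_mult[el]
    ifelse(is.na(m), 1, m)
  }
  baseline <- tidyr::expand_grid(element = elements, tissue = tissues) |>
    dplyr::mutate(
      baseline = unname(bl$base[.data$element]) *
        ifelse(.data$tissue == "roots", root_mult_of(.data$element), 1)
    )

  bias <- if (species == "rapeseed") 0.85 else 1.15
  ct <- default_crosstalks(match.arg(crosstalks))
  ct <- ct[ct$class %in% design$classes & ct$element %in% elements, ]

  deprivations <- grep("^-", design$classes, value = TRUE)
  fold <- tidyr::expand_grid(
    class = deprivations, element = elements,
    tissue = NA_character_
  ) |>
    dplyr::mutate(fold = bias)
  fold$fold[fold$element == deprived_element(fold$class)] <- deprived_fold
  # crosstalk templates override the bias (tissue-specific rows are kept
  # alongside the panel-wide row and win at lookup time)
  for (i in seq_len(nrow(ct))) {
    if (is.na(ct$tissue[i])) {
      hit <- fold$class == ct$class[i] & fold$element == ct$element[i]
      fold$fold[hit] <- ct$fold[i]
    }
  }
  ct_tissue <- ct[!is.na(ct$tissue), c("class", "element", "tissue", "fold")]
  fold <- dplyr::bind_rows(fold, ct_tissue)

  controls <- grep("^-", design$classes, value = TRUE, invert = TRUE)
  fold <- dplyr::bind_rows(
    tidyr::expand_grid(
      class = controls, element = elements,
      tissue = NA_character_
    ) |>
      dplyr::mutate(fold = 1),
    fold
  )
  fold$fold <- fold$fold^strength

  dw_baseline <- tibble::tibble(
    tissue = tissues,
    dw = c(
      roots = 0.6, OLB = 1.2, YLB = 0.8, OP = 0.5, YP = 0.3
    )[tissues] * if (species == "wheat") 0.5 else 1
  )
  dw_fold <- tidyr::expand_grid(class = design$classes, tissue = tissues) |>
    dplyr::mutate(fold = 1)
  if (b_root_dw && species == "rapeseed" && "-B" %in% design$classes) {
    dw_fold$fold[dw_fold$class == "-B" & dw_fold$tissue == "roots"] <- 0.6
  }

  eff <- structure(
    list(
      species = species,
      elements = elements,
      tissues = tissues,
      classes = design$classes,
      baseline = baseline,
      fold = fold,
      noise_sigma = noise_sigma,
      day_effect = day_effect^strength,
      bias = bias^strength,
      dw_baseline = dw_baseline,
      dw_fold = dw_fold,
      dw_sigma = dw_sigma
    ),
    class = "ion_effects"
  )
  validate_effects(eff)
  eff
}

validate_effects <- function(effects) {
  stopifnot(inherits(effects, "ion_effects"))
  if (any(effects$fold$fold <= 0)) {
    stop("all fold changes must be > 0", call. = FALSE)
  }
  if (any(effects$baseline$baseline <= 0)) {
    stop("all baselines must be > 0", call. = FALSE)
  }
  controls <- grep("^-", effects$classes, value = TRUE, invert = TRUE)
  ctrl_folds <- effects$fold$fold[effects$fold$class %in% controls]
  if (any(ctrl_folds != 1)) {
    stop("control classes must have fold change identically 1", call. = FALSE)
  }
  fm <- fold_matrix(effects)
  for (cl in grep("^-", effects$classes, value = TRUE)) {
    el <- deprived_element(cl)
    if (fm[cl, el] >= 1) {
      stop("deprived element fold for ", cl, " must deplete (< 1)", call. = FALSE)
    }
  }
  invisible(effects)
}

#' Look up the fold change for one class/element/tissue cell
#'
#' Tissue-specific template rows take precedence over panel-wide rows.
#'
#' @param effects An `ion_effects`.
#' @param class,element,tissue Scalars naming the cell.
#' @return A single fold change (> 0).
#' @export
fold_lookup <- function(effects, class, element, tissue) {
  f <- effects$fold
  hit <- f$class == class & f$element == element &
    !is.na(f$tissue) & f$tissue == tissue
  if (any(hit)) {
    return(f$fold[hit][1])
  }
  hit <- f$class == class & f$element == element & is.na(f$tissue)
  if (!any(hit)) {
    stop("no fold change recorded for ", class, "/", element, call. = FALSE)
  }
  f$fold[hit][1]
}

# class x element matrix of panel-wide folds (ignores tissue-specific rows)
fold_matrix <- function(effects) {
  f <- effects$fold[is.na(effects$fold$tissue), ]
  m <- matrix(1,
    nrow = length(effects$classes), ncol = length(effects$elements),
    dimnames = list(effects$classes, effects$elements)
  )
  m[cbind(f$class, f$element)] <- f$fold
  m
}

#' Truly perturbed element set of a deprivation class
#'
#' The elements whose fold change in the given tissue departs from the
#' species-wide direction bias: the deprived element itself plus its crosstalk
#' partners. This is the ground truth against which extracted ionomic
#' signatures are scored on synthetic data.
#'
#' @param effects An `ion_effects`.
#' @param class A deprivation class label (`"-X"`).
#' @param tissue Tissue in which the signature is read.
#' @return Character vector of element symbols.
#' @export
signature_truth <- function(effects, class, tissue) {
  if (!grepl("^-", class)) {
    stop("signature truth is defined for deprivation classes only", call. = FALSE)
  }
  folds <- vapply(
    effects$elements,
    function(el) fold_lookup(effects, class, el, tissue),
    numeric(1)
  )
  effects$elements[folds != effects$bias & folds != 1]
}

#' @export
print.ion_effects <- function(x, ...) {
  cat("<ion_effects> species:", x$species, "\n")
  cat(
    "  noise_sigma:", x$noise_sigma, " day_effect (D10):", x$day_effect,
    " bias:", round(x$bias, 3), "\n"
  )
  n_tmpl <- sum(x$fold$fold != 1 & x$fold$fold != x$bias)
  cat("  template cells (deprived + crosstalk):", n_tmpl, "\n")
  invisible(x)
}
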