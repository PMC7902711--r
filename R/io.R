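ION_META_COLS <- c("species", "tissue", "class", "replicate", "day", "dw_g")

#' Write an ionome table to CSV
#'
#' Fixed, documented column order: the metadata columns (`species`, `tissue`,
#' `class`, `replicate`, `day`, `dw_g`) first, then the element columns in
#' alphabetical order. UTF-8, plain CSV.
#'
#' @param table An `ion_table`.
#' @param path Output file (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_ionome_table <- function(table, path) {
  els <- sort(element_cols(table))
  out <- dplyr::as_tibble(table)[, c(ION_META_COLS, els)]
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(out, path)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' Read and validate an ionome table
#'
#' Accepts CSV or TSV (decided by extension). Checks the required metadata
#' columns, requires at least one element column, rejects negative
#' concentrations, non-positive dry weights and duplicate
#' (species, tissue, class, replicate, day) keys — each with the offending
#' row numbers — and warns about element columns absent from the design
#' panel.
#'
#' @param path Input file.
#' @param design Optional `ion_design`; when given, unknown element columns
#'   draw a warning and panel order is restored.
#' @return An `ion_table` tibble.
#' @export
read_ionome_table <- function(path, design = NULL) {
  tab <- if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  miss <- setdiff(ION_META_COLS, names(tab))
  if (length(miss) > 0) {
    stop(
      "missing metadata column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  els <- setdiff(names(tab), ION_META_COLS)
  els <- els[vapply(tab[els], is.numeric, logical(1))]
  if (length(els) == 0) {
    stop("no element columns found", call. = FALSE)
  }
  if (!is.null(design)) {
    unknown <- setdiff(els, design$elements$element)
    if (length(unknown) > 0) {
      warning(
        "element column(s) not in the design panel: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    ordered <- intersect(design$elements$element, els)
    els <- c(ordered, setdiff(els, ordered))
  }
  neg <- which(rowSums(as.matrix(tab[, els]) < 0) > 0)
  if (length(neg) > 0) {
    stop(
      "negative concentration(s) in row(s): ",
      paste(utils::head(neg, 10), collapse = ", "),
      call. = FALSE
    )
  }
  bad_dw <- which(!is.finite(tab$dw_g) | tab$dw_g <= 0)
  if (length(bad_dw) > 0) {
    stop(
      "non-positive dry weight in row(s): ",
      paste(utils::head(bad_dw, 10), collapse = ", "),
      call. = FALSE
    )
  }
  key <- do.call(paste, tab[, c("species", "tissue", "class", "replicate", "day")])
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup) > 0) {
    stop(
      "duplicate sample key in row(s): ",
      paste(utils::head(dup, 10), collapse = ", "),
      call. = FALSE
    )
  }
  tab <- tab[, c(ION_META_COLS, els)]
  class(tab) <- c("ion_table", class(tab))
  attr(tab, "elements") <- els
  tab
}

#' Write the design/effects/seed sidecar for a simulated dataset
#'
#' A YAML sidecar recording everything needed to regenerate the table:
#' the design layout, the effect model (baselines, fold changes, noise), and
#' the seed.
#'
#' @param design An `ion_design`.
#' @param effects An `ion_effects` or list of them.
#' @param seed The generation seed.
#' @param path Output `.yaml` file.
#' @return `path`, invisibly.
#' @export
write_run_sidecar <- function(design, effects, seed, path) {
  if (inherits(effects, "ion_effects")) effects <- list(effects)
  payload <- list(
    design = list(
      elements = as.list(design$elements),
      classes = design$classes,
      species = design$species,
      tissues = design$tissues,
      n_replicates = design$n_replicates
    ),
    effects = lapply(effects, function(e) {
      list(
        species = e$species,
        noise_sigma = e$noise_sigma,
        day_effect = e$day_effect,
        bias = e$bias,
        dw_sigma = e$dw_sigma,
        baseline = as.list(e$baseline),
        fold = as.list(e$fold),
        dw_baseline = as.list(e$dw_baseline)
      )
    }),
    seed = as.integer(seed)
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the package version, seeds, parameters and input-file MD5 hashes
#' of a pipeline stage, so any run can be reproduced (and verified) from the
#' manifest alone.
#'
#' @param path Output `.json` file.
#' @param stage Stage name (e.g. `"simulate"`, `"protocol"`).
#' @param seed Integer seed used by the stage.
#' @param params Named list of stage parameters.
#' @param inputs Character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, seed, params = list(),
                           inputs = character(0)) {
  manifest <- list(
    package = "ionosig",
    version = as.character(utils::packageVersion("ionosig")),
    stage = stage,
    seed = as.integer(seed),
    params = params,
    inputs = lapply(
      stats::setNames(as.list(inputs), basename(inputs)),
      function(f) unname(tools::md5sum(f))
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
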