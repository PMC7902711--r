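#' Per-class VIP matrix from a full-stratum PLS-DA model
#'
#' Fits (or reuses) a PLS-DA model on the complete stratum and returns the
#' deficiency-class x element matrix of per-class VIP scores — the raw
#' material of ionomic signatures. The full-data model (rather than any
#' single split's model) is used because it gives the most stable importance
#' estimates.
#'
#' @param data One species x tissue stratum with `class` and element columns,
#'   or a fitted `ion_pls`.
#' @param classes Classes to keep as rows (default: deprivation classes).
#' @param ... Passed to [plsda()] when `data` is a table (e.g. `ncomp`,
#'   `seed`).
#' @return An `ion_vip` matrix (classes x elements).
#' @export
vip_matrix <- function(data, classes = NULL, ...) {
  model <- if (inherits(data, "ion_pls")) data else plsda(data, ...)
  vm <- t(vip_scores(model, per_class = TRUE)) # classes x elements
  if (is.null(classes)) {
    classes <- grep("^-", rownames(vm), value = TRUE)
    if (length(classes) == 0) classes <- rownames(vm)
  }
  vm <- vm[classes, , drop = FALSE]
  structure(vm, class = c("ion_vip", "matrix"))
}

#' Grade VIP scores at the conventional thresholds
#'
#' Each cell receives the highest threshold it reaches among 1, 1.5 and 2
#' (0 below 1). VIP >= 1 is the conventional bar for an element to count as
#' part of a signature; the higher grades map to the darker grays of a
#' signature heatmap.
#'
#' @param vip Non-negative numeric matrix/vector of VIP scores.
#' @return Same shape, values in {0, 1, 1.5, 2}.
#' @examples
#' vip_threshold_grades(c(0.5, 1, 1.7, 2.3)) # 0 1 1.5 2
#' @export
vip_threshold_grades <- function(vip) {
  v <- unclass(vip)
  if (any(v < 0)) stop("VIP scores must be >= 0", call. = FALSE)
  g <- ifelse(v >= 2, 2, ifelse(v >= 1.5, 1.5, ifelse(v >= 1, 1, 0)))
  attributes(g) <- attributes(v)
  class(g) <- setdiff(class(g), "ion_vip")
  g
}

#' Tidy ionomic signature table
#'
#' For each deficiency class, the elements whose VIP grade reaches
#' `min_grade`, sorted by descending VIP. Classes whose surviving set is
#' empty are reported in the `no_signature` attribute (and message): their
#' ionome changes are too similar to other deficiencies to stand out.
#'
#' @param vip An `ion_vip` matrix (classes x elements).
#' @param min_grade Smallest grade retained (default 1).
#' @param quiet Suppress the no-signature message?
#' @return A tibble `class`, `element`, `vip`, `grade`; attribute
#'   `no_signature` lists signature-free classes.
#' @export
signature_table <- function(vip, min_grade = 1, quiet = FALSE) {
  grades <- vip_threshold_grades(vip)
  long <- tibble::tibble(
    class = rep(rownames(vip), times = ncol(vip)),
    element = rep(colnames(vip), each = nrow(vip)),
    vip = as.vector(unclass(vip)),
    grade = as.vector(grades)
  )
  out <- long |>
    dplyr::filter(.data$grade >= min_grade) |>
    dplyr::arrange(.data$class, dplyr::desc(.data$vip))
  empty <- setdiff(rownames(vip), unique(out$class))
  if (length(empty) > 0 && !quiet) {
    message(
      "no specific signature for: ", paste(empty, collapse = ", ")
    )
  }
  attr(out, "no_signature") <- empty
  out
}

#' Hierarchical clustering of signatures on principal components
#'
#' PCA of the VIP matrix (rows = deficiency classes; centered, not scaled,
#' all components retained by default — a lossless rotation, so the tree then
#' equals Ward clustering of the raw rows) followed by Ward.D2 linkage on the
#' retained scores.
#'
#' @param vip An `ion_vip` matrix with >= 2 class rows.
#' @param n_pcs Number of principal components to retain, or `"all"`.
#' @param min_grade Optional: zero out cells below this VIP grade before
#'   clustering, so only signature-worthy cells shape the tree.
#' @return An `ion_dendro`: `hclust` (the merge tree), `pca`, `n_pcs`.
#' @export
hcpc_cluster <- function(vip, n_pcs = "all", min_grade = NULL) {
  m <- unclass(vip)
  if (nrow(m) < 2) stop("need >= 2 classes to cluster", call. = FALSE)
  if (!is.null(min_grade)) {
    m[vip_threshold_grades(m) < min_grade] <- 0
  }
  pca <- pca_svd(m, scale = FALSE)
  k <- if (identical(n_pcs, "all")) ncol(pca$scores) else min(n_pcs, ncol(pca$scores))
  sc <- pca$scores[, seq_len(k), drop = FALSE]
  rownames(sc) <- rownames(m)
  hc <- stats::hclust(stats::dist(sc), method = "ward.D2")
  structure(
    list(hclust = hc, pca = pca, n_pcs = k),
    class = "ion_dendro"
  )
}

#' @export
print.ion_dendro <- function(x, ...) {
  cat(
    "<ion_dendro> Ward.D2 on ", x$n_pcs, " principal components; ",
    length(x$hclust$labels), " signatures\n",
    sep = ""
  )
  invisible(x)
}

#' Write a signature dendrogram as Newick
#'
#' @param dendro An `ion_dendro`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendro, path) {
  stopifnot(inherits(dendro, "ion_dendro"))
  ape::write.tree(ape::as.phylo(dendro$hclust), file = path)
  invisible(path)
}

#' Score signature recovery against a known perturbation set
#'
#' On synthetic data the generator records which elements each deprivation
#' class truly perturbs; this helper reports, per class, the fraction of that
#' truth set captured by the VIP >= `min_grade` signature.
#'
#' @param vip An `ion_vip` matrix.
#' @param effects The `ion_effects` used to generate the data.
#' @param tissue Tissue of the stratum the model was fitted on.
#' @param min_grade VIP grade defining signature membership.
#' @return A tibble `class`, `n_truth`, `n_recovered`, `recovery`.
#' @export
signature_recovery <- function(vip, effects, tissue, min_grade = 1) {
  sig <- signature_table(vip, min_grade = min_grade, quiet = TRUE)
  purrr::map_dfr(rownames(vip), function(cl) {
    truth <- signature_truth(effects, cl, tissue)
    found <- sig$element[sig$class == cl]
    tibble::tibble(
      class = cl,
      n_truth = length(truth),
      n_recovered = length(intersect(truth, found)),
      recovery = if (length(truth) > 0) {
        length(intersect(truth, found)) / length(truth)
      } else {
        NA_real_
      }
    )
  })
}
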