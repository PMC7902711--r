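#' Mid-ranks of a numeric vector
#'
#' Shared kernel of all rank tests in the package: ties receive the mean of
#' the ranks they span, so the rank sum is always n(n+1)/2.
#'
#' @param values Non-empty numeric vector, all finite.
#' @return Numeric vector of mid-ranks.
#' @examples
#' rank_with_ties(c(5, 5, 7)) # 1.5 1.5 3
#' @export
rank_with_ties <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("all values must be finite", call. = FALSE)
  }
  rank(values, ties.method = "average")
}

# sum of (t^3 - t) over tie groups
tie_cubic <- function(values) {
  t <- table(values)
  sum(t^3 - t)
}

new_rank_test <- function(statistic, p_value, method, exact,
                          tie_correction = 1, df = NA_real_) {
  structure(
    list(
      statistic = statistic, p_value = p_value, method = method,
      exact = exact, tie_correction = tie_correction, df = df
    ),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(
    x$method, ": statistic = ", signif(x$statistic, 5),
    ", p = ", signif(x$p_value, 4),
    if (x$exact) " (exact)" else " (approximate)", "\n",
    sep = ""
  )
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction, referred to a chi-square distribution
#' with k - 1 degrees of freedom. With identical values in every group the
#' statistic is defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return A `rank_test` with fields `statistic` (H), `p_value`, `df`,
#'   `tie_correction`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic # 7.2
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n_i <- lengths(groups)
  if (any(n_i < 1)) stop("every group needs >= 1 observation", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x))) stop("all values must be finite", call. = FALSE)
  n <- length(x)
  r <- rank_with_ties(x)
  g <- rep(seq_along(groups), n_i)
  r_sums <- tapply(r, g, sum)
  h_raw <- 12 / (n * (n + 1)) * sum(r_sums^2 / n_i) - 3 * (n + 1)
  corr <- 1 - tie_cubic(x) / (n^3 - n)
  if (corr <= 0) {
    # every observation identical: no evidence against the null
    return(new_rank_test(0, 1, "Kruskal-Wallis", FALSE,
      tie_correction = 0, df = length(groups) - 1
    ))
  }
  h <- h_raw / corr
  df <- length(groups) - 1
  new_rank_test(
    h, stats::pchisq(h, df, lower.tail = FALSE),
    "Kruskal-Wallis", FALSE,
    tie_correction = corr, df = df
  )
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided p by complete enumeration of all choose(na + nb, na)
#' rank-set labelings when the pooled sample is tie-free and no larger than
#' `exact_threshold`; otherwise a normal approximation with tie and
#' continuity corrections. The two-sided exact p doubles the smaller tail
#' probability (capped at 1).
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_threshold Largest pooled n for which the exact path is taken.
#' @return A `rank_test` with the rank-sum statistic W of `a`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4, 5))$p_value # 0.2
#' @export
wilcoxon_rank_sum <- function(a, b, exact_threshold = 12) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  x <- c(a, b)
  if (!all(is.finite(x))) stop("all values must be finite", call. = FALSE)
  na <- length(a)
  n <- length(x)
  r <- rank_with_ties(x)
  w <- sum(r[seq_len(na)])
  has_ties <- anyDuplicated(x) > 0
  if (!has_ties && n <= exact_threshold) {
    sums <- utils::combn(n, na, FUN = sum) # rank sums over all labelings
    p_le <- mean(sums <= w)
    p_ge <- mean(sums >= w)
    p <- min(1, 2 * min(p_le, p_ge))
    return(new_rank_test(w, p, "Wilcoxon rank-sum", TRUE))
  }
  mu <- na * (n + 1) / 2
  nb <- n - na
  sigma2 <- na * nb / 12 * ((n + 1) - tie_cubic(x) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(new_rank_test(w, 1, "Wilcoxon rank-sum", FALSE, tie_correction = 0))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  if (w == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_rank_test(w, p, "Wilcoxon rank-sum", FALSE,
    tie_correction = 1 - tie_cubic(x) / (n^3 - n)
  )
}

#' Dunn's post hoc test on pooled ranks
#'
#' Pairwise z statistics after a Kruskal-Wallis test, using pooled mid-ranks
#' with tie correction. P-values are Holm-adjusted by default (`adjust =
#' "none"` disables adjustment).
#'
#' @param groups Named (or unnamed) list of >= 3 numeric vectors.
#' @param adjust Method passed to [stats::p.adjust()].
#' @return A tibble with one row per pair: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = "holm") {
  stopifnot(is.list(groups), length(groups) >= 3)
  n_i <- lengths(groups)
  if (any(n_i < 1)) stop("every group needs >= 1 observation", call. = FALSE)
  labels <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labels
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- rank_with_ties(x)
  g <- rep(seq_along(groups), n_i)
  r_means <- tapply(r, g, mean)
  tie_term <- tie_cubic(x) / (12 * (n - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_i[i] + 1 / n_i[j]))
    z <- if (se > 0) (r_means[i] - r_means[j]) / se else 0
    tibble::tibble(
      group1 = labels[i], group2 = labels[j],
      z = unname(z), p_value = 2 * stats::pnorm(-abs(z))
    )
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb letter assignment: two groups share a letter iff their
#' pairwise comparison is non-significant at `alpha`.
#'
#' @param pairwise Tibble with columns `group1`, `group2` and a p-value column
#'   (`p_adjusted` if present, else `p_value`).
#' @param alpha Significance level.
#' @return A tibble `group`, `letters`.
#' @export
compact_letters <- function(pairwise, alpha = 0.05) {
  p <- pairwise[["p_adjusted"]] %||% pairwise[["p_value"]]
  groups <- unique(c(pairwise$group1, pairwise$group2))
  sets <- list(groups)
  sig <- which(p < alpha)
  for (k in sig) {
    g1 <- pairwise$group1[k]
    g2 <- pairwise$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  # order letters by first appearance of their groups
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- tibble::tibble(group = groups, letters = "")
  for (i in seq_along(sets)) {
    hit <- out$group %in% sets[[i]]
    out$letters[hit] <- paste0(out$letters[hit], letters[i])
  }
  out
}
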