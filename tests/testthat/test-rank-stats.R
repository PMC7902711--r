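test_that("mid-ranks handle ties and always sum to n(n+1)/2", {
  expect_equal(rank_with_ties(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_with_ties(c(5, 5, 7)), c(1.5, 1.5, 3))
  for (i in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)
    n <- length(x)
    expect_equal(sum(rank_with_ties(x)), n * (n + 1) / 2)
  }
  expect_error(rank_with_ties(c(1, NA)), "finite")
  expect_error(rank_with_ties(numeric(0)), "empty")
})

test_that("Kruskal-Wallis H matches the hand formula and base R", {
  res <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # identical groups: H = 0, p = 1
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # permuting the group order leaves H unchanged
  g <- list(rnorm(4), rnorm(5), rnorm(6))
  expect_equal(
    kruskal_wallis(g)$statistic,
    kruskal_wallis(g[c(3, 1, 2)])$statistic
  )
  # independent oracle: base R, with and without ties
  withr::with_seed(11, {
    for (i in 1:10) {
      g <- list(
        sample(1:8, 5, replace = TRUE),
        sample(1:8, 6, replace = TRUE),
        sample(1:8, 4, replace = TRUE)
      )
      ref <- stats::kruskal.test(g)
      mine <- kruskal_wallis(g)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("exact Wilcoxon p equals the enumeration distribution", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4, 5))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.2) # 2/10 labelings as extreme
  # identical samples under ties: approximate path, p = 1
  same <- wilcoxon_rank_sum(c(3, 3, 3), c(3, 3, 3))
  expect_false(same$exact)
  expect_equal(same$p_value, 1)
  # oracle: base R exact test over every rank configuration with n <= 8
  for (n in 4:8) {
    for (na in 2:(n - 2)) {
      sets <- utils::combn(n, na)
      for (j in seq_len(ncol(sets))) {
        a <- sets[, j]
        b <- setdiff(1:n, a)
        mine <- wilcoxon_rank_sum(a, b)
        ref <- stats::wilcox.test(a, b, exact = TRUE)
        expect_equal(mine$p_value, ref$p.value,
          tolerance = 1e-12,
          info = paste("n =", n, "subset", j)
        )
      }
    }
  }
})

test_that("approximate Wilcoxon agrees with the exact path on moderate n", {
  withr::with_seed(21, {
    for (i in 1:25) {
      a <- rnorm(6)
      b <- rnorm(6, mean = runif(1, 0, 2))
      p_exact <- wilcoxon_rank_sum(a, b, exact_threshold = 12)$p_value
      p_apx <- wilcoxon_rank_sum(a, b, exact_threshold = 0)$p_value
      expect_lt(abs(p_exact - p_apx), 0.05)
    }
  })
})

test_that("Dunn post hoc z statistics behave and adjustment is monotone", {
  withr::with_seed(5, {
    well_sep <- list(
      a = rnorm(8, 0, 0.1), b = rnorm(8, 5, 0.1), c = rnorm(8, 10, 0.1)
    )
  })
  res <- dunn_posthoc(well_sep)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_value < 0.05))
  expect_true(all(res$p_adjusted >= res$p_value))
  # two identical groups among three: their pairwise z is exactly 0
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  z_ab <- dunn_posthoc(g)$z[1]
  expect_equal(z_ab, 0)
  # independent check of the z formula on fixed data (no ties)
  x <- unlist(well_sep)
  r <- rank(x)
  n <- length(x)
  rm_a <- mean(r[1:8])
  rm_b <- mean(r[9:16])
  se <- sqrt(n * (n + 1) / 12 * (1 / 8 + 1 / 8))
  expect_equal(res$z[res$group1 == "a" & res$group2 == "b"],
    (rm_a - rm_b) / se,
    tolerance = 1e-12
  )
  expect_error(dunn_posthoc(list(1:3, 4:6)), "3")
})

test_that("compact letters encode the pairwise significance graph", {
  pw <- function(p_ab, p_ac, p_bc) {
    tibble::tibble(
      group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
      p_value = c(p_ab, p_ac, p_bc)
    )
  }
  # all pairs significant: three distinct letters
  all_sig <- compact_letters(pw(0.001, 0.001, 0.001))
  expect_equal(all_sig$letters, c("a", "b", "c"))
  # nothing significant: everyone shares "a"
  none <- compact_letters(pw(0.9, 0.5, 0.7))
  expect_equal(unique(none$letters), "a")
  # A~B ns, both differ from C
  mixed <- compact_letters(pw(0.8, 0.01, 0.01))
  expect_equal(mixed$letters[mixed$group == "A"], "a")
  expect_equal(mixed$letters[mixed$group == "B"], "a")
  expect_equal(mixed$letters[mixed$group == "C"], "b")
  # consistency: groups share a letter iff non-significant, on random graphs
  withr::with_seed(3, {
    for (i in 1:20) {
      groups <- LETTERS[1:4]
      cmb <- utils::combn(groups, 2)
      p <- runif(ncol(cmb))
      tab <- tibble::tibble(
        group1 = cmb[1, ], group2 = cmb[2, ], p_value = p
      )
      cld <- compact_letters(tab, alpha = 0.3)
      share <- function(g1, g2) {
        l1 <- strsplit(cld$letters[cld$group == g1], "")[[1]]
        l2 <- strsplit(cld$letters[cld$group == g2], "")[[1]]
        length(intersect(l1, l2)) > 0
      }
      for (j in seq_len(ncol(cmb))) {
        expect_equal(
          share(cmb[1, j], cmb[2, j]),
          p[j] >= 0.3,
          info = paste("iter", i, "pair", j)
        )
      }
    }
  })
})

test_that("Kruskal-Wallis with two groups tracks the Wilcoxon statistic", {
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- rnorm(6)
      b <- rnorm(7, 1)
      h <- kruskal_wallis(list(a, b))$statistic
      w <- wilcoxon_rank_sum(a, b, exact_threshold = 0)
      # H = z^2 up to the continuity correction; compare without it
      n <- 13
      mu <- 6 * (n + 1) / 2
      z2 <- (w$statistic - mu)^2 / (6 * 7 * (n + 1) / 12)
      expect_equal(h, z2, tolerance = 1e-10)
    }
  })
})
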