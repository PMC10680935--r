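test_that("psnr follows its definition and the hand-computed case", {
  # two-voxel case: MSE 0.005, R 1 -> 10*log10(200)
  ref <- array(0, c(2, 1, 1)); ref[2] <- 1
  x <- ref; x[2] <- 0.9
  m <- array(TRUE, c(2, 1, 1))
  expect_equal(psnr(x, ref, m), 10 * log10(200), tolerance = 1e-12)
  expect_equal(psnr(x, ref, m), 23.0103, tolerance = 1e-4)

  # identical images -> +Inf sentinel
  expect_identical(psnr(ref, ref, m), Inf)

  # brute-force agreement on random 8^3 pairs
  for (seed in 1:10) {
    set.seed(seed)
    d <- c(8, 8, 8)
    ref <- array(runif(512, 0.1, 1), d)
    x <- ref + array(rnorm(512, 0, 0.05), d)
    msk <- array(runif(512) > 0.3, d)
    if (!any(msk)) next
    brute <- {
      num <- 0; den <- 0; R <- -Inf
      for (i in which(msk)) {
        num <- num + (x[i] - ref[i])^2
        den <- den + 1
        R <- max(R, ref[i])
      }
      10 * log10(R^2 / (num / den))
    }
    expect_equal(psnr(x, ref, msk), brute, tolerance = 1e-9)
  }

  # more noise -> lower PSNR in expectation
  set.seed(99)
  ref <- array(runif(8^3, 0.2, 1), c(8, 8, 8))
  msk <- array(TRUE, c(8, 8, 8))
  vals <- vapply(c(0.01, 0.05, 0.1), function(s) {
    mean(vapply(1:10, function(i) {
      psnr(ref + array(rnorm(8^3, 0, s), c(8, 8, 8)), ref, msk)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  expect_error(psnr(x, ref, array(FALSE, c(8, 8, 8))), "empty mask")
  expect_error(psnr(ref, array(0, c(8, 8, 8)), msk), "degenerate")
})

test_that("intensity profiles trace the field through a constant phantom", {
  const <- array(5, c(8, 8, 8))
  expect_equal(intensity_profile(const, 3, 4, 4), rep(5, 8))
  expect_length(intensity_profile(const, 1, 2, 3), 8L)

  # a = u * b with constant u: profile correlates with the field's own
  b <- generate_bias_field(tiny_fspec(), c(16, 16, 16), seed = 4)
  a <- 0.5 * b$data
  pa <- intensity_profile(a, 3, 8, 8)
  pb <- intensity_profile(b$data, 3, 8, 8)
  expect_gt(cor(pa, pb), 0.99)

  expect_error(intensity_profile(const, 3, 9, 1), "slice_index")
  expect_error(intensity_profile(const, 3, 1, 0), "line_index")
})

test_that("percentile case selection uses interpolated percentiles", {
  scores <- tibble::tibble(id = sprintf("c%02d", 1:11), value = 1:11)
  sel <- percentile_cases(scores, c(90, 50, 10))
  expect_equal(sel$value[sel$percentile == 50], 6)

  # single case returned for every percentile
  one <- tibble::tibble(id = "only", value = 3.3)
  expect_equal(percentile_cases(one)$id, rep("only", 3))

  # order invariance
  perm <- scores[sample(11), ]
  expect_equal(percentile_cases(perm, c(90, 50, 10)),
               percentile_cases(scores, c(90, 50, 10)))

  expect_error(percentile_cases(scores[0, ]), "at least one")
})

test_that("wilcoxon p-values agree with independent references", {
  # no ties: cross-check against stats::wilcox.test exact p
  set.seed(21)
  for (n in c(6, 9, 12)) {
    d <- rnorm(n)
    p_pkg <- biasnet:::wilcoxon_signed_rank_p(d)
    p_ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }

  # all-tied magnitudes: exhaustive enumeration gives the smallest
  # attainable two-sided p for n = 6, namely 2/64
  expect_equal(biasnet:::wilcoxon_signed_rank_p(rep(1, 6)), 2 / 64)

  # zeros are dropped
  expect_equal(biasnet:::wilcoxon_signed_rank_p(c(0, 0, 0)), 1)
})

test_that("compare_methods reports medians, adjusted p and Cohen's d", {
  ids <- sprintf("s%02d", 1:8)
  set.seed(3)
  base <- rnorm(8, 30, 2)
  scores <- dplyr::bind_rows(
    tibble::tibble(case_id = ids, method = "A", value = base),
    tibble::tibble(case_id = ids, method = "B", value = base),
    tibble::tibble(case_id = ids, method = "C", value = base + rnorm(8, 1))
  )
  rep <- compare_methods(scores)

  # identical lists -> d = 0
  ab <- dplyr::filter(rep$pairwise, method_a == "A", method_b == "B")
  expect_equal(ab$cohens_d, 0)

  # 3 methods -> 3 pairs -> bonferroni multiplier 3
  expect_identical(nrow(rep$pairwise), 3L)
  expect_equal(rep$pairwise$p_adjusted,
               pmin(1, rep$pairwise$p_value * 3))

  # medians recomputed independently
  for (m in c("A", "B", "C")) {
    expect_equal(rep$medians$median[rep$medians$method == m],
                 median(scores$value[scores$method == m]))
  }

  # constant +1 shift on 6 pairs: d -> Inf sentinel, p = 2/64
  s6 <- dplyr::bind_rows(
    tibble::tibble(case_id = as.character(1:6), method = "x", value = 2:7),
    tibble::tibble(case_id = as.character(1:6), method = "y",
                   value = as.numeric(1:6))
  )
  r6 <- compare_methods(s6)
  expect_identical(r6$pairwise$cohens_d, Inf)
  expect_equal(r6$pairwise$p_value, 2 / 64)

  # misaligned cases fail loudly
  bad <- scores[-1, ]
  expect_error(compare_methods(bad), "aligned")

  # glance/tidy surfaces
  expect_identical(tidy(rep), rep$pairwise)
  expect_identical(glance(rep)$n_methods, 3L)
})

test_that("evaluation reports round-trip to disk", {
  dir <- withr::local_tempdir()
  ids <- sprintf("s%02d", 1:6)
  scores <- dplyr::bind_rows(
    tibble::tibble(case_id = ids, method = "A", value = rnorm(6, 30)),
    tibble::tibble(case_id = ids, method = "B", value = rnorm(6, 31))
  )
  rep <- compare_methods(scores)
  write_eval_report(rep, dir)
  per_case <- read.csv(file.path(dir, "per_case.csv"))
  expect_identical(nrow(per_case), 12L)
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(js$medians$median),
               sort(rep$medians$median), tolerance = 1e-12)
  # medians match an independent recomputation from the CSV
  agg <- tapply(per_case$value, per_case$method, median)
  expect_equal(sort(as.numeric(agg)), sort(rep$medians$median),
               tolerance = 1e-12)
})
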