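#' Masked peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE)` with the MSE computed over masked voxels and the
#' data range `R` taken as the masked maximum of the reference image.  The
#' masked convention matters: including the zero background would dominate
#' both terms, and it changes absolute dB values relative to whole-volume
#' PSNR.
#'
#' @param x Image under evaluation.
#' @param ref Reference image (same shape).
#' @param mask Mask with at least one foreground voxel.
#' @return PSNR in dB; `Inf` for identical images.
#' @examples
#' ref <- array(0, c(2, 1, 1)); ref[2] <- 1
#' x <- ref; x[2] <- 0.9
#' psnr(x, ref, array(TRUE, c(2, 1, 1)))  # 10*log10(200) ~ 23.01 dB
#' @export
psnr <- function(x, ref, mask) {
  check_same_shape(x, ref)
  lm <- loss_mask(mask, ref)
  rv <- vol_data(ref)[lm$m]
  xv <- vol_data(x)[lm$m]
  R <- max(rv)
  if (R <= 0) stop("degenerate reference: masked maximum is not positive",
                   call. = FALSE)
  mse <- mean((xv - rv)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

#' Extract an intensity profile along one in-slice line
#'
#' Takes the 2D slice with index `slice_index` along `axis` and returns the
#' voxel values along the line with index `line_index`; the profile runs
#' along the first in-plane axis, `line_index` addresses the second.
#'
#' @param vol Volume or array.
#' @param axis Slice-normal axis, 1..3.
#' @param slice_index Slice position along `axis`.
#' @param line_index Line position along the second in-plane axis.
#' @return Numeric vector of length `dim(vol)[first in-plane axis]`.
#' @export
intensity_profile <- function(vol, axis = 3, slice_index, line_index) {
  x <- vol_data(vol)
  d <- dim(x)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3", call. = FALSE)
  in_plane <- setdiff(1:3, axis)
  if (slice_index < 1 || slice_index > d[axis]) {
    stop("slice_index out of range [1, ", d[axis], "]", call. = FALSE)
  }
  if (line_index < 1 || line_index > d[in_plane[2]]) {
    stop("line_index out of range [1, ", d[in_plane[2]], "]", call. = FALSE)
  }
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[axis]] <- slice_index
  idx[[in_plane[2]]] <- line_index
  as.numeric(do.call(`[`, c(list(x), idx)))
}

#' Select cases nearest given score percentiles
#'
#' For each requested percentile, returns the case whose score is nearest
#' the linear-interpolation percentile of the score distribution, breaking
#' ties deterministically by the smaller id.
#'
#' @param scores A data frame / tibble with columns `id` and `value` (or a
#'   named numeric vector).
#' @param percentiles Percentiles in `[0, 100]` (default 90, 50, 10).
#' @return A tibble with `percentile`, `id`, `value`.
#' @export
percentile_cases <- function(scores, percentiles = c(90, 50, 10)) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble::tibble(id = names(scores), value = as.numeric(scores))
  }
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) < 1) stop("scores must contain at least one case", call. = FALSE)
  scores <- dplyr::arrange(scores, .data$id)
  purrr::map_dfr(percentiles, function(p) {
    q <- quantile(scores$value, p / 100, names = FALSE, type = 7)
    i <- which.min(abs(scores$value - q))  # first (smallest id) wins ties
    tibble::tibble(percentile = p, id = scores$id[i], value = scores$value[i])
  })
}

# Exact/approximate two-sided Wilcoxon signed-rank p-value on paired
# differences.  Zeros dropped; average ranks for tied magnitudes.  Exact
# null distribution from psignrank when there are no ties (n <= 25), by
# exhaustive sign-pattern enumeration when ties are present and n <= 14,
# otherwise a normal approximation with continuity and tie corrections.
wilcoxon_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    p <- if (W > n * (n + 1) / 4) {
      psignrank(W - 1, n, lower.tail = FALSE)
    } else {
      psignrank(W, n)
    }
    return(min(2 * p, 1))
  }
  if (ties && n <= 14) {
    # all 2^n sign assignments are equally likely under the null
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.numeric(signs %*% r)
    p_lo <- mean(Wall <= W)
    p_hi <- mean(Wall >= W)
    return(min(2 * min(p_lo, p_hi), 1))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(2 * pnorm(-abs(z)), 1)
}

# Cohen's d for paired data: mean(diff) / sd(diff); 0 when all differences
# are 0, +/-Inf sentinel when the differences are a nonzero constant.
cohens_d_paired <- function(diffs) {
  m <- mean(diffs)
  s <- sd(diffs)
  if (is.na(s) || s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / s
  }
}

#' Compare corrected-image quality across methods
#'
#' Given per-case scores (typically PSNR in dB) for two or more methods on a
#' shared set of cases, computes per-method medians and, for every method
#' pair, a two-sided Wilcoxon signed-rank p-value on the paired differences,
#' its Bonferroni adjustment (multiplier = number of pairs, capped at 1) and
#' Cohen's d for paired data (mean of differences over their SD).
#'
#' @param paired A data frame / tibble in long format with columns
#'   `case_id`, `method`, `value`, or in wide format with a `case_id` column
#'   and one column per method.
#' @return An object of class `bn_eval_report` with elements `per_case`
#'   (long tibble), `medians` and `pairwise`.
#' @export
compare_methods <- function(paired) {
  paired <- tibble::as_tibble(paired)
  if (!all(c("case_id", "method", "value") %in% names(paired))) {
    if (!"case_id" %in% names(paired)) {
      stop("paired needs a case_id column", call. = FALSE)
    }
    paired <- tidyr::pivot_longer(paired, cols = -"case_id",
                                  names_to = "method", values_to = "value")
  }
  methods <- sort(unique(paired$method))
  if (length(methods) < 2) stop("need at least 2 methods", call. = FALSE)
  wide <- tidyr::pivot_wider(paired, id_cols = "case_id",
                             names_from = "method", values_from = "value")
  if (anyNA(wide)) {
    stop("case ids are not aligned across methods", call. = FALSE)
  }
  medians <- dplyr::summarise(dplyr::group_by(paired, .data$method),
                              median = median(.data$value), .groups = "drop")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    diffs <- wide[[pr[1]]] - wide[[pr[2]]]
    p <- wilcoxon_signed_rank_p(diffs)
    tibble::tibble(method_a = pr[1], method_b = pr[2],
                   n = length(diffs),
                   median_diff = median(diffs),
                   p_value = p,
                   p_adjusted = min(1, p * n_pairs),
                   cohens_d = cohens_d_paired(diffs))
  })
  structure(list(per_case = paired, medians = medians, pairwise = pairwise),
            class = "bn_eval_report")
}

#' @export
print.bn_eval_report <- function(x, ...) {
  cat("<bn_eval_report>\n")
  cat("medians:\n")
  print(x$medians)
  cat("pairwise:\n")
  print(x$pairwise)
  invisible(x)
}

#' @rdname biasnet-tidiers
#' @exportS3Method generics::tidy
tidy.bn_eval_report <- function(x, ...) x$pairwise

#' @rdname biasnet-tidiers
#' @exportS3Method generics::glance
glance.bn_eval_report <- function(x, ...) {
  tibble::tibble(n_methods = nrow(x$medians),
                 n_cases = length(unique(x$per_case$case_id)),
                 best_method = x$medians$method[which.max(x$medians$median)],
                 best_median = max(x$medians$median))
}

#' @rdname biasnet-tidiers
#' @exportS3Method ggplot2::autoplot
autoplot.bn_eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_case,
                  ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "PSNR (dB)") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to disk
#'
#' Per-case scores as CSV, medians and pairwise statistics as JSON.
#'
#' @param report A `bn_eval_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_case, file.path(dir, "per_case.csv"), row.names = FALSE)
  jsonlite::write_json(list(medians = report$medians,
                            pairwise = report$pairwise),
                       file.path(dir, "summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Plot intensity profiles of several volumes along one line
#'
#' @param vols Named list of volumes sharing one grid.
#' @param axis,slice_index,line_index See [intensity_profile()].
#' @return A ggplot with one line per volume.
#' @export
plot_intensity_profiles <- function(vols, axis = 3, slice_index, line_index) {
  df <- purrr::imap_dfr(vols, function(v, nm) {
    y <- intensity_profile(v, axis, slice_index, line_index)
    tibble::tibble(volume = nm, position = seq_along(y), intensity = y)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$intensity,
                                   colour = .data$volume)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "voxel", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
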