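#' Measure wing melanization from a single-channel image
#'
#' The image is binarized (isodata/intermeans iterative threshold by
#' default, or a fixed cutoff); the filled black-region area is the black
#' pixels plus any enclosed white pixels (white not 4-connected to the
#' image border), and total melanization is filled black area minus the
#' enclosed white area — numerically the raw black pixel area. All areas
#' are reported in mm^2 via `px_per_mm`.
#'
#' @param image numeric matrix of intensities (0 = black, larger =
#'   lighter); values are not required to be in [0, 1].
#' @param px_per_mm image scale in pixels per mm (> 0).
#' @param threshold `"isodata"` or a fixed numeric cutoff; pixels with
#'   intensity strictly below the cutoff are black.
#' @return list with `black_area` (filled region, mm^2),
#'   `enclosed_white_area` (mm^2), `total_melanization` (mm^2), and the
#'   `threshold` used. A blank (all-white) image returns zeros with a
#'   warning.
#' @examples
#' img <- render_wing_image(12000, 2000, px_per_mm = 100)
#' measure_melanization(img$image, img$px_per_mm)
#' @export
measure_melanization <- function(image, px_per_mm, threshold = "isodata") {
  image <- as.matrix(image)
  if (px_per_mm <= 0) stop("`px_per_mm` must be > 0")
  thr <- if (is.numeric(threshold)) threshold else isodata_threshold(image)
  black <- image < thr
  if (!any(black)) {
    warning("blank image: no pixels below threshold")
    return(list(black_area = 0, enclosed_white_area = 0,
                total_melanization = 0, threshold = thr))
  }
  cnt <- cpp_count_holes(black)
  scale2 <- px_per_mm^2
  black_px <- cnt$black
  hole_px <- cnt$holes
  list(black_area = (black_px + hole_px) / scale2,
       enclosed_white_area = hole_px / scale2,
       total_melanization = black_px / scale2,
       threshold = thr)
}

# Iterative intermeans (isodata) threshold: midpoint between the means of
# the two classes it induces, iterated to a fixed point.
isodata_threshold <- function(image, max_iter = 100) {
  v <- as.vector(image)
  t0 <- mean(range(v))
  for (i in seq_len(max_iter)) {
    lo <- v[v < t0]; hi <- v[v >= t0]
    if (!length(lo) || !length(hi)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-9) return(t1)
    t0 <- t1
  }
  t0
}

#' Size-correct melanization by regression on wing area
#'
#' Computes the Pearson correlation between total melanization and wing
#' area (two-sided t-test p-value), fits ordinary least squares of
#' melanization on area, and attaches the residuals — the size-corrected
#' melanization used in all group comparisons.
#'
#' @param records data.frame with columns `wing_area` and
#'   `total_melanization` (e.g. from [sim_melanization()] or
#'   [read_melanization_csv()]).
#' @return list with `records` (input plus `residual_melanization`), `R`,
#'   `p_value`, `slope`, `intercept`. Constant wing area gives
#'   `status = "undefined"` with NA correlation.
#' @export
melanization_residuals <- function(records) {
  stopifnot(all(c("wing_area", "total_melanization") %in% names(records)))
  if (nrow(records) < 3) stop("need at least 3 records")
  if (sd(records$wing_area) < 1e-12) {
    records$residual_melanization <-
      records$total_melanization - mean(records$total_melanization)
    return(list(records = records, R = NA_real_, p_value = NA_real_,
                slope = NA_real_, intercept = NA_real_,
                status = "undefined"))
  }
  fit <- lm(total_melanization ~ wing_area, data = records)
  r <- cor(records$wing_area, records$total_melanization)
  n <- nrow(records)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  records$residual_melanization <- as.vector(stats::residuals(fit))
  list(records = records, R = r, p_value = p,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       status = "ok")
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::aov()]:
#' `F = MSB / MSW` with `groups - 1` and `N - groups` degrees of freedom.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @return an `anova_table`: list with `F`, `df_between`, `df_within`, `p`,
#'   `group_means`, `ms_within`, `group_n`.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2))
    stop("group(s) of size 1: ", paste(names(tab)[tab < 2], collapse = ", "))
  fit <- aov(values ~ factor(groups))
  an <- anova(fit)
  structure(list(F = an[1, "F value"], df_between = an[1, "Df"],
                 df_within = an[2, "Df"], p = an[1, "Pr(>F)"],
                 group_means = tapply(values, groups, mean),
                 ms_within = an[2, "Mean Sq"],
                 group_n = as.integer(tab), groups = names(tab),
                 fit = fit),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey's HSD pairwise comparisons
#'
#' Tukey-Kramer studentized-range test from the ANOVA's pooled within-group
#' mean square: `q = |m_i - m_j| / sqrt(MSW (1/n_i + 1/n_j) / 2)`, with
#' adjusted p-values from the studentized-range distribution on
#' (groups, df_within) via [stats::ptukey()].
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame, one row per pair: group1, group2, diff, q, p_adj,
#'   significant.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  an <- one_way_anova(values, groups)
  g <- length(an$groups)
  rows <- list()
  for (a in seq_len(g - 1)) for (b in (a + 1):g) {
    diff <- an$group_means[an$groups[b]] - an$group_means[an$groups[a]]
    se <- sqrt(an$ms_within * (1 / an$group_n[a] + 1 / an$group_n[b]) / 2)
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = g, df = an$df_within, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      group1 = an$groups[a], group2 = an$groups[b],
      diff = unname(diff), q = unname(q), p_adj = unname(p),
      significant = unname(p < alpha), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
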