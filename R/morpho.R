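#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of each landmark from
#' the configuration centroid — the standard isometric size measure in
#' geometric morphometrics.
#'
#' @param config k x 2 coordinate matrix.
#' @return numeric size; zero (with a warning) for a degenerate
#'   configuration of identical points.
#' @examples
#' centroid_size(rbind(c(0, 0), c(2, 0)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  cen <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2, cen)^2))
  if (cs == 0) warning("degenerate configuration: all landmarks identical")
  cs
}

# Optimal 2-D rotation (no reflection) of config b onto target a, both
# centered. Complex-arithmetic form: rotate by Arg(sum Conj(b) * a).
rotate_onto <- function(b, a) {
  zb <- complex(real = b[, 1], imaginary = b[, 2])
  za <- complex(real = a[, 1], imaginary = a[, 2])
  s <- sum(Conj(zb) * za)
  theta <- Arg(s)
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  b %*% R
}

#' Generalized Procrustes superimposition
#'
#' Removes translation, scale and rotation from a set of landmark
#' configurations: each configuration is centered and scaled to unit
#' centroid size, then iteratively rotated onto the current mean shape
#' (rotation only, no reflection) with the mean renormalized to unit
#' centroid size, until the mean changes by less than `tol`. By default
#' the aligned shapes are then orthogonally projected onto the tangent
#' space at the mean shape: without that projection the unit-size
#' constraint leaves second-order curvature variance in the scale and
#' rotation directions, so 12 two-dimensional landmarks would span more
#' than the expected 2k - 4 = 20 shape dimensions. Set `tangent = FALSE`
#' for raw partial-Procrustes coordinates.
#'
#' @param lms a `landmark_set` (see [landmark_set()] / [sim_landmarks()]).
#' @param tol convergence tolerance on the mean-shape change.
#' @param max_iter maximum iterations.
#' @param tangent project aligned shapes into the tangent space at the
#'   mean shape (default TRUE).
#' @return an `aligned_shapes` object: `coords` (12 x 2 x n aligned
#'   configurations), `centroid_size` (pre-scaling sizes), `mean_shape`
#'   (unit centroid size), `group`, `specimens`, `iterations`, `converged`.
#' @export
generalized_procrustes <- function(lms, tol = 1e-10, max_iter = 100,
                                   tangent = TRUE) {
  stopifnot(inherits(lms, "landmark_set"))
  n <- dim(lms$coords)[3]
  if (n < 2) stop("need at least 2 specimens")
  cs <- numeric(n)
  x <- lms$coords
  for (i in seq_len(n)) {
    xi <- scale(x[, , i], center = TRUE, scale = FALSE)
    cs[i] <- sqrt(sum(xi^2))
    if (cs[i] == 0) stop("specimen ", lms$specimens[i], " is degenerate")
    x[, , i] <- xi / cs[i]
  }
  mean_shape <- x[, , 1]
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (i in seq_len(n)) x[, , i] <- rotate_onto(x[, , i], mean_shape)
    new_mean <- apply(x, c(1, 2), mean)
    new_mean <- scale(new_mean, center = TRUE, scale = FALSE)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized Procrustes did not converge in ", max_iter,
            " iterations")
  if (tangent) {
    mu <- as.vector(mean_shape)
    mu <- mu / sqrt(sum(mu^2))
    for (i in seq_len(n)) {
      v <- as.vector(x[, , i])
      x[, , i] <- matrix(v - sum(v * mu) * mu + mu, 12, 2)
    }
  }
  structure(list(coords = x, centroid_size = setNames(cs, lms$specimens),
                 mean_shape = mean_shape, group = lms$group,
                 specimens = lms$specimens, iterations = iterations,
                 converged = converged, tangent = tangent),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("Aligned shapes: %d specimens, %d landmarks; %d iterations%s\n",
              dim(x$coords)[3], dim(x$coords)[1], x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Flatten an aligned-shapes array to an n x 24 matrix (x then y columns).
shapes_to_matrix <- function(aligned) {
  n <- dim(aligned$coords)[3]
  t(vapply(seq_len(n), function(i) as.vector(aligned$coords[, , i]),
           numeric(24)))
}

#' Allometry correction by multivariate regression on centroid size
#'
#' Ordinary least squares of every Procrustes coordinate on centroid size;
#' the residuals (plus, conventionally, nothing else) carry the
#' size-corrected shape variation used by all downstream analyses.
#' `percent_predicted` is the regression sum of squares over the total
#' shape sum of squares. With constant centroid size the regression is
#' undefined: residuals fall back to centered coordinates with a warning.
#'
#' @param aligned an `aligned_shapes` object.
#' @return a `shape_residuals` object: `residuals` (n x 24, centered),
#'   `regression_vector` (length 24, shape change per unit centroid size),
#'   `percent_predicted` (fraction in [0, 1]), `fitted`, `centroid_size`,
#'   `group`, `specimens`.
#' @export
allometry_correction <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  x <- shapes_to_matrix(aligned)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 specimens")
  cs <- aligned$centroid_size
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (sd(cs) < 1e-12) {
    warning("constant centroid size: allometry regression undefined; ",
            "returning centered coordinates")
    res <- xc
    beta <- rep(0, 24)
    pct <- 0
    fitted <- matrix(rep(colMeans(x), each = n), n, 24)
  } else {
    csc <- cs - mean(cs)
    beta <- as.vector(crossprod(xc, csc) / sum(csc^2))
    fitted_c <- outer(csc, beta)
    res <- xc - fitted_c
    pct <- sum(fitted_c^2) / sum(xc^2)
    fitted <- fitted_c + matrix(rep(colMeans(x), each = n), n, 24)
  }
  rownames(res) <- aligned$specimens
  structure(list(residuals = res, regression_vector = beta,
                 percent_predicted = pct, fitted = fitted,
                 centroid_size = cs, group = aligned$group,
                 specimens = aligned$specimens),
            class = "shape_residuals")
}

#' Covariance PCA of shape residuals
#'
#' Principal components of the allometry-corrected Procrustes coordinates
#' from the covariance matrix (no scaling). Superimposition removes two
#' translation, one rotation and one scale degree of freedom, so for 12
#' two-dimensional landmarks at most 20 eigenvalues are nonzero.
#'
#' @param res a `shape_residuals` object (or an `aligned_shapes`, in which
#'   case centered Procrustes coordinates are used directly).
#' @return an `ordination` object with `scores`, `eigenvalues`,
#'   `variance_fraction`, `group` attached.
#' @export
shape_pca <- function(res) {
  if (inherits(res, "aligned_shapes"))
    res <- structure(list(residuals =
                            scale(shapes_to_matrix(res), center = TRUE,
                                  scale = FALSE),
                          group = res$group, specimens = res$specimens),
                     class = "shape_residuals")
  stopifnot(inherits(res, "shape_residuals"))
  if (nrow(res$residuals) < 3) stop("need at least 3 specimens")
  out <- pca_ordination(res$residuals, items = res$specimens)
  out$group <- res$group
  out
}

#' Canonical variate analysis of shape residuals
#'
#' Finds axes maximizing among-group relative to within-group variance.
#' The data are first projected onto principal components with nonzero
#' variance (eigenvalue > 1e-12 of the largest) to guard against the rank
#' deficiency that Procrustes superimposition induces; the generalized
#' eigenproblem of among-group versus pooled within-group covariance is
#' solved there, and scores are scaled so the pooled within-group variance
#' per axis is 1. At two groups the single axis is Fisher's discriminant.
#'
#' @param res a `shape_residuals` object, or a plain matrix of variables.
#' @param groups group labels (defaults to `res$group`).
#' @return a `cva_result`: `scores` (n x axes), `eigenvalues`,
#'   `percent_among_variance`, `group_means` (groups x axes), `axes`
#'   (variables x axes, the canonical vectors in the original space),
#'   `group`.
#' @export
canonical_variates <- function(res, groups = NULL) {
  if (inherits(res, "shape_residuals")) {
    x <- res$residuals
    if (is.null(groups)) groups <- res$group
  } else x <- as.matrix(res)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(x))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2))
    stop("group(s) with fewer than 2 specimens: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  g <- length(tab)
  n <- nrow(x)
  # rank guard: project onto informative PCs
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  ev <- sv$d^2
  keep <- which(ev > 1e-12 * ev[1] & ev > 0)
  keep <- keep[seq_len(min(length(keep), n - g))]
  proj <- sv$v[, keep, drop = FALSE]
  z <- xc %*% proj
  means <- rowsum(z, groups) / as.vector(tab)
  grand <- colMeans(z)
  B <- crossprod(sweep(means, 2, grand) * sqrt(as.vector(tab))) / (g - 1)
  W <- crossprod(z - means[groups, , drop = FALSE]) / (n - g)
  # generalized symmetric eigenproblem via Cholesky of W
  Lc <- chol(W)
  M <- backsolve(Lc, t(backsolve(Lc, B, transpose = TRUE)), transpose = TRUE)
  ei <- eigen((M + t(M)) / 2, symmetric = TRUE)
  naxes <- min(g - 1, ncol(z))
  vals <- pmax(ei$values[seq_len(naxes)], 0)
  vecs <- backsolve(Lc, ei$vectors[, seq_len(naxes), drop = FALSE])
  # scale so pooled within-group variance per axis is 1 (a' W a = 1)
  nrm <- sqrt(colSums(vecs * (W %*% vecs)))
  vecs <- sweep(vecs, 2, nrm, "/")
  scores <- z %*% vecs
  colnames(scores) <- paste0("CV", seq_len(naxes))
  gm <- rowsum(scores, groups) / as.vector(tab)
  pct <- if (sum(vals) > 0) 100 * vals / sum(vals) else vals
  structure(list(scores = scores, eigenvalues = vals,
                 percent_among_variance = pct, group_means = gm,
                 axes = proj %*% vecs, group = groups),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("CVA: %d axes over %d groups\n", length(x$eigenvalues),
              nrow(x$group_means)))
  cat("Eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "),
      "\n")
  invisible(x)
}

#' Pairwise Procrustes distances between group mean shapes
#'
#' Distance between two groups is the square root of the summed squared
#' differences between their mean aligned configurations. Significance is
#' assessed by permuting specimen group labels within each pair and
#' recomputing the distance; the p-value uses the add-one continuity
#' correction `(1 + #{perm >= obs}) / (permutations + 1)`.
#'
#' @param aligned an `aligned_shapes` object.
#' @param groups labels (defaults to `aligned$group`).
#' @param permutations label permutations per pair (a warning is logged
#'   below 100).
#' @param seed integer seed.
#' @return list with symmetric `distance` and `p_value` matrices.
#' @export
procrustes_distances <- function(aligned, groups = NULL,
                                 permutations = 10000, seed = 1L) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  if (is.null(groups)) groups <- aligned$group
  if (permutations < 100)
    warning("fewer than 100 permutations: p-values are coarse")
  x <- shapes_to_matrix(aligned)
  gl <- sort(unique(groups))
  ng <- length(gl)
  if (ng < 2) stop("need at least 2 groups")
  dmat <- pmat <- matrix(0, ng, ng, dimnames = list(gl, gl))
  set.seed(seed)
  for (a in seq_len(ng - 1)) for (b in (a + 1):ng) {
    ia <- which(groups == gl[a]); ib <- which(groups == gl[b])
    xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
    obs <- sqrt(sum((colMeans(xa) - colMeans(xb))^2))
    xx <- rbind(xa, xb)
    na <- length(ia); ntot <- nrow(xx)
    ge <- 0L
    for (pp in seq_len(permutations)) {
      idx <- sample.int(ntot, na)
      d <- sqrt(sum((colMeans(xx[idx, , drop = FALSE]) -
                       colMeans(xx[-idx, , drop = FALSE]))^2))
      if (d >= obs) ge <- ge + 1L
    }
    dmat[a, b] <- dmat[b, a] <- obs
    pmat[a, b] <- pmat[b, a] <- (1 + ge) / (permutations + 1)
  }
  list(distance = dmat, p_value = pmat)
}

#' 95% confidence ellipse of a group mean in a 2-D ordination
#'
#' Ellipse of the mean (not of the data cloud): eigen-decomposition of the
#' sample covariance divided by n, with semi-axes scaled by the square
#' root of the 0.95 chi-square quantile on 2 degrees of freedom (5.991).
#'
#' @param scores n x 2 matrix of ordination scores for one group (n >= 3).
#' @param level confidence level.
#' @return list with `center` (length 2), `semi_axes` (length 2,
#'   descending), `angle` (radians, orientation of the major axis), `cov`.
#' @export
mean_confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2)
  n <- nrow(scores)
  if (n < 3) stop("need at least 3 specimens for a mean ellipse")
  cen <- colMeans(scores)
  S <- cov(scores) / n
  ei <- eigen(S, symmetric = TRUE)
  lam <- pmax(ei$values, 0)
  r <- sqrt(qchisq(level, df = 2) * lam)
  ang <- atan2(ei$vectors[2, 1], ei$vectors[1, 1])
  list(center = cen, semi_axes = r, angle = ang, cov = S, n = n)
}

#' Confidence ellipses for every group
#'
#' @param scores n x 2 score matrix.
#' @param groups group labels.
#' @param level confidence level.
#' @return data.frame: group, center_x, center_y, semi_major, semi_minor,
#'   angle, n.
#' @export
group_ellipses <- function(scores, groups, level = 0.95) {
  gl <- sort(unique(as.character(groups)))
  do.call(rbind, lapply(gl, function(g) {
    e <- mean_confidence_ellipse(scores[groups == g, , drop = FALSE], level)
    data.frame(group = g, center_x = e$center[1], center_y = e$center[2],
               semi_major = e$semi_axes[1], semi_minor = e$semi_axes[2],
               angle = e$angle, n = e$n, stringsAsFactors = FALSE)
  }))
}
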