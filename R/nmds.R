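#' Non-metric multidimensional scaling by iterative majorization
#'
#' Finds a low-dimensional configuration whose inter-point distances
#' reproduce the rank order of the input dissimilarities, minimizing
#' Kruskal's stress-1
#' `sqrt( sum (d - dhat)^2 / sum d^2 )`,
#' where `dhat` are the monotone (pool-adjacent-violators, via
#' [stats::isoreg()]) fitted values of the configuration distances on the
#' dissimilarity ranks. Each iteration alternates monotone regression with
#' a Guttman-transform configuration update; the best of several random
#' starts (plus a classical-scaling start) is returned.
#'
#' @param dissimilarity square symmetric non-negative matrix with zero
#'   diagonal.
#' @param dims embedding dimension (3 is conventional for summarizing
#'   pairwise G_ST among populations).
#' @param restarts number of random initial configurations in addition to
#'   the classical-scaling start.
#' @param max_iter maximum majorization iterations per start.
#' @param tol stop when stress improves by less than `tol`.
#' @param seed integer seed for the random starts.
#' @param init optional explicit starting configuration (n x dims matrix),
#'   used instead of the classical-scaling start.
#' @return an `ordination` object with `scores`, `stress` (Kruskal
#'   stress-1), `stress_trace` of the best start, `axis_count`,
#'   `method = "nmds"`.
#' @export
nmds_embed <- function(dissimilarity, dims = 3, restarts = 8, max_iter = 200,
                       tol = 1e-7, seed = 1L, init = NULL) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("`dissimilarity` must be square and symmetric")
  if (any(d < 0) || any(abs(diag(d)) > 1e-12))
    stop("`dissimilarity` must be non-negative with zero diagonal")
  n <- nrow(d)
  if (n <= dims) dims <- max(1L, n - 1L)
  low <- lower.tri(d)
  delta <- d[low]
  ord <- order(delta)
  m <- length(delta)
  set.seed(seed)

  run_start <- function(x0) {
    x <- x0
    dist_low <- function(x) as.vector(dist(x))
    dv <- dist_low(x)
    trace <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      # monotone regression of distances on dissimilarity ranks
      fit <- isoreg(seq_len(m), dv[ord])$yf
      dhat <- numeric(m); dhat[ord] <- fit
      stress <- sqrt(sum((dv - dhat)^2) / sum(dv^2))
      trace <- c(trace, stress)
      if (prev - stress < tol) break
      prev <- stress
      # Guttman transform for fixed dhat
      B <- matrix(0, n, n)
      ratio <- ifelse(dv > 1e-12, dhat / dv, 0)
      B[low] <- -ratio; B <- B + t(B)
      diag(B) <- -rowSums(B)
      x <- (B %*% x) / n
      dv <- dist_low(x)
    }
    list(scores = x, stress = trace[length(trace)], trace = trace)
  }

  starts <- list()
  if (!is.null(init)) {
    stopifnot(nrow(init) == n, ncol(init) == dims)
    starts[[1]] <- init
  } else {
    cm <- tryCatch(stats::cmdscale(d, k = dims), error = function(e) NULL)
    if (!is.null(cm) && ncol(cm) == dims) starts[[1]] <- cm
  }
  for (r in seq_len(restarts))
    starts[[length(starts) + 1]] <- matrix(rnorm(n * dims), n, dims)
  best <- NULL
  for (x0 in starts) {
    res <- run_start(x0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  scores <- best$scores
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("NMDS", seq_len(dims))
  structure(list(scores = scores, stress = best$stress,
                 stress_trace = best$trace, axis_count = dims,
                 method = "nmds"),
            class = "ordination")
}
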