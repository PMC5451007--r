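#' Filtering rules for a read-count dataset
#'
#' @param min_site_coverage_fraction minimum fraction of individuals that
#'   must have at least one read at a site (default 0.25).
#' @param biallelic_only drop sites reported with more than two alleles
#'   (requires `allele_count_per_site` in [filter_dataset()]).
#' @param min_reads_per_population minimum total reads per population at a
#'   site (default 15).
#' @param max_individual_missing_fraction individuals missing more than this
#'   fraction of loci are dropped (default 0.98).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(min_site_coverage_fraction = 0.25,
                        biallelic_only = TRUE,
                        min_reads_per_population = 15,
                        max_individual_missing_fraction = 0.98) {
  stopifnot(min_site_coverage_fraction >= 0, min_site_coverage_fraction <= 1,
            max_individual_missing_fraction >= 0,
            max_individual_missing_fraction <= 1,
            min_reads_per_population >= 0)
  structure(list(min_site_coverage_fraction = min_site_coverage_fraction,
                 biallelic_only = biallelic_only,
                 min_reads_per_population = min_reads_per_population,
                 max_individual_missing_fraction =
                   max_individual_missing_fraction),
            class = "filter_spec")
}

#' Filter a read-count dataset
#'
#' Applies, in order: (1) drop sites with more than two alleles (when
#' `allele_count_per_site` is supplied and `biallelic_only` is set);
#' (2) drop sites where fewer than `min_site_coverage_fraction` of
#' individuals have at least one read; (3) drop sites whose total read
#' count in any population falls below `min_reads_per_population`;
#' (4) drop individuals missing more than
#' `max_individual_missing_fraction` of the retained loci. Every removal is
#' logged with the rule that fired.
#'
#' @param rcm a [read_counts()] object.
#' @param spec a [filter_spec()].
#' @param allele_count_per_site optional integer vector, alleles observed
#'   per site (from upstream variant calling).
#' @return list with `rcm` (filtered; `NULL` with `status = "empty"` when
#'   nothing survives), `log` (data.frame item/type/rule), and `status`.
#' @export
filter_dataset <- function(rcm, spec = filter_spec(),
                           allele_count_per_site = NULL) {
  stopifnot(inherits(rcm, "read_counts"), inherits(spec, "filter_spec"))
  depth <- rcm$ref + rcm$alt
  n <- nrow(depth)
  log_entries <- list()
  drop_site <- rep(FALSE, ncol(depth))
  add_log <- function(items, type, rule) {
    if (length(items))
      log_entries[[length(log_entries) + 1]] <<-
        data.frame(item = items, type = type, rule = rule,
                   stringsAsFactors = FALSE)
  }
  if (spec$biallelic_only && !is.null(allele_count_per_site)) {
    if (length(allele_count_per_site) != ncol(depth))
      stop("`allele_count_per_site` must have one entry per locus")
    bad <- allele_count_per_site > 2
    add_log(rcm$loci[bad & !drop_site], "site", "multiallelic")
    drop_site <- drop_site | bad
  }
  cov_frac <- colMeans(depth > 0)
  bad <- cov_frac < spec$min_site_coverage_fraction
  add_log(rcm$loci[bad & !drop_site], "site", "site_coverage")
  drop_site <- drop_site | bad
  for (pk in unique(rcm$pop)) {
    pop_reads <- colSums(depth[rcm$pop == pk, , drop = FALSE])
    bad <- pop_reads < spec$min_reads_per_population
    add_log(rcm$loci[bad & !drop_site], "site",
            paste0("min_reads_population:", pk))
    drop_site <- drop_site | bad
  }
  keep_loci <- which(!drop_site)
  if (!length(keep_loci)) {
    return(list(rcm = NULL, status = "empty",
                log = do.call(rbind, log_entries)))
  }
  miss <- rowMeans(depth[, keep_loci, drop = FALSE] == 0)
  drop_ind <- miss > spec$max_individual_missing_fraction
  add_log(rcm$ind[drop_ind], "individual", "individual_missingness")
  keep_ind <- which(!drop_ind)
  if (!length(keep_ind)) {
    return(list(rcm = NULL, status = "empty",
                log = do.call(rbind, log_entries)))
  }
  out <- subset_read_counts(rcm, keep_ind, keep_loci)
  lg <- if (length(log_entries)) do.call(rbind, log_entries) else
    data.frame(item = character(), type = character(), rule = character(),
               stringsAsFactors = FALSE)
  list(rcm = out, status = "ok", log = lg)
}

#' PCA of genotype posterior probabilities
#'
#' Builds the individuals x (3 * loci) matrix of genotype posterior
#' probabilities, imputes missing cells with the column mean, mean-centers
#' columns without scaling, and eigendecomposes the covariance matrix (via
#' [stats::prcomp()]).
#'
#' @param gp genotype posterior array (individuals x loci x 3) as returned
#'   by [gibbs_allele_frequency()].
#' @return an `ordination` object: `scores` (individuals x axes),
#'   `variance_fraction`, `axis_count`, `method = "pca"`.
#' @export
genotype_pca <- function(gp) {
  stopifnot(length(dim(gp)) == 3, dim(gp)[3] == 3)
  n <- dim(gp)[1]
  if (n < 2) stop("need at least 2 individuals for PCA")
  x <- cbind(gp[, , 1], gp[, , 2], gp[, , 3])
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  pca_ordination(x, items = rownames(gp[, , 1]))
}

# Covariance PCA shared by genotype_pca and shape_pca.
pca_ordination <- function(x, items = rownames(x)) {
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  vf <- if (sum(ev) > 0) ev / sum(ev) else ev
  scores <- pc$x
  rownames(scores) <- items
  structure(list(scores = scores, variance_fraction = vf,
                 eigenvalues = ev, rotation = pc$rotation,
                 axis_count = ncol(scores), method = "pca"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d items, %d axes\n", toupper(x$method),
              nrow(x$scores), x$axis_count))
  if (x$method == "pca")
    cat("Variance fractions:",
        paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)),
              collapse = " "), "\n")
  else cat(sprintf("Kruskal stress-1: %.4f\n", x$stress))
  invisible(x)
}

#' Nei's multi-locus G_ST for a pair of frequency vectors
#'
#' `H_S` is the mean within-population expected heterozygosity
#' `2 p_k (1 - p_k)` over the two populations, `H_T = 2 p_bar (1 - p_bar)`
#' with `p_bar` the across-population mean frequency. The multi-locus value
#' is the ratio of sums over loci, `sum(H_T - H_S) / sum(H_T)`, which is
#' stable at nearly monomorphic loci.
#'
#' @param p1,p2 per-locus allele frequencies of the two populations.
#' @return G_ST in [0, 1]; `NA` when `sum(H_T)` is zero (no shared
#'   polymorphism).
#' @examples
#' gst_pair(0.2, 0.8)  # 0.36
#' @export
gst_pair <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  ht <- 2 * pbar * (1 - pbar)
  if (sum(ht) <= 0) return(NA_real_)
  max(0, sum(ht - hs) / sum(ht))
}

#' Pairwise G_ST with Bayesian credible intervals
#'
#' For every population pair, Nei's multi-locus G_ST is computed per
#' retained MCMC draw (pairing draws at matched iterations across the
#' independent population chains); the point estimate is the posterior
#' mean, and the 95% credible interval is the 2.5/97.5 percentile of the
#' per-draw values.
#'
#' @param afp an `allele_freq_posterior` from [gibbs_allele_frequency()].
#' @return a `gst_matrix`: list with `populations`, symmetric `estimate`,
#'   `ci_low`, `ci_high` matrices (diagonal 0), and `draws` (per-pair
#'   per-draw values, a list keyed "A|B").
#' @export
pairwise_gst <- function(afp) {
  stopifnot(inherits(afp, "allele_freq_posterior"))
  pops <- afp$populations
  if (length(pops) < 2) stop("need at least 2 populations")
  np <- length(pops)
  est <- lo <- hi <- matrix(0, np, np, dimnames = list(pops, pops))
  draws_list <- list()
  nd <- dim(afp$draws)[3]
  for (a in seq_len(np - 1)) for (b in (a + 1):np) {
    g <- vapply(seq_len(nd), function(t)
      gst_pair(afp$draws[a, , t], afp$draws[b, , t]), numeric(1))
    if (all(is.na(g))) {
      est[a, b] <- est[b, a] <- NA_real_
      lo[a, b] <- lo[b, a] <- hi[a, b] <- hi[b, a] <- NA_real_
    } else {
      est[a, b] <- est[b, a] <- mean(g, na.rm = TRUE)
      q <- quantile(g, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      lo[a, b] <- lo[b, a] <- q[1]
      hi[a, b] <- hi[b, a] <- q[2]
    }
    draws_list[[paste(pops[a], pops[b], sep = "|")]] <- g
  }
  structure(list(populations = pops, estimate = est, ci_low = lo,
                 ci_high = hi, draws = draws_list),
            class = "gst_matrix")
}

#' @export
print.gst_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise G_ST (lower triangle: estimate; upper: 95% CI)\n")
  print(format_gst_table(x, digits = digits), quote = FALSE)
  invisible(x)
}

# Lower-triangle estimates, upper-triangle "lo-hi" credible strings.
format_gst_table <- function(gst, digits = 3) {
  pops <- gst$populations
  np <- length(pops)
  out <- matrix("", np, np, dimnames = list(pops, pops))
  for (a in seq_len(np)) for (b in seq_len(np)) {
    if (a > b) out[a, b] <- formatC(gst$estimate[a, b], digits = digits,
                                    format = "f")
    if (a < b) out[a, b] <- paste0(
      formatC(gst$ci_low[a, b], digits = digits, format = "f"), "-",
      formatC(gst$ci_high[a, b], digits = digits, format = "f"))
  }
  out
}

# Tidy long-format G_ST table.
gst_long_table <- function(gst) {
  pops <- gst$populations
  np <- length(pops)
  rows <- list()
  for (a in seq_len(np - 1)) for (b in (a + 1):np)
    rows[[length(rows) + 1]] <- data.frame(
      pop1 = pops[a], pop2 = pops[b], gst = gst$estimate[a, b],
      ci_low = gst$ci_low[a, b], ci_high = gst$ci_high[a, b],
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Pseudo-haploid allele sampling
#'
#' Represents each individual-locus by a single sampled read: the call is
#' allele 2 with probability `alt / (ref + alt)`, otherwise allele 1;
#' zero-depth cells are missing. This sidesteps diploid genotype calling at
#' low depth and is the input representation for [admixture_gibbs()].
#'
#' @param rcm a [read_counts()] object.
#' @param seed integer seed.
#' @return a `pseudo_haploid` object: integer matrix (individuals x loci)
#'   with values 1, 2 or NA, population labels attached as attribute `pop`.
#' @export
pseudo_haploid_sample <- function(rcm, seed = 1L) {
  stopifnot(inherits(rcm, "read_counts"))
  set.seed(seed)
  depth <- rcm$ref + rcm$alt
  pr <- ifelse(depth > 0, rcm$alt / pmax(depth, 1), NA_real_)
  calls <- matrix(NA_integer_, nrow(depth), ncol(depth),
                  dimnames = dimnames(depth))
  nz <- which(depth > 0)
  calls[nz] <- 1L + (runif(length(nz)) < pr[nz])
  structure(calls, pop = rcm$pop, class = c("pseudo_haploid", "matrix"))
}
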