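#' Simulate population allele frequencies under the F-model
#'
#' Draws ancestral allele frequencies p0 uniformly on `p0_range`, then for
#' each population draws its frequency at each locus from a Beta
#' distribution with mean p0 and variance `F * p0 * (1 - p0)` (the F-model
#' of Beta-distributed drift: shape parameters `p0(1-F)/F` and
#' `(1-p0)(1-F)/F`). `F` controls how far populations drift apart and is
#' the generating analogue of among-population differentiation.
#'
#' @param loci number of biallelic loci.
#' @param populations character vector of population labels.
#' @param F differentiation parameter, strictly in (0, 1).
#' @param p0_range interval within (0, 1) for the ancestral frequency.
#' @param seed integer seed; the generator is a pure function of it.
#' @return An object of class `pop_freqs`: list with `loci`, `populations`,
#'   `p0` (length-loci vector), `F`, and `p`, a populations x loci matrix.
#' @examples
#' fr <- sim_pop_frequencies(100, c("early", "late"), F = 0.06, seed = 1)
#' range(fr$p)
#' @export
sim_pop_frequencies <- function(loci, populations, F, p0_range = c(0.05, 0.95),
                                seed = 1L) {
  if (!is.numeric(F) || length(F) != 1 || F <= 0 || F >= 1)
    stop("`F` must lie strictly in (0, 1)")
  if (loci < 1) stop("`loci` must be >= 1")
  if (length(p0_range) != 2 || p0_range[1] <= 0 || p0_range[2] >= 1 ||
      p0_range[1] > p0_range[2])
    stop("`p0_range` must be an interval within (0, 1)")
  populations <- as.character(populations)
  set.seed(seed)
  p0 <- runif(loci, p0_range[1], p0_range[2])
  a <- p0 * (1 - F) / F
  b <- (1 - p0) * (1 - F) / F
  p <- matrix(NA_real_, length(populations), loci,
              dimnames = list(populations, paste0("locus", seq_len(loci))))
  for (k in seq_along(populations)) p[k, ] <- rbeta(loci, a, b)
  structure(list(loci = loci, populations = populations, p0 = p0, F = F,
                 p = p),
            class = "pop_freqs")
}

# Read-count channel shared by the simulators: given genotypes (individuals x
# loci, copies of the alternate allele) simulate depths and alternate reads.
sim_reads_from_genotypes <- function(g, coverage, err, missing_rate) {
  n <- nrow(g); L <- ncol(g)
  depth <- rpois(n * L, coverage)
  depth[runif(n * L) < missing_rate] <- 0L
  e <- c(err, 0.5, 1 - err)[g + 1L]
  alt <- rbinom(n * L, depth, e)
  list(ref = matrix(as.integer(depth - alt), n, L),
       alt = matrix(as.integer(alt), n, L))
}

#' Simulate GBS-style read counts from F-model populations
#'
#' For each individual, genotypes are Hardy-Weinberg draws
#' `g ~ Binomial(2, p)` from its population's frequencies; sequencing depth
#' is `Poisson(coverage)` (zeroed with probability `missing_rate`), and
#' alternate-read counts are `Binomial(depth, e(g))` with a symmetric
#' per-read miscall rate: `e(0) = err`, `e(1) = 0.5`, `e(2) = 1 - err`.
#'
#' @param freqs a `pop_freqs` object from [sim_pop_frequencies()].
#' @param n_per_pop integer number of diploid individuals per population
#'   (recycled across populations).
#' @param coverage mean read depth per individual-locus (> 0).
#' @param err per-read miscall rate, in [0, 0.5).
#' @param missing_rate probability that an individual-locus has no reads at
#'   all, on top of Poisson zeros.
#' @param seed integer seed.
#' @return list with `rcm` (a [read_counts()] object) and `truth`, a list
#'   holding the generating `freqs`, the genotype matrix and the seed.
#' @examples
#' fr <- sim_pop_frequencies(50, c("A", "B"), F = 0.1, seed = 1)
#' sim <- sim_read_counts(fr, n_per_pop = 5, coverage = 8, seed = 2)
#' sim$rcm
#' @export
sim_read_counts <- function(freqs, n_per_pop, coverage = 8, err = 0.005,
                            missing_rate = 0, seed = 1L) {
  stopifnot(inherits(freqs, "pop_freqs"))
  if (coverage <= 0) stop("`coverage` must be > 0")
  if (err < 0 || err >= 0.5) stop("`err` must be in [0, 0.5)")
  npop <- length(freqs$populations)
  n_per_pop <- rep_len(as.integer(n_per_pop), npop)
  if (any(n_per_pop < 1)) stop("every population needs at least one individual")
  set.seed(seed)
  pop <- rep(freqs$populations, n_per_pop)
  n <- length(pop); L <- freqs$loci
  g <- matrix(0L, n, L)
  for (k in seq_len(npop)) {
    rows <- which(pop == freqs$populations[k])
    g[rows, ] <- matrix(rbinom(length(rows) * L, 2,
                               rep(freqs$p[k, ], each = length(rows))),
                        length(rows), L)
  }
  reads <- sim_reads_from_genotypes(g, coverage, err, missing_rate)
  rcm <- read_counts(reads$ref, reads$alt, pop)
  dimnames(g) <- dimnames(rcm$ref)
  list(rcm = rcm,
       truth = list(frequencies = freqs, genotypes = g, coverage = coverage,
                    err = err, missing_rate = missing_rate, seed = seed))
}

#' Simulate read counts for admixed individuals
#'
#' Cluster allele frequencies come from [sim_pop_frequencies()]; each of the
#' two allele copies of an individual at a locus first draws its cluster of
#' origin from the individual's admixture proportions `q`, then its allele
#' from that cluster's frequency. Read counts follow the same channel as
#' [sim_read_counts()].
#'
#' @param K number of source clusters (>= 1).
#' @param loci number of loci.
#' @param F cluster differentiation parameter in (0, 1).
#' @param q either an n x K matrix of per-individual admixture proportions
#'   (rows summing to 1), or a single positive number used as a symmetric
#'   Dirichlet parameter (requires `n_ind`).
#' @param n_ind number of individuals when `q` is a Dirichlet parameter.
#' @param coverage,err,missing_rate read channel parameters as in
#'   [sim_read_counts()].
#' @param p0_range ancestral frequency interval.
#' @param seed integer seed.
#' @return list with `rcm` and `truth` (including `q_true` and cluster
#'   frequencies). Individuals are labelled by their majority cluster.
#' @export
sim_admixed_read_counts <- function(K, loci, F, q, n_ind = NULL, coverage = 8,
                                    err = 0.005, missing_rate = 0,
                                    p0_range = c(0.05, 0.95), seed = 1L) {
  if (K < 1) stop("`K` must be >= 1")
  set.seed(seed)
  if (is.matrix(q)) {
    if (ncol(q) != K) stop("`q` must have K columns")
    if (any(abs(rowSums(q) - 1) > 1e-9))
      stop("rows of `q` must sum to 1 (tolerance 1e-9)")
  } else {
    if (is.null(n_ind)) stop("`n_ind` is required when `q` is a Dirichlet parameter")
    a <- matrix(rgamma(n_ind * K, shape = q), n_ind, K)
    q <- a / rowSums(a)
  }
  freqs <- sim_pop_frequencies(loci, paste0("cluster", seq_len(K)), F = F,
                               p0_range = p0_range,
                               seed = sample.int(.Machine$integer.max, 1))
  n <- nrow(q)
  g <- matrix(0L, n, loci)
  for (copy in 1:2) {
    # cluster of origin per individual-locus for this allele copy
    u <- matrix(runif(n * loci), n, loci)
    z <- matrix(1L, n, loci)
    if (K > 1) {
      cum <- t(apply(q, 1, cumsum))
      for (k in seq_len(K - 1))
        z <- z + (u > cum[, k])
    }
    pz <- matrix(freqs$p[cbind(as.vector(z), rep(seq_len(loci), each = n))],
                 n, loci)
    g <- g + matrix(rbinom(n * loci, 1, pz), n, loci)
  }
  reads <- sim_reads_from_genotypes(g, coverage, err, missing_rate)
  lab <- freqs$populations[apply(q, 1, which.max)]
  rcm <- read_counts(reads$ref, reads$alt, lab)
  dimnames(g) <- dimnames(rcm$ref)
  rownames(q) <- rcm$ind
  list(rcm = rcm,
       truth = list(frequencies = freqs, genotypes = g, q_true = q,
                    coverage = coverage, err = err, seed = seed))
}

#' Default 12-landmark wing template
#'
#' A fixed 12 x 2 coordinate template shaped like a generic insect forewing
#' (landmarks at vein junctions and vein-margin intersections), used as the
#' default `base_shape` in [sim_landmarks()]. Units are arbitrary; centroid
#' size is about 1.
#'
#' @return a 12 x 2 numeric matrix.
#' @export
wing_template <- function() {
  m <- matrix(c(
    0.00,  0.00,   # wing base
    0.25,  0.12,   # subcosta-margin
    0.55,  0.17,   # radius fork
    0.80,  0.14,   # R1-margin
    0.95,  0.05,   # wing apex
    0.90, -0.05,   # M1-margin
    0.78, -0.12,   # M3-margin
    0.60, -0.16,   # cubitus-margin
    0.38, -0.14,   # anal margin
    0.45, -0.02,   # discal cell distal
    0.30,  0.03,   # discal cell proximal
    0.15, -0.05),  # cubitus base
    ncol = 2, byrow = TRUE)
  rownames(m) <- paste0("lm", 1:12)
  scale(m, center = TRUE, scale = FALSE) / centroid_size(m)
}

#' Simulate landmark configurations with group, allometry and noise effects
#'
#' Each specimen's shape is `base + group effect + allometric_vector *
#' (cs - mean cs) + iid Gaussian coordinate noise`, where `cs` is the
#' specimen's target centroid size drawn uniformly on `cs_range`. The
#' configuration is then rescaled to centroid size `cs` and hit with a
#' random rotation and translation (no reflection) to mimic digitization of
#' photographed specimens.
#'
#' @param groups named integer vector: specimens per group.
#' @param base_shape 12 x 2 matrix of mean landmark coordinates.
#' @param shape_effects named list of per-group offsets (12 x 2 matrix or
#'   length-24 vector, xy interleaved by landmark rows); groups absent from
#'   the list get zero effect.
#' @param allometric_vector length-24 shape change per unit centroid size
#'   (12 x 2 accepted), applied around the mean size.
#' @param cs_range interval of centroid sizes (in digitized units, e.g. mm).
#' @param noise_sd per-coordinate digitization noise, in shape units.
#' @param seed integer seed.
#' @return An object of class `landmark_set`: list with `coords` (12 x 2 x n
#'   array), `group` (character), `specimens`, plus a `truth` element with
#'   the generating effects and target sizes.
#' @export
sim_landmarks <- function(groups, base_shape = wing_template(),
                          shape_effects = NULL, allometric_vector = NULL,
                          cs_range = c(18, 26), noise_sd = 0.005, seed = 1L) {
  base_shape <- as.matrix(base_shape)
  if (nrow(base_shape) != 12 || ncol(base_shape) != 2)
    stop("`base_shape` must be a 12 x 2 coordinate matrix")
  if (max(dist(base_shape)) < 1e-12)
    stop("degenerate base shape: all landmarks identical")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  as_config <- function(v) {
    if (is.null(v)) return(matrix(0, 12, 2))
    if (is.matrix(v)) return(v)
    matrix(v, 12, 2)
  }
  allo <- as_config(allometric_vector)
  set.seed(seed)
  grp <- rep(names(groups), groups)
  n <- length(grp)
  cs <- runif(n, cs_range[1], cs_range[2])
  cs_c <- cs - mean(cs)
  coords <- array(NA_real_, c(12, 2, n),
                  dimnames = list(rownames(base_shape), c("x", "y"), NULL))
  for (i in seq_len(n)) {
    eff <- as_config(shape_effects[[grp[i]]])
    sh <- base_shape + eff + allo * cs_c[i] +
      matrix(rnorm(24, 0, noise_sd), 12, 2)
    sh <- scale(sh, center = TRUE, scale = FALSE)
    sh <- sh / centroid_size(sh) * cs[i]
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    coords[, , i] <- sh %*% R +
      matrix(runif(2, -50, 50), 12, 2, byrow = TRUE)
  }
  specimens <- paste0(grp, "_", stats::ave(seq_len(n), grp, FUN = seq_along))
  dimnames(coords)[[3]] <- specimens
  structure(list(coords = coords, group = grp, specimens = specimens,
                 truth = list(base_shape = base_shape,
                              shape_effects = shape_effects,
                              allometric_vector = allo, cs_true = cs,
                              noise_sd = noise_sd, seed = seed)),
            class = "landmark_set")
}

#' Construct a landmark set from coordinates
#'
#' @param coords 12 x 2 x n array (or n x 24 matrix, xy pairs by landmark).
#' @param group character of group labels, length n.
#' @param specimens optional specimen identifiers.
#' @param side optional left/right indicator per specimen ("L"/"R"); see
#'   [mirror_side()].
#' @return a `landmark_set` object.
#' @export
landmark_set <- function(coords, group, specimens = NULL, side = NULL) {
  if (is.matrix(coords)) {
    n <- nrow(coords)
    if (ncol(coords) != 24) stop("expected 24 coordinate columns (12 landmarks)")
    a <- array(NA_real_, c(12, 2, n))
    for (i in seq_len(n)) a[, , i] <- matrix(coords[i, ], 12, 2)
    coords <- a
  }
  if (length(dim(coords)) != 3 || dim(coords)[1] != 12 || dim(coords)[2] != 2)
    stop("`coords` must be a 12 x 2 x n array")
  n <- dim(coords)[3]
  if (length(group) != n) stop("`group` must have one label per specimen")
  if (any(!is.finite(coords))) stop("landmark coordinates must be finite")
  if (is.null(specimens)) specimens <- paste0("spec", seq_len(n))
  if (anyDuplicated(specimens)) stop("specimen identifiers must be unique")
  if (!is.null(side) && length(side) != n)
    stop("`side` must have one entry per specimen")
  dimnames(coords) <- list(paste0("lm", 1:12), c("x", "y"), specimens)
  structure(list(coords = coords, group = as.character(group),
                 specimens = specimens, side = side),
            class = "landmark_set")
}

#' Mirror one wing side before superimposition
#'
#' Rotation fitting in [generalized_procrustes()] deliberately excludes
#' reflections, so when a right wing substitutes for a damaged left wing
#' it must be mirrored explicitly first. Specimens whose `side` flag
#' matches `side` have their x-coordinates negated.
#'
#' @param lms a `landmark_set` with a `side` element.
#' @param side the side to reflect (default "R").
#' @return the landmark set with flagged specimens mirrored and their flag
#'   rewritten to the opposite side.
#' @export
mirror_side <- function(lms, side = "R") {
  stopifnot(inherits(lms, "landmark_set"))
  if (is.null(lms$side)) return(lms)
  hit <- which(lms$side == side)
  for (i in hit) lms$coords[, 1, i] <- -lms$coords[, 1, i]
  lms$side[hit] <- setdiff(c("L", "R"), side)[1]
  lms
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set:", length(x$specimens), "specimens x 12 landmarks\n")
  print(table(x$group))
  invisible(x)
}

#' Simulate wing melanization measurements
#'
#' Total melanization (mm^2 of black) is generated as
#' `slope * area + offset(group) + Gaussian noise`, truncated at zero.
#' Both wing area and melanization are "measured" twice with small
#' measurement error, mirroring duplicate measurement protocols; the
#' averages are what downstream analysis uses.
#'
#' @param groups named integer vector: specimens per group.
#' @param area_range wing-area interval in mm^2.
#' @param slope melanization per unit wing area (mm^2 per mm^2).
#' @param group_offsets named numeric of per-group melanization offsets
#'   (mm^2); missing groups get 0.
#' @param noise_sd biological noise sd (mm^2).
#' @param measurement_sd sd of duplicate-measurement error (mm^2).
#' @param seed integer seed.
#' @return data.frame with specimen, group, area_1, area_2, wing_area,
#'   melanization_1, melanization_2, total_melanization; the generating
#'   parameters are attached as attribute `truth`.
#' @export
sim_melanization <- function(groups, area_range = c(150, 350), slope = 0.2,
                             group_offsets = NULL, noise_sd = 3,
                             measurement_sd = 0.5, seed = 1L) {
  if (any(area_range <= 0)) stop("`area_range` must be positive")
  if (!is.finite(slope)) stop("`slope` must be finite")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  set.seed(seed)
  grp <- rep(names(groups), groups)
  n <- length(grp)
  off <- rep(0, n)
  if (!is.null(group_offsets)) {
    hit <- grp %in% names(group_offsets)
    off[hit] <- unlist(group_offsets)[grp[hit]]
  }
  area <- runif(n, area_range[1], area_range[2])
  mel <- pmax(0, slope * area + off + rnorm(n, 0, noise_sd))
  a1 <- area + rnorm(n, 0, measurement_sd)
  a2 <- area + rnorm(n, 0, measurement_sd)
  m1 <- mel + rnorm(n, 0, measurement_sd)
  m2 <- mel + rnorm(n, 0, measurement_sd)
  out <- data.frame(
    specimen = paste0(grp, "_", stats::ave(seq_len(n), grp, FUN = seq_along)),
    group = grp, area_1 = a1, area_2 = a2, wing_area = (a1 + a2) / 2,
    melanization_1 = m1, melanization_2 = m2,
    total_melanization = (m1 + m2) / 2,
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(slope = slope, group_offsets = group_offsets,
                             noise_sd = noise_sd, area_true = area,
                             melanization_true = mel, seed = seed)
  out
}

#' Render a synthetic binary wing image with known pixel bookkeeping
#'
#' Draws a filled black rectangle ("wing") containing a rectangular white
#' hole on a white field, with exactly `filled_px` pixels in the filled
#' black region (black + hole) and `hole_px` pixels in the hole. Useful for
#' exact-area tests of [measure_melanization()].
#'
#' @param filled_px number of pixels in the filled black region (hole
#'   included).
#' @param hole_px number of enclosed white (hole) pixels; must leave a black
#'   border around the hole.
#' @param px_per_mm image scale (pixels per mm).
#' @param pad white margin in pixels around the blob.
#' @return list with `image` (numeric matrix, 0 = black, 1 = white),
#'   `px_per_mm`, and the exact `filled_px`, `hole_px`, `black_px` used.
#' @export
render_wing_image <- function(filled_px = 12000, hole_px = 2000,
                              px_per_mm = 100, pad = 10) {
  stopifnot(filled_px >= 1, hole_px >= 0, px_per_mm > 0)
  # most-square exact factorization h x w = n with h <= w
  near_square <- function(n) {
    h <- max(which(n %% seq_len(floor(sqrt(n))) == 0))
    c(h, n %/% h)
  }
  if (hole_px > 0) {
    hdim <- near_square(hole_px)
    odim <- near_square(filled_px)
    if (odim[1] < hdim[1] + 4 || odim[2] < hdim[2] + 4)
      stop("`filled_px` cannot enclose `hole_px` with a black border; ",
           "choose counts whose near-square factorizations nest")
  } else {
    hdim <- c(0L, 0L)
    odim <- near_square(filled_px)
  }
  img <- matrix(1, odim[1] + 2 * pad, odim[2] + 2 * pad)
  r0 <- pad + 1; c0 <- pad + 1
  img[r0:(r0 + odim[1] - 1), c0:(c0 + odim[2] - 1)] <- 0
  if (hole_px > 0) {
    hr <- r0 + 2; hc <- c0 + 2
    img[hr:(hr + hdim[1] - 1), hc:(hc + hdim[2] - 1)] <- 1
  }
  list(image = img, px_per_mm = px_per_mm,
       filled_px = filled_px, hole_px = hole_px,
       black_px = filled_px - hole_px)
}
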