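# Independent oracles and small fixture builders shared across tests.

# Hand-built read-count object from explicit matrices.
make_rcm <- function(ref, alt, pop) read_counts(ref, alt, pop)

# Brute-force one-way ANOVA by explicit two-loop sums of squares.
brute_anova_F <- function(values, groups) {
  gl <- unique(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in gl) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    for (x in v) ssw <- ssw + (x - mean(v))^2
  }
  dfb <- length(gl) - 1
  dfw <- length(values) - length(gl)
  list(F = (ssb / dfb) / (ssw / dfw), ssb = ssb, ssw = ssw,
       msw = ssw / dfw, dfb = dfb, dfw = dfw)
}

# Direct Fisher discriminant direction W^{-1}(m1 - m2) on full-rank data.
fisher_direction <- function(x, groups) {
  gl <- unique(groups)
  stopifnot(length(gl) == 2)
  x1 <- x[groups == gl[1], , drop = FALSE]
  x2 <- x[groups == gl[2], , drop = FALSE]
  W <- (crossprod(scale(x1, scale = FALSE)) +
          crossprod(scale(x2, scale = FALSE))) / (nrow(x) - 2)
  solve(W, colMeans(x1) - colMeans(x2))
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Apply a random rigid motion per specimen plus one global scale to a
# landmark set (digitization-style nuisance transforms; reflections and
# per-specimen scale excluded deliberately).
apply_similarity <- function(lms, global_scale = 1, seed = 1) {
  set.seed(seed)
  out <- lms
  for (i in seq_len(dim(lms$coords)[3])) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    out$coords[, , i] <- lms$coords[, , i] %*% R * global_scale +
      matrix(runif(2, -30, 30), 12, 2, byrow = TRUE)
  }
  out
}

flatten_shapes <- function(aligned) {
  n <- dim(aligned$coords)[3]
  t(vapply(seq_len(n), function(i) as.vector(aligned$coords[, , i]),
           numeric(24)))
}

# Multi-locus Nei G_ST from a genotype matrix's realized sample frequencies.
sample_gst <- function(genotypes, pop) {
  pops <- unique(pop)
  p1 <- colMeans(genotypes[pop == pops[1], , drop = FALSE]) / 2
  p2 <- colMeans(genotypes[pop == pops[2], , drop = FALSE]) / 2
  gst_pair(p1, p2)
}

# Optimal rotation angle taking centered config b onto centered config a.
align_angle <- function(b, a) {
  zb <- complex(real = b[, 1], imaginary = b[, 2])
  za <- complex(real = a[, 1], imaginary = a[, 2])
  Arg(sum(Conj(zb) * za))
}

# Express a truth vector (12 x 2, in the generator's base frame) in the
# aligned mean-shape frame and project out similarity components there.
truth_in_aligned_frame <- function(v, base, mean_shape) {
  bu <- scale(base, scale = FALSE)
  bu <- bu / sqrt(sum(bu^2))
  th <- align_angle(bu, mean_shape)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  vr <- matrix(v, 12, 2) %*% R
  m <- mean_shape
  u1 <- as.vector(m) / sqrt(sum(m^2))
  rot <- cbind(-m[, 2], m[, 1])
  u2 <- as.vector(rot) / sqrt(sum(rot^2))
  u3 <- rep(c(1, 0), each = 12) / sqrt(12)
  u4 <- rep(c(0, 1), each = 12) / sqrt(12)
  out <- as.vector(vr)
  for (u in list(u1, u2, u3, u4)) out <- out - sum(out * u) * u
  out
}

# A genuine (non-rigid) localized shape deformation of the given norm:
# spreads the anterior landmarks apart and pulls a posterior one inward.
shape_effect <- function(norm) {
  eff <- matrix(0, 12, 2)
  eff[3, 2] <- 1; eff[5, 2] <- 0.6; eff[9, 1] <- -0.8; eff[11, 2] <- -0.5
  eff / sqrt(sum(eff^2)) * norm
}
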