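#' Resolve a pipeline configuration
#'
#' Fills defaults for every tunable the pipeline exposes and, when
#' `full_scale` is set, switches the samplers to the full-scale settings
#' conventional for these model families (allele-frequency MCMC
#' 100,000/10,000; admixture MCMC 100,000/50,000). A configuration is a
#' plain named list and can be read from YAML with [read_config()].
#'
#' @param config named list (possibly partial) of settings; see Details.
#' @details Recognized blocks (all optional): `seed`; `full_scale`;
#'   `synthetic` (list with `genetics`, `landmarks`, `melanization`
#'   generator settings); `inputs` (paths: `read_counts_tsv`, `vcf`,
#'   `landmarks_csv`, `landmarks_tps`, `melanization_csv`); `filter`
#'   (arguments of [filter_spec()]); `err`; `freq_mcmc`
#'   (steps/burnin/thin); `admixture` (k_range, replicates, steps, burnin,
#'   thin, alpha); `nmds` (dims, restarts); `morpho` (tangent,
#'   permutations); `melanization` (threshold); `out_dir`.
#' @return the completed configuration (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  dflt <- list(
    seed = 1L,
    full_scale = FALSE,
    synthetic = NULL,
    inputs = list(),
    filter = list(),
    err = 0.005,
    freq_mcmc = list(steps = 2000, burnin = 500, thin = 5),
    admixture = list(k_range = 1:4, replicates = 3, steps = 1000,
                     burnin = 300, thin = 5, alpha = 1.0),
    nmds = list(dims = 3, restarts = 8),
    morpho = list(tangent = TRUE, permutations = 999),
    melanization = list(threshold = "isodata"),
    out_dir = "popwing_results")
  cfg <- utils::modifyList(dflt, config)
  if (isTRUE(cfg$full_scale)) {
    cfg$freq_mcmc$steps <- 100000
    cfg$freq_mcmc$burnin <- 10000
    cfg$admixture$steps <- 100000
    cfg$admixture$burnin <- 50000
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Load the pipeline inputs named in a configuration
#'
#' Reads whichever inputs the config declares (read counts from TSV or
#' VCF, landmarks from CSV or TPS, melanization table from CSV) or
#' generates them from the `synthetic` block. Malformed records abort with
#' the file and rule violated.
#'
#' @param config a [pipeline_config()].
#' @return list with any of `rcm`, `landmarks`, `melanization`, `truth`.
#' @export
load_inputs <- function(config) {
  config <- pipeline_config(unclass(config))
  out <- list(truth = list())
  inp <- config$inputs
  if (!is.null(inp$read_counts_tsv)) out$rcm <- read_read_counts_tsv(inp$read_counts_tsv)
  if (is.null(out$rcm) && !is.null(inp$vcf)) out$rcm <- read_read_counts_vcf(inp$vcf)
  if (!is.null(inp$landmarks_csv)) out$landmarks <- read_landmarks_csv(inp$landmarks_csv)
  if (is.null(out$landmarks) && !is.null(inp$landmarks_tps))
    out$landmarks <- read_landmarks_tps(inp$landmarks_tps)
  if (!is.null(inp$melanization_csv))
    out$melanization <- read_melanization_csv(inp$melanization_csv)
  syn <- config$synthetic
  if (!is.null(syn)) {
    seeds <- derive_seeds(config$seed, 4)
    if (is.null(out$rcm) && !is.null(syn$genetics)) {
      gs <- syn$genetics
      fr <- sim_pop_frequencies(gs$loci %||% 500,
                                gs$populations %||% c("early", "late"),
                                F = gs$F %||% 0.1,
                                seed = seeds[1])
      sim <- sim_read_counts(fr, n_per_pop = gs$n_per_pop %||% 15,
                             coverage = gs$coverage %||% 8,
                             err = gs$err %||% config$err,
                             missing_rate = gs$missing_rate %||% 0.02,
                             seed = seeds[2])
      out$rcm <- sim$rcm
      out$truth$genetics <- sim$truth
    }
    if (is.null(out$landmarks) && !is.null(syn$landmarks)) {
      ls_ <- syn$landmarks
      grp <- unlist(ls_$groups %||% c(early = 20, late = 20))
      eff <- ls_$effect_size %||% 0.02
      effects <- ls_$shape_effects
      if (is.null(effects)) {
        dir <- matrix(rep(c(1, -1), 12), 12, 2)
        dir <- dir / sqrt(sum(dir^2))
        effects <- setNames(lapply(seq_along(grp), function(i)
          dir * eff * (if (i %% 2) 1 else -1)), names(grp))
      }
      out$landmarks <- sim_landmarks(grp, shape_effects = effects,
                                     allometric_vector =
                                       ls_$allometric_vector,
                                     noise_sd = ls_$noise_sd %||% 0.01,
                                     seed = seeds[3])
      out$truth$landmarks <- out$landmarks$truth
    }
    if (is.null(out$melanization) && !is.null(syn$melanization)) {
      ms <- syn$melanization
      out$melanization <- sim_melanization(
        unlist(ms$groups %||% c(early = 25, late = 25)),
        slope = ms$slope %||% 0.2,
        group_offsets = ms$group_offsets %||% list(early = 8, late = -8),
        noise_sd = ms$noise_sd %||% 3, seed = seeds[4])
      out$truth$melanization <- attr(out$melanization, "truth")
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic fan-out of one master seed into per-stage seeds.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^31 - 2, n)
}

#' Run the full two-arm pipeline
#'
#' Genetic arm: filter -> allele-frequency Gibbs -> genotype PCA, pairwise
#' G_ST with credible intervals -> NMDS, diversity estimates;
#' pseudo-haploid sampling -> admixture over a K range -> Evanno delta-K.
#' Phenotypic arm: generalized Procrustes -> allometry correction ->
#' shape PCA with per-PC ANOVA/Tukey, CVA, Procrustes distances, mean
#' ellipses; melanization -> size-corrected residuals -> ANOVA/Tukey.
#' Either arm runs independently when only its inputs are present. All
#' randomness fans out deterministically from `config$seed`.
#'
#' @param config a [pipeline_config()] (or partial list).
#' @return a `run_report`: list of result tables plus `provenance`
#'   (config, seeds) and `warnings`.
#' @export
run_full_pipeline <- function(config = list()) {
  config <- pipeline_config(unclass(config))
  inputs <- load_inputs(config)
  seeds <- derive_seeds(config$seed, 10)
  report <- list(tables = list(), provenance = list(config = unclass(config),
                                                    stage_seeds = seeds),
                 warnings = character(0))
  note <- function(w) report$warnings <<- c(report$warnings, w)

  if (!is.null(inputs$rcm)) {
    flt <- filter_dataset(inputs$rcm, do.call(filter_spec, config$filter))
    if (identical(flt$status, "empty"))
      stop("stage filter: all sites removed")
    report$tables$filter_log <- flt$log
    rcm <- flt$rcm
    fm <- config$freq_mcmc
    gib <- gibbs_allele_frequency(rcm, err = config$err, steps = fm$steps,
                                  burnin = fm$burnin, thin = fm$thin,
                                  seed = seeds[1])
    pca <- genotype_pca(gib$gp)
    report$tables$genotype_pca_scores <- data.frame(
      ind = rownames(pca$scores), pop = rcm$pop,
      pca$scores[, seq_len(min(5, ncol(pca$scores))), drop = FALSE])
    report$tables$genotype_pca_variance <- data.frame(
      axis = seq_along(pca$variance_fraction),
      variance_fraction = pca$variance_fraction)
    if (length(unique(rcm$pop)) >= 2) {
      gst <- pairwise_gst(gib$afp)
      report$tables$gst_table2 <- format_gst_table(gst)
      report$tables$gst_long <- gst_long_table(gst)
      if (length(gst$populations) >= 3) {
        nm <- nmds_embed(gst$estimate, dims = min(config$nmds$dims,
                                                  length(gst$populations) - 1),
                         restarts = config$nmds$restarts, seed = seeds[2])
        report$tables$gst_nmds <- data.frame(pop = rownames(nm$scores),
                                             nm$scores,
                                             stress = nm$stress)
      }
    }
    report$tables$diversity <- diversity_estimates(rcm, err = config$err)
    phm <- pseudo_haploid_sample(rcm, seed = seeds[3])
    ad <- config$admixture
    scan <- admixture_k_scan(phm, k_range = ad$k_range,
                             replicates = ad$replicates, steps = ad$steps,
                             burnin = ad$burnin, thin = ad$thin,
                             alpha = ad$alpha, seed = seeds[4])
    report$tables$k_selection <- if (is.null(scan$delta_k)) scan$lnp else
      scan$delta_k
    best_k <- if (!is.null(scan$delta_k) &&
                  any(is.finite(scan$delta_k$delta_k)))
      scan$delta_k$K[which.max(scan$delta_k$delta_k)] else max(ad$k_range)
    q <- scan$Q_best[[as.character(best_k)]]
    report$tables$admixture_q <- data.frame(ind = rownames(q),
                                            pop = attr(phm, "pop"), q)
  }

  if (!is.null(inputs$landmarks)) {
    gpa <- generalized_procrustes(inputs$landmarks,
                                  tangent = isTRUE(config$morpho$tangent))
    if (!gpa$converged) note("GPA did not converge")
    resid <- allometry_correction(gpa)
    spca <- shape_pca(resid)
    report$tables$shape_pca_scores <- data.frame(
      specimen = rownames(spca$scores), group = resid$group,
      spca$scores[, seq_len(min(3, ncol(spca$scores))), drop = FALSE])
    report$tables$shape_pca_variance <- data.frame(
      axis = seq_along(spca$variance_fraction),
      variance_fraction = spca$variance_fraction,
      eigenvalue = spca$eigenvalues)
    report$tables$allometry <- data.frame(
      percent_predicted = resid$percent_predicted)
    pc_tests <- list()
    for (axis in seq_len(min(3, ncol(spca$scores)))) {
      an <- one_way_anova(spca$scores[, axis], resid$group)
      pc_tests[[axis]] <- data.frame(axis = axis, F = an$F,
                                     df_between = an$df_between,
                                     df_within = an$df_within, p = an$p)
      report$tables[[paste0("shape_pc", axis, "_tukey")]] <-
        tukey_hsd(spca$scores[, axis], resid$group)
    }
    report$tables$shape_pc_anova <- do.call(rbind, pc_tests)
    if (length(unique(resid$group)) >= 2) {
      cva <- canonical_variates(resid)
      report$tables$cva_scores <- data.frame(
        specimen = rownames(spca$scores), group = resid$group,
        cva$scores)
      report$tables$cva_summary <- data.frame(
        axis = seq_along(cva$eigenvalues), eigenvalue = cva$eigenvalues,
        percent_among_variance = cva$percent_among_variance)
      if (ncol(cva$scores) >= 2)
        report$tables$cva_ellipses <-
          group_ellipses(cva$scores[, 1:2], resid$group)
      pd <- procrustes_distances(gpa,
                                 permutations = config$morpho$permutations,
                                 seed = seeds[5])
      long <- list()
      gl <- rownames(pd$distance)
      for (a in seq_along(gl)[-length(gl)]) for (b in (a + 1):length(gl))
        long[[length(long) + 1]] <- data.frame(
          group1 = gl[a], group2 = gl[b],
          procrustes_distance = pd$distance[a, b], p = pd$p_value[a, b])
      report$tables$procrustes_distances <- do.call(rbind, long)
    }
  }

  if (!is.null(inputs$melanization)) {
    mr <- melanization_residuals(inputs$melanization)
    if (identical(mr$status, "undefined"))
      note("constant wing area: melanization size correction skipped")
    report$tables$melanization_regression <- data.frame(
      R = mr$R, p = mr$p_value, slope = mr$slope, intercept = mr$intercept)
    an <- one_way_anova(mr$records$residual_melanization, mr$records$group)
    report$tables$melanization_anova <- data.frame(
      F = an$F, df_between = an$df_between, df_within = an$df_within,
      p = an$p)
    report$tables$melanization_tukey <-
      tukey_hsd(mr$records$residual_melanization, mr$records$group)
    report$tables$melanization_group_means <- data.frame(
      group = names(an$group_means),
      mean_residual = as.vector(an$group_means))
  }

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report:", length(x$tables), "tables\n")
  cat(paste(" -", names(x$tables)), sep = "\n")
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  else cat("No warnings\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes every table as TSV under `dir` plus a human-readable
#' `summary.txt` naming each file, the producing configuration, and any
#' warnings ("no warnings" is stated explicitly). Writing is atomic per
#' file (write to a temporary name, then rename).
#'
#' @param report a `run_report` from [run_full_pipeline()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", dir, "'")
  files <- character(0)
  atomic_write <- function(fun, path) {
    tmp <- paste0(path, ".tmp")
    fun(tmp)
    file.rename(tmp, path)
    files <<- c(files, path)
  }
  for (nm in names(report$tables)) {
    tab <- report$tables[[nm]]
    path <- file.path(dir, paste0(nm, ".tsv"))
    atomic_write(function(p) write.table(tab, p, sep = "\t", quote = FALSE,
                                         row.names = is.matrix(tab)),
                 path)
  }
  sum_path <- file.path(dir, "summary.txt")
  atomic_write(function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines("popwing pipeline run", con)
    writeLines(paste0("seed: ", report$provenance$config$seed), con)
    writeLines(paste0("stage seeds: ",
                      paste(report$provenance$stage_seeds, collapse = " ")),
               con)
    writeLines("tables written:", con)
    writeLines(paste0("  ", names(report$tables), ".tsv"), con)
    if (length(report$warnings))
      writeLines(c("warnings:", paste0("  ", report$warnings)), con)
    else writeLines("no warnings", con)
  }, sum_path)
  invisible(files)
}
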