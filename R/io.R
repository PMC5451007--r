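#' Write and read a read-count matrix as long-format TSV
#'
#' Columns: locus_id, ind_id, pop, ref_count, alt_count (one row per
#' individual-locus cell).
#'
#' @param rcm a [read_counts()] object.
#' @param path output file.
#' @return `write_read_counts_tsv` returns `path` invisibly;
#'   `read_read_counts_tsv` returns a `read_counts` object.
#' @export
write_read_counts_tsv <- function(rcm, path) {
  stopifnot(inherits(rcm, "read_counts"))
  df <- data.frame(
    locus_id = rep(rcm$loci, each = length(rcm$ind)),
    ind_id = rep(rcm$ind, times = length(rcm$loci)),
    pop = rep(rcm$pop, times = length(rcm$loci)),
    ref_count = as.vector(rcm$ref),
    alt_count = as.vector(rcm$alt))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_counts_tsv
#' @export
read_read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "character",
                                  "integer", "integer"))
  need <- c("locus_id", "ind_id", "pop", "ref_count", "alt_count")
  if (!all(need %in% names(df)))
    stop("malformed read-count TSV '", path, "': expected columns ",
         paste(need, collapse = ", "))
  loci <- unique(df$locus_id); inds <- unique(df$ind_id)
  ref <- matrix(0L, length(inds), length(loci),
                dimnames = list(inds, loci))
  alt <- ref
  ref[cbind(df$ind_id, df$locus_id)] <- df$ref_count
  alt[cbind(df$ind_id, df$locus_id)] <- df$alt_count
  pop <- df$pop[match(inds, df$ind_id)]
  read_counts(ref, alt, pop)
}

#' Write a read-count matrix as a minimal VCF with per-sample AD
#'
#' Produces a VCFv4.2 file with one biallelic SNP record per locus and a
#' single `AD` FORMAT field carrying `ref,alt` depths per sample.
#' Population labels are written to a sidecar `<path>.popmap` tab file
#' (sample, pop) because VCF carries no population field.
#'
#' @param rcm a [read_counts()] object.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_read_counts_vcf <- function(rcm, path) {
  stopifnot(inherits(rcm, "read_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rcm$ind), collapse = "\t")), con)
  for (l in seq_along(rcm$loci)) {
    ad <- paste(rcm$ref[, l], rcm$alt[, l], sep = ",")
    writeLines(paste(c("1", l, rcm$loci[l], "A", "T", ".", "PASS", ".",
                       "AD", ad), collapse = "\t"), con)
  }
  write.table(data.frame(sample = rcm$ind, pop = rcm$pop),
              paste0(path, ".popmap"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF with AD fields into a read-count matrix
#'
#' Parses per-sample `AD` (allelic depth) fields of a biallelic VCF via the
#' vcfR package. Population labels come from `pop_map` (data.frame with
#' `sample` and `pop`, or a path to such a tab file; defaults to the
#' sidecar written by [write_read_counts_vcf()]).
#'
#' @param path VCF file.
#' @param pop_map population assignment (see above).
#' @return a [read_counts()] object.
#' @export
read_read_counts_vcf <- function(path, pop_map = paste0(path, ".popmap")) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || !nrow(ad)) stop("VCF '", path, "' carries no AD fields")
  ref <- vapply(seq_len(ncol(ad)), function(i)
    as.integer(vapply(strsplit(ad[, i], ","), `[`, character(1), 1)),
    integer(nrow(ad)))
  alt <- vapply(seq_len(ncol(ad)), function(i)
    as.integer(vapply(strsplit(ad[, i], ","), `[`, character(1), 2)),
    integer(nrow(ad)))
  ref <- t(matrix(ref, nrow(ad), ncol(ad)))
  alt <- t(matrix(alt, nrow(ad), ncol(ad)))
  rownames(ref) <- rownames(alt) <- colnames(ad)
  ids <- v@fix[, "ID"]
  colnames(ref) <- colnames(alt) <-
    ifelse(is.na(ids) | ids == ".", paste0("locus", seq_len(ncol(ref))), ids)
  if (is.character(pop_map))
    pop_map <- read.table(pop_map, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pop <- pop_map$pop[match(rownames(ref), pop_map$sample)]
  if (anyNA(pop)) stop("pop_map is missing samples: ",
                       paste(rownames(ref)[is.na(pop)], collapse = ", "))
  read_counts(ref, alt, pop)
}

#' Write and read landmark sets as CSV
#'
#' Wide CSV dialect: specimen, group, x1..x12, y1..y12.
#'
#' @param lms a `landmark_set`.
#' @param path file path.
#' @return the path (write) or a `landmark_set` (read).
#' @export
write_landmarks_csv <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  n <- dim(lms$coords)[3]
  xy <- t(vapply(seq_len(n),
                 function(i) c(lms$coords[, 1, i], lms$coords[, 2, i]),
                 numeric(24)))
  colnames(xy) <- c(paste0("x", 1:12), paste0("y", 1:12))
  df <- data.frame(specimen = lms$specimens, group = lms$group, xy)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("specimen", "group", paste0("x", 1:12), paste0("y", 1:12))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed landmark CSV '", path, "': missing ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(df)
  coords <- array(NA_real_, c(12, 2, n))
  for (i in seq_len(n)) {
    coords[, 1, i] <- as.numeric(df[i, paste0("x", 1:12)])
    coords[, 2, i] <- as.numeric(df[i, paste0("y", 1:12)])
  }
  if (any(!is.finite(coords))) {
    bad <- df$specimen[apply(coords, 3, function(m) any(!is.finite(m)))]
    stop("non-finite landmark coordinates for specimen(s): ",
         paste(bad, collapse = ", "))
  }
  landmark_set(coords, df$group, df$specimen)
}

#' Write and read landmark sets in TPS format
#'
#' Standard TPS records: `LM=12`, one "x y" line per landmark, `ID=` and
#' optional `SCALE=` lines. On reading, coordinates are multiplied by the
#' scale when present, and every record must carry exactly 12 landmarks.
#' Group labels are not part of TPS; they are taken from `groups` (by
#' specimen ID) or default to `"all"`.
#'
#' @param lms a `landmark_set`.
#' @param path file path.
#' @param groups named character: group per specimen ID (read only).
#' @param scale numeric SCALE to write (write only; omitted if `NULL`).
#' @return the path (write) or a `landmark_set` (read).
#' @export
write_landmarks_tps <- function(lms, path, scale = NULL) {
  stopifnot(inherits(lms, "landmark_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(lms$coords)[3])) {
    writeLines("LM=12", con)
    writeLines(paste(lms$coords[, 1, i], lms$coords[, 2, i]), con)
    if (!is.null(scale)) writeLines(paste0("SCALE=", scale), con)
    writeLines(paste0("ID=", lms$specimens[i]), con)
  }
  invisible(path)
}

#' @rdname write_landmarks_tps
#' @export
read_landmarks_tps <- function(path, groups = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines)
  if (!length(starts)) stop("no LM= records in TPS file '", path, "'")
  ends <- c(starts[-1] - 1, length(lines))
  specs <- list(); ids <- character(0); grp <- character(0)
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    nlm <- as.integer(sub("^LM=", "", block[1]))
    coord_lines <- block[seq_len(nlm) + 1]
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    id_line <- grep("^ID=", block, value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1]) else
      paste0("spec", r)
    if (nlm != 12 || nrow(xy) != 12 || any(!is.finite(xy)))
      stop("TPS record for specimen '", id, "' does not carry 12 landmarks")
    sc_line <- grep("^SCALE=", block, value = TRUE)
    if (length(sc_line)) xy <- xy * as.numeric(sub("^SCALE=", "", sc_line[1]))
    specs[[r]] <- xy
    ids <- c(ids, id)
  }
  coords <- array(NA_real_, c(12, 2, length(specs)))
  for (r in seq_along(specs)) coords[, , r] <- specs[[r]]
  grp <- if (is.null(groups)) rep("all", length(ids)) else
    unname(groups[ids])
  landmark_set(coords, grp, ids)
}

#' Read a melanization measurement CSV
#'
#' Expected columns: specimen, group, area_1, area_2, melanization_1,
#' melanization_2. Duplicate measurements are averaged into `wing_area`
#' and `total_melanization`.
#'
#' @param path CSV file.
#' @return data.frame ready for [melanization_residuals()].
#' @export
read_melanization_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("specimen", "group", "area_1", "area_2", "melanization_1",
            "melanization_2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed melanization CSV '", path, "': missing ",
         paste(missing_cols, collapse = ", "))
  df$wing_area <- (df$area_1 + df$area_2) / 2
  df$total_melanization <- (df$melanization_1 + df$melanization_2) / 2
  if (any(df$wing_area < 0) || any(df$total_melanization < 0))
    stop("negative areas in '", path, "'")
  df
}

#' Write a synthetic-truth ledger as JSON
#'
#' Persists the generating parameters of a simulation (seeds, F, slopes,
#' admixture proportions, ...) next to the simulated data so recovery
#' tests can find them.
#'
#' @param truth a list of generating parameters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  drop_big <- truth[!vapply(truth, function(x)
    is.matrix(x) && length(x) > 1e5, logical(1))]
  jsonlite::write_json(drop_big, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
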