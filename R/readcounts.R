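#' Read-count matrix container
#'
#' Holds per-individual, per-locus reference/alternate read counts with a
#' population label per individual. This is the raw input to all genetic
#' inference in the package.
#'
#' @param ref,alt integer matrices (individuals x loci) of reference and
#'   alternate read counts. Must share dimensions; row names are individual
#'   identifiers, column names locus identifiers (defaults supplied when
#'   absent).
#' @param pop character or factor of population labels, one per individual.
#' @return An object of class `read_counts`: a list with elements `ref`,
#'   `alt`, `pop` (character), `ind`, `loci`.
#' @examples
#' rc <- read_counts(matrix(5L, 2, 3), matrix(2L, 2, 3), pop = c("A", "B"))
#' dim(rc$ref)
#' @export
read_counts <- function(ref, alt, pop) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!all(dim(ref) == dim(alt)))
    stop("`ref` and `alt` must have identical dimensions")
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  ref[is.na(ref)] <- 0L; alt[is.na(alt)] <- 0L
  pop <- as.character(pop)
  if (length(pop) != nrow(ref))
    stop("`pop` must have one label per individual (row of `ref`)")
  if (any(is.na(pop)) || any(!nzchar(pop)))
    stop("population labels must be non-empty")
  if (is.null(rownames(ref))) rownames(ref) <- paste0("ind", seq_len(nrow(ref)))
  if (is.null(colnames(ref))) colnames(ref) <- paste0("locus", seq_len(ncol(ref)))
  dimnames(alt) <- dimnames(ref)
  if (anyDuplicated(rownames(ref))) stop("individual identifiers must be unique")
  if (anyDuplicated(colnames(ref))) stop("locus identifiers must be unique")
  structure(list(ref = ref, alt = alt, pop = pop,
                 ind = rownames(ref), loci = colnames(ref)),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat("Read-count matrix:", length(x$ind), "individuals x",
      length(x$loci), "loci\n")
  tab <- table(x$pop)
  cat("Populations:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
  depth <- x$ref + x$alt
  cat(sprintf("Mean depth %.2f; zero-depth cells %.1f%%\n",
              mean(depth), 100 * mean(depth == 0)))
  invisible(x)
}

#' @export
dim.read_counts <- function(x) c(length(x$ind), length(x$loci))

# Subset a read_counts object by individual/locus index, keeping labels.
subset_read_counts <- function(rcm, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_along(rcm$ind)
  if (is.null(loci)) loci <- seq_along(rcm$loci)
  read_counts(rcm$ref[ind, loci, drop = FALSE],
              rcm$alt[ind, loci, drop = FALSE],
              rcm$pop[ind])
}
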