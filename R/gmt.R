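#' Gene-set collections and the GMT format
#'
#' A gene-set collection is a named list of character vectors of gene ids
#' with an optional per-set description, mirroring the tab-delimited GMT
#' format used by curated collections such as Gene Ontology Biological
#' Processes: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param sets named list of character vectors (gene ids). Names must be
#'   unique; members must be nonempty unless the collection itself is empty.
#' @param descriptions optional character vector parallel to `sets`;
#'   defaults to `""`.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L) {
    out <- structure(list(sets = setNames(list(), character()),
                          descriptions = setNames(character(), character())),
                     class = "gene_set_collection")
    return(out)
  }
  nm <- names(sets)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop_fustx("all gene sets must be named")
  }
  if (anyDuplicated(nm)) {
    stop_fustx("duplicate gene set names: ",
               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) stop_fustx("gene sets must be nonempty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets, descriptions = setNames(descriptions, nm)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d sets", length(x$sets)))
  if (length(x$sets)) {
    cat(sprintf("; sizes %d-%d", min(lengths(x$sets)), max(lengths(x$sets))))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    nm <- names(collection$sets)[i]
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop_fustx("malformed GMT line(s) with fewer than 3 fields: ",
               paste(which(bad), collapse = ", "))
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- setNames(lapply(fields, function(f) f[-(1:2)]), nms)
  gene_set_collection(sets, desc)
}

#' Generate a toy gene-set collection
#'
#' Draws `n_sets` sets of sizes uniform in `sizes` from a synthetic gene
#' universe, for exercising over-representation analysis without curated
#' collections.
#'
#' @param n_sets number of sets.
#' @param sizes length-2 integer range of set sizes (inclusive).
#' @param universe character vector of gene ids to draw members from;
#'   defaults to `gene0001...` with 5x the maximum set size.
#' @param seed integer seed.
#' @return a [gene_set_collection()].
#' @export
make_toy_gmt <- function(n_sets, sizes = c(10L, 200L), universe = NULL,
                         seed = 1L) {
  n_sets <- check_count(n_sets, "n_sets", lower = 0L)
  stopifnot(length(sizes) == 2L, sizes[1] >= 1L, sizes[2] >= sizes[1])
  if (is.null(universe)) {
    universe <- sprintf("gene%04d", seq_len(5L * sizes[2]))
  }
  if (sizes[2] > length(universe)) {
    stop_fustx("maximum set size exceeds universe size")
  }
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- sample(seq(sizes[1], sizes[2]), 1L)
    sample(universe, k)
  })
  names(sets) <- sprintf("toy_set_%03d", seq_len(n_sets))
  gene_set_collection(sets, rep("synthetic toy set", n_sets))
}
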