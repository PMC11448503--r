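#' Read a GMT gene-set collection
#'
#' Broad dialect: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate genes within a set are dropped keeping the
#' first occurrence; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: a tibble with columns `set`,
#'   `description` and a list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    rlang::abort("no gene sets: GMT file is empty.",
                 class = "anchortraj_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.",
                         short[1]),
                 class = "anchortraj_format_error")
  }
  sets <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(sets)) {
    rlang::abort(sprintf("duplicate gene-set name: %s",
                         sets[duplicated(sets)][1]),
                 class = "anchortraj_format_error")
  }
  gene_set_collection(
    set = sets,
    description = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)])))
}

#' Construct a gene-set collection
#'
#' @param set character vector of unique set names (or, if `genes` is
#'   missing, a named list of character vectors).
#' @param description per-set description strings (defaults to `"."`).
#' @param genes list of character vectors of member genes.
#' @return A `gene_set_collection` tibble.
#' @export
gene_set_collection <- function(set, description = NULL, genes = NULL) {
  if (is.null(genes) && is.list(set)) {
    genes <- unname(set)
    set <- names(set)
  }
  if (is.null(description)) description <- rep(".", length(set))
  if (!length(set)) {
    rlang::abort("a gene-set collection needs at least one set.",
                 class = "anchortraj_validation_error")
  }
  if (any(!nzchar(set))) {
    rlang::abort("empty gene-set name.", class = "anchortraj_validation_error")
  }
  if (anyDuplicated(set)) {
    rlang::abort("duplicate gene-set names.", class = "anchortraj_validation_error")
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  out <- tibble::tibble(set = as.character(set),
                        description = as.character(description),
                        genes = genes)
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- mapply(function(s, d, g) paste(c(s, d, g), collapse = "\t"),
                  collection$set, collection$description, collection$genes)
  writeLines(lines, path)
  invisible(path)
}

# Coerce any of: collection tibble, named list of gene vectors.
as_gene_set_list <- function(collection) {
  if (inherits(collection, "gene_set_collection")) {
    stats::setNames(collection$genes, collection$set)
  } else if (is.list(collection) && !is.null(names(collection))) {
    lapply(collection, as.character)
  } else {
    rlang::abort("expected a gene_set_collection or a named list of gene vectors.",
                 class = "anchortraj_validation_error")
  }
}
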