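#' Gene set collection
#'
#' A named list of gene-ID vectors with a parallel description vector, the
#' in-memory form of a GMT file.
#'
#' @param sets named list of character vectors (unique names, non-empty sets).
#' @param description optional per-set description (recycled if length 1).
#' @export
gene_set_collection <- function(sets, description = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  if (any(lengths(sets) == 0)) stop("empty gene set(s)")
  description <- rep_len(as.character(description), length(sets))
  names(description) <- names(sets)
  structure(lapply(sets, as.character), description = description,
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d..%d\n", length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name<TAB>description<TAB>member...`.
#' Malformed lines (fewer than three fields) raise an error naming the line.
#'
#' @param path file path.
#' @return [gene_set_collection()] for the reader; the writer returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line %d in %s: need name, description and >= 1 member",
                 bad[1], path))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, vapply(parts, `[[`, "", 2L))
}

#' @param x a `gene_set_collection` (or plain named list of gene vectors).
#' @rdname read_gmt
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "description")
  if (is.null(desc)) desc <- rep("", length(x))
  lines <- vapply(seq_along(x), function(i)
    paste(c(names(x)[i], desc[i], x[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to an expression universe
#'
#' Drops members outside `universe`, then drops sets whose remaining size
#' falls outside `[min_size, max_size]` (logged).
#'
#' @param sets a `gene_set_collection` or named list.
#' @param universe character vector of usable gene IDs.
#' @param min_size,max_size post-filter size bounds.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 5, max_size = 500) {
  filtered <- lapply(sets, intersect, universe)
  keep <- lengths(filtered) >= min_size & lengths(filtered) <= max_size
  if (!all(keep))
    message(sprintf("dropping %d gene set(s) outside size bounds [%d, %d]: %s",
                    sum(!keep), min_size, max_size,
                    paste(utils::head(names(filtered)[!keep], 5), collapse = ", ")))
  if (!any(keep)) stop("no gene sets left after universe/size filtering")
  desc <- attr(sets, "description")
  gene_set_collection(filtered[keep],
                      if (is.null(desc)) "" else desc[keep])
}
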