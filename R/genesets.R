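#' Gene-set collections
#'
#' A gene-set collection is a named list of character vectors (the member
#' ids), with a parallel \code{"description"} attribute holding one free
#' text field per set (typically the source resource, e.g. a pathway
#' database or GO BP). Constructed by [gene_set_collection()] or
#' [read_gmt()].
#'
#' @param sets Named list of character vectors; names are set names,
#'   vectors the member ids. Members must be non-empty and duplicate-free.
#' @param descriptions Character vector, one per set (recycled from ""
#'   when omitted).
#' @return A \code{gene_set_collection} object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) ||
      (length(sets) && (is.null(names(sets)) || any(names(sets) == ""))))
    stop("'sets' must be a fully named list", call. = FALSE)
  if (!length(sets) && is.null(names(sets))) names(sets) <- character(0)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         names(sets)[duplicated(names(sets))][1L], call. = FALSE)
  for (nm in names(sets)) {
    if (!length(sets[[nm]]))
      stop(sprintf("set '%s' has no members", nm), call. = FALSE)
    if (anyDuplicated(sets[[nm]]))
      stop(sprintf("set '%s' has duplicate members", nm), call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("one description per set required", call. = FALSE)
  structure(sets, description = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x)
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d (median %g)\n",
              length(x), if (length(x)) min(sz) else 0L,
              if (length(x)) max(sz) else 0L, stats::median(sz)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set format: each line is
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Members
#' repeated within a line are deduplicated with a warning.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]),
         call. = FALSE)
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate set name in GMT: ", nms[duplicated(nms)][1L],
         call. = FALSE)
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) {
    mem <- f[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning(sprintf("set '%s': duplicate members removed", f[[1L]]),
              call. = FALSE)
      mem <- unique(mem)
    }
    mem
  })
  names(members) <- nms
  gene_set_collection(members, desc)
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to an analysis universe and size range
#'
#' Each set is intersected with \code{universe}; sets whose effective size
#' falls outside \code{[min_size, max_size]} are dropped. Effective sizes
#' are recorded in the \code{"effective_size"} attribute.
#'
#' @param collection A [gene_set_collection].
#' @param universe Character vector of feature ids under analysis.
#' @param min_size,max_size Inclusive size bounds after intersection
#'   (defaults 15 and 500, the usual enrichment convention).
#' @return The filtered [gene_set_collection].
#' @export
size_filter <- function(collection, universe, min_size = 15L,
                        max_size = 500L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (min_size > max_size)
    stop("min_size must be <= max_size", call. = FALSE)
  trimmed <- lapply(unclass(collection), intersect, y = universe)
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  out <- gene_set_collection(trimmed[keep],
                             attr(collection, "description")[keep])
  attr(out, "effective_size") <- lengths(trimmed[keep])
  out
}
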