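#' Read a miRNA-target link table
#'
#' TSV with columns \code{mirna_id}, \code{gene_id}, \code{database},
#' \code{validated} (0/1). Each row records that one resource reports the
#' miRNA-gene interaction; the same pair may appear under several
#' databases.
#'
#' @param path Path to the TSV.
#' @return Data.frame of link records.
#' @export
read_target_links <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character")
  need <- c("mirna_id", "gene_id", "database", "validated")
  if (!all(need %in% colnames(tab)))
    stop("target link table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$validated <- as.integer(tab$validated) == 1L
  validate_target_links(tab)
}

validate_target_links <- function(links) {
  bad <- which(!nzchar(links$mirna_id) | !nzchar(links$gene_id) |
                 !nzchar(links$database) | is.na(links$validated))
  if (length(bad))
    stop("malformed link rows: ", paste(utils::head(bad, 10L),
                                        collapse = ", "), call. = FALSE)
  links
}

#' Write a miRNA-target link table
#' @param links Data.frame of link records.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_target_links <- function(links, path) {
  out <- links
  out$validated <- as.integer(out$validated)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse multi-database links into consensus targets
#'
#' Groups link records per (miRNA, gene) pair and counts the distinct
#' source databases (the pair's hit score; database names are compared
#' case-insensitively). A pair is kept when it is experimentally
#' validated in any source or reported by at least \code{hit_threshold}
#' distinct databases -- the "hit score" reliability rule that guards
#' against single-database false positives.
#'
#' @param links Data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{database}, \code{validated} (logical or 0/1).
#' @param hit_threshold Minimum distinct-database count for unvalidated
#'   pairs (default 5).
#' @return Data.frame with one row per pair: \code{mirna_id},
#'   \code{gene_id}, \code{hit_score}, \code{validated}, \code{kept}.
#'   Kept/dropped totals are attached as attribute \code{"counts"}.
#' @export
build_consensus <- function(links, hit_threshold = 5L) {
  hit_threshold <- check_count(hit_threshold, "hit_threshold")
  links$validated <- as.logical(links$validated)
  validate_target_links(links)
  if (!nrow(links)) {
    out <- data.frame(mirna_id = character(0), gene_id = character(0),
                      hit_score = integer(0), validated = logical(0),
                      kept = logical(0), stringsAsFactors = FALSE)
    attr(out, "counts") <- c(kept = 0L, dropped = 0L)
    return(out)
  }
  key <- paste(links$mirna_id, links$gene_id, sep = "\r")
  db <- tolower(links$database)
  hit <- tapply(db, key, function(d) length(unique(d)))
  val <- tapply(links$validated, key, any)
  keys <- names(hit)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[[`, character(1), 1L),
    gene_id = vapply(parts, `[[`, character(1), 2L),
    hit_score = as.integer(hit),
    validated = as.logical(val[keys]),
    stringsAsFactors = FALSE)
  out$kept <- out$validated | out$hit_score >= hit_threshold
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(kept = sum(out$kept),
                           dropped = sum(!out$kept))
  out
}

#' Turn kept consensus targets into gene-set collections
#'
#' Either one set per miRNA (members = its kept target genes) or one set
#' per gene (members = the miRNAs targeting it), optionally restricted to
#' a feature universe such as the differentially expressed ids. Empty
#' sets are dropped.
#'
#' @param consensus Output of [build_consensus()].
#' @param orientation \code{"mirna_to_genes"} or \code{"gene_to_mirnas"}.
#' @param restrict_to Optional character vector to intersect members
#'   with.
#' @return A [gene_set_collection].
#' @export
target_sets <- function(consensus,
                        orientation = c("mirna_to_genes",
                                        "gene_to_mirnas"),
                        restrict_to = NULL) {
  orientation <- match.arg(orientation)
  kept <- consensus[consensus$kept, , drop = FALSE]
  if (orientation == "mirna_to_genes") {
    keys <- kept$mirna_id; vals <- kept$gene_id
  } else {
    keys <- kept$gene_id; vals <- kept$mirna_id
  }
  sets <- split(vals, keys)
  sets <- lapply(sets, unique)
  if (!is.null(restrict_to))
    sets <- lapply(sets, intersect, y = restrict_to)
  sets <- sets[lengths(sets) > 0L]
  gene_set_collection(sets,
                      rep(paste0("consensus targets (", orientation, ")"),
                          length(sets)))
}

#' Write a consensus target table as TSV
#' @param consensus Output of [build_consensus()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_consensus <- function(consensus, path) {
  out <- consensus
  out$validated <- as.integer(out$validated)
  out$kept <- as.integer(out$kept)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
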