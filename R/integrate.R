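#' Couple differentially expressed miRNAs and mRNAs through target sets
#'
#' Runs pre-ranked weighted-KS enrichment between the two DE arms using
#' the kept consensus miRNA-target links as gene sets. Two constructions
#' are supported:
#' \describe{
#'   \item{mirna_ranked (default)}{The ranked list is the DE miRNAs by
#'     signed fold change; each DE mRNA contributes a set of the miRNAs
#'     targeting it. An mRNA is "enriched" when its set passes the
#'     nominal-p and FDR-q thresholds jointly, and the miRNAs associated
#'     with it are that set's leading edge.}
#'   \item{mrna_ranked}{The ranked list is the DE mRNAs; each DE miRNA
#'     contributes its target-gene set, enriched miRNAs are those whose
#'     set passes, and the associated genes are the leading edge.}
#' }
#' The up- and down-regulated halves of the set-forming arm are analyzed
#' in separate runs and the results merged, so enrichment toward either
#' end of the ranking is assessed within each expression-direction
#' stream.
#'
#' @param mirna_de miRNA [de_table] with \code{direction} set (raw-p
#'   filter convention).
#' @param mrna_de mRNA [de_table] with \code{direction} set (BH filter
#'   convention).
#' @param consensus Output of [build_consensus()].
#' @param cfg An [enrich_config()]; \code{min_size} defaults here to 3
#'   because miRNA regulons restricted to DE features are small.
#' @param direction \code{"mirna_ranked"} or \code{"mrna_ranked"}.
#' @return List of class \code{integration_result}:
#'   \code{associations} (data.frame \code{set_feature},
#'   \code{set_feature_fc}, \code{partner}, \code{partner_fc},
#'   \code{set_stream}, \code{p_nominal}, \code{fdr_q}),
#'   \code{enrichment} (the full per-set enrichment table),
#'   \code{enriched_mirnas_up/down} and \code{enriched_targets_up/down}
#'   (data.frames of ids with fold changes), and \code{direction}.
#' @export
integrate_enrichment <- function(mirna_de, mrna_de, consensus,
                                 cfg = enrich_config(min_size = 3L),
                                 direction = c("mirna_ranked",
                                               "mrna_ranked")) {
  direction <- match.arg(direction)
  mirna_sig <- mirna_de[mirna_de$direction != "ns", , drop = FALSE]
  mrna_sig <- mrna_de[mrna_de$direction != "ns", , drop = FALSE]
  if (!nrow(mirna_sig) || !nrow(mrna_sig))
    stop("no differentially expressed features in one of the arms",
         call. = FALSE)
  if (!any(consensus$kept)) {
    warning("no kept consensus links; empty integration result")
    return(empty_integration(direction))
  }
  if (direction == "mirna_ranked") {
    rl_tab <- mirna_sig; set_tab <- mrna_sig
    orientation <- "gene_to_mirnas"
  } else {
    rl_tab <- mrna_sig; set_tab <- mirna_sig
    orientation <- "mirna_to_genes"
  }
  rl <- ranked_list(rl_tab$feature_id, rl_tab$fc_signed)
  res_list <- list(); assoc <- list()
  for (stream in c("up", "down")) {
    ids <- set_tab$feature_id[set_tab$direction == stream]
    if (!length(ids)) next
    sets <- target_sets(consensus, orientation,
                        restrict_to = rl_tab$feature_id)
    sets <- unclass(sets)[names(sets) %in% ids]
    if (!length(sets)) next
    coll <- gene_set_collection(sets)
    res <- suppressWarnings(run_preranked(rl, coll, cfg))
    if (!nrow(res)) next
    res$set_stream <- stream
    res_list[[stream]] <- res
    sig <- res[res$significant, , drop = FALSE]
    if (nrow(sig)) {
      le <- strsplit(sig$leading_edge, ",", fixed = TRUE)
      assoc[[stream]] <- data.frame(
        set_feature = rep(sig$set_name, lengths(le)),
        partner = unlist(le, use.names = FALSE),
        set_stream = stream,
        p_nominal = rep(sig$p_nominal, lengths(le)),
        fdr_q = rep(sig$fdr_q, lengths(le)),
        stringsAsFactors = FALSE)
    }
  }
  enrichment <- do.call(rbind, res_list)
  associations <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(set_feature = character(0), partner = character(0),
               set_stream = character(0), p_nominal = numeric(0),
               fdr_q = numeric(0), stringsAsFactors = FALSE)
  rownames(associations) <- NULL
  fc_of <- function(tab) stats::setNames(tab$fc_signed, tab$feature_id)
  dir_of <- function(tab) stats::setNames(tab$direction, tab$feature_id)
  set_fc <- fc_of(set_tab); rl_fc <- fc_of(rl_tab)
  associations$set_feature_fc <- unname(set_fc[associations$set_feature])
  associations$partner_fc <- unname(rl_fc[associations$partner])
  if (direction == "mirna_ranked") {
    mirna_ids <- unique(associations$partner)
    gene_ids <- unique(associations$set_feature)
    mirna_fc <- rl_fc; gene_fc <- set_fc
    mirna_dir <- dir_of(rl_tab); gene_dir <- dir_of(set_tab)
  } else {
    mirna_ids <- unique(associations$set_feature)
    gene_ids <- unique(associations$partner)
    mirna_fc <- set_fc; gene_fc <- rl_fc
    mirna_dir <- dir_of(set_tab); gene_dir <- dir_of(rl_tab)
  }
  pick <- function(ids, fc, dirs, want) {
    ids <- ids[dirs[ids] == want]
    data.frame(feature_id = ids, fc_signed = unname(fc[ids]),
               stringsAsFactors = FALSE)
  }
  structure(list(
    associations = associations,
    enrichment = enrichment,
    enriched_mirnas_up = pick(mirna_ids, mirna_fc, mirna_dir, "up"),
    enriched_mirnas_down = pick(mirna_ids, mirna_fc, mirna_dir, "down"),
    enriched_targets_up = pick(gene_ids, gene_fc, gene_dir, "up"),
    enriched_targets_down = pick(gene_ids, gene_fc, gene_dir, "down"),
    direction = direction), class = "integration_result")
}

empty_integration <- function(direction) {
  empty_fc <- data.frame(feature_id = character(0),
                         fc_signed = numeric(0), stringsAsFactors = FALSE)
  structure(list(
    associations = data.frame(set_feature = character(0),
                              partner = character(0),
                              set_stream = character(0),
                              p_nominal = numeric(0), fdr_q = numeric(0),
                              set_feature_fc = numeric(0),
                              partner_fc = numeric(0),
                              stringsAsFactors = FALSE),
    enrichment = NULL,
    enriched_mirnas_up = empty_fc, enriched_mirnas_down = empty_fc,
    enriched_targets_up = empty_fc, enriched_targets_down = empty_fc,
    direction = direction), class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(paste0(
    "integration_result (%s): %d up / %d down enriched miRNAs, ",
    "%d up / %d down target genes, %d associations\n"),
    x$direction, nrow(x$enriched_mirnas_up),
    nrow(x$enriched_mirnas_down), nrow(x$enriched_targets_up),
    nrow(x$enriched_targets_down), nrow(x$associations)))
  invisible(x)
}

#' Write integration outputs as TSV
#'
#' Emits the long-format association table and a one-row summary; the
#' ranking direction is recorded in a header comment of both files.
#'
#' @param ir An [integrate_enrichment()] result.
#' @param assoc_path,summary_path Output paths.
#' @return Invisibly, \code{assoc_path}.
#' @export
write_integration <- function(ir, assoc_path, summary_path) {
  header <- paste0("# direction=", ir$direction)
  writeLines(c(header, paste(colnames(ir$associations), collapse = "\t")),
             assoc_path)
  if (nrow(ir$associations))
    utils::write.table(ir$associations, assoc_path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  summary <- data.frame(
    direction = ir$direction,
    mirnas_up = nrow(ir$enriched_mirnas_up),
    mirnas_down = nrow(ir$enriched_mirnas_down),
    targets_up = nrow(ir$enriched_targets_up),
    targets_down = nrow(ir$enriched_targets_down),
    associations = nrow(ir$associations))
  writeLines(header, summary_path)
  suppressWarnings(
    utils::write.table(summary, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(assoc_path)
}
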