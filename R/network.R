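#' Annotate enriched miRNAs with pathways through shared genes
#'
#' For every (miRNA, significant pathway) pair, computes the overlap
#' between the miRNA's enriched target genes (from the integration stage)
#' and the differentially expressed genes belonging to the pathway; a
#' record is emitted whenever the overlap is non-empty. These overlap
#' genes are what tie a differentially expressed miRNA to the pathways
#' and biological processes its targets act in.
#'
#' @param ir An [integrate_enrichment()] result.
#' @param pathway_results Enrichment table from [run_preranked()] on the
#'   mRNA ranking versus the pathway/GO collection; only rows with
#'   \code{significant == TRUE} are used.
#' @param mrna_de mRNA [de_table] with \code{direction} set.
#' @param sets The pathway [gene_set_collection] (same one used for
#'   \code{pathway_results}).
#' @param categories Optional named character vector mapping lower-case
#'   keywords to category labels; the first keyword found in a pathway
#'   name assigns its category (default [default_categories()]).
#' @return Data.frame with columns \code{mirna_id}, \code{pathway_name},
#'   \code{overlap_genes} (comma-joined), \code{n_overlap},
#'   \code{category}.
#' @export
annotate_mirnas <- function(ir, pathway_results, mrna_de, sets,
                            categories = default_categories()) {
  sig_paths <- pathway_results$set_name[pathway_results$significant]
  de_genes <- mrna_de$feature_id[mrna_de$direction != "ns"]
  targets_by_mirna <- mirna_target_map(ir)
  recs <- list()
  for (mir in names(targets_by_mirna)) {
    tg <- targets_by_mirna[[mir]]
    for (pw in sig_paths) {
      ov <- intersect(tg, intersect(sets[[pw]], de_genes))
      if (length(ov))
        recs[[length(recs) + 1L]] <- data.frame(
          mirna_id = mir, pathway_name = pw,
          overlap_genes = paste(sort(ov), collapse = ","),
          n_overlap = length(ov),
          category = categorize(pw, categories),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(mirna_id = character(0),
                      pathway_name = character(0),
                      overlap_genes = character(0),
                      n_overlap = integer(0), category = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# miRNA -> associated enriched target genes, from the association table
# regardless of which arm was ranked.
mirna_target_map <- function(ir) {
  a <- ir$associations
  if (!nrow(a)) return(list())
  if (ir$direction == "mirna_ranked")
    split(a$set_feature, a$partner)
  else
    split(a$partner, a$set_feature)
}

#' Default pathway category keywords
#'
#' User-editable keyword-to-category mapping used by [annotate_mirnas()];
#' the first keyword (case-insensitive substring) found in a pathway name
#' assigns the category, otherwise \code{"Other"}.
#'
#' @return Named character vector: names are keywords, values category
#'   labels.
#' @export
default_categories <- function() {
  c(apopto = "Apoptosis", prolifer = "Proliferation",
    "cell cycle" = "Proliferation", signal = "Signaling",
    chemotaxis = "Chemotaxis", cancer = "Cancer", motility = "Motility",
    cholesterol = "Cholesterol", sterol = "Cholesterol",
    migration = "Migration", differentiation = "Differentiation")
}

categorize <- function(name, categories) {
  lo <- tolower(name)
  for (kw in names(categories))
    if (grepl(kw, lo, fixed = TRUE)) return(unname(categories[[kw]]))
  "Other"
}

#' Build the fold-change-weighted miRNA-gene-pathway network
#'
#' Nodes are the enriched miRNAs, their associated genes and the
#' annotated pathways; edges are typed \code{targets} (miRNA to gene,
#' weighted by the miRNA's signed fold change) and \code{member_of}
#' (gene to pathway, weighted by the gene's signed fold change). Node
#' attributes carry the node type, fold change and direction.
#'
#' @param ir An [integrate_enrichment()] result.
#' @param annotations Output of [annotate_mirnas()] (may have zero rows).
#' @param mirna_de,mrna_de DE tables supplying fold changes.
#' @return An \code{igraph} directed graph.
#' @export
build_network <- function(ir, annotations, mirna_de, mrna_de) {
  tmap <- mirna_target_map(ir)
  mirnas <- names(tmap)
  genes <- unique(unlist(tmap, use.names = FALSE))
  pathways <- unique(annotations$pathway_name)
  fc <- c(stats::setNames(mirna_de$fc_signed, mirna_de$feature_id),
          stats::setNames(mrna_de$fc_signed, mrna_de$feature_id))
  missing <- setdiff(c(mirnas, genes), names(fc))
  if (length(missing))
    stop("no fold change recorded for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  edges <- character(0); etype <- character(0); ew <- numeric(0)
  for (mir in mirnas) for (g in tmap[[mir]]) {
    edges <- c(edges, mir, g)
    etype <- c(etype, "targets"); ew <- c(ew, unname(fc[mir]))
  }
  if (nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      ov <- strsplit(annotations$overlap_genes[i], ",", fixed = TRUE)[[1]]
      for (g in ov) {
        edges <- c(edges, g, annotations$pathway_name[i])
        etype <- c(etype, "member_of"); ew <- c(ew, unname(fc[g]))
      }
    }
  }
  nodes <- data.frame(
    name = c(mirnas, genes, pathways),
    type = c(rep("mirna", length(mirnas)), rep("gene", length(genes)),
             rep("pathway", length(pathways))),
    stringsAsFactors = FALSE)
  nodes$fc <- ifelse(nodes$type == "pathway", NA_real_,
                     unname(fc[nodes$name]))
  nodes$direction <- ifelse(is.na(nodes$fc), "",
                            ifelse(nodes$fc >= 0, "up", "down"))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, nrow(nodes), name = nodes$name,
                            type = nodes$type, fc = nodes$fc,
                            direction = nodes$direction)
  if (length(edges))
    g <- igraph::add_edges(g, edges, type = etype, weight = ew)
  g
}

#' Export a regulatory network for Cytoscape
#'
#' Formats: \code{sif} (one edge per line,
#' \code{source<TAB>relation<TAB>target}, with a companion
#' \code{<path>.attrs.tsv} edge-attribute table for the weights),
#' \code{graphml} (typed node/edge attributes embedded) and
#' \code{edge_tsv} (flat table that [import_network_tsv()] reads back).
#'
#' @param network An igraph network from [build_network()].
#' @param path Output file path.
#' @param format One of \code{"sif"}, \code{"graphml"},
#'   \code{"edge_tsv"}.
#' @return Invisibly, \code{path}.
#' @export
export_network <- function(network, path,
                           format = c("sif", "graphml", "edge_tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network format: ",
                                              format[1L], call. = FALSE))
  el <- edge_frame(network)
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", el$source, el$type, el$target), path)
    writeLines(c("edge\tweight",
                 sprintf("%s\t%s",
                         sprintf("%s (%s) %s", el$source, el$type,
                                 el$target),
                         format(el$weight, digits = 15L, trim = TRUE))),
               paste0(path, ".attrs.tsv"))
  } else if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    nt <- igraph::vertex_attr(network, "type")
    names(nt) <- igraph::V(network)$name
    fcv <- igraph::vertex_attr(network, "fc")
    names(fcv) <- igraph::V(network)$name
    out <- data.frame(source = el$source, edge_type = el$type,
                      target = el$target, weight = el$weight,
                      source_type = unname(nt[el$source]),
                      target_type = unname(nt[el$target]),
                      source_fc = unname(fcv[el$source]),
                      target_fc = unname(fcv[el$target]),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

edge_frame <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  data.frame(source = el[, 1L], target = el[, 2L],
             type = if (igraph::ecount(network))
               igraph::edge_attr(network, "type") else character(0),
             weight = if (igraph::ecount(network))
               igraph::edge_attr(network, "weight") else numeric(0),
             stringsAsFactors = FALSE)
}

#' Rebuild a network from an edge_tsv export
#' @param path Path written by [export_network()] with
#'   \code{format = "edge_tsv"}.
#' @return An igraph network isomorphic to the exported one.
#' @export
import_network_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  nodes <- unique(data.frame(
    name = c(tab$source, tab$target),
    type = c(tab$source_type, tab$target_type),
    fc = c(tab$source_fc, tab$target_fc), stringsAsFactors = FALSE))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, nrow(nodes), name = nodes$name,
                            type = nodes$type, fc = nodes$fc,
                            direction = ifelse(is.na(nodes$fc), "",
                                               ifelse(nodes$fc >= 0,
                                                      "up", "down")))
  if (nrow(tab))
    g <- igraph::add_edges(g, as.vector(rbind(tab$source, tab$target)),
                           type = tab$edge_type, weight = tab$weight)
  g
}
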