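#' Pipeline run configuration
#'
#' Collects the input paths and every threshold of the integrated flow:
#' normalization, both differential-expression arms, pathway enrichment,
#' consensus targets, miRNA-mRNA integration, annotation and network
#' export. Defaults are the customary analysis settings: linear fold
#' change 1.5, p 0.05 (BH-adjusted for the mRNA arm, raw for the miRNA
#' arm), enrichment significance at nominal p < 0.05 and FDR q <= 0.25,
#' consensus hit threshold 5.
#'
#' @param mrna_matrix,mrna_design,mirna_matrix,mirna_design,gene_sets,target_links
#'   Input file paths (TSV / GMT as produced by [write_simulation()] or
#'   equivalent).
#' @param outdir Output directory for all intermediates.
#' @param fc_threshold,p_threshold,q_threshold,hit_threshold Filter and
#'   significance parameters.
#' @param weight_exponent,n_permutations Enrichment-engine parameters.
#' @param pathway_min_size,pathway_max_size,target_min_size Set-size
#'   bounds for pathway enrichment and for the (much smaller) target
#'   sets.
#' @param normalize Apply quantile normalization before DE
#'   (default TRUE).
#' @param already_log Input matrices are already log2 (default TRUE).
#' @param integration_direction Which arm is ranked in the integration
#'   stage (see [integrate_enrichment()]).
#' @param seed Integer seed for all permutation streams.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(mrna_matrix, mrna_design, mirna_matrix,
                       mirna_design, gene_sets, target_links, outdir,
                       fc_threshold = 1.5, p_threshold = 0.05,
                       q_threshold = 0.25, hit_threshold = 5L,
                       weight_exponent = 1, n_permutations = 1000L,
                       pathway_min_size = 15L, pathway_max_size = 500L,
                       target_min_size = 3L, normalize = TRUE,
                       already_log = TRUE,
                       integration_direction = "mirna_ranked",
                       seed = 1L) {
  paths <- c(mrna_matrix = mrna_matrix, mrna_design = mrna_design,
             mirna_matrix = mirna_matrix, mirna_design = mirna_design,
             gene_sets = gene_sets, target_links = target_links)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", names(missing), missing),
               collapse = ", "), call. = FALSE)
  structure(list(paths = as.list(paths), outdir = outdir,
                 fc_threshold = check_positive(fc_threshold,
                                               "fc_threshold"),
                 p_threshold = check_fraction(p_threshold, "p_threshold"),
                 q_threshold = check_fraction(q_threshold, "q_threshold"),
                 hit_threshold = check_count(hit_threshold,
                                             "hit_threshold"),
                 weight_exponent = weight_exponent,
                 n_permutations = check_count(n_permutations,
                                              "n_permutations", 100L),
                 pathway_min_size = as.integer(pathway_min_size),
                 pathway_max_size = as.integer(pathway_max_size),
                 target_min_size = as.integer(target_min_size),
                 normalize = isTRUE(normalize),
                 already_log = isTRUE(already_log),
                 integration_direction = integration_direction,
                 seed = as.integer(seed)),
            class = "run_config")
}

log_msg <- function(con, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full integrated mRNA-miRNA analysis
#'
#' Executes normalize -> differential expression (moderated t for the
#' mRNA arm, plain t for the miRNA arm) -> pathway/GO enrichment on the
#' mRNA ranking -> consensus target building -> miRNA-mRNA enrichment
#' integration -> pathway annotation of enriched miRNAs -> network
#' construction and export. Every intermediate is written to
#' \code{cfg$outdir} along with a machine-readable \code{summary.json}
#' and a run log recording the configuration and seed. A stage failure
#' aborts with the stage name; outputs of completed stages are retained.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the summary list.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(cfg$outdir, f)
  logc <- file(fp("run.log"), open = "wt")
  on.exit(close(logc))
  cfg_out <- cfg; cfg_out$paths <- lapply(cfg$paths, normalizePath)
  yaml::write_yaml(c(unclass(cfg_out),
                     package_version =
                       as.character(utils::packageVersion("mimir"))),
                   fp("config.yaml"))
  stage <- function(name, expr) {
    log_msg(logc, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  mrna <- stage("load_mrna", {
    m <- read_expr_matrix(cfg$paths$mrna_matrix, cfg$paths$mrna_design,
                          log2_scale = cfg$already_log)
    m <- log2_transform(m, already_log = cfg$already_log)
    if (cfg$normalize) quantile_normalize(m) else m
  })
  mirna <- stage("load_mirna", {
    m <- read_expr_matrix(cfg$paths$mirna_matrix,
                          cfg$paths$mirna_design,
                          log2_scale = cfg$already_log)
    m <- log2_transform(m, already_log = cfg$already_log)
    if (cfg$normalize) quantile_normalize(m) else m
  })
  mrna_de <- stage("de_mrna", {
    t <- apply_de_filter(moderated_t_test(mrna), cfg$fc_threshold,
                         cfg$p_threshold, "adjusted")
    write_de_table(t, fp("mrna_de.tsv"))
    t
  })
  cnt <- attr(mrna_de, "counts")
  log_msg(logc, sprintf("mRNA DE: %d up, %d down", cnt["up"],
                        cnt["down"]))
  mirna_de <- stage("de_mirna", {
    t <- apply_de_filter(plain_t_test(mirna), cfg$fc_threshold,
                         cfg$p_threshold, "raw")
    write_de_table(t, fp("mirna_de.tsv"))
    t
  })
  cnt_mi <- attr(mirna_de, "counts")
  log_msg(logc, sprintf("miRNA DE: %d up, %d down", cnt_mi["up"],
                        cnt_mi["down"]))
  pathway_cfg <- enrich_config(
    weight_exponent = cfg$weight_exponent,
    n_permutations = cfg$n_permutations,
    min_size = cfg$pathway_min_size, max_size = cfg$pathway_max_size,
    seed = cfg$seed, p_threshold = cfg$p_threshold,
    q_threshold = cfg$q_threshold)
  pathways <- stage("pathway_enrichment", {
    coll <- read_gmt(cfg$paths$gene_sets)
    rl <- rank_by_fc(mrna_de)
    res <- run_preranked(rl, coll, pathway_cfg)
    utils::write.table(res, fp("pathway_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })
  log_msg(logc, sprintf("pathway enrichment: %d significant of %d sets",
                        sum(pathways$significant), nrow(pathways)))
  consensus <- stage("consensus_targets", {
    links <- read_target_links(cfg$paths$target_links)
    ct <- build_consensus(links, cfg$hit_threshold)
    write_consensus(ct, fp("consensus_targets.tsv"))
    ct
  })
  ccnt <- attr(consensus, "counts")
  log_msg(logc, sprintf("consensus targets: %d kept, %d dropped",
                        ccnt["kept"], ccnt["dropped"]))
  int_cfg <- enrich_config(
    weight_exponent = cfg$weight_exponent,
    n_permutations = cfg$n_permutations,
    min_size = cfg$target_min_size,
    max_size = cfg$pathway_max_size, seed = cfg$seed,
    p_threshold = cfg$p_threshold, q_threshold = cfg$q_threshold)
  ir <- stage("integration", {
    r <- integrate_enrichment(mirna_de, mrna_de, consensus, int_cfg,
                              cfg$integration_direction)
    write_integration(r, fp("integration_associations.tsv"),
                      fp("integration_summary.tsv"))
    r
  })
  log_msg(logc, sprintf(
    "integration: %d/%d up/down miRNAs, %d/%d up/down targets",
    nrow(ir$enriched_mirnas_up), nrow(ir$enriched_mirnas_down),
    nrow(ir$enriched_targets_up), nrow(ir$enriched_targets_down)))
  ann <- stage("annotation", {
    coll <- read_gmt(cfg$paths$gene_sets)
    a <- annotate_mirnas(ir, pathways, mrna_de, coll)
    utils::write.table(a, fp("mirna_annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    a
  })
  net <- stage("network", {
    g <- build_network(ir, ann, mirna_de, mrna_de)
    export_network(g, fp("network.sif"), "sif")
    export_network(g, fp("network.graphml"), "graphml")
    export_network(g, fp("network_edges.tsv"), "edge_tsv")
    g
  })
  summary <- list(
    mrna_up = unname(cnt["up"]), mrna_down = unname(cnt["down"]),
    mirna_up = unname(cnt_mi["up"]),
    mirna_down = unname(cnt_mi["down"]),
    pathways_tested = nrow(pathways),
    pathways_significant = sum(pathways$significant),
    consensus_kept = unname(ccnt["kept"]),
    consensus_dropped = unname(ccnt["dropped"]),
    enriched_mirnas_up = nrow(ir$enriched_mirnas_up),
    enriched_mirnas_down = nrow(ir$enriched_mirnas_down),
    enriched_targets_up = nrow(ir$enriched_targets_up),
    enriched_targets_down = nrow(ir$enriched_targets_down),
    annotation_records = nrow(ann),
    network_nodes = igraph::vcount(net),
    network_edges = igraph::ecount(net),
    seed = cfg$seed)
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  log_msg(logc, "done")
  invisible(summary)
}
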