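#' Simulation configuration
#'
#' Parameters of the synthetic two-group expression study the generator
#' emulates: a small-n microarray design (three control and three
#' treated samples by default), planted log2 fold changes on a fraction
#' of features in both the mRNA and miRNA arms, multi-database
#' miRNA-target links with overlap noise and a validated subset, and
#' gene sets with planted enrichment among the differentially expressed
#' genes.
#'
#' @param n_genes,n_mirnas Feature counts for the two arms.
#' @param n_per_group Samples per group (default 3, a typical triplicate
#'   array design).
#' @param frac_de Fraction of features with a planted effect.
#' @param effect_log2fc Mean absolute planted log2 fold change.
#' @param noise_sd Residual SD on the log2 scale.
#' @param n_sets Number of gene sets generated.
#' @param set_size_range Integer interval of set sizes.
#' @param frac_enriched_sets Fraction of sets composed preferentially
#'   from planted differentially expressed genes of one sign.
#' @param enriched_purity Sampling weight: fraction of an enriched set's
#'   members drawn from the planted genes of its sign (default 0.8).
#' @param n_databases Number of simulated target-prediction databases.
#' @param db_recall Probability a true miRNA-gene link is reported by
#'   any one database.
#' @param db_fpr Probability a false (miRNA, gene) pair is reported by a
#'   database.
#' @param frac_validated Fraction of true links flagged experimentally
#'   validated.
#' @param targets_per_mirna Mean number of true target genes per planted
#'   miRNA (default 40).
#' @param seed Integer root seed; every artifact derives its own
#'   sub-stream from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L, n_mirnas = 300L,
                       n_per_group = 3L, frac_de = 0.1,
                       effect_log2fc = 1.5, noise_sd = 0.5,
                       n_sets = 50L, set_size_range = c(15L, 100L),
                       frac_enriched_sets = 0.2, enriched_purity = 0.8,
                       n_databases = 8L, db_recall = 0.7,
                       db_fpr = 0.001, frac_validated = 0.1,
                       targets_per_mirna = 40L, seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_mirnas = check_count(n_mirnas, "n_mirnas"),
    n_per_group = check_count(n_per_group, "n_per_group", min = 2L),
    frac_de = check_fraction(frac_de, "frac_de"),
    effect_log2fc = check_positive(effect_log2fc, "effect_log2fc"),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    n_sets = check_count(n_sets, "n_sets"),
    set_size_range = c(check_count(set_size_range[1L], "set_size_range"),
                       check_count(set_size_range[2L], "set_size_range")),
    frac_enriched_sets = check_fraction(frac_enriched_sets,
                                        "frac_enriched_sets"),
    enriched_purity = check_fraction(enriched_purity, "enriched_purity"),
    n_databases = check_count(n_databases, "n_databases"),
    db_recall = check_fraction(db_recall, "db_recall"),
    db_fpr = check_fraction(db_fpr, "db_fpr"),
    frac_validated = check_fraction(frac_validated, "frac_validated"),
    targets_per_mirna = check_count(targets_per_mirna,
                                    "targets_per_mirna"),
    seed = check_count(seed, "seed", min = 0L))
  if (cfg$set_size_range[1L] > cfg$set_size_range[2L] ||
      cfg$set_size_range[2L] > cfg$n_genes)
    stop_config("set_size_range",
                "must be an increasing interval within [1, n_genes]")
  class(cfg) <- "sim_config"
  cfg
}

feature_ids <- function(kind, n) {
  sprintf(if (kind == "mrna") "GENE%04d" else "mir-%04d", seq_len(n))
}

#' Simulate a two-group expression matrix with planted effects
#'
#' Values are baseline + group effect + noise on the log2 scale: each
#' feature's baseline is drawn Normal(7, 2) (log2 of a plausible
#' microarray intensity range), a \code{frac_de} subset gets a planted
#' signed log2 fold change added to the treated group (signs split
#' 50/50, magnitudes Normal(\code{effect_log2fc}, 0.1·effect) truncated
#' positive), and Gaussian noise with SD \code{noise_sd} is added
#' everywhere. Planted log2 fold changes of non-DE features are exactly
#' zero in the returned ground truth.
#'
#' @param cfg A [sim_config()].
#' @param feature_kind \code{"mrna"} or \code{"mirna"}.
#' @return List with \code{matrix} (an [expr_matrix] on the log2 scale)
#'   and \code{truth} (data.frame \code{feature_id},
#'   \code{planted_log2fc} for every feature).
#' @export
simulate_expression <- function(cfg, feature_kind = c("mrna", "mirna")) {
  stopifnot(inherits(cfg, "sim_config"))
  feature_kind <- match.arg(feature_kind)
  n_feat <- if (feature_kind == "mrna") cfg$n_genes else cfg$n_mirnas
  ids <- feature_ids(feature_kind, n_feat)
  n <- cfg$n_per_group
  with_seed(substream_seed(cfg$seed, paste0("expr_", feature_kind)), {
    baseline <- stats::rnorm(n_feat, mean = 7, sd = 2)
    n_de <- round(cfg$frac_de * n_feat)
    de_idx <- if (n_de) sort(sample.int(n_feat, n_de)) else integer(0)
    planted <- numeric(n_feat)
    if (n_de) {
      mag <- abs(stats::rnorm(n_de, cfg$effect_log2fc,
                              0.1 * cfg$effect_log2fc))
      sgn <- rep_len(c(1, -1), n_de)[sample.int(n_de)]
      planted[de_idx] <- sgn * mag
    }
    vals <- matrix(stats::rnorm(n_feat * 2L * n, sd = cfg$noise_sd),
                   nrow = n_feat)
    vals <- vals + baseline
    vals[, (n + 1L):(2L * n)] <- vals[, (n + 1L):(2L * n)] + planted
  })
  dimnames(vals) <- list(ids, c(sprintf("ctrl_%d", seq_len(n)),
                                sprintf("trt_%d", seq_len(n))))
  grp <- rep(c("control", "treated"), each = n)
  truth <- data.frame(feature_id = ids, planted_log2fc = planted,
                      stringsAsFactors = FALSE)
  list(matrix = expr_matrix(vals, grp, log2_scale = TRUE), truth = truth)
}

#' Simulate a multi-database miRNA-target link table
#'
#' Every planted-DE miRNA receives a regulon of true target genes
#' (biased toward planted-DE genes of the opposite sign, the canonical
#' repression pattern). Each true link is then reported independently by
#' each of \code{n_databases} with probability \code{db_recall};
#' spurious links over non-true (miRNA, gene) pairs appear per database
#' with probability \code{db_fpr}; a \code{frac_validated} subset of the
#' true links is flagged experimentally validated (and then always
#' reported by at least one source).
#'
#' @param cfg A [sim_config()].
#' @param gene_truth,mirna_truth Ground-truth data.frames from
#'   [simulate_expression()] for the two arms.
#' @return List with \code{links} (the per-database link table) and
#'   \code{true_links} (data.frame \code{mirna_id}, \code{gene_id}).
#' @export
simulate_target_db <- function(cfg, gene_truth, mirna_truth) {
  stopifnot(inherits(cfg, "sim_config"))
  de_mir <- mirna_truth$feature_id[mirna_truth$planted_log2fc != 0]
  mir_sign <- sign(mirna_truth$planted_log2fc[
    mirna_truth$planted_log2fc != 0])
  genes <- gene_truth$feature_id
  with_seed(substream_seed(cfg$seed, "target_db"), {
    true_pairs <- list()
    for (k in seq_along(de_mir)) {
      opp <- gene_truth$feature_id[
        sign(gene_truth$planted_log2fc) == -mir_sign[k]]
      n_t <- min(cfg$targets_per_mirna, length(genes) - 1L)
      n_opp <- min(length(opp), round(0.7 * n_t))
      chosen <- c(sample(opp, n_opp),
                  sample(setdiff(genes, opp), n_t - n_opp))
      true_pairs[[k]] <- data.frame(mirna_id = de_mir[k],
                                    gene_id = chosen,
                                    stringsAsFactors = FALSE)
    }
    true_links <- if (length(true_pairs)) do.call(rbind, true_pairs) else
      data.frame(mirna_id = character(0), gene_id = character(0),
                 stringsAsFactors = FALSE)
    n_true <- nrow(true_links)
    validated <- rep(FALSE, n_true)
    if (n_true)
      validated[sample.int(n_true, round(cfg$frac_validated * n_true))] <-
        TRUE
    dbs <- sprintf("DB%02d", seq_len(cfg$n_databases))
    rows <- list()
    if (n_true) {
      present <- matrix(stats::runif(n_true * cfg$n_databases) <
                          cfg$db_recall, nrow = n_true)
      # validated links must surface somewhere: force one source if missed
      orphan <- validated & rowSums(present) == 0L
      if (any(orphan))
        present[cbind(which(orphan),
                      sample.int(cfg$n_databases, sum(orphan),
                                 replace = TRUE))] <- TRUE
      for (d in seq_len(cfg$n_databases)) {
        sel <- present[, d]
        if (any(sel))
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = true_links$mirna_id[sel],
            gene_id = true_links$gene_id[sel], database = dbs[d],
            validated = validated[sel], stringsAsFactors = FALSE)
      }
    }
    # spurious links: uniform over (mirna, gene) pairs not in truth
    if (cfg$db_fpr > 0) {
      all_mir <- mirna_truth$feature_id
      true_key <- paste(true_links$mirna_id, true_links$gene_id)
      for (d in seq_len(cfg$n_databases)) {
        n_pairs <- length(all_mir) * length(genes)
        n_fp <- stats::rbinom(1L, n_pairs - n_true, cfg$db_fpr)
        if (n_fp > 0) {
          idx <- sample.int(n_pairs, min(n_fp * 2L + 10L, n_pairs))
          mi <- all_mir[(idx - 1L) %% length(all_mir) + 1L]
          ge <- genes[(idx - 1L) %/% length(all_mir) + 1L]
          ok <- !(paste(mi, ge) %in% true_key)
          keep <- which(ok)[seq_len(min(n_fp, sum(ok)))]
          if (length(keep))
            rows[[length(rows) + 1L]] <- data.frame(
              mirna_id = mi[keep], gene_id = ge[keep], database = dbs[d],
              validated = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  })
  links <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               database = character(0), validated = logical(0),
               stringsAsFactors = FALSE)
  rownames(links) <- NULL
  list(links = links, true_links = true_links)
}

#' Simulate a gene-set collection with planted enrichment
#'
#' A \code{frac_enriched_sets} fraction of the sets draws
#' \code{enriched_purity} of its members from the planted differentially
#' expressed genes of one sign (alternating up/down across enriched
#' sets) and the rest uniformly; the remaining sets are sampled
#' uniformly from all genes. Set sizes are uniform on
#' \code{set_size_range}.
#'
#' @param cfg A [sim_config()].
#' @param gene_truth Ground truth from [simulate_expression()].
#' @return List with \code{collection} (a [gene_set_collection]) and
#'   \code{enriched_sets} (data.frame \code{set_name}, \code{sign}).
#' @export
simulate_gene_sets <- function(cfg, gene_truth) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_truth$feature_id
  up <- genes[gene_truth$planted_log2fc > 0]
  down <- genes[gene_truth$planted_log2fc < 0]
  n_enr <- round(cfg$frac_enriched_sets * cfg$n_sets)
  with_seed(substream_seed(cfg$seed, "gene_sets"), {
    sizes <- sample(seq(cfg$set_size_range[1L], cfg$set_size_range[2L]),
                    cfg$n_sets, replace = TRUE)
    sets <- vector("list", cfg$n_sets)
    signs <- character(cfg$n_sets)
    for (i in seq_len(cfg$n_sets)) {
      if (i <= n_enr) {
        pool <- if (i %% 2L == 1L) up else down
        signs[i] <- if (i %% 2L == 1L) "up" else "down"
        n_core <- min(length(pool), round(cfg$enriched_purity * sizes[i]))
        members <- c(sample(pool, n_core),
                     sample(setdiff(genes, pool), sizes[i] - n_core))
      } else {
        signs[i] <- "none"
        members <- sample(genes, sizes[i])
      }
      sets[[i]] <- sort(members)
    }
  })
  names(sets) <- sprintf("SET%03d", seq_len(cfg$n_sets))
  desc <- ifelse(signs == "none", "background",
                 paste0("planted_", signs))
  coll <- gene_set_collection(sets, desc)
  list(collection = coll,
       enriched_sets = data.frame(
         set_name = names(sets)[seq_len(n_enr)],
         sign = signs[seq_len(n_enr)], stringsAsFactors = FALSE))
}

#' Generate the complete synthetic study
#'
#' Runs all three generators under one root seed and returns every
#' artifact plus the ground truth; [write_simulation()] serializes them
#' in the package's interchange formats.
#'
#' @param cfg A [sim_config()].
#' @return List with \code{mrna}, \code{mirna} (each \code{$matrix},
#'   \code{$truth}), \code{targets} (\code{$links},
#'   \code{$true_links}), \code{gene_sets} (\code{$collection},
#'   \code{$enriched_sets}) and \code{cfg}.
#' @export
simulate_study <- function(cfg = sim_config()) {
  mrna <- simulate_expression(cfg, "mrna")
  mirna <- simulate_expression(cfg, "mirna")
  targets <- simulate_target_db(cfg, mrna$truth, mirna$truth)
  gs <- simulate_gene_sets(cfg, mrna$truth)
  list(mrna = mrna, mirna = mirna, targets = targets, gene_sets = gs,
       cfg = cfg)
}

#' Write all simulated artifacts to a directory
#'
#' Emits \code{mrna_matrix.tsv} / \code{mrna_design.tsv},
#' \code{mirna_matrix.tsv} / \code{mirna_design.tsv},
#' \code{gene_sets.gmt}, \code{target_links.tsv} and the ground-truth
#' tables (\code{truth_*.tsv}).
#'
#' @param study Output of [simulate_study()].
#' @param outdir Directory (created if needed).
#' @return Invisibly, \code{outdir}.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_expr_matrix(study$mrna$matrix, fp("mrna_matrix.tsv"),
                    fp("mrna_design.tsv"))
  write_expr_matrix(study$mirna$matrix, fp("mirna_matrix.tsv"),
                    fp("mirna_design.tsv"))
  write_gmt(study$gene_sets$collection, fp("gene_sets.gmt"))
  write_target_links(study$targets$links, fp("target_links.tsv"))
  utils::write.table(study$mrna$truth, fp("truth_mrna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$mirna$truth, fp("truth_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$targets$true_links, fp("truth_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$gene_sets$enriched_sets,
                     fp("truth_sets.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(outdir)
}
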