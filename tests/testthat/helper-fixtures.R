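# Shared fixture builders. Everything is generated in code; no stored data.

# Tiny two-group expression matrix with explicit values.
toy_matrix <- function(values, n_control, n_treated,
                       ids = sprintf("F%02d", seq_len(nrow(values)))) {
  values <- as.matrix(values)
  colnames(values) <- c(sprintf("c%d", seq_len(n_control)),
                        sprintf("t%d", seq_len(n_treated)))
  rownames(values) <- ids
  expr_matrix(values, rep(c("control", "treated"),
                          c(n_control, n_treated)))
}

# Random log2-scale matrix (continuous, so tie-free almost surely).
random_matrix <- function(n_feat, n_per_group, seed = 1, sd = 1,
                          delta = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(n_feat * 2 * n_per_group, mean = 7, sd = sd),
                 nrow = n_feat)
  if (!is.null(delta))
    vals[, (n_per_group + 1):(2 * n_per_group)] <-
      vals[, (n_per_group + 1):(2 * n_per_group)] + delta
  toy_matrix(vals, n_per_group, n_per_group)
}

# Independent brute-force running-sum ES, written directly from the
# definition (cumulative weighted hit mass minus cumulative miss count).
es_brute_force <- function(ids, scores, members, weight_exponent = 1) {
  N <- length(ids)
  hit <- ids %in% members
  w <- abs(scores)^weight_exponent
  NR <- sum(w[hit])
  if (NR == 0) { w <- rep(1, N); NR <- sum(hit) }
  run <- numeric(N)
  ph <- 0; pm <- 0
  for (i in seq_len(N)) {
    if (hit[i]) ph <- ph + w[i] / NR else pm <- pm + 1 / (N - sum(hit))
    run[i] <- ph - pm
  }
  run[which.max(abs(run))]
}

# Step-up BH written from its definition, independent of stats::p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Hand-built integration fixture: one up-regulated miRNA whose kept
# consensus regulon is a block of down-regulated genes, plus background
# miRNAs/genes with unstructured targets.
regulon_fixture <- function(seed, n_genes = 200, n_targets = 30,
                            n_mirnas = 20) {
  set.seed(seed)
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  fc_g <- c((2^runif(n_genes / 2, 0.7, 2)),
            -(2^runif(n_genes / 2, 0.7, 2)))
  names(fc_g) <- gene_ids
  mrna_de <- make_de_table(gene_ids, unname(fc_g),
                           p_raw = runif(n_genes, 0, 0.001))
  mrna_de <- apply_de_filter(mrna_de, 1.5, 0.05, "adjusted")
  mir_ids <- sprintf("mir-%02d", seq_len(n_mirnas))
  fc_m <- c(2.5, 2^runif(n_mirnas - 1, 0.7, 2) *
              sample(c(1, -1), n_mirnas - 1, TRUE))
  mirna_de <- make_de_table(mir_ids, fc_m,
                            p_raw = runif(n_mirnas, 0, 0.01))
  mirna_de <- apply_de_filter(mirna_de, 1.5, 0.05, "raw")
  down_genes <- gene_ids[fc_g < 0]
  targets <- sample(down_genes, n_targets)
  links <- data.frame(
    mirna_id = c(rep("mir-01", n_targets),
                 sample(mir_ids[-1], 60, TRUE)),
    gene_id = c(targets, sample(gene_ids, 60, TRUE)),
    database = "DBX", validated = TRUE, stringsAsFactors = FALSE)
  links <- links[!duplicated(paste(links$mirna_id, links$gene_id)), ]
  list(mrna_de = mrna_de, mirna_de = mirna_de,
       consensus = build_consensus(links, 5), targets = targets)
}

# Hand-built DE table for filter / integration tests.
make_de_table <- function(ids, fc_signed, p_raw = rep(0.01, length(ids)),
                          direction = NULL) {
  log2fc <- sign(fc_signed) * log2(abs(fc_signed))
  tab <- data.frame(feature_id = ids, log2fc = log2fc,
                    fc_signed = fc_signed, t_stat = NA_real_, df = 4,
                    p_raw = p_raw, p_adj = bh_adjust(p_raw),
                    direction = if (is.null(direction)) "ns" else
                      direction,
                    stringsAsFactors = FALSE)
  tab
}
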