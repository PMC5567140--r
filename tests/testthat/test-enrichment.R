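rl_fixture <- function(N = 10, seed = 1) {
  set.seed(seed)
  ranked_list(sprintf("g%02d", 1:N), sort(rnorm(N), decreasing = TRUE))
}

test_that("ranked lists sort by score with deterministic id tie-break", {
  rl <- ranked_list(c("b", "a", "c"), c(1, 1, 5))
  expect_identical(rl$id, c("c", "a", "b"))
  expect_error(ranked_list(c("a", "a"), c(1, 2)), "duplicate")
})

test_that("singleton sets at the extremes reach ES of +1 and -1", {
  rl <- rl_fixture(10)
  for (pw in c(0, 1, 2)) {
    expect_equal(enrichment_score(rl, rl$id[1], pw)$es, 1)
    expect_equal(enrichment_score(rl, rl$id[10], pw)$es, -1)
  }
})

test_that("ES equals a brute-force running-sum evaluation", {
  set.seed(2)
  for (rep in 1:25) {
    N <- sample(8:40, 1)
    rl <- rl_fixture(N, seed = rep + 100)
    members <- sample(rl$id, sample(1:(N - 1), 1))
    pw <- sample(c(0, 0.5, 1, 2), 1)
    res <- enrichment_score(rl, members, pw)
    expect_equal(res$es, es_brute_force(rl$id, rl$score, members, pw),
                 tolerance = 1e-12)
    # running sum starts/ends consistently and stays in [-1, 1]
    expect_equal(res$running_sum[N], 0, tolerance = 1e-12)
    expect_true(all(res$running_sum <= 1 + 1e-12 &
                      res$running_sum >= -1 - 1e-12))
  }
})

test_that("ES agrees with the fgsea implementation of the weighted KS
           statistic", {
  for (rep in 1:10) {
    rl <- rl_fixture(50, seed = rep)
    members <- sample(rl$id, 8)
    stats <- stats::setNames(rl$score, rl$id)
    ref <- fgsea::calcGseaStat(stats, which(rl$id %in% members),
                               gseaParam = 1)
    expect_equal(enrichment_score(rl, members, 1)$es, ref,
                 tolerance = 1e-12)
  }
})

test_that("with weight zero the statistic is the classical two-sample KS
           distance on ranks", {
  set.seed(3)
  for (rep in 1:10) {
    rl <- rl_fixture(30, seed = rep + 50)
    members <- sample(rl$id, sample(3:10, 1))
    es <- enrichment_score(rl, members, 0)$es
    pos <- which(rl$id %in% members)
    D <- suppressWarnings(
      unname(stats::ks.test(pos, setdiff(1:30, pos))$statistic))
    expect_equal(abs(es), D, tolerance = 1e-12)
  }
})

test_that("ES is invariant to uniform positive rescaling of scores", {
  rl <- rl_fixture(20, seed = 4)
  members <- rl$id[c(2, 5, 11)]
  for (pw in c(0.5, 1, 2)) {
    base <- enrichment_score(rl, members, pw)$es
    rl2 <- ranked_list(rl$id, rl$score * 37.5)
    expect_equal(enrichment_score(rl2, members, pw)$es, base,
                 tolerance = 1e-12)
  }
})

test_that("leading edge is the in-set prefix (positive ES) or suffix
           (negative ES)", {
  rl <- rl_fixture(12, seed = 5)
  members <- rl$id[c(1, 2, 11)]
  res <- enrichment_score(rl, members, 1)
  expect_gt(res$es, 0)
  i_star <- which.max(abs(res$running_sum))
  expect_identical(res$leading_edge,
                   intersect(rl$id[1:i_star], members))
  neg <- enrichment_score(rl, rl$id[c(10, 11, 12)], 1)
  expect_lt(neg$es, 0)
  expect_true(all(neg$leading_edge %in% rl$id[c(10, 11, 12)]))
})

test_that("degenerate sets are rejected", {
  rl <- rl_fixture(6)
  expect_error(enrichment_score(rl, rl$id, 1), "entire ranked list")
  expect_error(enrichment_score(rl, "absent", 1), "no members")
})

test_that("the fast null-ES path agrees with the full running sum", {
  set.seed(6)
  for (rep in 1:30) {
    N <- sample(10:60, 1)
    rl <- rl_fixture(N, seed = rep + 200)
    s <- sample(1:(N - 1), 1)
    pos <- sample.int(N, s)
    w <- abs(rl$score)^1
    fast <- mimir:::es_from_positions(pos, w, N)[1]
    full <- enrichment_score(rl, rl$id[pos], 1)$es
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible, finite at boundary sizes,
           and symmetric for unweighted constant scores", {
  rl <- rl_fixture(40, seed = 7)
  cfg <- enrich_config(n_permutations = 100, seed = 42)
  a <- permutation_null(rl, c(5, 39), cfg)
  b <- permutation_null(rl, c(5, 39), cfg)
  expect_identical(a, b)
  expect_true(all(is.finite(a[["39"]])))
  # exchangeable null with p_w = 0: ES symmetric about zero
  cfg0 <- enrich_config(weight_exponent = 0, n_permutations = 2000,
                        seed = 8)
  null0 <- permutation_null(rl, 10, cfg0)[["10"]]
  se <- sd(null0) / sqrt(length(null0))
  expect_lt(abs(mean(null0)), 3 * se)
})

test_that("NES, nominal p and FDR behave definitionally", {
  cfg <- enrich_config(n_permutations = 100, seed = 1)
  null <- list("5" = c(seq(0.1, 0.5, length.out = 50),
                       -seq(0.1, 0.5, length.out = 50)))
  obs <- data.frame(set_name = c("mean_pos", "big", "neg"),
                    size = c(5L, 5L, 5L),
                    es = c(0.3, 0.9, -0.3))
  out <- nes_and_fdr(obs, null, cfg)
  expect_equal(out$nes[1], 1)                  # ES at the null mean
  expect_equal(out$p_nominal[2], 1 / 101)      # beyond every null value
  expect_equal(out$nes[3], -1)
  expect_true(all(out$fdr_q >= 0 & out$fdr_q <= 1, na.rm = TRUE))
  expect_identical(sign(out$nes), sign(out$es))
})

test_that("nominal p-values are calibrated for null-generated sets", {
  # sets drawn at random from the ranked universe are true nulls
  ps <- unlist(lapply(1:5, function(s) {
    rl <- rl_fixture(200, seed = 300 + s)
    sets <- lapply(1:30, function(i) sample(rl$id, 20))
    names(sets) <- sprintf("N%02d", 1:30)
    coll <- gene_set_collection(sets)
    res <- run_preranked(rl, coll,
                         enrich_config(n_permutations = 500, seed = s,
                                       min_size = 5))
    res$p_nominal
  }))
  frac <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)
})

test_that("pre-ranked pipeline recovers a planted top-decile set and is
           order-invariant", {
  set.seed(9)
  hits <- 0L
  for (s in 1:20) {
    rl <- rl_fixture(300, seed = 400 + s)
    planted <- sample(rl$id[1:30], 15)      # all members in top decile
    sets <- c(list(PLANTED = planted),
              lapply(1:10, function(i) sample(rl$id, 15)))
    names(sets) <- c("PLANTED", sprintf("BG%02d", 1:10))
    coll <- gene_set_collection(sets)
    res <- run_preranked(rl, coll,
                         enrich_config(n_permutations = 200,
                                       seed = s, min_size = 5))
    row <- res[res$set_name == "PLANTED", ]
    if (row$significant && row$fdr_q <= 0.25) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # shuffling collection order changes nothing but row order
  rl <- rl_fixture(100, seed = 10)
  sets <- lapply(1:8, function(i) sample(rl$id, 10))
  names(sets) <- sprintf("S%d", 1:8)
  cfg <- enrich_config(n_permutations = 100, seed = 3, min_size = 5)
  r1 <- run_preranked(rl, gene_set_collection(sets), cfg)
  r2 <- run_preranked(rl, gene_set_collection(rev(sets)), cfg)
  r2 <- r2[match(r1$set_name, r2$set_name), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("an empty collection after filtering warns and returns an
           empty table", {
  rl <- rl_fixture(20)
  coll <- gene_set_collection(list(tiny = rl$id[1:2]))
  expect_warning(res <- run_preranked(rl, coll,
                                      enrich_config(min_size = 10)),
                 "no gene set survives")
  expect_equal(nrow(res), 0)
})
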