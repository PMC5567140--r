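#' Ranked feature list for pre-ranked enrichment
#'
#' Orders features by a signed score (descending); ties are broken by
#' feature id in lexicographic order so the ranking is deterministic.
#'
#' @param ids Character vector of unique feature ids.
#' @param scores Numeric scores aligned to \code{ids} (typically the
#'   signed linear fold change).
#' @return A \code{ranked_list}: data.frame with columns \code{id},
#'   \code{score}, ordered by decreasing score.
#' @export
ranked_list <- function(ids, scores) {
  if (anyDuplicated(ids)) stop("duplicate ids in ranked list",
                               call. = FALSE)
  if (length(ids) != length(scores) || length(ids) < 2L)
    stop("need >= 2 (id, score) pairs", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(-scores, ids, method = "radix")
  structure(data.frame(id = as.character(ids)[ord], score = scores[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Ranked list of differentially expressed features from a DE table
#'
#' @param tab A [de_table] (usually after [apply_de_filter()]).
#' @param de_only Keep only features with \code{direction != "ns"}.
#' @return A [ranked_list] scored by signed linear fold change.
#' @export
rank_by_fc <- function(tab, de_only = FALSE) {
  if (de_only) tab <- tab[tab$direction != "ns", , drop = FALSE]
  ranked_list(tab$feature_id, tab$fc_signed)
}

#' Enrichment configuration
#'
#' @param weight_exponent Exponent on |score| in the running-sum weights
#'   (0 = classical unweighted KS, 1 = standard weighted form; default 1).
#' @param n_permutations Number of permutations for the null (>= 100,
#'   default 1000).
#' @param min_size,max_size Gene-set size bounds after restriction to the
#'   ranked universe.
#' @param seed Integer seed for the permutation stream.
#' @param p_threshold,q_threshold Significance cutoffs: a set is called
#'   significant when nominal p < \code{p_threshold} and FDR q <=
#'   \code{q_threshold} (defaults 0.05 and 0.25).
#' @return A list of class \code{enrich_config}.
#' @export
enrich_config <- function(weight_exponent = 1, n_permutations = 1000L,
                          min_size = 15L, max_size = 500L, seed = 1L,
                          p_threshold = 0.05, q_threshold = 0.25) {
  if (weight_exponent < 0) stop_config("weight_exponent",
                                       "must be >= 0")
  n_permutations <- check_count(n_permutations, "n_permutations",
                                min = 100L)
  check_fraction(p_threshold, "p_threshold")
  check_fraction(q_threshold, "q_threshold")
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = n_permutations,
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 seed = as.integer(seed),
                 p_threshold = p_threshold, q_threshold = q_threshold),
            class = "enrich_config")
}

# ES from sorted hit positions only: the running sum is piecewise linear
# between hits, so its extrema lie at hit positions (just after the hit
# increment) or immediately before a hit. O(|set|) per evaluation; used
# for the permutation null. `w` is the |score|^p weight of every ranked
# item. Returns c(ES, extremum_position).
es_from_positions <- function(pos, w, N) {
  pos <- sort.int(pos)
  nh <- length(pos)
  wh <- w[pos]
  NR <- sum(wh)
  if (NR <= 0) { wh <- rep(1, nh); NR <- nh }  # all-zero scores: equal mass
  miss_unit <- 1 / (N - nh)
  cum_hit <- cumsum(wh) / NR
  j <- seq_len(nh)
  after <- cum_hit - (pos - j) * miss_unit
  before <- c(0, cum_hit[-nh]) - (pos - j) * miss_unit
  i_max <- which.max(after); i_min <- which.min(before)
  if (after[i_max] >= -before[i_min]) {
    if (after[i_max] <= 0) return(c(0, pos[1L]))
    c(after[i_max], pos[i_max])
  } else {
    c(before[i_min], pos[i_min] - 1L)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score of one set
#'
#' Walks the ranked list accumulating \eqn{P_{hit} - P_{miss}}: in-set
#' items contribute their \eqn{|score|^{p_w}} mass (normalized by the
#' total in-set mass), out-of-set items a uniform \eqn{1/(N - N_H)} step.
#' The enrichment score is the running-sum value of largest magnitude;
#' the leading edge is the in-set items at or before the extremum
#' (positive ES) or at or after it (negative ES).
#'
#' @param rl A [ranked_list].
#' @param members Character vector: the set's members.
#' @param weight_exponent The weight exponent \eqn{p_w} (default 1).
#' @return List with \code{es}, \code{running_sum} (length-N numeric),
#'   \code{leading_edge} (character), \code{size_used}.
#' @export
enrichment_score <- function(rl, members, weight_exponent = 1) {
  stopifnot(inherits(rl, "ranked_list"))
  N <- nrow(rl)
  hit <- rl$id %in% members
  nh <- sum(hit)
  if (nh == 0L)
    stop("set has no members in the ranked list", call. = FALSE)
  if (nh == N)
    stop("set covers the entire ranked list; miss probability undefined",
         call. = FALSE)
  w <- abs(rl$score)^weight_exponent
  wh <- ifelse(hit, w, 0)
  NR <- sum(wh)
  if (NR <= 0) { wh <- as.numeric(hit); NR <- nh }
  running <- cumsum(wh) / NR - cumsum(!hit) / (N - nh)
  i_star <- which.max(abs(running))
  es <- running[i_star]
  leading <- if (es >= 0) rl$id[hit & seq_len(N) <= i_star]
             else rl$id[hit & seq_len(N) >= i_star]
  list(es = es, running_sum = running, leading_edge = leading,
       size_used = nh)
}

#' Permutation null enrichment scores by set size
#'
#' For each distinct set size draws \code{n_permutations} random same-size
#' subsets of the ranked items (tag permutation, the null appropriate for
#' pre-ranked input) and records their enrichment scores. Null pools are
#' shared across all sets of a size.
#'
#' @param rl A [ranked_list].
#' @param sizes Integer vector of set sizes needed.
#' @param cfg An [enrich_config()] (supplies the permutation count, weight
#'   exponent and seed).
#' @return Named list mapping each size (as character) to a numeric vector
#'   of null ES values.
#' @export
permutation_null <- function(rl, sizes, cfg = enrich_config()) {
  stopifnot(inherits(rl, "ranked_list"))
  N <- nrow(rl)
  w <- abs(rl$score)^cfg$weight_exponent
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L | sizes >= N))
    stop("null sizes must lie in [1, N-1]", call. = FALSE)
  with_seed(substream_seed(cfg$seed, "permutation_null"), {
    out <- lapply(sizes, function(s) {
      vapply(seq_len(cfg$n_permutations), function(b) {
        es_from_positions(sample.int(N, s), w, N)[1L]
      }, numeric(1))
    })
  })
  names(out) <- as.character(sizes)
  out
}

# Same-sign normalization constant: mean of the positive (or negative)
# null ES for the size. Returns NA when the pool side is empty.
null_side_mean <- function(null_es, positive) {
  side <- if (positive) null_es[null_es > 0] else -null_es[null_es < 0]
  if (!length(side)) return(NA_real_)
  mean(side)
}

#' Normalized enrichment scores, nominal p and FDR q
#'
#' NES is the observed ES divided by the mean same-sign null ES of the
#' same set size. The nominal p-value is the same-sign tail proportion of
#' the size-matched null. The FDR q-value compares, at each observed NES,
#' the fraction of the pooled same-sign null NES at least as extreme with
#' the fraction of same-sign observed NES at least as extreme, clipped to
#' [0, 1] and made monotone within each sign. Nominal p-values of zero
#' are stored as \code{1/(B+1)} so downstream log transforms stay finite.
#'
#' @param observed Data.frame with columns \code{set_name}, \code{size},
#'   \code{es} (one row per set).
#' @param null Output of [permutation_null()] covering every observed
#'   size.
#' @param cfg An [enrich_config()].
#' @return The input with columns \code{nes}, \code{p_nominal},
#'   \code{fdr_q}, \code{significant} appended. Sets whose sign has no
#'   null mass get \code{NA} NES and are never flagged significant.
#' @export
nes_and_fdr <- function(observed, null, cfg = enrich_config()) {
  B <- cfg$n_permutations
  n_sets <- nrow(observed)
  nes <- p_nom <- rep(NA_real_, n_sets)
  for (i in seq_len(n_sets)) {
    es <- observed$es[i]
    pool <- null[[as.character(observed$size[i])]]
    if (is.null(pool))
      stop("no null samples for size ", observed$size[i], call. = FALSE)
    if (es == 0) { nes[i] <- 0; p_nom[i] <- 1; next }
    pos <- es > 0
    m <- null_side_mean(pool, pos)
    if (is.na(m)) next  # sign never arises under the null: flagged NA
    nes[i] <- if (pos) es / m else -(-es / m)
    side <- if (pos) pool[pool > 0] else pool[pool < 0]
    tail_n <- if (pos) sum(side >= es) else sum(side <= es)
    p_nom[i] <- tail_n / length(side)
    if (p_nom[i] == 0) p_nom[i] <- 1 / (B + 1)
  }
  # pooled null NES: each null ES normalized by its own size/sign mean
  null_nes <- unlist(lapply(names(null), function(s) {
    pool <- null[[s]]
    mp <- null_side_mean(pool, TRUE); mn <- null_side_mean(pool, FALSE)
    ifelse(pool > 0, pool / mp, ifelse(pool < 0, pool / mn, 0))
  }), use.names = FALSE)
  null_nes <- null_nes[is.finite(null_nes)]
  fdr <- rep(NA_real_, n_sets)
  for (sign_pos in c(TRUE, FALSE)) {
    idx <- which(!is.na(nes) & (if (sign_pos) nes > 0 else nes < 0))
    if (!length(idx)) next
    nn <- if (sign_pos) null_nes[null_nes > 0] else null_nes[null_nes < 0]
    oo <- nes[idx]
    q <- vapply(oo, function(v) {
      num <- if (!length(nn)) 0 else {
        if (sign_pos) mean(nn >= v) else mean(nn <= v)
      }
      den <- if (sign_pos) mean(oo >= v) else mean(oo <= v)
      min(1, num / den)
    }, numeric(1))
    # monotone within sign: a more extreme NES never has a larger q
    ord <- order(if (sign_pos) -oo else oo)
    q_sorted <- q[ord]
    q_sorted <- rev(cummin(rev(q_sorted)))
    q[ord] <- q_sorted
    fdr[idx] <- q
  }
  fdr[!is.na(nes) & nes == 0] <- 1
  observed$nes <- nes
  observed$p_nominal <- p_nom
  observed$fdr_q <- fdr
  observed$significant <- !is.na(nes) & !is.na(p_nom) & !is.na(fdr) &
    p_nom < cfg$p_threshold & fdr <= cfg$q_threshold
  observed
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Full pipeline for one ranked list and one collection: restrict sets to
#' the ranked universe and the configured size range, compute the weighted
#' KS enrichment score and leading edge per set, build a shared
#' size-stratified permutation null, derive NES, nominal p and FDR q, and
#' return the table sorted by decreasing NES.
#'
#' @param rl A [ranked_list].
#' @param collection A [gene_set_collection].
#' @param cfg An [enrich_config()].
#' @return Data.frame with columns \code{set_name}, \code{size},
#'   \code{es}, \code{nes}, \code{p_nominal}, \code{fdr_q},
#'   \code{significant}, \code{leading_edge} (comma-joined ids).
#' @export
run_preranked <- function(rl, collection, cfg = enrich_config()) {
  stopifnot(inherits(rl, "ranked_list"),
            inherits(collection, "gene_set_collection"))
  filt <- size_filter(collection, rl$id, cfg$min_size,
                      min(cfg$max_size, nrow(rl) - 1L))
  if (!length(filt)) {
    warning("no gene set survives universe/size filtering")
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_nominal = numeric(0), fdr_q = numeric(0),
                      significant = logical(0),
                      leading_edge = character(0),
                      stringsAsFactors = FALSE))
  }
  scores <- lapply(names(filt), function(nm)
    enrichment_score(rl, filt[[nm]], cfg$weight_exponent))
  observed <- data.frame(
    set_name = names(filt),
    size = vapply(scores, function(s) as.integer(s$size_used), integer(1)),
    es = vapply(scores, `[[`, numeric(1), "es"),
    stringsAsFactors = FALSE)
  null <- permutation_null(rl, observed$size, cfg)
  observed <- nes_and_fdr(observed, null, cfg)
  observed$leading_edge <- vapply(scores, function(s)
    paste(s$leading_edge, collapse = ","), character(1))
  observed[order(-observed$nes), , drop = FALSE]
}
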