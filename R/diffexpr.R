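#' Differential expression tables
#'
#' Both test functions return a \code{data.frame} (a "DE table") with one
#' row per feature and columns:
#' \describe{
#'   \item{feature_id}{feature identifier (row order of the input matrix)}
#'   \item{log2fc}{treated minus control mean, log2 units}
#'   \item{fc_signed}{signed linear fold change: \code{2^log2fc} for
#'     up-regulation, \code{-2^(-log2fc)} for down-regulation, so a
#'     doubling prints as +2 and a halving as -2}
#'   \item{t_stat}{(moderated) t statistic}
#'   \item{df}{degrees of freedom of the reference t distribution}
#'   \item{p_raw}{two-sided p-value}
#'   \item{p_adj}{Benjamini-Hochberg adjusted p-value}
#'   \item{direction}{\code{up}, \code{down} or \code{ns}; set by
#'     [apply_de_filter()], initialized to \code{ns}}
#' }
#'
#' @name de_table
NULL

signed_fc <- function(log2fc) ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))

group_stats <- function(m) {
  g <- m$group
  n1 <- sum(g == "control"); n2 <- sum(g == "treated")
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples for a variance estimate",
         call. = FALSE)
  x1 <- m$values[, g == "control", drop = FALSE]
  x2 <- m$values[, g == "treated", drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  ss <- rowSums((x1 - mu1)^2) + rowSums((x2 - mu2)^2)
  dg <- n1 + n2 - 2L
  list(log2fc = mu2 - mu1, s2 = ss / dg, dg = dg, n1 = n1, n2 = n2)
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to moment-match the prior degrees of freedom.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# Moment-match the scaled inverse-chi-square prior (d0, s0^2) from the
# marginal distribution of log sample variances: for s_g^2 ~ s^2 chi^2_d/d
# scaled-F marginals, E[log s_g^2] and Var[log s_g^2] have digamma/trigamma
# closed forms. Returns d0 possibly infinite.
fit_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  n <- length(e)
  if (n < 2L)
    return(list(d0 = Inf, s0_sq = if (n) exp(mean(e)) else 1))
  evar <- sum((e - mean(e))^2) / (n - 1L)
  excess <- evar - trigamma(dg / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-feature two-group comparison with the hierarchical-model variance
#' shrinkage used for microarray data: per-feature pooled sample variances
#' \eqn{s_g^2} (with \eqn{d_g = n_1+n_2-2} df) are squeezed toward a prior
#' variance \eqn{s_0^2} with prior degrees of freedom \eqn{d_0}, both
#' estimated by moment-matching the marginal distribution of
#' \eqn{\log s_g^2}. The moderated statistic
#' \deqn{\tilde t_g = \frac{\Delta_g}{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}},
#'   \qquad \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#' is referred to a t distribution on \eqn{d_0 + d_g} degrees of freedom.
#'
#' Features with (numerically) zero sample variance are floored at machine
#' epsilon, flagged in the \code{zero_variance} column, and excluded from
#' the prior moment estimation.
#'
#' @param m An [expr_matrix] on the log2 scale with >= 2 samples per group.
#' @param d0,s0_sq Optional overrides of the estimated prior; \code{d0 = 0}
#'   recovers the ordinary pooled t-test, \code{d0 = Inf} the fully shrunk
#'   statistic with all posterior variances equal to \code{s0_sq}.
#' @return A [de_table] data.frame; the fitted prior is attached as
#'   attribute \code{"prior"} (list with \code{d0}, \code{s0_sq}).
#' @seealso [plain_t_test()] for the unmoderated miRNA-arm test.
#' @export
moderated_t_test <- function(m, d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  gs <- group_stats(m)
  s2 <- gs$s2
  zero <- s2 < .Machine$double.eps
  s2[zero] <- .Machine$double.eps
  prior <- fit_variance_prior(gs$s2[!zero], gs$dg)
  if (!is.null(d0)) prior$d0 <- d0
  if (!is.null(s0_sq)) prior$s0_sq <- s0_sq
  if (is.infinite(prior$d0)) {
    s_tilde <- rep(prior$s0_sq, length(s2))
    df_tot <- Inf
  } else if (prior$d0 == 0) {
    s_tilde <- s2
    df_tot <- gs$dg
  } else {
    s_tilde <- (prior$d0 * prior$s0_sq + gs$dg * s2) / (prior$d0 + gs$dg)
    df_tot <- prior$d0 + gs$dg
  }
  se <- sqrt(s_tilde * (1 / gs$n1 + 1 / gs$n2))
  t_stat <- gs$log2fc / se
  p <- 2 * stats::pt(-abs(t_stat), df = df_tot)
  out <- data.frame(
    feature_id = rownames(m$values),
    log2fc = unname(gs$log2fc),
    fc_signed = unname(signed_fc(gs$log2fc)),
    t_stat = unname(t_stat),
    df = df_tot,
    p_raw = unname(p),
    p_adj = bh_adjust(unname(p)),
    direction = "ns",
    zero_variance = unname(zero),
    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  out
}

#' Plain two-sample Student t-test per feature
#'
#' Ordinary pooled-variance two-sided t-test on \eqn{n_1+n_2-2} degrees of
#' freedom, the test used for the miRNA arm where no variance moderation
#' is applied. A BH-adjusted column is still computed, but the customary
#' miRNA filter uses the raw p-value (see [apply_de_filter()]).
#'
#' @inheritParams moderated_t_test
#' @return A [de_table] data.frame.
#' @export
plain_t_test <- function(m) {
  moderated_t_test(m, d0 = 0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (enforced monotone, capped at 1), with
#' the output aligned to the input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Apply fold-change and significance filters to a DE table
#'
#' Sets \code{direction} to \code{up}/\code{down} where the absolute
#' signed linear fold change meets \code{fc_threshold} and the chosen
#' p-value column is strictly below \code{p_threshold}; \code{ns}
#' otherwise. The fold-change threshold is on the signed linear scale,
#' so \code{fc_threshold = 1.5} means \eqn{|log2fc| \ge log2(1.5)}.
#'
#' @param tab A [de_table].
#' @param fc_threshold Positive linear fold-change threshold (default 1.5).
#' @param p_threshold Significance level (default 0.05).
#' @param p_column \code{"adjusted"} (BH, the mRNA convention) or
#'   \code{"raw"} (the miRNA convention).
#' @return The table with \code{direction} filled in; up/down counts are
#'   attached as attribute \code{"counts"}.
#' @export
apply_de_filter <- function(tab, fc_threshold = 1.5, p_threshold = 0.05,
                            p_column = c("adjusted", "raw")) {
  p_column <- match.arg(p_column)
  if (!is.numeric(fc_threshold) || fc_threshold <= 0)
    stop("'fc_threshold' must be positive", call. = FALSE)
  if (p_threshold <= 0 || p_threshold > 1)
    stop("'p_threshold' must be in (0, 1]", call. = FALSE)
  p <- if (p_column == "adjusted") tab$p_adj else tab$p_raw
  pass <- abs(tab$fc_signed) >= fc_threshold & p < p_threshold
  tab$direction <- ifelse(pass & tab$fc_signed > 0, "up",
                          ifelse(pass & tab$fc_signed < 0, "down", "ns"))
  attr(tab, "counts") <- c(up = sum(tab$direction == "up"),
                           down = sum(tab$direction == "down"))
  tab
}

#' Write / read a DE table as TSV
#' @param tab A [de_table].
#' @param path File path.
#' @return \code{path} (write) or the table (read).
#' @export
write_de_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
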