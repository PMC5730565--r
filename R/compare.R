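#' Kruskal-Wallis omnibus test on grouped correlation values
#'
#' Non-parametric one-way comparison of the park-wise correlation
#' distributions across platforms (used instead of ANOVA because the group
#' standard deviations differ). The H statistic is computed on pooled average
#' ranks with the standard tie correction and referred to a chi-square with
#' k - 1 degrees of freedom; with no ties the corrected statistic reduces to
#' the classical one.
#'
#' @param values numeric vector of correlation values.
#' @param groups group (platform) label per value.
#' @return list: `H`, `p`, `df`, `n` (named per-group sizes).
#' @export
kruskalWallis <- function(values, groups) {
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 finite values")
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter),
       n = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Dunn's post hoc test for all group pairs
#'
#' For each pair of groups, the difference of mean pooled ranks divided by
#' its tie-corrected standard error,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_g (t_g^3 - t_g)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with a two-sided p-value from the standard normal. Pairs are reported in
#' lexicographic group order, so `z` is the mean-rank of the first-named
#' group minus the second's.
#'
#' @inheritParams kruskalWallis
#' @return data.frame `group_i`, `group_j`, `z`, `p_raw` with
#'   k(k-1)/2 rows.
#' @export
dunnPosthoc <- function(values, groups) {
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 finite values")
  N <- length(values)
  r <- rank(values, ties.method = "average")
  mean_rank <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  g <- sort(names(sizes))
  pairs <- utils::combn(g, 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt(var_base * (1 / sizes[[pr[1L]]] + 1 / sizes[[pr[2L]]]))
    (mean_rank[[pr[1L]]] - mean_rank[[pr[2L]]]) / se
  })
  data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ], z = z,
             p_raw = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Holm-Sidak step-down familywise adjustment
#'
#' Sorts the m raw p-values ascending and sets
#' \eqn{\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}}, enforces
#' monotonicity down the sorted list with a running maximum, caps at 1, and
#' restores the input order. Uniformly less conservative than Bonferroni
#' while still controlling the familywise error rate (assuming independence
#' between the compared groups).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @examples
#' holmSidakAdjust(c(0.01, 0.02, 0.03))
#' @export
holmSidakAdjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Cross-platform comparison of pattern correlations
#'
#' Runs the full platform comparison on a park-correlation table: the
#' Kruskal-Wallis omnibus test over the per-platform distributions of
#' park-wise Pearson correlations, then Dunn's post hoc test for each
#' platform pair with Holm-Sidak-adjusted p-values. Parks excluded by the
#' autocorrelation screen, and undefined correlations, are removed first;
#' the `combined` source is not a platform and is left out of the omnibus
#' test.
#'
#' @param correlations a `ParkCorrelationTable` from [parkCorrelations()].
#' @param sources platform labels to compare; default: every source of type
#'   platform present (everything except `combined` and `official`).
#' @return list of class `"GroupComparison"`: `kw` (list from
#'   [kruskalWallis()]), `pairwise` (data.frame with `z`, `p_raw`,
#'   `p_adjusted`), `n_used`, `n_excluded`.
#' @export
comparePlatforms <- function(correlations, sources = NULL) {
  cc <- correlations
  if (is.null(sources))
    sources <- setdiff(unique(cc$source), c("combined", "official"))
  cc <- cc[cc$source %in% sources, , drop = FALSE]
  n_excl <- sum(cc$excluded | is.na(cc$pearson_r))
  cc <- cc[!cc$excluded & !is.na(cc$pearson_r), , drop = FALSE]
  kw <- kruskalWallis(cc$pearson_r, cc$source)
  pw <- dunnPosthoc(cc$pearson_r, cc$source)
  pw$p_adjusted <- holmSidakAdjust(pw$p_raw)
  structure(list(kw = kw, pairwise = pw, n_used = nrow(cc),
                 n_excluded = n_excl),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g (n = %d values)\n",
              x$kw$H, x$kw$df, x$kw$p, x$n_used))
  cat("Dunn's post hoc (Holm-Sidak adjusted):\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}
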