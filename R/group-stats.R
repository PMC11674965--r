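#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the pooled sample has at most 12 observations and
#' no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `a` relative to `b`.
#' @return List with `statistic` (the Mann-Whitney U for `a`), `p`, and
#'   `exact` (logical, whether the exact path was used).
#' @export
ranksum_test <- function(a, b, alternative = c("two.sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, forms the running maximum of
#' \eqn{(m - j + 1) p_{(j)}} capped at 1, and maps the adjusted values back
#' to the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Spearman rank correlation
#'
#' Midranks for ties; two-sided p-value via the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("degenerate input: constant vector in spearman_corr")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Group comparison of connectivity (or structural) metrics
#'
#' Runs a Wilcoxon rank-sum test per connection (and per direction for
#' directed metrics) between the two groups, then applies the
#' Holm-Bonferroni correction within each subsystem family separately.
#' For directed metrics both directions of every connection enter the same
#' family (e.g. family size 8 for the four dorsal connections).
#'
#' @param tbl Long table with columns `subject_id`, `connection`,
#'   `subsystem`, `metric`, `direction`, `value` (one row per subject per
#'   measurement), e.g. stacked [pairwise_connectivity()] output.
#' @param groups Named character vector mapping `subject_id` to
#'   `"gamer"` / `"nongamer"`.
#' @param metric Which metric to test (a single value present in
#'   `tbl$metric`).
#' @param alternative Test sidedness, default two-sided.
#' @return Data frame with one row per test: `connection`, `direction`,
#'   `metric`, `family`, group sizes and medians, `statistic`, `p_raw`,
#'   `p_holm`, and `n_dropped` (subjects missing that measurement).
#' @export
compare_groups <- function(tbl, groups, metric,
                           alternative = "two.sided") {
  stopifnot(metric %in% tbl$metric)
  tbl <- tbl[tbl$metric == metric, , drop = FALSE]
  unknown <- setdiff(unique(tbl$subject_id), names(groups))
  if (length(unknown))
    stop("subjects without a group label: ", paste(unknown, collapse = ", "))

  keys <- unique(tbl[, c("connection", "direction", "subsystem")])
  n_subj <- length(unique(tbl$subject_id))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- tbl$connection == keys$connection[i] &
      tbl$direction == keys$direction[i]
    sub <- tbl[sel, , drop = FALSE]
    sub <- sub[is.finite(sub$value), , drop = FALSE]
    g <- groups[sub$subject_id]
    a <- sub$value[g == "gamer"]
    b <- sub$value[g == "nongamer"]
    if (length(a) < 2 || length(b) < 2)
      stop("fewer than 2 subjects per group for ", keys$connection[i])
    rt <- ranksum_test(a, b, alternative)
    rows[[i]] <- data.frame(
      connection = keys$connection[i], direction = keys$direction[i],
      metric = metric, family = keys$subsystem[i],
      n_gamer = length(a), n_nongamer = length(b),
      n_dropped = n_subj - nrow(sub),
      median_gamer = stats::median(a), median_nongamer = stats::median(b),
      statistic = rt$statistic, p_raw = rt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_holm <- NA_real_
  for (fam in unique(out$family)) {
    in_fam <- out$family == fam
    out$p_holm[in_fam] <- holm_bonferroni(out$p_raw[in_fam])
  }
  out
}

#' Brain-behavior correlation for one connection
#'
#' Spearman correlation between a per-subject connectivity (or structural)
#' value and response time, over subjects having both; an ordinary
#' least-squares line on the raw values is returned for display only.
#'
#' @param tbl Long measurement table as in [compare_groups()].
#' @param rts Named numeric vector of response times (ms) per subject;
#'   subjects with missing (`NA`) response time are excluded.
#' @param connection Connection label (e.g. `"L SOG--L SPL"`).
#' @param metric Metric name in `tbl$metric`.
#' @param direction Direction label (default `"undirected"`; use `"a->b"` or
#'   `"b->a"` for directed metrics).
#' @return List with `connection`, `metric`, `direction`, `n`, `rho`, `p`,
#'   `slope`, `intercept`.
#' @export
brain_behavior <- function(tbl, rts, connection, metric,
                           direction = "undirected") {
  sel <- tbl$connection == connection & tbl$metric == metric &
    tbl$direction == direction
  sub <- tbl[sel, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no measurements for ", connection, " / ", metric, " / ", direction)
  rt <- rts[sub$subject_id]
  keep <- is.finite(sub$value) & !is.na(rt)
  x <- sub$value[keep]
  y <- unname(rt[keep])
  if (length(x) < 4)
    stop("fewer than 4 complete (value, RT) pairs for ", connection)
  sc <- spearman_corr(x, y)
  fit <- stats::lm(y ~ x)
  list(connection = connection, metric = metric, direction = direction,
       n = length(x), rho = sc$rho, p = sc$p,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
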