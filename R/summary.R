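#' Aggregate channel-level metrics to an organoid summary
#'
#' Per metric, the arithmetic mean over active, non-reference channels.
#' Network-level rows (channel `"ALL"`, e.g. `pct_connected`, `period_s`)
#' pass through unchanged. Metrics with no contributing channel are flagged
#' `NA`, never silently zero.
#'
#' @param metrics metric table: data.frame with `recording_id`,
#'   `channel_id`, `metric_name`, `value`.
#' @param active character vector of active channel ids (the active mask).
#' @param reference_channels channel ids excluded as reference electrodes.
#' @return an `mea_summary` data.frame: `recording_id`, `metric_name`,
#'   `value`, `n_channels`; attribute `empty` is TRUE when no channel was
#'   active.
#' @export
summarize_channels <- function(metrics, active,
                               reference_channels = character(0)) {
  stopifnot(all(c("recording_id", "channel_id", "metric_name", "value")
                %in% names(metrics)))
  if (length(unique(metrics$recording_id)) > 1)
    stop("metric table mixes recordings; summarize one at a time")
  use <- setdiff(active, reference_channels)
  chan <- metrics[metrics$channel_id != "ALL" & metrics$channel_id %in% use, ]
  net <- metrics[metrics$channel_id == "ALL", ]
  rows <- list()
  for (mn in unique(metrics$metric_name[metrics$channel_id != "ALL"])) {
    v <- chan$value[chan$metric_name == mn]
    v <- v[is.finite(v)]
    rows[[mn]] <- data.frame(
      recording_id = metrics$recording_id[1], metric_name = mn,
      value = if (length(v)) mean(v) else NA_real_,
      n_channels = length(v), stringsAsFactors = FALSE)
  }
  if (nrow(net))
    rows[["..net"]] <- data.frame(recording_id = net$recording_id,
                                  metric_name = net$metric_name,
                                  value = net$value,
                                  n_channels = NA_integer_,
                                  stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "empty") <- length(use) == 0
  class(out) <- c("mea_summary", class(out))
  out
}

#' Z-score matrix across a cohort
#'
#' Per metric (row), `(x - mean) / SD` across organoids (columns), using the
#' sample (n-1) SD. Zero-variance metrics give a flagged row of zeros.
#'
#' @param summaries data.frame with `recording_id`, `metric_name`, `value`
#'   (stacked [summarize_channels()] outputs) or a metrics x organoids
#'   matrix.
#' @return matrix of z-scores (metrics x organoids) with attribute
#'   `zero_variance` naming flagged metrics.
#' @export
zscore_matrix <- function(summaries) {
  m <- if (is.matrix(summaries)) summaries else {
    stopifnot(all(c("recording_id", "metric_name", "value") %in% names(summaries)))
    stats::xtabs(value ~ metric_name + recording_id, data = summaries)
  }
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 organoids")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  z <- (m - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  attr(z, "zero_variance") <- rownames(m)[flat]
  z
}

#' Rank-based group comparison against a reference group
#'
#' Kruskal-Wallis omnibus test over all groups plus Wilcoxon rank-sum
#' comparisons of each non-reference group against the reference, with
#' Holm family-wise correction. This is a thin convenience approximating
#' figure-style "ANOVA on ranks with many-to-one correction" statistics;
#' it is not the package's scientific contribution.
#'
#' @param values numeric vector of organoid-level metric values.
#' @param groups factor or character vector of group labels, same length.
#' @param reference the reference group label.
#' @return list with `kruskal` (the `htest`) and `comparisons`, a data.frame
#'   of `group`, `n`, `statistic`, `p_value`, `p_adjusted`. With a single
#'   group, `comparisons` has zero rows.
#' @export
group_compare <- function(values, groups, reference) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!reference %in% groups) stop("reference group not present")
  others <- setdiff(unique(groups), reference)
  kw <- if (length(others))
    stats::kruskal.test(values, factor(groups)) else NULL
  comp <- do.call(rbind, lapply(others, function(g) {
    w <- stats::wilcox.test(values[groups == g], values[groups == reference],
                            exact = FALSE)
    data.frame(group = g, n = sum(groups == g),
               statistic = unname(w$statistic), p_value = w$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(comp))
    comp <- data.frame(group = character(0), n = integer(0),
                       statistic = numeric(0), p_value = numeric(0),
                       p_adjusted = numeric(0))
  else comp$p_adjusted <- stats::p.adjust(comp$p_value, method = "holm")
  list(kruskal = kw, comparisons = comp)
}
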