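# Activity and morphometric summaries: per-channel mean firing rate,
# Kruskal-Wallis group comparisons, axon-length median/quartile profiles
# per condition, and tunnel-penetration fractions with Wilson intervals.

#' Mean firing rate per microchannel
#'
#' The electrode rate is spike count / duration; the channel rate
#' aggregates over the channel's electrodes (mean by default, so the
#' statistic is comparable across channels with different electrode
#' counts). Spike trains without a channel assignment are excluded with a
#' warning. The per-channel rate summarises the activity of the whole axon
#' bundle in the channel, not of a single cell.
#'
#' @param spike_trains named list of `spike_train` (or bare time vectors),
#'   names are electrode ids.
#' @param geometries a [channel_geometry()] or list of them.
#' @param duration_s recording duration, seconds (> 0).
#' @param aggregate how the channel rate aggregates electrode rates:
#'   `"mean"` (default), `"sum"` or `"max"`.
#' @return list with `channels` (data.frame `channel_id, channel_rate_hz,
#'   n_electrodes, duration_s`) and `electrodes` (data.frame `channel_id,
#'   electrode_id, rate_hz`).
#' @export
mean_firing_rate <- function(spike_trains, geometries, duration_s,
                             aggregate = c("mean", "sum", "max")) {
  check_positive(duration_s, "duration_s")
  aggregate <- match.arg(aggregate)
  if (inherits(geometries, "channel_geometry")) geometries <- list(geometries)
  agg_fun <- switch(aggregate, mean = mean, sum = sum, max = max)
  assigned <- unlist(lapply(geometries, `[[`, "electrode_ids"))
  orphans <- setdiff(names(spike_trains), assigned)
  if (length(orphans) > 0L)
    warning(sprintf("electrode(s) without channel assignment excluded: %s",
                    paste(orphans, collapse = ", ")))
  el_rows <- list(); ch_rows <- list()
  for (g in geometries) {
    rates <- vapply(g$electrode_ids, function(id) {
      st <- spike_trains[[id]]
      n <- if (is.null(st)) 0L
      else if (inherits(st, "spike_train")) length(st$times_s)
      else length(st)
      n / duration_s
    }, numeric(1))
    el_rows[[g$channel_id]] <- data.frame(
      channel_id = g$channel_id, electrode_id = g$electrode_ids,
      rate_hz = unname(rates), stringsAsFactors = FALSE)
    ch_rows[[g$channel_id]] <- data.frame(
      channel_id = g$channel_id, channel_rate_hz = agg_fun(rates),
      n_electrodes = length(rates), duration_s = duration_s,
      stringsAsFactors = FALSE)
  }
  list(channels = do.call(rbind, c(ch_rows, list(make.row.names = FALSE))),
       electrodes = do.call(rbind, c(el_rows, list(make.row.names = FALSE))))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom. When every observation across all groups is identical the
#' rank variance is zero; by convention H = 0 and p = 1 (no evidence of a
#' difference).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `H` and `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_param("groups", "need a list of at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop_param("groups", "every group must be non-empty")
  all_x <- unlist(groups)
  if (length(unique(all_x)) == 1L)
    return(list(H = 0, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Median and quartile summary of axon lengths per condition
#'
#' Conditions are typically channel widths (um) or channel counts; quartiles
#' use the linear-interpolation convention (`stats::quantile` type 7).
#'
#' @param length_table data.frame with columns `condition` and `length_um`
#'   (a `replicate_id` column may be present and is ignored here).
#' @return data.frame `condition, n, median_um, q1_um, q3_um`, one row per
#'   condition with n >= 1 (empty conditions are omitted).
#' @export
summarize_lengths <- function(length_table) {
  if (!is.data.frame(length_table) || nrow(length_table) == 0L)
    stop("invalid input: empty length table", call. = FALSE)
  if (!all(c("condition", "length_um") %in% names(length_table)))
    stop_param("length_table", "needs columns condition, length_um")
  out <- lapply(split(length_table$length_um, length_table$condition),
                function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(x), median_um = q[2], q1_um = q[1], q3_um = q[3])
  })
  keep <- !vapply(out, is.null, logical(1))
  res <- do.call(rbind, out[keep])
  res <- cbind(data.frame(condition = names(out)[keep],
                          stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res[, c("condition", "n", "median_um", "q1_um", "q3_um")]
}

#' Tunnel-penetration fraction with Wilson 95% interval
#'
#' Fraction of tunnels that have axons passing through, per tunnel width,
#' with a Wilson score interval (chosen over Wald because the number of
#' tunnels per width is small).
#'
#' @param penetration_table data.frame with columns `tunnel_width_nm,
#'   n_tunnels, n_passed`.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame `tunnel_width_nm, n_tunnels, n_passed, fraction,
#'   ci_low, ci_high`.
#' @export
penetration_fraction <- function(penetration_table, conf_level = 0.95) {
  pt <- penetration_table
  if (!all(c("tunnel_width_nm", "n_tunnels", "n_passed") %in% names(pt)))
    stop_param("penetration_table",
               "needs columns tunnel_width_nm, n_tunnels, n_passed")
  if (any(pt$n_tunnels < 1))
    stop("invalid input: n_tunnels must be >= 1", call. = FALSE)
  if (any(pt$n_passed > pt$n_tunnels | pt$n_passed < 0))
    stop("invalid input: n_passed must be in [0, n_tunnels]", call. = FALSE)
  ci <- t(mapply(function(x, n) {
    stats::prop.test(x, n, conf.level = conf_level,
                     correct = FALSE)$conf.int
  }, pt$n_passed, pt$n_tunnels))
  data.frame(tunnel_width_nm = pt$tunnel_width_nm,
             n_tunnels = pt$n_tunnels, n_passed = pt$n_passed,
             fraction = pt$n_passed / pt$n_tunnels,
             ci_low = ci[, 1], ci_high = ci[, 2])
}
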