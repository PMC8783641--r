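# Session- and group-level aggregation, thin wrappers for the standard
# group statistics, and the behavioural discrimination index.

#' Spatial-object discrimination index
#'
#' DI = (Tmo - Tuo) / (Tmo + Tuo): normalized preference for the moved
#' object, in \[-1, 1\].
#'
#' @param t_moved_s interaction time with the moved object, seconds.
#' @param t_unmoved_s interaction time with the unmoved object, seconds.
#' @return DI in \[-1, 1\].
#' @export
discrimination_index <- function(t_moved_s, t_unmoved_s) {
  if (t_moved_s < 0 || t_unmoved_s < 0)
    stop("interaction times must be non-negative", call. = FALSE)
  if (t_moved_s + t_unmoved_s <= 0)
    stop("at least one interaction time must be positive", call. = FALSE)
  (t_moved_s - t_unmoved_s) / (t_moved_s + t_unmoved_s)
}

#' Summarize one session
#'
#' Aggregates the per-event features into the standard session summary:
#' SWR incidence, ripple peak-power distribution statistics, median peak
#' frequency, mean cycle count and duration, burst-type percentages,
#' SPW-ripple correlation, and (optionally) per-layer band powers and MI.
#'
#' @param swrs paired SWR events with features ([pair_swr()] after
#'   [ripple_features()]).
#' @param bursts a [classify_bursts()] result for `swrs`.
#' @param immobility immobility periods.
#' @param session_id,group identifying labels.
#' @param band_powers optional named list (per layer) of band relative
#'   powers.
#' @param band_mi optional named list (per layer) of band MI values.
#' @return a `session_summary` list.
#' @export
summarize_session <- function(swrs, bursts, immobility, session_id = "s1",
                              group = NA_character_, band_powers = NULL,
                              band_mi = NULL) {
  missing_bits <- c()
  if (missing(swrs) || is.null(swrs)) missing_bits <- c(missing_bits, "swrs")
  if (missing(bursts) || is.null(bursts)) missing_bits <- c(missing_bits, "bursts")
  if (missing(immobility) || is.null(immobility))
    missing_bits <- c(missing_bits, "immobility")
  if (length(missing_bits))
    stop(sprintf("missing session inputs: %s",
                 paste(missing_bits, collapse = ", ")), call. = FALSE)
  kinds <- bursts$groups$kind
  n_groups <- length(kinds)
  pct <- function(k) if (n_groups) 100 * sum(kinds == k) / n_groups else 0
  corr <- if (nrow(swrs) >= 3L) spw_ripple_correlation(swrs) else NA_real_
  structure(list(
    session_id = session_id, group = group,
    n_swr = nrow(swrs),
    swr_incidence_hz = swr_incidence(swrs, immobility),
    peak_power_mean_sd = if (nrow(swrs)) mean(swrs$peak_power_sd) else NA_real_,
    peak_power_median_sd = if (nrow(swrs)) stats::median(swrs$peak_power_sd) else NA_real_,
    peak_freq_median_hz = if (!is.null(swrs$peak_freq_hz) && nrow(swrs))
      stats::median(swrs$peak_freq_hz, na.rm = TRUE) else NA_real_,
    cycles_mean = if (!is.null(swrs$n_cycles) && nrow(swrs))
      mean(swrs$n_cycles, na.rm = TRUE) else NA_real_,
    duration_mean_ms = if (nrow(swrs)) mean(swrs$duration_ms) else NA_real_,
    pct_singlet = pct("singlet"), pct_doublet = pct("doublet"),
    pct_triplet = pct("triplet"), pct_higher = pct("higher"),
    spw_ripple_correlation = corr,
    band_powers = band_powers, band_mi = band_mi),
    class = "session_summary")
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Orders the raw p-values increasingly, adjusts the i-th smallest as
#' 1 - (1 - p)^(m - i + 1), and enforces monotonicity cumulatively.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o]) ^ (m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare a summary field between two groups of sessions
#'
#' Thin wrappers around the standard tests: a two-sided Mann-Whitney U
#' test for scalar fields, or per-bin two-sided t tests with Holm-Sidak
#' step-down correction for multi-bin curves (e.g. the 16 theta-phase
#' bins).
#'
#' @param values_a,values_b numeric vectors (scalar field per session) for
#'   `mann_whitney`, or matrices (sessions x bins) for
#'   `multi_t_holm_sidak`.
#' @param method `"mann_whitney"` or `"multi_t_holm_sidak"`.
#' @param alpha decision level for the corrected tests.
#' @return for `mann_whitney`: list `statistic`, `p`. For
#'   `multi_t_holm_sidak`: list `statistic` (t per bin), `p` (raw),
#'   `p_adjusted`, `decisions` (logical per bin).
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("mann_whitney", "multi_t_holm_sidak"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (method == "mann_whitney") {
    if (length(values_a) < 3L || length(values_b) < 3L)
      stop("need at least 3 sessions per group", call. = FALSE)
    ht <- stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                             exact = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    if (!is.matrix(values_a) || !is.matrix(values_b))
      stop("multi_t_holm_sidak expects sessions x bins matrices",
           call. = FALSE)
    if (nrow(values_a) < 3L || nrow(values_b) < 3L)
      stop("need at least 3 sessions per group", call. = FALSE)
    if (ncol(values_a) != ncol(values_b))
      stop("groups must have the same number of bins", call. = FALSE)
    tt <- vapply(seq_len(ncol(values_a)), function(j) {
      ht <- stats::t.test(values_a[, j], values_b[, j],
                          alternative = "two.sided", var.equal = FALSE)
      c(unname(ht$statistic), ht$p.value)
    }, numeric(2))
    p_adj <- holm_sidak_adjust(tt[2L, ])
    list(statistic = tt[1L, ], p = tt[2L, ], p_adjusted = p_adj,
         decisions = p_adj < alpha)
  }
}
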