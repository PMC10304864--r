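# Adsorption-rate estimation from paired titers, replicate statistics and
# multiple-comparison correction.

#' Phage titer from plaque counts
#'
#' `titer = count * dilution_factor / plated_volume_mL`. A count of zero is
#' reported as below detection with upper bound
#' `1 * dilution_factor / plated_volume_mL` (one plaque-equivalent).
#'
#' @param plaque_count Non-negative plaque count(s).
#' @param dilution_factor Dilution factor(s) (>= 1).
#' @param plated_volume_mL Plated volume(s) in mL (> 0).
#' @return Data frame with `titer` (PFU/mL, NA when below detection),
#'   `below_detection` and `upper_bound`.
#' @export
titer_from_counts <- function(plaque_count, dilution_factor, plated_volume_mL) {
  if (any(plaque_count < 0) || any(dilution_factor < 1) ||
      any(plated_volume_mL <= 0)) {
    stop("need plaque_count >= 0, dilution_factor >= 1, plated_volume_mL > 0")
  }
  n <- max(length(plaque_count), length(dilution_factor), length(plated_volume_mL))
  count <- rep_len(plaque_count, n)
  dil <- rep_len(dilution_factor, n)
  vol <- rep_len(plated_volume_mL, n)
  titer <- count * dil / vol
  below <- count == 0
  data.frame(titer = ifelse(below, NA_real_, titer),
             below_detection = below,
             upper_bound = dil / vol)
}

#' Phage adsorption rate from paired titers
#'
#' `rate = -ln(t1/t0) / (time_h * cell_density)`, in mL cell^-1 h^-1.
#' A final titer above the starting titer gives a negative rate with a
#' warning (free phage increased; growth was not blocked).
#'
#' @param t0_titer,t1_titer Starting and final free-phage titers (PFU/mL, > 0).
#' @param time_h Incubation time in hours (> 0).
#' @param cell_density Host cell density in cells/mL (> 0).
#' @param per_minute Display option: divide by 60 to report
#'   mL cell^-1 min^-1 as classical adsorption constants do.
#' @return Adsorption rate (numeric, vectorised).
#' @export
adsorption_rate <- function(t0_titer, t1_titer, time_h, cell_density,
                            per_minute = FALSE) {
  if (any(t0_titer <= 0)) stop("t0_titer must be > 0")
  if (any(t1_titer <= 0)) {
    stop("t1_titer is zero: no final titer measurable; report a lower bound ",
         "on the rate from the titer detection limit instead")
  }
  if (any(time_h <= 0) || any(cell_density <= 0)) {
    stop("time_h and cell_density must be > 0")
  }
  rate <- -log(t1_titer / t0_titer) / (time_h * cell_density)
  if (any(rate < 0)) {
    warning("t1 exceeds t0 for some replicate(s): negative rate returned ",
            "(phage growth not blocked?)")
  }
  if (per_minute) rate / 60 else rate
}

#' Per-replicate adsorption rates from an assay count table
#'
#' Composes [titer_from_counts()] and [adsorption_rate()] over a table of
#' paired T0/T1 plate counts (columns `replicate_id`, `t0_count`, `t1_count`,
#' `dilution_t0`, `dilution_t1`, `volume_mL`, `time_h`, `cell_density`,
#' optionally `host`, `phage`).
#'
#' @param assays Data frame or CSV path.
#' @return Input with `t0_titer`, `t1_titer` and `rate` columns appended.
#' @export
adsorption_rates_from_counts <- function(assays) {
  if (is.character(assays)) assays <- utils::read.csv(assays)
  t0 <- titer_from_counts(assays$t0_count, assays$dilution_t0, assays$volume_mL)
  t1 <- titer_from_counts(assays$t1_count, assays$dilution_t1, assays$volume_mL)
  if (any(t0$below_detection)) stop("T0 plates with zero plaques; assay uninformative")
  if (any(t1$below_detection)) {
    stop("T1 plates with zero plaques; report a lower bound on the rate instead")
  }
  assays$t0_titer <- t0$titer
  assays$t1_titer <- t1$titer
  assays$rate <- adsorption_rate(t0$titer, t1$titer, assays$time_h,
                                 assays$cell_density)
  assays
}

#' Summarize replicate rate estimates
#'
#' Mean and t-distribution 95% confidence interval over replicate assays.
#'
#' @param rates Numeric vector of per-replicate rates (length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `rate_estimate`: `n`, `mean`, `ci_lower`, `ci_upper`.
#' @export
summarize_replicates <- function(rates, conf_level = 0.95) {
  n <- length(rates)
  if (n < 2) stop("need at least 2 replicate rates for a confidence interval")
  m <- mean(rates)
  half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * sd(rates) / sqrt(n)
  structure(list(n = n, mean = m, ci_lower = m - half, ci_upper = m + half,
                 conf_level = conf_level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> mean %.4g [%.4g, %.4g] (%d%% CI, n = %d)\n",
              x$mean, x$ci_lower, x$ci_upper, round(100 * x$conf_level), x$n))
  invisible(x)
}

#' Two-sample t test between replicate groups
#'
#' Unpaired Welch t test. `tails = "one"` tests the directional hypothesis
#' that group A's mean exceeds group B's (one-tailed p is half the two-tailed
#' p when t > 0). When both groups have zero variance, p is 1 for equal means
#' and 0 otherwise, by convention.
#'
#' @param group_a,group_b Numeric vectors (each length >= 2).
#' @param tails `"two"` (default) or `"one"`.
#' @return List with `t`, `p_value`, `df`, `mean_a`, `mean_b`, `tails`.
#' @export
compare_groups <- function(group_a, group_b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(t = if (equal) 0 else Inf * sign(mean(group_a) - mean(group_b)),
                p_value = if (equal) 1 else 0,
                df = NA_real_, mean_a = mean(group_a), mean_b = mean(group_b),
                tails = tails))
  }
  alt <- if (tails == "two") "two.sided" else "greater"
  tt <- stats::t.test(group_a, group_b, alternative = alt, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(group_a),
       mean_b = mean(group_b), tails = tails)
}

#' Holm-Bonferroni step-down correction
#'
#' Step-down procedure: sort p values ascending and compare the i-th to
#' `alpha / (m - i + 1)`, stopping at the first failure. Reported adjusted p
#' values are the standard monotone Holm adjustment (capped at 1); a test is
#' rejected iff its adjusted p is at most `alpha`, which is equivalent to the
#' stepping rule.
#'
#' @param p_values Numeric vector in [0,1].
#' @param alpha Family-wise error level (default 0.05).
#' @return Data frame in input order: `p`, `p_adjusted`, `reject`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      reject = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1)) stop("p values must lie in [0,1]")
  adj <- stats::p.adjust(p_values, method = "holm")
  data.frame(p = p_values, p_adjusted = adj, reject = adj <= alpha)
}
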