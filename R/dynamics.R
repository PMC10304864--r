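# Experiment-level dynamics: resistance fractions with detection limits,
# extinction/survival classification of titer trajectories, efficiency of
# plating and cross-streak test accounting.

#' Resistant fraction from a cross-streak survey
#'
#' `fraction = (n_tested - n_sensitive) / n_tested`. With zero sensitive
#' isolates, complete resistance cannot be distinguished from a resistant
#' fraction of at least `1 - 1/n`, so the result is flagged as at the
#' detection limit `(1 - 1/n) * 100` percent.
#'
#' @param n_tested Number of isolates tested (>= 1).
#' @param n_sensitive Number scored sensitive (0..n_tested).
#' @return List: `fraction_resistant`, `at_detection_limit`,
#'   `detection_limit_pct`.
#' @export
resistance_fraction <- function(n_tested, n_sensitive) {
  if (n_tested < 1) stop("n_tested must be >= 1")
  if (n_sensitive < 0 || n_sensitive > n_tested) {
    stop("n_sensitive must lie in 0..n_tested")
  }
  list(fraction_resistant = (n_tested - n_sensitive) / n_tested,
       at_detection_limit = n_sensitive == 0,
       detection_limit_pct = (1 - 1 / n_tested) * 100)
}

#' Classify a titer trajectory as survival- or extinction-bound
#'
#' A population is extinction-bound when its titer falls below the detection
#' limit and never recovers through the final observed day; the extinction
#' day is the first day of that terminal below-detection run. A dip below
#' detection followed by recovery is classed survival-bound.
#'
#' @param series Data frame with columns `day` (strictly increasing) and
#'   `titer` (PFU/mL; `NA` means below detection).
#' @param detection_limit Titer detection limit (default 100 PFU/mL).
#' @return List: `fate` (`"survival_bound"` or `"extinction_bound"`) and
#'   `extinction_day` (NA for survivors).
#' @export
classify_fate <- function(series, detection_limit = 100) {
  if (nrow(series) < 2) stop("need at least two observation days")
  ord <- order(series$day)
  day <- series$day[ord]
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  titer <- series$titer[ord]
  below <- is.na(titer) | titer < detection_limit
  n <- length(below)
  if (!below[n]) {
    return(list(fate = "survival_bound", extinction_day = NA_real_))
  }
  # first day of the terminal below-detection run
  i <- n
  while (i > 1 && below[i - 1]) i <- i - 1
  list(fate = "extinction_bound", extinction_day = day[i])
}

#' Efficiency of plating
#'
#' Ratio of a phage's titer on a test host to its titer on a permissive
#' reference host. When the test host shows no plaques, the titer detection
#' bound gives an upper bound on the EOP.
#'
#' @param test_titer Titer on the test host (PFU/mL), or the detection bound
#'   when `test_below_detection` is TRUE.
#' @param reference_titer Titer on the reference host (> 0).
#' @param test_below_detection Whether the test titer is a detection bound.
#' @return List: `eop`, `is_upper_bound`.
#' @export
efficiency_of_plating <- function(test_titer, reference_titer,
                                  test_below_detection = FALSE) {
  if (reference_titer <= 0) stop("reference titer must be > 0")
  list(eop = test_titer / reference_titer,
       is_upper_bound = isTRUE(test_below_detection))
}

#' Total number of resistance tests in an experimental design
#'
#' @param design Data frame with column `n_tested` (one row per population
#'   and day), or a numeric matrix/vector of per-day test counts.
#' @return Total test count.
#' @export
experiment_accounting <- function(design) {
  if (is.data.frame(design)) {
    if (nrow(design) == 0) return(0L)
    return(as.integer(sum(design$n_tested)))
  }
  as.integer(sum(design))
}
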