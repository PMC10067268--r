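#' Count accessible paths to a peak
#'
#' An accessible path (AP) is a single-mutation path whose fitness strictly
#' increases at every step and which terminates at the given peak. Paths that
#' are contiguous subsequences of other accessible paths are not counted, so
#' the count equals the number of maximal strictly-increasing paths into the
#' peak: those whose first node cannot be reached downhill from any further
#' genotype not already on the path. Enumeration is exhaustive depth-first
#' descent from the peak and is capped at
#' `getOption("peakwalk.ap_max_L", 10)`.
#'
#' @inheritParams find_peaks
#' @param peak A peak genotype string (must be a local maximum).
#' @return Integer count of maximal accessible paths into `peak`.
#' @examples
#' ls <- as_landscape(data.frame(
#'   genotype = c("00", "01", "10", "11"),
#'   fitness = c(2, 1, 1.5, 3)
#' ))
#' accessible_path_count(ls, "11")
#' @export
accessible_path_count <- function(landscape, peak) {
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  if (L > getOption("peakwalk.ap_max_L", 10L)) {
    stop("accessible-path enumeration is exponential; capped at L <= ",
      getOption("peakwalk.ap_max_L", 10L),
      call. = FALSE
    )
  }
  nb <- neighbour_matrix(L)
  p <- genotype_index(peak) + 1L
  if (!peak_mask(f, nb)[p]) {
    stop("`peak` (", peak, ") is not a local fitness maximum", call. = FALSE)
  }
  count_maximal_paths(f, nb, p)
}

count_maximal_paths <- function(f, nb, p) {
  on_path <- logical(length(f))
  descend <- function(v) {
    on_path[v] <<- TRUE
    lower <- nb[v, ][f[nb[v, ]] < f[v] & !on_path[nb[v, ]]]
    total <- if (length(lower) == 0) 1L else sum(vapply(lower, descend, integer(1)))
    on_path[v] <<- FALSE
    total
  }
  # the path must contain at least one mutation: branch over the peak's
  # downhill neighbours rather than counting the bare peak
  on_path[p] <- TRUE
  lower <- nb[p, ][f[nb[p, ]] < f[p]]
  sum(vapply(lower, descend, integer(1)))
}

#' Basin of attraction of a peak under the greedy adaptive walk
#'
#' The greedy adaptive walk moves deterministically to the fittest neighbour
#' while one is fitter than the current genotype (ties broken towards the
#' lowest genotype index). A peak's basin is the set of genotypes from which
#' this walk ends at that peak; in tie-free landscapes the basins partition
#' genotype space.
#'
#' @inheritParams accessible_path_count
#' @return Character vector of the genotypes in the basin (always contains the
#'   peak itself).
#' @export
greedy_basin <- function(landscape, peak) {
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  nb <- neighbour_matrix(L)
  p <- genotype_index(peak) + 1L
  if (!peak_mask(f, nb)[p]) {
    stop("`peak` (", peak, ") is not a local fitness maximum", call. = FALSE)
  }
  term <- greedy_terminals(f, nb)
  genotypes(L)[which(term == p)]
}

# terminal genotype (1-based) of the deterministic greedy walk from each node
greedy_terminals <- function(f, nb) {
  nbf <- matrix(f[nb], nrow = length(f))
  mx <- nbf[, 1]
  for (k in seq_len(ncol(nb))[-1]) mx <- pmax(mx, nbf[, k])
  cand <- ifelse(nbf == mx, nb, Inf)
  succ <- cand[, 1]
  for (k in seq_len(ncol(nb))[-1]) succ <- pmin(succ, cand[, k])
  succ <- ifelse(mx > f, succ, seq_along(f)) # stop at peaks/plateaus
  term <- seq_along(f)
  repeat {
    nxt <- succ[term]
    if (all(nxt == term)) break
    term <- nxt
  }
  term
}

#' Per-peak accessibility summary and two-peak differential measures
#'
#' For every peak, the accessible-path count and greedy-basin size. For
#' two-peak landscapes, [differential_accessibility()] returns the two
#' differential measures that predict the overall population-size dependence
#' of early adaptation: `delta_ap = AP(high) - AP(low)` and
#' `delta_basin = B(high) - B(low)`, plus the predicted label from
#' [predict_overall()].
#'
#' @inheritParams find_peaks
#' @return `accessibility_summary()`: a tibble with one row per peak
#'   (`peak`, `fitness`, `ap_count`, `basin_size`).
#'   `differential_accessibility()`: a one-row tibble with `delta_ap`,
#'   `delta_basin`, `prediction`.
#' @examples
#' accessibility_summary(lk_landscape(3, 1, seed = 1))
#' @export
accessibility_summary <- function(landscape) {
  pk <- find_peaks(landscape)
  f <- landscape_fitness(landscape)
  nb <- neighbour_matrix(landscape_L(landscape))
  term <- greedy_terminals(f, nb)
  tibble::tibble(
    peak = pk$genotype,
    fitness = pk$fitness,
    ap_count = vapply(
      pk$index + 1L,
      function(p) count_maximal_paths(f, nb, p), integer(1)
    ),
    basin_size = vapply(
      pk$index + 1L,
      function(p) sum(term == p), integer(1)
    )
  )
}

#' @rdname accessibility_summary
#' @export
differential_accessibility <- function(landscape) {
  acc <- accessibility_summary(landscape)
  if (nrow(acc) != 2) {
    stop("differential accessibility is defined for two-peak landscapes; found ",
      nrow(acc), " peak(s)",
      call. = FALSE
    )
  }
  if (acc$fitness[1] == acc$fitness[2]) {
    stop("the two peaks have exactly equal fitness; high/low is undefined",
      call. = FALSE
    )
  }
  # accessibility_summary orders by decreasing fitness: row 1 = high peak
  d_ap <- acc$ap_count[1] - acc$ap_count[2]
  d_b <- acc$basin_size[1] - acc$basin_size[2]
  tibble::tibble(
    delta_ap = d_ap,
    delta_basin = d_b,
    prediction = predict_overall(d_ap, d_b)
  )
}

#' Predict the overall population-size dependence from differential accessibility
#'
#' Classifies a two-peak landscape from the signs of its two differential
#' accessibility measures: both non-negative and not both zero predicts an
#' overall increasing mean height versus `N`; both non-positive and not both
#' zero predicts overall decreasing; both zero or strictly opposite signs
#' leave the behaviour undetermined.
#'
#' @param delta_ap Accessible-path count difference, high minus low peak.
#' @param delta_basin Greedy-basin size difference, high minus low peak.
#' @return Character vector of labels among `"predict_increasing"`,
#'   `"predict_decreasing"`, `"undetermined_both_zero"`,
#'   `"undetermined_conflict"`.
#' @examples
#' predict_overall(2, 1)
#' predict_overall(0, 0)
#' @export
predict_overall <- function(delta_ap, delta_basin) {
  dplyr::case_when(
    delta_ap == 0 & delta_basin == 0 ~ "undetermined_both_zero",
    delta_ap >= 0 & delta_basin >= 0 ~ "predict_increasing",
    delta_ap <= 0 & delta_basin <= 0 ~ "predict_decreasing",
    TRUE ~ "undetermined_conflict"
  )
}

#' Overall behaviour of mean height between N = 1 and the large-N limit
#'
#' @param hbar_n1 Mean height at `N = 1` (the pure-random-walk value).
#' @param hbar_large_n Mean height at the large-`N` anchor (`N = 1e4` by
#'   convention).
#' @param tol Absolute tolerance below which the difference counts as flat
#'   (default `1e-9` times the value scale; single-peak landscapes are exactly
#'   flat up to solver precision).
#' @return Character vector among `"increasing"`, `"decreasing"`, `"flat"`.
#' @export
overall_behaviour <- function(hbar_n1, hbar_large_n, tol = NULL) {
  if (is.null(tol)) tol <- 1e-9 * max(abs(c(hbar_n1, hbar_large_n)), 1e-300)
  d <- hbar_large_n - hbar_n1
  dplyr::case_when(
    abs(d) <= tol ~ "flat",
    d > 0 ~ "increasing",
    TRUE ~ "decreasing"
  )
}

#' Standard deviation of peak fitness values
#'
#' The population standard deviation of the fitnesses of a landscape's peaks;
#' for two peaks this is half the fitness gap. It bounds, and empirically
#' correlates with, the magnitude of the overall variation of mean height
#' with `N`.
#'
#' @inheritParams find_peaks
#' @return A single non-negative number (0 for single-peak landscapes).
#' @export
peak_fitness_sd <- function(landscape) {
  fp <- find_peaks(landscape)$fitness
  sqrt(mean((fp - mean(fp))^2))
}
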