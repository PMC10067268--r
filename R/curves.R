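#' Default population-size grid
#'
#' A near-geometric (factor ~sqrt(2)) grid from `N = 1` to `N = 1e4`. The
#' geometric spacing resolves both the small-`N` extrema of mean height
#' (typically at `N` of order 10-100) and the large-`N` saturation; the last
#' point, `N = 1e4`, doubles as the large-`N` anchor.
#'
#' @return Increasing integer vector starting at 1 and ending at 10000.
#' @export
default_N_grid <- function() {
  c(
    1, 2, 3, 4, 5, 7, 10, 14, 20, 28, 40, 56, 80, 113, 160, 226, 320, 452,
    640, 905, 1280, 1810, 2560, 3620, 5120, 7241, 10000
  )
}

#' Mean height of the first peak versus population size
#'
#' Evaluates `hbar` (and `sigma_h`) by exact first-step analysis on a grid of
#' population sizes. The value at the largest grid point (`N = 1e4` on the
#' default grid) serves as the large-`N` anchor `hbar_inf`; at `N = 1` both
#' walks reduce to the pure random walk.
#'
#' @inheritParams height_stats
#' @param N_grid Increasing vector of population sizes starting at 1.
#' @param include_sigma Also compute `sigma_h` per grid point.
#' @return A tibble of class `hbar_curve` with columns `N`, `hbar` (and
#'   `sigma_h`), carrying `walk` and the anchor in attributes.
#' @examples
#' curve <- hbar_curve(lk_landscape(3, 1, seed = 1), "moran",
#'   N_grid = c(1, 10, 100, 1000, 10000)
#' )
#' curve_summary(curve)
#' @export
hbar_curve <- function(landscape, walk = c("moran", "wright_fisher"),
                       N_grid = default_N_grid(), include_sigma = TRUE,
                       start_set = NULL) {
  walk <- match.arg(walk)
  if (N_grid[1] != 1 || is.unsorted(N_grid, strictly = TRUE)) {
    stop("`N_grid` must be strictly increasing and start at N = 1", call. = FALSE)
  }
  rows <- lapply(N_grid, function(N) {
    height_stats(landscape, walk, N, start_set = start_set)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("N", "hbar", if (include_sigma) "sigma_h")]
  attr(out, "walk") <- walk
  attr(out, "anchor_N") <- N_grid[length(N_grid)]
  class(out) <- c("hbar_curve", class(out))
  out
}

#' Classify the shape of a mean-height curve
#'
#' Detects interior extrema from sign changes of successive differences
#' exceeding a tolerance, and maps the extremum sequence to one of the
#' behaviour classes: `monotonic_increasing`, `monotonic_decreasing`,
#' `one_maximum`, `one_minimum`, `max_then_min`, `min_then_max`, `other`
#' (more than two extrema) or `flat`.
#'
#' @param curve An `hbar_curve`, or any data frame with columns `N` and
#'   `hbar`.
#' @param tol Absolute difference tolerance; defaults to `1e-9` times the
#'   curve's value scale, below genuine secondary extrema but above solver
#'   noise on deterministic first-step-analysis curves. For Monte Carlo
#'   curves pass ~2 standard errors instead.
#' @return A one-row tibble with `label` and `n_extrema`; the extrema
#'   themselves (grid `N` and value) are in `attr(, "extrema")`.
#' @export
classify_curve <- function(curve, tol = NULL) {
  v <- curve$hbar
  Ns <- curve$N
  if (is.null(tol)) tol <- 1e-9 * max(abs(v), 1e-300)
  ext <- find_extrema(v, tol)
  n_ext <- nrow(ext)
  label <- if (n_ext == 0) {
    d <- v[length(v)] - v[1]
    if (max(v) - min(v) <= tol) {
      "flat"
    } else if (d >= 0) "monotonic_increasing" else "monotonic_decreasing"
  } else if (n_ext == 1) {
    if (ext$type[1] == "max") "one_maximum" else "one_minimum"
  } else if (n_ext == 2) {
    if (ext$type[1] == "max") "max_then_min" else "min_then_max"
  } else {
    "other"
  }
  out <- tibble::tibble(label = label, n_extrema = n_ext)
  attr(out, "extrema") <- tibble::tibble(
    N = Ns[ext$index], hbar = v[ext$index], type = ext$type
  )
  out
}

# interior extrema of a curve: runs of successive differences with |d| > tol,
# an extremum wherever the run sign flips; located at the extreme value over
# the intervening (possibly flat) span
find_extrema <- function(v, tol) {
  d <- diff(v)
  sg <- sign(d) * (abs(d) > tol)
  nz <- which(sg != 0)
  idx <- integer(0)
  type <- character(0)
  if (length(nz) >= 2) {
    for (m in seq_len(length(nz) - 1)) {
      i1 <- nz[m]
      i2 <- nz[m + 1]
      if (sg[i1] != sg[i2]) {
        span <- (i1 + 1):i2
        if (sg[i1] > 0) {
          idx <- c(idx, span[which.max(v[span])])
          type <- c(type, "max")
        } else {
          idx <- c(idx, span[which.min(v[span])])
          type <- c(type, "min")
        }
      }
    }
  }
  tibble::tibble(index = idx, type = type)
}

#' Amplitudes of the extrema of a mean-height curve
#'
#' The amplitude of the `i`-th extremum (at grid size `N_i`, counting from
#' `N = 1`) is the mean of the value changes over the two adjacent
#' inter-extremum segments, `A_i = |hbar(N_i) - hbar(N_{i-1})|` and
#' `A_{i+1}`, where `N_0 = 1` and the final segment runs to the large-`N`
#' anchor.
#'
#' @inheritParams classify_curve
#' @return A tibble with one row per extremum: `N`, `type`, `amplitude`.
#' @export
extremum_amplitudes <- function(curve, tol = NULL) {
  v <- curve$hbar
  if (is.null(tol)) tol <- 1e-9 * max(abs(v), 1e-300)
  ext <- find_extrema(v, tol)
  if (nrow(ext) == 0) {
    return(tibble::tibble(N = numeric(0), type = character(0), amplitude = numeric(0)))
  }
  nodes <- c(1L, ext$index, length(v)) # N = 1, extrema, anchor
  seg <- abs(diff(v[nodes]))
  tibble::tibble(
    N = curve$N[ext$index],
    type = ext$type,
    amplitude = (seg[-length(seg)] + seg[-1]) / 2
  )
}

#' Summary of a mean-height curve
#'
#' @inheritParams classify_curve
#' @return A one-row tibble with `hbar_1` (value at `N = 1`), `hbar_inf`
#'   (value at the large-`N` anchor), `delta_hbar = hbar_inf - hbar_1`,
#'   `overshoot = max(hbar) - hbar_inf` and
#'   `relative_overshoot = overshoot / delta_hbar` (`NA` unless
#'   `delta_hbar > 0`).
#' @export
curve_summary <- function(curve) {
  v <- curve$hbar
  h1 <- v[1]
  hinf <- v[length(v)]
  delta <- hinf - h1
  os <- max(v) - hinf
  tibble::tibble(
    hbar_1 = h1,
    hbar_inf = hinf,
    delta_hbar = delta,
    overshoot = os,
    relative_overshoot = if (delta > 0) os / delta else NA_real_
  )
}
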