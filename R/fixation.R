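WALKS <- c(
  "moran", "wright_fisher", "pure_random",
  "natural_aw", "greedy_aw", "random_aw"
)

#' Fixation probability of a single mutant lineage
#'
#' Probability that the lineage of one mutant with selection coefficient
#' `s = f_mutant / f_wildtype - 1` takes over a population of size `N`, under
#' the Moran process or the Wright-Fisher model in the diffusion
#' approximation:
#' \deqn{P_{Moran} = \frac{1 - (1+s)^{-1}}{1 - (1+s)^{-N}}, \qquad
#'       P_{WF} = \frac{1 - e^{-2s}}{1 - e^{-2Ns}},}
#' with the neutral limit `1/N` at `s = 0`. Both equal 1 at `N = 1` (every
#' mutation fixes) and, for `s > 0`, tend to `s/(1+s)` (Moran) and
#' `1 - exp(-2s)` (Wright-Fisher) as `N` grows.
#'
#' Evaluation uses `log1p()`/`expm1()` so that large `N` and small `s` do not
#' overflow; `|s| < 1e-12` is treated as neutral.
#'
#' @param s Selection coefficient(s), each > -1.
#' @param N Population size(s), integer >= 1; recycled against `s`.
#' @return Numeric vector of fixation probabilities in (0, 1].
#' @examples
#' moran_fixation(0, 50) # neutral: 1/N
#' wf_fixation(0.1, 10)
#' @export
moran_fixation <- function(s, N) {
  check_sN(s, N)
  a <- log1p(s)
  out <- ifelse(abs(s) < 1e-12, 1 / N, expm1(-a) / expm1(-N * a))
  # deleterious branch can reach expm1 overflow (Inf): true value underflows to 0
  out[is.nan(out) | is.infinite(out)] <- 0
  out
}

#' @rdname moran_fixation
#' @export
wf_fixation <- function(s, N) {
  check_sN(s, N)
  out <- ifelse(abs(s) < 1e-12, 1 / N, expm1(-2 * s) / expm1(-2 * N * s))
  out[is.nan(out) | is.infinite(out)] <- 0
  out
}

check_sN <- function(s, N) {
  if (any(s <= -1)) stop("selection coefficients must satisfy s > -1", call. = FALSE)
  if (any(N < 1)) stop("population size N must be >= 1", call. = FALSE)
  invisible(TRUE)
}

# ---- per-proposal acceptance / weight matrix ------------------------------

# Raw acceptance probability (or weight, for adaptive walks) of each of the L
# possible mutations from each genotype: a 2^L x L matrix, column k = flip of
# site k. nb is the 1-based neighbour matrix.
acceptance_matrix <- function(f, nb, walk, N = NULL) {
  walk <- match.arg(walk, WALKS)
  nbf <- matrix(f[nb], nrow = length(f))
  s <- nbf / f - 1
  switch(walk,
    moran = {
      check_walk_N(N)
      matrix(moran_fixation(s, N), nrow = length(f))
    },
    wright_fisher = {
      check_walk_N(N)
      matrix(wf_fixation(s, N), nrow = length(f))
    },
    pure_random = matrix(1, length(f), ncol(nb)),
    natural_aw = pmax(s, 0),
    random_aw = (s > 0) * 1,
    greedy_aw = greedy_matrix(f, nb, nbf)
  )
}

greedy_matrix <- function(f, nb, nbf) {
  n <- length(f)
  L <- ncol(nb)
  mx <- nbf[, 1]
  for (k in seq_len(L)[-1]) mx <- pmax(mx, nbf[, k])
  # tie-break: among equally fit fittest neighbours, lowest genotype index
  cand <- ifelse(nbf == mx, nb, Inf)
  pick <- cand[, 1]
  for (k in seq_len(L)[-1]) pick <- pmin(pick, cand[, k])
  P <- matrix(0, n, L)
  up <- mx > f
  P[cbind(seq_len(n), max.col(-abs(nb - pick), "first"))] <- as.double(up)
  P
}

check_walk_N <- function(N) {
  if (is.null(N) || !is.numeric(N) || length(N) != 1 || N < 1 || !is.finite(N)) {
    stop("Moran/Wright-Fisher walks need a finite population size N >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

# Embedded-chain transition probabilities: each non-peak row of the raw
# acceptance matrix normalized to sum to 1. Peak rows are returned as zero and
# are treated as absorbing by first-passage computations. Errors on non-peak
# plateau nodes (no usable move), which only arise for adaptive walks on
# landscapes with fitness ties.
embedded_matrix <- function(f, nb, walk, N = NULL, peaks = NULL) {
  P <- acceptance_matrix(f, nb, walk, N)
  if (is.null(peaks)) peaks <- which(peak_mask(f, nb))
  rs <- rowSums(P)
  stuck <- rs <= 0 & !(seq_along(f) %in% peaks)
  if (any(stuck)) {
    stop(
      "no available move from non-peak genotype(s) ",
      paste(which(stuck) - 1L, collapse = ", "),
      " (fitness plateau under an adaptive walk)",
      call. = FALSE
    )
  }
  Pt <- P / rs
  Pt[peaks, ] <- 0
  list(ptilde = Pt, raw = P, raw_rowsum = rs, peaks = peaks)
}

#' Embedded-chain transition kernel of an origin-fixation walk
#'
#' In the weak-mutation regime the population hops between neighbouring
#' genotypes; conditioning on a move happening, the probability of hopping
#' from `i` to neighbour `l` is the fixation probability of that mutation
#' normalized over the `L` neighbours of `i`. Adaptive-walk variants
#' (`natural_aw`: weight proportional to `max(s, 0)`; `greedy_aw`: all mass on
#' the fittest fitter neighbour; `random_aw`: uniform over fitter neighbours)
#' are the large-`N` limits and ignore `N`, as does `pure_random` (uniform over
#' all neighbours, the `N = 1` behaviour).
#'
#' @param landscape A `fitness_landscape`.
#' @param walk One of `"moran"`, `"wright_fisher"`, `"pure_random"`,
#'   `"natural_aw"`, `"greedy_aw"`, `"random_aw"`.
#' @param N Population size (Moran / Wright-Fisher only).
#' @return A tibble with columns `from`, `to` (genotype strings), `prob`, and
#'   `from_is_peak`. Rows of non-peak genotypes sum to 1 over their `L`
#'   neighbours; peaks are absorbing (a single self-loop row with `prob = 1`).
#' @examples
#' transition_kernel(lk_landscape(3, 1, seed = 1), "moran", N = 10)
#' @export
transition_kernel <- function(landscape, walk = "moran", N = NULL) {
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  nb <- neighbour_matrix(L)
  emb <- embedded_matrix(f, nb, walk, N)
  gt <- genotypes(L)
  non_peak <- setdiff(seq_along(f), emb$peaks)
  out <- tibble::tibble(
    from = rep(gt[non_peak], ncol(nb)),
    to = gt[as.vector(nb[non_peak, ])],
    prob = as.vector(emb$ptilde[non_peak, ]),
    from_is_peak = FALSE
  )
  out <- dplyr::bind_rows(out, tibble::tibble(
    from = gt[emb$peaks], to = gt[emb$peaks],
    prob = 1, from_is_peak = TRUE
  ))
  dplyr::arrange(out, .data$from, .data$to)
}

#' Rescale walk time by population size
#'
#' The walk time `t` counts mutation events; mutations arise proportionally to
#' `N`, so the physical time to reach the first peak is proportional to `t/N`.
#'
#' @param tbar Mean walk time(s) in mutation events.
#' @param N Population size(s).
#' @return `tbar / N`.
#' @export
walk_time_rescaled <- function(tbar, N) {
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  tbar / N
}
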