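#' Simulate origin-fixation walks until the first peak is hit
#'
#' Simulates the embedded Markov chain of a walk (no rejected moves), stopping
#' when the current genotype is a local fitness peak. With
#' `record_time = TRUE`, the number of underlying mutation events is also
#' accumulated: per accepted step from genotype `i` the number of proposals is
#' geometric with success probability `mean(P_iq)` over the `L` neighbours
#' (`P` being the raw fixation probabilities), which reproduces the walk
#' simulated at the level of individual mutation events.
#'
#' `simulate_walks()` runs many walks vectorized. For small landscapes the
#' embedded kernel is precomputed; for large ones (`2^L > 65536`) transition
#' probabilities are evaluated on the fly for the active walks only, so
#' `L = 20` landscapes can be walked without building the full kernel.
#' `simulate_walk()` runs one walk and also records its trajectory.
#'
#' @inheritParams transition_kernel
#' @param start Starting genotype string(s). For `simulate_walks()`: `NULL`
#'   (each walk starts uniformly at random), a single genotype, or a vector of
#'   length `n_walks`.
#' @param n_walks Number of walks.
#' @param record_time Also accumulate the number of mutation events `t`
#'   (Moran, Wright-Fisher and pure-random walks only).
#' @param seed Optional seed for reproducibility.
#' @param max_steps Safety cap on accepted steps per walk; exceeding it is an
#'   error since every finite walk reaches a peak almost surely.
#' @return A tibble with one row per walk: `start`, `first_peak`, `height`
#'   (fitness of the first peak), `length` (number of fixations) and `time`
#'   (mutation events; `NA` unless `record_time`). `simulate_walk()` adds a
#'   `trajectory` list-column of visited genotypes.
#' @examples
#' ls <- lk_landscape(3, 1, seed = 1)
#' simulate_walks(ls, "moran", N = 10, n_walks = 5, seed = 1)
#' @export
simulate_walks <- function(landscape, walk = "moran", N = NULL, n_walks = 1,
                           start = NULL, record_time = FALSE, seed = NULL,
                           max_steps = 1e6) {
  walk <- match.arg(walk, WALKS)
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  if (record_time && !walk %in% c("moran", "wright_fisher", "pure_random")) {
    stop("`record_time` requires a walk with defined acceptance probabilities",
      call. = FALSE
    )
  }
  local_seed(seed, {
    state <- if (is.null(start)) {
      sample.int(length(f), n_walks, replace = TRUE)
    } else {
      rep_len(genotype_index(start) + 1L, n_walks)
    }
    eng <- if (length(f) > 65536) walk_engine_lazy else walk_engine_dense
    res <- eng(f, L, walk, N, state, record_time, max_steps)
    tibble::tibble(
      start = index_to_genotype(state - 1L, L),
      first_peak = index_to_genotype(res$state - 1L, L),
      height = f[res$state],
      length = res$len,
      time = res$tim
    )
  })
}

#' @rdname simulate_walks
#' @export
simulate_walk <- function(landscape, walk = "moran", N = NULL, start = NULL,
                          record_time = FALSE, seed = NULL, max_steps = 1e6) {
  walk <- match.arg(walk, WALKS)
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  nb <- neighbour_matrix(L)
  emb <- embedded_matrix(f, nb, walk, N)
  is_peak <- seq_along(f) %in% emb$peaks
  gt <- genotypes(L)

  local_seed(seed, {
    state <- if (is.null(start)) {
      sample.int(length(f), 1)
    } else {
      genotype_index(start)[1] + 1L
    }
    traj <- state
    len <- 0L
    tim <- if (record_time) 0 else NA_real_
    while (!is_peak[state]) {
      if (len >= max_steps) stop("walk exceeded max_steps", call. = FALSE)
      if (record_time) {
        tim <- tim + stats::rgeom(1, emb$raw_rowsum[state] / L) + 1
      }
      state <- nb[state, sample.int(L, 1, prob = emb$ptilde[state, ])]
      len <- len + 1L
      traj <- c(traj, state)
    }
    tibble::tibble(
      start = gt[traj[1]],
      first_peak = gt[state],
      height = f[state],
      length = len,
      time = tim,
      trajectory = list(gt[traj])
    )
  })
}

# ---- engines --------------------------------------------------------------

# row-wise cumulative sums without apply()
row_cumsum <- function(P) {
  for (k in seq_len(ncol(P))[-1]) P[, k] <- P[, k - 1] + P[, k]
  P
}

# precomputed-kernel engine for landscapes that fit comfortably in memory
walk_engine_dense <- function(f, L, walk, N, state, record_time, max_steps) {
  nb <- neighbour_matrix(L)
  emb <- embedded_matrix(f, nb, walk, N)
  cum <- row_cumsum(emb$ptilde)
  p_accept <- emb$raw_rowsum / L
  is_peak <- seq_along(f) %in% emb$peaks
  n_walks <- length(state)
  len <- integer(n_walks)
  tim <- if (record_time) numeric(n_walks) else rep(NA_real_, n_walks)
  active <- !is_peak[state]
  steps <- 0L
  while (any(active)) {
    steps <- steps + 1L
    if (steps > max_steps) stop("walk exceeded max_steps = ", max_steps, call. = FALSE)
    cur <- state[active]
    if (record_time) {
      tim[active] <- tim[active] + stats::rgeom(length(cur), p_accept[cur]) + 1
    }
    u <- stats::runif(length(cur))
    k <- rowSums(cum[cur, , drop = FALSE] < u) + 1L
    k[k > L] <- L # guard against cumsum rounding at 1
    state[active] <- nb[cbind(cur, k)]
    len[active] <- len[active] + 1L
    active[active] <- !is_peak[state[active]]
  }
  list(state = state, len = len, tim = tim)
}

# memory-light engine: per-step transition probabilities evaluated only for
# the genotypes currently visited
walk_engine_lazy <- function(f, L, walk, N, state, record_time, max_steps) {
  flip <- 2^((L - 1):0)
  n_walks <- length(state)
  len <- integer(n_walks)
  tim <- if (record_time) numeric(n_walks) else rep(NA_real_, n_walks)
  active <- rep(TRUE, n_walks)
  steps <- 0L
  while (any(active)) {
    steps <- steps + 1L
    if (steps > max_steps) stop("walk exceeded max_steps = ", max_steps, call. = FALSE)
    cur <- state[active]
    m <- length(cur)
    nbidx <- matrix(bitwXor(rep(cur - 1L, L), rep(flip, each = m)), m, L) + 1L
    s <- matrix(f[nbidx] / f[cur] - 1, m, L)
    still <- rowSums(s >= 0) > 0 # a peak has all neighbours strictly less fit
    if (!all(still)) {
      idx_active <- which(active)
      active[idx_active[!still]] <- FALSE
      if (!any(still)) break
      cur <- cur[still]
      nbidx <- nbidx[still, , drop = FALSE]
      s <- s[still, , drop = FALSE]
      m <- length(cur)
    }
    P <- switch(walk,
      moran = matrix(moran_fixation(s, N), m, L),
      wright_fisher = matrix(wf_fixation(s, N), m, L),
      pure_random = matrix(1, m, L),
      natural_aw = pmax(s, 0),
      random_aw = (s > 0) * 1,
      stop("walk '", walk, "' is not supported by the lazy engine", call. = FALSE)
    )
    rs <- rowSums(P)
    if (record_time && walk %in% c("moran", "wright_fisher", "pure_random")) {
      tim[active] <- tim[active] + stats::rgeom(m, rs / L) + 1
    }
    cum <- row_cumsum(P / rs)
    u <- stats::runif(m)
    k <- rowSums(cum < u) + 1L
    k[k > L] <- L
    state[active] <- nbidx[cbind(seq_len(m), k)]
    len[active] <- len[active] + 1L
  }
  list(state = state, len = len, tim = tim)
}
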