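#' First-step analysis: probability of hitting each peak first
#'
#' Conditioning on the first move of the embedded walk gives, for every
#' starting genotype `i` and every peak `j`, the linear system
#' \deqn{x_{ij} = \sum_{l \in G_i} \tilde P_{il}\, x_{lj}}
#' with boundary conditions `x_jj = 1` and `x_kj = 0` for other peaks `k`.
#' Solving it (one linear solve over the non-peak genotypes, with one
#' right-hand side per peak; unique because the non-peak sub-chain is strictly
#' substochastic) yields the exact probability that a walk from `i` reaches
#' peak `j` before any other peak.
#'
#' Dense solves are used for small landscapes and sparse (Matrix) solves above
#' `2^11` genotypes; landscapes beyond `getOption("peakwalk.fsa_max_L", 14)`
#' are rejected with a pointer to Monte Carlo simulation.
#'
#' @inheritParams transition_kernel
#' @return A tibble with columns `start`, `peak` (genotype strings) and
#'   `prob`, one row per start-peak pair. For every start, probabilities over
#'   peaks sum to 1.
#' @examples
#' ls <- lk_landscape(3, 1, seed = 1)
#' hitting_probabilities(ls, "moran", N = 10)
#' @export
hitting_probabilities <- function(landscape, walk = "moran", N = NULL) {
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  check_fsa_L(L)
  nb <- neighbour_matrix(L)
  sol <- fsa_hitting(f, L, nb, walk, N)
  gt <- genotypes(L)
  out <- tibble::tibble(
    start = rep(gt, ncol(sol$X)),
    peak = rep(gt[sol$peaks], each = length(f)),
    prob = as.vector(sol$X)
  )
  dplyr::arrange(out, .data$start, .data$peak)
}

#' Height of early adaptation: fitness of the first peak encountered
#'
#' The height `h` of a walk is the fitness of the first peak it hits. From the
#' first-step-analysis hitting probabilities, the conditional mean from start
#' `i` is \eqn{\bar h_i = \sum_j f_j x_{ij}}, and `hbar` averages \eqn{\bar
#' h_i} over the starting set (all genotypes by default, or the `n` fittest
#' via `start_set`). `sigma_h` is the standard deviation of `h` over both the
#' uniform random start and the walk randomness; `mean_sigma_hi` averages the
#' per-start standard deviation over starts.
#'
#' @inheritParams transition_kernel
#' @param start_set Optional character vector of starting genotypes (e.g. from
#'   [fittest_genotypes()]). Default: all genotypes, equally likely.
#' @return `height_stats()`: a one-row tibble with `walk`, `N`, `n_start`,
#'   `hbar`, `sigma_h`, `mean_sigma_hi`. `height_by_start()`: a tibble with
#'   `start`, `hbar_i`, `sigma_hi`.
#' @examples
#' ls <- lk_landscape(3, 1, seed = 1)
#' height_stats(ls, "moran", N = 100)
#' @export
height_stats <- function(landscape, walk = "moran", N = NULL, start_set = NULL) {
  hm <- height_moments(landscape, walk, N)
  keep <- start_rows(hm$gt, start_set)
  hbar <- mean(hm$h1[keep])
  Eh2 <- mean(hm$h2[keep])
  tibble::tibble(
    walk = walk,
    N = if (is.null(N)) NA_real_ else N,
    n_start = length(keep),
    hbar = hbar,
    sigma_h = sqrt(max(Eh2 - hbar^2, 0)),
    mean_sigma_hi = mean(sqrt(pmax(hm$h2[keep] - hm$h1[keep]^2, 0)))
  )
}

#' @rdname height_stats
#' @export
height_by_start <- function(landscape, walk = "moran", N = NULL,
                            start_set = NULL) {
  hm <- height_moments(landscape, walk, N)
  keep <- start_rows(hm$gt, start_set)
  tibble::tibble(
    start = hm$gt[keep],
    hbar_i = hm$h1[keep],
    sigma_hi = sqrt(pmax(hm$h2[keep] - hm$h1[keep]^2, 0))
  )
}

height_moments <- function(landscape, walk, N) {
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  check_fsa_L(L)
  sol <- fsa_hitting(f, L, neighbour_matrix(L), walk, N)
  fM <- f[sol$peaks]
  list(
    gt = genotypes(L),
    h1 = drop(sol$X %*% fM),
    h2 = drop(sol$X %*% fM^2)
  )
}

start_rows <- function(gt, start_set) {
  if (is.null(start_set)) return(seq_along(gt))
  keep <- match(start_set, gt)
  if (length(keep) == 0 || anyNA(keep)) {
    stop("`start_set` must be a non-empty set of genotypes of this landscape",
      call. = FALSE
    )
  }
  keep
}

#' Mean walk length and time to the first peak
#'
#' The length `l_i` (number of fixations) and time `t_i` (number of mutation
#' events, fixing or not) to reach the first peak from genotype `i` satisfy
#' first-step equations with zero boundary values at peaks:
#' `l_i = 1 + sum_l Ptilde_il l_l` and
#' `t_i = L / sum_q P_iq + sum_l Ptilde_il t_l`, where the per-step source
#' term of `t` is the mean number of geometric proposal trials until one
#' fixes. At `N = 1` every proposal is accepted, so `t = l` exactly. The
#' physical time is proportional to `t/N` since mutations arrive at a rate
#' proportional to `N`.
#'
#' @inheritParams height_stats
#' @return `length_time_stats()`: one-row tibble with `walk`, `N`, `lbar`,
#'   `tbar`, `tbar_over_N`. `length_time_by_start()`: tibble with `start`,
#'   `lbar_i`, `tbar_i`.
#' @export
length_time_stats <- function(landscape, walk = "moran", N = NULL,
                              start_set = NULL) {
  lt <- length_time_solve(landscape, walk, N)
  keep <- start_rows(lt$gt, start_set)
  tbar <- mean(lt$t[keep])
  tibble::tibble(
    walk = walk,
    N = if (is.null(N)) NA_real_ else N,
    lbar = mean(lt$l[keep]),
    tbar = tbar,
    tbar_over_N = if (is.null(N)) NA_real_ else tbar / N
  )
}

#' @rdname length_time_stats
#' @export
length_time_by_start <- function(landscape, walk = "moran", N = NULL,
                                 start_set = NULL) {
  lt <- length_time_solve(landscape, walk, N)
  keep <- start_rows(lt$gt, start_set)
  tibble::tibble(start = lt$gt[keep], lbar_i = lt$l[keep], tbar_i = lt$t[keep])
}

length_time_solve <- function(landscape, walk, N) {
  if (!walk %in% c("moran", "wright_fisher", "pure_random")) {
    stop("walk time is defined for walks with acceptance probabilities",
      call. = FALSE
    )
  }
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  check_fsa_L(L)
  nb <- neighbour_matrix(L)
  emb <- embedded_matrix(f, nb, walk, N)
  Q <- setdiff(seq_along(f), emb$peaks)
  l <- t <- numeric(length(f))
  if (length(Q) > 0) {
    sys <- absorbing_system(emb, Q, nb)
    rhs <- cbind(rep(1, length(Q)), L / emb$raw_rowsum[Q])
    sol <- solve_system(sys$A, rhs)
    l[Q] <- sol[, 1]
    t[Q] <- sol[, 2]
  }
  list(gt = genotypes(L), l = l, t = t)
}

#' Stationary distribution of the mutation-event chain
#'
#' At steady state the ergodic (non-absorbing) walk, with per-mutation-event
#' transition probabilities `P_ij / L` to neighbours and a self-loop for the
#' remainder, settles into a unique stationary distribution. The Moran chain
#' is exactly reversible: telescoping the detailed-balance ratios
#' `P_ij / P_ji = (f_j / f_i)^(N - 1)` gives the classical
#' `pi_i` proportional to `f_i^(N - 1)`, evaluated here in log space so large
#' `N` never underflows. The Wright-Fisher diffusion kernel with
#' `s = f_j/f_i - 1` satisfies detailed balance only approximately, so its
#' stationary distribution is obtained by an exact dense solve of
#' `pi P = pi` instead (capped at `L <= 12`, and at population sizes where
#' deleterious fixation probabilities do not underflow to zero).
#'
#' @inheritParams transition_kernel
#' @return A tibble with columns `genotype`, `fitness`, `prob`, carrying the
#'   mean steady-state fitness in `attr(, "mean_fitness")` (also returned by
#'   [steady_state_fitness()]). Mean steady-state fitness is non-decreasing in
#'   `N`.
#' @examples
#' stationary_distribution(lk_landscape(3, 1, seed = 1), "moran", N = 10)
#' @export
stationary_distribution <- function(landscape, walk = c("moran", "wright_fisher"),
                                    N = NULL) {
  walk <- match.arg(walk)
  check_walk_N(N)
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  n <- length(f)
  if (walk == "moran") {
    logpi <- (N - 1) * log(f)
    logpi <- logpi - max(logpi)
    pi <- exp(logpi) / sum(exp(logpi))
  } else {
    if (L > 12) {
      stop("Wright-Fisher stationary solve is capped at L <= 12", call. = FALSE)
    }
    nb <- neighbour_matrix(L)
    P <- matrix(0, n, n)
    raw <- acceptance_matrix(f, nb, walk, N)
    if (any(rowSums(raw > 0) == 0)) {
      stop(
        "deleterious fixation probabilities underflow at N = ", N,
        "; the chain is no longer ergodic in double precision",
        call. = FALSE
      )
    }
    for (k in seq_len(L)) {
      P[cbind(seq_len(n), nb[, k])] <- raw[, k] / L
    }
    diag(P) <- 1 - rowSums(P)
    A <- t(P) - diag(n)
    A[n, ] <- 1
    pi <- solve(A, c(rep(0, n - 1), 1))
    pi <- pmax(pi, 0)
    pi <- pi / sum(pi)
  }
  out <- tibble::tibble(genotype = genotypes(L), fitness = f, prob = pi)
  attr(out, "mean_fitness") <- sum(pi * f)
  out
}

#' @rdname stationary_distribution
#' @export
steady_state_fitness <- function(landscape, walk = c("moran", "wright_fisher"),
                                 N = NULL) {
  attr(stationary_distribution(landscape, walk, N), "mean_fitness")
}

# ---- solver internals -----------------------------------------------------

check_fsa_L <- function(L) {
  cap <- getOption("peakwalk.fsa_max_L", 14L)
  if (L > cap) {
    stop(
      "L = ", L, " is too large for dense first-step analysis (cap ", cap,
      "); use simulate_walks() instead",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# (I - Ptilde_QQ) over the non-peak set Q, plus bookkeeping to scatter
# transition mass that lands on peaks
absorbing_system <- function(emb, Q, nb) {
  n <- nrow(nb)
  q <- length(Q)
  pos <- integer(n)
  pos[Q] <- seq_len(q)
  use_sparse <- n > 2048
  if (use_sparse) {
    ii <- jj <- list()
    xx <- list()
    for (k in seq_len(ncol(nb))) {
      tgt <- nb[Q, k]
      in_Q <- pos[tgt] > 0L
      ii[[k]] <- which(in_Q)
      jj[[k]] <- pos[tgt[in_Q]]
      xx[[k]] <- -emb$ptilde[Q, k][in_Q]
    }
    A <- Matrix::sparseMatrix(
      i = c(seq_len(q), unlist(ii)),
      j = c(seq_len(q), unlist(jj)),
      x = c(rep(1, q), unlist(xx)),
      dims = c(q, q)
    )
  } else {
    A <- diag(q)
    for (k in seq_len(ncol(nb))) {
      tgt <- nb[Q, k]
      in_Q <- pos[tgt] > 0L
      A[cbind(which(in_Q), pos[tgt[in_Q]])] <-
        A[cbind(which(in_Q), pos[tgt[in_Q]])] - emb$ptilde[Q, k][in_Q]
    }
  }
  list(A = A, pos = pos, use_sparse = use_sparse)
}

solve_system <- function(A, B) {
  out <- if (inherits(A, "sparseMatrix")) {
    as.matrix(Matrix::solve(A, B))
  } else {
    solve(A, B)
  }
  matrix(out, nrow = nrow(B))
}

# full hitting-probability matrix X (2^L x n_M), peaks in ascending index order
fsa_hitting <- function(f, L, nb, walk, N, peaks = NULL) {
  emb <- embedded_matrix(f, nb, walk, N, peaks = peaks)
  peaks <- emb$peaks
  nM <- length(peaks)
  n <- length(f)
  X <- matrix(0, n, nM)
  X[cbind(peaks, seq_len(nM))] <- 1
  Q <- setdiff(seq_len(n), peaks)
  if (length(Q) > 0) {
    sys <- absorbing_system(emb, Q, nb)
    ppos <- integer(n)
    ppos[peaks] <- seq_len(nM)
    B <- matrix(0, length(Q), nM)
    for (k in seq_len(ncol(nb))) {
      tgt <- nb[Q, k]
      at_peak <- ppos[tgt] > 0L
      if (any(at_peak)) {
        idx <- cbind(which(at_peak), ppos[tgt[at_peak]])
        B[idx] <- B[idx] + emb$ptilde[Q, k][at_peak]
      }
    }
    X[Q, ] <- solve_system(sys$A, B)
  }
  list(X = X, peaks = peaks)
}
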