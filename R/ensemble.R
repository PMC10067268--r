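#' Configure an ensemble experiment
#'
#' Bundles everything needed to reproduce an ensemble study: the landscape
#' model and its parameters, the walk, the population-size grid, the execution
#' mode and the master seed. Per-landscape seeds are derived from the master
#' seed by a counter scheme, so identical configs reproduce identical
#' per-landscape records (bit-for-bit in `"fsa"` and `"peaks"` modes) and
#' ensembles can be chunked without changing results.
#'
#' @param model Landscape model: `"lk"`, `"lkp"`, `"hoc"`, `"rmf"`,
#'   `"eggbox"`, `"ising"`.
#' @param n Number of landscapes to generate (when `n_keep` is `NULL`).
#' @param L,K,scheme LK-family parameters (ignored by other models).
#' @param model_args Extra arguments for the model generator (e.g. `p` for
#'   `"lkp"`, `noise_sd` for `"rmf"`).
#' @param walk `"moran"` or `"wright_fisher"`.
#' @param N_grid Population-size grid (see [default_N_grid()]); the last point
#'   is the large-`N` anchor.
#' @param mode `"fsa"` (exact first-step analysis per landscape),
#'   `"simulate"` (Monte Carlo estimate of the curve) or `"peaks"` (peak
#'   counting only).
#' @param walks_per_start Walks per starting genotype in `"simulate"` mode.
#' @param keep Which landscapes enter the per-landscape analysis: `"all"`,
#'   `"multipeak"`, `"twopeak"` or `"singlepeak"`.
#' @param n_keep If not `NULL`, keep generating until this many landscapes
#'   pass the `keep` filter (all generated landscapes still count towards the
#'   peak-number statistics).
#' @param n_start If not `NULL`, restrict walk starting points to the
#'   `n_start` fittest genotypes of each landscape.
#' @param accessibility Compute the two-peak differential accessibility
#'   measures (needs `L` within the accessible-path cap).
#' @param times Also accumulate ensemble mean walk length and time per grid
#'   point (fsa mode).
#' @param seed Master seed (integer).
#' @return An `ensemble_config` list.
#' @examples
#' cfg <- ensemble_config(n = 50, L = 3, K = 1, seed = 1)
#' res <- run_ensemble(cfg)
#' glance(res)
#' @export
ensemble_config <- function(model = "lk", n = 1000, L = 3, K = 1,
                            scheme = "random", model_args = list(),
                            walk = c("moran", "wright_fisher"),
                            N_grid = default_N_grid(),
                            mode = c("fsa", "simulate", "peaks"),
                            walks_per_start = 100,
                            keep = c("all", "multipeak", "twopeak", "singlepeak"),
                            n_keep = NULL, n_start = NULL,
                            accessibility = TRUE, times = FALSE, seed = 1) {
  cfg <- list(
    model = match.arg(model, c("lk", "lkp", "hoc", "rmf", "eggbox", "ising")),
    n = n, L = L, K = K, scheme = scheme, model_args = model_args,
    walk = match.arg(walk), N_grid = N_grid, mode = match.arg(mode),
    walks_per_start = walks_per_start, keep = match.arg(keep),
    n_keep = n_keep, n_start = n_start,
    accessibility = accessibility && L <= getOption("peakwalk.ap_max_L", 10L),
    times = times, seed = seed
  )
  if (cfg$mode == "fsa") check_fsa_L(L)
  if (cfg$model %in% c("lk", "lkp")) check_lk_params(L, K, scheme)
  structure(cfg, class = "ensemble_config")
}

#' Run an ensemble experiment
#'
#' Streams landscapes from the configured generator (one derived seed per
#' landscape, never holding the ensemble in memory), computes per-landscape
#' early-adaptation summaries in the requested mode, and accumulates the
#' ensemble mean curve.
#'
#' @param config An [ensemble_config()].
#' @param progress Print a progress line every `progress` landscapes (0 = off).
#' @return An `ensemble_result` list with elements `per_landscape` (tibble of
#'   kept landscapes), `mean_curve` (ensemble mean of `hbar` per grid `N`,
#'   over kept landscapes), `n_generated`, `n_peaks_all` (integer vector of
#'   peak counts of every generated landscape) and `config`. Use [tidy()] and
#'   [glance()] to extract records and aggregates.
#' @export
run_ensemble <- function(config, progress = 0) {
  stopifnot(inherits(config, "ensemble_config"))
  cfg <- config
  nb <- neighbour_matrix(cfg$L)
  n_nodes <- 2^cfg$L
  want <- if (is.null(cfg$n_keep)) NA_integer_ else cfg$n_keep
  max_draw <- if (is.na(want)) cfg$n else max(100L, 60L * want)

  records <- list()
  n_peaks_all <- integer(0)
  curve_sum <- numeric(length(cfg$N_grid))
  lbar_sum <- tbar_sum <- numeric(length(cfg$N_grid))
  kept <- 0L
  i <- 0L
  while (i < max_draw && (is.na(want) || kept < want)) {
    i <- i + 1L
    f <- generate_fitness(cfg, derive_seed(cfg$seed, i))
    pk <- which(peak_mask(f, nb))
    n_pk <- length(pk)
    n_peaks_all[i] <- n_pk
    ok <- switch(cfg$keep,
      all = TRUE,
      multipeak = n_pk > 1,
      twopeak = n_pk == 2,
      singlepeak = n_pk == 1
    )
    if (!ok) next
    kept <- kept + 1L
    rec <- list(landscape = i, n_peaks = n_pk, seed = derive_seed(cfg$seed, i))

    if (cfg$mode != "peaks") {
      v <- if (cfg$mode == "fsa") {
        hbar_on_grid(f, nb, pk, cfg$walk, cfg$N_grid, n_start = cfg$n_start)
      } else {
        sim_hbar_grid(
          f, nb, pk, cfg$walk, cfg$N_grid, cfg$walks_per_start,
          seed = derive_seed(cfg$seed + 7L, i)
        )
      }
      curve_sum <- curve_sum + v
      if (cfg$times && cfg$mode == "fsa") {
        lt <- ltime_on_grid(f, nb, pk, cfg$walk, cfg$N_grid)
        lbar_sum <- lbar_sum + lt$l
        tbar_sum <- tbar_sum + lt$t
      }
      cc <- classify_curve(data.frame(N = cfg$N_grid, hbar = v))
      amps <- extremum_amplitudes(data.frame(N = cfg$N_grid, hbar = v))
      ratio_sum <- 0
      ratio_n <- 0L
      if (nrow(amps) >= 2) {
        a <- amps$amplitude
        others <- a[-which.max(a)]
        ratio_sum <- sum(max(a) / others)
        ratio_n <- length(others)
      }
      rec <- c(rec, list(
        hbar_1 = v[1], hbar_inf = v[length(v)],
        delta_hbar = v[length(v)] - v[1],
        overshoot = max(v) - v[length(v)],
        label = cc$label, n_extrema = cc$n_extrema,
        overall = overall_behaviour(v[1], v[length(v)]),
        amp_ratio_sum = ratio_sum, amp_ratio_n = ratio_n
      ))
    }

    if (cfg$accessibility && n_pk == 2 && f[pk[1]] != f[pk[2]]) {
      hi <- pk[order(f[pk], decreasing = TRUE)]
      term <- greedy_terminals(f, nb)
      rec <- c(rec, list(
        delta_ap = count_maximal_paths(f, nb, hi[1]) -
          count_maximal_paths(f, nb, hi[2]),
        delta_basin = sum(term == hi[1]) - sum(term == hi[2]),
        sigma_fM = abs(f[hi[1]] - f[hi[2]]) / 2
      ))
      rec$prediction <- predict_overall(rec$delta_ap, rec$delta_basin)
    }
    records[[kept]] <- rec
    if (progress > 0 && kept %% progress == 0) {
      message("landscape ", i, " generated, ", kept, " kept")
    }
  }

  per_landscape <- dplyr::bind_rows(lapply(records, tibble::as_tibble))
  out <- list(
    per_landscape = per_landscape,
    mean_curve = if (cfg$mode != "peaks" && kept > 0) {
      mc <- tibble::tibble(N = cfg$N_grid, mean_hbar = curve_sum / kept)
      if (cfg$times && cfg$mode == "fsa") {
        mc$mean_lbar <- lbar_sum / kept
        mc$mean_tbar <- tbar_sum / kept
      }
      mc
    },
    n_generated = i,
    n_peaks_all = n_peaks_all,
    config = cfg
  )
  class(out) <- "ensemble_result"
  out
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(
    "# Ensemble result: ", x$n_generated, " landscapes generated, ",
    nrow(x$per_landscape), " analysed (mode ", x$config$mode, ")\n",
    sep = ""
  )
  print(glance(x))
  invisible(x)
}

#' Sweep one experiment parameter
#'
#' Repeats [run_ensemble()] while varying one parameter and collects the
#' aggregate summaries.
#'
#' @inheritParams run_ensemble
#' @param over Which parameter to sweep: `"L"`, `"K"` or `"n_start"`.
#' @param values Values of the swept parameter.
#' @return A tibble of [glance()] rows, one per value, with the swept
#'   parameter in the first column.
#' @export
sweep_ensemble <- function(config, over = c("L", "K", "n_start"), values,
                           progress = 0) {
  over <- match.arg(over)
  rows <- lapply(values, function(val) {
    cfg <- config
    cfg[[over]] <- val
    cfg <- do.call(ensemble_config, cfg[setdiff(names(cfg), character(0))])
    dplyr::bind_cols(
      tibble::tibble(!!over := val),
      glance(run_ensemble(cfg, progress = progress))
    )
  })
  dplyr::bind_rows(rows)
}

# ---- fast internal paths --------------------------------------------------

# fitness vector for one landscape of the configured ensemble
generate_fitness <- function(cfg, seed) {
  args <- cfg$model_args
  switch(cfg$model,
    lk = local_seed(seed, lk_fitness(cfg$L, cfg$K, cfg$scheme)),
    lkp = ensure_positive(local_seed(
      seed,
      lk_fitness(cfg$L, cfg$K, cfg$scheme, p_neutral = args$p %||% 0.1)
    )),
    hoc = local_seed(seed, stats::runif(2^cfg$L)),
    rmf = landscape_fitness(do.call(
      rmf_landscape, c(list(L = cfg$L, seed = seed), args)
    )),
    eggbox = landscape_fitness(do.call(
      eggbox_landscape, c(list(L = cfg$L, seed = seed), args)
    )),
    ising = landscape_fitness(do.call(
      ising_landscape, c(list(L = cfg$L, seed = seed), args)
    ))
  )
}

# exact hbar on a grid of N: one linear solve per N with a single right-hand
# side (hbar_i = sum_j f_j x_ij solved directly)
hbar_on_grid <- function(f, nb, peaks, walk, Ns, n_start = NULL) {
  n <- length(f)
  L <- ncol(nb)
  Q <- setdiff(seq_len(n), peaks)
  fM <- f[peaks]
  start_idx <- if (is.null(n_start)) {
    seq_len(n)
  } else {
    order(f, decreasing = TRUE)[seq_len(n_start)]
  }
  if (length(Q) == 0) {
    return(rep(mean(f[start_idx]), length(Ns)))
  }
  pos <- integer(n)
  pos[Q] <- seq_along(Q)
  tgt <- nb[Q, , drop = FALSE]
  in_Q <- matrix(pos[tgt] > 0L, nrow = length(Q))
  SQ <- matrix(f[tgt] / f[Q] - 1, nrow = length(Q))
  h_all <- numeric(n)
  h_all[peaks] <- f[peaks]
  vapply(Ns, function(N) {
    P <- if (walk == "moran") {
      matrix(moran_fixation(SQ, N), nrow = length(Q))
    } else {
      matrix(wf_fixation(SQ, N), nrow = length(Q))
    }
    Pt <- P / rowSums(P)
    q <- length(Q)
    A <- diag(q)
    b <- numeric(q)
    for (k in seq_len(L)) {
      iq <- in_Q[, k]
      w <- which(iq)
      A[cbind(w, pos[tgt[w, k]])] <- A[cbind(w, pos[tgt[w, k]])] - Pt[w, k]
      wp <- which(!iq)
      b[wp] <- b[wp] + Pt[wp, k] * f[tgt[wp, k]]
    }
    h_all[Q] <- solve(A, b)
    mean(h_all[start_idx])
  }, numeric(1))
}

# exact mean walk length and time on a grid of N (uniform starts)
ltime_on_grid <- function(f, nb, peaks, walk, Ns) {
  n <- length(f)
  L <- ncol(nb)
  Q <- setdiff(seq_len(n), peaks)
  if (length(Q) == 0) {
    return(list(l = rep(0, length(Ns)), t = rep(0, length(Ns))))
  }
  pos <- integer(n)
  pos[Q] <- seq_along(Q)
  tgt <- nb[Q, , drop = FALSE]
  in_Q <- matrix(pos[tgt] > 0L, nrow = length(Q))
  SQ <- matrix(f[tgt] / f[Q] - 1, nrow = length(Q))
  lv <- tv <- numeric(length(Ns))
  for (m in seq_along(Ns)) {
    N <- Ns[m]
    P <- if (walk == "moran") {
      matrix(moran_fixation(SQ, N), nrow = length(Q))
    } else {
      matrix(wf_fixation(SQ, N), nrow = length(Q))
    }
    rs <- rowSums(P)
    Pt <- P / rs
    q <- length(Q)
    A <- diag(q)
    for (k in seq_len(L)) {
      w <- which(in_Q[, k])
      A[cbind(w, pos[tgt[w, k]])] <- A[cbind(w, pos[tgt[w, k]])] - Pt[w, k]
    }
    sol <- solve(A, cbind(rep(1, q), L / rs))
    lv[m] <- sum(sol[, 1]) / n
    tv[m] <- sum(sol[, 2]) / n
  }
  list(l = lv, t = tv)
}

# Monte Carlo hbar over a grid of N: walks_per_start embedded walks from every
# starting genotype at each N
sim_hbar_grid <- function(f, nb, peaks, walk, Ns, walks_per_start, seed = NULL) {
  n <- length(f)
  L <- ncol(nb)
  is_peak <- seq_len(n) %in% peaks
  local_seed(seed, {
    vapply(Ns, function(N) {
      emb <- embedded_matrix(f, nb, walk, N, peaks = peaks)
      cum <- row_cumsum(emb$ptilde)
      state <- rep(seq_len(n), walks_per_start)
      active <- !is_peak[state]
      while (any(active)) {
        cur <- state[active]
        u <- stats::runif(length(cur))
        k <- rowSums(cum[cur, , drop = FALSE] < u) + 1L
        k[k > L] <- L
        state[active] <- nb[cbind(cur, k)]
        active[active] <- !is_peak[state[active]]
      }
      mean(f[state])
    }, numeric(1))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
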