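#' Four-state classification of a time series
#'
#' Each interior point of a series of k values is classified by the
#' inequalities between it and its neighbours, yielding a derived sequence of
#' k - 2 states:
#'
#' * 1 (trough):    `x[t-1] >  x[t] <= x[t+1]`
#' * 2 (increase):  `x[t-1] <= x[t] <= x[t+1]`
#' * 3 (peak):      `x[t-1] <= x[t] >  x[t+1]`
#' * 4 (decrease):  `x[t-1] >  x[t] >  x[t+1]`
#'
#' Exactly one condition holds for every real triplet, ties included, so the
#' classification is a partition.  Ties are resolved by the inequalities as
#' written; no jitter is added.
#'
#' @param x Numeric series, length >= 3, no missing values.
#' @return Integer vector in `{1,2,3,4}` of length `length(x) - 2`, aligned
#'   to positions `2 .. k-1`.
#' @export
#' @examples
#' classify_states(c(3, 1, 2))  # trough
#' classify_states(c(1, 2, 3))  # increase
classify_states <- function(x) {
  if (anyNA(x))
    stop_eggsync("series contains missing values", "eggsync_missing_values")
  k <- length(x)
  if (k < 3)
    stop_eggsync("series must have at least 3 values", "eggsync_series_too_short")
  prv <- x[1:(k - 2)]
  cur <- x[2:(k - 1)]
  nxt <- x[3:k]
  down_in <- prv > cur          # arrived falling
  down_out <- cur > nxt         # leaves falling
  ifelse(down_in & !down_out, 1L,
    ifelse(!down_in & !down_out, 2L,
      ifelse(!down_in & down_out, 3L, 4L)))
}

#' Estimate the 4x4 state-transition matrix
#'
#' Counts one-step transitions in one or more state sequences (pooled), then
#' normalises each row by its total.  A state never observed as a source gets
#' the uniform row (1/4 each) so that a row-stochastic matrix is always
#' returned without distorting observed transitions.
#'
#' @param state_sequences An integer state vector or a list of them, values
#'   in `{1,2,3,4}`, each of length >= 2.
#' @return A `transition_matrix` object: the 4x4 probability matrix with the
#'   raw counts in `attr(,"counts")`.
#' @export
estimate_transition_matrix <- function(state_sequences) {
  if (!is.list(state_sequences)) state_sequences <- list(state_sequences)
  if (!length(state_sequences))
    stop_eggsync("no state sequences supplied", "eggsync_empty_input")
  counts <- matrix(0L, 4, 4, dimnames = list(from = 1:4, to = 1:4))
  for (s in state_sequences) {
    if (length(s) < 2)
      stop_eggsync("each state sequence needs length >= 2", "eggsync_series_too_short")
    if (!all(s %in% 1:4))
      stop_eggsync("states must lie in {1,2,3,4}", "eggsync_invalid_state")
    n <- length(s)
    tab <- table(factor(s[-n], levels = 1:4), factor(s[-1], levels = 1:4))
    counts <- counts + as.matrix(tab)
  }
  totals <- rowSums(counts)
  tau <- counts / ifelse(totals > 0, totals, 1)
  tau[totals == 0, ] <- 0.25
  structure(tau, counts = counts, class = c("transition_matrix", class(tau)))
}

#' Stationary distribution of a transition matrix
#'
#' Solves `s %*% T = s` by power iteration from the uniform vector
#' (tolerance 1e-10, capped iterations).  Non-ergodic chains (stationary
#' distribution not unique, e.g. the identity matrix) are detected from the
#' multiplicity of the unit eigenvalue and flagged via `attr(,"ergodic")`;
#' the fixed point reached from the uniform start is still returned.
#'
#' @param tmat Row-stochastic 4x4 matrix.
#' @param tol Convergence tolerance on the max-norm step (default 1e-10).
#' @param max_iter Iteration cap (default 100000).
#' @return Numeric vector of 4 probabilities summing to 1, with attribute
#'   `ergodic`.
#' @export
stationary_distribution <- function(tmat, tol = 1e-10, max_iter = 100000L) {
  check_stochastic(tmat)
  s <- rep(1 / 4, 4)
  for (i in seq_len(max_iter)) {
    s_new <- as.numeric(s %*% tmat)
    s_new <- s_new / sum(s_new)
    if (max(abs(s_new - s)) < tol) {
      ev <- eigen(t(tmat), only.values = TRUE)$values
      ergodic <- sum(abs(ev - 1) < 1e-8) == 1
      return(structure(s_new, ergodic = ergodic))
    }
    s <- s_new
  }
  stop_eggsync(sprintf(
    "power iteration did not converge in %d iterations (residual %.3e)",
    max_iter, max(abs(as.numeric(s %*% tmat) - s))),
    "eggsync_no_convergence")
}

check_stochastic <- function(tmat) {
  if (!is.matrix(tmat) || any(dim(tmat) != 4))
    stop_eggsync("transition matrix must be 4x4", "eggsync_invalid_state")
  if (any(tmat < 0) || any(abs(rowSums(tmat) - 1) > 1e-8))
    stop_eggsync("transition matrix rows must be nonnegative and sum to 1",
                 "eggsync_invalid_state")
  invisible(tmat)
}

#' State occupancy of two aligned state sequences
#'
#' For each time step, the proportion of series occupying each of the four
#' states; with two series the entries are 0, 1/2 or 1.
#'
#' @param state_a,state_b Integer state sequences of equal length.
#' @return Matrix with one row per time step and columns `s1..s4`; rows sum
#'   to 1.
#' @export
occupancy <- function(state_a, state_b) {
  if (length(state_a) != length(state_b))
    stop_eggsync("state sequences are misaligned (unequal lengths)",
                 "eggsync_misaligned")
  occ <- vapply(seq_along(state_a), function(t) {
    tabulate(c(state_a[t], state_b[t]), nbins = 4) / 2
  }, numeric(4))
  occ <- t(occ)
  colnames(occ) <- paste0("s", 1:4)
  occ
}

#' State-occupancy entropy
#'
#' Shannon entropy `H = -sum(s * ln s)` (natural log, `0 * ln 0 := 0`) of an
#' occupancy vector or of each row of an occupancy matrix.  `H` lies in
#' `[0, ln 4]`; with two series it is 0 (same state) or `ln 2`.
#'
#' @param s Occupancy vector of 4 proportions, or a matrix of rows of them.
#' @return Entropy in nats (scalar or one value per row).
#' @export
occupancy_entropy <- function(s) {
  if (is.matrix(s)) return(apply(s, 1, occupancy_entropy))
  if (length(s) != 4 || any(s < 0) || abs(sum(s) - 1) > 1e-8)
    stop_eggsync("occupancy vector must be 4 nonnegative proportions summing to 1",
                 "eggsync_invalid_state")
  p <- s[s > 0]
  -sum(p * log(p))
}

#' Simulate the independent-chains entropy null
#'
#' Approximates the null distribution of the occupancy entropy under the
#' hypothesis that the series are independent, stationary Markov chains
#' sharing the transition matrix `tmat`.  Each replicate simulates
#' `n_series` chains of `length` steps, the initial state drawn from the
#' stationary distribution of `tmat` (or from `init_probs`), and records the
#' occupancy entropy at every step.  The null expectation `H_null_mean`
#' pools all steps of all replicates (per-step means are kept for
#' diagnostics).
#'
#' @param tmat Row-stochastic 4x4 transition matrix.
#' @param length Number of time steps per chain (the state-sequence length).
#' @param n_sims Number of replicate chain sets (default 10000).
#' @param n_series Number of independent chains per replicate (default 2).
#' @param seed Optional RNG seed for reproducibility.
#' @param init_probs Optional length-4 initial-state distribution overriding
#'   the stationary one (e.g. empirical state frequencies).
#' @return A `null_entropy` object: list with `H_null_mean`, `draws` (all
#'   simulated H values), `per_step_mean`, `n_sims`, `length`, `seed`.
#'   `H_null_mean == 0` (degenerate dynamics) is flagged with a warning;
#'   Phi is undefined downstream in that case.
#' @export
simulate_null <- function(tmat, length, n_sims = 10000L, n_series = 2L,
                          seed = NULL, init_probs = NULL) {
  check_stochastic(tmat)
  if (n_sims < 1) stop_eggsync("n_sims must be >= 1", "eggsync_invalid_config")
  if (length < 1) stop_eggsync("chain length must be >= 1", "eggsync_invalid_config")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_probs)) init_probs <- as.numeric(stationary_distribution(tmat))
  ln2 <- log(2)
  # one matrix of current states, advanced in lock-step across replicates
  states <- matrix(sample.int(4L, n_sims * n_series, replace = TRUE,
                              prob = init_probs),
                   nrow = n_sims, ncol = n_series)
  H <- matrix(NA_real_, nrow = n_sims, ncol = length)
  step_entropy <- function(st) {
    if (ncol(st) == 2L) {
      ifelse(st[, 1] == st[, 2], 0, ln2)
    } else {
      apply(st, 1, function(r) occupancy_entropy(tabulate(r, 4) / length(r)))
    }
  }
  H[, 1] <- step_entropy(states)
  if (length > 1) {
    for (step in 2:length) {
      new_states <- states
      for (r in 1:4) {
        idx <- which(states == r)
        if (base::length(idx))
          new_states[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                                        prob = tmat[r, ])
      }
      states <- new_states
      H[, step] <- step_entropy(states)
    }
  }
  out <- list(H_null_mean = mean(H), draws = as.numeric(H),
              per_step_mean = colMeans(H), n_sims = as.integer(n_sims),
              length = as.integer(length), n_series = as.integer(n_series),
              seed = seed)
  if (out$H_null_mean == 0)
    warning("degenerate null: H_null_mean = 0; Phi is undefined")
  class(out) <- "null_entropy"
  out
}

#' Synchrony score
#'
#' `Phi_t = 1 - H_t / H_null_mean`.  Equals 1 exactly when the series occupy
#' the same state (H = 0); can be negative when the observed entropy exceeds
#' the independent-chains expectation.
#'
#' @param H_t Observed occupancy entropy (vectorised).
#' @param H_null_mean Expected entropy under the independence null; must be
#'   > 0.
#' @return Numeric vector of Phi values, each <= 1.
#' @export
phi <- function(H_t, H_null_mean) {
  if (!is.finite(H_null_mean) || H_null_mean <= 0)
    stop_eggsync("H_null_mean must be > 0: synchrony undefined for a degenerate null",
                 "eggsync_undefined_synchrony")
  1 - H_t / H_null_mean
}

#' One-sided synchrony p-value
#'
#' Empirical p-value toward synchrony (low entropy), with the add-one
#' correction: `p = (1 + #(null H <= H_t)) / (1 + n)`.
#'
#' @param H_t Observed entropy (vectorised).
#' @param null_sample Simulated null entropies (nonempty).
#' @return p-values in `(0, 1]`, monotone nondecreasing in `H_t`.
#' @export
synchrony_pvalue <- function(H_t, null_sample) {
  if (!length(null_sample))
    stop_eggsync("null sample is empty", "eggsync_empty_input")
  n <- length(null_sample)
  vapply(H_t, function(h) (1 + sum(null_sample <= h)) / (1 + n), numeric(1))
}

#' Full state-based Markov-chain synchrony analysis of two series
#'
#' Classifies both annual series into four states, estimates the transition
#' matrix (pooled over both series by default), simulates the
#' independent-chains entropy null, and returns per-year entropy `H_t`,
#' synchrony score `Phi_t` and one-sided p-values.
#'
#' @param series_a,series_b Annual series: either rows of an
#'   [annual_series()] data frame (columns `year`, `mean_volume_cm3`) or
#'   numeric vectors (optionally with a `years` attribute).  Year ranges
#'   must be equal and contiguous.
#' @param n_sims Null replicates (default 10000).
#' @param seed Optional RNG seed; the run is bitwise-reproducible given the
#'   seed.
#' @param alpha Significance level used by `summary()` (default 0.05).
#' @param pool_transitions Estimate one transition matrix from both state
#'   sequences pooled (default `TRUE`); otherwise series A alone is used.
#' @param init `"stationary"` (default) starts null chains from the
#'   stationary distribution of the fitted matrix; `"empirical"` uses the
#'   observed state frequencies.
#' @param keep_draws Keep all simulated null entropies in the result
#'   (needed for p-values; default `TRUE`).
#' @return A `synchrony_result` list: `times` (years t = 2..k-1), `H_t`,
#'   `phi_t`, `p_t`, `state_a`, `state_b`, `H_null_mean`, `null_quantiles`,
#'   `null_draws`, `transition_matrix`, `n_sims`, `seed`, `alpha`.
#' @export
run_synchrony <- function(series_a, series_b, n_sims = 10000L, seed = NULL,
                          alpha = 0.05, pool_transitions = TRUE,
                          init = c("stationary", "empirical"),
                          keep_draws = TRUE) {
  init <- match.arg(init)
  a <- series_values(series_a)
  b <- series_values(series_b)
  if (length(a$years) != length(b$years) || any(a$years != b$years))
    stop_eggsync("the two series must cover identical year ranges",
                 "eggsync_misaligned")
  if (any(diff(a$years) != 1))
    stop_eggsync("years must be contiguous", "eggsync_missing_year")
  sa <- classify_states(a$values)
  sb <- classify_states(b$values)
  seqs <- if (pool_transitions) list(sa, sb) else list(sa)
  tmat <- estimate_transition_matrix(seqs)
  init_probs <- if (init == "empirical") tabulate(c(sa, sb), 4) / (2 * length(sa)) else NULL
  null <- simulate_null(tmat, length = length(sa), n_sims = n_sims,
                        n_series = 2L, seed = seed, init_probs = init_probs)
  H_t <- occupancy_entropy(occupancy(sa, sb))
  if (null$H_null_mean > 0) {
    phi_t <- phi(H_t, null$H_null_mean)
  } else {
    phi_t <- rep(NA_real_, length(H_t))
  }
  p_t <- synchrony_pvalue(H_t, null$draws)
  out <- list(times = a$years[2:(length(a$years) - 1)],
              H_t = H_t, phi_t = phi_t, p_t = p_t,
              state_a = sa, state_b = sb,
              H_null_mean = null$H_null_mean,
              null_quantiles = quantile(null$draws, c(0.05, 0.5, 0.95),
                                        names = FALSE),
              null_draws = if (keep_draws) null$draws else NULL,
              transition_matrix = tmat,
              n_sims = as.integer(n_sims), seed = seed, alpha = alpha)
  class(out) <- "synchrony_result"
  out
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat("State-based Markov-chain synchrony analysis\n")
  cat(sprintf("  years: %d-%d (k-2 = %d interior points)\n",
              min(x$times), max(x$times), length(x$times)))
  cat(sprintf("  H_null_mean = %.4f nats (%d null sims)\n",
              x$H_null_mean, x$n_sims))
  sync_years <- x$times[abs(x$phi_t - 1) < 1e-12]
  cat(sprintf("  perfectly synchronised years (Phi_t = 1): %s\n",
              if (length(sync_years)) paste(sync_years, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
summary.synchrony_result <- function(object, ...) {
  df <- as.data.frame(object)
  df$significant <- df$p_t < object$alpha
  df
}

#' @export
as.data.frame.synchrony_result <- function(x, ...) {
  data.frame(year = x$times, H_t = x$H_t, phi_t = x$phi_t, p_t = x$p_t,
             state_a = x$state_a, state_b = x$state_b)
}

#' Write synchrony results
#'
#' `write_synchrony_csv` writes the per-year table
#' (`year,H_t,phi_t,p_t,state_a,state_b`); `synchrony_report` writes a JSON
#' run report with the null summary and transition matrix.
#'
#' @param result A `synchrony_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_synchrony_csv <- function(result, path) {
  write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synchrony_csv
#' @export
synchrony_report <- function(result, path = NULL) {
  rep <- list(
    n_sims = result$n_sims,
    seed = result$seed,
    H_null_mean = result$H_null_mean,
    null_quantiles = list(q05 = result$null_quantiles[1],
                          q50 = result$null_quantiles[2],
                          q95 = result$null_quantiles[3]),
    years_synchronized = result$times[abs(result$phi_t - 1) < 1e-12],
    transition_matrix = unclass(unname(result$transition_matrix))
  )
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(rep)
}
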