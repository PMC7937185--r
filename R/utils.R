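# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stage_seed <- function(seed, stage) {
  # Deterministic per-stage substream; offsets keep the derived seed < 2^31.
  offsets <- c(dataset = 11L, displacement = 23L, productivity = 37L,
               dhglm = 53L, syndrome = 71L, repeatability = 89L,
               chain = 101L)
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1009L + off
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)

stop_invariant <- function(msg) stop(msg, call. = FALSE)

#' Split-chain potential scale reduction factor
#'
#' Split-R-hat of Gelman et al.: each chain is halved, and the usual
#' between/within variance ratio is computed over the split halves.
#'
#' @param draws matrix of posterior draws, one column per chain.
#' @return scalar R-hat (NA if fewer than 4 draws per chain).
#' @keywords internal
#' @noRd
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= .Machine$double.eps) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size from autocorrelation (initial positive sequence)
#' @keywords internal
#' @noRd
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 8L) return(NA_real_)
  per_chain <- apply(draws, 2, function(x) {
    if (stats::var(x) <= .Machine$double.eps) return(length(x))
    ac <- stats::acf(x, lag.max = min(length(x) - 2L, 200L), plot = FALSE)$acf[-1]
    # sum consecutive pairs while positive (Geyer initial positive sequence)
    s <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    length(x) / (1 + 2 * s)
  })
  sum(per_chain)
}

#' Equal-tailed credible interval and posterior mean
#' @keywords internal
#' @noRd
post_summary <- function(x, level = 0.95) {
  alpha <- (1 - level) / 2
  q <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(mean = mean(x), lower = q[1], upper = q[2])
}

#' Check a square matrix is a valid correlation matrix
#' @keywords internal
#' @noRd
check_corr_matrix <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_invariant(sprintf("%s must be a square matrix", name))
  if (max(abs(m - t(m))) > tol)
    stop_invariant(sprintf("%s must be symmetric", name))
  if (max(abs(diag(m) - 1)) > tol)
    stop_invariant(sprintf("%s must have unit diagonal", name))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stop_invariant(sprintf("%s is not positive semidefinite (min eigenvalue %.3g)", name, min(ev)))
  invisible(TRUE)
}
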