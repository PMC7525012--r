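# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' Every generator draws from its own RNG stream keyed by (seed, name), so
#' adding or reordering generators never shifts another generator's output.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param name character stream label.
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483646)
}

# Evaluate `code` under a temporary RNG state seeded by (seed, name),
# restoring the caller's RNG state afterwards.
with_rng <- function(seed, name, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, name))
  force(code)
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Step-up adjustment: with p-values sorted ascending, the adjusted value at
#' rank i is `min_{j >= i} (m * p_(j) / j)`, capped at 1, mapped back to the
#' input order. Equals the raw p-value when `length(p) == 1`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (no NA).
#' @return numeric vector of BH-adjusted values, same order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("bh_fdr: NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("bh_fdr: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}

# Upper-tail hypergeometric probability P(X >= k) drawing `n` from a
# population of size `N` containing `K` successes. Identical to the one-sided
# (greater) Fisher exact p-value on the corresponding 2x2 table.
hyper_upper_tail <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Half-open interval overlap test used by brute-force oracles and small
# internal checks: [s1, e1) and [s2, e2) share >= 1 base.
overlaps_halfopen <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
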