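#' @keywords internal
"_PACKAGE"

# Complement map used whenever counts or bases are flipped from the
# reference (plus) strand onto the transcribed strand of a '-' gene.
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(b) unname(.COMPLEMENT[b])

#' Derive a child RNG seed from a master seed
#'
#' The simulator uses one master seed per run and derives an independent
#' child seed per sample (and per replicate), so that any individual sample
#' can be regenerated without replaying the whole cohort.  The derivation is
#' a fixed multiplicative congruential step, kept below 2^31 so the result
#' is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param index child index (integer >= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647 # 2^31 - 1
  x <- (abs(as.double(seed)) %% m)
  x <- (x * 48271 + 0.5 + as.double(index) * 2654435) %% m
  as.integer(floor(x))
}

# Multinomial split of n error reads uniformly over the three alternative
# bases, vectorised over positions (avoids per-position rmultinom calls).
split_errors_3 <- function(n) {
  c1 <- stats::rbinom(length(n), n, 1 / 3)
  rest <- n - c1
  c2 <- stats::rbinom(length(n), rest, 1 / 2)
  cbind(c1, c2, rest - c2, deparse.level = 0)
}

stop_if_not_fraction <- function(x, name, open = FALSE) {
  lo <- if (open) x > 0 else x >= 0
  hi <- if (open) x < 1 else x <= 1
  if (!all(is.finite(x) & lo & hi)) {
    stop(sprintf("'%s' must be in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}
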