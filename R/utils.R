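#' Derive a child RNG seed from a master seed and a label
#'
#' Stable string hash used to give each simulation scenario its own seed
#' stream: the same (master seed, label) pair always maps to the same child
#' seed, independently of the order scenarios are run in.
#'
#' @param master integer master seed.
#' @param label character scenario label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  x <- as.numeric(master) %% m
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    x <- (x * 31 + ch) %% m
  }
  as.integer(max(1, x))
}

# shared argument checkers -------------------------------------------------

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  lo <- if (open) x > 0 else x >= 0
  hi <- if (open) x < 1 else x <= 1
  if (!lo || !hi) {
    stop(sprintf("'%s' must lie in %s0, 1%s", name,
                 if (open) "(" else "[", if (open) ")" else "]"),
         call. = FALSE)
  }
  x
}

check_rho <- function(rho, allow_negative = FALSE, kmax = NULL) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho)) {
    stop("'rho' must be a single finite number", call. = FALSE)
  }
  if (rho >= 1) stop("'rho' must be < 1", call. = FALSE)
  if (!allow_negative && rho < 0) {
    stop("'rho' must be non-negative for the closed-form design effects",
         call. = FALSE)
  }
  if (allow_negative && !is.null(kmax) && kmax > 1 && rho <= -1 / (kmax - 1)) {
    stop(sprintf("'rho' must exceed -1/(K-1) = %.4f for a positive definite
                  exchangeable correlation matrix", -1 / (kmax - 1)),
         call. = FALSE)
  }
  rho
}

round2 <- function(x) round(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
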