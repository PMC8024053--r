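# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Draw n samples from MVN(mu, Sigma) via Cholesky (rows = draws).
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  L <- chol(Sigma)
  matrix(rnorm(n * p), n, p) %*% L + matrix(mu, n, p, byrow = TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## A column is treated as an indicator (left uncentered) when all values are 0/1.
is_indicator <- function(x) all(x %in% c(0, 1))

stop_jmels <- function(..., class) {
  stop(structure(class = c(class, "jmels_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
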