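#' @useDynLib morphoclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rlnorm rgamma rbeta rexp rpois dlnorm dgamma
#'   dexp dbeta dunif qgamma qlnorm qbeta median quantile sd var acf
#'   pgamma plnorm lm coef pf setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# deterministic child seed streams from one user seed; kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(i)) %% 2147483647L)
}
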