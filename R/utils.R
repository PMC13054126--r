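#' Draw from a truncated normal distribution
#'
#' Samples from N(mean, sd^2) restricted to (lower, upper). One-sided
#' truncation uses the inverse-CDF method, switching to an exponential
#' rejection sampler in the far tail so draws remain numerically stable for
#' standardized truncation points beyond 8. This is the device used to sample
#' latent liabilities of binary (threshold) traits given their observed
#' category.
#'
#' @param n number of draws.
#' @param mean,sd mean and standard deviation of the untruncated normal.
#' @param lower,upper truncation bounds (may be -Inf / Inf).
#' @return numeric vector of n draws inside (lower, upper).
#' @examples
#' set.seed(1)
#' x <- rtnorm(1000, mean = 0, sd = 2, lower = 0)
#' all(x > 0)
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (sd <= 0) stop("'sd' must be positive")
  if (lower >= upper) stop("'lower' must be below 'upper'")
  .rtnorm_cpp(as.integer(n), mean, sd, lower, upper)
}

# internal argument checks ---------------------------------------------------

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

.check_pd <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", name))
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop(sprintf("'%s' must be symmetric", name))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("'%s' must be positive-definite", name))
  invisible(m)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  eval.parent(substitute(expr))
}
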