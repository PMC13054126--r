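# Posterior summaries: heritability and correlation transforms of the
# stored (G0, R0) draws, shortest HPD intervals, the Geweke convergence
# diagnostic and the magnitude classifications customary in animal
# breeding.

#' Heritability
#'
#' h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2). The default method is a plain
#' (vectorized) transform of variance components; the `animal_model` method
#' applies it draw by draw to the stored chain of a trait and returns a
#' [posterior_summary()].
#'
#' @param sigma_a2 additive genetic variance (or an `animal_model` fit).
#' @param sigma_e2 residual variance (or, for fits, the trait name/index).
#' @param ... passed on to methods.
#' @return numeric heritability, or a posterior summary for fits.
#' @examples
#' heritability(6321.23, 28687.29)  # 0.18 at 2 dp
#' @export
heritability <- function(sigma_a2, sigma_e2, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.default <- function(sigma_a2, sigma_e2, ...) {
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0))
    stop("variance components must be non-negative")
  tot <- sigma_a2 + sigma_e2
  if (any(tot <= 0)) stop("total variance must be positive")
  sigma_a2 / tot
}

#' @rdname heritability
#' @param prob HPD probability for the summary.
#' @export
heritability.animal_model <- function(sigma_a2, sigma_e2 = 1, prob = 0.95, ...) {
  fit <- sigma_a2; trait <- sigma_e2
  j <- if (is.character(trait)) match(trait, fit$traits) else as.integer(trait)
  if (is.na(j)) stop("unknown trait")
  h2 <- heritability.default(fit$samples$G0[j, j, ], fit$samples$R0[j, j, ])
  posterior_summary(h2, prob = prob)
}

#' Posterior correlation from stored covariance draws
#'
#' r = cov(i,j) / sqrt(var_i var_j) applied draw by draw to the G0 (genetic)
#' or R0 (residual) chain, then summarized. Draws with a non-positive
#' variance are skipped (count reported in the summary's `n_skipped`).
#'
#' @param draws an `animal_model` fit or a t x t x S array of covariance
#'   draws.
#' @param trait_i,trait_j trait names or indices.
#' @param which "genetic" (G0 draws) or "residual" (R0 draws); ignored when
#'   `draws` is already an array.
#' @param prob HPD probability.
#' @return a [posterior_summary()] with an extra `n_skipped` field.
#' @export
genetic_correlation <- function(draws, trait_i, trait_j, which = "genetic",
                                prob = 0.95) {
  if (inherits(draws, "animal_model")) {
    arr <- if (which == "residual") draws$samples$R0 else draws$samples$G0
    i <- if (is.character(trait_i)) match(trait_i, draws$traits) else trait_i
    j <- if (is.character(trait_j)) match(trait_j, draws$traits) else trait_j
  } else {
    arr <- draws; i <- trait_i; j <- trait_j
  }
  if (is.na(i) || is.na(j)) stop("unknown trait")
  vi <- arr[i, i, ]; vj <- arr[j, j, ]; cij <- arr[i, j, ]
  ok <- vi > 0 & vj > 0
  r <- cij[ok] / sqrt(vi[ok] * vj[ok])
  out <- posterior_summary(r, prob = prob)
  out$n_skipped <- sum(!ok)
  out
}

#' @rdname genetic_correlation
#' @export
residual_correlation <- function(draws, trait_i, trait_j, prob = 0.95) {
  genetic_correlation(draws, trait_i, trait_j, which = "residual", prob = prob)
}

#' Shortest highest-posterior-density interval
#'
#' The shortest contiguous interval over the sorted sample containing
#' ceiling(prob * n) draws; ties are broken toward the lowest left
#' endpoint.
#'
#' @param samples numeric vector (>= 20 draws).
#' @param prob interval probability (default 0.95).
#' @return c(lower, upper).
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 20L) stop("need at least 20 samples for an HPD interval")
  if (prob <= 0 || prob >= 1) stop("'prob' must be in (0, 1)")
  s <- sort(samples)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  width <- s[seq.int(m, n)] - s[seq.int(1, n - m + 1)]
  k <- which.min(width)            # which.min takes the first (lowest) start
  c(s[k], s[k + m - 1])
}

# Spectral density at frequency zero via an AR(p) fit (Yule-Walker, AIC
# order selection): s0 = innovation variance / (1 - sum of AR coefficients)^2.
# Robust across iid and strongly autocorrelated chains.
.spectrum0 <- function(x) {
  fit <- try(stats::ar(x, aic = TRUE,
                       order.max = min(20L, floor(length(x) / 4))),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(var(x))
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' z = (mean of the first `frac_first` of the chain - mean of the last
#' `frac_last`) / sqrt(asymptotic variances), with each segment's variance
#' estimated from its spectral density at zero (AR-fitted, automatic order
#' selection). |z| > 1.96 flags nonstationarity at the 5% level.
#'
#' @param chain numeric vector of consecutive draws (>= 100).
#' @param frac_first,frac_last leading/trailing fractions (defaults 0.1 and
#'   0.5).
#' @return the z statistic.
#' @export
geweke_z <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  chain <- chain[!is.na(chain)]
  n <- length(chain)
  if (n < 100L) stop("need a chain of at least 100 draws")
  if (var(chain) == 0) stop("zero-variance chain: Geweke z undefined")
  n1 <- max(2L, floor(frac_first * n))
  n2 <- max(2L, floor(frac_last * n))
  x1 <- chain[seq_len(n1)]
  x2 <- chain[seq.int(n - n2 + 1L, n)]
  s1 <- .spectrum0(x1); s2 <- .spectrum0(x2)
  d <- mean(x1) - mean(x2)
  denom <- s1 / n1 + s2 / n2
  # degenerate segments (e.g. a chain stuck at one value early on) have zero
  # spectral variance: any mean shift is then infinitely significant
  if (denom <= 0) return(sign(d) * Inf)
  d / sqrt(denom)
}

#' Summarize a posterior sample
#'
#' Mean, SD, shortest HPD interval and (when the chain is long enough) the
#' Geweke z statistic.
#'
#' @param samples numeric vector of draws in chain order.
#' @param prob HPD probability.
#' @return list of class "posterior_summary": mean, sd, hpd_low, hpd_high,
#'   prob, n_samples, geweke_z.
#' @export
posterior_summary <- function(samples, prob = 0.95) {
  samples <- samples[!is.na(samples)]
  hpd <- hpd_interval(samples, prob)
  z <- if (length(samples) >= 100L && var(samples) > 0)
    geweke_z(samples) else NA_real_
  structure(list(mean = mean(samples), sd = sd(samples),
                 hpd_low = hpd[1], hpd_high = hpd[2], prob = prob,
                 n_samples = length(samples), geweke_z = z),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("mean %.4f  sd %.4f  %d%% HPD [%.4f, %.4f]  n %d  Geweke z %s\n",
              x$mean, x$sd, round(100 * x$prob), x$hpd_low, x$hpd_high,
              x$n_samples,
              if (is.na(x$geweke_z)) "NA" else sprintf("%.2f", x$geweke_z)))
  invisible(x)
}

#' Magnitude classification of genetic parameters
#'
#' Heritabilities: low below 0.20, moderate from 0.20 to 0.40, high above
#' 0.40 (Bourdon's bands). Correlations (classified on |r|): low below
#' 0.30, moderate from 0.30 to 0.70, high above 0.70 (Hill's bands). Band
#' edges are inclusive for "moderate".
#'
#' @param value estimate (vectorized); heritabilities must lie in
#'   \[0, 1\], correlations in \[-1, 1\].
#' @param kind "heritability" or "correlation".
#' @return character vector: "low", "moderate" or "high".
#' @export
classify_estimate <- function(value, kind = c("heritability", "correlation")) {
  kind <- match.arg(kind)
  if (kind == "heritability") {
    if (any(value < 0 | value > 1)) stop("heritability must be in [0, 1]")
    x <- value; lo <- 0.20; hi <- 0.40
  } else {
    if (any(value < -1 | value > 1)) stop("correlation must be in [-1, 1]")
    x <- abs(value); lo <- 0.30; hi <- 0.70
  }
  ifelse(x < lo, "low", ifelse(x <= hi, "moderate", "high"))
}
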