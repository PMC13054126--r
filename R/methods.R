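# S3 methods for fitted animal models.

#' @export
print.animal_model <- function(x, ...) {
  cat("Multi-trait Bayesian animal model (Gibbs sampling)\n")
  cat(sprintf("  traits: %s%s\n", paste(x$traits, collapse = ", "),
              if (length(x$binary))
                sprintf(" (binary: %s)", paste(x$binary, collapse = ", "))
              else ""))
  cat(sprintf("  %d animals, %d with records; genetic effect: %s\n",
              x$n_animals, x$n_records,
              if (x$genetic) "yes" else "no"))
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d -> %d stored draws\n",
              x$chain$n_iter, x$chain$burn_in, x$chain$thin, x$n_kept))
  invisible(x)
}

#' Posterior means of the (co)variance matrices
#'
#' @param object an `animal_model` fit.
#' @param ... unused.
#' @return list with posterior-mean G0 and R0.
#' @export
coef.animal_model <- function(object, ...) {
  list(G0 = apply(object$samples$G0, c(1, 2), mean),
       R0 = apply(object$samples$R0, c(1, 2), mean))
}

#' Summarize a fitted animal model
#'
#' Per trait: posterior summaries of the additive and residual variances and
#' of heritability (with Bourdon's magnitude class); per trait pair:
#' posterior summaries of the genetic and residual correlations (with
#' Hill's class).
#'
#' @param object an `animal_model` fit.
#' @param prob HPD probability (default 0.95).
#' @param ... unused.
#' @return object of class "summary.animal_model" with data.frames
#'   `heritability`, `genetic_correlations`, `residual_correlations`.
#' @export
summary.animal_model <- function(object, prob = 0.95, ...) {
  t <- length(object$traits)
  h2 <- do.call(rbind, lapply(seq_len(t), function(j) {
    va <- posterior_summary(object$samples$G0[j, j, ], prob)
    ve <- posterior_summary(object$samples$R0[j, j, ], prob)
    h <- heritability(object, j, prob = prob)
    data.frame(trait = object$traits[j], var_a = va$mean, var_e = ve$mean,
               h2 = h$mean, sd = h$sd, hpd_low = h$hpd_low,
               hpd_high = h$hpd_high, geweke_z = h$geweke_z,
               class = classify_estimate(min(max(h$mean, 0), 1),
                                         "heritability"),
               stringsAsFactors = FALSE)
  }))
  corr_tab <- function(which) {
    if (t < 2L) return(NULL)
    pairs <- which(upper.tri(diag(t)), arr.ind = TRUE)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      r <- genetic_correlation(object, i, j, which = which, prob = prob)
      data.frame(trait_i = object$traits[i], trait_j = object$traits[j],
                 r = r$mean, sd = r$sd, hpd_low = r$hpd_low,
                 hpd_high = r$hpd_high, geweke_z = r$geweke_z,
                 class = classify_estimate(max(-1, min(1, r$mean)),
                                           "correlation"),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(heritability = h2,
                 genetic_correlations = if (object$genetic) corr_tab("genetic"),
                 residual_correlations = corr_tab("residual"),
                 n_kept = object$n_kept, prob = prob),
            class = "summary.animal_model")
}

#' @export
print.summary.animal_model <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summaries from %d stored draws (HPD %d%%)\n\n",
              x$n_kept, round(100 * x$prob)))
  cat("Heritabilities and variance components:\n")
  print(format(x$heritability, digits = digits), row.names = FALSE)
  if (!is.null(x$genetic_correlations)) {
    cat("\nGenetic correlations:\n")
    print(format(x$genetic_correlations, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$residual_correlations)) {
    cat("\nResidual correlations:\n")
    print(format(x$residual_correlations, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Trace plots of variance-component chains
#'
#' @param x an `animal_model` fit.
#' @param what "h2" (per-trait heritability chains) or "variance"
#'   (additive and residual variances).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.animal_model <- function(x, what = c("h2", "variance"), ...) {
  what <- match.arg(what)
  t <- length(x$traits)
  if (what == "h2") {
    m <- sapply(seq_len(t), function(j)
      x$samples$G0[j, j, ] / (x$samples$G0[j, j, ] + x$samples$R0[j, j, ]))
    matplot(m, type = "l", lty = 1, xlab = "stored draw",
            ylab = expression(h^2), ...)
    legend("topright", legend = x$traits, col = seq_len(t), lty = 1, bty = "n")
  } else {
    m <- cbind(sapply(seq_len(t), function(j) x$samples$G0[j, j, ]),
               sapply(seq_len(t), function(j) x$samples$R0[j, j, ]))
    matplot(m, type = "l", lty = 1, xlab = "stored draw", ylab = "variance", ...)
    legend("topright", legend = c(paste0("Va_", x$traits),
                                  paste0("Ve_", x$traits)),
           col = seq_len(2 * t), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Posterior-mean breeding values
#'
#' @param fit an `animal_model` fit run with `store_effects = TRUE`.
#' @return data.frame: animal plus one posterior-mean EBV column per trait.
#' @export
breeding_values <- function(fit) {
  stopifnot(inherits(fit, "animal_model"))
  if (is.null(fit$breeding_values))
    stop("fit was run with store_effects = FALSE")
  data.frame(animal = rownames(fit$breeding_values),
             fit$breeding_values, row.names = NULL,
             stringsAsFactors = FALSE)
}
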