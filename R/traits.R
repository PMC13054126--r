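# Auxiliary performance phenotypes: ADG and metabolic weight from the
# weight-on-day regression, residual feed intake and residual gain from
# cohort-level Koch regressions, frame score from ultrasound/height
# measurements and the linear age adjustment of weight to 450 days.

#' Fit average daily gain by least squares
#'
#' Ordinary least-squares regression of weight on day-on-test: the intercept
#' estimates the initial weight and the slope the average daily gain (ADG).
#'
#' @param weights body weights, kg.
#' @param days day-on-test for each weight (>= 2 distinct values).
#' @return list of class "adg_fit": alpha (kg), beta (kg/day), residual_sd.
#' @export
fit_adg <- function(weights, days) {
  if (length(weights) != length(days)) stop("weights and days must match")
  keep <- complete.cases(weights, days)
  weights <- weights[keep]; days <- days[keep]
  if (length(unique(days)) < 2L)
    stop("need at least two distinct days to fit ADG")
  fit <- lm(weights ~ days)
  rsd <- if (fit$df.residual > 0)
    sqrt(sum(resid(fit)^2) / fit$df.residual) else NA_real_
  structure(list(alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
                 residual_sd = rsd),
            class = "adg_fit")
}

#' Mid-test metabolic weight
#'
#' (alpha + beta x days_on_test / 2)^0.75: the body weight predicted at the
#' middle of the test period, raised to the metabolic exponent 0.75 (Kleiber
#' scaling), as used in Koch-style feed-efficiency regressions.
#'
#' @param fit an [fit_adg()] result (or list with alpha and beta).
#' @param days_on_test length of the test period, days.
#' @return metabolic weight, kg^0.75.
#' @export
metabolic_weight <- function(fit, days_on_test) {
  mid <- fit$alpha + fit$beta * days_on_test / 2
  if (any(mid <= 0)) stop("mid-test weight must be positive")
  mid^0.75
}

#' Residual feed intake within a cohort
#'
#' RFI is the residual of the cohort-level OLS regression of dry-matter
#' intake on average daily gain and metabolic weight: the part of intake not
#' explained by growth and maintenance. Residuals sum to zero and are
#' orthogonal to both predictors within the cohort; lower RFI = more
#' efficient.
#'
#' @param dmi mean daily dry-matter intake per animal, kg/day.
#' @param adg average daily gain per animal, kg/day.
#' @param mw metabolic weight per animal, kg^0.75.
#' @param cohort optional factor splitting animals into regression cohorts
#'   (e.g. feed-efficiency test); each cohort is fitted separately.
#' @return per-animal RFI, kg DM/day.
#' @export
residual_feed_intake <- function(dmi, adg, mw, cohort = NULL) {
  .koch_residual(response = dmi, x1 = adg, x2 = mw, cohort = cohort,
                 what = "RFI")
}

#' Residual gain within a cohort
#'
#' RG is the residual of the cohort-level OLS regression of average daily
#' gain on dry-matter intake and metabolic weight; higher RG = faster growth
#' than intake and size predict.
#'
#' @inheritParams residual_feed_intake
#' @return per-animal RG, kg/day.
#' @export
residual_gain <- function(adg, dmi, mw, cohort = NULL) {
  .koch_residual(response = adg, x1 = dmi, x2 = mw, cohort = cohort,
                 what = "RG")
}

.koch_residual <- function(response, x1, x2, cohort, what) {
  n <- length(response)
  if (length(x1) != n || length(x2) != n)
    stop("inputs must have equal length")
  if (is.null(cohort)) cohort <- rep(1L, n)
  out <- rep(NA_real_, n)
  for (g in unique(cohort)) {
    idx <- which(cohort == g)
    if (length(idx) < 4L)
      stop(sprintf("%s cohort '%s' has fewer observations (%d) than the 4 the regression needs",
                   what, g, length(idx)))
    X <- cbind(1, x1[idx], x2[idx])
    if (qr(X)$rank < 3L)
      stop(sprintf("%s cohort '%s': collinear predictors, singular fit", what, g))
    fit <- lm.fit(X, response[idx])
    out[idx] <- fit$residuals
  }
  out
}

#' Frame score from ultrasound and height measurements
#'
#' Sex-specific multiple-regression frame equations:
#' males  -20.35 + 0.1305 REA + 0.2633 BFT - 0.5901 RFT + 0.1139 HH + 0.0056 AGE;
#' females -11.87 + 0.1316 REA - 0.2457 BFT - 0.6218 RFT + 0.1139 HH +
#' 0.0009507 AGE. All fat depths enter in centimetres (field records often
#' store rump fat in mm; convert before calling, or use `rft_mm`).
#'
#' @param sex "male" or "female" (vectorized alongside the predictors).
#' @param rea ribeye area, cm^2.
#' @param bft subcutaneous backfat thickness, cm.
#' @param rft rump fat thickness, cm (or give `rft_mm`).
#' @param hh hip height, cm.
#' @param age age at measurement, days.
#' @param rft_mm rump fat in millimetres, converted to cm internally
#'   (provide either `rft` or `rft_mm`).
#' @return numeric frame score.
#' @export
frame_score <- function(sex, rea, bft, rft = NULL, hh, age, rft_mm = NULL) {
  if (is.null(rft)) {
    if (is.null(rft_mm)) stop("provide 'rft' (cm) or 'rft_mm' (mm)")
    rft <- rft_mm / 10
  }
  n <- max(length(sex), length(rea), length(bft), length(rft), length(hh),
           length(age))
  sex <- rep_len(sex, n); rea <- rep_len(rea, n); bft <- rep_len(bft, n)
  rft <- rep_len(rft, n); hh <- rep_len(hh, n); age <- rep_len(age, n)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be \"male\" or \"female\"")
  male <- sex == "male"
  out <- numeric(n)
  out[male] <- -20.35 + 0.1305 * rea[male] + 0.2633 * bft[male] -
    0.5901 * rft[male] + 0.1139 * hh[male] + 0.0056 * age[male]
  out[!male] <- -11.87 + 0.1316 * rea[!male] - 0.2457 * bft[!male] -
    0.6218 * rft[!male] + 0.1139 * hh[!male] + 0.0009507 * age[!male]
  out
}

#' Adjust weight to 450 days of age
#'
#' Linear age adjustment: W450 = weight + ADG x (450 - age), with ADG taken
#' from the growth window around 450 days (the fit of [fit_adg()] on weights
#' recorded between 405 and 495 days of age is the recommended source).
#'
#' @param weight_kg observed weight, kg.
#' @param age_days age at weighing, days (405-495 recommended).
#' @param adg_window average daily gain over the adjustment window, kg/day.
#' @return adjusted weight at 450 days, kg.
#' @export
adjust_weight_450 <- function(weight_kg, age_days, adg_window) {
  if (anyNA(adg_window)) stop("ADG for the adjustment window is missing")
  weight_kg + adg_window * (450 - age_days)
}

#' Feed-efficiency traits from a feedlot log
#'
#' Per-animal ADG (weight-on-day regression), mid-test metabolic weight,
#' mean DMI, and cohort-level RFI and RG.
#'
#' @param log data.frame with columns animal, day, weight_kg, dmi_kg.
#' @param cohort optional named vector mapping animal -> test cohort; one
#'   cohort assumed when absent.
#' @return data.frame: animal, adg, mw075, dmi_mean, rfi, rg.
#' @export
efficiency_traits <- function(log, cohort = NULL) {
  need <- c("animal", "day", "weight_kg", "dmi_kg")
  if (!all(need %in% names(log)))
    stop("log needs columns: ", paste(need, collapse = ", "))
  ids <- unique(log$animal)
  per <- lapply(ids, function(id) {
    li <- log[log$animal == id, , drop = FALSE]
    fit <- fit_adg(li$weight_kg, li$day)
    dot <- diff(range(li$day))
    data.frame(animal = id, adg = fit$beta,
               mw075 = metabolic_weight(fit, dot),
               dmi_mean = mean(li$dmi_kg), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  coh <- if (is.null(cohort)) rep(1L, nrow(per)) else cohort[per$animal]
  per$rfi <- residual_feed_intake(per$dmi_mean, per$adg, per$mw075, coh)
  per$rg <- residual_gain(per$adg, per$dmi_mean, per$mw075, coh)
  per
}
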