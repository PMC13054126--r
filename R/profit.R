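# Economic feedlot phenotypes: accumulated profitability (AFP, $ over the
# evaluation window) and profit per arroba of carcass gain (PFT). Carcass
# output is expressed in arrobas (15 kg of carcass); live weight is first
# shrunk (fasting shrink) and converted through the sex-specific carcass
# dressing percentage.

#' Economic configuration for the profit engine
#'
#' Prices and carcass conversion constants, standardized across animals the
#' way commercial feedlot evaluations standardize them (one diet price, one
#' daily overhead and one arroba price for every batch).
#'
#' @param diet_price_kg diet cost, $ per kg of dry matter.
#' @param feedlot_daily_overhead non-feed cost, $ per animal-day.
#' @param arroba_price price paid per arroba (15 kg of carcass), $.
#' @param dressing_pct_female,dressing_pct_male carcass dressing, percent of
#'   shrunk body weight.
#' @param shrink_factor fasting shrink: shrunk body weight as a fraction of
#'   live weight.
#' @param kg_per_arroba kilograms of carcass per arroba.
#' @return an object of class "econ_config".
#' @export
econ_config <- function(diet_price_kg = 1.30, feedlot_daily_overhead = 2.06,
                        arroba_price = 300,
                        dressing_pct_female = 55.34,
                        dressing_pct_male = 58.55,
                        shrink_factor = 0.96, kg_per_arroba = 15) {
  if (diet_price_kg < 0 || feedlot_daily_overhead < 0 || arroba_price < 0)
    stop("prices must be non-negative")
  for (d in c(dressing_pct_female, dressing_pct_male))
    if (d <= 0 || d >= 100) stop("dressing percentages must be in (0, 100)")
  if (shrink_factor <= 0 || shrink_factor > 1)
    stop("'shrink_factor' must be in (0, 1]")
  if (kg_per_arroba <= 0) stop("'kg_per_arroba' must be positive")
  structure(list(diet_price_kg = diet_price_kg,
                 feedlot_daily_overhead = feedlot_daily_overhead,
                 arroba_price = arroba_price,
                 dressing_pct_female = dressing_pct_female,
                 dressing_pct_male = dressing_pct_male,
                 shrink_factor = shrink_factor,
                 kg_per_arroba = kg_per_arroba),
            class = "econ_config")
}

#' Shrunk body weight
#'
#' Live weight after the fasting shrink (default 96% of body weight).
#'
#' @param weight_kg live body weight, kg (vectorized).
#' @param shrink_factor shrink fraction.
#' @return shrunk body weight, kg.
#' @export
shrunk_body_weight <- function(weight_kg, shrink_factor = 0.96) {
  if (any(weight_kg < 0, na.rm = TRUE)) stop("weight must be non-negative")
  shrink_factor * weight_kg
}

#' Accumulated arrobas of carcass
#'
#' Converts shrunk body weight to carcass arrobas:
#' sbw x dressing/100 / kg_per_arroba.
#'
#' @param sbw_kg shrunk body weight, kg.
#' @param dressing_pct carcass dressing, percent (0-100, exclusive).
#' @param kg_per_arroba kg of carcass per arroba.
#' @return accumulated arrobas.
#' @export
accumulated_arroba <- function(sbw_kg, dressing_pct, kg_per_arroba = 15) {
  if (any(sbw_kg < 0, na.rm = TRUE)) stop("sbw must be non-negative")
  if (any(dressing_pct <= 0 | dressing_pct >= 100))
    stop("dressing must be in (0, 100)")
  sbw_kg * dressing_pct / 100 / kg_per_arroba
}

#' Daily and total arroba gain from an accumulated-arroba series
#'
#' Daily gains are first differences of the accumulated series (the day-1
#' gain is zero by convention); the total gain is the last minus the first
#' accumulated value, which the daily gains telescope to exactly.
#'
#' @param accumulated per-day accumulated arrobas (length >= 2).
#' @return list with `daily` (same length as input, first element 0) and
#'   `total`.
#' @export
arroba_gain_series <- function(accumulated) {
  if (length(accumulated) < 2L)
    stop("need at least two days of accumulated arrobas")
  daily <- c(0, diff(accumulated))
  list(daily = daily, total = accumulated[length(accumulated)] - accumulated[1])
}

#' Daily feeding cost
#'
#' DMI x diet price + daily overhead.
#'
#' @param dmi_kg dry-matter intake, kg/day (vectorized).
#' @param cfg an [econ_config()].
#' @return cost, $/day.
#' @export
daily_cost <- function(dmi_kg, cfg = econ_config()) {
  if (any(dmi_kg < 0, na.rm = TRUE)) stop("DMI must be non-negative")
  dmi_kg * cfg$diet_price_kg + cfg$feedlot_daily_overhead
}

#' Daily revenue
#'
#' Arroba price x daily arroba gain; negative on days the animal loses
#' carcass weight.
#'
#' @param arroba_gain_day arroba gain of the day (vectorized).
#' @param cfg an [econ_config()].
#' @return revenue, $/day.
#' @export
daily_revenue <- function(arroba_gain_day, cfg = econ_config()) {
  cfg$arroba_price * arroba_gain_day
}

#' Profit series and accumulated profitability for one animal
#'
#' Runs the full chain live weight -> shrunk weight -> accumulated arrobas ->
#' daily gains -> daily revenue/cost/profit, and accumulates. AFP is the sum
#' of daily profits over the window and equals total revenue minus total
#' cost by construction.
#'
#' @param day integer day index (strictly increasing, length >= 2).
#' @param weight_kg live weights, kg.
#' @param dmi_kg dry-matter intakes, kg/day.
#' @param sex "male" or "female" (selects the carcass dressing).
#' @param cfg an [econ_config()].
#' @return object of class "profit_result": list with afp, total_revenue,
#'   total_cost, total_arroba_gain, pft ($/arroba; NA when the total gain is
#'   zero) and the daily series (arroba, gain, revenue, cost, profit).
#' @export
profit_series <- function(day, weight_kg, dmi_kg, sex, cfg = econ_config()) {
  if (length(day) < 2L) stop("need at least two daily records")
  if (is.unsorted(day, strictly = TRUE)) stop("days must be strictly increasing")
  if (length(weight_kg) != length(day) || length(dmi_kg) != length(day))
    stop("day, weight_kg and dmi_kg must have equal length")
  if (!sex %in% c("male", "female"))
    stop("unknown sex '", sex, "': must be \"male\" or \"female\"")
  dressing <- if (sex == "male") cfg$dressing_pct_male else cfg$dressing_pct_female
  sbw <- shrunk_body_weight(weight_kg, cfg$shrink_factor)
  acc <- accumulated_arroba(sbw, dressing, cfg$kg_per_arroba)
  gain <- arroba_gain_series(acc)
  revenue <- daily_revenue(gain$daily, cfg)
  cost <- daily_cost(dmi_kg, cfg)
  profit <- revenue - cost
  afp <- sum(profit)
  res <- list(afp = afp,
              total_revenue = sum(revenue),
              total_cost = sum(cost),
              total_arroba_gain = gain$total,
              pft = if (abs(gain$total) < 1e-12) NA_real_ else afp / gain$total,
              daily = data.frame(day = day, arroba = acc,
                                 arroba_gain = gain$daily,
                                 revenue = revenue, cost = cost,
                                 profit = profit))
  class(res) <- "profit_result"
  res
}

#' @export
print.profit_result <- function(x, ...) {
  cat(sprintf(
    "Feedlot profit over %d days: AFP = %.2f $ (revenue %.2f - cost %.2f), %s\n",
    nrow(x$daily), x$afp, x$total_revenue, x$total_cost,
    if (is.na(x$pft)) "PFT undefined (zero gain)"
    else sprintf("PFT = %.2f $/arroba (%.2f $/kg basis / 15)", x$pft, x$pft / 15)))
  invisible(x)
}

#' Profit per arroba gained
#'
#' PFT = AFP / total arroba gain. Undefined (NA) when the total gain is
#' zero; in batch mode the phenotype is reported missing rather than raising
#' an error.
#'
#' @param result a [profit_series()] result.
#' @param per_kg if TRUE, return the per-kilogram value (divide by 15).
#' @return profit per arroba (or per kg) of carcass gain.
#' @export
profit_per_gain <- function(result, per_kg = FALSE) {
  stopifnot(inherits(result, "profit_result"))
  if (is.na(result$pft)) return(NA_real_)
  if (per_kg) result$pft / 15 else result$pft
}

#' Batch profit phenotypes from a feedlot log
#'
#' Applies [profit_series()] to every animal of a long-format feedlot log.
#'
#' @param log data.frame with columns animal, day, weight_kg, dmi_kg.
#' @param meta data.frame with columns animal and sex.
#' @param cfg an [econ_config()].
#' @param window optional c(first, last) day window; defaults to each
#'   animal's full log.
#' @return data.frame: animal, afp, pft, total_cost, total_revenue,
#'   total_arroba_gain, n_days.
#' @export
profit_phenotypes <- function(log, meta, cfg = econ_config(), window = NULL) {
  need <- c("animal", "day", "weight_kg", "dmi_kg")
  if (!all(need %in% names(log)))
    stop("log needs columns: ", paste(need, collapse = ", "))
  if (!all(c("animal", "sex") %in% names(meta)))
    stop("meta needs columns animal and sex")
  sx <- setNames(meta$sex, meta$animal)
  ids <- unique(log$animal)
  miss <- setdiff(ids, names(sx))
  if (length(miss)) stop("no sex metadata for: ", paste(head(miss), collapse = ", "))
  rows <- lapply(ids, function(id) {
    li <- log[log$animal == id, , drop = FALSE]
    li <- li[order(li$day), , drop = FALSE]
    if (!is.null(window))
      li <- li[li$day >= window[1] & li$day <= window[2], , drop = FALSE]
    if (nrow(li) < 2L)
      return(data.frame(animal = id, afp = NA_real_, pft = NA_real_,
                        total_cost = NA_real_, total_revenue = NA_real_,
                        total_arroba_gain = NA_real_, n_days = nrow(li)))
    r <- profit_series(li$day, li$weight_kg, li$dmi_kg, sx[[id]], cfg)
    data.frame(animal = id, afp = r$afp, pft = r$pft,
               total_cost = r$total_cost, total_revenue = r$total_revenue,
               total_arroba_gain = r$total_arroba_gain, n_days = nrow(li))
  })
  do.call(rbind, rows)
}
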