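#' Parameters of the Roberts & Lowe conception ledger
#'
#' The ledger estimates annual conceptions among married women aged 20-29 in
#' England and Wales in 1971 from two reliable counts (women, births) and
#' five speculative rates: coital frequency, the unprotected fraction of
#' coital acts, menstrual cycle length, fertile-period length and the
#' probability of fertilisation per fertile-period act. Defaults are the
#' original published values.
#'
#' @param n_women number of married women aged 20-29 (census count).
#' @param coital_freq acts of coitus per woman per week.
#' @param weeks_per_year weeks per year (52).
#' @param unprotected_frac proportion of coital acts that are unprotected.
#' @param cycle_len menstrual cycle length in days.
#' @param fertile_len fertile period length in days; must not exceed
#'   `cycle_len`.
#' @param p_fert probability of fertilisation for an unprotected act during
#'   the fertile period.
#' @param n_births infants born (live and still) in the year.
#' @return an object of class `conception_params`.
#' @seealso [conception_ledger()], [adjusted_params()],
#'   [simulate_sensitivity()]
#' @export
roberts_lowe_params <- function(n_women = 2437000, coital_freq = 2,
                                weeks_per_year = 52, unprotected_frac = 0.25,
                                cycle_len = 28, fertile_len = 2,
                                p_fert = 0.5, n_births = 505000) {
  assert_count(n_women, "n_women")
  assert_count(n_births, "n_births")
  assert_count(weeks_per_year, "weeks_per_year", positive = TRUE)
  for (nm in c("coital_freq", "unprotected_frac", "cycle_len", "fertile_len",
               "p_fert")) {
    assert_count(get(nm), nm, positive = TRUE)
  }
  assert_probability(unprotected_frac, "unprotected_frac")
  assert_probability(p_fert, "p_fert")
  if (fertile_len > cycle_len) {
    stop("'fertile_len' cannot exceed 'cycle_len'", call. = FALSE)
  }
  structure(list(n_women = n_women, coital_freq = coital_freq,
                 weeks_per_year = weeks_per_year,
                 unprotected_frac = unprotected_frac, cycle_len = cycle_len,
                 fertile_len = fertile_len, p_fert = p_fert,
                 n_births = n_births),
            class = "conception_params")
}

#' Evaluate the conception ledger
#'
#' Chains the ledger arithmetic: annual coital acts, unprotected acts, acts
#' during the fertile period (fraction `fertile_len / cycle_len` of
#' unprotected acts), fertilised ova, and embryos lost (ova minus births).
#' All intermediates are returned unrounded.
#'
#' @param p a [roberts_lowe_params()] object.
#' @return an object of class `conception_ledger`: a named list with
#'   `acts_per_year`, `unprotected_acts`, `fertile_period_acts`,
#'   `fertilised_ova`, `embryos_lost` and `loss_fraction`
#'   (= lost / ova, a proportion; negative when births exceed estimated
#'   conceptions).
#' @export
#' @examples
#' conception_ledger(roberts_lowe_params())$loss_fraction  # ~0.78
conception_ledger <- function(p) {
  stopifnot(inherits(p, "conception_params"))
  acts <- p$n_women * p$coital_freq * p$weeks_per_year
  unprotected <- acts * p$unprotected_frac
  fertile <- unprotected * (p$fertile_len / p$cycle_len)
  ova <- fertile * p$p_fert
  if (!is.finite(ova) || ova <= 0) {
    stop("degenerate parameter set: no fertilised ova, loss undefined",
         call. = FALSE)
  }
  lost <- ova - p$n_births
  structure(list(acts_per_year = acts, unprotected_acts = unprotected,
                 fertile_period_acts = fertile, fertilised_ova = ova,
                 embryos_lost = lost, loss_fraction = lost / ova),
            class = "conception_ledger")
}

#' @export
print.conception_ledger <- function(x, ...) {
  cat("Conception ledger (per year):\n")
  cat(sprintf("  acts of coitus          %15.0f\n", x$acts_per_year))
  cat(sprintf("  unprotected acts        %15.0f\n", x$unprotected_acts))
  cat(sprintf("  fertile-period acts     %15.0f\n", x$fertile_period_acts))
  cat(sprintf("  fertilised ova          %15.0f\n", x$fertilised_ova))
  cat(sprintf("  embryos lost            %15.0f\n", x$embryos_lost))
  cat(sprintf("  loss fraction           %15.1f%%\n", 100 * x$loss_fraction))
  invisible(x)
}

#' Deterministic scenario adjustment of ledger parameters
#'
#' Multiplies the four non-cycle speculative rates (coital frequency,
#' unprotected fraction, fertile-period length, fertilisation probability)
#' by `speculative_factor` and cycle length by `cycle_factor`, leaving the
#' reliable counts untouched. No intermediate rounding is applied: the low
#' scenario works with an unprotected fraction of 0.1875 and a cycle of
#' 30.8 days even though summary tables display "19%" and "31".
#'
#' @param p a [roberts_lowe_params()] object.
#' @param speculative_factor multiplier for the four speculative rates
#'   (0.75 for the low scenario, 1.25 for the high).
#' @param cycle_factor multiplier for cycle length (1.10 low, 0.90 high;
#'   note the factors move in opposite directions because a longer cycle
#'   dilutes the fertile window).
#' @return a new `conception_params` object.
#' @export
#' @examples
#' conception_ledger(adjusted_params(roberts_lowe_params(), 0.75, 1.10))
adjusted_params <- function(p, speculative_factor, cycle_factor) {
  stopifnot(inherits(p, "conception_params"))
  if (speculative_factor <= 0 || cycle_factor <= 0) {
    stop("adjustment factors must be positive", call. = FALSE)
  }
  roberts_lowe_params(
    n_women = p$n_women,
    coital_freq = p$coital_freq * speculative_factor,
    weeks_per_year = p$weeks_per_year,
    unprotected_frac = p$unprotected_frac * speculative_factor,
    cycle_len = p$cycle_len * cycle_factor,
    fertile_len = p$fertile_len * speculative_factor,
    p_fert = p$p_fert * speculative_factor,
    n_births = p$n_births
  )
}

# Draw n sets of the five speculative parameters, independently Normal with
# sd = cv * mean; biologically impossible draws (non-positive values,
# probabilities above 1, fertile period longer than the cycle) are redrawn.
# Returns the draws plus the redraw count.
sample_speculative <- function(p, n, cv) {
  means <- c(coital_freq = p$coital_freq, unprotected_frac = p$unprotected_frac,
             cycle_len = p$cycle_len, fertile_len = p$fertile_len,
             p_fert = p$p_fert)
  draw <- function(n) {
    vapply(means, function(mu) stats::rnorm(n, mu, cv * mu), numeric(n))
  }
  m <- draw(n)
  if (n == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(means)))
  invalid <- function(m) {
    m[, "coital_freq"] <= 0 | m[, "unprotected_frac"] <= 0 |
      m[, "unprotected_frac"] > 1 | m[, "cycle_len"] <= 0 |
      m[, "fertile_len"] <= 0 | m[, "fertile_len"] > m[, "cycle_len"] |
      m[, "p_fert"] <= 0 | m[, "p_fert"] > 1
  }
  bad <- invalid(m)
  n_redrawn <- 0L
  while (any(bad)) {
    k <- sum(bad)
    n_redrawn <- n_redrawn + k
    repl <- draw(k)
    if (k == 1L) repl <- matrix(repl, nrow = 1,
                                dimnames = list(NULL, names(means)))
    m[bad, ] <- repl
    bad <- invalid(m)
  }
  list(draws = m, n_redrawn = n_redrawn)
}

# Loss percentages for a matrix of speculative draws under fixed reliable
# values. Losses are not truncated: draws with fewer estimated ova than
# births yield negative loss.
loss_from_draws <- function(p, draws) {
  ova <- p$n_women * draws[, "coital_freq"] * p$weeks_per_year *
    draws[, "unprotected_frac"] *
    (draws[, "fertile_len"] / draws[, "cycle_len"]) * draws[, "p_fert"]
  100 * (ova - p$n_births) / ova
}

#' Monte Carlo sensitivity analysis of the conception ledger
#'
#' Each of the five speculative parameters is drawn independently from a
#' normal distribution centred on its ledger value with coefficient of
#' variation `cv` (no covariance). Per repetition, `n_records` parameter
#' sets are drawn and the embryo-loss percentage evaluated for each; the
#' mean, median and percentile bounds of the losses are recorded, then
#' averaged over `n_reps` repetitions. Draws outside the biologically
#' meaningful domain (non-positive values, probabilities above 1, fertile
#' period exceeding the cycle) are rejected and redrawn; the count is
#' reported. Loss values themselves are not truncated, so the left tail
#' extends below zero when sampled ova fall short of births.
#'
#' @param p a [roberts_lowe_params()] object.
#' @param cv coefficient of variation applied to each speculative value
#'   (default 0.20).
#' @param n_records parameter sets per repetition (default 10000).
#' @param n_reps repetitions (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param percentiles lower/upper percentile bounds summarised per
#'   repetition, as percentages (default `c(2.5, 97.5)`).
#' @return an object of class `sensitivity_result`: a list with
#'   `mean_of_means`, `mean_of_medians`, `mean_lower_percentile`,
#'   `mean_upper_percentile` (all loss percentages), `n_redrawn`, the
#'   configuration, and `per_rep`, a data frame of the per-repetition
#'   summaries.
#' @export
#' @examples
#' simulate_sensitivity(roberts_lowe_params(), n_records = 1000, n_reps = 20,
#'                      seed = 1)
simulate_sensitivity <- function(p, cv = 0.20, n_records = 10000,
                                 n_reps = 1000, seed = NULL,
                                 percentiles = c(2.5, 97.5)) {
  stopifnot(inherits(p, "conception_params"))
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  assert_count(n_records, "n_records", positive = TRUE)
  assert_count(n_reps, "n_reps", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  per_rep <- matrix(NA_real_, nrow = n_reps, ncol = 4,
                    dimnames = list(NULL, c("mean", "median", "lower", "upper")))
  n_redrawn <- 0L
  if (cv == 0) {
    loss <- 100 * conception_ledger(p)$loss_fraction
    per_rep[, ] <- loss
  } else {
    for (r in seq_len(n_reps)) {
      s <- sample_speculative(p, n_records, cv)
      n_redrawn <- n_redrawn + s$n_redrawn
      loss <- loss_from_draws(p, s$draws)
      qq <- percentile(loss, percentiles / 100)
      per_rep[r, ] <- c(mean(loss), stats::median(loss), qq[1], qq[2])
    }
  }
  structure(list(
    mean_of_means = mean(per_rep[, "mean"]),
    mean_of_medians = mean(per_rep[, "median"]),
    mean_lower_percentile = mean(per_rep[, "lower"]),
    mean_upper_percentile = mean(per_rep[, "upper"]),
    n_redrawn = n_redrawn,
    cv = cv, n_records = n_records, n_reps = n_reps,
    percentiles = percentiles,
    per_rep = as.data.frame(per_rep)
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Monte Carlo sensitivity (%d reps x %d records, CV = %.2f):\n",
              x$n_reps, x$n_records, x$cv))
  cat(sprintf("  mean of means      %6.1f%%\n", x$mean_of_means))
  cat(sprintf("  mean of medians    %6.1f%%\n", x$mean_of_medians))
  cat(sprintf("  mean %4.1fth pctile %6.1f%%\n", x$percentiles[1],
              x$mean_lower_percentile))
  cat(sprintf("  mean %4.1fth pctile %6.1f%%\n", x$percentiles[2],
              x$mean_upper_percentile))
  cat(sprintf("  redrawn parameter sets: %d\n", x$n_redrawn))
  invisible(x)
}

#' Draw a pooled sample of simulated embryo-loss values
#'
#' Convenience wrapper for histogram-style output: a single pool of `n`
#' loss percentages under the same sampling scheme as
#' [simulate_sensitivity()].
#'
#' @inheritParams simulate_sensitivity
#' @param n number of loss values to draw.
#' @return numeric vector of loss percentages.
#' @export
draw_loss_values <- function(p, n, cv = 0.20, seed = NULL) {
  stopifnot(inherits(p, "conception_params"))
  assert_count(n, "n", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  s <- sample_speculative(p, n, cv)
  loss_from_draws(p, s$draws)
}

#' Bin loss values into a half-open histogram
#'
#' @param losses numeric vector of loss percentages.
#' @param bin_width bin width in percentage points (default 0.25).
#' @return data frame with `bin_start`, `bin_end` and `frequency`; bins are
#'   half-open `[start, end)` and frequencies sum to `length(losses)`.
#'   Empty input yields a zero-row table.
#' @export
export_loss_histogram <- function(losses, bin_width = 0.25) {
  if (bin_width <= 0) stop("'bin_width' must be positive", call. = FALSE)
  if (length(losses) == 0) {
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      frequency = integer(0)))
  }
  k <- floor(losses / bin_width)
  tab <- table(k)
  idx <- as.numeric(names(tab))
  data.frame(bin_start = idx * bin_width,
             bin_end = (idx + 1) * bin_width,
             frequency = as.integer(tab))
}
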