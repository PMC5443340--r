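#' Conditional stage probabilities of human reproduction
#'
#' A single menstrual cycle is decomposed into five conditional stages:
#' sperm-ovum co-localisation (`pi_soc`), fertilisation (`pi_fert`),
#' implantation as marked by hCG elevation (`pi_hcg`), progression to
#' clinical recognition (`pi_clin`) and live birth (`pi_lb`). Each is the
#' probability of the stage succeeding given that all upstream stages
#' succeeded, so cumulative products of consecutive stages are per-cycle
#' fecundabilities.
#'
#' @param pi_soc probability that sperm and ovum co-localise in the cycle.
#' @param pi_fert probability of fertilisation given co-localisation.
#' @param pi_hcg probability a fertilised ovum implants (detectable hCG).
#' @param pi_clin probability an implanted embryo reaches clinical
#'   recognition.
#' @param pi_lb probability a clinical pregnancy ends in live birth.
#' @return an object of class `stage_probabilities`: a named list of the
#'   five probabilities.
#' @seealso [fecundabilities()], [loss_fractions()]
#' @export
#' @examples
#' stage_probabilities(0.9, 30 / 36 / 0.9, 21 / 30, 15 / 21, 0.8)
stage_probabilities <- function(pi_soc, pi_fert, pi_hcg, pi_clin, pi_lb) {
  p <- list(pi_soc = pi_soc, pi_fert = pi_fert, pi_hcg = pi_hcg,
            pi_clin = pi_clin, pi_lb = pi_lb)
  for (nm in names(p)) assert_probability(p[[nm]], nm)
  structure(p, class = "stage_probabilities")
}

#' @export
print.stage_probabilities <- function(x, ...) {
  cat("Conditional stage probabilities (per cycle):\n")
  cat(sprintf("  %-8s %.4f\n", names(x), unlist(x)), sep = "")
  invisible(x)
}

#' Per-cycle fecundabilities from stage probabilities
#'
#' Cumulative products of the conditional stage probabilities give the four
#' per-cycle fecundabilities: total (any fertilisation), detectable (hCG
#' elevation), apparent (clinical pregnancy) and effective (live birth).
#'
#' @param p a [stage_probabilities()] object.
#' @return an object of class `fecundabilities` with elements `fec_tot`,
#'   `fec_hcg`, `fec_clin` and `fec_lb`, each a per-cycle probability.
#'   They are non-increasing in that order.
#' @export
#' @examples
#' fecundabilities(stage_probabilities(0.9, 30 / 36 / 0.9, 0.7, 15 / 21, 0.8))
fecundabilities <- function(p) {
  stopifnot(inherits(p, "stage_probabilities"))
  fec_tot <- p$pi_soc * p$pi_fert
  structure(list(
    fec_tot  = fec_tot,
    fec_hcg  = fec_tot * p$pi_hcg,
    fec_clin = fec_tot * p$pi_hcg * p$pi_clin,
    fec_lb   = fec_tot * p$pi_hcg * p$pi_clin * p$pi_lb
  ), class = "fecundabilities")
}

#' Embryo-loss fractions implied by stage probabilities
#'
#' The probability that a fertilised ovum perishes before implantation is
#' `1 - pi_hcg`; the probability it perishes before clinical recognition is
#' `1 - pi_hcg * pi_clin`.
#'
#' @inheritParams fecundabilities
#' @return named numeric vector with elements `preimplantation` and
#'   `preclinical`, both in \[0, 1\] with `preclinical >= preimplantation`.
#' @export
loss_fractions <- function(p) {
  stopifnot(inherits(p, "stage_probabilities"))
  c(preimplantation = 1 - p$pi_hcg,
    preclinical     = 1 - p$pi_hcg * p$pi_clin)
}

#' Life table of egg survival over the first two weeks
#'
#' Chains per-cycle fertilisation and the two post-fertilisation transition
#' probabilities into survivor counts per `cycles_start` cycles: cycles at
#' risk, fertilised eggs (week 0), implanted embryos (week 1) and embryos
#' surviving to the first missed period (week 2).
#'
#' @param fert_per_cycle probability of fertilisation per cycle
#'   (`pi_soc * pi_fert`).
#' @param pi_hcg probability a fertilised egg implants.
#' @param pi_clin probability an implanted embryo survives to the missed
#'   period.
#' @param cycles_start number of cycles at risk (default 100).
#' @return a data frame of class `egg_life_table` with one row per stage and
#'   columns `stage`, `survivors` (unrounded), `survivors_rounded` and
#'   `transition_probability` (probability of surviving from the previous
#'   stage; `NA` for the first row). Rounding is display-only; all chaining
#'   uses unrounded values.
#' @export
#' @examples
#' build_egg_life_table(30 / 36, 21 / 30, 15 / 21)
build_egg_life_table <- function(fert_per_cycle, pi_hcg, pi_clin,
                                 cycles_start = 100) {
  assert_probability(pi_hcg, "pi_hcg")
  assert_probability(pi_clin, "pi_clin")
  assert_count(cycles_start, "cycles_start", positive = TRUE)
  if (!is.numeric(fert_per_cycle) || fert_per_cycle < 0) {
    stop("'fert_per_cycle' must be a non-negative number", call. = FALSE)
  }
  trans <- c(NA_real_, fert_per_cycle, pi_hcg, pi_clin)
  survivors <- cycles_start * cumprod(c(1, fert_per_cycle, pi_hcg, pi_clin))
  out <- data.frame(
    stage = c("cycles", "fertilised_eggs", "implanted_embryos",
              "missed_first_period"),
    survivors = survivors,
    survivors_rounded = round_half_up(survivors),
    transition_probability = trans,
    stringsAsFactors = FALSE
  )
  class(out) <- c("egg_life_table", "data.frame")
  out
}

#' Two-component exponential pregnancy-survival model
#'
#' Boklage's descriptive model of embryo survival as a mixture of a rapidly
#' and a slowly decaying exponential,
#' `P(t) = w_fast * exp(-r_fast * t) + w_slow * exp(-r_slow * t)`, with `t`
#' in days post-fertilisation. The default coefficients are the published
#' ones (weights 0.73/0.27, rates 0.155 and 0.00042 per day). The model is
#' evaluated as printed; no re-fitting is attempted.
#'
#' @param w_fast,w_slow mixture weights; must sum to 1.
#' @param r_fast,r_slow non-negative decay rates per day.
#' @return an object of class `boklage_model`.
#' @seealso [boklage_survival()]
#' @export
boklage_model <- function(w_fast = 0.73, r_fast = 0.155,
                          w_slow = 0.27, r_slow = 0.00042) {
  if (abs(w_fast + w_slow - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  if (r_fast < 0 || r_slow < 0) stop("decay rates must be >= 0", call. = FALSE)
  structure(list(w_fast = w_fast, r_fast = r_fast,
                 w_slow = w_slow, r_slow = r_slow),
            class = "boklage_model")
}

#' Evaluate the two-exponential survival model
#'
#' @param t time in days post-fertilisation; vectorised, must be >= 0.
#' @param model a [boklage_model()].
#' @return survival probabilities at each `t`.
#' @export
#' @examples
#' boklage_survival(c(0, 21, 100))
boklage_survival <- function(t, model = boklage_model()) {
  stopifnot(inherits(model, "boklage_model"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  model$w_fast * exp(-model$r_fast * t) + model$w_slow * exp(-model$r_slow * t)
}
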