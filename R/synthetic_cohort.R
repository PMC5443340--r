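#' Configuration for a synthetic hCG cohort study
#'
#' Emulates the design of the prospective hCG studies: couples intending to
#' conceive are monitored cycle by cycle until the first hCG-detected
#' pregnancy (then resolved to clinical recognition and live birth) or
#' until `max_cycles`, when they are censored. The cohort is a latent
#' two-point mixture of normally fertile and sub-fertile couples, the
#' structure identified by re-analysis of the large hCG cohorts. Defaults
#' are Wilcox-like: 28.1% sub-fertile; fertile couples with
#' `pi_soc = 0.80` (sub-daily coital frequency), per-cycle hCG
#' fecundability 43.2% and `pi_clin = 0.783`; `pi_lb` chosen so that about
#' one third of hCG pregnancies fail before live birth.
#'
#' @param n_couples number of couples.
#' @param subfertile_prop proportion of couples in the sub-fertile class.
#' @param fertile,subfertile [stage_probabilities()] for the two classes.
#' @param max_cycles maximum monitored cycles per couple.
#' @param seed optional integer seed stored with the configuration.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_couples = 221,
                          subfertile_prop = 0.281,
                          fertile = stage_probabilities(
                            pi_soc = 0.80, pi_fert = 0.90, pi_hcg = 0.60,
                            pi_clin = 0.783, pi_lb = 0.851),
                          subfertile = stage_probabilities(
                            pi_soc = 0.80, pi_fert = 0.30, pi_hcg = 0.25,
                            pi_clin = 0.783, pi_lb = 0.851),
                          max_cycles = 6, seed = NULL) {
  assert_count(n_couples, "n_couples", positive = TRUE)
  assert_probability(subfertile_prop, "subfertile_prop")
  assert_count(max_cycles, "max_cycles", positive = TRUE)
  stopifnot(inherits(fertile, "stage_probabilities"),
            inherits(subfertile, "stage_probabilities"))
  structure(list(n_couples = n_couples, subfertile_prop = subfertile_prop,
                 fertile = fertile, subfertile = subfertile,
                 max_cycles = max_cycles, seed = seed),
            class = "cohort_config")
}

#' Simulate a per-cycle hCG cohort study
#'
#' Each couple draws its fertility class once, then progresses through
#' per-cycle Bernoulli stages with that class's probabilities: an hCG
#' pregnancy occurs with probability `pi_soc * pi_fert * pi_hcg`; a
#' detected pregnancy becomes clinical with probability `pi_clin` and ends
#' in live birth with probability `pi_lb`. Follow-up stops at the first
#' hCG-positive cycle (one pregnancy per couple, no return to risk after a
#' loss, matching the denominators of the raw fecundability estimators) or
#' at `max_cycles`, when the couple is censored.
#'
#' @param cfg a [cohort_config()].
#' @return data frame with one row per monitored cycle: `couple`, `cycle`,
#'   `subfertile`, `hcg_positive`, `clinical`, `live_birth`, `censored`
#'   (`TRUE` on a couple's last cycle if never hCG-positive). Within every
#'   row `live_birth` implies `clinical` implies `hcg_positive`.
#' @export
#' @examples
#' head(simulate_cohort(cohort_config(n_couples = 20, seed = 1)))
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_couples
  sub <- stats::runif(n) < cfg$subfertile_prop
  fec_hcg <- function(p) p$pi_soc * p$pi_fert * p$pi_hcg
  p_hcg <- ifelse(sub, fec_hcg(cfg$subfertile), fec_hcg(cfg$fertile))
  p_clin <- ifelse(sub, cfg$subfertile$pi_clin, cfg$fertile$pi_clin)
  p_lb <- ifelse(sub, cfg$subfertile$pi_lb, cfg$fertile$pi_lb)
  rows <- vector("list", cfg$max_cycles)
  active <- rep(TRUE, n)
  for (cy in seq_len(cfg$max_cycles)) {
    idx <- which(active)
    if (length(idx) == 0) break
    hcg <- stats::runif(length(idx)) < p_hcg[idx]
    clin <- hcg & (stats::runif(length(idx)) < p_clin[idx])
    lb <- clin & (stats::runif(length(idx)) < p_lb[idx])
    rows[[cy]] <- data.frame(
      couple = idx, cycle = cy, subfertile = sub[idx],
      hcg_positive = hcg, clinical = clin, live_birth = lb,
      censored = !hcg & cy == cfg$max_cycles
    )
    active[idx[hcg]] <- FALSE
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$couple, out$cycle), ]
  rownames(out) <- NULL
  out
}

#' Raw study-level estimators applied to a simulated cohort
#'
#' The same ratio estimators used for the real hCG studies: raw hCG and
#' clinical fecundability are pregnancies over all monitored cycles;
#' survival to clinical recognition and loss to live birth are proportions
#' of detected pregnancies.
#'
#' @param records output of [simulate_cohort()].
#' @return a list with `n_cycles`, `n_hcg`, `raw_fec_hcg_pct`,
#'   `raw_fec_clin_pct`, `survival_to_clinical_pct`,
#'   `loss_to_livebirth_pct` and `defined` (`FALSE`, with `NA` survival and
#'   loss, when no pregnancy was detected).
#' @export
estimate_from_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("empty record table", call. = FALSE)
  }
  n_cycles <- nrow(records)
  n_hcg <- sum(records$hcg_positive)
  n_clin <- sum(records$clinical)
  n_lb <- sum(records$live_birth)
  defined <- n_hcg > 0
  list(
    n_cycles = n_cycles, n_hcg = n_hcg,
    raw_fec_hcg_pct = 100 * n_hcg / n_cycles,
    raw_fec_clin_pct = 100 * n_clin / n_cycles,
    survival_to_clinical_pct = if (defined) 100 * n_clin / n_hcg else NA_real_,
    loss_to_livebirth_pct = if (defined) 100 * (n_hcg - n_lb) / n_hcg
                            else NA_real_,
    defined = defined
  )
}

#' Configuration for a synthetic cross-sectional embryo-collection study
#'
#' Makes the longitudinal truth behind a Hertig-style cross-sectional
#' design explicit. Cases are sampled at fixed cycle-day strata; for each,
#' fertilisation occurs with `true_fert_rate` (coital timing folded in,
#' since the strata already condition on ovulation), a fertilised embryo is
#' abnormal with `true_abnormal_frac`, normal embryos survive through week
#' two while abnormal embryos clear implantation only with
#' `abnormal_implant_prob`, and a surviving embryo is found with the
#' stratum's `detection_prob`. Default detection probabilities are
#' calibrated so that, under the implied truth of the canonical 107-case
#' data (fertilisation 30/36, half of embryos abnormal, 40% of abnormal
#' embryos implanting), the expected observed counts match the canonical
#' table.
#'
#' @param n_cases cases per stratum (days 16-17, 18-19, 20-24, >= 25).
#' @param true_fert_rate probability a case's cycle produced a fertilised
#'   ovum.
#' @param true_abnormal_frac proportion of fertilised ova that are
#'   abnormal.
#' @param abnormal_implant_prob probability an abnormal embryo implants.
#' @param detection_prob probability per stratum of finding an embryo that
#'   is present.
#' @param seed optional integer seed.
#' @return an object of class `hertig_sampler_config`.
#' @export
hertig_sampler_config <- function(n_cases = c(9, 15, 47, 36),
                                  true_fert_rate = 30 / 36,
                                  true_abnormal_frac = 0.5,
                                  abnormal_implant_prob = 0.4,
                                  detection_prob = c(1 / 7.5, 7 / 12.5,
                                                     5 / (47 * 3.5 / 6),
                                                     1),
                                  seed = NULL) {
  stopifnot(length(n_cases) == 4, all(n_cases >= 0),
            length(detection_prob) == 4)
  assert_probability(true_fert_rate, "true_fert_rate")
  assert_probability(true_abnormal_frac, "true_abnormal_frac")
  assert_probability(abnormal_implant_prob, "abnormal_implant_prob")
  for (d in detection_prob) assert_probability(d, "detection_prob")
  structure(list(n_cases = n_cases, true_fert_rate = true_fert_rate,
                 true_abnormal_frac = true_abnormal_frac,
                 abnormal_implant_prob = abnormal_implant_prob,
                 detection_prob = detection_prob, seed = seed),
            class = "hertig_sampler_config")
}

#' Simulate a cross-sectional embryo-collection study
#'
#' Draws one observed case set under the generative model of
#' [hertig_sampler_config()]: embryos in the two pre-implantation strata
#' are present whenever fertilisation occurred; in the implantation and
#' post-missed-period strata abnormal embryos are present only if they
#' implanted. A present embryo is recorded (with its normal/abnormal type)
#' if detected; otherwise the case is recorded as embryo-free.
#'
#' @param cfg a [hertig_sampler_config()].
#' @return a [hertig_cases()] frequency table.
#' @export
#' @examples
#' simulate_hertig_study(hertig_sampler_config(seed = 1))
simulate_hertig_study <- function(cfg) {
  stopifnot(inherits(cfg, "hertig_sampler_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  counts <- matrix(0, nrow = 4, ncol = 3)
  post_implantation <- c(FALSE, FALSE, TRUE, TRUE)
  for (s in 1:4) {
    n <- cfg$n_cases[s]
    if (n == 0) next
    fert <- stats::runif(n) < cfg$true_fert_rate
    abn <- fert & (stats::runif(n) < cfg$true_abnormal_frac)
    present <- fert
    if (post_implantation[s]) {
      present[abn] <- stats::runif(sum(abn)) < cfg$abnormal_implant_prob
    }
    found <- present & (stats::runif(n) < cfg$detection_prob[s])
    n_abn <- sum(found & abn)
    n_norm <- sum(found & !abn)
    counts[s, ] <- c(n - n_norm - n_abn, n_norm, n_abn)
  }
  hertig_cases(counts)
}
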