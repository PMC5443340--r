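#' Thirteen prospective hCG early-pregnancy studies
#'
#' Summary counts from the thirteen cohort studies that used hCG assays to
#' detect pregnancies from around implantation: women monitored cycle by
#' cycle, pregnancies classified as hCG-detected and (if they progressed)
#' clinically recognised. Monitored-cycle counts are unavailable for three
#' studies (Sasaki 2008, Cole 2012, Mumford 2016) and stored as `NA`, as is
#' the hCG-to-live-birth loss for Videla-Rivero 1987. The reported
#' loss-to-live-birth percentage is stored as published rather than
#' recomputed, because live-birth counts are not available for every study
#' and endpoint definitions differ (some follow up only to late pregnancy).
#'
#' @return data frame with columns `first_author`, `year`, `n_women`,
#'   `n_cycles`, `hcg_pregnancies`, `clinical_pregnancies`,
#'   `reported_loss_to_livebirth` (percent).
#' @export
#' @examples
#' nrow(studies_fixture())  # 13
studies_fixture <- function() {
  data.frame(
    first_author = c("Miller", "Edmonds", "Whittaker", "Videla-Rivero",
                     "Walker", "Wilcox", "Hakim", "Zinaman", "Wang",
                     "Sasaki", "Koot", "Cole", "Mumford"),
    year = c(1980L, 1982L, 1983L, 1987L, 1988L, 1988L, 1995L, 1996L, 2003L,
             2008L, 2011L, 2012L, 2016L),
    n_women = c(197L, 82L, 91L, 27L, 38L, 221L, 74L, 200L, 518L, 110L, 46L,
                168L, 1088L),
    n_cycles = c(623L, 198L, 226L, 27L, 75L, 707L, 305L, 432L, 1561L, NA,
                 103L, NA, NA),
    hcg_pregnancies = c(152L, 118L, 92L, 12L, 25L, 198L, 66L, 116L, 618L,
                        62L, 30L, 127L, 785L),
    clinical_pregnancies = c(102L, 51L, 85L, 5L, 25L, 155L, 52L, 101L,
                             466L, 50L, 24L, 99L, 730L),
    reported_loss_to_livebirth = c(42.4, 61.9, 19.6, NA, 16.0, 31.3, 37.9,
                                   31.3, 35.7, 32.3, 26.7, 36.2, 23.9),
    stringsAsFactors = FALSE
  )
}

#' Raw per-cycle hCG fecundability
#'
#' The proportion of monitored cycles in which an hCG pregnancy was
#' detected, as a percentage rounded to one decimal. With women followed
#' until their first detected pregnancy, this pools fertile and sub-fertile
#' couples over all contributed cycles and therefore underestimates the
#' fecundability of normally fertile couples.
#'
#' @param r one or more rows of [studies_fixture()] (any data frame with
#'   `hcg_pregnancies` and `n_cycles` columns).
#' @return numeric vector of percentages; `NA` where cycle counts are
#'   missing.
#' @export
raw_fec_hcg <- function(r) {
  out <- ifelse(is.na(r$n_cycles) | r$n_cycles <= 0, NA_real_,
                100 * r$hcg_pregnancies / r$n_cycles)
  round_half_up(out, 1)
}

#' Survival from hCG detection to clinical recognition
#'
#' The percentage of hCG-detected pregnancies that reached clinical
#' recognition; its complement is the early ("occult" or "biochemical")
#' pregnancy-loss rate.
#'
#' @param r one or more rows of [studies_fixture()].
#' @return numeric vector of percentages, one decimal; errors when a row
#'   has no hCG pregnancies.
#' @export
survival_to_clinical <- function(r) {
  if (any(r$hcg_pregnancies <= 0)) {
    stop("survival undefined for studies with no hCG pregnancies",
         call. = FALSE)
  }
  round_half_up(100 * r$clinical_pregnancies / r$hcg_pregnancies, 1)
}

#' Early and clinical loss rates from a loss breakdown
#'
#' Given a study's detected hCG pregnancies split into pre-clinical
#' (early/occult) and clinical losses, the early loss rate is the
#' pre-clinical losses over all detected pregnancies, and the clinical loss
#' rate is the clinical losses over the pregnancies surviving to clinical
#' recognition.
#'
#' @param hcg_total detected hCG pregnancies.
#' @param preclinical_losses losses before clinical recognition.
#' @param clinical_losses losses after clinical recognition.
#' @return named numeric vector `c(early, clinical)` of unrounded
#'   percentages.
#' @export
#' @examples
#' loss_rates(198, 43, 19)  # 21.7%, 12.3% -- the original classification
#' loss_rates(199, 48, 15)  # 24.1%, 9.9%  -- after case re-allocation
loss_rates <- function(hcg_total, preclinical_losses, clinical_losses) {
  assert_count(hcg_total, "hcg_total", positive = TRUE)
  assert_count(preclinical_losses, "preclinical_losses")
  assert_count(clinical_losses, "clinical_losses")
  if (preclinical_losses + clinical_losses > hcg_total) {
    stop("losses exceed detected pregnancies", call. = FALSE)
  }
  at_risk_clinical <- hcg_total - preclinical_losses
  if (at_risk_clinical == 0 && clinical_losses > 0) {
    stop("clinical losses with no pregnancies surviving to clinical stage",
         call. = FALSE)
  }
  c(early = 100 * preclinical_losses / hcg_total,
    clinical = if (at_risk_clinical == 0) 0
               else 100 * clinical_losses / at_risk_clinical)
}

#' Recomputed summary table for the hCG studies
#'
#' Augments [studies_fixture()] with the recomputed per-study statistics:
#' raw hCG fecundability, survival from hCG detection to clinical
#' recognition, and the early-loss percentage (its complement).
#'
#' @param studies defaults to [studies_fixture()].
#' @return the input data frame with columns `raw_fec_hcg_pct`,
#'   `survival_to_clinical_pct` and `early_loss_pct` appended.
#' @export
hcg_summary <- function(studies = studies_fixture()) {
  studies$raw_fec_hcg_pct <- raw_fec_hcg(studies)
  studies$survival_to_clinical_pct <- survival_to_clinical(studies)
  studies$early_loss_pct <- round_half_up(
    100 - 100 * studies$clinical_pregnancies / studies$hcg_pregnancies, 1)
  studies
}
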