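hertig_strata <- c("days_16_17", "days_18_19", "days_20_24", "days_25_plus")
hertig_outcomes <- c("none", "normal", "abnormal")

#' Construct a Hertig-style case set
#'
#' A frequency table of hysterectomy cases cross-classified by cycle-day
#' stratum (days 16-17: embryo in the fallopian tube; 18-19: free in the
#' uterus; 20-24: implanting; >= 25: past the first missed period) and
#' embryo outcome (no embryo found, normal embryo, abnormal embryo).
#'
#' @param counts 4 x 3 numeric matrix of case counts, rows = strata in the
#'   order days 16-17, 18-19, 20-24, >= 25; columns = outcomes none,
#'   normal, abnormal.
#' @return a data frame of class `hertig_cases` in long form with columns
#'   `stratum`, `outcome` and `n`.
#' @seealso [hertig_fixture()] for the canonical 107-case data.
#' @export
hertig_cases <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 3L)) || any(counts < 0)) {
    stop("'counts' must be a 4 x 3 matrix of non-negative counts",
         call. = FALSE)
  }
  out <- data.frame(
    stratum = factor(rep(hertig_strata, 3L), levels = hertig_strata),
    outcome = factor(rep(hertig_outcomes, each = 4L),
                     levels = hertig_outcomes),
    n = as.vector(counts)
  )
  class(out) <- c("hertig_cases", "data.frame")
  out
}

#' The canonical 107-case embryo-collection data
#'
#' Hertig and Rock's 107 cases judged optimal for embryo recovery: women of
#' proven fertility who had ovulated, had coitus within a day of ovulation
#' and were free of conditions interfering with conception. Thirty-four
#' embryos were found, 24 normal and 10 abnormal. Counts per stratum:
#' days 16-17, 9 cases (1 normal embryo); days 18-19, 15 cases (3 normal,
#' 4 abnormal); days 20-24, 47 cases (5 normal); days >= 25, 36 cases
#' (15 normal, 6 abnormal). An alternative classification reported
#' elsewhere treats three embryos (C-8299, C-8000, C-8290) as abnormal on
#' positional grounds, giving a 21/13 normal/abnormal split; this fixture
#' uses the 24/10 classification.
#'
#' @return a [hertig_cases()] frequency table totalling 107 cases.
#' @export
#' @examples
#' sum(hertig_fixture()$n)  # 107
hertig_fixture <- function() {
  hertig_cases(matrix(c(
    # none, normal, abnormal
    8,  1, 0,   # days 16-17
    8,  3, 4,   # days 18-19
    42, 5, 0,   # days 20-24
    15, 15, 6   # days >= 25
  ), nrow = 4, byrow = TRUE))
}

# counts for one stratum x outcome cell
case_count <- function(c, stratum, outcome) {
  sum(c$n[c$stratum == stratum & c$outcome == outcome])
}

#' Embryo-loss estimates from pre- and post-implantation embryo counts
#'
#' The derivation behind Hertig's reproductive-efficiency figures. From the
#' pre-implantation sample, the abnormal fraction is
#' `p = m_abn / (m_norm + m_abn)`. Assuming all normal embryos implant and
#' the normal:abnormal ratio at fertilisation equals the pre-implantation
#' ratio, the `k_norm` normal implanted embryos imply
#' `abnormal_total = k_norm * p / (1 - p)` abnormal fertilisations among
#' the late cases, of which `abnormal_total - k_abn` failed to implant
#' unobserved. The remaining late cases are unfertilised (possibly a
#' negative count when the implied fertilisation rate exceeds 100%).
#'
#' @param n_late number of late (post-missed-period) cases.
#' @param k_norm,k_abn normal and abnormal implanted embryos observed among
#'   the late cases.
#' @param m_norm,m_abn normal and abnormal embryos observed in the
#'   pre-implantation sample.
#' @return an object of class `hertig_estimates`: a list with percentages
#'   `fertility` (normal implanted embryos per late case), `sterility`
#'   (implied abnormal fertilisations per late case), `infertility`
#'   (implied unfertilised; may be negative), `fertilisation_rate` (may
#'   exceed 100), `preimplant_loss` and `preimplant_survival`,
#'   `postimplant_survival`, `detection_rate`; implied counts
#'   `abnormal_total` and `failed_implant`; and flags `valid` (estimates
#'   computable: requires late cases, pre-implantation embryos and
#'   `m_norm > 0`) and `consistent` (`failed_implant >= 0`; observed
#'   abnormal implants exceeding the implied total signal internally
#'   inconsistent data, as when the days 20-24 stratum is forced into the
#'   derivation). When `valid` is `FALSE` the numeric fields are `NA`
#'   rather than an error, so bootstrap replicates can be filtered.
#' @export
#' @examples
#' derive_estimates(36, 15, 6, 4, 4)  # fertility ~41.7%, loss 30%
derive_estimates <- function(n_late, k_norm, k_abn, m_norm, m_abn) {
  for (nm in c("n_late", "k_norm", "k_abn", "m_norm", "m_abn")) {
    assert_count(get(nm), nm)
  }
  invalid <- n_late == 0 || (m_norm + m_abn) == 0 || m_norm == 0
  if (invalid) {
    na <- NA_real_
    return(structure(list(
      fertility = na, sterility = na, infertility = na,
      fertilisation_rate = na, abnormal_total = na, failed_implant = na,
      preimplant_loss = na, preimplant_survival = na,
      postimplant_survival = na, detection_rate = na,
      valid = FALSE, consistent = NA
    ), class = "hertig_estimates"))
  }
  p <- m_abn / (m_norm + m_abn)
  abnormal_total <- k_norm * p / (1 - p)
  failed_implant <- abnormal_total - k_abn
  fertilised <- k_norm + abnormal_total
  unfertilised <- n_late - fertilised
  structure(list(
    fertility = 100 * k_norm / n_late,
    sterility = 100 * abnormal_total / n_late,
    infertility = 100 * unfertilised / n_late,
    fertilisation_rate = 100 * fertilised / n_late,
    abnormal_total = abnormal_total,
    failed_implant = failed_implant,
    preimplant_loss = 100 * failed_implant / fertilised,
    preimplant_survival = 100 * (1 - failed_implant / fertilised),
    postimplant_survival = 100 * k_norm / (k_norm + k_abn),
    detection_rate = 100 * (k_norm + k_abn) / n_late,
    valid = TRUE,
    consistent = failed_implant >= 0
  ), class = "hertig_estimates")
}

#' @export
print.hertig_estimates <- function(x, ...) {
  if (!x$valid) {
    cat("Embryo-loss estimates: not computable from these counts\n")
    return(invisible(x))
  }
  cat("Embryo-loss estimates (% of late cases unless stated):\n")
  for (nm in c("fertility", "sterility", "infertility", "fertilisation_rate",
               "preimplant_loss", "preimplant_survival",
               "postimplant_survival", "detection_rate")) {
    cat(sprintf("  %-22s %7.1f\n", nm, x[[nm]]))
  }
  if (!x$consistent) {
    cat("  note: observed abnormal implants exceed the implied total\n")
  }
  invisible(x)
}

#' Embryo-loss estimates from a case set
#'
#' Maps a [hertig_cases()] table onto [derive_estimates()]: the
#' pre-implantation sample pools the days 16-17 and 18-19 strata, the late
#' sample is the days >= 25 stratum, and the days 20-24 stratum is excluded
#' (its five normal, zero abnormal embryos are irreconcilable with the
#' derivation's assumptions, the omission made in the original analysis).
#'
#' @param c a [hertig_cases()] table.
#' @return a `hertig_estimates` object; see [derive_estimates()].
#' @export
#' @examples
#' estimates_from_caseset(hertig_fixture())
estimates_from_caseset <- function(c) {
  stopifnot(inherits(c, "hertig_cases"))
  pre <- hertig_strata[1:2]
  late <- hertig_strata[4]
  derive_estimates(
    n_late = sum(c$n[c$stratum == late]),
    k_norm = case_count(c, late, "normal"),
    k_abn = case_count(c, late, "abnormal"),
    m_norm = sum(c$n[c$stratum %in% pre & c$outcome == "normal"]),
    m_abn = sum(c$n[c$stratum %in% pre & c$outcome == "abnormal"])
  )
}

#' Expand a case-set frequency table to one row per case
#'
#' @param c a [hertig_cases()] table.
#' @return data frame with one row per case and columns `stratum`,
#'   `outcome`.
#' @export
as_case_table <- function(c) {
  stopifnot(inherits(c, "hertig_cases"))
  idx <- rep(seq_len(nrow(c)), c$n)
  out <- data.frame(stratum = c$stratum[idx], outcome = c$outcome[idx])
  rownames(out) <- NULL
  out
}

#' Balanced bootstrap of a case set
#'
#' Balanced random resampling: the case set is expanded to individual
#' cases, `n_datasets` copies are concatenated, the pooled collection is
#' randomly permuted and sliced into `n_datasets` pseudo-datasets of the
#' original size. Consequently every original case appears exactly
#' `n_datasets` times across the whole collection (pooled cell counts are
#' exactly `n_datasets` times the originals), removing the between-replicate
#' sampling imbalance of the ordinary bootstrap.
#'
#' @param c a [hertig_cases()] table.
#' @param n_datasets number of pseudo-datasets to generate.
#' @param seed optional integer seed.
#' @return list of `n_datasets` [hertig_cases()] tables.
#' @export
#' @examples
#' bs <- balanced_bootstrap(hertig_fixture(), 10, seed = 1)
#' Reduce(`+`, lapply(bs, `[[`, "n")) / 10  # pooled counts / B = original
balanced_bootstrap <- function(c, n_datasets, seed = NULL) {
  stopifnot(inherits(c, "hertig_cases"))
  assert_count(n_datasets, "n_datasets", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  size <- sum(c$n)
  cell <- rep(seq_len(nrow(c)), c$n)          # cell index per original case
  pooled <- rep(cell, n_datasets)
  pooled <- pooled[sample.int(length(pooled))]
  dataset <- rep(seq_len(n_datasets), each = size)
  lapply(split(pooled, dataset), function(ix) {
    counts <- tabulate(ix, nbins = nrow(c))
    hertig_cases(matrix(counts, nrow = 4))
  })
}

#' Percentile summary of the bootstrapped embryo-loss estimates
#'
#' Applies [estimates_from_caseset()] to each balanced-bootstrap
#' pseudo-dataset and summarises six derived quantities (fertility,
#' sterility, infertility, pre-implantation survival, post-implantation
#' survival, detection rate) by their median and percentile confidence
#' bounds. Replicates for which the derivation is not computable (no late
#' cases, no pre-implantation embryos, or an all-abnormal pre-implantation
#' sample) are excluded and counted in `n_invalid`; replicates with a
#' negative implied implantation failure are retained, since they yield
#' finite (out-of-range) estimates.
#'
#' @param c a [hertig_cases()] table.
#' @param n_datasets number of pseudo-datasets (default 500).
#' @param level confidence level as a percentage (default 95).
#' @param seed optional integer seed.
#' @return a list of class `bootstrap_summary` with `summary`, a data frame
#'   (rows = quantities; columns `median`, `lower`, `upper` in percent),
#'   `n_datasets`, `n_invalid` and `level`.
#' @export
#' @examples
#' bootstrap_summary(hertig_fixture(), n_datasets = 100, seed = 1)
bootstrap_summary <- function(c, n_datasets = 500, level = 95, seed = NULL) {
  if (level <= 0 || level >= 100) {
    stop("'level' must be in (0, 100)", call. = FALSE)
  }
  reps <- balanced_bootstrap(c, n_datasets, seed = seed)
  quantities <- c("fertility", "sterility", "infertility",
                  "preimplant_survival", "postimplant_survival",
                  "detection_rate")
  vals <- vapply(reps, function(d) {
    e <- estimates_from_caseset(d)
    if (!e$valid) rep(NA_real_, length(quantities))
    else unlist(e[quantities])
  }, numeric(length(quantities)))
  ok <- !is.na(vals[1, ])
  if (!any(ok)) stop("all bootstrap replicates were invalid", call. = FALSE)
  alpha <- (100 - level) / 100
  s <- t(apply(vals[, ok, drop = FALSE], 1, function(v) {
    c(median = stats::median(v),
      lower = percentile(v, alpha / 2),
      upper = percentile(v, 1 - alpha / 2))
  }))
  structure(list(
    summary = data.frame(quantity = quantities, s, row.names = NULL),
    n_datasets = n_datasets, n_invalid = sum(!ok), level = level
  ), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Balanced bootstrap (%d datasets, %d invalid excluded), %g%% CIs:\n",
              x$n_datasets, x$n_invalid, x$level))
  df <- x$summary
  df[-1] <- lapply(df[-1], round_half_up)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The "exact" interval obtained by inverting binomial tail probabilities,
#' computed via beta quantiles: the lower bound is the `alpha/2` quantile of
#' `Beta(k, n - k + 1)` (0 when `k = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when `k = n`).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level as a percentage (default 95).
#' @return a list of class `binomial_ci` with `method`, `level`, `estimate`
#'   (`k/n`) and the `lower` and `upper` proportions.
#' @export
#' @examples
#' clopper_pearson(21, 36)  # [0.408, 0.745]
clopper_pearson <- function(k, n, level = 95) {
  assert_count(n, "n", positive = TRUE)
  assert_count(k, "k")
  if (k > n) stop("'k' cannot exceed 'n'", call. = FALSE)
  alpha <- (100 - level) / 100
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(method = "clopper_pearson", level = level, estimate = k / n,
                 lower = lower, upper = upper), class = "binomial_ci")
}

#' Agresti-Coull approximate binomial confidence interval
#'
#' Adjusted Wald interval: with `z` the standard-normal quantile at
#' `1 - alpha/2`, the pseudo-counts `n~ = n + z^2` and
#' `p~ = (k + z^2 / 2) / n~` give bounds `p~ +/- z * sqrt(p~ (1 - p~) / n~)`.
#' Bounds are reported unclipped and can fall outside \[0, 1\] for extreme
#' `k`.
#'
#' @inheritParams clopper_pearson
#' @return a `binomial_ci` object; see [clopper_pearson()].
#' @export
#' @examples
#' agresti_coull(21, 36)  # [0.418, 0.732]
agresti_coull <- function(k, n, level = 95) {
  assert_count(n, "n", positive = TRUE)
  assert_count(k, "k")
  if (k > n) stop("'k' cannot exceed 'n'", call. = FALSE)
  alpha <- (100 - level) / 100
  z <- stats::qnorm(1 - alpha / 2)
  n_t <- n + z^2
  p_t <- (k + z^2 / 2) / n_t
  half <- z * sqrt(p_t * (1 - p_t) / n_t)
  structure(list(method = "agresti_coull", level = level, estimate = k / n,
                 lower = p_t - half, upper = p_t + half),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%s %g%% CI for %.3f: [%.3f, %.3f]\n", x$method, x$level,
              x$estimate, x$lower, x$upper))
  invisible(x)
}
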