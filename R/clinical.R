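#' Kaplan-Meier progression-free survival curves
#'
#' Product-limit estimate per group with censoring marks preserved.
#'
#' @param time Follow-up time (months), >= 0.
#' @param event Event indicator (1 = progression, 0 = censored); >= 1 event
#'   overall required.
#' @param group Group label per subject (any number of groups).
#' @return Data frame with one row per distinct time within group: `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curves <- function(time, event, group) {
  if (any(time < 0)) stop("negative times")
  if (sum(event) < 1) stop("need >= 1 event")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(unique(as.character(group)), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times, referred to a 1-df chi-square distribution.
#'
#' @inheritParams km_curves
#' @return List with `chisq`, `p`, and the per-group observed/expected event
#'   counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly 2 groups required")
  if (min(table(group)) < 1) stop("a group has no subjects")
  if (sum(event) < 1) stop("need >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Association test for a 2 x k contingency table
#'
#' Chi-square with continuity correction for 2 x 2 tables, plain chi-square
#' for 2 x k, and Fisher's exact (hypergeometric) test automatically for
#' 2 x 2 tables with any expected count below 5. The method used is
#' reported.
#'
#' @param counts Non-negative integer matrix with 2 rows.
#' @return List with `statistic` (chi-square value, or the odds-ratio
#'   estimate for Fisher), `p` and `method`.
#' @export
categorical_association <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("counts must have 2 rows")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero table")
  if (ncol(counts) == 2) {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(counts)
      return(list(statistic = unname(ft$estimate), p = ft$p.value,
                  method = "fisher"))
    }
    ct <- stats::chisq.test(counts, correct = TRUE)
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chisq-corrected")
  } else {
    ct <- stats::chisq.test(counts, correct = FALSE)
    list(statistic = unname(ct$statistic), p = ct$p.value, method = "chisq")
  }
}
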