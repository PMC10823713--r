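#' Stratify a bulk cohort by signature score quartiles
#'
#' The per-patient score is the mean expression over the signature genes
#' present in the cohort matrix. Patients in the top floor(q * n) scores
#' form the high group, the bottom floor(q * n) the low group (default
#' q = 0.25), and the middle is excluded. Boundary ties are broken by
#' stable patient-id order.
#'
#' @param cohort List with \code{expr} (genes x patients) and
#'   \code{patient_id} (see [simulate_survival_cohort()]).
#' @param signature Character vector of gene symbols.
#' @param config An [nc_config()] object (\code{surv_quantile}).
#' @return A list: \code{group} (named factor \code{high}/\code{low}/
#'   \code{excluded} per patient) and \code{score}.
#' @export
stratify_by_signature <- function(cohort, signature, config = nc_config()) {
  present <- intersect(unique(signature), rownames(cohort$expr))
  if (length(present) == 0) stop("no signature gene present in cohort")
  n <- ncol(cohort$expr)
  if (n < 8) stop("need >= 8 patients to stratify")
  score <- colMeans(cohort$expr[present, , drop = FALSE])
  if (length(unique(score)) == 1) {
    stop("all patient scores identical: no stratification possible")
  }
  k <- floor(config$surv_quantile * n)
  ids <- cohort$patient_id %||% colnames(cohort$expr)
  ord_low <- order(score, ids)    # ties broken by stable patient-id order
  ord_high <- order(-score, ids)
  group <- rep("excluded", n)
  group[ord_low[seq_len(k)]] <- "low"
  group[ord_high[seq_len(k)]] <- "high"
  if (sum(group == "low") < k) {
    stop("high and low strata overlap: too many tied scores")
  }
  list(group = setNames(factor(group, c("low", "excluded", "high")), ids),
       score = setNames(score, ids), n_high = k, n_low = k)
}

#' Two-sided log-rank test with Kaplan-Meier curves
#'
#' Compares the survival of the high and low strata with the standard
#' log-rank test and returns the product-limit (KM) estimates per group.
#' With zero events overall the comparison is untestable (p = NA).
#'
#' @param cohort List with \code{time}, \code{event} aligned to patients.
#' @param groups Result of [stratify_by_signature()] (or a factor with
#'   levels including \code{high}, \code{low}).
#' @return A list: \code{p}, \code{chisq}, \code{km} (data.frame: group,
#'   time, surv, n_risk, n_event), \code{n_high}, \code{n_low},
#'   \code{testable}.
#' @export
logrank_km <- function(cohort, groups) {
  grp <- if (is.list(groups)) groups$group else groups
  use <- grp %in% c("high", "low")
  if (sum(grp[use] == "high") == 0 || sum(grp[use] == "low") == 0) {
    stop("both strata must be non-empty")
  }
  time <- cohort$time[use]
  event <- cohort$event[use]
  g <- droplevels(factor(grp[use], c("low", "high")))
  if (sum(event) == 0) {
    return(list(p = NA_real_, chisq = NA_real_, km = NULL,
                n_high = sum(g == "high"), n_low = sum(g == "low"),
                testable = FALSE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  strata_lab <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  km <- data.frame(group = strata_lab, time = fit$time, surv = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   stringsAsFactors = FALSE)
  list(p = p, chisq = unname(sd$chisq), km = km,
       n_high = sum(g == "high"), n_low = sum(g == "low"), testable = TRUE)
}

#' Cox model for the signature stratum adjusted for age and stage
#'
#' Proportional-hazards fit of the high-vs-low indicator with age and
#' one-hot stage (reference: first level in sorted order) as covariates;
#' the Wald p of the group term is reported. Non-convergence or
#' separation is flagged in the result rather than raised.
#'
#' @param cohort List with \code{time}, \code{event}, \code{age},
#'   \code{stage}.
#' @param groups Result of [stratify_by_signature()].
#' @return A list: \code{hr}, \code{ci_lower}, \code{ci_upper}, \code{p}
#'   for high vs low, \code{converged}, \code{warnings}, \code{fit}.
#' @export
cox_adjusted <- function(cohort, groups) {
  grp <- if (is.list(groups)) groups$group else groups
  use <- grp %in% c("high", "low")
  g <- droplevels(factor(grp[use], c("low", "high")))
  if (length(unique(g)) < 2) stop("group indicator is constant: no contrast")
  df <- data.frame(time = cohort$time[use], event = cohort$event[use],
                   group = g, age = cohort$age[use],
                   stage = factor(cohort$stage[use],
                                  sort(unique(cohort$stage[use]))))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group + age + stage,
                    data = df),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  row <- grep("^grouphigh", rownames(sm$coefficients))
  list(hr = unname(sm$coefficients[row, "exp(coef)"]),
       ci_lower = unname(sm$conf.int[row, "lower .95"]),
       ci_upper = unname(sm$conf.int[row, "upper .95"]),
       p = unname(sm$coefficients[row, "Pr(>|z|)"]),
       converged = length(warns) == 0,
       warnings = warns, fit = fit)
}

#' Gene-subset bootstrap stability of a signature's survival association
#'
#' Repeats the stratification + log-rank analysis \code{surv_n_boot}
#' times (default 200), each round on a random subset of the signature
#' genes (default 80%, without replacement, at least 2 genes), and
#' reports the vector of round p-values together with its
#' \code{surv_report_q} empirical quantile (default 0.90, type-7
#' interpolation). A stable association keeps even the quantile p small.
#' Rounds whose subset has no gene present in the cohort are redrawn (at
#' most 100 retries each).
#'
#' @param cohort List with \code{expr}, \code{time}, \code{event}.
#' @param signature Character vector of gene symbols (>= 3 present).
#' @param config An [nc_config()] object.
#' @param seed Seed (default \code{config$seed}).
#' @return A list: \code{p_boot} (length \code{surv_n_boot}),
#'   \code{p_quantile}, \code{quantile_level}, \code{p_full} (whole
#'   signature).
#' @export
bootstrap_stability <- function(cohort, signature, config = nc_config(),
                                seed = NULL) {
  signature <- unique(signature)
  present <- intersect(signature, rownames(cohort$expr))
  if (length(present) < 3) stop("need >= 3 signature genes present")
  full <- logrank_km(cohort, stratify_by_signature(cohort, present, config))
  set.seed(seed %||% config$seed)
  n_sub <- max(2L, round(config$surv_boot_frac * length(present)))
  p_boot <- numeric(config$surv_n_boot)
  for (b in seq_len(config$surv_n_boot)) {
    for (try in seq_len(100)) {
      sub <- sample(present, n_sub)
      ok <- length(intersect(sub, rownames(cohort$expr))) > 0
      if (ok) break
    }
    strat <- stratify_by_signature(cohort, sub, config)
    p_boot[b] <- logrank_km(cohort, strat)$p
  }
  list(p_boot = p_boot,
       p_quantile = unname(quantile(p_boot, config$surv_report_q, type = 7,
                                    na.rm = TRUE)),
       quantile_level = config$surv_report_q,
       p_full = full$p)
}
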