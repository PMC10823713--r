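flat_cohort <- function(n = 40, score = NULL) {
  expr <- matrix(if (is.null(score)) rnorm(n) else score, nrow = 1,
                 dimnames = list("SIG", sprintf("PT%03d", 1:n)))
  list(expr = expr, time = rep(100, n), event = rep(1L, n),
       age = rep(60, n), stage = rep("I", n),
       patient_id = colnames(expr))
}

test_that("stratification takes floor(q n) per tail and survives ties", {
  set.seed(1)
  co <- flat_cohort(100)
  st <- stratify_by_signature(co, "SIG")
  expect_equal(sum(st$group == "high"), 25)
  expect_equal(sum(st$group == "low"), 25)
  expect_equal(sum(st$group == "excluded"), 50)
  co10 <- flat_cohort(10)
  st10 <- stratify_by_signature(co10, "SIG")
  expect_equal(sum(st10$group == "high"), 2)
  expect_equal(sum(st10$group == "low"), 2)
  # singleton signature: score equals that gene's expression
  expect_equal(unname(st10$score), unname(co10$expr["SIG", ]))
  # monotone transform of the score leaves strata unchanged
  co_t <- co
  co_t$expr["SIG", ] <- exp(co$expr["SIG", ])
  expect_identical(stratify_by_signature(co_t, "SIG")$group, st$group)
  # identical scores cannot stratify
  expect_error(stratify_by_signature(flat_cohort(20, score = rep(1, 20)),
                                     "SIG"), "identical")
})

test_that("log-rank: identical groups give p = 1, KM curves behave", {
  sp <- survival_cohort_spec(n = 60, hazard_ratio = 3, seed = 2)
  sv <- simulate_survival_cohort(sp)
  st <- stratify_by_signature(sv$cohort, sp$signature_genes)
  # duplicate the high group's data into both strata: no difference
  hi <- which(st$group == "high")
  co_same <- list(time = rep(sv$cohort$time[hi], 2),
                  event = rep(sv$cohort$event[hi], 2))
  g_same <- factor(rep(c("high", "low"), each = length(hi)),
                   c("low", "excluded", "high"))
  expect_equal(logrank_km(co_same, g_same)$p, 1, tolerance = 1e-9)
  # label swap leaves p unchanged
  lk <- logrank_km(sv$cohort, st)
  flip <- st
  flip$group <- factor(c(low = "high", excluded = "excluded",
                         high = "low")[as.character(st$group)],
                       c("low", "excluded", "high"))
  expect_equal(logrank_km(sv$cohort, flip)$p, lk$p)
  # KM curves start at <= 1 and never increase
  for (g in unique(lk$km$group)) {
    s <- lk$km$surv[lk$km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
  # zero events: untestable
  co0 <- sv$cohort
  co0$event <- rep(0L, length(co0$event))
  expect_false(logrank_km(co0, st)$testable)
})

test_that("Cox adjustment matches unadjusted HR absent confounding", {
  ratios <- vapply(1:10, function(s) {
    sp <- survival_cohort_spec(n = 400, hazard_ratio = 2.5, seed = s)
    sv <- simulate_survival_cohort(sp)
    st <- stratify_by_signature(sv$cohort, sp$signature_genes)
    adj <- cox_adjusted(sv$cohort, st)
    grp <- st$group[st$group %in% c("high", "low")]
    use <- st$group %in% c("high", "low")
    un <- survival::coxph(
      survival::Surv(sv$cohort$time[use], sv$cohort$event[use]) ~
        droplevels(st$group[use]))
    adj$hr / unname(exp(stats::coef(un)))
  }, numeric(1))
  expect_true(all(ratios > 0.8 & ratios < 1.25))
})

test_that("Cox recovers a planted effect under age confounding", {
  hits <- vapply(1:10, function(s) {
    sp <- survival_cohort_spec(n = 300, hazard_ratio = 3, seed = s,
                               age_confounding = 3, age_hazard = 0.03)
    sv <- simulate_survival_cohort(sp)
    st <- stratify_by_signature(sv$cohort, sp$signature_genes)
    cox_adjusted(sv$cohort, st)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
  # constant group is an error
  sp <- survival_cohort_spec(n = 50, seed = 1)
  sv <- simulate_survival_cohort(sp)
  g <- factor(rep("high", 50), c("low", "excluded", "high"))
  expect_error(cox_adjusted(sv$cohort, g), "constant")
})

test_that("gene-subset bootstrap is deterministic and degenerate-stable", {
  sp <- survival_cohort_spec(n = 120, hazard_ratio = 2.5, seed = 3)
  sv <- simulate_survival_cohort(sp)
  cfg <- nc_config(surv_n_boot = 50, seed = 9)
  b1 <- bootstrap_stability(sv$cohort, sp$signature_genes, cfg)
  b2 <- bootstrap_stability(sv$cohort, sp$signature_genes, cfg)
  expect_identical(b1$p_boot, b2$p_boot)
  expect_equal(b1$p_quantile,
               unname(quantile(b1$p_boot, 0.9, type = 7)))
  expect_gte(b1$p_quantile, median(b1$p_boot))
  # genes with identical expression rows: every subset scores identically,
  # so all bootstrap p equal the full-signature p
  co <- sv$cohort
  co$expr <- rbind(D1 = co$expr["SIG01", ], D2 = co$expr["SIG01", ],
                   D3 = co$expr["SIG01", ], D4 = co$expr["SIG01", ])
  bd <- bootstrap_stability(co, c("D1", "D2", "D3", "D4"), cfg)
  expect_true(all(abs(bd$p_boot - bd$p_full) < 1e-12))
  expect_equal(bd$p_quantile, bd$p_full)
  expect_error(bootstrap_stability(co, c("D1", "D2"), cfg), ">= 3")
})
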