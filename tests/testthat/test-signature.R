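test_that("the default signature carries the five published genes", {
  expect_identical(signature_genes(),
                   c("GNPDA1", "GPD1", "GRASP", "HOXC11", "MSLN"))
  spec <- signature_spec(signature_genes(), "low_value_at_risk", 0.5)
  expect_s3_class(spec, "signature_spec")
  expect_identical(nrow(spec), 5L)
  expect_error(signature_spec(c("A", "A"), "low_value_at_risk", 0.5),
               "unique")
  expect_error(signature_spec("A", "sideways", 0.5), "risk_direction")
})

test_that("risk coding counts genes at risk with ties at risk for low-value genes", {
  genes <- paste0("g", 1:5)
  spec <- signature_spec(genes,
                         c(rep("low_value_at_risk", 3),
                           rep("high_value_at_risk", 2)),
                         cutoff = 0.5)
  df <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4"),
    time_months = rep(10, 4), event = rep(1, 4),
    # p1: 3 at risk (g1-g3 low); p2: none; p3: exactly 2; p4: tie on g1
    g1 = c(0.1, 0.9, 0.1, 0.5),
    g2 = c(0.2, 0.9, 0.2, 0.9),
    g3 = c(0.3, 0.9, 0.9, 0.9),
    g4 = c(0.1, 0.1, 0.1, 0.1),
    g5 = c(0.2, 0.2, 0.2, 0.2)
  )
  co <- survival_cohort(df, genes)
  risk <- code_risk(co, spec)
  expect_identical(risk$n_risk, c(3L, 0L, 2L, 1L))
  expect_identical(as.character(risk$group), c(">=3", "0-1", "2", "0-1"))
  # partition: each patient in exactly one group, counts sum to n
  expect_identical(sum(table(risk$group)), 4L)

  # missing values: complete-case with a warning
  df$g2[2] <- NA
  co2 <- survival_cohort(df, genes)
  expect_warning(risk2 <- code_risk(co2, spec), "excluded")
  expect_identical(nrow(risk2), 3L)
})

test_that("adding a gene at risk never lowers the risk group", {
  grp_rank <- function(g) match(g, risk_group_levels())
  genes <- paste0("g", 1:5)
  spec <- signature_spec(genes, "low_value_at_risk", 0.5)
  set.seed(99)
  for (i in 1:20) {
    vals <- runif(5)
    df <- data.frame(patient_id = "p", time_months = 10, event = 1,
                     t(setNames(vals, genes)))
    base_grp <- code_risk(survival_cohort(df, genes), spec)$group
    # push one above-cutoff gene to the at-risk side
    safe <- which(vals > 0.5)
    if (!length(safe)) next
    vals2 <- vals
    vals2[safe[1]] <- 0.1
    df2 <- data.frame(patient_id = "p", time_months = 10, event = 1,
                      t(setNames(vals2, genes)))
    new_grp <- code_risk(survival_cohort(df2, genes), spec)$group
    expect_gte(grp_rank(new_grp), grp_rank(base_grp))
  }
})

test_that("Kaplan-Meier matches the product-limit hand example and oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$event_times, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))

  # censored mixtures against the independent product-limit oracle
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    time <- sample(1:15, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) next
    km2 <- km_estimate(time, event)
    expect_equal(km2$survival,
                 km_oracle(time, event, km2$event_times),
                 tolerance = 1e-12)
    # monotone non-increasing, starts at or below 1
    expect_true(all(diff(km2$survival) <= 1e-12))
    expect_true(all(km2$survival >= 0 & km2$survival <= 1))
  }

  # all censored: survival stays 1
  km3 <- km_estimate(c(5, 10), c(0, 0))
  expect_length(km3$event_times, 0)
  expect_equal(survival_at(km3, 60), 1)

  # single patient with an event
  km4 <- km_estimate(4, 1)
  expect_equal(survival_at(km4, 4), 0)

  expect_error(km_estimate(numeric(0), integer(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("survival_at is a right-continuous step lookup", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(survival_at(km, 0.5), 1)       # before the first event
  expect_equal(survival_at(km, 2), 1 / 3)     # post-step value at an event
  expect_equal(survival_at(km, 2.9), 1 / 3)
  expect_equal(survival_at(km, 60), 0)
  # non-increasing in t
  ts <- seq(0.5, 5, by = 0.5)
  vals <- vapply(ts, function(t) survival_at(km, t), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(survival_at(km, 0), "positive")
})

test_that("multi-group log-rank reduces to the two-sample test at k = 2", {
  set.seed(12)
  time <- rexp(40, 0.1)
  event <- rbinom(40, 1, 0.7)
  group <- sample(c("low", "high"), 40, replace = TRUE)
  two <- logrank_test(time, event, group)
  multi <- multi_group_logrank(time, event, group)
  expect_equal(multi$statistic, two$statistic, tolerance = 1e-12)
  expect_identical(multi$df, 1L)

  # three identical groups -> statistic 0
  t3 <- rep(c(1, 2, 3), 3)
  e3 <- rep(1, 9)
  g3 <- rep(c("a", "b", "c"), each = 3)
  m3 <- multi_group_logrank(t3, e3, g3)
  expect_equal(m3$statistic, 0, tolerance = 1e-12)
  expect_identical(m3$df, 2L)

  # all censored: degenerate null
  m0 <- multi_group_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0),
                            c("a", "a", "b", "b"))
  expect_true(m0$degenerate)
  expect_equal(m0$p, 1)

  expect_error(multi_group_logrank(1:3, c(1, 1, 1), c("a", "a", "a")),
               "two non-empty")
})

test_that("ordered planted hazards separate the three risk groups", {
  set.seed(55)
  hits <- vapply(1:20, function(i) {
    n <- 200
    time <- c(rexp(n, 0.04), rexp(n, 0.04 * 1.5), rexp(n, 0.04 * 2.5))
    cens <- rexp(3 * n, 0.01)
    obs <- pmin(time, cens, 120)
    ev <- as.integer(time <= cens & time <= 120)
    grp <- rep(c("0-1", "2", ">=3"), each = n)
    multi_group_logrank(obs, ev, grp)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("univariate Cox recovers a planted HR of 2 and reports references", {
  cfg <- sim_config(seed = 61, n_genes = 1, n_patients_per_cohort = 2000,
                    covariate_hr = list(stage = c(Late = 2.0)))
  cs <- simulate_survival_cohorts(cfg)
  res <- cox_univariate(cs$cohort_a, "stage")
  ref <- res[res$level == "Early", ]
  expect_true(ref$reference)
  expect_equal(ref$hr, 1)
  late <- res[res$level == "Late", ]
  expect_gt(late$hr, 1.8)
  expect_lt(late$hr, 2.2)
  expect_true(late$ci_low <= late$hr && late$hr <= late$ci_high)
  expect_lt(late$p, 0.001)

  # null covariate: CI covers 1
  res0 <- cox_univariate(cs$cohort_a, "debulk")
  sub <- res0[res0$level == "Suboptimal", ]
  expect_true(sub$ci_low < 1 && sub$ci_high > 1)
})

test_that("multivariate Cox jointly recovers independent planted effects", {
  cfg <- sim_config(seed = 71, n_genes = 5, n_patients_per_cohort = 2000,
                    risk_genes = data.frame(gene = paste0("gene_0000", 1:5),
                                            direction = "hypo",
                                            hazard_ratio = 1.6),
                    covariate_hr = list(stage = c(Late = 3.5)))
  cs <- simulate_survival_cohorts(cfg)
  co <- cs$cohort_a
  spec <- signature_spec(
    paste0("gene_0000", 1:5), "low_value_at_risk",
    vapply(paste0("gene_0000", 1:5),
           function(g) median(cohort_values(co, g)), numeric(1))
  )
  risk <- code_risk(co, spec)
  res <- cox_multivariate(co, risk)
  late <- res[res$term == "stage" & res$level == "Late", ]
  # log-HR within 15% of the planted value
  expect_lt(abs(log(late$hr) - log(3.5)) / log(3.5), 0.15)
  hi <- res[res$term == "risk_group" & res$level == ">=3", ]
  expect_gt(hi$hr, 1)
  expect_lt(hi$p, 0.05)
  expect_identical(unique(res$term),
                   c("risk_group", "stage", "grade", "debulk"))
})

test_that("RRS selections translate into signature directions and cutoffs", {
  cs <- fixture_risky_cohorts(seed = 83, hr = 3, n = 300, n_genes = 3)
  scr <- rrs_screen(cs$cohort_a, cs$cohort_b, genes = "gene_00001")
  expect_identical(scr$verdict, "selected_hypo_risk")
  spec <- derive_signature_from_rrs(scr, cs$cohort_a)
  expect_identical(spec$risk_direction, "low_value_at_risk")
  grid <- quantile_cutoffs(cohort_values(cs$cohort_a, "gene_00001"))
  expect_true(spec$cutoff %in% as.numeric(grid))
  # mirrored rule
  scr2 <- data.frame(gene = "gene_00002", verdict = "selected_hyper_risk",
                     stringsAsFactors = FALSE)
  spec2 <- derive_signature_from_rrs(scr2, cs$cohort_a, cutoff = "median")
  expect_identical(spec2$risk_direction, "high_value_at_risk")
  expect_equal(spec2$cutoff,
               median(cohort_values(cs$cohort_a, "gene_00002")))
  expect_error(derive_signature_from_rrs(
    data.frame(gene = "g", verdict = "not_selected"), cs$cohort_a),
    "no genes")
})
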