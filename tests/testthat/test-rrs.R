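test_that("quantile cutoffs match the interpolation oracle and edge rules", {
  q <- quantile_cutoffs(1:101)
  expect_length(q, 5L)
  expect_identical(names(q), c("q25", "q33", "q50", "q67", "q75"))
  expect_equal(unname(q[["q50"]]), 51)
  expect_true(all(diff(q) >= 0))

  set.seed(8)
  x <- runif(20)
  q2 <- quantile_cutoffs(x)
  probs <- c(0.25, 1 / 3, 0.5, 2 / 3, 0.75)
  for (i in 1:5) {
    expect_equal(unname(q2[[i]]), quantile_oracle(x, probs[i]))
  }

  qc <- quantile_cutoffs(rep(0.4, 12))
  expect_true(attr(qc, "degenerate"))
  expect_error(quantile_cutoffs(1:9), "at least 10")
  expect_error(quantile_cutoffs(c(1:10, NA)), "finite")
})

test_that("dichotomize sends ties low and partitions every patient", {
  expect_identical(dichotomize(c(1, 2, 3), 2), c("low", "low", "high"))
  x <- runif(25)
  lab <- dichotomize(x, median(x))
  expect_equal(sum(lab == "low") + sum(lab == "high"), 25)
  # all values below the threshold: high arm empty, condition votes 0
  lab0 <- dichotomize(c(1, 2), 10)
  expect_true(all(lab0 == "low"))
  sc <- score_condition(c(5, 8), c(1, 1), lab0)
  expect_identical(sc$vote, 0L)
})

test_that("endpoint restriction administratively censors at the horizon", {
  r <- restrict_endpoint(c(40, 10, 36), c(1, 1, 1), 36)
  expect_equal(r$time, c(36, 10, 36))
  expect_identical(r$event, c(0L, 1L, 1L))
  ov <- restrict_endpoint(c(40, 10), c(1, 0), Inf)
  expect_equal(ov$time, c(40, 10))
  expect_identical(ov$event, c(1L, 0L))
  expect_error(restrict_endpoint(1, 1, 0), "positive")
})

test_that("log-rank matches the hand-computed 2x2 table evaluation", {
  # all events: low at {1, 2}, high at {5, 6}; O-E tables give chisq 49/17
  time <- c(1, 2, 5, 6)
  event <- c(1, 1, 1, 1)
  group <- c("low", "low", "high", "high")
  lr <- logrank_test(time, event, group)
  oracle <- logrank_oracle(time, event, group)
  expect_equal(oracle$statistic, 49 / 17)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_identical(lr$inferior_group, "low")  # excess events in the low arm

  # identical groups: null result
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1),
                      c("low", "low", "high", "high"))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  expect_identical(lr0$inferior_group, "none")

  # dominance: all-event arm is inferior to an all-censored arm
  lr1 <- logrank_test(c(1, 2, 100, 100), c(1, 1, 0, 0),
                      c("low", "low", "high", "high"))
  expect_identical(lr1$inferior_group, "low")
  expect_lt(lr1$p, 0.2)

  expect_error(logrank_test(numeric(0), integer(0), character(0)), "empty")
})

test_that("log-rank equals the brute-force oracle on random small fixtures", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    time <- sample(1:12, n, replace = TRUE)  # force ties
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("low", "high"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    lr <- logrank_test(time, event, group)
    or <- logrank_oracle(time, event, group)
    expect_equal(lr$statistic, or$statistic, tolerance = 1e-9)
    if (!lr$degenerate && abs(or$excess_first) > 1e-9) {
      expected_inferior <- if (or$excess_first > 0) or$first_group else
        setdiff(c("low", "high"), or$first_group)
      expect_identical(lr$inferior_group, expected_inferior)
    }
  }
})

test_that("condition votes follow the +1/-1/0 rule", {
  # significant inferior-low split
  time <- c(rep(2, 8), rep(50, 8))
  event <- c(rep(1, 8), rep(0, 8))
  labels <- c(rep("low", 8), rep("high", 8))
  sc <- score_condition(time, event, labels)
  expect_lt(sc$logrank_p, 0.05)
  expect_identical(sc$vote, 1L)
  sc_flip <- score_condition(time, event,
                             ifelse(labels == "low", "high", "low"))
  expect_identical(sc_flip$vote, -1L)
  # non-significant association votes 0
  sc0 <- score_condition(c(1, 3, 2, 4), c(1, 1, 1, 1),
                         c("low", "low", "high", "high"))
  expect_gt(sc0$logrank_p, 0.05)
  expect_identical(sc0$vote, 0L)
})

test_that("the RRS grid has 15 ordered conditions and a bounded total", {
  cs <- fixture_risky_cohorts(seed = 11, hr = 2.5, n = 120)
  r <- compute_rrs(cs$cohort_a, "gene_00001")
  expect_identical(nrow(r$votes), 15L)
  expect_identical(r$votes$cutoff_id,
                   rep(c("q25", "q33", "q50", "q67", "q75"), each = 3))
  expect_identical(r$votes$endpoint_id, rep(c("18m", "36m", "overall"), 5))
  expect_true(all(r$votes$vote %in% c(-1L, 0L, 1L)))
  expect_identical(r$total, sum(r$votes$vote))
  expect_true(r$total >= -15 && r$total <= 15)
  # thresholds ascend with the cutoff grid
  expect_true(all(diff(unique(r$votes$threshold)) >= 0))

  expect_error(compute_rrs(toy_cohort(1:5, rep(1, 5), runif(5)), "g1"),
               "10 analyzable")
})

test_that("negating the molecular values negates every vote and the total", {
  cs <- fixture_risky_cohorts(seed = 23, hr = 3, n = 150)
  co <- cs$cohort_a
  r_fwd <- compute_rrs(co, "gene_00001")
  co_neg <- co
  co_neg$data$gene_00001 <- -co_neg$data$gene_00001
  r_bwd <- compute_rrs(co_neg, "gene_00001")
  # cutoff k of -v mirrors cutoff (6-k) of v; totals must negate exactly
  expect_identical(r_bwd$total, -r_fwd$total)
  fwd_votes <- matrix(r_fwd$votes$vote, nrow = 3)   # endpoint x cutoff
  bwd_votes <- matrix(r_bwd$votes$vote, nrow = 3)
  expect_identical(bwd_votes, -fwd_votes[, 5:1])
})

test_that("dual-cohort concordance follows the strict |total| >= 2 rule", {
  mk <- function(total, gene = "g") {
    structure(list(gene = gene, cohort_id = "x", votes = NULL, total = total),
              class = "rrs_result")
  }
  expect_identical(select_concordant(mk(5), mk(3)), "selected_hypo_risk")
  expect_identical(select_concordant(mk(-3), mk(-2)), "selected_hyper_risk")
  expect_identical(select_concordant(mk(5), mk(-3)), "not_selected")
  expect_identical(select_concordant(mk(1), mk(1)), "not_selected")
  expect_identical(select_concordant(mk(1), mk(1), rule = "sign"),
                   "selected_hypo_risk")
  expect_error(select_concordant(mk(2, "a"), mk(2, "b")), "different genes")
})

test_that("planted hypomethylation risk drives strongly positive totals", {
  cs <- fixture_risky_cohorts(seed = 37, hr = 2.5, n = 300)
  ra <- compute_rrs(cs$cohort_a, "gene_00001")
  rb <- compute_rrs(cs$cohort_b, "gene_00001")
  expect_gte(ra$total, 2L)
  expect_gte(rb$total, 2L)
  expect_identical(select_concordant(ra, rb), "selected_hypo_risk")
})

test_that("rrs_screen reports both cohorts and honours the BH option", {
  cs <- fixture_risky_cohorts(seed = 41, hr = 2.5, n = 200, n_genes = 4)
  scr <- rrs_screen(cs$cohort_a, cs$cohort_b)
  expect_identical(nrow(scr), 4L)
  expect_identical(scr$verdict[scr$gene == "gene_00001"],
                   "selected_hypo_risk")
  scr_bh <- rrs_screen(cs$cohort_a, cs$cohort_b, adjust = "BH")
  # BH can only prune votes relative to raw p-values
  expect_true(all(abs(scr_bh$total_a) <= abs(scr$total_a) + 15L))
  expect_identical(scr_bh$gene, scr$gene)
})
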