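test_that("PSI point estimates use junction-count normalization", {
  ## two inclusion junctions vs one skipping junction: (20/2)/((20/2)+(10/1))
  p <- estimate_psi(junction_count_record("e", "s", c(10, 10), 10))
  expect_equal(p$psi, 0.5)
  expect_identical(c(p$k, p$s), c(10L, 10L))
  expect_equal(c(p$posterior_alpha, p$posterior_beta), c(11, 11))

  expect_equal(estimate_psi(junction_count_record("e", "s", c(0, 0), 30))$psi, 0)

  z <- estimate_psi(junction_count_record("e", "s", c(0, 0), 0))
  expect_false(z$defined)
  expect_true(is.na(z$psi))
  expect_equal(c(z$posterior_alpha, z$posterior_beta), c(1, 1))
  expect_true(z$ci_low <= 0.5 && z$ci_high >= 0.5)

  q <- estimate_psi(junction_count_record("e", "s", 7, 3))
  expect_true(q$ci_low <= q$psi && q$psi <= q$ci_high)
})

test_that("the Bayes factor matches its closed form on the worked examples", {
  mk <- function(s, inc, skip) junction_count_record("e", s, inc, skip)
  ## no data cannot discriminate the models
  expect_equal(bayes_factor_diff(mk("a", 0, 0), mk("b", 0, 0))$bayes_factor, 1)
  ## (5 of 5) vs (0 of 5): B(6,1)B(1,6)/B(6,6) = 2772/36 = 77
  d <- bayes_factor_diff(mk("a", 5, 0), mk("b", 0, 5))
  expect_equal(d$bayes_factor, 77, tolerance = 1e-10)
  expect_true(d$significant)
  ## identical data favor the shared model
  d2 <- bayes_factor_diff(mk("a", 5, 5), mk("b", 5, 5))
  expect_equal(d2$bayes_factor, 0.5049303, tolerance = 1e-6)
  expect_false(d2$significant)
  expect_error(bayes_factor_diff(mk("a", 1, 1),
                                 junction_count_record("other", "b", 1, 1)),
               "different events")
})

test_that("the Bayes factor is symmetric and at most 1 on identical data", {
  mk <- function(s, inc, skip) junction_count_record("e", s, inc, skip)
  set.seed(9)
  for (i in 1:30) {
    ka <- sample(0:20, 1); sa <- sample(0:20, 1)
    kb <- sample(0:20, 1); sb <- sample(0:20, 1)
    b1 <- bayes_factor_diff(mk("a", ka, sa), mk("b", kb, sb))$bayes_factor
    b2 <- bayes_factor_diff(mk("b", kb, sb), mk("a", ka, sa))$bayes_factor
    expect_equal(b1, b2, tolerance = 1e-12)
  }
  for (n in 1:15) {
    k <- sample(0:n, 1)
    self <- bayes_factor_diff(mk("a", k, n - k), mk("b", k, n - k))$bayes_factor
    expect_lte(self, 1 + 1e-12)
  }
})

test_that("closed-form Bayes factor agrees with numerical integration (spot grid)", {
  mk <- function(s, inc, skip) junction_count_record("e", s, inc, skip)
  set.seed(4)
  for (i in 1:25) {
    na <- sample(0:25, 1); ka <- if (na > 0) sample(0:na, 1) else 0L
    nb <- sample(0:25, 1); kb <- if (nb > 0) sample(0:nb, 1) else 0L
    closed <- bayes_factor_diff(mk("a", ka, na - ka), mk("b", kb, nb - kb))$bayes_factor
    oracle <- bf_numeric_oracle(ka, na, kb, nb)
    expect_equal(closed, oracle, tolerance = 1e-6)
  }
})

test_that("event enumeration reproduces the canonical toy patterns", {
  mk <- function(id, strand, s, e) transcript_model(id, "g", "c", strand, s, e)
  ## cassette exon
  se <- enumerate_as_events(list(mk("t1", "+", c(101, 301, 501), c(200, 400, 600)),
                                 mk("t2", "+", c(101, 501), c(200, 600))))
  expect_identical(se$event_type, "SE")
  expect_identical(c(se$var_start, se$var_end), c(301L, 400L))
  ## retained intron
  ri <- enumerate_as_events(list(mk("t1", "+", c(101, 301), c(200, 400)),
                                 mk("t2", "+", 101, 400)))
  expect_identical(ri$event_type, "RI")
  expect_identical(c(ri$var_start, ri$var_end), c(201L, 300L))
  ## minus-strand pair with a shifted exon start is an A5SS, not A3SS
  a5 <- enumerate_as_events(list(mk("t1", "-", c(101, 301), c(200, 400)),
                                 mk("t2", "-", c(101, 241), c(200, 400))))
  expect_identical(a5$event_type, "A5SS")
  ## ...whereas the identical geometry on the plus strand is an A3SS
  a3 <- enumerate_as_events(list(mk("t1", "+", c(101, 301), c(200, 400)),
                                 mk("t2", "+", c(101, 241), c(200, 400))))
  expect_identical(a3$event_type, "A3SS")
  ## single-transcript gene: no events
  expect_identical(nrow(enumerate_as_events(list(mk("t1", "+", 101, 400)))), 0L)
})

test_that("gain/loss direction follows the delta-PSI sign at BF >= 10", {
  ev <- data.frame(event_id = "g:SE:1:2", event_type = "SE",
                   stringsAsFactors = FALSE)
  mkdiff <- function(dpsi, bf) {
    data.frame(event_id = "g:SE:1:2", transition = "a->b", delta_psi = dpsi,
               bayes_factor = bf, significant = bf >= 10,
               stringsAsFactors = FALSE)
  }
  expect_identical(classify_gain_loss(ev, mkdiff(0.6, 50))$direction, "gain")
  expect_identical(classify_gain_loss(ev, mkdiff(-0.6, 50))$direction, "loss")
  expect_identical(classify_gain_loss(ev, mkdiff(0.6, 2))$direction, "none")
  ## non-SE events never receive a direction
  ri <- data.frame(event_id = "g:SE:1:2", event_type = "RI",
                   stringsAsFactors = FALSE)
  expect_warning(out <- classify_gain_loss(ri, mkdiff(0.6, 50)), "SE")
  expect_identical(out$direction, "none")
})

test_that("persistence requires every later stage to hold the new form", {
  expect_true(as.logical(event_persists(c(0.1, 0.1, 0.7, 0.7, 0.6), 2)))
  expect_false(as.logical(event_persists(c(0.1, 0.1, 0.7, 0.12, 0.1), 2)))
  r <- event_persists(c(0.1, 0.1, 0.7, NA, 0.7), 2)
  expect_false(as.logical(r))
  expect_match(attr(r, "reason"), "undefined")
  ## loss direction mirrors the rule
  expect_true(as.logical(event_persists(c(0.8, 0.8, 0.2, 0.25, 0.2), 2)))
  expect_error(event_persists(c(0.1, 0.7), 2), "transition_index")
})

test_that("overlap_sets returns exact Venn counts", {
  disjoint <- overlap_sets(list(a = c("x", "y"), b = "z", c = "w"))
  expect_true(all(disjoint$n_intersection[disjoint$degree > 1] == 0))
  ident <- overlap_sets(list(a = c("x", "y"), b = c("x", "y")))
  expect_identical(ident$n_intersection[ident$sets == "a&b"], 2L)
  planted <- overlap_sets(list(germ = c(paste0("g", 1:10), "shared1", "shared2"),
                               neural = c(paste0("n", 1:8), "shared1", "shared2")))
  expect_identical(planted$n_intersection[planted$sets == "germ&neural"], 2L)
  expect_error(overlap_sets(list(c("a"))), "named")
})

test_that("a small planted cohort is recovered by the quantification chain", {
  cfg <- cohort_config(n_genes = 300, seed = 17)
  b <- simulate_cohort(cfg)
  diffs <- diff_splice_table(b$records, cfg$stage_names)
  cl <- classify_gain_loss(b$events, diffs)
  tf <- tally_frequencies(cl)
  row <- tf[tf$transition == "SG_diff->SC_preL", ]
  expect_gt(row$n_significant, 280)
  expect_equal(row$frac_SE, 0.55, tolerance = 0.03)
  expect_equal(row$gain_loss_ratio, 2, tolerance = 0.2)
  ## transitions with no change are flagged with undefined fractions
  first <- tf[tf$transition == "SG_und->SG_diff", ]
  expect_true(first$flagged)
  expect_true(is.na(first$frac_SE))
})

test_that("posterior mean converges to the true PSI at high depth", {
  set.seed(31)
  depth <- 800
  for (psi in seq(0.1, 0.9, by = 0.2)) {
    err <- replicate(200, {
      k <- rbinom(1, depth, psi)
      est <- estimate_psi(junction_count_record("e", "s", k, depth - k))
      abs(est$posterior_alpha / (est$posterior_alpha + est$posterior_beta) - psi)
    })
    expect_gte(mean(err <= 0.05), 0.95)
  }
})
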