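# Filtering, summaries, NetNegInt, repeated-measures inference.

test_that("filter_trials keeps correct trials and books removals", {
  d <- design_spec(n_subjects = 3)
  tr <- gen_trials(d, rt_model_params(err_rate = 0), 2)
  expect_message(out <- filter_trials(tr), "removed 0 incorrect")
  expect_equal(nrow(out), nrow(tr))

  tr10 <- tr[1:10, ]
  tr10$correct <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1)
  tr10$subject <- 1; tr10$polarity <- rep(c("positive", "negative"), 5)
  tr10$probe_type <- rep(c("linguistic", "linguistic", "symbolic", "symbolic"),
                         length.out = 10)
  suppressMessages(out10 <- filter_trials(tr10))
  expect_equal(nrow(out10), 7)
  expect_equal(unname(attr(out10, "n_removed")["incorrect"]), 3)
})

test_that("per-subject RT trimming matches a brute-force two-pass oracle", {
  d <- design_spec(n_subjects = 6)
  tr <- gen_trials(d, rt_model_params(), 31)
  pol <- filter_policy(correct_only = TRUE, sd_limit = 2)
  suppressMessages(out <- filter_trials(tr, pol))

  # oracle: direct two-pass computation on the accuracy-filtered table
  ref <- tr[tr$correct == 1, ]
  keep <- logical(nrow(ref))
  for (s in unique(ref$subject)) {
    i <- ref$subject == s
    keep[i] <- ref$rt_ms[i] <= mean(ref$rt_ms[i]) + 2 * sd(ref$rt_ms[i])
  }
  expect_equal(out$rt_ms, ref$rt_ms[keep])
})

test_that("filtering that empties a cell fails loudly", {
  d <- design_spec(n_subjects = 2)
  tr <- gen_trials(d, rt_model_params(err_rate = 0), 3)
  kill <- tr$subject == 1 & tr$polarity == "negative" & tr$probe_type == "linguistic"
  tr$correct[kill] <- 0
  expect_error(suppressMessages(filter_trials(tr)), "empty cell.*subject 1")
})

test_that("condition_summary computes textbook means and SDs", {
  tab <- data.frame(subject = 1,
                    polarity = rep(c("positive", "negative"), each = 2),
                    probe_type = "linguistic",
                    proportion = 1, token = 1:2,
                    rt_ms = c(800, 1000, 700, 700), correct = 1)
  cs <- condition_summary(tab)
  pos <- cs[cs$polarity == "positive", ]
  expect_equal(pos$mean_rt, 900)
  expect_equal(pos$sd_rt, sqrt(sum((c(800, 1000) - 900)^2) / 1))  # 141.421...
  expect_equal(pos$sd_rt, 141.4214, tolerance = 1e-4)
  neg <- cs[cs$polarity == "negative", ]
  expect_equal(neg$mean_rt, 700)
  expect_equal(neg$sd_rt, 0)

  d <- design_spec(n_subjects = 2)
  tr <- gen_trials(d, rt_model_params(), 4)
  expect_equal(nrow(condition_summary(tr, by_proportion = TRUE)), 20)
})

test_that("net_neg_int reproduces arithmetic on group condition means", {
  # one subject whose cell means are the published group means:
  # less 1035.3, more 882.8, '<' 971.4, '>' 888.0
  m <- matrix(c(882.8, 1035.3, 888.0, 971.4), 1)  # posL negL posS negS
  tab <- cellmeans_table(m)
  nn <- net_neg_int(tab)
  expect_equal(nn$delta_ling, 152.5)
  expect_equal(nn$delta_symb, 83.4)
  expect_equal(nn$net, 69.1, tolerance = 1e-12)
  expect_equal(nn$per_subject$net, 69.1, tolerance = 1e-12)

  # all means equal -> zero everywhere
  nn0 <- net_neg_int(cellmeans_table(matrix(rep(900, 4), 1)))
  expect_equal(nn0$net, 0)

  # swapping polarity labels negates the net
  tab2 <- tab
  tab2$polarity <- ifelse(tab$polarity == "positive", "negative", "positive")
  expect_equal(net_neg_int(tab2)$net, -nn$net)
})

test_that("vector-form NetNegInt mean equals grand-means form when balanced", {
  d <- design_spec(n_subjects = 9)
  tr <- gen_trials(d, rt_model_params(), 8)
  nn <- net_neg_int(tr)
  expect_equal(mean(nn$per_subject$net), nn$net, tolerance = 1e-9)
})

test_that("rm-ANOVA interaction F equals the squared paired t on the contrast", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(exp(rnorm(21 * 4, 6.8, 0.3)), 21)
    tab <- cellmeans_table(m)
    an <- rm_anova_2x2_log(tab)
    lg <- log(m)
    dd <- (lg[, 2] - lg[, 1]) - (lg[, 4] - lg[, 3])  # (negL-posL)-(negS-posS)
    tt <- paired_t(dd, rep(0, 21))
    fi <- an[an$effect == "polarity:probe_type", ]
    expect_equal(fi$F, tt$t^2, tolerance = 1e-10)
    expect_equal(fi$p, tt$p, tolerance = 1e-10)
    expect_equal(fi$df1, 1)
    expect_equal(fi$df2, 20)
  }
})

test_that("rm-ANOVA is location invariant and vanishes for null contrasts", {
  set.seed(7)
  m <- matrix(exp(rnorm(10 * 4, 6.8, 0.2)), 10)
  a1 <- rm_anova_2x2_log(cellmeans_table(m))
  a2 <- rm_anova_2x2_log(cellmeans_table(m * 3))  # constant shift on log scale
  expect_equal(a1$F, a2$F, tolerance = 1e-8)

  # zero interaction contrast for every subject
  base <- exp(rnorm(10, 6.8, 0.2))
  m0 <- cbind(base, base * 1.2, base * 1.05, base * 1.26)
  a0 <- rm_anova_2x2_log(cellmeans_table(m0))
  expect_equal(a0$F[a0$effect == "polarity:probe_type"], 0, tolerance = 1e-9)
})

test_that("rm-ANOVA rejects subjects with missing cells", {
  m <- matrix(exp(rnorm(4 * 4, 6.8, 0.2)), 4)
  tab <- cellmeans_table(m)
  tab <- tab[!(tab$subject == 2 & tab$polarity == "negative" &
                 tab$probe_type == "symbolic"), ]
  expect_error(rm_anova_2x2_log(tab), "missing cells: 2")
})

test_that("paired_t matches hand computation and handles degenerate input", {
  # differences 1,2,3: mean 2, sd 1, t = 2*sqrt(3)
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  shift <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(shift$t, Inf)
  expect_equal(shift$p, 0)
  expect_true(shift$degenerate)

  a <- c(5, 9, 4, 7); b <- c(3, 10, 2, 5)
  expect_equal(paired_t(a, b)$t, -paired_t(b, a)$t)
  expect_equal(paired_t(a, b)$p, paired_t(b, a)$p)
})

test_that("interaction test holds its type-I error rate under the null", {
  d <- design_spec(n_subjects = 21)
  p0 <- rt_model_params(delta_ling = 80, delta_symb = 80)  # null interaction
  nsim <- 500
  rej <- 0
  for (i in seq_len(nsim)) {
    tr <- gen_trials(d, p0, 5000 + i)
    an <- rm_anova_2x2_log(tr)
    if (an$p[an$effect == "polarity:probe_type"] <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})

test_that("interaction rejection rate grows with the injected net effect", {
  d <- design_spec(n_subjects = 21)
  rates <- sapply(c(0, 60, 150), function(net) {
    rej <- 0
    for (i in 1:60) {
      tr <- gen_trials(d, rt_model_params(delta_ling = 80 + net, delta_symb = 80),
                       9000 + i)
      an <- rm_anova_2x2_log(tr)
      if (an$p[an$effect == "polarity:probe_type"] <= 0.05) rej <- rej + 1
    }
    rej / 60
  })
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.8)
})
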