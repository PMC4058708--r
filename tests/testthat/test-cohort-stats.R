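test_that("window averages use the available epochs only", {
  tl <- data.frame(start_hour = c(1, 10, 40), network_size = c(8, 12, 13),
                   C_rel = c(1, 2, NA))
  expect_equal(period_average(tl, 24)$network_size, 10)
  expect_equal(period_average(tl, 72)$network_size, 11)   # stop at 40 h
  expect_equal(period_average(tl, 72)$C_rel, 1.5)         # NA skipped
  expect_true(is.na(period_average(tl[tl$start_hour > 50, ], 72)$network_size))

  const <- data.frame(start_hour = c(2, 5), network_size = c(7, 7))
  expect_equal(period_average(const, 24)$network_size, 7)

  metrics <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                        start_hour = c(1, 30, 1, 30),
                        network_size = c(8, 12, 4, 6))
  ss <- subject_summaries(metrics, windows = c(24, 48))
  expect_equal(nrow(ss), 4)
  expect_equal(ss$network_size[ss$subject_id == "a" & ss$window_h == 48], 10)
})

test_that("group comparison is a pooled two-sample t-test with the expected symmetries", {
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- compare_groups(c(a, b), rep(c(TRUE, FALSE), each = 3))
  # textbook pooled t: means 2 and 5, pooled sd 1
  expect_equal(r$t, (2 - 5) / (1 * sqrt(2 / 3)))
  expect_equal(r$p, 2 * pt(abs(r$t), df = 4, lower.tail = FALSE))
  swapped <- compare_groups(c(a, b), rep(c(FALSE, TRUE), each = 3))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)
  expect_error(compare_groups(c(1, 2, 3), c(TRUE, FALSE, FALSE)), "at least 2")
})

test_that("CPC correlation is tie-aware Spearman with exact small-sample p", {
  dec <- correlate_cpc(c(10, 8, 5, 3, 1), c(1, 2, 3, 4, 5))
  expect_equal(dec$rho, -1)

  # mid-rank hand computation for {1,1,2} vs {1,2,3}
  r <- correlate_cpc(c(1, 1, 2), c(1, 2, 3))
  rx <- c(1.5, 1.5, 3); ry <- c(1, 2, 3)
  expect_equal(r$rho, sum((rx - 2) * (ry - 2)) /
                 sqrt(sum((rx - 2)^2) * sum((ry - 2)^2)))

  # the exact permutation p matches cor.test's exact method when tie-free
  set.seed(4)
  x <- rnorm(7); y <- sample(1:7)
  mine <- correlate_cpc(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  # independence at larger n: near-zero rho, asymptotic p
  set.seed(5)
  big <- correlate_cpc(rnorm(60), sample(1:5, 60, TRUE))
  expect_lt(abs(big$rho), 0.3)
  expect_equal(big$method, "asymptotic (tie-corrected)")

  expect_true(is.na(correlate_cpc(rep(1, 5), c(1, 2, 3, 4, 5))$rho))
  expect_error(correlate_cpc(1:2, 1:2), "at least 3")
})

test_that("sum-of-ranks scores are centered oriented rank sums", {
  # one subject dominating every oriented component
  s2 <- data.frame(network_size = c(10, 5), n_connections = c(50, 20),
                   C_rel = c(1.1, 2.0), L_rel = c(1.1, 0.8))
  sr2 <- sum_of_ranks(s2, c(TRUE, FALSE))
  expect_equal(sr2$scores, c(2, -2))

  same <- data.frame(network_size = rep(3, 4), n_connections = rep(9, 4),
                     C_rel = rep(1, 4), L_rel = rep(1, 4))
  expect_equal(sum_of_ranks(same, c(TRUE, TRUE, FALSE, FALSE))$scores,
               rep(0, 4))

  # 4 subjects against an independent ranking oracle
  s4 <- data.frame(network_size = c(12, 9, 5, 7),
                   n_connections = c(60, 40, 15, 30),
                   C_rel = c(1.2, 1.5, 3.0, 2.0),
                   L_rel = c(1.15, 1.0, 0.7, 0.9))
  sr4 <- sum_of_ranks(s4, c(TRUE, TRUE, FALSE, FALSE))
  oracle <- rank(s4$network_size) + rank(s4$n_connections) +
    rank(-s4$C_rel) + rank(s4$L_rel) - 4 * 2.5
  expect_equal(sr4$scores, unname(oracle))
  expect_equal(sum(sr4$scores), 0)

  # subjects with a missing component are excluded but reported
  s5 <- rbind(s4, data.frame(network_size = 1, n_connections = 2,
                             C_rel = NA, L_rel = 0.5))
  sr5 <- sum_of_ranks(s5, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sr5$excluded, 5L)
  expect_true(is.na(sr5$scores[5]))
  expect_equal(sum(sr5$scores, na.rm = TRUE), 0)
})

test_that("the exact rank-sum test matches reference distributions", {
  set.seed(6)
  x <- rnorm(6); y <- rnorm(5) + 0.5
  mine <- sfnet:::.ranksum_test(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # fully separated groups hit the combinatorial minimum
  expect_equal(sfnet:::.ranksum_test(1:10, 11:20)$p, 2 / choose(20, 10))
  # tie-aware: enumerate all group assignments directly as the oracle
  v <- c(1, 2, 2, 3, 4, 4, 5, 6); g1 <- c(1, 2, 5, 7)
  r <- rank(v)
  obs <- sum(r[g1])
  combos <- utils::combn(8, 4)
  sums <- apply(combos, 2, function(ix) sum(r[ix]))
  p_or <- min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
  expect_equal(sfnet:::.ranksum_test(v[g1], v[-g1])$p, p_or)
})

test_that("ROC analysis reports sensitivity at full specificity and the U/AUC identity", {
  sep <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(TRUE, FALSE), each = 3),
                      direction = ">")
  expect_equal(sep$auc, 1)
  expect_equal(sep$sens_at_full_spec, 1)

  flat <- roc_analysis(rep(1, 6), rep(c(TRUE, FALSE), each = 3))
  expect_equal(flat$sens_at_full_spec, 0)

  set.seed(9)
  sc <- rnorm(30); poor <- rep(c(TRUE, FALSE), 15)
  r <- roc_analysis(sc, poor, direction = ">")
  U <- wilcox.test(sc[!poor], sc[poor])$statistic
  expect_equal(r$auc, unname(U) / (15 * 15))
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("adding label noise cannot raise sensitivity at full specificity", {
  set.seed(10)
  scores <- c(rnorm(15, 0), rnorm(15, 3))
  labels <- rep(c(TRUE, FALSE), each = 15)      # poor outcome = low scores
  sens <- sapply(c(0, 3, 6), function(k) {
    lab <- labels
    if (k > 0) { flip <- sample(30, k); lab[flip] <- !lab[flip] }
    roc_analysis(scores, lab, direction = ">")$sens_at_full_spec
  })
  expect_true(all(diff(sens) <= 0))
})

test_that("subgroup contrasts pool the malignant visual classes and exclude bursts", {
  md <- data.frame(
    subject_id = sprintf("s%02d", 1:10),
    ssep_status = c(rep("bilateral_absent", 3), rep("present", 7)),
    visual_eeg = c("iso_electric", "low_voltage", "low_voltage",
                   "burst_suppression", "burst_suppression",
                   rep("diffuse_slowing", 5)))
  set.seed(11)
  worse <- c(rnorm(3, 4), rnorm(2, 8), rnorm(5, 10))
  summ <- data.frame(subject_id = md$subject_id,
                     network_size = worse, n_connections = worse * 5,
                     L_rel = worse / 10, C_rel = 3 - worse / 5,
                     SWI = 3 - worse / 6)
  tab <- subgroup_compare(summ, md, "visual_eeg")
  expect_setequal(tab$metric, c("network_size", "n_connections", "L_rel",
                                "C_rel", "SWI", "sum_of_ranks"))
  # burst subjects excluded: 3 vs 5 subjects in the contrast
  expect_equal(unique(tab$n1[tab$metric != "sum_of_ranks"]), 3)
  expect_equal(unique(tab$n2[tab$metric != "sum_of_ranks"]), 5)
  # malignant group has smaller networks by construction
  expect_lt(tab$mean1[tab$metric == "network_size"],
            tab$mean2[tab$metric == "network_size"])

  ssep <- subgroup_compare(summ, md, "ssep")
  expect_equal(unique(ssep$n1[ssep$metric != "sum_of_ranks"]), 3)
  expect_equal(unique(ssep$n2[ssep$metric != "sum_of_ranks"]), 7)

  md2 <- md; md2$ssep_status <- "present"
  expect_error(subgroup_compare(summ, md2, "ssep"), "empty group")
})
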