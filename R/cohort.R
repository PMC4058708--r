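#' Average a subject's metric timeline over a clinical window
#'
#' Mean of each metric over the epochs whose start hour lies in [0, window);
#' subjects whose registration stopped early contribute the epochs they have.
#' Metrics missing in every contributing epoch stay missing.
#'
#' @param timeline data.frame with `start_hour` plus metric columns.
#' @param window_h window end in hours (24, 48 or 72 in the study design).
#' @return One-row data.frame of window means (all NA when no epoch falls in
#'   the window).
#' @export
period_average <- function(timeline, window_h) {
  metric_cols <- setdiff(names(timeline), c("subject_id", "start_hour"))
  sel <- timeline$start_hour < window_h
  out <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(metric_cols)), metric_cols)))
  if (!any(sel)) return(out)
  m <- colMeans(timeline[sel, metric_cols, drop = FALSE], na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  as.data.frame(as.list(m))
}

#' Per-subject window summaries for a cohort metrics table
#'
#' @param metrics data.frame with `subject_id`, `start_hour` and metric
#'   columns (one row per subject-epoch).
#' @param windows window ends in hours.
#' @return data.frame with one row per subject x window (`window_h` column).
#' @export
subject_summaries <- function(metrics, windows = c(24, 48, 72)) {
  out <- list()
  for (sid in unique(metrics$subject_id)) {
    tl <- metrics[metrics$subject_id == sid, , drop = FALSE]
    for (w in windows) {
      row <- period_average(tl, w)
      if (all(is.na(row))) next   # no registration in this window
      out[[length(out) + 1L]] <- cbind(
        data.frame(subject_id = sid, window_h = w), row)
    }
  }
  do.call(rbind, out)
}

#' Two-sample comparison of a metric between outcome groups
#'
#' Classic pooled-variance two-sample t-test (two-sided) with group
#' means and standard deviations.
#'
#' @param values per-subject metric values.
#' @param group1 logical vector, TRUE for the first group (e.g. survivors).
#' @return List with `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`, `t`, `p`.
#' @export
compare_groups <- function(values, group1) {
  keep <- !is.na(values) & !is.na(group1)
  values <- values[keep]; group1 <- group1[keep]
  x <- values[group1]; y <- values[!group1]
  if (length(x) < 2 || length(y) < 2)
    .stopf("each group needs at least 2 non-missing subjects")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
       mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
       t = unname(tt$statistic), p = tt$p.value)
}

# all permutations of 1..n (n small) as a matrix, one permutation per row
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation with CPC score
#'
#' Tie-aware Spearman rank correlation (Pearson correlation of mid-ranks).
#' The two-sided p-value is exact for n <= 8 (full enumeration of rank
#' permutations) and uses the asymptotic tie-corrected approximation
#' otherwise.
#'
#' @param values per-subject metric.
#' @param cpc per-subject CPC scores (1-5).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
correlate_cpc <- function(values, cpc) {
  keep <- !is.na(values) & !is.na(cpc)
  values <- values[keep]; cpc <- cpc[keep]
  n <- length(values)
  if (n < 3) .stopf("need at least 3 subjects for a correlation")
  if (stats::sd(values) == 0 || stats::sd(cpc) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rx <- rank(values); ry <- rank(cpc)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    P <- .all_perms(n)
    ry_c <- ry - mean(ry)
    rx_c <- rx - mean(rx)
    num <- matrix(ry_c[P], nrow(P), n) %*% rx_c
    rhos <- num / (sqrt(sum(rx_c^2)) * sqrt(sum(ry_c^2)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    ct <- suppressWarnings(
      stats::cor.test(values, cpc, method = "spearman", exact = FALSE))
    p <- ct$p.value
    method <- "asymptotic (tie-corrected)"
  }
  list(rho = unname(rho), p = p, n = n, method = method)
}

#' Centered sum-of-ranks composite and its group contrast
#'
#' Each of the four metrics — network size, number of connections, relative
#' clustering coefficient and relative path length — is ranked across the
#' cohort (mid-ranks for ties) and centered by subtracting the mean rank.
#' Components are oriented so that every one points the same way
#' (`orientation`, default: size, connections and L ascending, C inverted);
#' the per-subject score is the sum of the four oriented centered ranks, so
#' scores sum to zero across the cohort. Subjects missing any component are
#' excluded (and listed in `excluded`). Groups are compared with the
#' Wilcoxon rank-sum test on the scores.
#'
#' @param summary data.frame with columns `network_size`, `n_connections`,
#'   `C_rel`, `L_rel` (one row per subject).
#' @param group1 logical vector, TRUE for the first group.
#' @param orientation named numeric signs for
#'   c(network_size, n_connections, C_rel, L_rel).
#' @return List with `scores` (NA for excluded subjects), `excluded`
#'   (indices), `mean1`, `sd1`, `mean2`, `sd2`, `W`, `p`.
#' @export
sum_of_ranks <- function(summary, group1,
                         orientation = c(network_size = 1, n_connections = 1,
                                         C_rel = -1, L_rel = 1)) {
  comps <- names(orientation)
  stopifnot(all(comps %in% names(summary)))
  X <- as.matrix(summary[, comps, drop = FALSE])
  complete <- stats::complete.cases(X)
  N <- sum(complete)
  scores <- rep(NA_real_, nrow(X))
  if (N >= 2) {
    cent <- apply(X[complete, , drop = FALSE], 2,
                  function(v) rank(v) - (N + 1) / 2)
    scores[complete] <- as.vector(cent %*% orientation)
  }
  g1 <- group1 & complete; g2 <- !group1 & complete
  if (sum(g1) < 1 || sum(g2) < 1)
    .stopf("both groups need subjects with all four metrics")
  wt <- .ranksum_test(scores[g1], scores[g2])
  list(scores = scores, excluded = which(!complete),
       mean1 = mean(scores[g1]), sd1 = stats::sd(scores[g1]),
       mean2 = mean(scores[g2]), sd2 = stats::sd(scores[g2]),
       W = wt$W, p = wt$p)
}

# Wilcoxon rank-sum test; exact permutation distribution (tie-aware via
# mid-ranks) for cohorts up to `exact_max` subjects, computed by dynamic
# programming over the distribution of size-n1 rank subsets; normal
# approximation beyond.
.ranksum_test <- function(x, y, exact_max = 40) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (N > exact_max) {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    return(list(W = W, p = wt$p.value))
  }
  u <- round(2 * r)  # mid-ranks doubled: integers
  smax <- sum(u)
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, n1 + 1, smax + 1)
  f[1, 1] <- 1
  for (i in seq_along(u)) {
    for (k in min(n1, i):1) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) f[k + 1, nz + u[i]] <- f[k + 1, nz + u[i]] + f[k, nz]
    }
  }
  dist <- f[n1 + 1, ]
  tot <- sum(dist)
  obs <- round(2 * W)
  p_le <- sum(dist[seq_len(obs + 1)]) / tot
  p_ge <- sum(dist[(obs + 1):(smax + 1)]) / tot
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

#' ROC analysis of a prognostic score
#'
#' Full ROC curve over all thresholds (via pROC) plus the operating point of
#' interest for prognostication: the maximum sensitivity among thresholds
#' with 100% specificity (zero false positives).
#'
#' @param scores per-subject scores.
#' @param poor logical vector, TRUE for the poor-outcome class.
#' @param direction as in [pROC::roc]: "<" means higher scores predict poor
#'   outcome, ">" lower; "auto" picks the direction with AUC >= 0.5.
#' @return List with `auc`, `sens_at_full_spec`, `curve` (data.frame of
#'   threshold, sensitivity, specificity) and the `pROC::roc` object.
#' @export
roc_analysis <- function(scores, poor, direction = "auto") {
  keep <- !is.na(scores) & !is.na(poor)
  scores <- scores[keep]; poor <- poor[keep]
  if (length(unique(poor)) < 2)
    .stopf("ROC analysis needs both outcome classes")
  r <- pROC::roc(response = factor(poor, levels = c(FALSE, TRUE)),
                 predictor = scores, direction = direction,
                 levels = c("FALSE", "TRUE"), quiet = TRUE)
  cd <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity"), transpose = FALSE)
  full_spec <- cd$sensitivity[cd$specificity >= 1 - 1e-12]
  list(auc = as.numeric(pROC::auc(r)),
       sens_at_full_spec = if (length(full_spec)) max(full_spec) else 0,
       curve = cd, roc = r)
}

#' Compare network metrics between clinical subgroups
#'
#' Two groupings from the study design: `ssep` contrasts bilaterally absent
#' versus (uni- or bilaterally) present cortical SSEP responses; `visual_eeg`
#' contrasts the pooled iso-electric + low-voltage categories against diffuse
#' slowing (burst suppression and other categories are excluded from this
#' contrast). Per metric, a pooled-variance t-test as in [compare_groups()];
#' the sum-of-ranks contrast is appended.
#'
#' @param summary per-subject window summary (one row per subject) with the
#'   metric columns.
#' @param metadata data.frame with `subject_id`, `ssep_status`, `visual_eeg`.
#' @param grouping `"ssep"` or `"visual_eeg"`.
#' @param metrics metric columns to compare.
#' @return data.frame, one row per metric plus one for the sum-of-ranks
#'   composite: group means, sds, ns, statistic, p.
#' @export
subgroup_compare <- function(summary, metadata, grouping = c("ssep", "visual_eeg"),
                             metrics = c("network_size", "n_connections",
                                         "L_rel", "C_rel", "SWI")) {
  grouping <- match.arg(grouping)
  md <- metadata[match(summary$subject_id, metadata$subject_id), ]
  if (grouping == "ssep") {
    in_contrast <- rep(TRUE, nrow(md))
    group1 <- md$ssep_status == "bilateral_absent"
  } else {
    in_contrast <- md$visual_eeg %in% c("iso_electric", "low_voltage",
                                        "diffuse_slowing")
    group1 <- md$visual_eeg %in% c("iso_electric", "low_voltage")
  }
  s <- summary[in_contrast, , drop = FALSE]
  g1 <- group1[in_contrast]
  if (sum(g1) == 0 || sum(!g1) == 0)
    .stopf("grouping '%s' leaves an empty group", grouping)
  rows <- lapply(metrics, function(mc) {
    r <- compare_groups(s[[mc]], g1)
    data.frame(metric = mc, mean1 = r$mean1, sd1 = r$sd1, n1 = r$n1,
               mean2 = r$mean2, sd2 = r$sd2, n2 = r$n2,
               statistic = r$t, p = r$p)
  })
  sr <- sum_of_ranks(s, g1)
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "sum_of_ranks", mean1 = sr$mean1, sd1 = sr$sd1, n1 = sum(g1),
    mean2 = sr$mean2, sd2 = sr$sd2, n2 = sum(!g1),
    statistic = sr$W, p = sr$p)
  do.call(rbind, rows)
}
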