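test_that("subgroup medians summarise the partitioned library", {
  vals <- rbind(s1 = c(1, 2, 9, 5), s2 = c(4, 4, 4, 7))
  colnames(vals) <- c("g001", "g002", "g003", "g004")
  lib <- partition_library(c("H5N3", "H4N2F1", "H3N1F2", "H3N1S1"),
                           colnames(vals))
  rmx <- make_rm(vals, group = c("ctrl", "CD"), library = lib)
  sm <- subgroup_median(rmx, by = c("all", "class"))
  expect_equal(sm$median_log2_rfu[sm$sample_id == "s1" &
                                    sm$subgroup == "all"],
               median(c(1, 2, 9, 5)))
  # singleton subgroup median is that cell
  expect_equal(sm$median_log2_rfu[sm$sample_id == "s1" &
                                    sm$subgroup == "sialylated_only"], 5)
  # fucosylated_only covers g002 (F1) and g003 (F2)
  expect_equal(sm$median_log2_rfu[sm$sample_id == "s2" &
                                    sm$subgroup == "fucosylated_only"],
               median(c(4, 4)))
  expect_true(all(sm$n_glycans[sm$subgroup == "all"] == 4))
})

test_that("selected-pair ANOVA matches the pooled pairwise reference", {
  set.seed(101)
  groups <- rep(c("ctrl", "UC", "CD"), times = c(8, 7, 9))
  values <- rnorm(length(groups)) + 5 * (groups == "CD")
  res <- selected_pair_anova(values, groups)
  # F statistic against the stock linear-model ANOVA
  ref_f <- anova(lm(values ~ factor(groups)))$`F value`[1]
  expect_equal(attr(res, "F"), ref_f, tolerance = 1e-12)
  # raw pairwise p against pairwise.t.test with pooled SD, no adjustment
  ref_p <- pairwise.t.test(values, factor(groups, c("ctrl", "UC", "CD")),
                           p.adjust.method = "none", pool.sd = TRUE)$p.value
  expect_equal(res$p_value[res$comparison == "ctrl_vs_UC"],
               ref_p["UC", "ctrl"], tolerance = 1e-12)
  expect_equal(res$p_value[res$comparison == "ctrl_vs_CD"],
               ref_p["CD", "ctrl"], tolerance = 1e-12)
  # Bonferroni identity with factor exactly 2, capped at 1
  expect_equal(res$adj_p_value, pmin(1, 2 * res$p_value))
  expect_true(all(res$adj_p_value >= res$p_value))
  # shifted CD detected, UC not
  expect_lt(res$adj_p_value[res$comparison == "ctrl_vs_CD"], 0.05)
  expect_gt(res$adj_p_value[res$comparison == "ctrl_vs_UC"], 0.05)
})

test_that("ANOVA null case and input validation behave", {
  values <- rep(c(3, 3, 3), times = c(4, 4, 4))
  groups <- rep(c("ctrl", "UC", "CD"), each = 4)
  res <- selected_pair_anova(values, groups)
  expect_equal(res$p_value, c(1, 1))
  expect_equal(res$adj_p_value, c(1, 1))
  expect_error(selected_pair_anova(1:5, c("ctrl", "ctrl", "UC", "UC", "CD")),
               ">= 2")
})

test_that("Kruskal-Wallis/Dunn selected pairs match hand-computed ranks", {
  values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  groups <- rep(c("ctrl", "UC", "CD"), each = 3)
  res <- selected_pair_kw_dunn(values, groups)
  # no ties: sigma2 = N(N+1)/12 = 7.5; mean ranks 2, 5, 8
  expect_equal(res$statistic[res$comparison == "ctrl_vs_UC"],
               3 / sqrt(7.5 * (2 / 3)), tolerance = 1e-12)
  expect_equal(res$statistic[res$comparison == "ctrl_vs_CD"],
               6 / sqrt(7.5 * (2 / 3)), tolerance = 1e-12)
  expect_gt(res$statistic[2], res$statistic[1])
  expect_equal(attr(res, "H"),
               unname(kruskal.test(values, factor(groups))$statistic),
               tolerance = 1e-12)
})

test_that("KW/Dunn is invariant under strictly monotone transforms", {
  set.seed(33)
  values <- rnorm(30)
  groups <- rep(c("ctrl", "UC", "CD"), each = 10)
  r1 <- selected_pair_kw_dunn(values, groups)
  r2 <- selected_pair_kw_dunn(exp(values) + 3, groups)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(attr(r1, "H"), attr(r2, "H"), tolerance = 1e-12)
})

test_that("KW/Dunn flags the all-identical degenerate case with p = 1", {
  res <- selected_pair_kw_dunn(rep(2, 9), rep(c("ctrl", "UC", "CD"), 3))
  expect_true(all(res$degenerate))
  expect_equal(res$p_value, c(1, 1))
})

test_that("trigamma_inverse inverts trigamma over many magnitudes", {
  y <- c(1e-7, 1e-4, 0.05, 0.5, 2, 20, 1e8)
  expect_equal(trigamma(trigamma_inverse(y)), y, tolerance = 1e-6)
})

test_that("moderated variances are bracketed by prior and sample variance", {
  set.seed(17)
  for (rep in 1:5) {
    s2 <- rchisq(50, df = 4) / 4 * exp(rnorm(50, 0, 0.5))
    mod <- moderate_variances(s2, df = 4)
    lo <- pmin(mod$var_prior, s2)
    hi <- pmax(mod$var_prior, s2)
    expect_true(all(mod$var_post >= lo - 1e-12))
    expect_true(all(mod$var_post <= hi + 1e-12))
  }
})

test_that("differential fit handles flat glycans and degenerate variance", {
  vals <- cbind(flat = rep(3, 8), vary = c(1, 2, 3, 4, 2, 3, 4, 5))
  rmx <- make_rm(vals, group = rep(c("ctrl", "CD"), each = 4))
  de <- fit_differential(rmx, "ctrl", "CD")
  expect_equal(de$logFC[de$glycan_id == "flat"], 0)
  expect_equal(de$p_value[de$glycan_id == "flat"], 1)
  # all-zero variance falls back to ordinary t with warning
  allflat <- make_rm(cbind(a = rep(3, 6), b = rep(4, 6)),
                     group = rep(c("ctrl", "CD"), each = 3))
  expect_warning(de2 <- fit_differential(allflat, "ctrl", "CD"),
                 "falling back")
  expect_equal(de2$logFC, c(0, 0))
})

test_that("unmoderated fit reproduces the pooled two-sample t-test", {
  set.seed(55)
  vals <- matrix(rnorm(10 * 15), 10, 15)
  rmx <- make_rm(vals, group = rep(c("ctrl", "CD"), times = c(4, 6)))
  de <- fit_differential(rmx, "ctrl", "CD", moderation = FALSE)
  for (j in c(1, 7, 15)) {
    tt <- t.test(vals[5:10, j], vals[1:4, j], var.equal = TRUE)
    expect_equal(de$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(de$p_value[j], tt$p.value, tolerance = 1e-12)
    expect_equal(de$logFC[j], mean(vals[5:10, j]) - mean(vals[1:4, j]),
                 tolerance = 1e-12)
  }
})

test_that("moderated fit agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(77)
  # heterogeneous per-glycan scales so the prior df is finite
  scales <- exp(rnorm(40, 0, 0.8))
  vals <- sapply(scales, function(s) rnorm(12, sd = s))
  rmx <- make_rm(vals, group = rep(c("ctrl", "CD"), each = 6))
  de <- fit_differential(rmx, "ctrl", "CD", moderation = TRUE)
  design <- cbind(1, rep(c(0, 1), each = 6))
  fit <- limma::eBayes(limma::lmFit(t(vals), design))
  expect_equal(attr(de, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "var_prior"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$s2_post, unname(fit$s2.post), tolerance = 1e-8)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("swapping the contrast negates logFC and preserves p-values", {
  set.seed(88)
  vals <- matrix(rnorm(12 * 25, sd = rep(exp(rnorm(25, 0, 0.5)),
                                         each = 12)), 12, 25)
  rmx <- make_rm(vals, group = rep(c("ctrl", "CD"), each = 6))
  ab <- fit_differential(rmx, "ctrl", "CD")
  ba <- fit_differential(rmx, "CD", "ctrl")
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("hit selection applies the |logFC| and raw-p rule with ordering", {
  de <- data.frame(glycan_id = c("a", "b", "c", "d", "e"),
                   logFC = c(4.02, 1.9, -2.5, 2.6, 3.0),
                   t = 0, p_value = c(0.001, 0.001, 0.03, 0.2, 0.05),
                   adj_p_value = NA, stringsAsFactors = FALSE)
  hits <- select_hits(de)
  expect_identical(hits$glycan_id, c("a", "e", "c"))
  expect_identical(hits$direction, c("increased", "increased", "decreased"))
  # boundary: |logFC| must exceed 2 strictly, p at alpha is kept
  expect_false("b" %in% hits$glycan_id)
  expect_true("e" %in% hits$glycan_id)
  expect_false("d" %in% hits$glycan_id)
})

test_that("isotype correlation recovers exact and degenerate cases", {
  g <- matrix(rnorm(3 * 20), 3, 20)
  rmg <- make_rm(g)
  rmm <- make_rm(g)          # IgM identical -> r = 1
  res <- isotype_correlation(rmg, rmm)
  expect_equal(res$r, rep(1, 3), tolerance = 1e-12)
  rmm2 <- make_rm(-g + 5)    # anti-correlated -> r = -1
  expect_equal(isotype_correlation(rmg, rmm2)$r, rep(-1, 3),
               tolerance = 1e-12)
  g2 <- g
  g2[2, ] <- 7               # constant vector -> flagged NA
  res3 <- isotype_correlation(make_rm(g2), rmm)
  expect_true(res3$degenerate[2])
  expect_true(is.na(res3$r[2]))
  expect_false(any(res3$degenerate[c(1, 3)]))
})

test_that("identical samples merge first at distance zero", {
  set.seed(9)
  x <- rnorm(30)
  vals <- rbind(a = x, b = rnorm(30), c = x)
  hc <- correlation_cluster(make_rm(vals))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_identical(sort(hc$merge[1, ]), c(-3L, -1L))
  expect_false(is.unsorted(hc$height))
  R <- attr(hc, "correlation")
  expect_equal(unname(diag(R)), rep(1, 3), tolerance = 1e-12)
  expect_equal(R, t(R), tolerance = 1e-12)
})

test_that("constant sample vectors make clustering fail with the id", {
  vals <- rbind(s1 = rnorm(10), s2 = rep(2, 10))
  expect_error(correlation_cluster(make_rm(vals)), "s2")
})

test_that("complete-linkage merges equal the brute-force oracle and hclust", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    vals <- matrix(rnorm(n * 12), n, 12)
    rownames(vals) <- sprintf("s%d", seq_len(n))
    hc <- correlation_cluster(make_rm(vals))
    D <- 1 - cor(t(vals))
    orc <- oracle_complete_linkage(D)
    expect_identical(hc$merge, orc$merge)
    expect_equal(hc$height, orc$height, tolerance = 1e-12)
    # stock hclust agrees on heights and on every induced partition
    ref <- hclust(as.dist(D), method = "complete")
    expect_equal(hc$height, ref$height, tolerance = 1e-12)
    for (k in 2:(n - 1)) {
      a <- cutree(hc, k)
      b <- cutree(ref, k)
      expect_identical(outer(a, a, "=="), outer(b, b, "=="))
    }
  }
})

test_that("MFI normalization is a guarded scale-invariant ratio", {
  expect_equal(normalize_mfi(1000, 10), 100)
  expect_equal(normalize_mfi(2000, 20), normalize_mfi(1000, 10))
  expect_error(normalize_mfi(100, 0), "> 0")
  expect_error(normalize_mfi(100, -1), "> 0")
})
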