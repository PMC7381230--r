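#' Per-sample subgroup medians of log2 reactivity
#'
#' The whole-array summary (`all`) uses every glycan including unknowns;
#' decoration subgroups use only glycans whose class or band is
#' unambiguous. Empty subgroups are omitted with a warning.
#'
#' @param rm A `reactivity_matrix`.
#' @param partition Classified library from [partition_library()]; defaults
#'   to the matrix's attached library.
#' @param by Which keys to summarise: any of `"all"`, `"class"`,
#'   `"fucose_band"`, `"sialic_band"`.
#' @return Long data frame: `sample_id`, `group`, `subgroup`,
#'   `median_log2_rfu`, `n_glycans`.
#' @export
subgroup_median <- function(rm, partition = rm$library,
                            by = c("all", "class", "fucose_band",
                                   "sialic_band")) {
  stopifnot(inherits(rm, "reactivity_matrix"), !is.null(partition))
  by <- match.arg(by, several.ok = TRUE)
  X <- rm$values
  part <- partition[match(colnames(X), partition$glycan_id), ]
  sets <- list()
  if ("all" %in% by) sets[["all"]] <- colnames(X)
  if ("class" %in% by) {
    for (cl in setdiff(unique(part$class), c("unknown", "ambiguous"))) {
      sets[[cl]] <- part$glycan_id[part$class == cl]
    }
  }
  if ("fucose_band" %in% by) {
    for (b in setdiff(unique(part$fucose_band), c("F0", "unknown", "ambiguous"))) {
      sets[[b]] <- part$glycan_id[part$fucose_band == b]
    }
  }
  if ("sialic_band" %in% by) {
    for (b in setdiff(unique(part$sialic_band), c("S0", "unknown", "ambiguous"))) {
      sets[[b]] <- part$glycan_id[part$sialic_band == b]
    }
  }
  empty <- names(sets)[vapply(sets, length, 0L) == 0L]
  if (length(empty) > 0) {
    warning(sprintf("empty subgroup(s) omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
    sets <- sets[setdiff(names(sets), empty)]
  }
  grp <- if (!is.null(rm$samples$group)) rm$samples$group
         else rep(NA_character_, nrow(X))
  out <- do.call(rbind, lapply(names(sets), function(key) {
    cols <- sets[[key]]
    data.frame(sample_id = rownames(X), group = grp, subgroup = key,
               median_log2_rfu = apply(X[, cols, drop = FALSE], 1,
                                       stats::median),
               n_glycans = length(cols), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

group_test_result <- function(comparison, method, statistic, p, n_pairs = 2,
                              n_a, n_b, degenerate = FALSE) {
  data.frame(comparison = comparison, method = method, statistic = statistic,
             p_value = p, adj_p_value = pmin(1, p * n_pairs),
             n_a = n_a, n_b = n_b, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' One-way ANOVA with Bonferroni-adjusted selected pairs
#'
#' Fits a one-way ANOVA over the three serum groups, then tests only the
#' two selected pairs ctrl-vs-UC and ctrl-vs-CD with pairwise t-statistics
#' using the pooled within-group variance (df = N - k) and a Bonferroni
#' factor of exactly 2. UC vs CD is never tested.
#'
#' @param values Numeric vector of per-sample statistics.
#' @param groups Factor or character with levels `ctrl`, `UC`, `CD`.
#' @return Data frame with rows `ctrl_vs_UC` and `ctrl_vs_CD`; the overall
#'   F statistic and its p-value are attached as attributes `"F"` and
#'   `"F_p_value"`.
#' @export
selected_pair_anova <- function(values, groups) {
  groups <- factor(groups, levels = c("ctrl", "UC", "CD"))
  stopifnot(length(values) == length(groups), !anyNA(groups))
  n <- table(groups)
  if (any(n < 2)) {
    stop(sprintf("every group needs >= 2 observations (got %s)",
                 paste(sprintf("%s=%d", names(n), n), collapse = ", ")),
         call. = FALSE)
  }
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  msw <- ssw / (N - k)
  f_stat <- (ssb / (k - 1)) / msw
  f_p <- stats::pf(f_stat, k - 1, N - k, lower.tail = FALSE)
  pair_row <- function(b) {
    se <- sqrt(msw * (1 / n[["ctrl"]] + 1 / n[[b]]))
    tt <- if (se == 0) 0 else (means[[b]] - means[["ctrl"]]) / se
    p <- if (se == 0) 1 else 2 * stats::pt(-abs(tt), df = N - k)
    group_test_result(paste0("ctrl_vs_", b), "anova_bonferroni", tt, p,
                      n_a = n[["ctrl"]], n_b = n[[b]])
  }
  out <- rbind(pair_row("UC"), pair_row("CD"))
  attr(out, "F") <- f_stat
  attr(out, "F_p_value") <- f_p
  out
}

#' Kruskal-Wallis test with Dunn's selected-pair post hoc
#'
#' The omnibus H statistic (tie-corrected) comes from
#' [stats::kruskal.test()]; Dunn's z for the two selected pairs is computed
#' from the mean ranks with the tie-corrected large-sample variance and a
#' Bonferroni factor of 2. If every value is identical the test is
#' undefined and both pairs return p = 1 flagged `degenerate`.
#'
#' @inheritParams selected_pair_anova
#' @return Data frame with rows `ctrl_vs_UC` and `ctrl_vs_CD`; the H
#'   statistic and its p-value attached as attributes `"H"` and
#'   `"H_p_value"`.
#' @export
selected_pair_kw_dunn <- function(values, groups) {
  groups <- factor(groups, levels = c("ctrl", "UC", "CD"))
  stopifnot(length(values) == length(groups), !anyNA(groups))
  n <- table(groups)
  if (any(n < 2)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    out <- rbind(
      group_test_result("ctrl_vs_UC", "kw_dunn", 0, 1,
                        n_a = n[["ctrl"]], n_b = n[["UC"]], degenerate = TRUE),
      group_test_result("ctrl_vs_CD", "kw_dunn", 0, 1,
                        n_a = n[["ctrl"]], n_b = n[["CD"]], degenerate = TRUE))
    attr(out, "H") <- 0
    attr(out, "H_p_value") <- 1
    return(out)
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  pair_row <- function(b) {
    se <- sqrt(sigma2 * (1 / n[["ctrl"]] + 1 / n[[b]]))
    z <- (rbar[[b]] - rbar[["ctrl"]]) / se
    group_test_result(paste0("ctrl_vs_", b), "kw_dunn", z,
                      2 * stats::pnorm(-abs(z)),
                      n_a = n[["ctrl"]], n_b = n[[b]])
  }
  out <- rbind(pair_row("UC"), pair_row("CD"))
  attr(out, "H") <- unname(kw$statistic)
  attr(out, "H_p_value") <- kw$p.value
  out
}

#' Invert the trigamma function
#'
#' Newton iteration for `trigamma(x) = y`, used by the scaled-F
#' method-of-moments fit; asymptotic branches for extreme arguments.
#'
#' @param y Positive numeric vector.
#' @return `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  out <- y
  hi <- y > 1e7
  lo <- !hi & y < 1e-6
  out[hi] <- 1 / sqrt(y[hi])
  out[lo] <- 1 / y[lo]
  mid <- !hi & !lo
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:60) {
      tri <- trigamma(x)
      step <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + step
      if (max(-step / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes fit of a scaled-F model to sample variances
#'
#' Treats per-feature residual variances `s2` (each with `df` residual
#' degrees of freedom) as draws from `s0^2 * F(df, d0)` and estimates the
#' prior df `d0` and prior variance `s0^2` by matching the moments of
#' `log(s2)` (digamma/trigamma matching). When the observed log-variances
#' are under-dispersed relative to the chi-square sampling noise the
#' trigamma inversion has no positive solution and `d0 = Inf` is returned
#' (every variance shrunk fully to the common value).
#'
#' @param s2 Positive per-feature variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with `df_prior` (`d0`) and `var_prior` (`s0^2`).
#' @export
fit_scaled_f <- function(s2, df) {
  stopifnot(length(s2) >= 2L, df > 0)
  m <- stats::median(s2)
  if (m == 0) {
    stop("more than half of the variances are exactly zero", call. = FALSE)
  }
  s2 <- pmax(s2, 1e-5 * m)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(df_prior = d0, var_prior = s02)
}

#' Shrink per-feature variances toward the empirical-Bayes prior
#'
#' Posterior variance `(d0 * s0^2 + df * s2) / (d0 + df)`; with `d0 = Inf`
#' every posterior equals `s0^2`. Each posterior lies between `s0^2` and
#' the feature's own `s2` (bracketing contract).
#'
#' @inheritParams fit_scaled_f
#' @return List with `var_post`, `df_prior`, `var_prior`.
#' @export
moderate_variances <- function(s2, df) {
  fit <- fit_scaled_f(s2, df)
  d0 <- fit$df_prior
  s02 <- fit$var_prior
  var_post <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + df * s2) / (d0 + df)
  list(var_post = var_post, df_prior = d0, var_prior = s02)
}

#' Per-glycan differential reactivity between two serum groups
#'
#' Fits, for every glycan, the two-group linear model on log2 RFU and tests
#' the contrast with a moderated t-statistic: the pooled residual variance
#' `s_g^2` (df `= nA + nB - 2`) is shrunk toward an empirical-Bayes prior
#' estimated across glycans ([moderate_variances()]), and
#' `t_g = logFC_g / (s_post_g * sqrt(1/nA + 1/nB))` is referred to a t
#' distribution on `d0 + df` degrees of freedom. `logFC` is the difference
#' of group means, `mean(groupB) - mean(groupA)`. With `moderation =
#' FALSE` the ordinary pooled two-sample t-test is used. If every glycan
#' has zero variance, moderation falls back to the ordinary t with a
#' warning.
#'
#' @param rm A `reactivity_matrix`.
#' @param group_a,group_b Group labels to contrast (reference first).
#' @param moderation Use empirical-Bayes variance shrinkage (default TRUE).
#' @return Data frame with one row per glycan: `glycan_id`,
#'   `composition_label` (if a library is attached), `logFC`, `t`,
#'   `p_value`, `adj_p_value` (Benjamini-Hochberg), `s2`, `s2_post`,
#'   `df_total`. Hyperparameters attached as attributes `"df_prior"` and
#'   `"var_prior"`.
#' @export
fit_differential <- function(rm, group_a = "ctrl", group_b = "CD",
                             moderation = TRUE) {
  stopifnot(inherits(rm, "reactivity_matrix"),
            !is.null(rm$samples$group))
  X <- rm$values
  grp <- rm$samples$group
  A <- X[grp == group_a, , drop = FALSE]
  B <- X[grp == group_b, , drop = FALSE]
  na <- nrow(A)
  nb <- nrow(B)
  if (na < 2 || nb < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  ma <- colMeans(A)
  mb <- colMeans(B)
  va <- colSums(sweep(A, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(B, 2, mb)^2) / (nb - 1)
  df_res <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df_res
  logfc <- mb - ma
  d0 <- 0
  s02 <- NA_real_
  if (moderation && all(s2 == 0)) {
    warning("all per-glycan variances are zero; falling back to ordinary t",
            call. = FALSE)
    moderation <- FALSE
  }
  if (moderation) {
    mod <- moderate_variances(s2, df_res)
    s2_post <- mod$var_post
    d0 <- mod$df_prior
    s02 <- mod$var_prior
    df_total <- d0 + df_res
  } else {
    s2_post <- s2
    df_total <- df_res
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tt <- ifelse(se == 0, ifelse(logfc == 0, 0, sign(logfc) * Inf), logfc / se)
  df_t <- if (is.infinite(df_total)) Inf else df_total
  p <- ifelse(is.infinite(tt), 0,
              2 * stats::pt(-abs(tt), df = df_t))
  out <- data.frame(glycan_id = colnames(X), logFC = logfc, t = tt,
                    p_value = p, adj_p_value = stats::p.adjust(p, "BH"),
                    s2 = s2, s2_post = s2_post,
                    df_total = rep(df_total, length(p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(rm$library)) {
    out$composition_label <- rm$library$composition_label[
      match(out$glycan_id, rm$library$glycan_id)]
    out <- out[, c("glycan_id", "composition_label",
                   setdiff(names(out), c("glycan_id", "composition_label")))]
  }
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s02
  attr(out, "n_a") <- na
  attr(out, "n_b") <- nb
  out
}

#' Select differential-reactivity hits by the logFC rule
#'
#' A glycan is a hit when `|logFC| > logfc_threshold` and its raw p-value
#' is `<= alpha`; hits are split by direction (increased / decreased) and
#' sorted by `|logFC|` descending. BH-adjusted p-values are carried along
#' for reference but the rule itself uses raw p.
#'
#' @param de Result of [fit_differential()].
#' @param logfc_threshold Absolute log2 fold-change threshold (default 2).
#' @param alpha Raw p-value threshold (default 0.05).
#' @return Subset of `de` with a `direction` column, ordered by `|logFC|`.
#' @export
select_hits <- function(de, logfc_threshold = 2, alpha = 0.05) {
  keep <- abs(de$logFC) > logfc_threshold & de$p_value <= alpha
  hits <- de[keep, , drop = FALSE]
  hits$direction <- ifelse(hits$logFC > 0, "increased", "decreased")
  hits <- hits[order(-abs(hits$logFC)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-sample Pearson correlation between isotype channels
#'
#' For each serum the IgG and IgM log2 reactivity vectors over the common
#' glycan set are correlated (Pearson, two-sided test). Samples with a
#' zero-variance vector in either channel are flagged and return `NA`.
#'
#' @param rm_igg,rm_igm `reactivity_matrix` objects for the two channels
#'   over the same samples and glycans.
#' @return Data frame: `sample_id`, `r`, `p_value`, `degenerate`.
#' @export
isotype_correlation <- function(rm_igg, rm_igm) {
  stopifnot(inherits(rm_igg, "reactivity_matrix"),
            inherits(rm_igm, "reactivity_matrix"))
  G <- rm_igg$values
  M <- rm_igm$values
  stopifnot(identical(dim(G), dim(M)),
            identical(colnames(G), colnames(M)),
            identical(rownames(G), rownames(M)))
  res <- lapply(seq_len(nrow(G)), function(i) {
    x <- G[i, ]
    y <- M[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(sample_id = rownames(G)[i], r = NA_real_,
                        p_value = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(sample_id = rownames(G)[i], r = unname(ct$estimate),
               p_value = ct$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Complete-linkage clustering of samples on correlation distance
#'
#' Builds the pairwise Pearson correlation matrix of all samples (over
#' glycans), takes distance `1 - r`, and agglomerates with the
#' complete-linkage rule: the distance between two clusters is the maximum
#' pairwise distance between their members. Ties are broken
#' deterministically by the lowest (i, j) cluster-index pair in creation
#' order. A sample with a constant reactivity vector has undefined
#' correlations and is a fatal error.
#'
#' @param rm A `reactivity_matrix` (or a plain samples x features matrix).
#' @return An object of class `hclust` (merge/height/order/labels) with
#'   the correlation matrix attached as attribute `"correlation"`.
#' @export
correlation_cluster <- function(rm) {
  X <- if (inherits(rm, "reactivity_matrix")) rm$values else as.matrix(rm)
  if (nrow(X) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant reactivity vector for sample(s): %s",
                 paste(rownames(X)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  R <- stats::cor(t(X))
  D <- 1 - R
  hc <- complete_linkage(D, labels = rownames(X))
  attr(hc, "correlation") <- R
  hc
}

# Agglomerative complete linkage over a symmetric distance matrix.
# Re-scans the active cluster-pair distances at every step; ties broken by
# the smallest (i, j) pair of active-cluster indices (creation order:
# singletons first, merged clusters appended). Returns an hclust-compatible
# structure (negative entries = singletons, positive = earlier merges).
complete_linkage <- function(D, labels = NULL) {
  n <- nrow(D)
  stopifnot(n >= 2, isTRUE(all.equal(D, t(D))))
  cd <- D                      # current cluster-distance matrix
  ids <- -seq_len(n)           # hclust codes of active clusters
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(ids)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (cd[i, j] < best_d) {
          best_d <- cd[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]
    j <- best[2L]
    pair <- sort(c(ids[i], ids[j]))
    merge[s, ] <- pair
    height[s] <- best_d
    new_d <- pmax(cd[i, ], cd[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(m), c(i, j))
    cd <- cd[keep, keep, drop = FALSE]
    cd <- rbind(cbind(cd, new_d), c(new_d, 0))
    ids <- c(ids[keep], s)
  }
  structure(
    list(merge = merge, height = height, order = merge_order(merge),
         labels = labels, method = "complete",
         dist.method = "1 - pearson", call = match.call()),
    class = "hclust"
  )
}

merge_order <- function(merge) {
  rec <- function(step) {
    unlist(lapply(merge[step, ], function(v) {
      if (v < 0) -v else rec(v)
    }))
  }
  rec(nrow(merge))
}

#' Normalize a mean fluorescence intensity by serum IgG concentration
#'
#' Puts flow-cytometry MFI values from different sera on a common scale by
#' dividing by each serum's total IgG concentration. Scale-invariant:
#' doubling both MFI and concentration leaves the result unchanged.
#'
#' @param mfi Mean fluorescence intensity (vectorised).
#' @param igg_concentration Serum IgG concentration, same length or scalar;
#'   must be strictly positive.
#' @return `mfi / igg_concentration` (fluorescence per concentration unit).
#' @export
normalize_mfi <- function(mfi, igg_concentration) {
  if (any(igg_concentration <= 0)) {
    stop("IgG concentration must be > 0", call. = FALSE)
  }
  mfi / igg_concentration
}
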