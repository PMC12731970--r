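#' Nonparametric group-comparison battery
#'
#' The statistical toolkit used to compare skill groups: a Monte-Carlo
#' (Lilliefors-style) Kolmogorov-Smirnov normality screen, the Friedman
#' test for within-participant factors (tie-corrected, with exact
#' enumeration for small layouts), Bonferroni-adjusted pairwise rank tests
#' for between-group and between-trial contrasts, and Cohen's d effect
#' sizes.
#'
#' @name stats-battery
NULL

new_stats_result <- function(test_name, statistic, p_value,
                             p_adjusted = p_value, effect_size_d = NA_real_,
                             comparison = "", method = "") {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, p_adjusted = min(1, p_adjusted),
                 effect_size_d = effect_size_d, comparison = comparison,
                 method = method),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("<%s> %s: statistic %.4g, p %.4g (adj %.4g), d %.3g\n",
              x$test_name, x$comparison, x$statistic, x$p_value,
              x$p_adjusted, x$effect_size_d))
  invisible(x)
}

#' Composite Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic against a normal with mean and SD estimated from
#' the sample; because the parameters are estimated, the p-value is
#' obtained by seeded Monte-Carlo simulation of the null distribution
#' (the Lilliefors construction) rather than the standard KS tables.
#'
#' @param x numeric sample, n >= 5, non-constant.
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed RNG seed for the null simulation.
#' @return a `stats_result` with the D statistic and Monte-Carlo p-value.
#' @export
ks_normality <- function(x, reps = 10000, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop("ks_normality requires n >= 5")
  if (stats::sd(x) < 1e-12) stop("degenerate (constant) sample")
  d_obs <- lilliefors_stat(x)
  set.seed(as.integer(seed))
  d_null <- vapply(seq_len(reps),
                   function(i) lilliefors_stat(stats::rnorm(n)), numeric(1))
  p <- (sum(d_null >= d_obs) + 1) / (reps + 1)
  new_stats_result("ks_normality", d_obs, p,
                   method = sprintf("Lilliefors Monte-Carlo (%d reps)", reps))
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort(stats::pnorm(x, mean(x), stats::sd(x)))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Friedman test for complete block designs
#'
#' Ranks within blocks (average ranks on ties), computes the tie-corrected
#' chi-square statistic with k - 1 degrees of freedom, and obtains the
#' p-value by exact enumeration over all within-block rank permutations
#' when the layout is small enough (no ties and `(k!)^n <= exact_limit`),
#' falling back to the asymptotic chi-square distribution otherwise.
#'
#' @param block_matrix numeric matrix, n blocks (rows) x k conditions
#'   (columns), complete (no missing cells).
#' @param exact_limit maximum number of permutation configurations for
#'   exact enumeration (default 1e5).
#' @return a `stats_result`.
#' @export
friedman <- function(block_matrix, exact_limit = 1e5) {
  m <- as.matrix(block_matrix)
  if (any(!is.finite(m))) stop("block matrix must be complete")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 conditions")
  ranks <- t(apply(m, 1, rank))
  stat <- friedman_stat_from_ranks(ranks, n, k)
  has_ties <- any(apply(m, 1, function(r) anyDuplicated(r) > 0))
  n_config <- factorial(k)^n
  if (!has_ties && is.finite(n_config) && n_config <= exact_limit) {
    perms <- all_permutations(k)
    stats_null <- enumerate_friedman(perms, n, k)
    p <- mean(stats_null >= stat - 1e-9)
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "asymptotic chi-square"
  }
  new_stats_result("friedman", stat, p, method = method)
}

friedman_stat_from_ranks <- function(ranks, n, k) {
  rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  # tie correction
  ties <- apply(ranks, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  })
  corr <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (corr <= 0) return(0)
  stat / corr
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# Null distribution of the Friedman statistic: every block independently
# takes one of the k! rank orderings.
enumerate_friedman <- function(perms, n, k) {
  np <- nrow(perms)
  idx <- rep(1L, n)
  total <- np^n
  out <- numeric(total)
  for (cfg in seq_len(total)) {
    ranks <- perms[idx, , drop = FALSE]
    rj <- colSums(ranks)
    out[cfg] <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
    # odometer increment
    i <- 1L
    while (i <= n) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= np) break
      idx[i] <- 1L
      i <- i + 1L
    }
  }
  out
}

#' Pairwise comparisons with Bonferroni adjustment
#'
#' Between independent groups: Wilcoxon rank-sum per pair. Between paired
#' conditions: Wilcoxon signed-rank. Adjusted p-values are
#' `min(1, p * m)` with `m` the number of comparisons in the family.
#' Cohen's d is attached to every comparison.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of group labels (same length); for
#'   `kind = "paired"` exactly two groups with equal lengths and aligned
#'   order are required.
#' @param kind "independent" (rank-sum) or "paired" (signed-rank).
#' @param m_family family size for the Bonferroni adjustment; defaults to
#'   the number of pairs.
#' @return data.frame with one row per pair: comparison, statistic, p,
#'   p_adjusted, d, significance marker ("*" p < 0.05, "**" p < 0.001).
#' @export
pairwise_bonferroni <- function(values, groups,
                                kind = c("independent", "paired"),
                                m_family = NULL) {
  kind <- match.arg(kind)
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- m_family %||% length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (kind == "paired") {
      if (length(x) != length(y))
        stop("paired comparison requires equal lengths")
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      d <- cohens_d(x, y, paired = TRUE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      d <- cohens_d(x, y)
    }
    p_adj <- min(1, wt$p.value * m)
    data.frame(comparison = paste(pr[1], "vs", pr[2]),
               statistic = unname(wt$statistic),
               p_value = wt$p.value, p_adjusted = p_adj,
               effect_size_d = d,
               significance = sig_marker(p_adj),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

sig_marker <- function(p) ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", ""))

#' Cohen's d
#'
#' Independent samples: difference in means over the pooled standard
#' deviation (n - 1 denominators). Paired: mean difference over the SD of
#' the differences. The sign follows `x - y`.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param paired logical.
#' @return effect size d.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per sample")
  if (paired) {
    if (length(x) != length(y)) stop("paired d requires equal lengths")
    dd <- x - y
    s <- stats::sd(dd)
    if (s < 1e-12) {
      if (mean(dd) == 0) return(0)
      stop("zero variance of differences")
    }
    return(mean(dd) / s)
  }
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 < 1e-24) {
    if (mean(x) == mean(y)) return(0)
    stop("zero pooled variance")
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Full group-comparison analysis of a cohort
#'
#' Runs the complete comparison battery over a cohort's metric records,
#' per metric: a normality screen per group x trial; Friedman tests across
#' the four within-participant tooth conditions per group x trial (and, for
#' manipulation time, across the four trial-1 task positions); pairwise
#' between-group comparisons (rank-sum, Bonferroni m = 6) per tooth x
#' trial; and the paired trial-1 vs trial-2 comparison per group
#' (signed-rank, m = 1). Cohen's d accompanies every pairwise comparison.
#'
#' @param records cohort data.frame from [generate_cohort()]; needs
#'   records from at least two groups.
#' @param metrics which metric columns to analyse.
#' @param valid_only drop records failing the validity criteria
#'   (default TRUE; records with unknown validity are kept).
#' @param ks_reps Monte-Carlo replicates for the normality screen.
#' @param seed seed for all Monte-Carlo p-values.
#' @return object of class `mirror_report`: list of data.frames
#'   (`normality`, `friedman`, `pairwise_groups`, `trials`).
#' @export
analyze_cohort <- function(records,
                           metrics = c("distance_mm", "ratio_pct",
                                       "ellipticity", "time_s"),
                           valid_only = TRUE, ks_reps = 2000, seed = 1) {
  if (length(unique(records$group)) < 2)
    stop("need records from at least 2 groups")
  if (valid_only && "valid" %in% names(records))
    records <- records[is.na(records$valid) | records$valid, ]
  metrics <- intersect(metrics, names(records))
  metrics <- metrics[vapply(metrics,
                            function(m) !all(is.na(records[[m]])), logical(1))]
  trials <- sort(unique(records$trial))
  groups <- unique(records$group)

  norm_rows <- list(); fried_rows <- list()
  pair_rows <- list(); trial_rows <- list()
  ks_i <- 0

  for (met in metrics) {
    for (g in groups) for (tr in trials) {
      x <- records[[met]][records$group == g & records$trial == tr]
      x <- x[is.finite(x)]
      if (length(x) >= 5 && stats::sd(x) > 1e-12) {
        ks_i <- ks_i + 1
        ks <- ks_normality(x, reps = ks_reps, seed = seed + ks_i)
        norm_rows[[length(norm_rows) + 1]] <- data.frame(
          metric = met, group = g, trial = tr, n = length(x),
          statistic = ks$statistic, p_value = ks$p_value,
          normal = ks$p_value >= 0.05, stringsAsFactors = FALSE)
      }
    }

    # within-participant tooth factor, per group x trial
    for (g in groups) for (tr in trials) {
      sub <- records[records$group == g & records$trial == tr, ]
      bm <- block_matrix(sub, "participant_id", "tooth", met)
      if (!is.null(bm)) {
        fr <- friedman(bm)
        fried_rows[[length(fried_rows) + 1]] <- data.frame(
          metric = met, factor = "tooth", group = g, trial = tr,
          n_blocks = nrow(bm), statistic = fr$statistic,
          p_value = fr$p_value, method = fr$method,
          significance = sig_marker(fr$p_value), stringsAsFactors = FALSE)
      }
    }
    if (met == "time_s" && 1 %in% trials) {
      for (g in groups) {
        sub <- records[records$group == g & records$trial == 1, ]
        bm <- block_matrix(sub, "participant_id", "task_index", met)
        if (!is.null(bm)) {
          fr <- friedman(bm)
          fried_rows[[length(fried_rows) + 1]] <- data.frame(
            metric = met, factor = "task", group = g, trial = 1,
            n_blocks = nrow(bm), statistic = fr$statistic,
            p_value = fr$p_value, method = fr$method,
            significance = sig_marker(fr$p_value), stringsAsFactors = FALSE)
        }
      }
    }

    # between-group families, per tooth x trial (m = 6 for 4 groups)
    for (th in sort(unique(records$tooth))) for (tr in trials) {
      sub <- records[records$tooth == th & records$trial == tr, ]
      if (length(unique(sub$group)) < 2) next
      pw <- pairwise_bonferroni(sub[[met]], sub$group, "independent")
      pw$metric <- met; pw$tooth <- th; pw$trial <- tr
      pair_rows[[length(pair_rows) + 1]] <- pw
    }

    # trial 1 vs trial 2, paired within participant, per group (m = 1)
    if (all(c(1, 2) %in% trials)) {
      for (g in groups) {
        sub <- records[records$group == g, ]
        t1 <- tapply(sub[[met]][sub$trial == 1],
                     sub$participant_id[sub$trial == 1], mean)
        t2 <- tapply(sub[[met]][sub$trial == 2],
                     sub$participant_id[sub$trial == 2], mean)
        common <- intersect(names(t1), names(t2))
        if (length(common) >= 5) {
          x <- as.numeric(t1[common]); y <- as.numeric(t2[common])
          wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
          trial_rows[[length(trial_rows) + 1]] <- data.frame(
            metric = met, group = g, comparison = "Trial 1 vs Trial 2",
            n = length(common), statistic = unname(wt$statistic),
            p_value = wt$p.value, p_adjusted = min(1, wt$p.value),
            effect_size_d = cohens_d(x, y, paired = TRUE),
            significance = sig_marker(wt$p.value), stringsAsFactors = FALSE)
        }
      }
    }
  }

  structure(list(normality = bind_or_null(norm_rows),
                 friedman = bind_or_null(fried_rows),
                 pairwise_groups = bind_or_null(pair_rows),
                 trials = bind_or_null(trial_rows)),
            class = "mirror_report")
}

bind_or_null <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL

# participant x condition matrix of one metric; NULL unless complete with
# >= 2 blocks and >= 2 conditions.
block_matrix <- function(sub, block_col, cond_col, value_col) {
  if (!nrow(sub)) return(NULL)
  tb <- tapply(sub[[value_col]], list(sub[[block_col]], sub[[cond_col]]),
               mean)
  tb <- tb[stats::complete.cases(tb), , drop = FALSE]
  if (is.null(dim(tb)) || nrow(tb) < 2 || ncol(tb) < 2) return(NULL)
  tb
}

#' @export
print.mirror_report <- function(x, ...) {
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat("==", nm, "==\n")
    print(utils::head(x[[nm]], 10))
    if (nrow(x[[nm]]) > 10) cat("...", nrow(x[[nm]]), "rows\n")
  }
  invisible(x)
}

#' Export an analysis report
#'
#' @param report a [analyze_cohort()] report.
#' @param json_path,csv_path output paths (either may be NULL).
#' @return invisibly, the list of written paths.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  written <- character()
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    flat <- lapply(names(report), function(nm) {
      df <- report[[nm]]
      if (is.null(df)) return(NULL)
      df$section <- nm
      df
    })
    flat <- flat[!vapply(flat, is.null, logical(1))]
    all_cols <- unique(unlist(lapply(flat, names)))
    flat <- lapply(flat, function(df) {
      for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA
      df[all_cols]
    })
    utils::write.csv(do.call(rbind, flat), csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}
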