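# Cohort-level statistics shared by all modalities: classical one-way ANOVA
# with Bonferroni-adjusted pairwise post tests, unpaired t-tests, and an
# exact / normal-approximation Mann-Whitney U test.  These are authored here
# (rather than delegated wholesale to wrappers) because the pipeline's group
# comparisons are contract operations with their own oracle tests.

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA on a list of numeric groups, as used
#' to compare relative CBV across treatment days within a cohort.
#'
#' @param groups named or unnamed list of numeric vectors, one per group;
#'   at least two groups with at least two finite observations each.
#' @return list with elements `F`, `df_between`, `df_within`, `p`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  stop_if(!is.list(groups) || length(groups) < 2L,
          "need at least two groups")
  groups <- lapply(groups, as.numeric)
  stop_if(any(!vapply(groups, function(g) all(is.finite(g)), logical(1))),
          "observations must be finite")
  n <- lengths(groups)
  stop_if(any(n < 2L), "each group needs at least two observations")
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- sum(n) - length(groups)
  stop_if(ss_within <= 0 && ss_between <= 0,
          "zero variance everywhere; F undefined")
  stop_if(ss_within <= 0, "zero within-group variance; F undefined")
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(F = f, df_between = df_b, df_within = df_w,
       p = pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Pairwise Bonferroni post test
#'
#' All pairwise unpaired t-tests between groups, each compared to
#' `alpha / n_pairs` — the Bonferroni post test applied after a one-way
#' ANOVA across time points.
#'
#' @param groups list of numeric vectors as in [one_way_anova()].
#' @param alpha family-wise significance level (default 0.05).
#' @param var_equal use the classical pooled-variance t-test (default TRUE,
#'   matching era-standard Prism defaults); FALSE gives Welch.
#' @return data.frame with one row per pair: `group1`, `group2`, `t`, `p`,
#'   `p_threshold`, `significant`.
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05, var_equal = TRUE) {
  stop_if(!is.numeric(alpha) || alpha <= 0 || alpha >= 1,
          "'alpha' must be in (0, 1)")
  stop_if(!is.list(groups) || length(groups) < 2L,
          "need at least two groups")
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_along(groups))
  pairs <- combn(seq_along(groups), 2L)
  thr <- alpha / ncol(pairs)
  res <- apply(pairs, 2L, function(ix) {
    tt <- t.test(groups[[ix[1]]], groups[[ix[2]]], var.equal = var_equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
             t = res["t", ], p = res["p", ], p_threshold = thr,
             significant = res["p", ] < thr, row.names = NULL)
}

# Mid-ranks of the pooled sample.
pooled_midranks <- function(a, b) rank(c(a, b), ties.method = "average")

# Exact null distribution of the rank sum of group A: enumerate every
# C(na+nb, na) assignment of the pooled mid-ranks to group A.
mw_exact_p <- function(r, na, u_obs) {
  sums <- combn(r, na, sum)
  u_all <- sums - na * (na + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, used for the tortuosity
#' group comparison. For small samples (`n_a + n_b <= 12` by default under
#' `mode = "auto"`) the null distribution is enumerated exactly over all
#' assignments of the pooled mid-ranks; otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @return list with `U` (statistic for sample `a`) and `p_two_sided`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  stop_if(length(a) == 0L || length(b) == 0L, "both samples must be non-empty")
  stop_if(any(!is.finite(c(a, b))), "observations must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- pooled_midranks(a, b)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "exact" || (mode == "auto" && n <= 12L)) {
    p <- mw_exact_p(r, na, u)
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = u, p_two_sided = p)
}

#' Unpaired two-sample t-test p-value
#'
#' Thin wrapper used by the morphometry and IHC comparisons; classical
#' pooled-variance test by default.
#'
#' @inheritParams bonferroni_pairwise
#' @param a,b numeric samples with at least two values each.
#' @return list with `t`, `df`, `p`.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  stop_if(length(a) < 2L || length(b) < 2L,
          "need at least two values per group")
  stop_if(var(a) == 0 && var(b) == 0 && mean(a) == mean(b),
          "zero variance in both groups with equal means; t undefined")
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
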