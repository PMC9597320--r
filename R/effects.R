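# Screening statistics: pooled SD, Hedges bias-corrected standardized mean
# difference with normal-approximation CI and pooled-variance t-test, the
# genotype x parameter effect matrix, and contract-level one-/two-way ANOVA
# with Tukey HSD compact letter displays.

#' Summary statistics for one group
#' @param x numeric vector, length >= 2.
#' @return list(n, mean, sd).
#' @export
group_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("group needs at least 2 finite observations")
  list(n = length(x), mean = mean(x), sd = stats::sd(x))
}

#' Pooled, weighted standard deviation of two groups
#'
#' sqrt(((n1-1) SD1^2 + (n2-1) SD2^2) / (n1 + n2 - 2)).
#'
#' @param g1,g2 lists with n, mean, sd (see [group_stats()]).
#' @return the pooled SD.
#' @export
pooled_sd <- function(g1, g2) {
  if (g1$n + g2$n <= 2) stop("pooled SD undefined: n1 + n2 - 2 <= 0 degrees of freedom")
  sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2))
}

#' Hedges effect size of treatment vs control
#'
#' Standardized mean difference d = (mean1 - mean2) / SD_pooled with the
#' small-sample bias correction d * (1 - 3/(4 N - 9)), N = n1 + n2
#' (Hedges d, often written g).  The confidence interval uses the
#' Hedges-Olkin normal-approximation standard error
#' SE = sqrt(N/(n1 n2) + d_corrected^2 / (2 N)); the p-value comes from the
#' two-tailed pooled-variance Student t-test of the mean difference with
#' N - 2 degrees of freedom.
#'
#' @param treat,control group summaries (lists with n, mean, sd).
#' @param level confidence level, default 0.95.
#' @return list of class `effect_size`: mean_diff, sd_pooled, d_biased,
#'   d_corrected, ci_low, ci_high, p_value, df, stars, infinite (TRUE when
#'   SD_pooled is 0 but the means differ).
#' @export
hedges_effect <- function(treat, control, level = 0.95) {
  sp <- pooled_sd(treat, control)
  n1 <- treat$n; n2 <- control$n; N <- n1 + n2
  md <- treat$mean - control$mean
  corr <- 1 - 3 / (4 * N - 9)
  if (sp == 0) {
    if (md == 0) {
      res <- list(mean_diff = 0, sd_pooled = 0, d_biased = 0, d_corrected = 0,
                  ci_low = 0, ci_high = 0, p_value = 1, df = N - 2L,
                  stars = "ns", infinite = FALSE)
      class(res) <- "effect_size"
      return(res)
    }
    warning("zero pooled SD with non-zero mean difference: infinite effect")
    res <- list(mean_diff = md, sd_pooled = 0,
                d_biased = sign(md) * Inf, d_corrected = sign(md) * Inf,
                ci_low = sign(md) * Inf, ci_high = sign(md) * Inf,
                p_value = 0, df = N - 2L, stars = "***", infinite = TRUE)
    class(res) <- "effect_size"
    return(res)
  }
  d <- md / sp
  g <- d * corr
  se <- sqrt(N / (n1 * n2) + g^2 / (2 * N))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tstat <- md / (sp * sqrt(1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = N - 2)
  res <- list(mean_diff = md, sd_pooled = sp, d_biased = d, d_corrected = g,
              ci_low = g - z * se, ci_high = g + z * se,
              p_value = p, df = N - 2L, stars = p_stars(p), infinite = FALSE)
  class(res) <- "effect_size"
  res
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Hedges d = %.3f [%.3f, %.3f], mean diff = %.3g, p = %.3g %s\n",
              x$d_corrected, x$ci_low, x$ci_high, x$mean_diff, x$p_value, x$stars))
  invisible(x)
}

#' Genotype x parameter effect-size matrix
#'
#' For every genotype and every parameter column, summarizes the stress and
#' control arms and computes the Hedges effect.  Genotypes missing one arm
#' (or with < 2 plants per arm) are excluded with a warning; missing cells
#' are flagged, never imputed.
#'
#' @param dataset per-plant table with columns genotype, treatment and the
#'   parameters in `parameters`.
#' @param parameters character vector of parameter columns (default: all
#'   numeric columns except identity keys).
#' @param level confidence level for the CIs.
#' @return list of class `effect_matrix`: `table` (long data.frame:
#'   genotype, parameter, mean_diff, sd_pooled, d_biased, d_corrected,
#'   ci_low, ci_high, p_value, stars), plus matrices `mean_diff` and
#'   `d_corrected` (genotype x parameter).
#' @export
effect_matrix <- function(dataset, parameters = NULL, level = 0.95) {
  stopifnot(is.data.frame(dataset), all(c("genotype", "treatment") %in% names(dataset)))
  if (is.null(parameters)) {
    skip <- c("sample_id", "genotype", "treatment", "replicate")
    parameters <- names(dataset)[vapply(dataset, is.numeric, TRUE) &
                                   !names(dataset) %in% skip]
  }
  genos <- sort(unique(dataset$genotype))
  rows <- list()
  for (g in genos) {
    sub <- dataset[dataset$genotype == g, , drop = FALSE]
    ns <- sum(sub$treatment == "stress"); nc <- sum(sub$treatment == "control")
    if (ns < 2 || nc < 2) {
      warning("genotype ", g, " lacks >= 2 plants in both arms; excluded")
      next
    }
    for (p in parameters) {
      xs <- sub[sub$treatment == "stress", p]
      xc <- sub[sub$treatment == "control", p]
      ok_s <- sum(is.finite(xs)) >= 2; ok_c <- sum(is.finite(xc)) >= 2
      if (!ok_s || !ok_c) {
        rows[[paste(g, p)]] <- data.frame(
          genotype = g, parameter = p, n_stress = sum(is.finite(xs)),
          n_control = sum(is.finite(xc)), mean_diff = NA_real_,
          sd_pooled = NA_real_, d_biased = NA_real_, d_corrected = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
          stars = NA_character_, flag = "missing", stringsAsFactors = FALSE)
        next
      }
      es <- hedges_effect(group_stats(xs), group_stats(xc), level)
      rows[[paste(g, p)]] <- data.frame(
        genotype = g, parameter = p, n_stress = sum(is.finite(xs)),
        n_control = sum(is.finite(xc)), mean_diff = es$mean_diff,
        sd_pooled = es$sd_pooled, d_biased = es$d_biased,
        d_corrected = es$d_corrected, ci_low = es$ci_low,
        ci_high = es$ci_high, p_value = es$p_value, stars = es$stars,
        flag = if (es$infinite) "infinite" else "", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  to_mat <- function(col) {
    m <- matrix(NA_real_, nrow = length(unique(tab$genotype)), ncol = length(parameters),
                dimnames = list(sort(unique(tab$genotype)), parameters))
    m[cbind(tab$genotype, tab$parameter)] <- tab[[col]]
    m
  }
  structure(list(table = tab, mean_diff = to_mat("mean_diff"),
                 d_corrected = to_mat("d_corrected"), parameters = parameters),
            class = "effect_matrix")
}

# Greedy insert-absorb compact letter display from a logical "significantly
# different" pairwise matrix.  Groups sharing a letter are not significantly
# different.
compact_letters <- function(diff_mat) {
  groups <- rownames(diff_mat)
  n <- length(groups)
  cols <- list()                     # each column: logical membership vector
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(cols)) {
      members <- which(cols[[ci]])
      if (all(!diff_mat[i, members])) { cols[[ci]][i] <- TRUE; placed <- TRUE }
    }
    if (!placed) {
      newcol <- rep(FALSE, n); newcol[i] <- TRUE
      # absorb every earlier group not different from i
      for (j in seq_len(n)) if (j != i && !diff_mat[i, j]) {
        # j joins only if compatible with all current members
        members <- which(newcol)
        if (all(!diff_mat[j, members])) newcol[j] <- TRUE
      }
      cols[[length(cols) + 1]] <- newcol
    }
  }
  # absorb: drop columns whose membership is a subset of another column
  keep <- rep(TRUE, length(cols))
  for (a in seq_along(cols)) for (b in seq_along(cols)) {
    if (a != b && keep[a] && keep[b] &&
        all(cols[[a]] <= cols[[b]]) && !identical(cols[[a]], cols[[b]]))
      keep[a] <- FALSE
  }
  cols <- cols[keep]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(seq_len(n), function(i)
    paste(letters_used[vapply(cols, `[`, TRUE, i)], collapse = ""), "")
  names(out) <- groups
  out
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Classical one-way ANOVA across groups followed by Tukey honest
#' significant difference pairwise tests at alpha = 0.05, summarized as a
#' compact letter display (greedy insert-absorb): groups sharing a letter
#' are not significantly different.
#'
#' @param values named list of numeric vectors (one per group), or a
#'   data.frame with columns `value` and `group`.
#' @param alpha significance level for the letters.
#' @return list: F, df1, df2, p, letters (named character vector),
#'   tukey (the [stats::TukeyHSD()] table).
#' @export
anova_oneway_tukey <- function(values, alpha = 0.05) {
  if (is.data.frame(values)) {
    values <- split(values$value, values$group)
  }
  small <- names(values)[lengths(lapply(values, function(x) x[is.finite(x)])) < 2]
  if (length(small)) {
    warning("group(s) with n < 2 dropped: ", paste(small, collapse = ", "))
    values <- values[!names(values) %in% small]
  }
  if (length(values) < 2) stop("need at least 2 groups with n >= 2")
  df <- data.frame(value = unlist(values, use.names = FALSE),
                   group = factor(rep(names(values), lengths(values))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  Fv <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  ssw <- sum(unlist(lapply(split(df$value, df$group),
                           function(x) (x - mean(x))^2)))
  degenerate <- ssw <= .Machine$double.eps * sum(df$value^2)
  if (degenerate) {
    # within-group variance is exactly zero
    if (diff(range(df$value)) == 0) { Fv <- 0; p <- 1 } else { Fv <- Inf; p <- 0 }
  }
  gl <- levels(df$group)
  diff_mat <- matrix(FALSE, length(gl), length(gl), dimnames = list(gl, gl))
  tk <- NULL
  if (degenerate && is.infinite(Fv)) {
    ms <- vapply(split(df$value, df$group), mean, 0)
    diff_mat[] <- outer(ms[gl], ms[gl], `!=`)
  }
  if (!degenerate) {
    # Tukey-Kramer studentized-range pairwise tests
    mse <- an["Residuals", "Mean Sq"]; dfr <- an["Residuals", "Df"]
    ns <- vapply(split(df$value, df$group), length, 0L)
    ms <- vapply(split(df$value, df$group), mean, 0)
    pairs <- utils::combn(gl, 2)
    rows <- apply(pairs, 2, function(pr) {
      a <- pr[1]; b <- pr[2]
      se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
      q <- abs(ms[[a]] - ms[[b]]) / se
      p <- stats::ptukey(q, nmeans = length(gl), df = dfr, lower.tail = FALSE)
      data.frame(group1 = a, group2 = b, diff = ms[[a]] - ms[[b]],
                 p_adj = p, stringsAsFactors = FALSE)
    })
    tk <- do.call(rbind, rows)
    for (i in seq_len(nrow(tk))) {
      sig <- tk$p_adj[i] < alpha
      diff_mat[tk$group1[i], tk$group2[i]] <- sig
      diff_mat[tk$group2[i], tk$group1[i]] <- sig
    }
  }
  list(F = Fv, df1 = as.integer(an[1, "Df"]),
       df2 = as.integer(an["Residuals", "Df"]), p = p,
       letters = compact_letters(diff_mat), tukey = tk)
}

#' Two-way ANOVA with Type III sums of squares
#'
#' Linear model value ~ A * B under sum-to-zero contrasts; Type III SS by
#' model comparison: for each term, the increase in residual SS when that
#' term's columns are removed from the full sum-to-zero design.  Intended
#' for the genotype x treatment design.  Agrees with `car::Anova(type = 3)`
#' and, unlike it, tolerates noise-free (zero-residual) data, where the
#' F statistics are reported as Inf/NaN rather than refusing the fit.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (e.g. genotype and treatment), each
#'   with >= 2 levels and every cell occupied.
#' @return list: `table` (data.frame with term, SS, df, F, p for A, B,
#'   A:B and residuals) and `r_squared` of the full model.
#' @export
anova_twoway_type3 <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) stop("both factors need >= 2 levels")
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", levels(fa)[empty[1]], " x ", levels(fb)[empty[2]],
         " (Type III SS undefined)")
  }
  df <- data.frame(y = values, A = fa, B = fb)
  X <- stats::model.matrix(~ A * B, df,
                           contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  asgn <- attr(X, "assign")          # 0 = intercept, 1 = A, 2 = B, 3 = A:B
  rss <- function(cols) {
    f <- stats::lm.fit(X[, cols, drop = FALSE], df$y)
    sum(f$residuals^2)
  }
  rss_full <- rss(seq_len(ncol(X)))
  ss <- vapply(1:3, function(term) rss(which(asgn != term)) - rss_full, 0)
  dfs <- vapply(1:3, function(term) sum(asgn == term), 0L)
  df_res <- nrow(X) - ncol(X)
  mse <- rss_full / df_res
  Fv <- (ss / dfs) / mse
  pv <- stats::pf(Fv, dfs, df_res, lower.tail = FALSE)
  tab <- data.frame(term = c("factor_a", "factor_b", "interaction", "residuals"),
                    SS = c(ss, rss_full), df = c(dfs, df_res),
                    F = c(Fv, NA), p = c(pv, NA),
                    stringsAsFactors = FALSE)
  tss <- sum((df$y - mean(df$y))^2)
  list(table = tab, r_squared = if (tss > 0) 1 - rss_full / tss else 1)
}
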