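# Hedges effect sizes, the effect matrix and ANOVA contracts.

gs <- function(n, mean, sd) list(n = n, mean = mean, sd = sd)

test_that("pooled SD matches hand arithmetic and is symmetric", {
  expect_equal(pooled_sd(gs(6, 0, 3), gs(6, 0, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_equal(round(pooled_sd(gs(6, 0, 3), gs(6, 0, 4)), 4), 3.5355)
  expect_equal(pooled_sd(gs(5, 1, 2), gs(9, 2, 2)), 2, tolerance = 1e-12)
  expect_equal(pooled_sd(gs(4, 0, 1), gs(7, 0, 3)),
               pooled_sd(gs(7, 0, 3), gs(4, 0, 1)))
  expect_error(pooled_sd(gs(1, 0, 1), gs(1, 0, 1)), "degrees of freedom")
})

test_that("the worked Hedges example gives d = 1 and correction 0.92308", {
  es <- hedges_effect(gs(6, 12, 2), gs(6, 10, 2))
  expect_equal(es$d_biased, 1.0, tolerance = 1e-12)
  expect_equal(es$d_corrected, 1 - 3 / 39, tolerance = 1e-12)
  expect_equal(round(es$d_corrected, 5), 0.92308)
  expect_lte(abs(es$d_corrected), abs(es$d_biased))
  expect_true(es$ci_low <= es$d_corrected && es$d_corrected <= es$ci_high)
})

test_that("swapping arms flips every sign; identical samples give p = 1", {
  es1 <- hedges_effect(gs(8, 5, 1.5), gs(10, 3, 2))
  es2 <- hedges_effect(gs(10, 3, 2), gs(8, 5, 1.5))
  expect_equal(es1$d_corrected, -es2$d_corrected, tolerance = 1e-12)
  expect_equal(es1$mean_diff, -es2$mean_diff)
  expect_equal(es1$ci_low, -es2$ci_high, tolerance = 1e-12)
  expect_equal(es1$p_value, es2$p_value, tolerance = 1e-12)
  same <- hedges_effect(gs(6, 4, 1), gs(6, 4, 1))
  expect_equal(same$d_corrected, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$ci_low, -same$ci_high, tolerance = 1e-12)
})

test_that("degenerate zero-variance groups are handled explicitly", {
  z <- hedges_effect(gs(5, 2, 0), gs(5, 2, 0))
  expect_equal(z$d_corrected, 0); expect_equal(z$p_value, 1)
  expect_warning(inf <- hedges_effect(gs(5, 3, 0), gs(5, 2, 0)), "infinite")
  expect_true(inf$infinite)
  expect_identical(inf$d_corrected, Inf)
})

test_that("the small-sample correction factor lies in (0,1) and tends to 1", {
  N <- c(4, 6, 12, 50, 1000)
  cf <- 1 - 3 / (4 * N - 9)
  expect_true(all(cf > 0 & cf < 1))
  expect_true(all(diff(cf) > 0))
  expect_equal(cf[5], 1, tolerance = 1e-3)
})

test_that("effect_matrix has genotype x parameter shape with flagged gaps", {
  set.seed(41)
  df <- expand.grid(genotype = paste0("g", 1:4),
                    treatment = c("control", "stress"), rep = 1:5,
                    stringsAsFactors = FALSE)
  df$p1 <- rnorm(nrow(df)); df$p2 <- rnorm(nrow(df)); df$p3 <- rnorm(nrow(df))
  em <- effect_matrix(df, c("p1", "p2", "p3"))
  expect_identical(dim(em$d_corrected), c(4L, 3L))
  expect_identical(nrow(em$table), 12L)
  # duplicated arms: all mean differences 0
  dup <- df; dup$treatment <- "control"
  dup2 <- dup; dup2$treatment <- "stress"
  em0 <- effect_matrix(rbind(dup, dup2), c("p1", "p2", "p3"))
  expect_true(all(em0$table$mean_diff == 0))
  # a genotype missing an arm is excluded with a warning
  expect_warning(em1 <- effect_matrix(df[!(df$genotype == "g4" & df$treatment == "stress"), ],
                                      c("p1", "p2")), "g4")
  expect_false("g4" %in% em1$table$genotype)
})

test_that("an injected standardized shift of 1 is recovered without bias", {
  set.seed(42)
  d_hat <- vapply(1:2000, function(i) {
    x <- rnorm(10, 1, 1); y <- rnorm(10, 0, 1)
    hedges_effect(group_stats(x), group_stats(y))$d_corrected
  }, 0)
  expect_lt(abs(mean(d_hat) - 1), 0.05)
})

test_that("one-way ANOVA with Tukey letters matches the SS oracle", {
  set.seed(43)
  groups <- lapply(1:5, function(i) rnorm(7, mean = i * 0.3))
  names(groups) <- paste0("g", 1:5)
  res <- anova_oneway_tukey(groups)
  orc <- anova_ss_oracle(groups)
  expect_equal(res$F, orc$F, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_identical(res$df1, 4L)
  expect_identical(res$df2, 30L)
})

test_that("letters: identical groups share one letter, separated groups differ", {
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  res <- anova_oneway_tukey(same)
  expect_equal(res$F, 0)
  expect_true(all(res$letters == "a"))
  set.seed(44)
  far <- list(lo = rnorm(6, 0, 0.1), hi = rnorm(6, 10, 0.1))
  res2 <- anova_oneway_tukey(far)
  expect_false(res2$letters[["lo"]] == res2$letters[["hi"]])
  expect_warning(anova_oneway_tukey(list(a = 1:5, b = 2, c = 3:8)), "n < 2")
})

test_that("Tukey p-values agree with stats::TukeyHSD on clean group names", {
  set.seed(45)
  df <- data.frame(value = rnorm(30), group = rep(c("A", "B", "C"), each = 10))
  res <- anova_oneway_tukey(df)
  tk <- TukeyHSD(aov(value ~ group, df))$group
  ours <- res$tukey
  key <- paste0(ours$group2, "-", ours$group1)
  expect_equal(unname(tk[key, "p adj"]), ours$p_adj, tolerance = 1e-8)
})

test_that("two-way Type III ANOVA: balanced equals sequential, additive has no interaction", {
  set.seed(46)
  d <- expand.grid(A = paste0("a", 1:3), B = c("x", "y"), r = 1:4)
  d$y <- rnorm(nrow(d), as.integer(factor(d$A)) + 2 * (d$B == "y"))
  res <- anova_twoway_type3(d$y, d$A, d$B)
  seq_ss <- anova(lm(y ~ A * B, d))      # Type I on balanced data
  expect_equal(res$table$SS[1:3], seq_ss[c("A", "B", "A:B"), "Sum Sq"],
               tolerance = 1e-8)
  # additive noise-free: zero interaction, SS conservation
  d$y0 <- as.integer(factor(d$A)) + 2 * (d$B == "y")
  res0 <- anova_twoway_type3(d$y0, d$A, d$B)
  expect_lt(res0$table$SS[3], 1e-12)
  expect_equal(sum(res0$table$SS), sum((d$y0 - mean(d$y0))^2), tolerance = 1e-10)
  expect_equal(res0$r_squared, 1, tolerance = 1e-12)
  # empty cell is named
  gone <- !(d$A == "a1" & d$B == "x")
  expect_error(anova_twoway_type3(d$y[gone], d$A[gone], d$B[gone]),
               "empty cell: a1 x x")
})

test_that("Type III SS agree with car::Anova on unbalanced noisy data", {
  set.seed(47)
  d <- expand.grid(A = paste0("a", 1:3), B = c("x", "y"), r = 1:5)
  d <- d[-c(1, 8, 14), ]               # unbalance the cells
  d$y <- rnorm(nrow(d), as.integer(factor(d$A)) * (d$B == "y"))
  res <- anova_twoway_type3(d$y, d$A, d$B)
  fit <- lm(y ~ A * B, d, contrasts = list(A = "contr.sum", B = "contr.sum"))
  ref <- car::Anova(fit, type = 3)
  expect_equal(res$table$SS[1:3], ref[c("A", "B", "A:B"), "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(res$table$F[1:3], ref[c("A", "B", "A:B"), "F value"],
               tolerance = 1e-10)
  expect_equal(res$table$p[1:3], ref[c("A", "B", "A:B"), "Pr(>F)"],
               tolerance = 1e-10)
})
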