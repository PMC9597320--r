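# Double-normalized W curves, averaging and delta-band amplitudes.

w_of <- function(tr, lo, hi) normalize_between(tr, extract_cardinal_points(tr), lo, hi)

test_that("W curves anchor at 0 and 1 and ignore affine fluorescence changes", {
  set.seed(21)
  tr <- random_transient(noise_cv = 0)
  w <- w_of(tr, "O", "J")
  expect_equal(w$w[1], 0, tolerance = 1e-12)
  expect_equal(w$w[length(w$w)], 1, tolerance = 1e-12)
  tr2 <- transient(tr$sample_id, tr$genotype, tr$treatment, tr$replicate,
                   tr$times, 2.5 * tr$values + 100)
  w2 <- w_of(tr2, "O", "J")
  expect_equal(w2$w, w$w, tolerance = 1e-10)
})

test_that("a fluorescence curve linear in t gives w = 0.5 at the F-range midpoint", {
  times <- c(10, 50, 150, 300, 1025, 2000, 30000, 1e5, 3e5, 1e6)
  vals <- 400 + (times - 50) * 0.4          # linear; 1025 us is the F-midpoint of O-J
  vals[times < 50] <- 400
  tr <- node_transient(vals, times)
  w <- w_of(tr, "O", "J")
  expect_equal(w$w[w$times == 1025], 0.5, tolerance = 1e-12)
})

test_that("mean_curve reproduces identical curves and mirrored pairs", {
  set.seed(22)
  tr <- random_transient(noise_cv = 0)
  w <- w_of(tr, "O", "K")
  m <- mean_curve(list(w, w, w))
  expect_equal(m$w, w$w, tolerance = 1e-12)
  expect_identical(m$n_averaged, 3L)
  mirrored <- w
  target <- w$w * 0.8
  mirrored$w <- 2 * target - w$w
  m2 <- mean_curve(list(w, mirrored))
  expect_equal(m2$w, target, tolerance = 1e-12)
  expect_error(mean_curve(list()), "empty")
  expect_error(mean_curve(list(w, w_of(tr, "O", "J"))), "mixed normalizations")
})

test_that("mean curve error shrinks roughly as 1/sqrt(n)", {
  shp <- transient_shape()
  truth <- w_of(simulate_transient(shp, default_time_grid(80), 0), "O", "J")
  err <- sapply(c(5, 20, 80), function(n) {
    set.seed(23)
    reps <- replicate(n, w_of(simulate_transient(shp, default_time_grid(80), 0.05),
                              "O", "J"), simplify = FALSE)
    max(abs(mean_curve(reps)$w - truth$w))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 2)    # 16x replication should beat 2x easily
})

test_that("delta of identical arms is zero and delta is antisymmetric", {
  set.seed(24)
  tr <- random_transient(noise_cv = 0)
  w <- w_of(tr, "O", "J")
  d0 <- delta_band(w, w, "K")
  expect_true(all(d0$delta_w == 0))
  expect_identical(d0$amplitude, 0)
  tr2 <- random_transient(noise_cv = 0)
  w2 <- w_of(tr2, "O", "J")
  dab <- delta_band(w, w2, "K")
  dba <- delta_band(w2, w, "K")
  expect_identical(dab$delta_w, -dba$delta_w)
  expect_identical(dab$amplitude, -dba$amplitude)
})

test_that("a constructed in-window bump is recovered exactly", {
  set.seed(25)
  tr <- random_transient(noise_cv = 0)
  w <- w_of(tr, "O", "J")
  wb <- w
  win <- default_band_windows()$K
  inside <- w$times >= win[1] & w$times <= win[2]
  wb$w[inside] <- wb$w[inside] + 0.05
  d <- delta_band(wb, w, "K")
  expect_equal(d$amplitude, 0.05, tolerance = 1e-12)
  expect_true(d$t_at_amplitude >= win[1] && d$t_at_amplitude <= win[2])
})

test_that("band/normalization pairing is enforced", {
  set.seed(26)
  tr <- random_transient(noise_cv = 0)
  expect_error(delta_band(w_of(tr, "O", "J"), w_of(tr, "O", "J"), "L"),
               "L-band needs O-K")
  expect_error(delta_band(w_of(tr, "O", "K"), w_of(tr, "O", "K"), "K"),
               "K-band needs O-J")
})

test_that("OEC-damage archetype gives a positive K-band matching a fine-grid scan", {
  ctrl <- transient_shape()
  oec <- ojipscreen:::apply_stress_deltas(ctrl, archetype_specs()$cluster2$stress_deltas)
  w_c <- w_of(simulate_transient(ctrl, default_time_grid(120), 0), "O", "J")
  w_s <- w_of(simulate_transient(oec, default_time_grid(120), 0, treatment = "stress"),
              "O", "J")
  d <- delta_band(w_s, w_c, "K")
  expect_gt(d$amplitude, 0)
  # brute-force scan on a 100x denser grid of the same noiseless model
  w_cd <- w_of(simulate_transient(ctrl, default_time_grid(12000), 0), "O", "J")
  w_sd <- w_of(simulate_transient(oec, default_time_grid(12000), 0), "O", "J")
  dd <- delta_band(w_sd, w_cd, "K")
  expect_lt(abs(d$amplitude - dd$amplitude) / abs(dd$amplitude), 0.01)
})

test_that("null two-arm amplitude contracts with replication", {
  shp <- transient_shape()
  mean_amp <- function(n, seeds = 8) {
    mean(vapply(seq_len(seeds), function(s) {
      set.seed(300 + s)
      arm <- function() mean_curve(replicate(n,
        w_of(simulate_transient(shp, default_time_grid(80), 0.02), "O", "J"),
        simplify = FALSE))
      abs(delta_band(arm(), arm(), "K")$amplitude)
    }, 0))
  }
  expect_lt(mean_amp(80), mean_amp(5) / 2)
})

test_that("band_table reports per-genotype amplitudes with letters", {
  cfg <- default_simulation_config(5L)
  cfg$genotypes <- c(A = "control_like", B = "cluster2", C = "cluster3")
  cfg$replication$transients <- 8
  ds <- simulate_experiment(cfg)
  bt <- band_table(ds$transients, "K")
  expect_setequal(bt$table$genotype, c("A", "B", "C"))
  expect_gt(bt$table$amplitude[bt$table$genotype == "B"], 0)
  expect_lt(bt$table$amplitude[bt$table$genotype == "C"], 0)
  expect_true(all(nchar(bt$table$letters) >= 1))
  expect_true(all(bt$table$n == 8))
})
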