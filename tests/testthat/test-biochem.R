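# Biochemical index equations: membrane integrity, water content,
# electrolyte leakage, MDA, proline, pigments.

test_that("cell membrane integrity matches the hand-worked conductivity example", {
  p <- conductivity_set(30, 10, 100)
  c0 <- conductivity_set(10, 5, 100)
  expect_equal(cell_membrane_integrity(p, c0), (0.6 / 0.85) * 100,
               tolerance = 1e-12)
  expect_equal(round(cell_membrane_integrity(p, c0), 3), 70.588)
})

test_that("CMI is 100 for control-equal damage and 0 at total leakage", {
  c0 <- conductivity_set(10, 5, 100)
  expect_equal(cell_membrane_integrity(c0, c0), 100, tolerance = 1e-12)
  p <- conductivity_set(60, 40, 100)    # P_int == P_tot
  expect_equal(cell_membrane_integrity(p, c0), 0, tolerance = 1e-12)
  leaked <- conductivity_set(60, 41, 100)
  expect_error(cell_membrane_integrity(p, leaked), "undefined control")
})

test_that("CMI is invariant under common rescaling of conductivities", {
  p <- conductivity_set(30, 10, 100); c0 <- conductivity_set(10, 5, 100)
  p2 <- conductivity_set(30 * 7, 10 * 7, 100 * 7)
  c2 <- conductivity_set(10 * 3, 5 * 3, 100 * 3)
  expect_equal(cell_membrane_integrity(p2, c2),
               cell_membrane_integrity(p, c0), tolerance = 1e-12)
})

test_that("relative water content spans its closed range", {
  expect_equal(relative_water_content(1.0, 1.0, 0.2), 100)
  expect_equal(relative_water_content(0.2, 1.0, 0.2), 0)
  expect_equal(relative_water_content(0.8, 1.0, 0.2), 75)
  expect_error(relative_water_content(0.8, 0.7, 0.2), "turgid")
  expect_error(relative_water_content(0.1, 1.0, 0.2), "fresh")
})

test_that("electrolyte leakage is the conductivity ratio in percent", {
  expect_equal(electrolyte_leakage(20, 80), 25)
  expect_equal(electrolyte_leakage(80, 80), 100)
  expect_equal(electrolyte_leakage(0, 80), 0)
  expect_error(electrolyte_leakage(5, 0), "EC2")
})

test_that("MDA follows the 155 mM-1 cm-1 extinction conversion", {
  expect_equal(mda_content(0.3, 0.3, 1, 0.02, "dry"), 0)
  # dA = 0.155 -> 0.001 mM; 1 ml -> 1 nmol; / 0.02 g DW -> 50 nmol/g DW
  expect_equal(mda_content(0.175, 0.02, 1, 0.02, "dry"), 50, tolerance = 1e-12)
  # fresh-mass basis with dry matter fraction 0.1: same dry mass
  expect_equal(mda_content(0.175, 0.02, 1, 0.2, "fresh", dry_matter_fraction = 0.1),
               50, tolerance = 1e-12)
  expect_equal(mda_content(0.175, 0.02, 2, 0.02, "dry"),
               2 * mda_content(0.175, 0.02, 1, 0.02, "dry"))
  expect_warning(v <- mda_content(0.1, 0.2, 1, 0.02, "dry"), "negative")
  expect_lt(v, 0)
})

test_that("proline uses an OLS standard curve", {
  cal2 <- data.frame(concentration = c(0, 1), a520 = c(0, 0.5))
  r <- proline_content(0.25, cal2, 1, 0.01, "dry")
  expect_equal(r$value, 50, tolerance = 1e-12)     # C = 0.5 umol/ml
  expect_equal(proline_content(0, cal2, 1, 0.01, "dry")$value, 0)
  expect_error(proline_content(0.2, data.frame(concentration = c(0, 1),
                                               a520 = c(0.5, 0)), 1, 1),
               "slope")
  expect_warning(proline_content(0.9, cal2, 1, 0.01, "dry"), "extrapolated")
})

test_that("proline calibration CIs cover the true slope at the nominal rate", {
  true_slope <- 2; true_int <- 0.01
  conc <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4)
  cover <- vapply(1:500, function(s) {
    set.seed(1000 + s)
    cal <- data.frame(concentration = conc,
                      a520 = true_int + true_slope * conc + rnorm(6, 0, 0.02))
    fit <- lm(a520 ~ concentration, cal)
    ci <- confint(fit)["concentration", ]
    ci[1] <= true_slope && true_slope <= ci[2]
  }, TRUE)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("pigment equations reproduce their printed coefficients", {
  z <- pigment_content(0, 0, 0)
  expect_equal(unlist(z[c("chl_a", "chl_b", "car")]), c(chl_a = 0, chl_b = 0, car = 0))
  # single-wavelength cases force one pigment negative, which must warn
  expect_warning(p_a <- pigment_content(0, 0, 1), "negative")
  expect_equal(p_a$chl_a, 11.24, tolerance = 1e-12)
  p_car <- suppressWarnings(pigment_content(1, 0, 0))
  expect_equal(p_car$car, 1000 / 214, tolerance = 1e-12)
  expect_equal(round(p_car$car, 4), 4.6729)
  # linearity in absorbances
  p1 <- pigment_content(0.2, 0.2, 0.5)
  p2 <- pigment_content(0.4, 0.4, 1.0)
  expect_equal(p2$chl_a, 2 * p1$chl_a, tolerance = 1e-12)
  expect_equal(p2$car, 2 * p1$car, tolerance = 1e-12)
})

test_that("biochem_table derives one row per sample per index", {
  set.seed(31)
  raw <- simulate_biochem("cluster2", "G1", n_reps = 3)
  tab <- biochem_table(raw, synthetic_proline_calibration())
  expect_setequal(unique(tab$index),
                  c("rwc", "el", "mda_leaf", "mda_root", "proline_leaf",
                    "proline_root", "chl_a", "chl_b", "car", "chl_to_car"))
  expect_identical(nrow(tab), nrow(raw) * 10L)
  expect_true(all(tab$value[tab$index == "rwc"] <= 100))
  # stress arm: proline up, RWC down relative to control
  med <- function(idx, arm) stats::median(tab$value[tab$index == idx & tab$treatment == arm])
  expect_gt(med("proline_leaf", "stress"), med("proline_leaf", "control"))
  expect_lt(med("rwc", "stress"), med("rwc", "control"))
})
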