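# Synthetic experiment generator with known ground truth.
#
# Forward model for one OJIP transient: a sum of log-time Hill sigmoids,
#   F(t) = F0 + (FM - F0) * sum_s a_s / (1 + (tau_s / t)^h_s),
# one component per apparent rise phase (K, J, I, P).  This reproduces the
# O-J-I-P step morphology on a log time axis with few parameters; it is a
# phenomenological device, not a biophysical model of PSII kinetics.
#
# Four stress-response archetypes perturb the control shape the way the
# four response groups of a PEG-screening experiment behave: archetype
# "cluster2" (drought-susceptible, OEC damage) raises F0, lowers FM and
# adds K-step amplitude, producing positive K- and L-bands; "cluster3"
# (donor-side stabilized) lowers both F0 and FM and removes K-step
# amplitude (negative bands); "cluster1" shifts amplitude from the P to
# the I phase (higher V_I, lower deltaR0/PI_TOT); "cluster4" does the
# opposite (lower V_I, larger Sm/N).  Correlated biochemical traits follow
# the same archetypes (proline up, leaf MDA up / root MDA down, RWC down
# ~10%, pigments variable).

#' Construct a transient shape (forward-model parameters)
#'
#' @param F0 minimal fluorescence, > 0 (instrument units).
#' @param FM maximal fluorescence, > F0.
#' @param amplitudes named numeric c(K=, J=, I=, P=), all >= 0, summing
#'   to 1: the fraction of variable fluorescence contributed by each rise
#'   phase.
#' @param taus named half-rise times in microseconds, strictly increasing
#'   across K < J < I < P (defaults 300, 2000, 30000, 200000).
#' @param hills named log-time Hill slopes, all > 0.
#' @return object of class `transient_shape`.
#' @export
transient_shape <- function(F0 = 400, FM = 2000,
                            amplitudes = c(K = 0.25, J = 0.35, I = 0.25, P = 0.15),
                            taus = c(K = 300, J = 2000, I = 30000, P = 200000),
                            hills = c(K = 1.4, J = 1.6, I = 2.0, P = 2.5)) {
  steps <- c("K", "J", "I", "P")
  stopifnot(all(steps %in% names(amplitudes)), all(steps %in% names(taus)),
            all(steps %in% names(hills)))
  amplitudes <- amplitudes[steps]; taus <- taus[steps]; hills <- hills[steps]
  if (F0 <= 0) stop("F0 must be positive")
  if (FM <= F0) stop("FM must exceed F0")
  if (any(amplitudes < 0)) stop("step amplitudes must be >= 0")
  if (abs(sum(amplitudes) - 1) > 1e-12) stop("step amplitudes must sum to 1")
  if (any(diff(taus) <= 0)) stop("step times must satisfy tau_K < tau_J < tau_I < tau_P")
  if (any(hills <= 0)) stop("Hill slopes must be positive")
  structure(list(F0 = F0, FM = FM, amplitudes = amplitudes,
                 taus = taus, hills = hills),
            class = "transient_shape")
}

# model fluorescence at times t (us), noiseless
shape_fluorescence <- function(shape, t) {
  acc <- 0
  for (s in c("K", "J", "I", "P"))
    acc <- acc + shape$amplitudes[[s]] / (1 + (shape$taus[[s]] / t)^shape$hills[[s]])
  shape$F0 + (shape$FM - shape$F0) * acc
}

#' Default log-spaced acquisition grid (microseconds)
#' @param n number of points (default 120) from 10 us to 1 s.
#' @export
default_time_grid <- function(n = 120) 10^seq(1, 6, length.out = n)

#' Simulate one transient from a shape
#'
#' Evaluates the forward model on the grid and applies multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` per point
#' (`noise_cv = 0` is deterministic).  Uses the current RNG state.
#'
#' @param shape a [transient_shape()].
#' @param grid time grid in microseconds within [10 us, 1 s].
#' @param noise_cv per-point noise CV, >= 0.
#' @param sample_id,genotype,treatment,replicate labels for the result.
#' @return a [transient()].
#' @export
simulate_transient <- function(shape, grid = default_time_grid(), noise_cv = 0,
                               sample_id = "sim", genotype = "G",
                               treatment = "control", replicate = 1L) {
  if (min(grid) < 10 || max(grid) > 1e6) stop("grid must lie within [10 us, 1 s]")
  f <- shape_fluorescence(shape, grid)
  if (noise_cv > 0) f <- f * (1 + stats::rnorm(length(f), 0, noise_cv))
  f <- pmax(f, .Machine$double.eps)
  transient(sample_id, genotype, treatment, replicate, grid, f)
}

#' Calibrate a shape to a target relative variable fluorescence at J
#'
#' Re-balances the pre-J (K, J) against the post-J (I, P) amplitude mass so
#' that the model's V at the J step equals `target_vj`, keeping the total
#' at 1.  Inverse helper for building test fixtures with known V_J.
#'
#' @param shape a [transient_shape()].
#' @param target_vj desired V_J in (0, 1).
#' @return the recalibrated `transient_shape`.
#' @export
calibrate_shape_vj <- function(shape, target_vj) {
  if (target_vj <= 0 || target_vj >= 1) stop("target V_J must be in (0, 1)")
  vj_of <- function(lambda) {
    a <- shape$amplitudes
    pre <- a[c("K", "J")] * lambda
    post_scale <- (1 - sum(pre)) / sum(a[c("I", "P")])
    if (post_scale < 0) return(NA_real_)
    a[c("K", "J")] <- pre
    a[c("I", "P")] <- a[c("I", "P")] * post_scale
    s2 <- shape; s2$amplitudes <- a
    # measure V_J the way the JIP engine does: F0 at the 50 us origin and
    # FM at the end of the recording, not the asymptotic model parameters
    f0 <- shape_fluorescence(s2, 50)
    fm <- shape_fluorescence(s2, 1e6)
    (shape_fluorescence(s2, shape$taus[["J"]]) - f0) / (fm - f0) - target_vj
  }
  upper <- 0.999 / sum(shape$amplitudes[c("K", "J")])
  sol <- stats::uniroot(vj_of, lower = 1e-6, upper = upper, tol = 1e-12)
  a <- shape$amplitudes
  a[c("K", "J")] <- a[c("K", "J")] * sol$root
  a[c("I", "P")] <- a[c("I", "P")] * (1 - sum(a[c("K", "J")])) / sum(a[c("I", "P")])
  a <- a / sum(a)
  transient_shape(shape$F0, shape$FM, a, shape$taus, shape$hills)
}

#' Stress-response archetype specifications
#'
#' Returns the named list of archetypes.  `stress_deltas` perturb the
#' control transient shape; `trait_effects` are multiplicative stress
#' effects on the biochemical index targets.
#' @export
archetype_specs <- function() {
  list(
    cluster1 = list(                      # I-phase gain: V_I up, PI_TOT down
      stress_deltas = list(F0_mult = 1.0, FM_mult = 1.05, a_K_add = 0,
                           a_shift = c(from = "P", to = "I", by = 0.06)),
      trait_effects = c(rwc = 0.92, el = 1.2, mda_leaf = 1.0, mda_root = 0.9,
                        proline_leaf = 1.0, proline_root = 1.0,
                        chl_a = 1.0, chl_b = 1.0, car = 1.0)),
    cluster2 = list(                      # OEC damage: positive K/L bands
      stress_deltas = list(F0_mult = 1.1, FM_mult = 0.9, a_K_add = 0.08,
                           a_shift = NULL),
      trait_effects = c(rwc = 0.88, el = 1.6, mda_leaf = 1.4, mda_root = 0.8,
                        proline_leaf = 1.5, proline_root = 1.4,
                        chl_a = 0.95, chl_b = 0.95, car = 1.0)),
    cluster3 = list(                      # donor-side stabilized: negative bands
      stress_deltas = list(F0_mult = 0.85, FM_mult = 0.85, a_K_add = -0.04,
                           a_shift = NULL),
      trait_effects = c(rwc = 0.9, el = 1.3, mda_leaf = 1.6, mda_root = 0.9,
                        proline_leaf = 2.0, proline_root = 1.8,
                        chl_a = 1.0, chl_b = 1.0, car = 0.8)),
    cluster4 = list(                      # P-phase gain: V_I down, Sm/N up
      stress_deltas = list(F0_mult = 1.0, FM_mult = 1.0, a_K_add = 0,
                           a_shift = c(from = "I", to = "P", by = 0.06)),
      trait_effects = c(rwc = 0.95, el = 1.1, mda_leaf = 1.0, mda_root = 1.0,
                        proline_leaf = 2.5, proline_root = 2.2,
                        chl_a = 1.0, chl_b = 1.0, car = 1.0)),
    control_like = list(
      stress_deltas = list(F0_mult = 1, FM_mult = 1, a_K_add = 0, a_shift = NULL),
      trait_effects = c(rwc = 1, el = 1, mda_leaf = 1, mda_root = 1,
                        proline_leaf = 1, proline_root = 1,
                        chl_a = 1, chl_b = 1, car = 1))
  )
}

# apply an archetype's stress deltas to a shape
apply_stress_deltas <- function(shape, deltas) {
  a <- shape$amplitudes
  if (!is.null(deltas$a_shift)) {
    by <- as.numeric(deltas$a_shift[["by"]])
    from <- deltas$a_shift[["from"]]; to <- deltas$a_shift[["to"]]
    by <- min(by, a[[from]])
    a[[from]] <- a[[from]] - by
    a[[to]] <- a[[to]] + by
  }
  if (deltas$a_K_add != 0) {
    others <- setdiff(names(a), "K")
    add <- max(deltas$a_K_add, -a[["K"]])
    a[["K"]] <- a[["K"]] + add
    a[others] <- a[others] * (1 - a[["K"]]) / sum(a[others])
  }
  a <- a / sum(a)
  transient_shape(shape$F0 * deltas$F0_mult, shape$FM * deltas$FM_mult,
                  a, shape$taus, shape$hills)
}

# per-genotype lognormal jitter on shape parameters (between-genotype CV)
jitter_shape <- function(shape, cv) {
  if (cv <= 0) return(shape)
  ln <- function(n) exp(stats::rnorm(n, 0, cv))
  a <- shape$amplitudes * ln(4)
  a <- a / sum(a)
  transient_shape(shape$F0 * ln(1), shape$FM * ln(1),
                  a, shape$taus, shape$hills * ln(4))
}

# ---- biochemical raw-measurement synthesis -------------------------------

# control-condition index targets and assay constants
.biochem_base <- list(
  rwc = 92, el = 10, mda_leaf = 20, mda_root = 15,      # %, %, nmol/g DW
  proline_leaf = 5, proline_root = 4,                   # umol/g DW
  chl_a = 0.06, chl_b = 0.025, car = 0.02,              # mg/ml extract
  tw = 1.0, dw = 0.2, el_ec2 = 400,
  mda_vol_ml = 1, mda_mass_g = 0.2, mda_dmf = 0.1, mda_a600 = 0.02,
  pro_vol_ml = 1, pro_mass_g = 0.1, pro_dmf = 0.1,
  pig_vol_ml = 2, pig_mass_g = 0.1,
  cal_slope = 2.0, cal_intercept = 0
)

#' The proline standard curve used by the synthetic experiment
#' @return data.frame with columns concentration (umol/ml) and a520.
#' @export
synthetic_proline_calibration <- function() {
  conc <- c(0, 0.025, 0.05, 0.1, 0.2, 0.4)
  data.frame(concentration = conc,
             a520 = .biochem_base$cal_slope * conc + .biochem_base$cal_intercept)
}

# invert the index formulas: raw measurements achieving given index targets
raw_from_targets <- function(tg) {
  b <- .biochem_base
  rwc <- min(tg[["rwc"]], 100)
  fw <- b$dw + rwc / 100 * (b$tw - b$dw)
  dA_leaf <- tg[["mda_leaf"]] * (b$mda_mass_g * b$mda_dmf) * 155 /
    (1000 * b$mda_vol_ml)
  dA_root <- tg[["mda_root"]] * (b$mda_mass_g * b$mda_dmf) * 155 /
    (1000 * b$mda_vol_ml)
  conc_leaf <- tg[["proline_leaf"]] * (b$pro_mass_g * b$pro_dmf) / b$pro_vol_ml
  conc_root <- tg[["proline_root"]] * (b$pro_mass_g * b$pro_dmf) / b$pro_vol_ml
  chl_a <- tg[["chl_a"]]; chl_b <- tg[["chl_b"]]; car <- tg[["car"]]
  det <- 11.24 * 20.13 - 2.04 * 4.19
  a661 <- (20.13 * chl_a + 2.04 * chl_b) / det
  a644 <- (4.19 * chl_a + 11.24 * chl_b) / det
  a470 <- (214 * car + 1.90 * chl_a + 63.14 * chl_b) / 1000
  list(fw = fw, tw = b$tw, dw = b$dw,
       el_ec1 = tg[["el"]] / 100 * b$el_ec2, el_ec2 = b$el_ec2,
       mda_a532 = b$mda_a600 + dA_leaf, mda_a600 = b$mda_a600,
       mda_root_a532 = b$mda_a600 + dA_root, mda_root_a600 = b$mda_a600,
       mda_vol_ml = b$mda_vol_ml, mda_mass_g = b$mda_mass_g, mda_dmf = b$mda_dmf,
       pro_a520 = b$cal_slope * conc_leaf + b$cal_intercept,
       pro_root_a520 = b$cal_slope * conc_root + b$cal_intercept,
       pro_vol_ml = b$pro_vol_ml, pro_mass_g = b$pro_mass_g, pro_dmf = b$pro_dmf,
       pig_a470 = a470, pig_a644_8 = a644, pig_a661_6 = a661,
       pig_vol_ml = b$pig_vol_ml, pig_mass_g = b$pig_mass_g)
}

#' Simulate raw biochemical measurements for one genotype
#'
#' Generates raw assay rows (weights, conductivities, absorbances) for both
#' treatment arms such that the derived indices hit the archetype's target
#' means with lognormal replicate noise.  Uses the current RNG state.
#'
#' @param archetype archetype name (see [archetype_specs()]) or a spec list.
#' @param genotype genotype label.
#' @param geno_mult named multiplicative genotype effect on each trait
#'   (default all 1).
#' @param n_reps replicates per arm, >= 2.
#' @param noise_cv lognormal replicate CV on the index targets.
#' @return data.frame of raw measurement rows (both arms).
#' @export
simulate_biochem <- function(archetype, genotype = "G", geno_mult = NULL,
                             n_reps = 6, noise_cv = 0.08) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  spec <- if (is.character(archetype)) {
    sp <- archetype_specs()[[archetype]]
    if (is.null(sp)) stop("unknown archetype '", archetype, "'")
    sp
  } else archetype
  traits <- names(spec$trait_effects)
  if (is.null(geno_mult)) geno_mult <- stats::setNames(rep(1, length(traits)), traits)
  base <- unlist(.biochem_base[traits])
  rows <- list()
  for (arm in c("control", "stress")) {
    eff <- if (arm == "stress") spec$trait_effects else stats::setNames(rep(1, length(traits)), traits)
    for (r in seq_len(n_reps)) {
      # weighing-based RWC has far smaller replicate error than the
      # colorimetric assays; scale its CV down accordingly
      cvs <- rep(noise_cv, length(traits))
      cvs[traits == "rwc"] <- 0.3 * noise_cv
      noise <- exp(stats::rnorm(length(traits), 0, cvs))
      tg <- base * geno_mult[traits] * eff[traits] * noise
      names(tg) <- traits
      if (tg[["rwc"]] > 100) tg[["rwc"]] <- 100   # turgid tissue cannot exceed saturation
      raw <- raw_from_targets(tg)
      rows[[paste(arm, r)]] <- data.frame(
        sample_id = paste(genotype, arm, r, sep = "_"),
        genotype = genotype, treatment = arm, replicate = r,
        raw, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# PEG-test conductivity rows for the initial CMI screen
simulate_cmi <- function(genotype, target_cmi, n_reps = 3, noise_cv = 0.06) {
  c_ratio <- 0.15
  rows <- list()
  for (r in seq_len(n_reps)) {
    cmi <- target_cmi * exp(stats::rnorm(1, 0, noise_cv))
    p_ratio <- min(1 - cmi / 100 * (1 - c_ratio), 0.99)
    c_r <- min(max(c_ratio * exp(stats::rnorm(1, 0, noise_cv)), 0.02), 0.9)
    rows[[r]] <- data.frame(
      genotype = genotype, replicate = r,
      p_deh = 0.6 * p_ratio * 120, p_reh = 0.4 * p_ratio * 120, p_tot = 120,
      c_deh = 0.6 * c_r * 100, c_reh = 0.4 * c_r * 100, c_tot = 100,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default genotype panel: 18 winter wheat genotypes across 4 archetypes
#' @return named character vector genotype -> archetype.
#' @export
default_genotype_panel <- function() {
  c("Osk_251-02" = "cluster1", "Osk_108-04" = "cluster1", "Osk_44-11" = "cluster1",
    "Osk_70-14" = "cluster1", "L459-2012" = "cluster1",
    "Osk_54-15" = "cluster2", "Osk_114-08" = "cluster2", "Osk_84-15" = "cluster2",
    "Osk_78-14" = "cluster2",
    "Osk_111-08" = "cluster3", "Osk_51-15" = "cluster3", "Osk_381-06" = "cluster3",
    "Osk_4.40-7-82" = "cluster3", "Osk_106-03" = "cluster3", "Osk_52-13" = "cluster3",
    "Osk_102-03" = "cluster4", "Osk_120-06" = "cluster4", "L259-2009" = "cluster4")
}

#' Default simulation configuration
#'
#' 18 genotypes in 4 archetypes, 20 transient replicates and 6 biochemical
#' replicates per arm, 1% per-point transient noise, 2% replicate shape CV,
#' 3% between-genotype shape CV.
#' @param seed master seed.
#' @return config list understood by [simulate_experiment()].
#' @export
default_simulation_config <- function(seed = 1L) {
  list(genotypes = default_genotype_panel(),
       replication = list(transients = 20, biochem = 6, cmi = 3),
       noise = list(transient_cv = 0.01, rep_cv = 0.02, geno_cv = 0.03,
                    biochem_cv = 0.08),
       grid_points = 120,
       seed = as.integer(seed))
}

#' Simulate a full labelled screening experiment
#'
#' Deterministic for a given master seed: all randomness flows through
#' named substreams (transients, biochem) derived from it.
#'
#' @param config configuration list, see [default_simulation_config()];
#'   `config$genotypes` maps genotype -> archetype name.
#' @param seed master seed (overrides `config$seed` when given).
#' @return object of class `synthetic_dataset`: list(transients =
#'   [transient_set()], biochem = raw measurement data.frame, cmi =
#'   PEG-test conductivity data.frame, truth = named archetype vector,
#'   config_echo, seed).
#' @export
simulate_experiment <- function(config = default_simulation_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)
  specs <- archetype_specs()
  unknown <- setdiff(unique(config$genotypes), names(specs))
  if (length(unknown)) stop("unknown archetype name(s): ", paste(unknown, collapse = ", "))
  genos <- names(config$genotypes)
  nz <- config$noise
  grid <- default_time_grid(config$grid_points %||% 120)
  trs <- with_substream(seed, "transients", {
    out <- list()
    for (g in genos) {
      arch <- specs[[config$genotypes[[g]]]]
      ctrl_shape <- jitter_shape(transient_shape(), nz$geno_cv)
      stress_shape <- apply_stress_deltas(ctrl_shape, arch$stress_deltas)
      for (arm in c("control", "stress")) {
        base_shape <- if (arm == "control") ctrl_shape else stress_shape
        for (r in seq_len(config$replication$transients)) {
          shp <- jitter_shape(base_shape, nz$rep_cv)
          out[[length(out) + 1]] <- simulate_transient(
            shp, grid, nz$transient_cv,
            sample_id = paste(g, arm, r, sep = "_"),
            genotype = g, treatment = arm, replicate = r)
        }
      }
    }
    out
  })
  bio <- with_substream(seed, "biochem", {
    tabs <- lapply(genos, function(g) {
      traits <- names(specs[[config$genotypes[[g]]]]$trait_effects)
      gm <- stats::setNames(exp(stats::rnorm(length(traits), 0, nz$geno_cv)), traits)
      gm[c("rwc", "el")] <- 1   # bounded indices: genotype effect through noise only
      simulate_biochem(config$genotypes[[g]], g, gm,
                       config$replication$biochem, nz$biochem_cv)
    })
    do.call(rbind, tabs)
  })
  cmi <- with_substream(seed, "cmi", {
    do.call(rbind, lapply(genos, function(g)
      simulate_cmi(g, stats::runif(1, 45, 65), config$replication$cmi)))
  })
  structure(list(transients = transient_set(trs, metadata = list(seed = seed)),
                 biochem = bio, cmi = cmi,
                 truth = config$genotypes,
                 config_echo = config, seed = seed),
            class = "synthetic_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> seed %d: %d transients, %d biochem rows, %d genotypes\n",
              x$seed, length(x$transients), nrow(x$biochem), length(x$truth)))
  print(table(archetype = x$truth))
  invisible(x)
}
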