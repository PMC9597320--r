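# JIP-test: cardinal fluorescence points and the derived energy-flux,
# quantum-yield and performance parameters.
#
# The fast fluorescence rise is read at the conventional cardinal steps
# O (50 us), L (150 us), K (300 us), J (2 ms), I (30 ms) and its maximum P.
# From these the JIP-test derives specific fluxes per active reaction
# centre (ABS/RC, TR0/RC, ET0/RC, RE0/RC, DI0/RC), phenomenological fluxes
# per excited cross-section (CS0 and CSm bases), quantum yields and
# efficiencies (phiP0, psiE0, phiE0, deltaR0, phiR0), the electron-carrier
# pool descriptors (M0, Sm, N) and the performance indices PI_ABS / PI_TOT
# with their log10 driving forces.

#' Default cardinal step times (microseconds)
#'
#' O is the 50 us origin; L, K, J, I follow the JIP-test convention
#' (150 us, 300 us, 2 ms, 30 ms).
#' @export
default_markers <- function() {
  c(O = 50, L = 150, K = 300, J = 2000, I = 30000)
}

#' Extract cardinal fluorescence points from a transient
#'
#' Fluorescence at each marker is interpolated linearly in log10(time),
#' matching the log-spaced sampling of continuous-excitation fluorometers.
#' FM is the curve maximum, tFM the first time attaining it, and `area` the
#' complementary area between the curve and the FM level integrated
#' (trapezoidally, on the recorded grid) from the O marker to tFM.
#'
#' @param tr a [transient()].
#' @param markers named vector of step times in microseconds; must contain
#'   O, L, K, J, I and lie inside the recorded range.
#' @return an object of class `cardinal_points`: list with F0, FL, FK, FJ,
#'   FI, FM, tFM, area, markers and a `truncated_p` flag (TRUE when the
#'   maximum sits on the last sample with a positive end slope, i.e. the P
#'   phase was likely cut off).
#' @export
extract_cardinal_points <- function(tr, markers = default_markers()) {
  stopifnot(inherits(tr, "transient"))
  need <- c("O", "L", "K", "J", "I")
  if (!all(need %in% names(markers)))
    stop("markers must name steps ", paste(need, collapse = ", "))
  t <- tr$times; f <- tr$values
  rng <- range(t)
  for (s in need) {
    if (markers[[s]] < rng[1] || markers[[s]] > rng[2])
      stop("range error: marker ", s, " (", markers[[s]],
           " us) outside recorded range [", rng[1], ", ", rng[2], "] us")
  }
  fm_idx <- which.max(f)                      # ties: which.max takes the first
  fm <- f[fm_idx]; tfm <- t[fm_idx]
  n <- length(f)
  truncated <- fm_idx == n && n >= 2 && f[n] > f[n - 1]
  at <- interp_logtime(t, f, markers[need])
  names(at) <- need
  # complementary area on the recorded grid, O marker to tFM
  keep <- t > markers[["O"]] & t < tfm
  tt <- c(markers[["O"]], t[keep], tfm)
  ff <- c(at[["O"]], f[keep], fm)
  area <- if (length(tt) > 1) sum(diff(tt) * (2 * fm - ff[-1] - ff[-length(ff)])) / 2 else 0
  structure(list(F0 = at[["O"]], FL = at[["L"]], FK = at[["K"]],
                 FJ = at[["J"]], FI = at[["I"]], FM = fm, tFM = tfm,
                 area = max(area, 0), markers = markers[need],
                 truncated_p = truncated),
            class = "cardinal_points")
}

#' Relative variable fluorescence curve
#'
#' V(t) = (F(t) - F0) / (FM - F0) on the recorded grid, together with its
#' values at the L, K, J, I markers (VL, VK, VJ, VI).
#'
#' @param tr a [transient()].
#' @param cp its [extract_cardinal_points()] record.
#' @return list with `times`, `v` and named marker values.
#' @export
variable_fluorescence_curve <- function(tr, cp) {
  fv <- cp$FM - cp$F0
  if (fv <= 0) stop("degenerate transient: FM <= F0")
  list(times = tr$times,
       v = (tr$values - cp$F0) / fv,
       VL = (cp$FL - cp$F0) / fv,
       VK = (cp$FK - cp$F0) / fv,
       VJ = (cp$FJ - cp$F0) / fv,
       VI = (cp$FI - cp$F0) / fv)
}

# canonical parameter order; column labels for output tables follow the
# customary transliteration of the JIP-test symbols
.jip_names <- c(
  "Fo_Fm", "VL", "VK", "VJ", "VI", "Mo", "Sm", "N", "Sm_tFm",
  "ABS_RC", "DIo_RC", "TRo_RC", "ETo_RC", "REo_RC",
  "phiPo", "psiEo", "phiEo", "dRo", "phiRo",
  "ABS_CSo", "DIo_CSo", "TRo_CSo", "ETo_CSo", "REo_CSo",
  "ABS_CSm", "DIo_CSm", "TRo_CSm", "ETo_CSm", "REo_CSm",
  "RC_CSo", "RC_CSm",
  "PI_ABS", "PI_TOT", "DF_ABS", "DF_TOT",
  "gRC_1-gRC", "phiPo_1-phiPo", "psiEo_1-psiEo", "dRo_1-dRo")

#' Names of all JIP-test parameters computed by [compute_jip_parameters()]
#' @return character vector of column labels.
#' @export
jip_parameter_names <- function() .jip_names

#' Compute the full JIP-test parameter record for one transient
#'
#' All standard derivations from the cardinal points: M0 = 4 (F300us - F0)
#' / (FM - F0) per ms; Sm = complementary area / (FM - F0) with time in ms;
#' N = Sm M0 / VJ; yields phiP0 = 1 - F0/FM, psiE0 = 1 - VJ, phiE0 =
#' phiP0 psiE0, deltaR0 = (1 - VI)/(1 - VJ), phiR0 = phiE0 deltaR0;
#' specific fluxes TR0/RC = M0/VJ, ABS/RC = TR0/RC / phiP0, ET0/RC =
#' TR0/RC psiE0, RE0/RC = TR0/RC psiE0 deltaR0, DI0/RC = ABS/RC - TR0/RC;
#' phenomenological fluxes on the CS0 (ABS/CS0 ~ F0) and CSm (ABS/CSm ~ FM)
#' bases as yield x ABS/CS; RC/CS = phiP0 (VJ/M0) ABS/CS; the ratio
#' parameters gammaRC/(1-gammaRC) = phiP0 VJ / M0, phiP0/(1-phiP0),
#' psiE0/(1-psiE0), deltaR0/(1-deltaR0); and PI_ABS, PI_TOT with DF = log10.
#'
#' @param tr a [transient()].
#' @param cp its [extract_cardinal_points()] record.
#' @return named list of class `jip_parameters` (all entries numeric,
#'   names as [jip_parameter_names()]).  If a performance index is not
#'   positive its driving force is NaN and a warning is raised.
#' @export
compute_jip_parameters <- function(tr, cp) {
  fv <- cp$FM - cp$F0
  if (fv <= 0) stop("degenerate transient: FM <= F0")
  vf <- variable_fluorescence_curve(tr, cp)
  VL <- vf$VL; VK <- vf$VK; VJ <- vf$VJ; VI <- vf$VI
  if (VJ <= 0 || VJ >= 1 || VI >= 1)
    stop("parameter-domain error: VJ=", signif(VJ, 4), ", VI=", signif(VI, 4),
         " leave the JIP ratios undefined")
  F300 <- cp$FK   # K marker sits at 300 us by convention
  if (!isTRUE(all.equal(cp$markers[["K"]], 300)))
    F300 <- interp_logtime(tr$times, tr$values, 300)
  M0 <- 4 * (F300 - cp$F0) / fv            # per ms (0.25 ms interval)
  Sm <- (cp$area / 1000) / fv              # time in ms
  N  <- Sm * M0 / VJ
  Sm_tFm <- Sm / (cp$tFM / 1000)
  phiP0 <- 1 - cp$F0 / cp$FM
  psiE0 <- 1 - VJ
  phiE0 <- phiP0 * psiE0
  dR0   <- (1 - VI) / (1 - VJ)
  phiR0 <- phiE0 * dR0
  TR0_RC <- M0 / VJ
  ABS_RC <- TR0_RC / phiP0
  ET0_RC <- TR0_RC * psiE0
  RE0_RC <- TR0_RC * psiE0 * dR0
  DI0_RC <- ABS_RC - TR0_RC
  cs <- function(abs_cs) c(ABS = abs_cs, DI = abs_cs * (1 - phiP0),
                           TR = abs_cs * phiP0, ET = abs_cs * phiE0,
                           RE = abs_cs * phiR0, RC = phiP0 * (VJ / M0) * abs_cs)
  cs0 <- cs(cp$F0); csm <- cs(cp$FM)
  gRC_r   <- phiP0 * VJ / M0
  phiP0_r <- phiP0 / (1 - phiP0)
  psiE0_r <- psiE0 / (1 - psiE0)
  dR0_r   <- dR0 / (1 - dR0)
  PI_ABS <- gRC_r * phiP0_r * psiE0_r
  PI_TOT <- PI_ABS * dR0_r
  DF_ABS <- if (PI_ABS > 0) log10(PI_ABS) else { warning("PI_ABS <= 0; DF_ABS is NaN"); NaN }
  DF_TOT <- if (PI_TOT > 0) log10(PI_TOT) else { warning("PI_TOT <= 0; DF_TOT is NaN"); NaN }
  out <- c(cp$F0 / cp$FM, VL, VK, VJ, VI, M0, Sm, N, Sm_tFm,
           ABS_RC, DI0_RC, TR0_RC, ET0_RC, RE0_RC,
           phiP0, psiE0, phiE0, dR0, phiR0,
           cs0[["ABS"]], cs0[["DI"]], cs0[["TR"]], cs0[["ET"]], cs0[["RE"]],
           csm[["ABS"]], csm[["DI"]], csm[["TR"]], csm[["ET"]], csm[["RE"]],
           cs0[["RC"]], csm[["RC"]],
           PI_ABS, PI_TOT, DF_ABS, DF_TOT,
           gRC_r, phiP0_r, psiE0_r, dR0_r)
  names(out) <- .jip_names
  structure(as.list(out), class = "jip_parameters")
}

#' JIP-test parameter table for a whole transient set
#'
#' Runs [extract_cardinal_points()] and [compute_jip_parameters()] on every
#' transient and returns one row per plant with identity keys followed by
#' all parameter columns.
#'
#' @param ts a [transient_set()].
#' @param markers cardinal step times, see [default_markers()].
#' @return a data.frame: sample_id, genotype, treatment, replicate, then
#'   the [jip_parameter_names()] columns.
#' @export
jip_table <- function(ts, markers = default_markers()) {
  stopifnot(inherits(ts, "transient_set"))
  labs <- set_labels(ts)
  vals <- t(vapply(ts$transients, function(tr) {
    cp <- extract_cardinal_points(tr, markers)
    unlist(compute_jip_parameters(tr, cp))
  }, numeric(length(.jip_names))))
  colnames(vals) <- .jip_names
  cbind(labs, as.data.frame(vals, check.names = FALSE))
}
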