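# Biochemical and physiological stress indices from raw measurements:
# conductivities (membrane integrity, electrolyte leakage), tissue weights
# (relative water content), and spectrophotometric assays (malondialdehyde,
# free proline, photosynthetic pigments).

#' Conductivity readings from the PEG desiccation test
#'
#' @param dehydration conductivity after the 24 h desiccation step (uS/cm).
#' @param rehydration conductivity after the 24 h rehydration step (uS/cm).
#' @param total conductivity after heat-killing the tissue (uS/cm).
#' @return a `conductivity_set` list.
#' @export
conductivity_set <- function(dehydration, rehydration, total) {
  if (any(c(dehydration, rehydration, total) <= 0))
    stop("conductivities must be positive")
  if (total < dehydration || total < rehydration)
    stop("total (heat-kill) conductivity must be >= each single reading")
  if (dehydration + rehydration > 2 * total)
    stop("dehydration + rehydration exceeds twice the total conductivity")
  structure(list(dehydration = dehydration, rehydration = rehydration,
                 total = total), class = "conductivity_set")
}

#' Cell membrane integrity (CMI, %)
#'
#' CMI = [(1 - P_int/P_tot) / (1 - C_int/C_tot)] x 100, where the internal
#' leakage P_int is the sum of the dehydration and rehydration readings of
#' the PEG-treated sample and P_tot its heat-kill reading; C is the
#' water control.  100 means membrane damage equal to the control; higher
#' values mean less damage.
#'
#' @param p [conductivity_set()] of the PEG-treated sample.
#' @param c_ctrl [conductivity_set()] of the water control.
#' @return CMI in percent.  If P_int > P_tot the raw (negative) value is
#'   returned with a warning, never clipped.
#' @export
cell_membrane_integrity <- function(p, c_ctrl) {
  p_int <- p$dehydration + p$rehydration
  c_int <- c_ctrl$dehydration + c_ctrl$rehydration
  if (c_int >= c_ctrl$total)
    stop("undefined control: control internal leakage >= total (fully leaked)")
  if (p_int > p$total)
    warning("treatment internal leakage exceeds its heat-kill total; CMI < 0 returned as-is")
  100 * (1 - p_int / p$total) / (1 - c_int / c_ctrl$total)
}

#' Relative water content (RWC, %)
#'
#' RWC = (FW - DW)/(TW - DW) x 100 from fresh, turgid and oven-dry weights.
#'
#' @param fresh,turgid,dry tissue weights in g, turgid >= fresh >= dry > 0.
#' @return RWC in percent (0-100 under the weight ordering).
#' @export
relative_water_content <- function(fresh, turgid, dry) {
  if (dry <= 0 || fresh < dry || turgid < fresh)
    stop("weights must satisfy turgid >= fresh >= dry > 0")
  if (turgid <= dry) stop("degenerate weights: turgid <= dry")
  100 * (fresh - dry) / (turgid - dry)
}

#' Electrolyte leakage (EL, %)
#'
#' EL = (EC1 / EC2) x 100: initial conductivity over the absolute
#' conductivity after heat disruption of the membranes.
#'
#' @param ec1 initial conductivity (uS/cm).
#' @param ec2 conductivity after heat kill (uS/cm), > 0.
#' @return EL in percent.
#' @export
electrolyte_leakage <- function(ec1, ec2) {
  if (ec2 <= 0) stop("heat-kill conductivity EC2 must be positive")
  100 * ec1 / ec2
}

#' Malondialdehyde content (nmol per g dry weight)
#'
#' TBARS assay: the non-specific absorbance at 600 nm is subtracted from
#' the 532 nm reading and converted with the MDA molar extinction
#' coefficient 155 mM^-1 cm^-1.  With the extract volume in ml this yields
#' nmol of MDA, expressed per g dry weight.  When the tissue was weighed
#' fresh, the dry mass is `tissue_mass * dry_matter_fraction`.
#'
#' @param a532,a600 absorbances at 532 (specific) and 600 nm (non-specific).
#' @param extract_volume_ml reaction/extract volume in ml.
#' @param tissue_mass_g extracted tissue mass in g.
#' @param mass_basis "fresh" or "dry" - basis of `tissue_mass_g`.
#' @param dry_matter_fraction fraction in (0, 1]; used only for
#'   `mass_basis = "fresh"`.
#' @param path_cm optical path length in cm.
#' @param dilution extra dilution factor of the reaction mix (default 1).
#' @return MDA in nmol per g dry weight.  A negative difference A532 - A600
#'   is propagated with a warning, never clipped.
#' @export
mda_content <- function(a532, a600, extract_volume_ml, tissue_mass_g,
                        mass_basis = c("fresh", "dry"),
                        dry_matter_fraction = 1, path_cm = 1, dilution = 1) {
  mass_basis <- match.arg(mass_basis)
  if (extract_volume_ml <= 0 || tissue_mass_g <= 0)
    stop("extract volume and tissue mass must be positive")
  if (dry_matter_fraction <= 0 || dry_matter_fraction > 1)
    stop("dry_matter_fraction must be in (0, 1]")
  da <- a532 - a600
  if (da < 0) warning("A532 < A600: negative MDA value returned as-is")
  conc_mM <- da / (155 * path_cm)                    # mM = umol/ml
  nmol <- conc_mM * extract_volume_ml * dilution * 1000
  dw <- if (mass_basis == "fresh") tissue_mass_g * dry_matter_fraction else tissue_mass_g
  nmol / dw
}

#' Free proline content (umol per g dry weight)
#'
#' Ninhydrin assay read at 520 nm against an L-proline standard curve.  An
#' ordinary least-squares line A = a C + b is fitted to the calibration
#' pairs; the sample concentration is C = (A520 - b)/a, scaled by extract
#' volume and expressed per g dry weight.
#'
#' @param a520 sample absorbance at 520 nm.
#' @param calibration data.frame or matrix with columns `concentration`
#'   (umol/ml) and `a520`; at least two distinct concentrations.
#' @param extract_volume_ml extract (toluene fraction) volume in ml.
#' @param tissue_mass_g extracted tissue mass in g.
#' @param mass_basis,dry_matter_fraction as in [mda_content()].
#' @param dilution extra dilution factor.
#' @return list: `value` (umol/g DW), `slope`, `intercept`, `r_squared`,
#'   `extrapolated` (TRUE when A520 falls outside the calibrated range).
#' @export
proline_content <- function(a520, calibration, extract_volume_ml, tissue_mass_g,
                            mass_basis = c("fresh", "dry"),
                            dry_matter_fraction = 1, dilution = 1) {
  mass_basis <- match.arg(mass_basis)
  cal <- as.data.frame(calibration)
  if (!all(c("concentration", "a520") %in% names(cal)))
    stop("calibration needs columns 'concentration' and 'a520'")
  if (length(unique(cal$concentration)) < 2)
    stop("calibration error: need >= 2 distinct concentrations")
  fit <- stats::lm(a520 ~ concentration, data = cal)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (a <= 0) stop("calibration error: non-positive slope")
  sst <- sum((cal$a520 - mean(cal$a520))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  extrap <- a520 < min(cal$a520) || a520 > max(cal$a520)
  if (extrap) warning("A520 outside the calibrated range: extrapolated")
  conc <- (a520 - b) / a                            # umol/ml
  dw <- if (mass_basis == "fresh") tissue_mass_g * dry_matter_fraction else tissue_mass_g
  list(value = conc * extract_volume_ml * dilution / dw,
       slope = a, intercept = b, r_squared = r2, extrapolated = extrap)
}

#' Photosynthetic pigment content
#'
#' Acetone-extract equations:
#' Chl a = 11.24 A661.6 - 2.04 A644.8;
#' Chl b = 20.13 A644.8 - 4.19 A661.6;
#' Car = (1000 A470 - 1.90 Chl a - 63.14 Chl b) / 214  (all mg/ml).
#'
#' @param a470,a644_8,a661_6 absorbances at 470, 644.8 and 661.6 nm.
#' @param extract_volume_ml extract volume in ml (for per-g values).
#' @param tissue_mass_g fresh tissue mass in g.
#' @return list with mg/ml concentrations (`chl_a`, `chl_b`, `car`,
#'   `chl_total`), ratios (`chl_to_car`, `chl_a_to_b`, NA when a
#'   denominator is not positive), and mg per g fresh weight
#'   (`chl_a_per_g`, `chl_b_per_g`, `car_per_g`).  Negative pigment values
#'   are returned with a warning.
#' @export
pigment_content <- function(a470, a644_8, a661_6,
                            extract_volume_ml = 1, tissue_mass_g = 1) {
  if (any(c(a470, a644_8, a661_6) < 0)) stop("absorbances must be >= 0")
  chl_a <- 11.24 * a661_6 - 2.04 * a644_8
  chl_b <- 20.13 * a644_8 - 4.19 * a661_6
  car <- (1000 * a470 - 1.90 * chl_a - 63.14 * chl_b) / 214
  if (chl_a < 0 || chl_b < 0 || car < 0)
    warning("negative pigment value returned as-is")
  per_g <- extract_volume_ml / tissue_mass_g
  list(chl_a = chl_a, chl_b = chl_b, car = car,
       chl_total = chl_a + chl_b,
       chl_to_car = if (car > 0) (chl_a + chl_b) / car else NA_real_,
       chl_a_to_b = if (chl_b > 0) chl_a / chl_b else NA_real_,
       chl_a_per_g = chl_a * per_g, chl_b_per_g = chl_b * per_g,
       car_per_g = car * per_g)
}

#' Derive the tidy index table from a raw biochemical measurement table
#'
#' Consumes the raw-measurement CSV dialect written by the synthetic
#' generator (one row per sample with assay columns) and returns one row
#' per sample per index, long format.
#'
#' @param raw data.frame with identity columns (sample_id, genotype,
#'   treatment, replicate) and the assay columns described in the package
#'   vignette (fw/tw/dw, el_ec1/el_ec2, mda_*, pro_*, pig_*).
#' @param proline_calibration calibration table for [proline_content()].
#' @return data.frame: sample_id, genotype, treatment, replicate, index,
#'   value.
#' @export
biochem_table <- function(raw, proline_calibration) {
  stopifnot(is.data.frame(raw))
  need <- c("sample_id", "genotype", "treatment", "replicate")
  if (!all(need %in% names(raw)))
    stop("raw table must carry columns ", paste(need, collapse = ", "))
  one <- function(r) {
    idx <- c(
      rwc = relative_water_content(r$fw, r$tw, r$dw),
      el = electrolyte_leakage(r$el_ec1, r$el_ec2),
      mda_leaf = mda_content(r$mda_a532, r$mda_a600, r$mda_vol_ml,
                             r$mda_mass_g, "fresh", r$mda_dmf),
      mda_root = mda_content(r$mda_root_a532, r$mda_root_a600, r$mda_vol_ml,
                             r$mda_mass_g, "fresh", r$mda_dmf),
      proline_leaf = proline_content(r$pro_a520, proline_calibration,
                                     r$pro_vol_ml, r$pro_mass_g, "fresh",
                                     r$pro_dmf)$value,
      proline_root = proline_content(r$pro_root_a520, proline_calibration,
                                     r$pro_vol_ml, r$pro_mass_g, "fresh",
                                     r$pro_dmf)$value)
    pig <- pigment_content(r$pig_a470, r$pig_a644_8, r$pig_a661_6,
                           r$pig_vol_ml, r$pig_mass_g)
    c(idx, chl_a = pig$chl_a_per_g, chl_b = pig$chl_b_per_g,
      car = pig$car_per_g, chl_to_car = pig$chl_to_car)
  }
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    r <- as.list(raw[i, ])
    v <- one(r)
    data.frame(sample_id = r$sample_id, genotype = r$genotype,
               treatment = r$treatment, replicate = r$replicate,
               index = names(v), value = unname(v),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
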