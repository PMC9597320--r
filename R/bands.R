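# L- and K-band analysis of double-normalized induction curves.
#
# W_OK = (Ft - F0)/(FK - F0) and W_OJ = (Ft - F0)/(FJ - F0) are relative
# variable fluorescence curves normalized between two cardinal steps.
# Subtracting the control mean curve from the stress mean curve reveals
# bands hidden between the anchors: the L-band (within O-K, around 150 us,
# PSII energetic connectivity) and the K-band (within O-J, around 300 us,
# oxygen-evolving-complex inhibition).  A positive K-band marks OEC damage;
# a negative one increased donor-side stability.

.band_spec <- list(
  L = list(pair = c("O", "K"), window = c(80, 300)),
  K = list(pair = c("O", "J"), window = c(200, 1000))
)

#' Default band windows (microseconds)
#' @return named list with L (80-300 us within W_OK) and K (200-1000 us
#'   within W_OJ) windows.
#' @export
default_band_windows <- function() lapply(.band_spec, `[[`, "window")

#' Double-normalize a transient between two cardinal steps
#'
#' w(t) = (F(t) - F_lo)/(F_hi - F_lo) restricted to [t_lo, t_hi], endpoints
#' included by interpolation so that w = 0 at the lower anchor and w = 1 at
#' the upper anchor exactly.
#'
#' @param tr a [transient()].
#' @param cp its [extract_cardinal_points()] record.
#' @param lo,hi step labels among O, L, K, J, I ("lo" may also be "O").
#' @return object of class `w_curve`: list(norm_lo, norm_hi, times, w,
#'   n_averaged = 1).
#' @export
normalize_between <- function(tr, cp, lo = "O", hi = "J") {
  fstep <- c(O = cp$F0, L = cp$FL, K = cp$FK, J = cp$FJ, I = cp$FI)
  tstep <- cp$markers
  if (!lo %in% names(fstep) || !hi %in% names(fstep))
    stop("unknown step label; use O, L, K, J or I")
  flo <- fstep[[lo]]; fhi <- fstep[[hi]]
  tlo <- tstep[[lo]]; thi <- tstep[[hi]]
  if (fhi <= flo) stop("degenerate normalization: F(", hi, ") <= F(", lo, ")")
  keep <- tr$times > tlo & tr$times < thi
  tt <- c(tlo, tr$times[keep], thi)
  ff <- c(flo, tr$values[keep], fhi)
  structure(list(norm_lo = lo, norm_hi = hi, times = tt,
                 w = (ff - flo) / (fhi - flo), n_averaged = 1L),
            class = "w_curve")
}

# resample a w_curve onto a target grid, linear in log10(time)
resample_w <- function(wc, grid) {
  w <- stats::approx(log10(wc$times), wc$w, xout = log10(grid), rule = 2)$y
  structure(list(norm_lo = wc$norm_lo, norm_hi = wc$norm_hi, times = grid,
                 w = w, n_averaged = wc$n_averaged),
            class = "w_curve")
}

#' Pointwise mean of normalized curves
#'
#' Curves are resampled onto the first curve's grid (linear in log-time)
#' and averaged arithmetically.
#'
#' @param curves list of [normalize_between()] curves sharing one
#'   normalization pair.
#' @return a `w_curve` with `n_averaged` set to the number of curves.
#' @export
mean_curve <- function(curves) {
  if (length(curves) == 0) stop("cannot average an empty collection of curves")
  lo <- unique(vapply(curves, `[[`, "", "norm_lo"))
  hi <- unique(vapply(curves, `[[`, "", "norm_hi"))
  if (length(lo) != 1 || length(hi) != 1)
    stop("mixed normalizations: all curves must share the same anchor pair")
  grid <- curves[[1]]$times
  mat <- vapply(curves, function(wc) resample_w(wc, grid)$w, numeric(length(grid)))
  structure(list(norm_lo = lo, norm_hi = hi, times = grid,
                 w = rowMeans(as.matrix(mat)), n_averaged = length(curves)),
            class = "w_curve")
}

#' Treatment-minus-control divergence and band amplitude
#'
#' delta W = W_stress - W_control on the common grid; the band amplitude is
#' the signed value of the largest |delta W| inside the band window
#' (earliest time wins at ties).  The L-band requires O-K normalized
#' curves, the K-band O-J ones.
#'
#' @param w_stress,w_control `w_curve` objects with matching anchors.
#' @param band "L" or "K".
#' @param window optional band window override, c(lo_us, hi_us).
#' @param genotype label attached to the result.
#' @return object of class `band_result`: list(band, times, delta_w,
#'   amplitude, t_at_amplitude, genotype).
#' @export
delta_band <- function(w_stress, w_control, band = c("K", "L"),
                       window = NULL, genotype = NA_character_) {
  band <- match.arg(band)
  spec <- .band_spec[[band]]
  for (wc in list(w_stress, w_control)) {
    if (!identical(c(wc$norm_lo, wc$norm_hi), spec$pair))
      stop("usage error: ", band, "-band needs ", spec$pair[1], "-",
           spec$pair[2], " normalized curves, got ", wc$norm_lo, "-", wc$norm_hi)
  }
  if (is.null(window)) window <- spec$window
  grid <- w_stress$times
  ctrl <- resample_w(w_control, grid)
  dw <- w_stress$w - ctrl$w
  inw <- which(grid >= window[1] & grid <= window[2])
  if (length(inw) == 0) stop("band window [", window[1], ", ", window[2],
                             "] us contains no grid points")
  i <- inw[which.max(abs(dw[inw]))]          # which.max: first (earliest) tie
  structure(list(band = band, times = grid, delta_w = dw,
                 amplitude = dw[i], t_at_amplitude = grid[i],
                 genotype = genotype),
            class = "band_result")
}

#' Per-genotype band analysis of a transient set
#'
#' For each genotype, stress and control replicate curves are normalized
#' (O-J for the K-band, O-K for the L-band), averaged per arm, and the
#' stress-minus-control divergence amplitude extracted.  Dispersion is the
#' SD of per-replicate amplitudes obtained by pairing each stress replicate
#' curve against the control mean curve.  A one-way ANOVA with Tukey HSD
#' letters across genotypes is run on those per-replicate amplitudes.
#'
#' @param ts a [transient_set()].
#' @param band "K" or "L".
#' @param markers cardinal step times.
#' @param window optional band window override.
#' @return list with `table` (data.frame: genotype, band, amplitude,
#'   t_at_amplitude, n, sd, letters), `anova` (the [anova_oneway_tukey()]
#'   record) and `curves` (per-genotype mean delta-W curves).
#' @export
band_table <- function(ts, band = c("K", "L"), markers = default_markers(),
                       window = NULL) {
  band <- match.arg(band)
  pair <- .band_spec[[band]]$pair
  labs <- set_labels(ts)
  genos <- sort(unique(labs$genotype))
  rows <- list(); reps <- list(); curves <- list()
  for (g in genos) {
    idx_s <- which(labs$genotype == g & labs$treatment == "stress")
    idx_c <- which(labs$genotype == g & labs$treatment == "control")
    if (length(idx_s) == 0 || length(idx_c) == 0) {
      warning("genotype ", g, " lacks a treatment arm; skipped in band analysis")
      next
    }
    mk_curves <- function(idx) lapply(idx, function(i) {
      tr <- ts$transients[[i]]
      normalize_between(tr, extract_cardinal_points(tr, markers), pair[1], pair[2])
    })
    cs <- mk_curves(idx_s); cc <- mk_curves(idx_c)
    m_s <- mean_curve(cs); m_c <- mean_curve(cc)
    br <- delta_band(m_s, m_c, band, window, genotype = g)
    amps <- vapply(cs, function(wc)
      delta_band(wc, m_c, band, window, genotype = g)$amplitude, 0)
    rows[[g]] <- data.frame(genotype = g, band = band,
                            amplitude = br$amplitude,
                            t_at_amplitude = br$t_at_amplitude,
                            n = length(amps), sd = stats::sd(amps),
                            stringsAsFactors = FALSE)
    reps[[g]] <- amps
    curves[[g]] <- br
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  aov_res <- NULL
  if (length(reps) >= 2 && all(lengths(reps) >= 2)) {
    aov_res <- anova_oneway_tukey(reps)
    tab$letters <- vapply(tab$genotype, function(g) aov_res$letters[[g]], "")
  }
  list(table = tab, anova = aov_res, curves = curves)
}
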