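# Independent oracles and fixture builders used across the test files.

# Straight-line transcription of the JIP-test formula sheet, written
# independently of the package internals: own interpolation, own
# integration, formulas one per line.
jip_oracle <- function(times, values, markers = c(O = 50, L = 150, K = 300,
                                                  J = 2000, I = 30000)) {
  fat <- function(t0) approx(log10(times), values, xout = log10(t0))$y
  F0 <- fat(markers[["O"]]); FL <- fat(markers[["L"]]); FK <- fat(markers[["K"]])
  FJ <- fat(markers[["J"]]); FI <- fat(markers[["I"]])
  FM <- max(values); tFM <- times[which(values == FM)[1]]
  sel <- times > markers[["O"]] & times < tFM
  tt <- c(markers[["O"]], times[sel], tFM)
  ff <- c(F0, values[sel], FM)
  area <- 0
  if (length(tt) > 1) for (i in seq_len(length(tt) - 1))
    area <- area + (tt[i + 1] - tt[i]) * ((FM - ff[i]) + (FM - ff[i + 1])) / 2
  FV <- FM - F0
  VL <- (FL - F0) / FV; VK <- (FK - F0) / FV
  VJ <- (FJ - F0) / FV; VI <- (FI - F0) / FV
  F300 <- fat(300)
  M0 <- 4 * (F300 - F0) / FV
  Sm <- (area / 1000) / FV
  N <- Sm * M0 / VJ
  Sm_tFm <- Sm / (tFM / 1000)
  phiP0 <- 1 - F0 / FM
  psiE0 <- 1 - VJ
  phiE0 <- phiP0 * psiE0
  dR0 <- (1 - VI) / (1 - VJ)
  phiR0 <- phiE0 * dR0
  TR0_RC <- M0 / VJ
  ABS_RC <- TR0_RC / phiP0
  ET0_RC <- TR0_RC * psiE0
  RE0_RC <- TR0_RC * psiE0 * dR0
  DI0_RC <- ABS_RC - TR0_RC
  ABS_CS0 <- F0; ABS_CSm <- FM
  gRC <- phiP0 * VJ / M0
  PI_ABS <- gRC * (phiP0 / (1 - phiP0)) * (psiE0 / (1 - psiE0))
  PI_TOT <- PI_ABS * (dR0 / (1 - dR0))
  c("Fo_Fm" = F0 / FM, VL = VL, VK = VK, VJ = VJ, VI = VI,
    Mo = M0, Sm = Sm, N = N, Sm_tFm = Sm_tFm,
    ABS_RC = ABS_RC, DIo_RC = DI0_RC, TRo_RC = TR0_RC, ETo_RC = ET0_RC,
    REo_RC = RE0_RC,
    phiPo = phiP0, psiEo = psiE0, phiEo = phiE0, dRo = dR0, phiRo = phiR0,
    ABS_CSo = ABS_CS0, DIo_CSo = ABS_CS0 * (1 - phiP0),
    TRo_CSo = ABS_CS0 * phiP0, ETo_CSo = ABS_CS0 * phiE0,
    REo_CSo = ABS_CS0 * phiR0,
    ABS_CSm = ABS_CSm, DIo_CSm = ABS_CSm * (1 - phiP0),
    TRo_CSm = ABS_CSm * phiP0, ETo_CSm = ABS_CSm * phiE0,
    REo_CSm = ABS_CSm * phiR0,
    RC_CSo = gRC * ABS_CS0, RC_CSm = gRC * ABS_CSm,
    PI_ABS = PI_ABS, PI_TOT = PI_TOT,
    DF_ABS = log10(PI_ABS), DF_TOT = log10(PI_TOT),
    "gRC_1-gRC" = gRC, "phiPo_1-phiPo" = phiP0 / (1 - phiP0),
    "psiEo_1-psiEo" = psiE0 / (1 - psiE0), "dRo_1-dRo" = dR0 / (1 - dR0))
}

# random valid transient for property suites (uses current RNG state)
random_transient <- function(id = "r", noise_cv = 0.01) {
  a <- rgamma(4, shape = c(3, 4, 3, 2))
  a <- a / sum(a)
  names(a) <- c("K", "J", "I", "P")
  shp <- transient_shape(
    F0 = runif(1, 250, 700),
    FM = runif(1, 1500, 3000),
    amplitudes = a,
    hills = c(K = runif(1, 1.1, 1.8), J = runif(1, 1.3, 2.0),
              I = runif(1, 1.6, 2.4), P = runif(1, 2.0, 3.0)))
  simulate_transient(shp, default_time_grid(100), noise_cv, sample_id = id)
}

# hand-built transient whose marker values are exact grid nodes
node_transient <- function(vals, times = c(10, 50, 150, 300, 2000, 30000,
                                           1e5, 2e5, 3e5, 1e6)) {
  transient("node", "G", "control", 1L, times, vals)
}

# textbook one-way ANOVA from sums of squares, no stats::aov
anova_ss_oracle <- function(values) {
  all <- unlist(values)
  grand <- mean(all)
  ssb <- sum(vapply(values, function(x) length(x) * (mean(x) - grand)^2, 0))
  ssw <- sum(vapply(values, function(x) sum((x - mean(x))^2), 0))
  df1 <- length(values) - 1
  df2 <- length(all) - length(values)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# oblimin criterion computed independently (direct sum transcription)
oblimin_crit_oracle <- function(L, gamma = 0) {
  p <- nrow(L); k <- ncol(L)
  L2 <- L^2
  tot <- 0
  for (j in seq_len(k)) for (l in seq_len(k)) {
    if (j == l) next
    term <- sum(L2[, j] * L2[, l])
    if (gamma != 0) term <- term - gamma / p * sum(L2[, j]) * sum(L2[, l])
    tot <- tot + term
  }
  tot / 4
}

# reference oblique rotation by general-purpose optimization over the
# rotation matrix T (columns normalized to unit length), independent of
# the gradient-projection path
oblimin_reference <- function(A, gamma = 0) {
  k <- ncol(A)
  obj <- function(theta) {
    Tm <- matrix(theta, k, k)
    Tm <- sweep(Tm, 2, sqrt(colSums(Tm^2)), `/`)
    L <- tryCatch(A %*% t(solve(Tm)), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    oblimin_crit_oracle(L, gamma)
  }
  fit <- optim(as.numeric(diag(k)), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  Tm <- matrix(fit$par, k, k)
  Tm <- sweep(Tm, 2, sqrt(colSums(Tm^2)), `/`)
  L <- A %*% t(solve(Tm))
  sgn <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(L[, j])); if (L[i, j] < 0) -1 else 1
  }, 0)
  list(pattern = sweep(L, 2, sgn, `*`), criterion = fit$value)
}

# match reference pattern columns to implementation columns by maximal
# absolute correlation, returning the permuted/sign-aligned reference
align_columns <- function(ref, target) {
  k <- ncol(target)
  perm <- integer(k); used <- logical(k)
  for (j in seq_len(k)) {
    cors <- vapply(seq_len(k), function(l)
      if (used[l]) -Inf else abs(sum(ref[, l] * target[, j])), 0)
    perm[j] <- which.max(cors)
    used[perm[j]] <- TRUE
  }
  out <- ref[, perm, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(out[, j]))
    if (sign(out[i, j]) != sign(target[i, j])) out[, j] <- -out[, j]
  }
  out
}
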