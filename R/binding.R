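#' Normalize a raw fluorescence titration
#'
#' value(L) = 100 * (raw(L) - blank(L)) / (raw(0) - blank(0)): the
#' unlabeled-vesicle contribution is subtracted and the no-vesicle point
#' defines 100%.
#'
#' @param raw data.frame `conc_mg_ml`, `fluor`, optional `replicate`
#' @param blank data.frame on the same concentration grid (including 0)
#' @return normalized data.frame `conc_mg_ml`, `fluor_pct`, `replicate`
#' @export
normalizeFluorescence <- function(raw, blank) {
  if (!all(sort(unique(raw$conc_mg_ml)) %in% sort(unique(blank$conc_mg_ml))))
    stop("raw and blank series must share the concentration grid")
  if (!any(raw$conc_mg_ml == 0)) stop("series must include the 0 concentration")
  bl <- tapply(blank$fluor, blank$conc_mg_ml, mean)
  b <- bl[as.character(raw$conc_mg_ml)]
  anchorRaw <- mean(raw$fluor[raw$conc_mg_ml == 0])
  anchor <- anchorRaw - bl[["0"]]
  if (anchor <= 0)
    stop("raw signal at zero concentration does not exceed the blank")
  data.frame(conc_mg_ml = raw$conc_mg_ml,
             fluor_pct = 100 * (raw$fluor - b) / anchor,
             replicate = raw$replicate %||% 1L,
             row.names = NULL)
}

#' Fit the saturation-binding model to a titration
#'
#' Nonlinear least squares of F(L) = F0 + A*L/(K_D + L) over all
#' replicates, with multi-start initialization over a K_D grid and the
#' K_D standard error taken from the fit covariance. A sign-flipped
#' (quenching) variant is available. Near-zero amplitude makes K_D
#' unidentifiable; this is flagged rather than silently returned.
#'
#' @param data data.frame `conc_mg_ml`, `fluor_pct`, `replicate` (as from
#'   [generateBindingData()] or [normalizeFluorescence()])
#' @param decreasing fit the sign-flipped model F0 - A*L/(K_D + L)
#' @return a [BindingFit-class]
#' @export
fitBinding <- function(data, decreasing = FALSE) {
  L <- data$conc_mg_ml
  y <- data$fluor_pct
  if (length(unique(L)) < 4)
    stop("at least 4 distinct concentrations required")
  sgn <- if (decreasing) -1 else 1
  model <- function(p) p[1] + sgn * p[2] * L / (p[3] + L)
  rss <- function(p) sum((y - model(p))^2)
  F0g <- mean(y[L == 0]) %||% y[1]
  if (!is.finite(F0g)) F0g <- y[which.min(L)]
  Ag <- sgn * (mean(y[L == max(L)]) - F0g)
  span <- diff(range(y))
  starts <- unique(pmin(pmax(10^seq(-3, 0, length.out = 8) * max(L), 1e-6), max(L) * 10))
  best <- NULL
  for (k0 in starts) {
    fit <- stats::optim(c(F0g, max(Ag, span / 2, 1e-3), k0), rss,
                        method = "L-BFGS-B",
                        lower = c(-Inf, -Inf, 1e-9), hessian = FALSE)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## polish + covariance via Gauss-Newton at the optimum
  p <- best$par
  for (it in 1:50) {
    J <- cbind(1, sgn * L / (p[3] + L), -sgn * p[2] * L / (p[3] + L)^2)
    r <- y - model(p)
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(3), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    pn <- p + as.numeric(step)
    pn[3] <- max(pn[3], 1e-9)
    if (rss(pn) <= rss(p) + 1e-12) p <- pn
    if (sqrt(sum(step^2)) < 1e-12 * max(1, sqrt(sum(p^2)))) break
  }
  J <- cbind(1, sgn * L / (p[3] + L), -sgn * p[2] * L / (p[3] + L)^2)
  dof <- length(y) - 3
  s2 <- rss(p) / max(dof, 1)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e)
    matrix(NA_real_, 3, 3))
  kdSe <- sqrt(cov[3, 3])
  if (p[3] <= min(L[L > 0]) / 2 || p[3] >= max(L) * 2)
    warning("fitted K_D lies outside the sampled concentration range; ",
            "the design may not span half-saturation")
  identifiable <- is.finite(kdSe) && abs(p[2]) > 2 * sqrt(cov[2, 2])
  if (!identifiable)
    warning("amplitude indistinguishable from 0: K_D is not identifiable")
  new("BindingFit", F0 = p[1], A = sgn * p[2], kd = p[3], kdSe = kdSe,
      dG = NA_real_, dGse = NA_real_,
      diagnostics = list(rss = rss(p), converged = TRUE,
                         identifiable = identifiable, dof = dof,
                         sigma2 = s2, cov = cov))
}

#' Convert a dissociation constant to a binding free energy
#'
#' K_D in mg/mL of total lipid is converted to molar through the
#' mole-fraction-weighted mean lipid molar mass, then
#' dG = R*T*ln(K_D[M] / c0) with the 1 M reference state. Defaults match
#' a 59:30:10:1 DOPC/SM/CHOL/GM1 vesicle composition.
#'
#' @param kd dissociation constant (mg/mL total lipid)
#' @param kdSe optional standard error of `kd` (first-order propagation:
#'   d(dG) = R*T*dK_D/K_D)
#' @param moleFractions lipid mole fractions (must sum to 1)
#' @param molarMasses lipid molar masses (g/mol)
#' @param temperature temperature (K)
#' @param reference reference concentration (M)
#' @return named list: `dG` (kJ/mol), `dGse`, `kdMolar`, `meanMolarMass`
#' @examples
#' kdToDg(0.013)  # approx -27.1 kJ/mol at 298.15 K
#' @export
kdToDg <- function(kd, kdSe = NA_real_,
                   moleFractions = c(DOPC = 0.59, SM = 0.30,
                                     CHOL = 0.10, GM1 = 0.01),
                   molarMasses = c(DOPC = 786.1, SM = 731.1,
                                   CHOL = 386.7, GM1 = 1545.0),
                   temperature = 298.15, reference = 1) {
  if (abs(sum(moleFractions) - 1) > 1e-8) stop("mole fractions must sum to 1")
  if (any(molarMasses <= 0)) stop("molar masses must be > 0")
  mbar <- sum(moleFractions * molarMasses[names(moleFractions)])
  kdM <- kd / mbar          # mg/mL = g/L; / (g/mol) = mol/L
  dG <- kBoltz * temperature * log(kdM / reference)
  dGse <- if (is.finite(kdSe)) kBoltz * temperature * kdSe / kd else NA_real_
  list(dG = dG, dGse = dGse, kdMolar = kdM, meanMolarMass = mbar)
}

#' @rdname kdToDg
#' @param fit a [BindingFit-class]; returns the fit with `dG`/`dGse` filled
#' @param ... passed on to `kdToDg`
#' @export
bindingFreeEnergy <- function(fit, ...) {
  r <- kdToDg(fit@kd, fit@kdSe, ...)
  fit@dG <- r$dG
  fit@dGse <- r$dGse
  fit
}

#' Compare computational and experimental binding free energies
#'
#' Per-compound table of the simulated and measured dG, their absolute
#' discrepancy, and a pass/fail against a force-field-error threshold
#' (default 9 kJ/mol, the upper end of the typical coarse-grained
#' force-field error range of roughly 4-9 kJ/mol).
#'
#' @param computational named numeric vector of dG from sampling (kJ/mol)
#' @param experimental named numeric vector of dG from binding fits
#'   (kJ/mol), same names
#' @param threshold acceptance threshold (kJ/mol)
#' @return data.frame with columns compound, dG_computational,
#'   dG_experimental, discrepancy, pass
#' @examples
#' compareAffinities(c(SQ = -22.75, TRO = -16.71),
#'                   c(SQ = -27.36, TRO = -24.93))
#' @export
compareAffinities <- function(computational, experimental, threshold = 9) {
  nm <- names(computational)
  stopifnot(!is.null(nm), all(nm %in% names(experimental)))
  disc <- abs(computational - experimental[nm])
  data.frame(compound = nm,
             dG_computational = as.numeric(computational),
             dG_experimental = as.numeric(experimental[nm]),
             discrepancy = as.numeric(disc),
             pass = as.numeric(disc) <= threshold,
             row.names = NULL)
}

#' Read / write binding titration CSV
#'
#' Plain CSV with header `conc_mg_ml,fluor_pct,replicate`.
#'
#' @param data titration data.frame
#' @param path file path
#' @export
writeBindingCsv <- function(data, path) {
  utils::write.csv(data[c("conc_mg_ml", "fluor_pct", "replicate")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeBindingCsv
#' @export
readBindingCsv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("conc_mg_ml", "fluor_pct", "replicate") %in% colnames(df)))
  df
}
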