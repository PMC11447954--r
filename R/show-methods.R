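setMethod("show", "PotentialSpec", function(object) {
  cat("PotentialSpec <", object@kind, ">\n", sep = "")
  p <- object@params
  if (!is.null(p$barrier))
    cat("  barrier:", p$barrier, "kJ/mol\n")
  if (!is.null(p$deltaG))
    cat("  programmed deltaG:", p$deltaG, "kJ/mol\n")
  if (object@kind == "mini_bilayer")
    cat("  ", p$nLipidTypes, "+", p$nExcludedTypes, "lipid site types x",
        p$sitesPerType, "sites; solute beads:", p$soluteBeads, "\n")
})

setMethod("show", "ToySystem", function(object) {
  cat("ToySystem <", object@spec@kind, ">: ", nrow(object@coords0),
      " particle(s), ", ncol(object@coords0), "D",
      if (any(object@periodic)) " (periodic x,y)" else "", "\n", sep = "")
})

setMethod("show", "Trajectory", function(object) {
  T <- dim(object@frames)[1]
  cat("Trajectory: ", T, " frames x ", dim(object@frames)[2],
      " particle(s), ", object@temperature, " K, ",
      "t = ", signif(object@times[T], 4), " ps",
      if (any(object@bias != 0)) " [biased]" else "", "\n", sep = "")
})

setMethod("show", "DescriptorSet", function(object) {
  cat("DescriptorSet: ", nrow(object@values), " frames x ",
      ncol(object@values), " features (", object@nBeads, " beads x ",
      object@nGroups, " groups)\n", sep = "")
})

setMethod("show", "TicaModel", function(object) {
  cat("TicaModel: lag ", signif(object@lag, 4), " (", object@lagUnit,
      ")\n  eigenvalues: ", paste(signif(object@evals, 4), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "DeepTicaModel", function(object) {
  cat("DeepTicaModel [", paste(object@arch, collapse = "-"), "] tanh\n",
      "  eigenvalues: ", paste(signif(object@evals, 4), collapse = ", "),
      "\n  trained ", nrow(object@trainLog), " epochs (seed ",
      object@seed, ")\n", sep = "")
})

setMethod("show", "OpesState", function(object) {
  cat("OpesState: ", nrow(object@kernels), " kernels after ",
      object@nDeposits, " deposits; barrier ", object@barrier,
      " kJ/mol, gamma ", signif(object@gamma, 4), "\n", sep = "")
})

setMethod("show", "ExpandedState", function(object) {
  Ts <- 1 / (kBoltz * range(object@betas))
  cat("ExpandedState: ", length(object@betas), " beta points, ",
      round(min(Ts)), "-", round(max(Ts)), " K, ",
      object@nSamples, " samples\n", sep = "")
})

setMethod("show", "FreeEnergySurface", function(object) {
  cat("FreeEnergySurface along ", paste(object@cvNames, collapse = ", "),
      ": ", paste(vapply(object@grid, length, 1L), collapse = " x "),
      " bins, ", sum(!is.na(object@values)), " occupied, T = ",
      object@temperature, " K\n", sep = "")
})

setMethod("show", "BasinResult", function(object) {
  cat(sprintf("BasinResult: dG = %.2f +/- %.2f kJ/mol, barrier = %.2f kJ/mol at %.3g%s\n",
              object@dG, object@dGse, object@barrier,
              object@barrierLocation,
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: K_D = %.4g +/- %.2g mg/mL, F0 = %.1f%%, A = %.1f%%",
              object@kd, object@kdSe, object@F0, object@A))
  if (is.finite(object@dG))
    cat(sprintf(", dG = %.2f +/- %.2f kJ/mol", object@dG, object@dGse))
  cat("\n")
})
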