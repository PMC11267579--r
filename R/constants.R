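# Physical constants in the engine's unit system:
# length nm, time ps, energy kJ/mol, mass u, charge e, temperature K,
# pressure bar.

#' @keywords internal
KB <- 0.00831446261815324 # kJ mol^-1 K^-1

#' @keywords internal
COULOMB_K <- 138.935458 # kJ mol^-1 nm e^-2, 1/(4 pi eps0)

#' @keywords internal
PRESSURE_FACTOR <- 16.6054 # 1 kJ mol^-1 nm^-3 in bar
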