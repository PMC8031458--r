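# shared fixtures: the packaged simvastatin study and small synthetic curves

table1_curves <- function() {
  read_solubility_table(system.file("extdata", "simvastatin_solubility.csv",
                                    package = "soluthermo"))
}

sim_fusion <- function() {
  read_fusion_properties(system.file("extdata", "simvastatin_fusion.json",
                                     package = "soluthermo"))
}

hansen_fixture <- function() {
  read_hansen_table(system.file("extdata", "hansen_parameters.csv",
                                package = "soluthermo"))
}

m59_curve <- function() {
  solubility_curve("20 mM M59", c(300.2, 310.2, 320.2),
                   c(1.15e-2, 1.33e-2, 1.54e-2),
                   surfactant = "M59", conc_mM = 20)
}

# noiseless curve obeying ln x = a + b/T exactly
exact_vh_curve <- function(a, b, temps, id = "exact") {
  solubility_curve(id, temps, exp(a + b / temps))
}

# noiseless curve obeying ln x = A + B/T + C ln T exactly
exact_apl_curve <- function(A, B, C, temps, id = "exact-apl") {
  solubility_curve(id, temps, exp(A + B / temps + C * log(temps)))
}
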