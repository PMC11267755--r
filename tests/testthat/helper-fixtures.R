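# shared fixtures, built in code

# toy registry: a 100.000 Da chromophore stand-in (no formula) plus Gly,
# for linear-scaffold bookkeeping oracles
toy_registry <- function() {
  reg <- default_registry()
  validate_registry(dplyr::bind_rows(
    reg,
    tibble::tibble(id = "ChrToy", name = "toy chromophore",
                   role = "chromophore_acyl", class = "chromophore",
                   formula = NA_character_, mono_mass = 100.0,
                   nominal_mass = 100L)
  ))
}

# linear 8xGly scaffold on the toy chromophore
toy_linear_scaffold <- function() {
  pvd_scaffold(residues = rep("Gly", 8), chromophore = "ChrToy",
               cycle_span = NULL, registry = toy_registry())
}

native_variant <- function() pvd_variant(pvd_scaffold())

ser_variant <- function() pvd_variant(pvd_scaffold(), c("8" = "Ser"))

# default candidate alphabet of the study's annotation runs
study_alphabet <- c("Thr", "Ser", "Val", "Leu/Ile", "azHA")

# neutral masses used across quantification tests (PVD-Ser / PVD-Thr)
M_SER <- 1319.57
M_THR <- 1333.59

# the study's titration design (see methods vignette)
titration_ratios <- c(0.05, 0.1, 0.25, 0.5, 1)
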