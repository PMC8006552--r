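# Independent brute-force transcriptions of the hydraulic formulas.
# These share no code with the package: lengths enter in um and are
# converted inline, and each expression is written from the closed form
# directly, so they serve as equivalence oracles for the implementation.

o_lumen_resistance <- function(L_um, T_um, mu = 1.002e-9, beta = 0.5, l = 2.2) {
  L <- L_um / 1000
  T_ <- T_um / 1000
  (8 * mu * beta * l) * (L + T_)^4 / (pi * (L * T_)^4)
}

o_pore_count <- function(Dmc_um, Dpo_um, tf_um) {
  (Dmc_um / (0.63 * Dpo_um + tf_um))^2
}

o_pit_resistance <- function(Npo, Dpe_um, Da_um, ta_um, mu = 1.002e-9) {
  Dpe <- Dpe_um / 1000
  Da <- Da_um / 1000
  ta <- ta_um / 1000
  margo <- 24 * mu / (Npo * Dpe^3)
  canal <- 128 * ta * mu / (pi * Da^4)
  aperture <- 24 * mu / Da^3
  margo + 2 * canal + 2 * aperture
}

# alpha [m^-2] times wall area L*l [m^2]
o_pit_count <- function(L_um, alpha_m2 = 6.5e8, l_mm = 2.2) {
  alpha_m2 * (L_um * 1e-6) * (l_mm * 1e-3)
}

# Reference per-cell table bundled with the package (published outputs
# for the two Larix rings); resistance columns in 1e-3 MPa s mm^-3.
read_reference <- function() {
  path <- system.file("extdata", "larix_t10_reference.csv",
                      package = "ringhydro")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Per-cell hydraulics for both bundled rings under the larix profile,
# computed once per test run.
larix_cells <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- hydraulic_profile("larix")
      cache <<- lapply(larix_rings(), tracheid_hydraulics, params = p)
    }
    cache
  }
})
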