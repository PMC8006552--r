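#' Number of pores in the margo
#'
#' The margo is idealised as an annulus of area equal to a circle of
#' diameter `Dmc`, packed with equally sized pores of diameter `Dpo`
#' separated by strands of thickness `t_f`. Each pore plus its share of
#' strand occupies a square of side `0.63 * Dpo + t_f`, giving
#' `Npo = Dmc^2 / (0.63 * Dpo + t_f)^2`. The count is real-valued; no
#' rounding is applied.
#'
#' @param Dmc Diameter of the circle whose area equals membrane minus
#'   torus, um.
#' @param Dpo Margo pore diameter, um.
#' @param t_f Margo strand thickness, um (>= 0).
#' @return Real-valued pore count (> 0). Vectorised.
#' @export
#' @examples
#' margo_pore_count(6.062, 0.2121, 0.140)  # ~491 pores
margo_pore_count <- function(Dmc, Dpo, t_f) {
  stopifnot(all(Dmc > 0), all(Dpo > 0), all(t_f >= 0))
  Dmc^2 / (0.63 * Dpo + t_f)^2
}

#' Resistance of a single bordered pit
#'
#' Water crossing from one tracheid to its neighbour passes, in series,
#' through an aperture, a canal through the wall, the porous margo of the
#' membrane, and the second canal and aperture. The pit resistance is the
#' series sum
#' `R_pit = R_margo + 2 R_canal + 2 R_aperture`, with
#' \itemize{
#'   \item margo: `24 mu / (Npo * Dpe^3 * f(eps))` — `Npo` parallel
#'     orifice-like pores of equivalent diameter `Dpe`, with `f(eps)`
#'     correcting for interaction between streams through neighbouring
#'     pores (default: no interaction, f = 1);
#'   \item canal (each): Hagen-Poiseuille tube of diameter `Da` and
#'     length `t_a`, `128 t_a mu / (pi Da^4)`;
#'   \item aperture (each): sharp-edged orifice of diameter `Da`,
#'     `24 mu / Da^3`.
#' }
#' All lengths are converted from um to mm internally, so resistances are
#' in MPa s mm^-3.
#'
#' @param geom A `pit_geometry` data frame from [derive_pit_geometry()].
#' @param params A [model_params()] object.
#' @return A data frame of class `pit_resistance` with columns `R_margo`,
#'   `R_canals` (the 2x canal term), `R_apertures` (the 2x aperture term),
#'   and their sum `R_pit`, all MPa s mm^-3, one row per pit.
#' @export
#' @examples
#' p <- model_params(maxDm = 22)
#' g <- derive_pit_geometry(10, 8.857, p)
#' pit_resistance(g, p)  # canal-dominated latewood-sized pit, ~91 MPa s mm^-3
pit_resistance <- function(geom, params) {
  stopifnot(inherits(params, "model_params"))
  req <- c("Da", "Dpe", "Npo", "t_a")
  if (!all(req %in% names(geom))) {
    stop("pit_resistance: geom lacks column(s) ",
         paste(setdiff(req, names(geom)), collapse = ", "), call. = FALSE)
  }
  if (any(geom$Da <= 0) || any(geom$Npo <= 0)) {
    stop("pit_resistance: degenerate pit geometry (Da or Npo not positive)",
         call. = FALSE)
  }
  mu <- params$mu
  f_eps <- params$margo_interaction(params$epsilon)
  Da <- um_to_mm(geom$Da)
  Dpe <- um_to_mm(geom$Dpe)
  t_a <- um_to_mm(geom$t_a)

  R_margo <- 24 * mu / (geom$Npo * Dpe^3 * f_eps)
  R_canals <- 2 * 128 * t_a * mu / (pi * Da^4)
  R_apertures <- 2 * 24 * mu / Da^3

  out <- data.frame(R_margo = R_margo, R_canals = R_canals,
                    R_apertures = R_apertures,
                    R_pit = R_margo + R_canals + R_apertures)
  class(out) <- c("pit_resistance", "data.frame")
  out
}
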