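#' Derive bordered-pit geometry from tracheid dimensions
#'
#' Applies the Pinaceae isometric scaling relationships to infer every pit
#' dimension from the radial lumen diameter alone, so that no pit
#' measurements are needed. The membrane diameter grows proportionally
#' with the lumen (`Dm = c_Dm * L`) until it hits the anatomical cap
#' `maxDm` — wide tracheids accommodate larger but not unboundedly large
#' pits — and every other dimension scales off the membrane:
#' torus `Dt = c_Dt * Dm`, aperture `Da = c_Da * Dm`, margo pore
#' `Dpo = c_Dpo * Dm`. The margo annulus (membrane minus torus) is
#' summarised by the diameter `Dmc` of the circle of equal area,
#' `Dmc = sqrt(Dm^2 - Dt^2)`, which with the pore diameter and the margo
#' strand thickness determines the pore count `Npo` (see
#' [margo_pore_count()]). The pit canal length `t_a` equals the wall
#' thickness of the owning tracheid.
#'
#' @param L Radial lumen diameter(s), um. Vectorised.
#' @param WT Radial wall thickness(es), um; recycled against `L`.
#' @param params A [model_params()] object.
#' @param pos Optional 1-based cell positions used in error messages.
#'
#' @return A data frame of class `pit_geometry` with one row per cell and
#'   columns `Dm`, `Dt`, `Da`, `Dpo`, `Dpe`, `Dmc` (all um), `t_a` (um),
#'   `Npo` (real-valued pore count), and `capped` (logical: membrane hit
#'   `maxDm`).
#' @export
#' @examples
#' p <- model_params(maxDm = 25)
#' derive_pit_geometry(c(36.09, 20.76), c(3.58, 3.85), p)
derive_pit_geometry <- function(L, WT, params, pos = seq_along(L)) {
  stopifnot(inherits(params, "model_params"))
  n <- max(length(L), length(WT))
  L <- rep_len(L, n)
  WT <- rep_len(WT, n)
  pos <- rep_len(pos, n)
  bad_L <- !is.finite(L) | L <= 0
  if (any(bad_L)) {
    stop("derive_pit_geometry: non-positive lumen diameter L at cell position(s) ",
         paste(pos[bad_L], collapse = ", "), call. = FALSE)
  }
  bad_WT <- !is.finite(WT) | WT <= 0
  if (any(bad_WT)) {
    stop("derive_pit_geometry: non-positive wall thickness WT at cell position(s) ",
         paste(pos[bad_WT], collapse = ", "), call. = FALSE)
  }

  Dm <- pmin(params$c_Dm * L, params$maxDm)
  capped <- params$c_Dm * L >= params$maxDm
  Dt <- params$c_Dt * Dm
  Da <- params$c_Da * Dm
  Dpo <- params$c_Dpo * Dm
  Dmc <- sqrt(Dm^2 - Dt^2)

  geom <- data.frame(Dm = Dm, Dt = Dt, Da = Da, Dpo = Dpo,
                     Dpe = Dpo, Dmc = Dmc, t_a = WT,
                     Npo = NA_real_, capped = capped)
  if (!is.null(params$dpe_map)) geom$Dpe <- params$dpe_map(geom)
  geom$Npo <- margo_pore_count(Dmc, Dpo, params$t_f)
  class(geom) <- c("pit_geometry", "data.frame")
  geom
}
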