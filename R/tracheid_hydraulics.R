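#' Hydraulic diameter of a rectangular lumen
#'
#' Equivalent circular diameter for laminar flow through the rectangular
#' tracheid cross-section: `Dh = 2 L T / (L + T)`. For a square lumen
#' (L = T) this reduces to the side length; for a slit (L >> T) it tends
#' to 2T.
#'
#' @param L Radial lumen diameter, um.
#' @param T_ Tangential lumen diameter, um.
#' @return Hydraulic diameter, um. Vectorised.
#' @export
hydraulic_diameter <- function(L, T_) {
  stopifnot(all(L > 0), all(T_ > 0))
  2 * L * T_ / (L + T_)
}

#' Lumen resistance of a tracheid
#'
#' Hagen-Poiseuille resistance of the rectangular lumen over the
#' effective path length `beta * l` (water travels only a fraction `beta`
#' of the tracheid before crossing a pit into the next cell):
#' `Rlum = 8 mu beta l (L + T)^4 / (pi L^4 T^4)`.
#' Algebraically identical to circular Hagen-Poiseuille
#' `128 mu beta l / (pi Dh^4)` with the hydraulic diameter of
#' [hydraulic_diameter()].
#'
#' @param L,T_ Radial and tangential lumen diameters, um.
#' @param params A [model_params()] object (uses `mu`, `beta`, `l`).
#' @return Resistance in MPa s mm^-3. Vectorised.
#' @export
#' @examples
#' p <- model_params()
#' lumen_resistance(36.09, 22.84, p)  # ~0.073 MPa s mm^-3
lumen_resistance <- function(L, T_, params) {
  stopifnot(inherits(params, "model_params"), all(L > 0), all(T_ > 0))
  Lmm <- um_to_mm(L)
  Tmm <- um_to_mm(T_)
  8 * params$mu * params$beta * params$l * (Lmm + Tmm)^4 /
    (pi * Lmm^4 * Tmm^4)
}

#' Number of pits per tracheid
#'
#' Product of the radial wall area (`l * L`, counting both radial walls
#' via the density calibration) and the pit density `alpha`. The count is
#' real-valued and used unrounded in all resistance formulas; rounding to
#' integer is presentation-only (the report writer applies it).
#'
#' @param L Radial lumen diameter, um.
#' @param params A [model_params()] object (uses `alpha` m^-2, `l` mm).
#' @return Real-valued pit count. Vectorised.
#' @export
#' @examples
#' pit_count(36.09, model_params())  # 51.6, reported as 52
pit_count <- function(L, params) {
  stopifnot(inherits(params, "model_params"), all(L > 0))
  alpha_mm2 <- params$alpha * 1e-6  # m^-2 -> mm^-2
  alpha_mm2 * um_to_mm(L) * params$l
}

#' Earlywood/latewood classification by Mork's rule
#'
#' A cell is earlywood iff its lumen exceeds twice its wall thickness
#' (`L > 2 WT`, strict); the tie and thicker-walled cells are latewood.
#'
#' @param L Radial lumen diameter, um.
#' @param WT Radial wall thickness, um.
#' @return Character vector, `"EW"` or `"LW"`.
#' @export
mork_class <- function(L, WT) ifelse(L > 2 * WT, "EW", "LW")

#' Per-tracheid hydraulics for a tracheidogram
#'
#' The workhorse of the model: for each cell of an ordered tracheidogram
#' it derives the tangential lumen diameter (`T = TD - 2 WT`), hydraulic
#' diameter, Mork class, cell-wall area, pit geometry by isometric
#' scaling, the single-pit resistance, the pit count, and assembles
#' \itemize{
#'   \item `Rlum` — lumen resistance ([lumen_resistance()]);
#'   \item `Rwall` — all `Npit` pits act in parallel, split evenly over
#'     the two radial walls, so `Rwall = 2 R_pit / Npit`;
#'   \item `R = Rlum + Rwall` and `K = 1/R`.
#' }
#'
#' @param trg A tracheidogram: data frame with columns `pos`, `L` (um),
#'   `WT` (um) — e.g. from [read_tracheidograms()] or
#'   [generate_tracheidogram()] — or a bare data frame with those columns.
#' @param params A [model_params()] object.
#' @return A data frame of class `tracheid_hydraulics`, one row per cell:
#'   `pos`, `wood_class`, `L`, `WT`, `T`, `Dh`, `CWA` (um^2), `Npit`
#'   (unrounded), the pit geometry columns of [derive_pit_geometry()],
#'   the pit resistance components of [pit_resistance()], and `Rwall`,
#'   `Rlum`, `R` (MPa s mm^-3), `K` (MPa^-1 s^-1 mm^3). The ring label,
#'   if present on the input, is carried in attribute `ring_id`.
#' @export
#' @examples
#' trg <- data.frame(pos = 1:2, L = c(36.09, 29.68), WT = c(3.58, 3.86))
#' h <- tracheid_hydraulics(trg, hydraulic_profile("larix"))
#' h[, c("pos", "wood_class", "Npit", "Rwall", "Rlum", "R", "K")]
tracheid_hydraulics <- function(trg, params) {
  stopifnot(inherits(params, "model_params"))
  req <- c("pos", "L", "WT")
  if (!all(req %in% names(trg))) {
    stop("tracheid_hydraulics: input lacks column(s) ",
         paste(setdiff(req, names(trg)), collapse = ", "), call. = FALSE)
  }
  if (nrow(trg) == 0L) {
    stop("tracheid_hydraulics: empty tracheidogram", call. = FALSE)
  }
  L <- trg$L
  WT <- trg$WT
  pos <- trg$pos

  T_ <- params$TD - 2 * WT
  bad_T <- T_ <= 0
  if (any(bad_T)) {
    stop("tracheid_hydraulics: wall thickness WT >= TD/2 leaves no tangential ",
         "lumen at cell position(s) ", paste(pos[bad_T], collapse = ", "),
         call. = FALSE)
  }

  geom <- derive_pit_geometry(L, WT, params, pos = pos)
  pit <- pit_resistance(geom, params)

  Npit <- pit_count(L, params)
  Rlum <- lumen_resistance(L, T_, params)
  Rwall <- 2 * pit$R_pit / Npit
  R <- Rlum + Rwall

  out <- data.frame(
    pos = pos,
    wood_class = mork_class(L, WT),
    L = L, WT = WT, T = T_,
    Dh = hydraulic_diameter(L, T_),
    CWA = (L + 2 * WT) * (T_ + 2 * WT) - L * T_,
    Npit = Npit
  )
  out <- cbind(out, as.data.frame(geom), as.data.frame(pit))
  out$Rwall <- Rwall
  out$Rlum <- Rlum
  out$R <- R
  out$K <- 1 / R
  attr(out, "ring_id") <- attr(trg, "ring_id", exact = TRUE)
  class(out) <- c("tracheid_hydraulics", "data.frame")
  out
}
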