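#' Integrate per-cell hydraulics to the tree-ring level
#'
#' Tracheids of a radial file exchange water mainly with their tangential
#' neighbours, so the representative radial file is modelled as a set of
#' isolated parallel resistances: ring conductance is the plain sum of
#' per-cell conductances, `Kring = sum(K_i)`, and `Rring = 1/Kring`.
#' Alongside the totals, the cumulative conductance profile in
#' tracheidogram order (pith to bark), the earlywood/latewood conductance
#' shares, the pit contribution (see [pit_contribution()]), and a
#' ring-width proxy `sum(L + 2 WT)` are reported.
#'
#' @param cells A `tracheid_hydraulics` data frame from
#'   [tracheid_hydraulics()], in tracheidogram order.
#' @param ring_id Optional ring label (tree, year); defaults to the label
#'   carried on `cells`.
#' @return An object of class `ring_hydraulics`: a list with `ring_id`,
#'   `n_cells`, `Kring` (MPa^-1 s^-1 mm^3), `Kring_m3` (MPa^-1 s^-1 m^3),
#'   `Rring`, `Ronlylum` (MPa s mm^-3), `Pitcontr` (fraction in [0, 1)),
#'   `cum_K` (per-cell cumulative conductance proportion, ends at 1),
#'   `ew_share`, `lw_share` (conductance fractions by Mork class),
#'   `ring_width` (um), and the `cells` table.
#' @export
#' @examples
#' trg <- data.frame(pos = 1:3, L = c(36, 20, 6), WT = c(3.6, 4, 6))
#' ring <- integrate_ring(tracheid_hydraulics(trg, hydraulic_profile("larix")))
#' ring$Kring
integrate_ring <- function(cells, ring_id = attr(cells, "ring_id")) {
  if (!inherits(cells, "tracheid_hydraulics")) {
    stop("integrate_ring: cells must come from tracheid_hydraulics()",
         call. = FALSE)
  }
  if (nrow(cells) == 0L) {
    stop("integrate_ring: empty tracheidogram", call. = FALSE)
  }
  Kring <- sum(cells$K)
  Rring <- 1 / Kring
  Ronlylum <- 1 / sum(1 / cells$Rlum)
  shares <- wood_class_shares(cells)

  structure(
    list(
      ring_id = if (is.null(ring_id)) NA_character_ else ring_id,
      n_cells = nrow(cells),
      Kring = Kring,
      Kring_m3 = conductance_to_m3(Kring),
      Rring = Rring,
      Ronlylum = Ronlylum,
      Pitcontr = 1 - Ronlylum / Rring,
      cum_K = cumsum(cells$K) / Kring,
      ew_share = shares[["EW"]],
      lw_share = shares[["LW"]],
      ring_width = sum(cells$L + 2 * cells$WT),
      cells = cells
    ),
    class = "ring_hydraulics"
  )
}

#' @export
print.ring_hydraulics <- function(x, ...) {
  cat(sprintf("<ring_hydraulics> %s: %d cells\n", x$ring_id, x$n_cells))
  cat(sprintf("  Kring    = %.4g MPa^-1 s^-1 mm^3  (= %.4g MPa^-1 s^-1 m^3)\n",
              x$Kring, x$Kring_m3))
  cat(sprintf("  Rring    = %.4g MPa s mm^-3\n", x$Rring))
  cat(sprintf("  Pitcontr = %.1f%%   latewood share = %.2f%%\n",
              100 * x$Pitcontr, 100 * x$lw_share))
  invisible(x)
}

#' Pit contribution to total ring resistance
#'
#' Fraction of ring resistance attributable to bordered pits: the ring is
#' recomputed as if each tracheid consisted of its lumen only
#' (`Ronlylum = 1 / sum(1/Rlum_i)`), and the contribution is
#' `1 - Ronlylum / Rring`. Removing the pits can only lower resistance,
#' so the fraction lies in [0, 1).
#'
#' @param cells A `tracheid_hydraulics` data frame.
#' @return Fraction in [0, 1).
#' @export
pit_contribution <- function(cells) {
  stopifnot(inherits(cells, "tracheid_hydraulics"), nrow(cells) > 0L)
  Rring <- 1 / sum(1 / (cells$Rlum + cells$Rwall))
  Ronlylum <- 1 / sum(1 / cells$Rlum)
  1 - Ronlylum / Rring
}

#' Earlywood/latewood conductance shares
#'
#' Fraction of ring conductance carried by each Mork class; the two
#' shares sum to 1 (a class absent from the ring has share 0).
#'
#' @param cells A `tracheid_hydraulics` data frame.
#' @return Named numeric vector `c(EW = ..., LW = ...)`.
#' @export
wood_class_shares <- function(cells) {
  stopifnot(inherits(cells, "tracheid_hydraulics"), nrow(cells) > 0L)
  Ktot <- sum(cells$K)
  c(EW = sum(cells$K[cells$wood_class == "EW"]) / Ktot,
    LW = sum(cells$K[cells$wood_class == "LW"]) / Ktot)
}

#' Lumen diameter where wall and lumen resistance balance
#'
#' Under a wall-thickness law `WT(L)`, narrow latewood-sized cells are
#' pit-dominated (`Rwall > Rlum`) and wide earlywood cells are
#' lumen-dominated. This scans L on a fine grid, locates the sign change
#' of `Rwall - Rlum`, and linearly interpolates the crossover diameter.
#'
#' @param params A [model_params()] object.
#' @param wt_law Function `L -> WT` (um -> um); defaults to the law
#'   attached to the profile, else [wt_law_linear()].
#' @param L_range Scan range in um (default 4 to 40).
#' @param step Grid step, um (default 0.1; must be <= 0.1 for the
#'   documented accuracy).
#' @return Crossover lumen diameter, um.
#' @export
#' @examples
#' crossover_diameter(hydraulic_profile("pinaceae"))  # ~18 um
crossover_diameter <- function(params, wt_law = NULL,
                               L_range = c(4, 40), step = 0.1) {
  stopifnot(inherits(params, "model_params"),
            length(L_range) == 2L, L_range[1] < L_range[2], step > 0)
  if (is.null(wt_law)) {
    wt_law <- attr(params, "wt_law", exact = TRUE)
    if (is.null(wt_law)) wt_law <- wt_law_linear()
  }
  L <- seq(L_range[1], L_range[2], by = step)
  trg <- data.frame(pos = seq_along(L), L = L, WT = wt_law(L))
  h <- tracheid_hydraulics(trg, params)
  d <- h$Rwall - h$Rlum
  s <- which(diff(sign(d)) != 0)
  if (length(s) == 0L) {
    stop("crossover_diameter: Rwall - Rlum does not change sign in [",
         L_range[1], ", ", L_range[2], "] um; widen L_range", call. = FALSE)
  }
  i <- s[1]
  # linear interpolation between bracketing grid points
  L[i] + step * d[i] / (d[i] - d[i + 1])
}

#' Ring-level summary table
#'
#' One row per ring: identity, cell count, conductance in both unit
#' bases, resistance, pit contribution, latewood share, and ring-width
#' proxy. This is the table [write_ring_report()] serialises.
#'
#' @param rings A `ring_hydraulics` object or list of them.
#' @return A data frame with one row per ring.
#' @export
ring_table <- function(rings) {
  if (inherits(rings, "ring_hydraulics")) rings <- list(rings)
  do.call(rbind, lapply(rings, function(r) {
    data.frame(
      ring_id = r$ring_id,
      n_cells = r$n_cells,
      Kring_mm3 = r$Kring,
      Kring_m3 = r$Kring_m3,
      Rring_mm3 = r$Rring,
      Pitcontr = r$Pitcontr,
      lw_share = r$lw_share,
      ring_width_um = r$ring_width,
      stringsAsFactors = FALSE
    )
  }))
}
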