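#' Specification for a synthetic tracheidogram
#'
#' Describes the idealised within-ring anatomy the generator emulates: an
#' earlywood plateau of wide thin-walled cells followed by a monotone
#' decline to narrow thick-walled latewood, with multiplicative lognormal
#' noise on the lumen profile. Wall thickness follows `wt_law` applied to
#' the noiseless lumen profile, so the earlywood/latewood classification
#' stays stable at low noise.
#'
#' @param n_cells Number of cells in the radial file (>= 2).
#' @param L_max Earlywood plateau lumen diameter, um.
#' @param L_min Final latewood lumen diameter, um (`L_min < L_max`).
#' @param plateau_fraction Fraction of positions on the plateau, in
#'   [0, 1).
#' @param ramp Decline shape from plateau to `L_min`: `"cosine"`
#'   (default; smooth half-cosine) or `"linear"`.
#' @param wt_law Function mapping L (um) to WT (um); default
#'   [wt_law_linear()].
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise on L (>= 0; 0 disables noise).
#' @param seed Integer seed; required once `noise_cv > 0`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 30, L_max = 40, L_min = 4,
                           plateau_fraction = 0.35,
                           ramp = c("cosine", "linear"),
                           wt_law = wt_law_linear(),
                           noise_cv = 0.05, seed = NULL) {
  ramp <- match.arg(ramp)
  stopifnot(n_cells >= 2, L_min > 0, L_min < L_max,
            plateau_fraction >= 0, plateau_fraction < 1,
            is.function(wt_law), noise_cv >= 0)
  if (noise_cv > 0 && is.null(seed)) {
    stop("synthetic_spec: a seed is required when noise_cv > 0",
         call. = FALSE)
  }
  structure(
    list(n_cells = as.integer(n_cells), L_max = L_max, L_min = L_min,
         plateau_fraction = plateau_fraction, ramp = ramp,
         wt_law = wt_law, noise_cv = noise_cv, seed = seed),
    class = "synthetic_spec"
  )
}

# noiseless lumen profile: plateau then monotone decline to L_min
.profile_L <- function(spec) {
  n <- spec$n_cells
  n_plateau <- floor(spec$plateau_fraction * n)
  n_ramp <- n - n_plateau
  frac <- seq_len(n_ramp) / n_ramp  # 0 -> 1 over the decline
  ramp <- switch(spec$ramp,
    cosine = spec$L_min + (spec$L_max - spec$L_min) * (1 + cos(pi * frac)) / 2,
    linear = spec$L_max + (spec$L_min - spec$L_max) * frac
  )
  c(rep(spec$L_max, n_plateau), ramp)
}

#' Generate a synthetic tracheidogram
#'
#' Builds the noiseless lumen profile of the spec, multiplies it by
#' lognormal noise with unit mean and coefficient of variation
#' `noise_cv`, clips to `[L_min, L_max]`, and derives wall thickness from
#' the noiseless profile via `wt_law`. Deterministic given the seed: the
#' generator draws exactly `n_cells` normal deviates from a freshly
#' seeded Mersenne-Twister stream, so identical specs yield identical
#' rings on any platform.
#'
#' @param spec A [synthetic_spec()].
#' @param ring_id Label for the generated ring.
#' @return A `tracheidogram` data frame (`pos`, `L`, `WT`) as accepted by
#'   [tracheid_hydraulics()].
#' @export
#' @examples
#' trg <- generate_tracheidogram(synthetic_spec(noise_cv = 0))
#' plot(trg$pos, trg$L, type = "b")
generate_tracheidogram <- function(spec, ring_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  L0 <- .profile_L(spec)
  WT <- spec$wt_law(L0)
  if (any(WT <= 0)) {
    stop("generate_tracheidogram: wt_law produces non-positive WT over the ",
         "lumen range [", spec$L_min, ", ", spec$L_max, "] um", call. = FALSE)
  }
  L <- L0
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    # draw from a private, freshly seeded stream; leave the caller's
    # RNG state untouched
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    z <- stats::rnorm(spec$n_cells)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    L <- L0 * exp(sdlog * z - sdlog^2 / 2)
    L <- pmin(pmax(L, spec$L_min), spec$L_max)
  }
  out <- data.frame(pos = seq_len(spec$n_cells), L = L, WT = WT)
  attr(out, "ring_id") <- ring_id
  class(out) <- c("tracheidogram", "data.frame")
  out
}

#' Sweep ring conductance over a grid of synthetic specs
#'
#' Generates one ring per grid row, runs the full hydraulic pipeline on
#' each, and tabulates ring-level outputs. Used for desk-scale
#' sensitivity experiments, e.g. how conductance scales with cell number
#' (a ring-width proxy) or with the earlywood/latewood balance.
#' Reproducible: ring `j` is generated with child seed `seed + j`, so
#' rings can be regenerated independently and in any order.
#'
#' @param grid A data frame with columns among `n_cells`, `L_max`,
#'   `L_min`, `plateau_fraction`, `noise_cv` (missing columns take the
#'   [synthetic_spec()] defaults); one ring per row.
#' @param params A [model_params()] object.
#' @param seed Master integer seed.
#' @param wt_law Wall-thickness law shared by all rings.
#' @return A data frame with one row per ring: the grid columns plus
#'   `ring_width_um`, `Kring_mm3`, `Kring_m3`, `Pitcontr`, `lw_share`.
#' @export
#' @examples
#' grid <- expand.grid(n_cells = c(15, 30, 60), noise_cv = 0.05)
#' sweep_ring_conductance(grid, hydraulic_profile("larix"), seed = 1)
sweep_ring_conductance <- function(grid, params, seed,
                                   wt_law = wt_law_linear()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            inherits(params, "model_params"))
  if (missing(seed) || is.null(seed)) {
    stop("sweep_ring_conductance: an explicit seed is required",
         call. = FALSE)
  }
  defaults <- formals(synthetic_spec)
  fields <- c("n_cells", "L_max", "L_min", "plateau_fraction", "noise_cv")
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    args <- list(wt_law = wt_law, seed = seed + j)
    for (f in fields) {
      args[[f]] <- if (f %in% names(grid)) grid[[f]][j] else eval(defaults[[f]])
    }
    spec <- do.call(synthetic_spec, args)
    trg <- generate_tracheidogram(spec, ring_id = sprintf("syn-%03d", j))
    ring <- integrate_ring(tracheid_hydraulics(trg, params))
    cbind(
      as.data.frame(args[fields]),
      data.frame(ring_width_um = ring$ring_width,
                 Kring_mm3 = ring$Kring,
                 Kring_m3 = ring$Kring_m3,
                 Pitcontr = ring$Pitcontr,
                 lw_share = ring$lw_share)
    )
  })
  do.call(rbind, rows)
}
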