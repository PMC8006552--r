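#' Run the full pipeline on a tracheidogram file
#'
#' Reads tracheidograms, computes per-cell and ring-level hydraulics, and
#' writes one per-cell report per ring, a per-ring report, and a JSON run
#' manifest into `outdir`. This is the programmatic core of the `ring`
#' subcommand of the bundled command-line script
#' (`system.file("cli", "ringhydro.R", package = "ringhydro")`).
#'
#' @param input Path to a delimited tracheidogram table
#'   (see [read_tracheidograms()]).
#' @param outdir Output directory (created if absent).
#' @param params A [model_params()] object, e.g. from
#'   [hydraulic_profile()].
#' @param delim Delimiter passed to [read_tracheidograms()].
#' @return Invisibly, the list of `ring_hydraulics` objects.
#' @export
#' @examples
#' \donttest{
#' input <- system.file("extdata", "larix_t10_tracheidograms.csv",
#'                      package = "ringhydro")
#' out <- run_ring(input, tempdir(), hydraulic_profile("larix"))
#' ring_table(out)
#' }
run_ring <- function(input, outdir, params = hydraulic_profile("larix"),
                     delim = "auto") {
  trgs <- read_tracheidograms(input, delim = delim)
  if (length(trgs) == 0L) {
    stop("run_ring: input contains no tracheidograms: ", input,
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rings <- lapply(trgs, function(trg) {
    integrate_ring(tracheid_hydraulics(trg, params))
  })
  for (rid in names(rings)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", rid)
    write_cell_report(rings[[rid]]$cells,
                      file.path(outdir, paste0("cells_", safe, ".csv")))
  }
  write_ring_report(rings, file.path(outdir, "rings.csv"))
  write_manifest(file.path(outdir, "manifest.json"), params, inputs = input)
  invisible(rings)
}

#' Resistance curves over a lumen-diameter range
#'
#' Evaluates single-tracheid and single-pit resistances on a grid of
#' lumen diameters under a wall-thickness law: the data behind
#' resistance-versus-size curves. Per row: L, WT, the pit components
#' (`R_margo`, `R_canals`, `R_apertures`, `R_pit`), `Rlum`, `Rwall`, `R`,
#' `K`, the wall and lumen shares of total resistance, and the Mork
#' class.
#'
#' @param params A [model_params()] object; defaults to the
#'   `"pinaceae"` curve profile.
#' @param L Grid of lumen diameters, um.
#' @param wt_law Wall-thickness law; defaults to the one attached to the
#'   profile, else [wt_law_linear()].
#' @param path Optional CSV output path.
#' @return The curve data frame (invisibly if `path` is given).
#' @export
#' @examples
#' cv <- run_curves(L = c(10, 20))
#' cv[, c("L", "R", "wall_share")]
run_curves <- function(params = hydraulic_profile("pinaceae"),
                       L = seq(4, 40, by = 0.5), wt_law = NULL,
                       path = NULL) {
  stopifnot(length(L) >= 1L, all(L > 0))
  if (is.null(wt_law)) {
    wt_law <- attr(params, "wt_law", exact = TRUE)
    if (is.null(wt_law)) wt_law <- wt_law_linear()
  }
  trg <- data.frame(pos = seq_along(L), L = L, WT = wt_law(L))
  h <- tracheid_hydraulics(trg, params)
  out <- data.frame(
    L = h$L, WT = h$WT, wood_class = h$wood_class,
    R_margo = h$R_margo, R_canals = h$R_canals,
    R_apertures = h$R_apertures, R_pit = h$R_pit,
    Npit = h$Npit, Rwall = h$Rwall, Rlum = h$Rlum, R = h$R, K = h$K,
    wall_share = h$Rwall / h$R, lumen_share = h$Rlum / h$R
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Run a synthetic-ring sweep and write its outputs
#'
#' Thin wrapper around [sweep_ring_conductance()] that writes the sweep
#' table and a manifest into `outdir`.
#'
#' @param grid Spec grid (see [sweep_ring_conductance()]).
#' @param outdir Output directory.
#' @param params A [model_params()] object.
#' @param seed Master seed (required).
#' @return Invisibly, the sweep data frame.
#' @export
run_simulate <- function(grid, outdir, params = hydraulic_profile("larix"),
                         seed) {
  if (missing(seed) || is.null(seed)) {
    stop("run_simulate: an explicit seed is required", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sweep <- sweep_ring_conductance(grid, params, seed = seed)
  utils::write.csv(sweep, file.path(outdir, "sweep.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(file.path(outdir, "manifest.json"), params, seed = seed)
  invisible(sweep)
}
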