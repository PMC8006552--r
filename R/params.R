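#' Model constants and tunable parameters
#'
#' Bundles every constant of the hydraulic model: water viscosity, tracheid
#' geometry defaults, pit density, tracheid overlap, the isometric scaling
#' coefficients that map lumen diameter to pit dimensions, and the
#' margo-pore interaction hook. All internal hydraulics use the MPa-s-mm
#' unit system (resistances in MPa s mm^-3, conductances in MPa^-1 s^-1
#' mm^3); lengths are supplied in the units stated per argument.
#'
#' @param mu Dynamic viscosity of water at 20 degrees C, MPa s
#'   (default 1.002e-9, i.e. 1.002e-3 Pa s).
#' @param t_f Mean thickness of margo strands, um (default 0.140).
#' @param l Axial tracheid length, mm (default 2.2).
#' @param TD Tracheid tangential (outer) diameter, um (default 30).
#' @param alpha Pit density per radial-wall area, m^-2 (default 6.5e8).
#' @param beta Tracheid-overlap factor, dimensionless in (0, 1]; 0.5 means
#'   water travels half the tracheid length before crossing a pit.
#' @param maxDm Maximum pit-membrane diameter, um. Pinaceae pits level off
#'   in wide tracheids; the cap is a per-run calibration (22 um for the
#'   single-tracheid benchmark profile, 25 um for the Siberian larch rings).
#' @param c_Dm Membrane/lumen isometric slope (default 0.70).
#' @param c_Dt Torus/membrane ratio (default 0.50).
#' @param c_Da Aperture/membrane ratio (default 0.25).
#' @param c_Dpo Margo-pore/membrane ratio (default 0.03030).
#' @param epsilon Fraction of margo area occupied by pores, in [0, 1).
#'   Only consumed by `margo_interaction`.
#' @param margo_interaction Function of `epsilon` returning the correction
#'   factor for interacting streams through neighbouring margo pores.
#'   Must satisfy f(0) = 1 and be monotone. Default: no interaction
#'   (identically 1).
#' @param dpe_map Optional function `(geom) -> Dpe um` substituting another
#'   equivalent-pore-diameter mapping; `NULL` (default) sets Dpe = Dpo.
#'
#' @return An object of class `model_params` (a validated list).
#' @seealso [hydraulic_profile()] for the two documented calibrations.
#' @export
#' @examples
#' p <- model_params(maxDm = 22)
#' p$alpha
model_params <- function(mu = 1.002e-9,
                         t_f = 0.140,
                         l = 2.2,
                         TD = 30,
                         alpha = 6.5e8,
                         beta = 0.5,
                         maxDm = 25,
                         c_Dm = 0.70,
                         c_Dt = 0.50,
                         c_Da = 0.25,
                         c_Dpo = 0.03030,
                         epsilon = 0,
                         margo_interaction = NULL,
                         dpe_map = NULL) {
  num <- c(mu = mu, t_f = t_f, l = l, TD = TD, alpha = alpha, beta = beta,
           maxDm = maxDm, c_Dm = c_Dm, c_Dt = c_Dt, c_Da = c_Da,
           c_Dpo = c_Dpo, epsilon = epsilon)
  if (any(!is.finite(num))) {
    stop("model_params: non-finite value for ",
         paste(names(num)[!is.finite(num)], collapse = ", "), call. = FALSE)
  }
  lengths <- c(mu = mu, l = l, TD = TD, alpha = alpha, maxDm = maxDm,
               c_Dm = c_Dm, c_Dt = c_Dt, c_Da = c_Da, c_Dpo = c_Dpo)
  if (any(lengths <= 0)) {
    stop("model_params: non-positive value for ",
         paste(names(lengths)[lengths <= 0], collapse = ", "), call. = FALSE)
  }
  if (t_f < 0) stop("model_params: t_f must be >= 0", call. = FALSE)
  if (beta <= 0 || beta > 1) {
    stop("model_params: beta must lie in (0, 1]", call. = FALSE)
  }
  if (epsilon < 0 || epsilon >= 1) {
    stop("model_params: epsilon must lie in [0, 1)", call. = FALSE)
  }
  # aperture narrower than torus narrower than membrane
  if (!(c_Da < c_Dt && c_Dt < 1)) {
    stop("model_params: require c_Da < c_Dt < 1", call. = FALSE)
  }
  if (is.null(margo_interaction)) margo_interaction <- function(epsilon) 1
  stopifnot(is.function(margo_interaction))
  if (!is.null(dpe_map)) stopifnot(is.function(dpe_map))

  structure(
    list(mu = mu, t_f = t_f, l = l, TD = TD, alpha = alpha, beta = beta,
         maxDm = maxDm, c_Dm = c_Dm, c_Dt = c_Dt, c_Da = c_Da,
         c_Dpo = c_Dpo, epsilon = epsilon,
         margo_interaction = margo_interaction, dpe_map = dpe_map),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  mu     = %.4g MPa s     (water viscosity)\n", x$mu))
  cat(sprintf("  l      = %.3g mm        (tracheid length)\n", x$l))
  cat(sprintf("  TD     = %.3g um        (tangential diameter)\n", x$TD))
  cat(sprintf("  alpha  = %.4g m^-2     (pit density)\n", x$alpha))
  cat(sprintf("  beta   = %.3g           (overlap factor)\n", x$beta))
  cat(sprintf("  t_f    = %.3g um        (margo strand thickness)\n", x$t_f))
  cat(sprintf("  maxDm  = %.3g um        (pit membrane cap)\n", x$maxDm))
  cat(sprintf("  isometry: Dm = %.2g L, Dt = %.2g Dm, Da = %.2g Dm, Dpo = %.4g Dm\n",
              x$c_Dm, x$c_Dt, x$c_Da, x$c_Dpo))
  cat(sprintf("  epsilon = %.3g (margo pore fraction), f(eps) = %.4g\n",
              x$epsilon, x$margo_interaction(x$epsilon)))
  invisible(x)
}

#' Named parameter profiles
#'
#' Two documented calibrations of the model:
#' \describe{
#'   \item{`"pinaceae"`}{maxDm = 22 um. The literature-calibrated set used
#'     for single-tracheid and single-pit resistance curves, paired with
#'     the linear wall-thickness law `WT = -8/70 * L + 10` (available as
#'     `attr(, "wt_law")`).}
#'   \item{`"larix"`}{maxDm = 25 um. The calibration for dominant
#'     *Larix sibirica* trees used with the bundled Siberian tracheidogram
#'     fixture; wall thickness comes from measurements, so no law is
#'     attached.}
#' }
#' All other constants are shared defaults (see [model_params()]).
#'
#' @param name `"pinaceae"` or `"larix"`.
#' @param ... Overrides forwarded to [model_params()].
#' @return A `model_params` object; for `"pinaceae"` the wall-thickness
#'   law is attached as attribute `"wt_law"`.
#' @export
#' @examples
#' p <- hydraulic_profile("pinaceae")
#' attr(p, "wt_law")(10)  # WT at L = 10 um
hydraulic_profile <- function(name = c("pinaceae", "larix"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    pinaceae = model_params(maxDm = 22, ...),
    larix    = model_params(maxDm = 25, ...)
  )
  if (name == "pinaceae") attr(p, "wt_law") <- wt_law_linear()
  attr(p, "profile") <- name
  p
}

#' Linear wall-thickness law
#'
#' Returns `WT(L) = slope * L + intercept` (um), the idealised relation
#' used for resistance curves: thin-walled wide earlywood cells grade into
#' thick-walled narrow latewood cells.
#'
#' @param slope um of wall per um of lumen (default -8/70).
#' @param intercept WT at L = 0, um (default 10).
#' @return A vectorised function of L (um).
#' @export
wt_law_linear <- function(slope = -8 / 70, intercept = 10) {
  force(slope); force(intercept)
  function(L) slope * L + intercept
}

#' Serialize parameters to a flat key-value file
#'
#' Writes the numeric fields of a `model_params` object as `key = value`
#' lines (function hooks are not serialized; a non-default
#' `margo_interaction` or `dpe_map` must be re-attached in code).
#'
#' @param params A `model_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  num <- params[vapply(params, is.numeric, logical(1))]
  lines <- sprintf("%s = %.17g", names(num), unlist(num))
  writeLines(lines, path)
  invisible(path)
}

#' Read parameters from a flat key-value file
#'
#' Inverse of [write_params()]. Unknown keys are an error; missing keys
#' fall back to [model_params()] defaults.
#'
#' @param path File of `key = value` lines (`#` comments allowed).
#' @return A `model_params` object.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("read_params: malformed line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  known <- setdiff(names(formals(model_params)),
                   c("margo_interaction", "dpe_map"))
  if (any(!keys %in% known)) {
    stop("read_params: unknown key(s): ",
         paste(setdiff(keys, known), collapse = ", "), call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("read_params: non-numeric value for ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  do.call(model_params, as.list(stats::setNames(vals, keys)))
}

# ---- unit helpers ---------------------------------------------------------
# Internal base: MPa, s, mm. The m^3 basis differs by a factor 1e9
# (1 mm^-3 = 1e9 m^-3), a classic scale trap, so conversions are explicit.

#' Convert resistance from MPa s mm^-3 to MPa s m^-3
#' @param R Resistance in MPa s mm^-3.
#' @return Resistance in MPa s m^-3 (multiplied by 1e9).
#' @export
resistance_to_m3 <- function(R) R * 1e9

#' Convert conductance from MPa^-1 s^-1 mm^3 to MPa^-1 s^-1 m^3
#' @param K Conductance in MPa^-1 s^-1 mm^3.
#' @return Conductance in MPa^-1 s^-1 m^3 (multiplied by 1e-9).
#' @export
conductance_to_m3 <- function(K) K * 1e-9

# um -> mm, used everywhere lengths enter a hydraulic formula
um_to_mm <- function(x) x * 1e-3
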