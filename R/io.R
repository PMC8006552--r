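#' Read tracheidograms from a delimited text file
#'
#' Reads per-ring ordered tables of tracheid measurements as exported by
#' cell-anatomy pipelines. The file must have a header with columns for
#' the ring identity, the cell position, the radial lumen diameter, and
#' the radial wall thickness; recognised header names (case-insensitive)
#' are `ring`/`ring_id`/`tree`, `pos`/`position`/`i`, `l`/`lumen`/`l_um`,
#' and `wt`/`wall`/`wt_um`. L and WT are micrometres throughout — no unit
#' autodetection is attempted, since silent unit errors are the dominant
#' failure mode with anatomical tables.
#'
#' Rows are sorted by position within ring; duplicate or non-consecutive
#' positions, non-numeric or non-positive measurements, and wall
#' thicknesses that leave no tangential lumen (`WT >= TD/2`) are rejected
#' with the offending ring and position named.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter: `"auto"` (default; tries comma, tab,
#'   semicolon on the header) or one of `","`, `"\t"`, `";"`.
#' @param TD Tracheid tangential diameter used for the wall-thickness
#'   sanity check, um.
#' @return A named list of tracheidograms, one per ring in file order:
#'   data frames of class `tracheidogram` with columns `pos`, `L`, `WT`
#'   and attribute `ring_id`. An empty file yields an empty list with a
#'   warning.
#' @export
#' @examples
#' path <- system.file("extdata", "larix_t10_tracheidograms.csv",
#'                     package = "ringhydro")
#' trgs <- read_tracheidograms(path)
#' names(trgs)
read_tracheidograms <- function(path, delim = "auto", TD = 30) {
  if (!file.exists(path)) {
    stop("read_tracheidograms: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("read_tracheidograms: ", path, " is empty; returning no rings")
    return(structure(list(), names = character(0)))
  }
  if (identical(delim, "auto")) {
    counts <- vapply(c(",", "\t", ";"),
                     function(d) lengths(regmatches(lines[1],
                                                    gregexpr(d, lines[1], fixed = TRUE))),
                     integer(1))
    if (all(counts == 0L)) {
      stop("read_tracheidograms: could not detect a delimiter (comma, tab, ",
           "semicolon) in the header of ", path, call. = FALSE)
    }
    delim <- names(which.max(counts))
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, strip.white = TRUE)

  canon <- c(ring = "ring", ring_id = "ring", tree = "ring",
             pos = "pos", position = "pos", i = "pos",
             l = "L", lumen = "L", l_um = "L",
             wt = "WT", wall = "WT", wt_um = "WT")
  hits <- canon[match(tolower(names(df)), names(canon))]
  missing <- setdiff(c("ring", "pos", "L", "WT"), hits)
  if (length(missing) > 0L) {
    stop("read_tracheidograms: ", path, " lacks column(s) for ",
         paste(missing, collapse = ", "),
         " (recognised headers: ring/ring_id/tree, pos/position/i, ",
         "l/lumen/l_um, wt/wall/wt_um)", call. = FALSE)
  }
  df <- df[!is.na(hits)]
  names(df) <- hits[!is.na(hits)]

  for (col in c("pos", "L", "WT")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | !is.finite(v)
    if (any(bad)) {
      stop("read_tracheidograms: non-numeric ", col, " in ", path,
           " at data row(s) ", paste(which(bad), collapse = ", "),
           call. = FALSE)
    }
    df[[col]] <- v
  }

  rings <- unique(df$ring)
  out <- lapply(rings, function(rid) {
    g <- df[df$ring == rid, c("pos", "L", "WT")]
    g <- g[order(g$pos), , drop = FALSE]
    if (anyDuplicated(g$pos)) {
      stop("read_tracheidograms: duplicate position(s) ",
           paste(unique(g$pos[duplicated(g$pos)]), collapse = ", "),
           " in ring ", rid, " of ", path, call. = FALSE)
    }
    if (!identical(as.integer(g$pos), seq_len(nrow(g)))) {
      stop("read_tracheidograms: positions in ring ", rid, " of ", path,
           " are not consecutive from 1", call. = FALSE)
    }
    bad <- g$L <= 0 | g$WT <= 0
    if (any(bad)) {
      stop("read_tracheidograms: non-positive L or WT in ring ", rid,
           " at position(s) ", paste(g$pos[bad], collapse = ", "),
           call. = FALSE)
    }
    wide <- g$WT >= TD / 2
    if (any(wide)) {
      stop("read_tracheidograms: WT >= TD/2 (no tangential lumen) in ring ",
           rid, " at position(s) ", paste(g$pos[wide], collapse = ", "),
           call. = FALSE)
    }
    rownames(g) <- NULL
    attr(g, "ring_id") <- as.character(rid)
    class(g) <- c("tracheidogram", "data.frame")
    g
  })
  stats::setNames(out, as.character(rings))
}

#' Bundled Larix sibirica tracheidograms
#'
#' Two measured tracheidograms from tree T10 of a *Larix sibirica* stand
#' near Shira, southern Siberia: the annual rings of 1994 (21 cells) and
#' 2009 (15 cells). The rings have similar widths (~0.6 mm) but very
#' different cell structure, which makes them the package's worked
#' example for ring-level contrasts. Use with the `"larix"` profile
#' (`maxDm = 25` um).
#'
#' @return A named list of two `tracheidogram` data frames
#'   (`"T10-1994"`, `"T10-2009"`).
#' @export
#' @examples
#' trgs <- larix_rings()
#' vapply(trgs, nrow, integer(1))
larix_rings <- function() {
  path <- system.file("extdata", "larix_t10_tracheidograms.csv",
                      package = "ringhydro", mustWork = TRUE)
  read_tracheidograms(path)
}

# Per-cell report column formats. Resistance columns are written in
# units of 1e-3 MPa s mm^-3 (the reference-table scale) as integers;
# conductance in MPa^-1 s^-1 mm^3 with 2 decimals.
.cell_report_cols <- function(cells, cum_K) {
  data.frame(
    POS = cells$pos,
    EW_LW = cells$wood_class,
    L_um = sprintf("%.2f", cells$L),
    WT_um = sprintf("%.2f", cells$WT),
    CWA_um2 = sprintf("%.2f", cells$CWA),
    N_pit = sprintf("%d", as.integer(round(cells$Npit))),
    D_m_um = sprintf("%.2f", cells$Dm),
    D_a_um = sprintf("%.2f", cells$Da),
    D_t_um = sprintf("%.2f", cells$Dt),
    R_wall = sprintf("%.0f", 1e3 * cells$Rwall),
    R_lum = sprintf("%.0f", 1e3 * cells$Rlum),
    R = sprintf("%.0f", 1e3 * cells$R),
    K = sprintf("%.2f", cells$K),
    cum_K = sprintf("%.4f", cum_K),
    stringsAsFactors = FALSE
  )
}

#' Write a per-cell report
#'
#' Writes one CSV row per tracheid with the reference column layout:
#' position, Mork class, inputs, cell-wall area, rounded pit count, pit
#' diameters (2 decimals), resistances in 1e-3 MPa s mm^-3 (integers),
#' conductance in MPa^-1 s^-1 mm^3 (2 decimals), and the cumulative
#' conductance proportion (4 decimals). A sidecar
#' `<path>.inputs.csv` echoes `ring,pos,L,WT` at full precision so the
#' report round-trips losslessly through [read_tracheidograms()].
#'
#' @param cells A `tracheid_hydraulics` data frame (possibly empty for a
#'   header-only file).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_report <- function(cells, path) {
  stopifnot(inherits(cells, "tracheid_hydraulics"))
  cum_K <- if (nrow(cells) > 0L) cumsum(cells$K) / sum(cells$K) else numeric(0)
  out <- .cell_report_cols(cells, cum_K)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  rid <- attr(cells, "ring_id", exact = TRUE)
  sidecar <- data.frame(
    ring = rep(if (is.null(rid)) NA_character_ else rid, nrow(cells)),
    pos = cells$pos,
    L = sprintf("%.17g", cells$L),
    WT = sprintf("%.17g", cells$WT)
  )
  utils::write.csv(sidecar, paste0(path, ".inputs.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-ring report
#'
#' One CSV row per ring with the [ring_table()] columns.
#'
#' @param rings A `ring_hydraulics` object or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ring_report <- function(rings, path) {
  utils::write.csv(ring_table(rings), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: the numeric model
#' parameters, profile name if any, input file MD5 hashes, seed, and the
#' package version.
#'
#' @param path Output JSON path.
#' @param params A [model_params()] object.
#' @param inputs Character vector of input file paths (hashed).
#' @param seed Integer seed or `NULL`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, inputs = character(0), seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  num <- params[vapply(params, is.numeric, logical(1))]
  manifest <- list(
    package = "ringhydro",
    version = as.character(utils::packageVersion("ringhydro")),
    profile = attr(params, "profile", exact = TRUE),
    params = num,
    inputs = if (length(inputs) > 0L) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else NULL,
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
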