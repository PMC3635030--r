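#' Construct an ROI atlas
#'
#' An atlas is a table of spherical regions of interest: 1-based
#' contiguous indices, unique names, an optional network label, a centre
#' in MNI millimetre coordinates and a sphere radius (default 5 mm, the
#' standard choice for functionally defined ROI sets).
#'
#' @param index 1-based ROI indices, contiguous `1..N`.
#' @param name Unique ROI names.
#' @param x,y,z Sphere centres in MNI mm.
#' @param network Optional network membership labels.
#' @param radius Sphere radius in mm (recycled; default 5).
#' @return Data frame of class `roi_atlas`.
#' @export
roi_atlas <- function(index, name, x, y, z, network = NA_character_,
                      radius = 5) {
  n <- length(index)
  assert_that(n >= 1, "atlas must contain at least one ROI")
  assert_that(all(index == seq_len(n)), "ROI indices must be contiguous 1..N")
  assert_that(!anyDuplicated(name), "ROI names must be unique")
  assert_that(all(is.finite(c(x, y, z))), "ROI centres must be finite")
  radius <- rep_len(radius, n)
  assert_that(all(radius > 0), "sphere radius must be > 0")
  structure(data.frame(index = as.integer(index), name = as.character(name),
                       network = rep_len(as.character(network), n),
                       x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                       radius = as.numeric(radius),
                       stringsAsFactors = FALSE),
            class = c("roi_atlas", "data.frame"))
}

#' Read an ROI atlas from a CSV/TSV table
#'
#' Expects columns `index, name, x, y, z` and optionally `network`,
#' `radius` (missing radius defaults to 5 mm).
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv` -> tab, otherwise comma).
#' @return An [roi_atlas()].
#' @export
read_atlas <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("index", "name", "x", "y", "z")
  assert_that(all(need %in% names(df)),
              "atlas table needs columns: ", paste(need, collapse = ", "))
  roi_atlas(df$index, df$name, df$x, df$y, df$z,
            network = if ("network" %in% names(df)) df$network else NA_character_,
            radius = if ("radius" %in% names(df)) df$radius else 5)
}

#' Write an ROI atlas table
#'
#' @param atlas An [roi_atlas()].
#' @param path Output path (`.tsv` writes tab-delimited).
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(atlas, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic ROI atlas on a regular lattice
#'
#' Places `n_rois` sphere centres on a 3-D lattice with the given
#' spacing, centred at the MNI origin.  This is a synthetic stand-in
#' used for testing extraction and export code paths; it carries no
#' anatomical meaning.
#'
#' @param n_rois Number of ROIs.
#' @param spacing_mm Lattice spacing between sphere centres (default 20 mm,
#'   comfortably larger than twice the default 5 mm radius so spheres
#'   never overlap).
#' @param radius Sphere radius in mm.
#' @return An [roi_atlas()] with names `ROI_001`, ...
#' @export
synthetic_atlas <- function(n_rois, spacing_mm = 20, radius = 5) {
  assert_that(is_count(n_rois), "`n_rois` must be a positive integer")
  side <- ceiling(n_rois^(1 / 3))
  g <- expand.grid(ix = seq_len(side), iy = seq_len(side), iz = seq_len(side))
  g <- g[seq_len(n_rois), , drop = FALSE]
  centre <- (side + 1) / 2
  roi_atlas(index = seq_len(n_rois),
            name = sprintf("ROI_%03d", seq_len(n_rois)),
            x = (g$ix - centre) * spacing_mm,
            y = (g$iy - centre) * spacing_mm,
            z = (g$iz - centre) * spacing_mm,
            network = "synthetic",
            radius = radius)
}
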