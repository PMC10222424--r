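#' Default phantom configuration
#'
#' Geometry of the desk-scale heart-torso phantom, expressed in physical
#' units on a fixed 50 x 50-unit square domain so that the simulated tissue
#' is independent of grid resolution (the grid step is `50 / rows`). The
#' torso fills the domain (its rectangle corners are the "vertices" used for
#' probe placement); two elliptical lungs sit in the upper half; the heart
#' is an ellipse whose upper part is atrial tissue and lower part
#' ventricular tissue, separated by a 1-unit fibrous barrier bridged only by
#' the atrioventricular node; the His bundle, bundle branches and Purkinje
#' fibers descend from the node inside an insulating sheath that opens into
#' the ventricles at the Purkinje layer; each half of the heart encloses a
#' passive blood chamber; and an optional ~1-unit electrode layer wraps the
#' outside of the torso.
#'
#' @param rows,cols Grid dimensions (at least 100 x 100).
#' @param include_electrode_layer Whether to add the outer electrode layer
#'   (the conventional two-point experiment runs without it).
#' @param heart Optional list overriding the heart ellipse, with elements
#'   `center_y`, `center_x`, `radius_y`, `radius_x` as fractions of the
#'   domain (defaults 0.55, 0.50, 0.155, 0.165).
#' @param params A [dynamic_params()] object.
#' @return A configuration list accepted by [build_phantom()].
#' @export
phantom_config <- function(rows = 150, cols = 150,
                           include_electrode_layer = TRUE,
                           heart = NULL, params = dynamic_params()) {
  hdef <- list(center_y = 0.55, center_x = 0.50,
               radius_y = 0.155, radius_x = 0.165)
  if (!is.null(heart)) {
    unknown <- setdiff(names(heart), names(hdef))
    if (length(unknown))
      stop("unknown heart geometry field(s): ", paste(unknown, collapse = ", "))
    hdef[names(heart)] <- heart
  }
  list(rows = as.integer(rows), cols = as.integer(cols),
       domain_units = 50, include_electrode_layer = isTRUE(include_electrode_layer),
       heart = hdef, params = params)
}

#' Build the heart-torso tissue phantom
#'
#' Rasterises the phantom geometry onto a labelled grid and validates its
#' topology: every mandatory region present and non-empty, no direct contact
#' between atria and ventricles (the atrioventricular node is the only
#' bridge across the fibrous barrier), and a contiguous conduction path
#' sinoatrial node to atria to atrioventricular node to His bundle to bundle
#' branches to Purkinje fibers to ventricles.
#'
#' @param config A list from [phantom_config()].
#' @return A `tissue_phantom`: list with `labels` (integer matrix of region
#'   codes), `spacing` (grid step in units), `params`, and the config used.
#' @export
build_phantom <- function(config = phantom_config()) {
  nr <- config$rows; nc <- config$cols
  if (is.null(nr) || is.null(nc) || nr < 100L || nc < 100L)
    stop("phantom grid must be at least 100 x 100 (got ",
         nr %||% "?", " x ", nc %||% "?", ")")
  h <- config$domain_units / nr
  lab <- paint_regions(nr, nc, h, config$heart, config$include_electrode_layer)
  phantom <- phantom_from_labels(lab, spacing = h, params = config$params,
                                 validate = FALSE)
  phantom$config <- config
  validate_phantom(phantom,
                   require_electrode = config$include_electrode_layer)
  phantom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rasterise the phantom geometry; all sizes in physical units
paint_regions <- function(nr, nc, h, heart, electrode) {
  lab <- matrix(region_id("torso"), nr, nc)
  Y <- (row(lab) - 0.5) * h
  X <- (col(lab) - 0.5) * h
  Ur <- nr * h; Uc <- nc * h
  ell <- function(y0, x0, ry, rx) ((Y - y0) / ry)^2 + ((X - x0) / rx)^2 <= 1
  box <- function(y1, y2, x1, x2) Y >= y1 & Y < y2 & X >= x1 & X < x2
  lab[ell(0.32 * Ur, 0.24 * Uc, 0.16 * Ur, 0.11 * Uc)] <- region_id("lung")
  lab[ell(0.32 * Ur, 0.76 * Uc, 0.16 * Ur, 0.11 * Uc)] <- region_id("lung")
  hy0 <- heart$center_y * Ur; hx0 <- heart$center_x * Uc
  hry <- heart$radius_y * Ur; hrx <- heart$radius_x * Uc
  H <- ell(hy0, hx0, hry, hrx)
  bt <- hy0 - 0.2 * hry                    # top of the fibrous barrier band
  lab[H & Y < bt] <- region_id("atria")
  lab[H & Y >= bt + 1] <- region_id("ventricles")
  lab[ell(bt - 0.45 * hry, hx0 + 0.38 * hrx, 0.28 * hry, 0.26 * hrx) &
        lab == region_id("atria")] <- region_id("blood_chamber")
  lab[ell(hy0 + 0.52 * hry, hx0 - 0.18 * hrx, 0.26 * hry, 0.32 * hrx) &
        lab == region_id("ventricles")] <- region_id("blood_chamber")
  lab[H & Y >= bt & Y < bt + 1] <- region_id("fibrous_barrier")
  lab[box(bt - 1, bt + 1, hx0 - 1, hx0 + 1)] <- region_id("atrioventricular_node")
  his <- box(bt + 1, bt + 3, hx0 - 1, hx0 + 1)
  lab[his] <- region_id("his_bundle")
  L <- 0.35 * hrx
  br <- box(bt + 3, bt + 5, hx0 - L, hx0 + L)
  lab[br] <- region_id("bundle_branches")
  # one-cell insulating sheath so the His bundle and branches do not leak
  # into the working myocardium before the Purkinje layer
  tree <- his | br
  dil <- tree
  dil[-1, ] <- dil[-1, ] | tree[-nr, ]; dil[-nr, ] <- dil[-nr, ] | tree[-1, ]
  dil[, -1] <- dil[, -1] | tree[, -nc]; dil[, -nc] <- dil[, -nc] | tree[, -1]
  sheath <- dil & !tree &
    (lab == region_id("ventricles") | lab == region_id("blood_chamber"))
  lab[sheath] <- region_id("fibrous_barrier")
  lab[box(bt + 5, bt + 5 + max(1.2 * h, 0.55), hx0 - L - 1, hx0 + L + 1)] <-
    region_id("purkinje_fibers")
  sa <- ell(bt - 0.62 * hry, hx0 - 0.45 * hrx, 0.22 * hry, 0.20 * hrx)
  lab[sa & lab == region_id("atria")] <- region_id("sinoatrial_node")
  if (electrode) {
    ew <- max(2 * h, 1)
    lab[Y < ew | Y > Ur - ew | X < ew | X > Uc - ew] <- region_id("electrode_layer")
  }
  lab
}

#' Wrap a label matrix as a tissue phantom
#'
#' Low-level constructor used by [build_phantom()] and by tests that need
#' non-anatomical geometries (homogeneous strips, single cells, all-passive
#' sheets). With `validate = TRUE` the anatomical topology checks of
#' [validate_phantom()] are applied.
#'
#' @param labels Integer matrix of region codes (see [region_names()]), or a
#'   character matrix of region names.
#' @param spacing Grid step in physical units.
#' @param params A [dynamic_params()] object.
#' @param validate Whether to run the anatomical validation.
#' @return A `tissue_phantom`.
#' @export
phantom_from_labels <- function(labels, spacing = 0.5,
                                params = dynamic_params(), validate = FALSE) {
  if (is.character(labels)) {
    labels <- matrix(region_id(labels), nrow(labels), ncol(labels))
  }
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > 12L))
    stop("labels must be region codes 1..12")
  phantom <- structure(
    list(labels = labels, spacing = spacing, params = params, config = NULL),
    class = "tissue_phantom")
  if (validate) validate_phantom(phantom)
  phantom
}

# TRUE if any cell of region a is 4-adjacent to a cell of region b
regions_adjacent <- function(labels, a, b) {
  A <- labels == region_id(a)
  B <- labels == region_id(b)
  nr <- nrow(labels); nc <- ncol(labels)
  any(A[-nr, ] & B[-1, ]) || any(A[-1, ] & B[-nr, ]) ||
    any(A[, -nc] & B[, -1]) || any(A[, -1] & B[, -nc])
}

#' Validate phantom topology
#'
#' Checks that all mandatory regions are present, that the fibrous barrier
#' fully insulates atria from ventricles (no direct 4-adjacency), and that
#' the conduction chain is contiguous from the sinoatrial node to the
#' ventricles, with the atrioventricular node bridging the barrier.
#'
#' @param phantom A `tissue_phantom`.
#' @param require_electrode Whether the electrode layer is mandatory.
#' @return The phantom, invisibly; errors describe the first failure.
#' @export
validate_phantom <- function(phantom, require_electrode = FALSE) {
  lab <- phantom$labels
  mandatory <- setdiff(region_names(), "electrode_layer")
  if (require_electrode) mandatory <- region_names()
  counts <- tabulate(lab, nbins = 12L)
  missing <- mandatory[counts[region_id(mandatory)] == 0L]
  if (length(missing))
    stop("phantom is missing region(s): ", paste(missing, collapse = ", "))
  if (regions_adjacent(lab, "atria", "ventricles"))
    stop("atria and ventricles are in direct contact; the fibrous barrier ",
         "must insulate them everywhere except at the atrioventricular node")
  chain <- active_regions()
  for (i in seq_len(length(chain) - 1L)) {
    if (!regions_adjacent(lab, chain[i], chain[i + 1L]))
      stop("disconnected conduction path: ", chain[i], " does not touch ",
           chain[i + 1L])
  }
  invisible(phantom)
}

#' Specify a surface probe
#'
#' A `conventional_pair` probe measures the potential difference between a
#' detection point and a reference point on the torso boundary (the
#' classical differential lead). A `single_position` probe reads the trace
#' at one point on the electrode-layer/torso contact, with no reference.
#'
#' @param kind `"conventional_pair"` or `"single_position"`.
#' @param point_a Detection point, `c(row, col)`.
#' @param point_b Reference point for a conventional pair (ignored
#'   otherwise).
#' @param name Probe name used in the recording.
#' @return A `probe_spec`.
#' @export
probe_spec <- function(kind = c("conventional_pair", "single_position"),
                       point_a, point_b = NULL, name = kind) {
  kind <- match.arg(kind)
  if (kind == "conventional_pair" && is.null(point_b))
    stop("a conventional pair needs both a detection and a reference point")
  structure(list(kind = kind, point_a = as.integer(point_a),
                 point_b = if (!is.null(point_b)) as.integer(point_b),
                 name = name),
            class = "probe_spec")
}

#' Default probes for a phantom
#'
#' The conventional differential lead uses the upper-left torso vertex as
#' the detection point and the lower-left vertex as the reference point.
#' When the phantom has an electrode layer, a single-position probe is
#' placed at the electrode cell touching the torso nearest the upper-left
#' vertex (the contact point of the charge sensor).
#'
#' @param phantom A `tissue_phantom`.
#' @return Named list of `probe_spec`s (`conventional`, and `single` when an
#'   electrode layer is present).
#' @export
default_probes <- function(phantom) {
  lab <- phantom$labels
  nr <- nrow(lab); nc <- ncol(lab)
  has_el <- any(lab == region_id("electrode_layer"))
  # first torso cell on the main diagonal from the upper-left corner
  off <- 1L
  while (off < nr && lab[off, off] != region_id("torso")) off <- off + 1L
  det <- c(off, off)
  ref <- c(nr - off + 1L, off)
  probes <- list(conventional = probe_spec("conventional_pair", det, ref,
                                           name = "conventional"))
  if (has_el) {
    # electrode cell in contact with the detection-side torso cell
    probes$single <- probe_spec("single_position", c(off - 1L, off),
                                name = "single")
  }
  probes
}
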