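#' Flow-field observations
#'
#' Container for the velocity observations that drive the stress inference:
#' one row per measurement point, in the non-dimensional simulation frame
#' (axial coordinate `z` centred on the cell, source pole at `+R_half`;
#' radial coordinate `r` signed, spanning both image half-planes; the
#' forward model mirrors `v_r` for points with \eqn{r < 0}).
#'
#' @param z,r Point coordinates (non-dimensional; `|r| <= F(z)`).
#' @param v_z,v_r Measured velocity components at each point.
#' @param scale Named list recording the physical scales of the data:
#'   `length_um` (the cell short radius in micrometres that maps to 1),
#'   `velocity_um_s` (the velocity in micrometres per second that maps
#'   to 1) and `viscosity_pa_s` (cytoplasmic viscosity in Pascal seconds).
#'   Used only when converting estimated stress back to physical units.
#' @param cell Optional cell label (e.g. `"Ce1"`).
#' @param shape Optional [make_sphere()] / [make_capsule()] boundary; when
#'   given, all points are checked to lie inside it.
#' @return An object of class `observations` with fields `points` (data
#'   frame `z`, `r`, `v_z`, `v_r`), `n`, `scale`, `cell`.
#' @export
observations <- function(z, r, v_z, v_r, scale = list(), cell = NA_character_,
                         shape = NULL) {
  n <- length(z)
  stopifnot(length(r) == n, length(v_z) == n, length(v_r) == n)
  if (!n) stopf("no observation points")
  pts <- data.frame(z = as.numeric(z), r = as.numeric(r),
                    v_z = as.numeric(v_z), v_r = as.numeric(v_r))
  if (anyNA(pts)) stopf("observations contain missing values")
  if (!is.null(shape)) {
    if (any(abs(pts$r) > shape$F(pts$z) + 1e-9)) {
      stopf("observation points outside the boundary (|r| > F(z))")
    }
  }
  default_scale <- list(length_um = NA_real_, velocity_um_s = NA_real_,
                        viscosity_pa_s = NA_real_)
  scale <- modifyList(default_scale, scale)
  structure(list(points = pts, n = n, scale = scale, cell = cell),
            class = "observations")
}

#' @export
print.observations <- function(x, ...) {
  cat(sprintf("Flow observations: %d points%s\n", x$n,
              if (!is.na(x$cell)) paste0(" (cell ", x$cell, ")") else ""))
  print(head(x$points, 4))
  if (x$n > 4) cat("...\n")
  invisible(x)
}

#' Rescale raw axial coordinates to the simulation frame
#'
#' Maps raw axial pixel coordinates onto the non-dimensional distance from
#' the source pole: `scale * (Z_max - Z_PIV) / (Z_max - Z_min)`, where
#' `Z_max`/`Z_min` are the source/drain pole coordinates and the scale
#' factor is the non-dimensional source-drain distance: 55/13 for the
#' C. elegans capsule, 2.0 for the mouse sphere.
#'
#' @param z_piv Raw axial coordinates of the data points.
#' @param z_max,z_min Source and drain pole coordinates (`z_max > z_min`;
#'   all points within).
#' @param species `"celegans"` or `"mouse"`, fixing the scale factor; or
#'   supply `scale_length` directly.
#' @param scale_length Non-dimensional source-drain distance (overrides
#'   `species`).
#' @return Non-dimensional distances from the source pole.
#' @export
rescale_axial <- function(z_piv, z_max, z_min,
                          species = c("celegans", "mouse"),
                          scale_length = NULL) {
  if (z_max <= z_min) stopf("`z_max` must exceed `z_min`")
  if (any(z_piv < z_min - 1e-9 | z_piv > z_max + 1e-9)) {
    stopf("data points outside [z_min, z_max]")
  }
  if (is.null(scale_length)) {
    species <- match.arg(species)
    scale_length <- if (species == "celegans") 55 / 13 else 2.0
  }
  scale_length * (z_max - z_piv) / (z_max - z_min)
}

#' Fit raw radial positions into the simulation boundary
#'
#' Per axial station, the outermost measured points are mapped onto the
#' lower/upper boundary radius `-F(z)` / `+F(z)` and points in between are
#' interpolated linearly, reproducing how scattered image-plane data are
#' fitted into the idealised outline. Stations are formed by binning `z`
#' to the nearest of `n_bins` uniform stations.
#'
#' @param z Non-dimensional centred axial coordinates.
#' @param r_raw Raw radial coordinates (image plane; any units, both
#'   half-planes).
#' @param shape Target boundary.
#' @param n_bins Number of axial stations (default 14).
#' @return List with `r` (fitted non-dimensional signed radius) and
#'   `flagged` (logical: stations with a single point, where the fitted
#'   radius is centred at 0).
#' @export
fit_radial <- function(z, r_raw, shape, n_bins = 14) {
  stopifnot(length(z) == length(r_raw))
  L <- shape$half_length
  stations <- seq(-L, L, length.out = n_bins + 1L)
  bin <- findInterval(z, stations, rightmost.closed = TRUE)
  r_out <- numeric(length(z))
  flagged <- logical(length(z))
  for (b in unique(bin)) {
    i <- which(bin == b)
    zc <- mean(z[i])
    Fb <- shape$F(zc)
    if (length(i) < 2L || diff(range(r_raw[i])) == 0) {
      r_out[i] <- 0
      flagged[i] <- TRUE
    } else {
      lo <- min(r_raw[i]); hi <- max(r_raw[i])
      r_out[i] <- -Fb + (r_raw[i] - lo) / (hi - lo) * 2 * Fb
    }
  }
  list(r = r_out, flagged = flagged)
}

#' Tangential velocity of cortical points
#'
#' Projects the velocity of boundary-adjacent points onto the local unit
#' tangent of the cell outline, signed positive from the source pole
#' towards the drain pole. Points in the lower half-plane (\eqn{r < 0}) are
#' mirrored before projecting.
#'
#' @param z Axial coordinates (centred frame).
#' @param r Signed radial coordinates.
#' @param v_z,v_r Velocity components.
#' @param shape Boundary shape.
#' @return Data frame with columns `z` and `v_t`.
#' @export
project_cortical <- function(z, r, v_z, v_r, shape) {
  d1 <- shape$dF(z)
  d1[!is.finite(d1)] <- 0
  vr_m <- ifelse(r < 0, -v_r, v_r) # mirror lower half-plane
  v_t <- -(v_z + d1 * vr_m) / sqrt(1 + d1^2)
  data.frame(z = z, v_t = v_t)
}

# canonical 4-column sheet layout
.obs_header <- c("D(Sc(z))", "Sc(r)", "v_z", "v_r")

#' Read and write observation tables
#'
#' The on-disk layout is the 4-column sheet format used for deposited flow
#' fields: `D(Sc(z))` (non-dimensional distance from the source pole),
#' `Sc(r)` (non-dimensional signed radius), `v_z` and `v_r` (velocity
#' components), one CSV file per cell. File stems named `Ce1`..`Ce6` /
#' `Mm1`..`Mm7` are recognised as C. elegans / mouse cells and select the
#' default boundary; otherwise pass `shape` explicitly. Rows with missing
#' or non-numeric entries are dropped with a warning. Values round-trip
#' losslessly through [write_observations()].
#'
#' @param path CSV file path.
#' @param shape Boundary used to convert distance-from-source to the
#'   centred frame (and to validate the points). Defaults from the cell
#'   label in the file name when recognised.
#' @param scale Physical scales, as in [observations()].
#' @return An `observations` object.
#' @examples
#' # a synthetic example cell (generated by synth_cells(), not measured)
#' path <- system.file("extdata", "Ce1_synthetic.csv",
#'                     package = "streamstress")
#' obs <- read_observations(path)
#' obs
#' @export
read_observations <- function(path, shape = NULL, scale = list()) {
  cell <- sub("\\..*$", "", basename(path))
  if (is.null(shape)) {
    if (grepl("^Ce", cell)) {
      shape <- make_capsule()
    } else if (grepl("^Mm", cell)) {
      shape <- make_sphere()
    } else {
      stopf("cannot infer the boundary from file name '%s'; pass `shape`", cell)
    }
  }
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(.obs_header, names(df))
  if (length(missing_cols)) {
    stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[, .obs_header]
  num <- as.data.frame(lapply(df, function(x) suppressWarnings(as.numeric(x))))
  bad <- !stats::complete.cases(num)
  if (any(bad)) {
    warning(sprintf("%d malformed row(s) dropped from %s", sum(bad),
                    basename(path)))
    num <- num[!bad, , drop = FALSE]
  }
  names(num) <- c("d", "r", "v_z", "v_r")
  observations(z = axial_from_source(shape, num$d), r = num$r,
               v_z = num$v_z, v_r = num$v_r,
               scale = scale, cell = cell, shape = shape)
}

#' @rdname read_observations
#' @param obs An `observations` object.
#' @param R_half Half source-drain distance used to write the
#'   distance-from-source column (defaults to `shape$half_length` when a
#'   shape is given, else to the largest `|z|`).
#' @export
write_observations <- function(obs, path, shape = NULL, R_half = NULL) {
  stopifnot(inherits(obs, "observations"))
  R_half <- R_half %||% (if (!is.null(shape)) shape$half_length else
    max(abs(obs$points$z)))
  out <- data.frame(R_half - obs$points$z, obs$points$r,
                    obs$points$v_z, obs$points$v_r, check.names = FALSE)
  names(out) <- .obs_header
  utils::write.csv(format(out, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
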