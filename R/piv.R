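#' Image stacks for particle image velocimetry
#'
#' A minimal container for an intensity volume: a 3D array (`x`, `y`, `z`;
#' 2D frames have z-extent 1) with its voxel size in micrometres. The
#' default anisotropic voxel, `(0.26, 0.26, 1.0)` um, matches light-sheet
#' acquisition where the axial sampling is coarse.
#'
#' @param intensities Numeric array (2D matrices are promoted to z-extent
#'   1); non-negative.
#' @param voxel_um Voxel edge lengths in um (length 3, positive).
#' @param time Optional acquisition time stamp (seconds).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, voxel_um = c(0.26, 0.26, 1.0),
                        time = NA_real_) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  }
  stopifnot(length(dim(intensities)) == 3L)
  if (any(intensities < 0)) stopf("intensities must be non-negative")
  if (length(voxel_um) != 3L || any(voxel_um <= 0)) {
    stopf("`voxel_um` must be 3 positive lengths")
  }
  structure(list(intensities = intensities, voxel_um = voxel_um,
                 time = time), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Image stack %d x %d x %d, voxel %.3g x %.3g x %.3g um\n",
              d[1L], d[2L], d[3L], x$voxel_um[1L], x$voxel_um[2L],
              x$voxel_um[3L]))
  invisible(x)
}

#' @rdname image_stack
#' @param path TIFF file (multi-page files are read as z-planes).
#' @export
read_image_stack <- function(path, voxel_um = c(0.26, 0.26, 1.0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L] # drop colour channels
    arr[, , i] <- p
  }
  image_stack(arr, voxel_um = voxel_um)
}

#' @rdname image_stack
#' @param stack An `image_stack` to write.
#' @export
write_image_stack <- function(stack, path) {
  arr <- stack$intensities
  mx <- max(arr)
  if (mx > 0) arr <- arr / mx # TIFF expects [0, 1]
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

.as_array <- function(x) if (inherits(x, "image_stack")) x$intensities else x

# default multi-pass schedule: window sizes and search ranges per pass
.piv_windows <- list(c(33L, 33L, 1L), c(29L, 29L, 1L), c(25L, 25L, 1L))
.piv_ranges <- list(c(5L, 5L, 0L), c(2L, 2L, 1L), c(1L, 1L, 0L))

window_slice <- function(A, center, half, shift = c(0L, 0L, 0L)) {
  lo <- center - half + shift
  hi <- center + half + shift
  d <- dim(A)
  if (any(lo < 1L) || any(hi > d)) return(NULL)
  A[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
}

#' Integer-pixel displacement by multi-pass cross-correlation
#'
#' Finds the integer shift maximising the windowed cross-correlation
#' \eqn{R(\xi,\eta,\lambda) = \sum_A I_1(x) I_2(x+\xi, y+\eta, z+\lambda)},
#' normalised by the energy of the shifted window (without the
#' normalisation the raw product sum is biased towards brighter regions
#' and identical frames need not peak at zero shift), in three passes with shrinking interrogation windows (default 33x33x1,
#' 29x29x1, 25x25x1) and search ranges (±5,±5,0), (±2,±2,±1), (±1,±1,0),
#' each pass refining around the previous optimum. The searched z-range is
#' kept small because the axial voxel is about four times coarser than the
#' lateral ones. Ties are broken towards the smallest `|shift|`, then
#' lexicographically.
#'
#' @param I1,I2 Image stacks (or arrays) at times `t` and `t + dt`.
#' @param center Integer voxel position `c(x, y, z)` of the interrogation
#'   window centre.
#' @param windows,ranges Lists of per-pass window sizes and search ranges
#'   (odd window sizes).
#' @return List with `shift` (integer vector `xi, eta, lambda`) and `flag`
#'   (`"ok"`, `"flat"` for a zero-variance window, `"range"` when the
#'   optimum sits on the cumulative search boundary, `"oob"` when the
#'   window does not fit).
#' @export
integer_displacement <- function(I1, I2, center,
                                 windows = .piv_windows,
                                 ranges = .piv_ranges) {
  A1 <- .as_array(I1); A2 <- .as_array(I2)
  if (!identical(dim(A1), dim(A2))) stopf("stack dimensions differ")
  center <- as.integer(center)
  shift <- c(0L, 0L, 0L)
  flag <- "ok"
  on_edge <- FALSE
  for (p in seq_along(windows)) {
    w <- as.integer(windows[[p]])
    half <- (w - 1L) %/% 2L
    rg <- as.integer(ranges[[p]])
    # z window of extent 1 cannot support z-search beyond the volume
    base <- window_slice(A1, center, half)
    if (is.null(base)) return(list(shift = shift, flag = "oob"))
    if (stats::var(as.vector(base)) == 0) {
      return(list(shift = shift, flag = "flat"))
    }
    cand <- expand.grid(dx = -rg[1L]:rg[1L], dy = -rg[2L]:rg[2L],
                        dz = if (rg[3L] > 0) -rg[3L]:rg[3L] else 0L)
    best <- NULL
    best_R <- -Inf
    for (i in seq_len(nrow(cand))) {
      d <- shift + c(cand$dx[i], cand$dy[i], cand$dz[i])
      win2 <- window_slice(A2, center, half, d)
      if (is.null(win2)) next
      # energy-normalised correlation: the raw product sum is biased
      # towards brighter windows, so identical frames need not peak at
      # zero shift without the normalisation
      e2 <- sum(win2^2)
      if (e2 == 0) next
      R <- sum(base * win2) / sqrt(e2)
      take <- if (is.null(best)) {
        TRUE
      } else if (R > best_R + 1e-12) {
        TRUE
      } else if (abs(R - best_R) <= 1e-12) {
        sum(d^2) < sum(best^2) ||
          (sum(d^2) == sum(best^2) &&
             paste(d, collapse = ",") < paste(best, collapse = ","))
      } else FALSE
      if (take) {
        best <- d
        best_R <- R
      }
    }
    if (is.null(best)) return(list(shift = shift, flag = "oob"))
    shift <- as.integer(best)
  }
  cum <- cumsum_range(ranges, length(ranges))
  if (any(abs(shift) >= cum & cum > 0L)) flag <- "range"
  list(shift = shift, flag = flag)
}

cumsum_range <- function(ranges, upto) {
  Reduce(`+`, lapply(ranges[seq_len(upto)], as.integer))
}

#' Sub-pixel displacement by the gradient (optical-flow) solve
#'
#' After integer alignment, solves the 3x3 least-squares normal equations
#' of the linearised brightness-constancy model,
#' \deqn{\left(\sum_A \nabla I\,\nabla I^{\top}\right) (u, v, w)^{\top} =
#' \sum_A \nabla I\, f_t,} where the gradients are central differences
#' inside the aligned second window and \eqn{f_t = I_1 - I_2} is the
#' two-frame temporal difference (this sign makes positive `u` mean motion
#' towards larger `x`, consistent with the correlation search). Windows
#' with z-extent below 3 drop the `w` component (2D special case), and an
#' ill-conditioned system (condition number above 1e8, e.g. the aperture
#' problem on a 1D ramp) zeroes the unresolved components and flags the
#' vector.
#'
#' @param I1,I2 Image stacks or arrays.
#' @param center Interrogation centre (integer voxels).
#' @param integer_shift Integer shift from [integer_displacement()].
#' @param window Window size used for the gradient sums (default the final
#'   correlation pass, 25x25x1).
#' @return List with `uvw` (numeric length 3) and `flag` (`"ok"`,
#'   `"singular"`, `"oob"`, `"large"` when a component exceeds 1 pixel).
#' @export
subpixel_displacement <- function(I1, I2, center, integer_shift = c(0L, 0L, 0L),
                                  window = c(25L, 25L, 1L)) {
  A1 <- .as_array(I1); A2 <- .as_array(I2)
  center <- as.integer(center)
  half <- (as.integer(window) - 1L) %/% 2L
  # pad by 1 where gradients are taken so central differences stay inside
  gpad <- ifelse(window > 1L, half + 1L, half)
  base <- window_slice(A1, center, gpad)
  moved <- window_slice(A2, center, gpad, as.integer(integer_shift))
  if (is.null(base) || is.null(moved)) {
    return(list(uvw = c(0, 0, 0), flag = "oob"))
  }
  d <- dim(moved)
  use_z <- d[3L] >= 3L
  core <- function(A, which) {
    i <- 2:(d[1L] - 1L); j <- 2:(d[2L] - 1L)
    k <- if (use_z) 2:(d[3L] - 1L) else seq_len(d[3L])
    switch(which,
      c = A[i, j, k, drop = FALSE],
      gx = (A[i + 1L, j, k, drop = FALSE] - A[i - 1L, j, k, drop = FALSE]) / 2,
      gy = (A[i, j + 1L, k, drop = FALSE] - A[i, j - 1L, k, drop = FALSE]) / 2,
      gz = (A[i, j, k + 1L, drop = FALSE] - A[i, j, k - 1L, drop = FALSE]) / 2)
  }
  fx <- core(moved, "gx"); fy <- core(moved, "gy")
  fz <- if (use_z) core(moved, "gz") else NULL
  ft <- core(base, "c") - core(moved, "c")
  grads <- if (use_z) list(fx, fy, fz) else list(fx, fy)
  m <- length(grads)
  Mmat <- matrix(0, m, m)
  b <- numeric(m)
  for (a in seq_len(m)) {
    for (bb in a:m) {
      Mmat[a, bb] <- Mmat[bb, a] <- sum(grads[[a]] * grads[[bb]])
    }
    b[a] <- sum(grads[[a]] * ft)
  }
  flag <- "ok"
  sol <- rep(0, m)
  sv <- svd(Mmat)$d
  cn <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cn) || cn > 1e8) {
    flag <- "singular"
    # solve the well-conditioned subspace, zero the rest
    ev <- eigen(Mmat, symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-8
    if (any(keep)) {
      sol <- ev$vectors[, keep, drop = FALSE] %*%
        ((t(ev$vectors[, keep, drop = FALSE]) %*% b) / ev$values[keep])
      sol <- as.vector(sol)
    }
  } else {
    sol <- solve(Mmat, b)
  }
  uvw <- c(sol, rep(0, 3L - m))
  if (flag == "ok" && any(abs(uvw) > 1)) flag <- "large"
  list(uvw = uvw, flag = flag)
}

#' Velocity field from an image-stack pair
#'
#' Runs the multi-pass integer correlation and sub-pixel gradient solve on
#' a regular grid of interrogation centres, then converts the pixel
#' displacements to um/s with the per-axis voxel size and frame interval:
#' velocity = displacement * voxel / dt, componentwise. Interrogation
#' windows that would leave the volume are skipped; invalid vectors are
#' flagged, never interpolated.
#'
#' @param I1,I2 Image stacks (arrays accepted; voxel size then taken from
#'   `voxel_um`).
#' @param dt Frame interval in seconds (> 0).
#' @param spacing Centre spacing in voxels (default: half the final
#'   correlation window laterally, 1 axially).
#' @param voxel_um Voxel size override.
#' @param windows,ranges Multi-pass schedule, as in
#'   [integer_displacement()].
#' @return An object of class `velocity_field`: a data frame with voxel
#'   positions, pixel displacements (`u_px`, `v_px`, `w_px`), velocities
#'   (`vx_um_s`, `vy_um_s`, `vz_um_s`) and a `flag` column.
#' @export
piv_field <- function(I1, I2, dt, spacing = NULL, voxel_um = NULL,
                      windows = .piv_windows, ranges = .piv_ranges) {
  if (dt <= 0) stopf("`dt` must be positive")
  if (inherits(I1, "image_stack") && is.null(voxel_um)) {
    voxel_um <- I1$voxel_um
  }
  voxel_um <- voxel_um %||% c(0.26, 0.26, 1.0)
  A1 <- .as_array(I1); A2 <- .as_array(I2)
  if (!identical(dim(A1), dim(A2))) stopf("stack dimensions differ")
  d <- dim(A1)
  wfin <- as.integer(windows[[length(windows)]])
  if (is.null(spacing)) {
    spacing <- pmax(c(wfin[1L] %/% 2L, wfin[2L] %/% 2L, 1L), 1L)
  }
  spacing <- rep(as.integer(spacing), length.out = 3L)
  w1 <- as.integer(windows[[1L]])
  half1 <- (w1 - 1L) %/% 2L
  rtot <- cumsum_range(ranges, length(ranges))
  margin <- half1 + rtot
  # single-plane (2D) axes cannot honour an axial search margin; shifts
  # that leave the volume are simply never winners there
  margin[d == 1L] <- 0L
  centers <- expand.grid(
    x = seq_from_margin(d[1L], margin[1L], spacing[1L]),
    y = seq_from_margin(d[2L], margin[2L], spacing[2L]),
    z = seq_from_margin(d[3L], margin[3L], spacing[3L])
  )
  if (!nrow(centers)) stopf("volume too small for the interrogation windows")
  res <- lapply(seq_len(nrow(centers)), function(i) {
    ctr <- as.integer(centers[i, ])
    ip <- integer_displacement(A1, A2, ctr, windows, ranges)
    if (ip$flag %in% c("flat", "oob")) {
      return(data.frame(x = ctr[1L], y = ctr[2L], z = ctr[3L],
                        u_px = NA_real_, v_px = NA_real_, w_px = NA_real_,
                        flag = ip$flag))
    }
    sp <- subpixel_displacement(A1, A2, ctr, ip$shift,
                                window = windows[[length(windows)]])
    disp <- ip$shift + sp$uvw
    flag <- if (ip$flag != "ok") ip$flag else sp$flag
    data.frame(x = ctr[1L], y = ctr[2L], z = ctr[3L],
               u_px = disp[1L], v_px = disp[2L], w_px = disp[3L],
               flag = flag)
  })
  out <- do.call(rbind, res)
  out$vx_um_s <- out$u_px * voxel_um[1L] / dt
  out$vy_um_s <- out$v_px * voxel_um[2L] / dt
  out$vz_um_s <- out$w_px * voxel_um[3L] / dt
  structure(out[, c("x", "y", "z", "u_px", "v_px", "w_px",
                    "vx_um_s", "vy_um_s", "vz_um_s", "flag")],
            class = c("velocity_field", "data.frame"),
            dt = dt, voxel_um = voxel_um)
}

seq_from_margin <- function(n, margin, by) {
  lo <- margin + 1L
  hi <- n - margin
  if (hi < lo) return(integer(0))
  seq(lo, hi, by = by)
}

#' Average velocity fields over time
#'
#' Componentwise mean over a list of fields on identical interrogation
#' grids; invalid vectors are excluded per position (a position with no
#' valid vector stays flagged).
#'
#' @param fields List of [piv_field()] results.
#' @return A single `velocity_field`.
#' @export
average_fields <- function(fields) {
  if (!length(fields)) stopf("empty field list")
  ref <- fields[[1L]]
  for (f in fields[-1L]) {
    if (!identical(f[, c("x", "y", "z")], ref[, c("x", "y", "z")])) {
      stopf("interrogation grids differ")
    }
  }
  cols <- c("u_px", "v_px", "w_px", "vx_um_s", "vy_um_s", "vz_um_s")
  valid <- sapply(fields, function(f) f$flag %in% c("ok", "large"))
  out <- ref
  for (cc in cols) {
    vals <- sapply(fields, function(f) f[[cc]])
    vals[!valid] <- NA
    out[[cc]] <- rowMeans(vals, na.rm = TRUE)
    out[[cc]][rowSums(valid) == 0L] <- NA_real_
  }
  out$flag <- ifelse(rowSums(valid) > 0L, "ok", "invalid")
  out
}
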