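# Projection of voxel electric fields onto Purkinje-cell axes along the
# cortical iso-surface, and mapping of per-cell sensitivity curves to
# spatial response maps.

#' Extract the cortical iso-surface from a voxel grid
#'
#' Marching-tetrahedra triangulation of the scalar field at the given
#' isovalue. Outward unit normals are computed from the (negated) field
#' gradient, sampled by central differences at the nearest voxel; each
#' vertex records its owning voxel. Vertices owned by nuclei-labelled
#' voxels ("white matter") are removed together with their faces, since
#' those locations carry no Purkinje cells.
#'
#' @param grid a `ctdcs_voxel_grid`
#' @param isovalue iso-surface level (default 0.5)
#' @param drop_nuclei drop nuclei-adjacent faces (default TRUE)
#' @return `ctdcs_surface`: list with `vertices` (n x 3, mm), `faces`
#'   (m x 3 indices), `normals` (n x 3 outward unit vectors), `voxel`
#'   (n x 3 owning-voxel indices)
#' @export
extract_surface <- function(grid, isovalue = 0.5, drop_nuclei = TRUE) {
  f <- grid$field
  if (isovalue <= min(f) || isovalue >= max(f))
    stop("isovalue outside the data range: empty surface")
  mesh <- .march_tets(as.double(f), as.integer(grid$dim), isovalue)
  if (nrow(mesh$vertices) == 0) stop("empty surface at this isovalue")
  vox_idx <- pmin(pmax(round(mesh$vertices) + 1, 1),
                  matrix(grid$dim, nrow(mesh$vertices), 3, byrow = TRUE))
  # central-difference gradient at the owning voxel; outward = -gradient
  d <- grid$dim
  grad <- matrix(0, nrow(mesh$vertices), 3)
  ii <- vox_idx[, 1]; jj <- vox_idx[, 2]; kk <- vox_idx[, 3]
  gidx <- function(i, j, k) cbind(i, j, k)
  grad[, 1] <- f[gidx(pmin(ii + 1, d[1]), jj, kk)] - f[gidx(pmax(ii - 1, 1), jj, kk)]
  grad[, 2] <- f[gidx(ii, pmin(jj + 1, d[2]), kk)] - f[gidx(ii, pmax(jj - 1, 1), kk)]
  grad[, 3] <- f[gidx(ii, jj, pmin(kk + 1, d[3]))] - f[gidx(ii, jj, pmax(kk - 1, 1))]
  nrm <- -grad
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  verts_mm <- sweep(mesh$vertices * grid$spacing, 2, -grid$origin, "-")
  keep <- rep(TRUE, nrow(verts_mm))
  if (drop_nuclei && !is.null(grid$labels))
    keep <- grid$labels[vox_idx] != 2L
  faces <- mesh$faces
  fkeep <- keep[faces[, 1]] & keep[faces[, 2]] & keep[faces[, 3]]
  faces <- faces[fkeep, , drop = FALSE]
  newid <- cumsum(keep)
  faces[] <- newid[faces]
  structure(list(vertices = verts_mm[keep, , drop = FALSE],
                 faces = faces,
                 normals = nrm[keep, , drop = FALSE],
                 voxel = vox_idx[keep, , drop = FALSE],
                 spacing = grid$spacing),
            class = "ctdcs_surface")
}

#' @export
print.ctdcs_surface <- function(x, ...) {
  cat(sprintf("Cortical surface: %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), surface_mesh_area(x)))
  invisible(x)
}

#' Total triangulated surface area (mm^2)
#' @param surface a `ctdcs_surface`
#' @export
surface_mesh_area <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Project the voxel field onto the Purkinje-cell axes of a surface
#'
#' The somato-axonal axis at each vertex is the negated outward normal
#' (dendrites grow outward, perpendicular to the folds). `theta` is the
#' angle between the local field vector and that axis; the signed
#' projection follows the cell convention: field toward the axonal
#' terminal is anodal and negative, so `E_proj = -|E| cos(theta)`.
#'
#' @param surface a `ctdcs_surface`
#' @param grid the owning `ctdcs_voxel_grid` with an EF attached
#' @return data.frame with `e_proj` (V/m, signed), `theta` (deg; `NA` where
#'   the field vanishes) and `intensity` (V/m)
#' @export
project_field <- function(surface, grid) {
  if (is.null(grid$ef)) stop("grid has no electric field")
  vi <- surface$voxel
  E <- cbind(grid$ef[[1]][vi], grid$ef[[2]][vi], grid$ef[[3]][vi])
  axis <- -surface$normals
  inten <- sqrt(rowSums(E^2))
  ct <- rowSums(E * axis) / ifelse(inten > 0, inten, 1)
  ct <- pmin(1, pmax(-1, ct))
  theta <- acos(ct) * 180 / pi
  theta[inten == 0] <- NA_real_
  data.frame(e_proj = ifelse(inten > 0, -inten * ct, 0),
             theta = theta, intensity = inten)
}

#' Per-metric sensitivity curve over the field-intensity grid
#'
#' Runs the experiment that defines a metric once per field intensity
#' (theta = 0), averaging over seeds where the drive is stochastic.
#' Intensities where the metric is undefined (e.g. no spike within the
#' simulated window) are recorded as `NA` and the curve is still returned.
#'
#' @param model the cell model
#' @param metric one of `"tonic_rate"`, `"T_d"`, `"T_sp"`,
#'   `"mean_T_burst"`, `"mean_FR"`
#' @param intensities field grid, V/m (default 13 values in [-1.5, 1.5])
#' @param seeds seeds for stochastic drives (used by `mean_FR`)
#' @param delta_syn synaptic gain offset for `mean_FR`
#' @param ... passed on to the experiment runner
#' @return `ctdcs_sens_curve`: data.frame with `E`, `value`; attribute
#'   `baseline` (value at `E = 0`), `metric`
#' @export
build_sensitivity_curve <- function(model, metric,
                                    intensities = seq(-1.5, 1.5, length.out = 13),
                                    seeds = c(1, 2, 3), delta_syn = 0, ...) {
  runner <- switch(metric,
    tonic_rate = function(E) exp_tonic_rate(model, E = E, ...)$rate_hz,
    T_d = function(E) exp_pc_td(model, E = E, ...)$t_d,
    T_sp = function(E) exp_pc_cs(model, E = E, ...)$t_sp,
    mean_T_burst = function(E) exp_pc_burst(model, E = E, ...)$mean_t_burst,
    mean_FR = function(E) exp_pc_scenario3(model, E = E, seeds = seeds,
                                           delta_syn = delta_syn, ...)$rate_hz,
    stop("unknown metric: ", metric))
  vals <- vapply(intensities, function(E) {
    v <- tryCatch(runner(E), error = function(e) NA_real_)
    if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
  }, 0)
  out <- data.frame(E = intensities, value = vals)
  if (!any(intensities == 0))
    stop("the intensity grid must include the baseline E = 0")
  structure(out, class = c("ctdcs_sens_curve", "data.frame"),
            metric = metric, baseline = vals[intensities == 0][1])
}

#' Sensitivity curve from precomputed values
#'
#' @param intensities field grid (V/m), must include 0
#' @param values metric values (may contain `NA`)
#' @param metric metric name
#' @export
sensitivity_curve <- function(intensities, values, metric = "metric") {
  stopifnot(length(intensities) == length(values), any(intensities == 0),
            !is.unsorted(intensities))
  structure(data.frame(E = intensities, value = values),
            class = c("ctdcs_sens_curve", "data.frame"),
            metric = metric, baseline = values[intensities == 0][1])
}

#' Map a sensitivity curve onto surface projections
#'
#' Piecewise-linear interpolation of the curve at every vertex's projected
#' intensity, clamped at the ends of the curve grid. Vertices whose
#' projection falls next to an undefined curve point are flagged absent
#' (`NA`). Percent change is relative to the curve baseline at `E = 0`.
#'
#' @param projections output of [project_field()]
#' @param curve a sensitivity curve
#' @return `ctdcs_metric_map`: data.frame with `e_proj`, `theta`, `value`,
#'   `pct_change`
#' @export
map_metric <- function(projections, curve) {
  E <- curve$E; val <- curve$value
  if (min(E) > -1.5 + 1e-9 || max(E) < 1.5 - 1e-9)
    stop("curve must cover [-1.5, +1.5] V/m")
  x <- pmin(max(E), pmax(min(E), projections$e_proj))
  ok <- !is.na(val)
  v <- approx(E[ok], val[ok], xout = x, rule = 2)$y
  # flag vertices whose bracketing grid interval touches an undefined point
  if (any(!ok)) {
    lo <- findInterval(x, E)
    lo <- pmin(pmax(lo, 1), length(E) - 1)
    bad <- !ok[lo] | !ok[lo + 1]
    v[bad] <- NA_real_
  }
  base <- attr(curve, "baseline")
  structure(data.frame(e_proj = projections$e_proj, theta = projections$theta,
                       value = v,
                       pct_change = 100 * (v - base) / base),
            class = c("ctdcs_metric_map", "data.frame"),
            metric = attr(curve, "metric"), baseline = base)
}

#' Summarise a metric map
#'
#' Fractions of vertices beyond the intensity thresholds (default +-0.5 and
#' +-1.5 V/m), anodal/cathodal/zero population fractions, a theta histogram,
#' and the fractions with absolute percent change beyond the change
#' thresholds.
#'
#' @param map a `ctdcs_metric_map`
#' @param thresholds intensity thresholds, V/m
#' @param change_thresholds percent-change thresholds
#' @param theta_breaks histogram breaks for theta, degrees
#' @return list with `intensity_fractions` (data.frame), `anodal_fraction`,
#'   `cathodal_fraction`, `zero_fraction`, `theta_hist`, `change_fractions`
#' @export
summarize_map <- function(map, thresholds = c(0.5, 1.5),
                          change_thresholds = c(10, 20, 30),
                          theta_breaks = seq(0, 180, by = 10)) {
  n <- nrow(map)
  intens <- do.call(rbind, lapply(thresholds, function(th) {
    data.frame(threshold = th,
               anodal_beyond = sum(map$e_proj < -th) / n,
               cathodal_beyond = sum(map$e_proj > th) / n)
  }))
  th <- map$theta[!is.na(map$theta)]
  hist <- graphics::hist(th, breaks = theta_breaks, plot = FALSE)
  chg <- vapply(change_thresholds, function(ct)
    sum(abs(map$pct_change) > ct, na.rm = TRUE) / n, 0)
  list(intensity_fractions = intens,
       anodal_fraction = sum(map$e_proj < 0) / n,
       cathodal_fraction = sum(map$e_proj > 0) / n,
       zero_fraction = sum(map$e_proj == 0) / n,
       theta_hist = data.frame(mid = hist$mids, density = hist$density,
                               count = hist$counts),
       change_fractions = setNames(chg, paste0("gt", change_thresholds)),
       n_vertices = n)
}

#' Export a surface as Wavefront OBJ
#' @param surface a `ctdcs_surface`
#' @param path output file
#' @export
write_surface_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  f <- surface$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
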