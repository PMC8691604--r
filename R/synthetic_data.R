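# Synthetic stand-ins for the pipeline's external inputs: a folded cortical
# shell voxelised on a 600-um lattice, point-source electric-field grids
# emulating the dosimetry output, and fixture spike trains with known ISI
# statistics.

#' Folded cortical shell specification
#'
#' @param radius mean shell radius, mm
#' @param thickness cortical depth carrying Purkinje cells, mm (default 1.2)
#' @param fold_wavelength folia wavelength along the surface, mm
#' @param fold_amplitude folia amplitude, mm (must be below the radius)
#' @param spacing voxel lattice spacing, mm (default 0.6, i.e. 600 um)
#' @param seed seed controlling the fold phases
#' @export
cortical_shell_spec <- function(radius = 12, thickness = 1.2,
                                fold_wavelength = 6, fold_amplitude = 1.5,
                                spacing = 0.6, seed = 1) {
  stopifnot(radius > 0, thickness > 0, fold_amplitude >= 0,
            fold_amplitude < radius, fold_wavelength > 0, spacing > 0)
  structure(list(radius = radius, thickness = thickness,
                 fold_wavelength = fold_wavelength,
                 fold_amplitude = fold_amplitude,
                 spacing = spacing, seed = seed),
            class = "ctdcs_shell_spec")
}

# local outer-surface radius of the folded shell at polar angle theta,
# azimuth phi (folds run as parallel transverse ridges plus a weaker
# azimuthal modulation so surface normals span a wide angular range)
shell_radius_fun <- function(spec) {
  ph <- with_seed(spec$seed, runif(2, 0, 2 * pi))
  function(theta, phi) {
    spec$radius +
      spec$fold_amplitude * (
        0.8 * sin(2 * pi * spec$radius * theta / spec$fold_wavelength + ph[1]) +
        0.2 * sin(2 * pi * spec$radius * sin(theta) * phi /
                    spec$fold_wavelength + ph[2]))
  }
}

#' Generate a folded cortical voxel grid
#'
#' Voxelises a sinusoidally folded spherical shell on the 600-um lattice.
#' The scalar field is 0.5 exactly on the outer surface and varies linearly
#' with the signed distance to it in a band of one voxel (clamped to [0, 1]
#' elsewhere), so iso-surface extraction at 0.5 recovers the folded surface
#' with sub-voxel accuracy. Voxels within `thickness` mm of the outer
#' surface are labelled cortex; everything deeper (white matter plus nuclei)
#' is labelled nuclei. Deterministic for a fixed seed.
#'
#' @param spec a [cortical_shell_spec()]
#' @return `ctdcs_voxel_grid`: list with `dim`, `spacing`, `origin` (mm),
#'   `field` (3D array), `labels` (3D array: 0 outside, 1 cortex, 2 nuclei),
#'   and `spec`
#' @export
gen_folded_cortex <- function(spec) {
  stopifnot(inherits(spec, "ctdcs_shell_spec"))
  if (spec$fold_amplitude > 0 && spec$spacing > spec$fold_wavelength / 4)
    stop("voxel spacing larger than a quarter fold wavelength: folds unresolvable")
  rfun <- shell_radius_fun(spec)
  rmax <- spec$radius + spec$fold_amplitude + 3 * spec$spacing
  nhalf <- ceiling(rmax / spec$spacing)
  ax <- spec$spacing * (-nhalf:nhalf)   # symmetric lattice about the origin
  nd <- length(ax)
  origin <- c(ax[1], ax[1], ax[1])
  crd <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(crd$x^2 + crd$y^2 + crd$z^2)
  theta <- acos(pmin(1, pmax(-1, ifelse(r > 0, crd$z / r, 1))))
  phi <- atan2(crd$y, crd$x)
  rs <- rfun(theta, phi)
  sd_out <- rs - r                       # signed distance proxy (mm, + inside)
  f <- pmin(1, pmax(0, 0.5 + sd_out / (2 * spec$spacing)))
  lab <- integer(length(f))
  lab[sd_out >= 0] <- 2L                 # interior: nuclei unless cortical
  lab[sd_out >= 0 & sd_out <= spec$thickness] <- 1L
  structure(list(dim = c(nd, nd, nd), spacing = spec$spacing, origin = origin,
                 field = array(f, c(nd, nd, nd)),
                 labels = array(lab, c(nd, nd, nd)),
                 spec = spec),
            class = "ctdcs_voxel_grid")
}

#' @export
print.ctdcs_voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid %dx%dx%d at %.1f mm spacing\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing))
  cat(sprintf("  cortex voxels: %d, nuclei voxels: %d\n",
              sum(x$labels == 1L), sum(x$labels == 2L)))
  if (!is.null(x$ef))
    cat(sprintf("  EF present; cortex median intensity %.2f V/m\n",
                median(voxel_intensity(x)[x$labels == 1L])))
  invisible(x)
}

# voxel centre coordinates (n x 3, mm)
voxel_coords <- function(grid) {
  axs <- lapply(1:3, function(i) grid$origin[i] +
                  (seq_len(grid$dim[i]) - 1) * grid$spacing)
  as.matrix(expand.grid(x = axs[[1]], y = axs[[2]], z = axs[[3]]))
}

#' Per-voxel field intensity
#' @param grid a `ctdcs_voxel_grid` with an EF attached
#' @return 3D array of |E| (V/m)
#' @export
voxel_intensity <- function(grid) {
  if (is.null(grid$ef)) stop("grid has no electric field; run gen_voxel_field")
  sqrt(grid$ef[[1]]^2 + grid$ef[[2]]^2 + grid$ef[[3]]^2)
}

#' Attach a point-source electric field to a voxel grid
#'
#' Superposes the fields of current point sources in an unbounded
#' homogeneous medium, `E(x) = sum_k I_k (x - p_k) / (4 pi sigma |x - p_k|^3)`,
#' which is curl- and divergence-free away from the sources and has a
#' closed-form magnitude for validation. With `current_scale = NULL`
#' (default) the field is scaled so the median cortex-voxel intensity is
#' `target_median` V/m, emulating the printed whole-cortex summaries of a
#' 2-mA montage (bulk at 0.4-0.5 V/m with a roughly 1% tail above 1 V/m for
#' the default electrode standoff); a numeric `current_scale` is applied
#' as-is, so the field is exactly linear in it.
#'
#' @param grid a `ctdcs_voxel_grid`
#' @param electrodes matrix/data.frame with columns x, y, z (mm) and
#'   current (signed, arbitrary units; at least one source and one sink)
#' @param current_scale numeric scale, or `NULL` for median normalisation
#' @param target_median target median cortex intensity (V/m) when
#'   normalising
#' @param sigma medium conductivity (arbitrary units; folded into the scale)
#' @return the grid with `ef` (list of three 3D arrays, V/m) attached
#' @export
gen_voxel_field <- function(grid, electrodes = default_electrodes(grid),
                            current_scale = NULL, target_median = 0.45,
                            sigma = 1) {
  el <- as.data.frame(electrodes)
  stopifnot(all(c("x", "y", "z", "current") %in% names(el)), nrow(el) >= 2)
  if (!any(el$current > 0) || !any(el$current < 0))
    stop("need at least one source and one sink electrode")
  rmax_in <- grid$spec$radius + grid$spec$fold_amplitude
  din <- sqrt(el$x^2 + el$y^2 + el$z^2)
  if (any(din <= rmax_in)) stop("electrode inside the cortical shell")
  crd <- voxel_coords(grid)
  ex <- ey <- ez <- numeric(nrow(crd))
  for (k in seq_len(nrow(el))) {
    dx <- crd[, 1] - el$x[k]; dy <- crd[, 2] - el$y[k]; dz <- crd[, 3] - el$z[k]
    r3 <- (dx^2 + dy^2 + dz^2)^(3 / 2)
    f <- el$current[k] / (4 * pi * sigma) / r3
    ex <- ex + f * dx; ey <- ey + f * dy; ez <- ez + f * dz
  }
  if (is.null(current_scale)) {
    inten <- sqrt(ex^2 + ey^2 + ez^2)
    med <- median(inten[grid$labels == 1L])
    current_scale <- target_median / med
  }
  grid$ef <- list(array(ex * current_scale, grid$dim),
                  array(ey * current_scale, grid$dim),
                  array(ez * current_scale, grid$dim))
  grid
}

#' Default two-electrode montage for a shell grid
#'
#' One pad-like anode close to the shell surface (standoff tuned so the
#' cortical intensity distribution shows the expected ~1% tail above 1 V/m
#' once normalised) and a distant return electrode.
#'
#' @param grid a `ctdcs_voxel_grid`
#' @export
default_electrodes <- function(grid) {
  R <- grid$spec$radius + grid$spec$fold_amplitude
  data.frame(x = c(0, 0), y = c(0, 3 * R),
             z = c(R + 1.5 * grid$spec$radius, -2 * R),
             current = c(1, -1))
}

#' Fixture spike trains with known ISI statistics
#'
#' Generates spike trains whose CoV and maximum-ISI statistics are known by
#' construction, for testing the pattern classifier and burst decomposition:
#' \describe{
#' \item{regular}{`list(kind = "regular", rate)`: zero-CoV train.}
#' \item{gamma}{`list(kind = "gamma", rate, shape)`: gamma-distributed ISIs;
#'   CoV tends to `1/sqrt(shape)`.}
#' \item{burst}{`list(kind = "burst", n_bursts, spikes_per_burst, intra_isi,
#'   gap)`: bursts of fixed structure.}
#' \item{sparse}{`list(kind = "sparse", times)`: a handful of spikes followed
#'   by silence to the end of the window.}
#' }
#'
#' @param recipe recipe list (see Details)
#' @param duration window length, ms
#' @param seed RNG seed
#' @return a [spike_train()]
#' @export
gen_fixture_trains <- function(recipe, duration = 10000, seed = 1) {
  kind <- recipe$kind
  times <- switch(kind,
    regular = seq(0, duration, by = 1000 / recipe$rate)[-1],
    gamma = with_seed(seed, {
      shape <- recipe$shape
      mean_isi <- 1000 / recipe$rate
      n <- ceiling(duration / mean_isi * 2) + 20
      isi <- stats::rgamma(n, shape = shape, rate = shape / mean_isi)
      tt <- cumsum(isi)
      tt[tt < duration]
    }),
    burst = {
      nb <- recipe$n_bursts; ns <- recipe$spikes_per_burst
      onset <- (seq_len(nb) - 1) * (recipe$gap + (ns - 1) * recipe$intra_isi)
      as.numeric(t(outer(onset, (seq_len(ns) - 1) * recipe$intra_isi, "+")))
    },
    sparse = recipe$times,
    stop("unknown fixture recipe: ", kind))
  times <- sort(times[times <= duration])
  spike_train(times, t0 = 0, t1 = duration)
}

# ---------------------------------------------------------------------------
# NIfTI import/export --------------------------------------------------------

#' Write a voxel grid (field components and labels) as NIfTI volumes
#'
#' One volume per electric-field component (`<prefix>_Ex/Ey/Ez.nii`), one
#' for the scalar field (`<prefix>_F.nii`) and one for the tissue labels
#' (`<prefix>_labels.nii`), all stored as double precision so the round
#' trip is bit-exact.
#'
#' @param grid a `ctdcs_voxel_grid`
#' @param prefix output path prefix
#' @return invisibly, the written file names
#' @export
write_grid_nifti <- function(grid, prefix) {
  pd <- rep(grid$spacing, 3)
  as_vol <- function(arr) {
    RNifti::asNifti(array(as.double(arr), grid$dim),
                    reference = list(pixdim = c(-1, pd, 0, 0, 0, 0)),
                    datatype = "double")
  }
  files <- c(F = paste0(prefix, "_F.nii"),
             labels = paste0(prefix, "_labels.nii"))
  RNifti::writeNifti(as_vol(grid$field), files[["F"]])
  RNifti::writeNifti(as_vol(grid$labels), files[["labels"]])
  if (!is.null(grid$ef)) {
    for (i in 1:3) {
      fn <- paste0(prefix, "_E", c("x", "y", "z")[i], ".nii")
      RNifti::writeNifti(as_vol(grid$ef[[i]]), fn)
      files <- c(files, fn)
    }
  }
  invisible(files)
}

#' Read a voxel grid written by [write_grid_nifti()]
#'
#' @param prefix path prefix used when writing
#' @param spec optionally, the originating [cortical_shell_spec()] (restores
#'   the metadata needed by the field generator)
#' @export
read_grid_nifti <- function(prefix, spec = NULL) {
  f <- RNifti::readNifti(paste0(prefix, "_F.nii"))
  lab <- RNifti::readNifti(paste0(prefix, "_labels.nii"))
  spacing <- signif(RNifti::pixdim(f)[1], 6)  # header stores float32
  d <- dim(f)
  g <- structure(list(dim = d, spacing = spacing,
                      origin = -(d - 1) / 2 * spacing,
                      field = array(as.double(f), d),
                      labels = array(as.integer(lab), d),
                      spec = spec),
                 class = "ctdcs_voxel_grid")
  exf <- paste0(prefix, "_Ex.nii")
  if (file.exists(exf)) {
    g$ef <- lapply(c("x", "y", "z"), function(a) {
      array(as.double(RNifti::readNifti(paste0(prefix, "_E", a, ".nii"))), d)
    })
  }
  g
}
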