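#' @useDynLib ctdcs, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef lm median optim quantile rexp runif sd setNames
#' @importFrom utils head read.csv tail write.csv
NULL

SECTION_LABELS <- c("soma", "dendrite", "hillock", "AIS", "axon")

#' Compartmental morphology
#'
#' A morphology is a rooted tree of cylindrical compartments. Each compartment
#' is a straight segment with proximal and distal endpoints (um), a diameter
#' (um), one of five section labels (soma, dendrite, hillock, AIS, axon) and a
#' free-form region tag used for channel placement. The root (soma) has parent
#' 0, and compartments are ordered so every parent precedes its children,
#' which is the ordering the tree solver expects.
#'
#' @param compartments data.frame with columns `id`, `parent`, `x0`, `y0`,
#'   `z0`, `x1`, `y1`, `z1`, `diam`, `section`, and optionally `region`
#'   (defaults to the section label). Coordinates in um.
#' @param axis somato-axonal axis: unit 3-vector pointing from the soma
#'   towards the axonal terminal.
#' @return object of class `ctdcs_morphology`
#' @export
morphology <- function(compartments, axis) {
  df <- as.data.frame(compartments)
  need <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1", "diam", "section")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("morphology is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$region)) df$region <- df$section
  n <- nrow(df)
  if (!all(df$id == seq_len(n)))
    stop("compartment ids must be 1..n in order")
  df$id <- as.integer(df$id)
  df$parent <- as.integer(df$parent)
  if (sum(df$parent == 0L) != 1L)
    stop("invalid morphology: exactly one root compartment required")
  if (any(df$parent >= df$id))
    stop("invalid morphology: parents must precede children (parent < id)")
  if (any(df$parent < 0L))
    stop("invalid morphology: negative parent index")
  bad <- setdiff(unique(df$section), SECTION_LABELS)
  if (length(bad))
    stop("unknown section labels: ", paste(bad, collapse = ", "))
  df$L <- sqrt((df$x1 - df$x0)^2 + (df$y1 - df$y0)^2 + (df$z1 - df$z0)^2)
  if (any(df$L <= 0)) stop("invalid morphology: zero-length compartment")
  if (any(df$diam <= 0)) stop("invalid morphology: non-positive diameter")
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("invalid morphology: degenerate somato-axonal axis (zero vector)")
  axis <- axis / nrm
  structure(list(compartments = df, axis = axis), class = "ctdcs_morphology")
}

#' @export
print.ctdcs_morphology <- function(x, ...) {
  df <- x$compartments
  cat("Compartmental morphology:", nrow(df), "compartments\n")
  tab <- table(df$section)
  for (s in names(tab)) {
    sel <- df$section == s
    cat(sprintf("  %-9s %4d compartments, total length %.1f um\n",
                s, tab[[s]], sum(df$L[sel])))
  }
  cat(sprintf("  somato-axonal axis: (%.2f, %.2f, %.2f)\n",
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

# compartment midpoints (um), n x 3
morph_midpoints <- function(morph) {
  df <- morph$compartments
  cbind((df$x0 + df$x1) / 2, (df$y0 + df$y1) / 2, (df$z0 + df$z1) / 2)
}

# lateral membrane area per compartment, cm^2 (cylinder, pi * d * L)
morph_area_cm2 <- function(morph) {
  df <- morph$compartments
  pi * df$diam * df$L * 1e-8
}

#' Total membrane surface area of a model or morphology
#'
#' Cylindrical lateral areas summed over all compartments; used to convert
#' between injected current and current density.
#'
#' @param x a `ctdcs_morphology` or `ctdcs_neuron_model`
#' @return area in cm^2
#' @export
surface_area <- function(x) {
  if (inherits(x, "ctdcs_neuron_model")) x <- x$morph
  sum(morph_area_cm2(x))
}

# a deterministic unit vector orthogonal to u
orthogonal_unit <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v / sqrt(sum(v^2))
}

# Signed distance (um) of each compartment midpoint from the soma midpoint,
# measured along the field direction (axis rotated by theta degrees).
morph_field_distance <- function(morph, theta_deg) {
  a <- morph$axis
  b <- orthogonal_unit(a)
  th <- theta_deg * pi / 180
  u <- cos(th) * a + sin(th) * b
  mid <- morph_midpoints(morph)
  soma <- which(morph$compartments$section == "soma")[1]
  drop((mid - matrix(mid[soma, ], nrow(mid), 3, byrow = TRUE)) %*% u)
}

# straight chain of compartments appended to a morphology under construction;
# `rows` is a list of data.frames, returns ids of the new compartments
morph_chain <- function(rows, from_id, from_xyz, n, total_L, diam, dirvec,
                        section, region = section, taper_to = NULL) {
  dirvec <- dirvec / sqrt(sum(dirvec^2))
  L <- total_L / n
  diams <- if (is.null(taper_to)) rep(diam, n) else seq(diam, taper_to, length.out = n)
  start_id <- if (length(rows)) max(vapply(rows, function(r) max(r$id), 0)) else 0
  ids <- start_id + seq_len(n)
  p0 <- from_xyz
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- p0 + L * dirvec
    out[[i]] <- data.frame(
      id = ids[i], parent = if (i == 1) from_id else ids[i - 1],
      x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3],
      diam = diams[i], section = section, region = region,
      stringsAsFactors = FALSE)
    p0 <- p1
  }
  list(rows = c(rows, out), ids = ids, end = p0)
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent). Type codes map
#' to section labels: 1 soma, 2 axon, 3/4 dendrite; other codes become axon.
#' Each SWC point becomes the distal end of a compartment whose proximal end
#' is its parent point; the soma sample becomes a single cylindrical root.
#'
#' @param path file path
#' @param axis somato-axonal axis (unit 3-vector); default `c(0, 0, 1)`
#' @return a [morphology()] object
#' @export
read_swc <- function(path, axis = c(0, 0, 1)) {
  raw <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  if (!nrow(raw)) stop("empty SWC file: ", path)
  o <- order(raw$id)
  raw <- raw[o, ]
  idmap <- setNames(seq_len(nrow(raw)), raw$id)
  sect <- c("soma", "axon", "dendrite", "dendrite")[pmin(raw$type, 4)]
  sect[raw$type < 1 | raw$type > 4] <- "axon"
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (raw$parent[i] == -1) {
      # root: represent the soma sample as a cylinder of length 2r
      rows[[i]] <- data.frame(
        id = i, parent = 0L,
        x0 = raw$x[i] - raw$r[i], y0 = raw$y[i], z0 = raw$z[i],
        x1 = raw$x[i] + raw$r[i], y1 = raw$y[i], z1 = raw$z[i],
        diam = 2 * raw$r[i], section = sect[i], region = sect[i],
        stringsAsFactors = FALSE)
    } else {
      p <- idmap[[as.character(raw$parent[i])]]
      rows[[i]] <- data.frame(
        id = i, parent = p,
        x0 = raw$x[p], y0 = raw$y[p], z0 = raw$z[p],
        x1 = raw$x[i], y1 = raw$y[i], z1 = raw$z[i],
        diam = 2 * raw$r[i], section = sect[i], region = sect[i],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  len <- sqrt((df$x1 - df$x0)^2 + (df$y1 - df$y0)^2 + (df$z1 - df$z0)^2)
  drop_ids <- df$id[len <= 0 & df$parent != 0L]
  # reparent children of dropped (zero-length) samples before removing them
  while (length(drop_ids)) {
    reroute <- setNames(df$parent[match(drop_ids, df$id)], drop_ids)
    hit <- df$parent %in% drop_ids
    df$parent[hit] <- as.integer(reroute[as.character(df$parent[hit])])
    df <- df[!df$id %in% drop_ids, ]
    len <- sqrt((df$x1 - df$x0)^2 + (df$y1 - df$y0)^2 + (df$z1 - df$z0)^2)
    drop_ids <- df$id[len <= 0 & df$parent != 0L]
  }
  idmap2 <- setNames(seq_len(nrow(df)), df$id)
  df$parent <- ifelse(df$parent == 0L, 0L, as.integer(idmap2[as.character(df$parent)]))
  df$id <- seq_len(nrow(df))
  morphology(df, axis)
}
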