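# Unit icosahedron (circumradius 1) with a five-fold axis along +z:
# face-plane unit normals and the common plane distance (inradius).
.icosa <- local({
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1))
  )
  V <- V / sqrt(1 + phi^2)            # circumradius 1
  # rotate the vertex (0, vy, vz) onto +z (five-fold axis along z)
  vy <- V[1, 2]; vz <- V[1, 3]
  R <- rbind(c(1, 0, 0), c(0, vz, -vy), c(0, vy, vz))
  V <- V %*% t(R)
  # faces: triples of mutually adjacent vertices (edge length for R_c = 1)
  edge <- 4 / sqrt(10 + 2 * sqrt(5))
  adj <- as.matrix(stats::dist(V)) < edge * 1.01
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) faces[[length(faces) + 1L]] <- c(i, j, k)
  }
  stopifnot(length(faces) == 20L)
  N <- t(vapply(faces, function(f) {
    n <- colSums(V[f, ]); n / sqrt(sum(n^2))
  }, numeric(3)))
  d <- sum(N[1, ] * V[faces[[1]][1], ])      # inradius, ~0.7947
  rho <- max(sqrt(V[, 1]^2 + V[, 2]^2))      # equatorial vertex radius ~0.8944
  list(normals = N, inradius = d, eq_radius = rho, vertices = V)
})

# Axis-aligned orientations (proper rotations, exact entries).
# Matrices map lab coordinates into the phage frame (z_model = long axis).
.orientations <- list(
  top   = diag(3),                                      # long axis along beam
  side  = rbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0)),   # long axis along lab x
  side2 = rbind(c(0, 0, -1), c(-1, 0, 0), c(0, 1, 0))   # long axis along lab y
)

#' Build a parametric T4-like phage model
#'
#' An elongated icosahedral protein capsid (intersection of the 20 face
#' half-spaces of an icosahedron, scaled anisotropically along its five-fold
#' axis) whose interior holds the genome as concentric cylindrical DNA shells
#' separated by a fixed gap, the rest being vitreous ice.  The number of DNA
#' shells, and a continuous truncation of their axial extent, are chosen so
#' that the DNA occupies the requested fraction of the capsid interior.
#'
#' @param capsid_length Outer apex-to-apex length along the long axis, nm.
#' @param capsid_width Outer equatorial width (max diameter normal to the
#'   axis), nm.
#' @param shell_thickness Protein shell thickness, nm.
#' @param dna_gap Radial gap between DNA shells, nm.
#' @param dna_shell_thickness Radial thickness of each DNA shell, nm.
#' @param dna_volume_fraction Target DNA volume as a fraction of the capsid
#'   interior volume (0 gives a hollow, ice-filled capsid).
#' @param materials Named list of `em_material` providing at least
#'   `protein`, `dna`, `ice`.
#' @return An `em_specimen` (not yet embedded; see [embed_in_ice()]).
#' @export
build_phage <- function(capsid_length = 110, capsid_width = 80,
                        shell_thickness = 3, dna_gap = 1,
                        dna_shell_thickness = 2, dna_volume_fraction = 0.40,
                        materials = default_materials()) {
  stopifnot(capsid_length > 0, capsid_width > 0, shell_thickness > 0,
            dna_gap >= 0, dna_shell_thickness > 0,
            dna_volume_fraction >= 0, dna_volume_fraction < 1)
  if (2 * shell_thickness >= min(capsid_length, capsid_width)) {
    stop("shell thicker than the capsid itself", call. = FALSE)
  }
  geom <- list(
    length = capsid_length, width = capsid_width, shell = shell_thickness,
    dna_gap = dna_gap, dna_t = dna_shell_thickness,
    target_fraction = dna_volume_fraction
  )
  inner_w <- capsid_width - 2 * shell_thickness
  r_start <- inner_w / 2 - dna_gap
  annuli <- NULL
  z_cut <- capsid_length / 2
  if (dna_volume_fraction > 0) {
    if (r_start <= dna_shell_thickness) {
      stop("DNA shells do not fit inside the capsid interior", call. = FALSE)
    }
    pitch <- dna_shell_thickness + dna_gap
    n_max <- floor((r_start - dna_shell_thickness) / pitch) + 1L
    outer <- r_start - (seq_len(n_max) - 1L) * pitch
    annuli_all <- data.frame(outer = outer, inner = outer - dna_shell_thickness)
    # lattice volume estimator on the capsid interior
    frac_of <- function(ann, zc) .dna_fraction(geom, ann, zc)
    fr_n <- vapply(seq_len(n_max), function(n)
      frac_of(annuli_all[seq_len(n), ], z_cut), numeric(1))
    n_use <- if (fr_n[n_max] <= dna_volume_fraction) n_max else
      which(fr_n >= dna_volume_fraction)[1L]
    annuli <- annuli_all[seq_len(n_use), ]
    # shrink the axial extent continuously to land on the target fraction
    if (frac_of(annuli, z_cut) > dna_volume_fraction) {
      lo <- 0; hi <- z_cut
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (frac_of(annuli, mid) > dna_volume_fraction) hi <- mid else lo <- mid
      }
      z_cut <- (lo + hi) / 2
    }
  } else {
    annuli <- data.frame(outer = numeric(0), inner = numeric(0))
  }
  structure(
    list(kind = "phage", geom = geom, annuli = annuli, z_cut = z_cut,
         materials = materials,
         palette = c("ice", "protein", "dna"),
         orientation = .orientations$top, orientation_name = "top",
         center = NULL, bounds = NULL),
    class = "em_specimen"
  )
}

# Classify points given in the phage frame (origin at capsid centre, z along
# the long axis).  Returns 1 = background ice, 2 = protein, 3 = DNA.
.classify_model_frame <- function(model, q) {
  g <- model$geom
  if (g$width <= 0) return(rep.int(1L, nrow(q)))   # featureless slab
  ico <- .icosa
  scale_to_unit <- function(pts, w, l) {
    cbind(pts[, 1] / ((w / 2) / ico$eq_radius),
          pts[, 2] / ((w / 2) / ico$eq_radius),
          pts[, 3] / (l / 2))
  }
  inside_icosa <- function(pts_unit) {
    s <- pts_unit %*% t(ico$normals)
    smax <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
    smax <= ico$inradius
  }
  out <- rep.int(1L, nrow(q))
  # cheap bounding-box prefilter
  bb <- abs(q[, 1]) <= g$width / 2 & abs(q[, 2]) <= g$width / 2 &
    abs(q[, 3]) <= g$length / 2
  if (!any(bb)) return(out)
  qb <- q[bb, , drop = FALSE]
  in_outer <- inside_icosa(scale_to_unit(qb, g$width, g$length))
  in_inner <- rep(FALSE, nrow(qb))
  iw <- g$width - 2 * g$shell; il <- g$length - 2 * g$shell
  in_inner[in_outer] <- inside_icosa(
    scale_to_unit(qb[in_outer, , drop = FALSE], iw, il))
  cls <- rep.int(1L, nrow(qb))
  cls[in_outer & !in_inner] <- 2L
  if (nrow(model$annuli)) {
    rr <- sqrt(qb[, 1]^2 + qb[, 2]^2)
    in_dna <- rep(FALSE, nrow(qb))
    for (k in seq_len(nrow(model$annuli))) {
      in_dna <- in_dna | (rr <= model$annuli$outer[k] & rr > model$annuli$inner[k])
    }
    in_dna <- in_dna & in_inner & abs(qb[, 3]) <= model$z_cut
    cls[in_dna] <- 3L
  }
  out[bb] <- cls
  out
}

# DNA volume fraction of the capsid interior, by exact column heights of the
# inner icosahedron on a fixed transverse lattice (deterministic, no RNG).
# For a unit icosahedron the admissible Z at fixed (X, Y) is an interval
# bounded by the face planes with n_z != 0.
.dna_fraction <- function(geom, annuli, z_cut, h = 0.25) {
  ico <- .icosa
  iw <- geom$width - 2 * geom$shell
  il <- geom$length - 2 * geom$shell
  sxy <- (iw / 2) / ico$eq_radius
  sz <- il / 2
  w2 <- iw / 2
  ax <- seq(-w2 + h / 2, w2, by = h)
  X <- rep(ax, times = length(ax)) / sxy
  Y <- rep(ax, each = length(ax)) / sxy
  Npl <- ico$normals; d <- ico$inradius
  up <- which(Npl[, 3] > 1e-12); dn <- which(Npl[, 3] < -1e-12)
  zhi <- rep(Inf, length(X)); zlo <- rep(-Inf, length(X))
  for (i in up) {
    zhi <- pmin(zhi, (d - Npl[i, 1] * X - Npl[i, 2] * Y) / Npl[i, 3])
  }
  for (i in dn) {
    zlo <- pmax(zlo, (d - Npl[i, 1] * X - Npl[i, 2] * Y) / Npl[i, 3])
  }
  height <- pmax(0, zhi - zlo) * sz            # interior column height, nm
  v_interior <- sum(height) * h^2
  if (v_interior <= 0 || nrow(annuli) == 0) return(0)
  rr <- sqrt((X * sxy)^2 + (Y * sxy)^2)
  in_dna <- rep(FALSE, length(rr))
  for (k in seq_len(nrow(annuli))) {
    in_dna <- in_dna | (rr <= annuli$outer[k] & rr > annuli$inner[k])
  }
  # DNA column: overlap of [zlo, zhi] (scaled to nm) with [-z_cut, z_cut]
  ov <- pmax(0, pmin(zhi * sz, z_cut) - pmax(zlo * sz, -z_cut))
  v_dna <- sum(ov[in_dna]) * h^2
  v_dna / v_interior
}

#' Featureless slab specimen
#'
#' A specimen with no bodies: the slab is filled entirely by the background
#' material.  Useful for attenuation/flat-field references and uniform-medium
#' Monte Carlo checks.
#'
#' @param materials Named list of `em_material`.
#' @param background Palette name of the background material (default
#'   `"ice"`; use `"vacuum"` for an empty field).
#' @return An `em_specimen` (embed with [embed_in_ice()]).
#' @export
ice_slab <- function(materials = default_materials(), background = "ice") {
  structure(
    list(kind = "slab",
         geom = list(length = 0, width = 0, shell = 0),
         annuli = data.frame(outer = numeric(0), inner = numeric(0)),
         z_cut = 0, materials = materials,
         palette = unique(c(background, "ice", "protein", "dna")),
         orientation = .orientations$top, orientation_name = "top",
         center = NULL, bounds = NULL),
    class = "em_specimen"
  )
}

#' Embed a specimen model in a slab of vitreous ice
#'
#' Sets the slab bounds along the beam axis and the depth of the model centre.
#' The background ice fills all volume not claimed by a body.  Errors if the
#' model protrudes from the slab for its current orientation.
#'
#' @param model An `em_specimen`.
#' @param ice_thickness Slab thickness along the beam, nm.
#' @param depth_of_center Depth of the capsid centre below the entrance
#'   surface, nm (default: slab midplane).
#' @param orientation `"top"`, `"side"`, `"side2"` (the three orthogonal
#'   views) or a 3x3 rotation matrix mapping lab to model coordinates.
#' @return The updated `em_specimen`.
#' @export
embed_in_ice <- function(model, ice_thickness,
                         depth_of_center = ice_thickness / 2,
                         orientation = model$orientation_name) {
  stopifnot(inherits(model, "em_specimen"), ice_thickness > 0)
  if (is.character(orientation)) {
    R <- .orientations[[orientation]]
    if (is.null(R)) stop("unknown orientation '", orientation, "'", call. = FALSE)
    model$orientation_name <- orientation
  } else {
    R <- orientation
    stopifnot(is.matrix(R), all(dim(R) == c(3, 3)),
              max(abs(crossprod(R) - diag(3))) < 1e-9)
    model$orientation_name <- "custom"
  }
  model$orientation <- R
  # beam-axis half extent of the rotated capsid (convex: vertices suffice);
  # q_model = R p_lab, so the lab beam axis e_z is R e_z = R[, 3] in the
  # model frame
  g <- model$geom
  ico_v <- .icosa$vertices
  verts <- cbind(ico_v[, 1] * (g$width / 2) / .icosa$eq_radius,
                 ico_v[, 2] * (g$width / 2) / .icosa$eq_radius,
                 ico_v[, 3] * g$length / 2)
  half_z <- max(abs(verts %*% R[, 3]))
  if (depth_of_center - half_z < -1e-9 ||
      depth_of_center + half_z > ice_thickness + 1e-9) {
    stop(sprintf("model (half extent %.1f nm) protrudes from %g nm slab at depth %g nm",
                 half_z, ice_thickness, depth_of_center), call. = FALSE)
  }
  model$bounds <- c(thickness = ice_thickness)
  model$depth <- depth_of_center
  model
}

#' Classify lab-frame points into materials
#'
#' @param model An embedded `em_specimen`.
#' @param pts n x 3 matrix of lab coordinates in nm (z along the beam,
#'   origin at the entrance-surface corner of the field).
#' @param field_center c(x, y) position of the capsid centre, nm.
#' @return Integer vector indexing `model$palette`.
#' @export
classify_points <- function(model, pts, field_center) {
  center <- c(field_center[1], field_center[2], model$depth)
  q <- sweep(pts, 2L, center) %*% t(model$orientation)
  .classify_model_frame(model, q)
}

#' Rasterise a specimen into per-slice material maps
#'
#' Voxel-centre sampling: slice i covers depths [(i-1) dt, i dt) and is
#' sampled at its central plane; each cell takes the material of the body
#' containing its centre (background ice elsewhere).  Deterministic.
#'
#' @param model An embedded `em_specimen`.
#' @param N Grid size per side (powers of two preferred for the FFT stages).
#' @param L Field width, nm.
#' @param delta_t Slice thickness, nm; must divide the slab thickness.
#' @return An `em_matmaps` object: list of N x N integer slice maps plus
#'   `palette`, `materials`, `N`, `L`, `delta_t`, `pixel`.
#' @export
rasterize <- function(model, N, L, delta_t) {
  stopifnot(inherits(model, "em_specimen"), N > 0, L > 0, delta_t > 0)
  if (is.null(model$bounds)) stop("model not embedded; call embed_in_ice() first",
                                  call. = FALSE)
  t_total <- model$bounds[["thickness"]]
  nz <- round(t_total / delta_t)
  if (abs(nz * delta_t - t_total) > 1e-9) {
    stop("delta_t must divide the slab thickness exactly", call. = FALSE)
  }
  px <- L / N
  ax <- (seq_len(N) - 0.5) * px
  grid2 <- cbind(rep(ax, times = N), rep(ax, each = N))  # x fastest
  center <- c(L / 2, L / 2, model$depth)
  R <- model$orientation
  # phage bounding sphere for cheap slice rejection
  rad <- sqrt((model$geom$length / 2)^2 + (model$geom$width / 2)^2)
  maps <- vector("list", nz)
  for (i in seq_len(nz)) {
    zc <- (i - 0.5) * delta_t
    if (abs(zc - model$depth) > rad) {
      maps[[i]] <- matrix(1L, N, N)
      next
    }
    pts <- cbind(grid2[, 1] - center[1], grid2[, 2] - center[2], zc - center[3])
    q <- pts %*% t(R)
    maps[[i]] <- matrix(.classify_model_frame(model, q), N, N)
  }
  structure(
    list(maps = maps, palette = model$palette, materials = model$materials,
         N = N, L = L, delta_t = delta_t, pixel = px, thickness = t_total),
    class = "em_matmaps"
  )
}

#' @export
print.em_matmaps <- function(x, ...) {
  cat(sprintf("<em_matmaps> %d slices of %dx%d, L = %g nm, dt = %g nm\n",
              length(x$maps), x$N, x$N, x$L, x$delta_t))
  invisible(x)
}

#' Per-material voxel volumes of a rasterised model
#'
#' @param maps An `em_matmaps`.
#' @return Named numeric vector of volumes in nm^3 (sums exactly to
#'   L^2 * thickness).
#' @export
voxel_volumes <- function(maps) {
  vox <- maps$pixel^2 * maps$delta_t
  counts <- integer(length(maps$palette))
  for (m in maps$maps) {
    tb <- tabulate(m, nbins = length(maps$palette))
    counts <- counts + tb
  }
  stats::setNames(counts * vox, maps$palette)
}
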