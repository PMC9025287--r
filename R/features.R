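# Spatial-heterogeneity features of the habitat label map, plus whole-tumor
# texture panels for the conventional radiomics comparators.  Texture
# definitions follow the IBSI / PyRadiomics conventions; the habitat map is
# used with bin size one, i.e. the habitat labels are the gray levels.

label_volume <- function(map) {
  if (inherits(map, "habitat_map")) map$labels else map
}

# ---- GLCM ------------------------------------------------------------------

# Per-direction symmetric co-occurrence probability matrices at distance 1
# over the 13 unique 3D directions.  Levels are the distinct nonzero labels.
glcm_matrices <- function(labels) {
  g <- sort(unique(labels[labels > 0]))
  if (length(g) == 0) stop("empty ROI", call. = FALSE)
  lut <- integer(max(g)); lut[g] <- seq_along(g)
  d <- dim(labels)
  dirs <- unique_directions_3d()
  out <- list()
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    i1 <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    j1 <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    k1 <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    a <- labels[i1, j1, k1, drop = FALSE]
    b <- labels[i1 + o[1], j1 + o[2], k1 + o[3], drop = FALSE]
    sel <- a > 0 & b > 0
    if (!any(sel)) next
    ia <- lut[a[sel]]; ib <- lut[b[sel]]
    ng <- length(g)
    cnt <- matrix(tabulate((ib - 1L) * ng + ia, ng * ng), ng, ng)
    C <- cnt + t(cnt)                       # symmetrize
    out[[length(out) + 1]] <- C / sum(C)
  }
  if (length(out) == 0) stop("no voxel pairs in any direction", call. = FALSE)
  list(levels = g, p = out)
}

glcm_features_one <- function(p, g) {
  ng <- length(g)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(g * px); mu_y <- sum(g * py)
  s2x <- sum((g - mu_x)^2 * px); s2y <- sum((g - mu_y)^2 * py)
  gi <- matrix(g, ng, ng); gj <- t(gi)
  dif <- abs(gi - gj); sm <- gi + gj
  # difference / sum distributions
  kd <- sort(unique(as.vector(dif)))
  pd <- vapply(kd, function(v) sum(p[dif == v]), 0)
  ks <- sort(unique(as.vector(sm)))
  ps <- vapply(ks, function(v) sum(p[sm == v]), 0)
  log2p <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- log2p(p)
  hx <- log2p(px); hy <- log2p(py)
  pipj <- outer(px, py)
  nz <- p > 0 & pipj > 0
  hxy1 <- -sum(p[nz] * log2(pipj[nz]))
  nz2 <- pipj > 0
  hxy2 <- -sum(pipj[nz2] * log2(pipj[nz2]))
  da <- sum(kd * pd)
  corr <- if (s2x <= 0 || s2y <= 0) 1 else
    (sum(p * gi * gj) - mu_x * mu_y) / sqrt(s2x * s2y)
  imc1 <- if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  # MCC on the sub-matrix with positive marginals
  keep <- px > 0 & py > 0
  mcc <- if (sum(keep) < 2) 1 else {
    ps_ <- p[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    A <- sweep(ps_, 2, pyk, `/`)
    Q <- sweep(A %*% t(ps_), 1, pxk, `/`)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(Autocorrelation = sum(p * gi * gj),
    ClusterProminence = sum(p * (gi + gj - mu_x - mu_y)^4),
    ClusterShade = sum(p * (gi + gj - mu_x - mu_y)^3),
    ClusterTendency = sum(p * (gi + gj - mu_x - mu_y)^2),
    Contrast = sum(p * (gi - gj)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = log2p(pd),
    DifferenceVariance = sum(pd * (kd - da)^2),
    Id = sum(p / (1 + dif)),
    Idm = sum(p / (1 + dif^2)),
    Idmn = sum(p / (1 + dif^2 / ng^2)),
    Idn = sum(p / (1 + dif / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[dif > 0] / dif[dif > 0]^2),
    JointAverage = mu_x,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * ps),
    SumEntropy = log2p(ps),
    SumSquares = s2x)
}

#' Gray-level co-occurrence (GLCM) features of a habitat map
#'
#' Builds symmetric co-occurrence matrices at distance 1 over the 13 unique
#' 3D directions, computes the 24 IBSI/PyRadiomics GLCM features per
#' direction, and averages feature values over directions.  Habitat labels
#' act as gray levels (bin size one).  Degenerate conventions for a
#' single-label map: Correlation = 1, IMC1 = 0, MCC = 1.
#'
#' @param map a \code{habitat_map} or 3D integer label volume (0 = outside
#'   ROI).
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(map) {
  labels <- label_volume(map)
  gm <- glcm_matrices(labels)
  vals <- vapply(gm$p, glcm_features_one, numeric(24), g = gm$levels)
  rowMeans(vals)
}

# ---- GLSZM -----------------------------------------------------------------

# Zones: 26-connected components of equal nonzero label.
glszm_zones <- function(labels) {
  d <- dim(labels)
  idx <- which(labels > 0)
  if (length(idx) == 0) stop("empty ROI", call. = FALSE)
  vid <- integer(prod(d)); vid[idx] <- seq_along(idx)
  dirs <- unique_directions_3d()
  eA <- integer(0); eB <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    i1 <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    j1 <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    k1 <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    a <- labels[i1, j1, k1, drop = FALSE]
    b <- labels[i1 + o[1], j1 + o[2], k1 + o[3], drop = FALSE]
    sel <- a > 0 & a == b
    if (!any(sel)) next
    lin_a <- array(seq_len(prod(d)), d)[i1, j1, k1, drop = FALSE][sel]
    off <- o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    eA <- c(eA, vid[lin_a]); eB <- c(eB, vid[lin_a + off])
  }
  gph <- igraph::graph_from_data_frame(
    data.frame(from = eA, to = eB),
    directed = FALSE,
    vertices = data.frame(name = seq_along(idx)))
  comp <- igraph::components(gph)
  memb <- comp$membership[as.character(seq_along(idx))]
  zone_size <- as.integer(table(memb)[as.character(seq_len(comp$no))])
  first_idx <- tapply(seq_along(idx), memb, min)
  zone_gray <- labels[idx][first_idx[as.character(seq_len(comp$no))]]
  data.frame(gray = as.integer(zone_gray), size = zone_size)
}

#' Gray-level size-zone (GLSZM) features of a habitat map
#'
#' Zones are 26-connected components of voxels sharing a label; the 16
#' IBSI/PyRadiomics GLSZM features are computed from the zone-size by
#' gray-level count table.  Habitat labels act as gray levels.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(map) {
  labels <- label_volume(map)
  z <- glszm_zones(labels)
  np <- sum(labels > 0)
  nz <- nrow(z)
  g <- z$gray; s <- z$size
  pg <- as.numeric(table(g)) / nz          # per gray level zone fraction
  ps <- as.numeric(table(s)) / nz
  glev <- sort(unique(g)); slev <- sort(unique(s))
  mu_g <- sum(glev * pg); mu_s <- sum(slev * ps)
  cell <- table(g, s) / nz
  cellv <- cell[cell > 0]
  c(SmallAreaEmphasis = sum(1 / s^2) / nz,
    LargeAreaEmphasis = sum(s^2) / nz,
    GrayLevelNonUniformity = sum(tapply(rep(1, nz), g, sum)^2) / nz,
    GrayLevelNonUniformityNormalized =
      sum(tapply(rep(1, nz), g, sum)^2) / nz^2,
    SizeZoneNonUniformity = sum(tapply(rep(1, nz), s, sum)^2) / nz,
    SizeZoneNonUniformityNormalized =
      sum(tapply(rep(1, nz), s, sum)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(pg * (glev - mu_g)^2),
    ZoneVariance = sum(ps * (slev - mu_s)^2),
    ZoneEntropy = -sum(cellv * log2(cellv)),
    LowGrayLevelZoneEmphasis = sum(1 / g^2) / nz,
    HighGrayLevelZoneEmphasis = sum(g^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (g^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(g^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / g^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(g^2 * s^2) / nz)
}

# ---- histogram -------------------------------------------------------------

#' First-order histogram features of the habitat label distribution
#'
#' The default four-feature set is entropy (bits), uniformity (energy),
#' skewness and kurtosis (uncorrected, i.e. 3 for a Gaussian) of the label
#' histogram at bin size one.  For a constant (single-label) map skewness
#' and kurtosis are defined as 0.
#'
#' @inheritParams glcm_features
#' @param set character vector choosing the emitted features.
#' @return named numeric vector.
#' @export
histogram_features <- function(map, set = c("Entropy", "Uniformity",
                                            "Skewness", "Kurtosis")) {
  labels <- label_volume(map)
  v <- labels[labels > 0]
  if (length(v) == 0) stop("empty ROI", call. = FALSE)
  p <- as.numeric(table(v)) / length(v)
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  all <- c(Entropy = -sum(p[p > 0] * log2(p[p > 0])),
           Uniformity = sum(p^2),
           Skewness = if (s2 > 0) mean((v - mu)^3) / s2^1.5 else 0,
           Kurtosis = if (s2 > 0) mean((v - mu)^4) / s2^2 else 0)
  all[set]
}

# ---- shape -----------------------------------------------------------------

# Marching-tetrahedra iso-surface (level 0.5) of the mask: the binary mask
# is first smoothed with a separable Gaussian (SD 1 voxel) so that surface
# vertices, found by linear interpolation along tetrahedron edges, land on
# a sub-voxel-accurate surface; meshing the raw binary volume with midpoint
# vertices overestimates the area of smooth shapes by its jagged facets.
# The cube between 8 neighboring voxel centers is split into 6 tetrahedra,
# each contributing 0-2 triangles.  Returns surface area and mesh volume.
mesh_surface <- function(mask, spacing, smooth_sd = 1) {
  d <- dim(mask)
  padw <- 4L
  pad <- array(0, d + 2L * padw)
  pad[padw + (1:d[1]), padw + (1:d[2]), padw + (1:d[3])] <- mask + 0
  if (smooth_sd > 0)
    for (a in 1:3)
      pad <- apply_axis(pad, gauss_kernel_matrix(dim(pad)[a], smooth_sd), a)
  dp <- dim(pad)
  nx <- dp[1] - 1L; ny <- dp[2] - 1L; nz <- dp[3] - 1L
  corner <- function(ox, oy, oz)
    pad[(1:nx) + ox, (1:ny) + oy, (1:nz) + oz, drop = FALSE]
  # corner order: bit0 = x, bit1 = y, bit2 = z
  cv <- list(corner(0, 0, 0), corner(1, 0, 0), corner(0, 1, 0),
             corner(1, 1, 0), corner(0, 0, 1), corner(1, 0, 1),
             corner(0, 1, 1), corner(1, 1, 1))
  cmin <- cv[[1]]; cmax <- cv[[1]]
  for (q in 2:8) { cmin <- pmin(cmin, cv[[q]]); cmax <- pmax(cmax, cv[[q]]) }
  mixed <- which(cmin < 0.5 & cmax > 0.5)
  if (length(mixed) == 0) return(list(area = 0, volume = 0, n_tri = 0))
  vals <- vapply(cv, function(a) a[mixed], numeric(length(mixed)))
  if (length(mixed) == 1L) vals <- matrix(vals, nrow = 1)
  ar <- arrayInd(mixed, c(nx, ny, nz))
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  area <- 0; vol6 <- 0; n_tri <- 0
  emit <- function(q1, q2, q3, ref) {
    nrm <- c(
      (q2[2] - q1[2]) * (q3[3] - q1[3]) - (q2[3] - q1[3]) * (q3[2] - q1[2]),
      (q2[3] - q1[3]) * (q3[1] - q1[1]) - (q2[1] - q1[1]) * (q3[3] - q1[3]),
      (q2[1] - q1[1]) * (q3[2] - q1[2]) - (q2[2] - q1[2]) * (q3[1] - q1[1]))
    ctr <- (q1 + q2 + q3) / 3
    if (sum(nrm * (ctr - ref)) < 0) { tmp <- q2; q2 <- q3; q3 <- tmp
      nrm <- -nrm }
    area <<- area + sqrt(sum(nrm^2)) / 2
    vol6 <<- vol6 + sum(q1 * c(
      q2[2] * q3[3] - q2[3] * q3[2],
      q2[3] * q3[1] - q2[1] * q3[3],
      q2[1] * q3[2] - q2[2] * q3[1]))
    n_tri <<- n_tri + 1
  }
  for (m in seq_along(mixed)) {
    orig <- ar[m, ]
    pts <- sweep(corner_off, 2, orig, `+`)
    pts <- sweep(pts, 2, spacing, `*`)
    v <- vals[m, ]
    for (t in 1:6) {
      tv <- tets[t, ]
      ins <- v[tv] > 0.5
      cnt <- sum(ins)
      if (cnt == 0 || cnt == 4) next
      P <- pts[tv, , drop = FALSE]
      V <- v[tv]
      vert <- function(i, j) {       # iso crossing on edge i-j
        t <- (0.5 - V[i]) / (V[j] - V[i])
        t <- min(max(t, 0), 1)
        P[i, ] + t * (P[j, ] - P[i, ])
      }
      if (cnt == 1 || cnt == 3) {
        a <- if (cnt == 1) which(ins) else which(!ins)
        oth <- setdiff(1:4, a)
        ref <- colMeans(P[ins, , drop = FALSE])
        emit(vert(a, oth[1]), vert(a, oth[2]), vert(a, oth[3]), ref)
      } else {
        a <- which(ins); b <- which(!ins)
        m1 <- vert(a[1], b[1])
        m2 <- vert(a[1], b[2])
        m3 <- vert(a[2], b[2])
        m4 <- vert(a[2], b[1])
        ref <- colMeans(P[a, , drop = FALSE])
        emit(m1, m2, m3, ref)
        emit(m1, m3, m4, ref)
      }
    }
  }
  list(area = area, volume = abs(vol6) / 6, n_tri = n_tri)
}

max_pairwise <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- 0
  step <- 512L
  for (s in seq(1, n, by = step)) {
    blk <- pts[s:min(n, s + step - 1L), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(pts^2), `+`) -
      2 * blk %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(0, best))
}

boundary_voxels <- function(mask) {
  d <- dim(mask)
  er <- mask
  shift_and <- function(m, o) {
    out <- array(FALSE, d)
    i1 <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    j1 <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    k1 <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    out[i1, j1, k1] <- m[i1 + o[1], j1 + o[2], k1 + o[3]]
    out
  }
  interior <- mask
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & shift_and(mask, o)
  mask & !interior
}

#' Shape features of the tumor ROI
#'
#' The 14 IBSI/PyRadiomics 3D shape descriptors: mesh and voxel volume,
#' surface area, surface-to-volume ratio, sphericity, maximum 3D and
#' per-plane 2D diameters, PCA axis lengths, elongation and flatness.
#' Surface area and mesh volume come from a marching-tetrahedra
#' iso-surface of the binary mask; diameters use boundary voxel centers.
#' Masks too small to mesh (a single voxel) fall back to voxel-based
#' estimates, flagged via \code{attr(x, "voxel_fallback")}.
#'
#' @param mask 3D logical/binary array.
#' @param spacing voxel spacing in mm.
#' @return named numeric vector of 14 features (mm-based units).
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  mask <- array(mask > 0, dim(mask))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3)
  n <- sum(mask)
  voxvol <- n * prod(spacing)
  idx <- arrayInd(which(mask), dim(mask))
  pts <- sweep(idx, 2, spacing, `*`)
  ms <- mesh_surface(mask, spacing)
  fallback <- n < 2 || ms$volume <= 0
  if (fallback) {
    a_face <- 2 * (spacing[1] * spacing[2] + spacing[1] * spacing[3] +
                   spacing[2] * spacing[3]) * n
    ms <- list(area = a_face, volume = voxvol)
  }
  bidx <- arrayInd(which(boundary_voxels(mask)), dim(mask))
  bpts <- sweep(bidx, 2, spacing, `*`)
  max3d <- max_pairwise(bpts)
  plane_max <- function(fix_axis, keep) {
    vals <- unique(bidx[, fix_axis])
    m <- 0
    for (v in vals) {
      sel <- bidx[, fix_axis] == v
      if (sum(sel) >= 2)
        m <- max(m, max_pairwise(bpts[sel, keep, drop = FALSE]))
    }
    m
  }
  ev <- if (n >= 2) {
    e <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    pmax(e, 0)
  } else c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  out <- c(MeshVolume = ms$volume,
           VoxelVolume = voxvol,
           SurfaceArea = ms$area,
           SurfaceVolumeRatio = ms$area / ms$volume,
           Sphericity = (36 * pi * ms$volume^2)^(1 / 3) / ms$area,
           Maximum3DDiameter = max3d,
           Maximum2DDiameterSlice = plane_max(3, c(1, 2)),
           Maximum2DDiameterColumn = plane_max(2, c(1, 3)),
           Maximum2DDiameterRow = plane_max(1, c(2, 3)),
           MajorAxisLength = major,
           MinorAxisLength = minor,
           LeastAxisLength = least,
           Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
           Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
  attr(out, "voxel_fallback") <- fallback
  out
}

# ---- proportions and assembled vectors -------------------------------------

#' Per-habitat volume fractions
#'
#' The volume of each habitat divided by the tumor volume; sums to 1.
#'
#' @param map a \code{habitat_map} or label volume.
#' @param k number of habitats (taken from the map when available).
#' @return named numeric vector of length k.
#' @export
habitat_proportions <- function(map, k = NULL) {
  labels <- label_volume(map)
  k <- k %||% (if (inherits(map, "habitat_map")) map$k else
    max(labels))
  v <- labels[labels > 0]
  if (length(v) == 0) stop("empty ROI", call. = FALSE)
  prop <- tabulate(v, k) / length(v)
  names(prop) <- paste0("habitat_", seq_len(k))
  prop
}

#' Assemble the habitat heterogeneity feature vector
#'
#' Concatenates 4 histogram + 24 GLCM + 16 GLSZM features of the habitat
#' map and 14 shape features of the ROI (58 features), optionally followed
#' by the k habitat proportions.
#'
#' @param map a \code{habitat_map}.
#' @param mask ROI mask for the shape block (defaults to
#'   \code{map$labels > 0}).
#' @param spacing voxel spacing (defaults to the map's).
#' @param include_proportions append the habitat-proportion features.
#' @return named numeric vector (length 58, or 58 + k).
#' @export
habitat_feature_vector <- function(map, mask = NULL, spacing = NULL,
                                   include_proportions = TRUE) {
  labels <- label_volume(map)
  mask <- mask %||% (labels > 0)
  spacing <- spacing %||%
    (if (inherits(map, "habitat_map")) map$spacing else c(1, 1, 1))
  hist4 <- histogram_features(labels)
  names(hist4) <- paste0("hist_", names(hist4))
  gl <- glcm_features(labels)
  names(gl) <- paste0("glcm_", names(gl))
  gz <- glszm_features(labels)
  names(gz) <- paste0("glszm_", names(gz))
  sh <- shape_features(mask, spacing)
  fb <- attr(sh, "voxel_fallback")
  names(sh) <- paste0("shape_", names(sh))
  out <- c(hist4, gl, gz, sh)
  if (include_proportions)
    out <- c(out, habitat_proportions(map))
  attr(out, "voxel_fallback") <- fb
  out
}

#' Whole-tumor texture features of a continuous image
#'
#' Conventional radiomics comparator: the image is discretized inside the
#' ROI with a fixed bin count and the habitat-map texture machinery is
#' reused on the discretized labels.  The default panel emits the 24 GLCM
#' features per image (three images per analysis give the 72-feature
#' comparator panels); \code{panel = "all"} adds GLSZM and histogram
#' blocks.
#'
#' @param image 3D numeric array.
#' @param roi 3D logical mask.
#' @param n_bins fixed bin count (default 32).
#' @param panel \code{"glcm"} or \code{"all"}.
#' @return named numeric vector.
#' @export
whole_tumor_features <- function(image, roi, n_bins = 32,
                                 panel = c("glcm", "all")) {
  panel <- match.arg(panel)
  stopifnot_volume(image)
  roi <- array(roi > 0, dim(roi))
  v <- image[roi]
  if (length(v) == 0) stop("empty ROI", call. = FALSE)
  lo <- min(v); hi <- max(v)
  labels <- array(0L, dim(image))
  if (lo == hi) {
    warning("constant image inside ROI; degenerate single-bin discretization",
            call. = FALSE)
    labels[roi] <- 1L
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1)
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    labels[roi] <- pmin(pmax(idx, 1L), n_bins)
  }
  gl <- glcm_features(labels)
  names(gl) <- paste0("glcm_", names(gl))
  if (panel == "glcm") return(gl)
  gz <- glszm_features(labels)
  names(gz) <- paste0("glszm_", names(gz))
  h <- histogram_features(labels)
  names(h) <- paste0("hist_", names(h))
  c(h, gl, gz)
}

#' Z-score features using development-cohort statistics
#'
#' Normalizes each feature as \eqn{(x - \mu)/\sigma} with mean and SD taken
#' from the development cohort; a validation cohort must be normalized with
#' the development statistics, never its own.  Constant features
#' (\eqn{\sigma = 0}) are dropped with a warning.
#'
#' @param x numeric matrix (patients x features) with column names.
#' @param stats optional statistics from a previous call (its
#'   \code{"zstats"} attribute or the list itself); when \code{NULL}, the
#'   statistics are computed from \code{x} and attached to the result.
#' @return normalized matrix with attribute \code{"zstats"} (list with
#'   \code{mean}, \code{sd}, \code{features}).
#' @export
z_score_normalize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("features must be named", call. = FALSE)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    drop <- sd == 0 | !is.finite(sd)
    if (any(drop))
      warning("dropping constant feature(s): ",
              paste(colnames(x)[drop], collapse = ", "), call. = FALSE)
    stats <- list(mean = mu[!drop], sd = sd[!drop],
                  features = colnames(x)[!drop])
  } else if (!is.null(attr(stats, "zstats"))) {
    stats <- attr(stats, "zstats")
  }
  miss <- setdiff(stats$features, colnames(x))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  z <- sweep(sweep(x[, stats$features, drop = FALSE], 2, stats$mean),
             2, stats$sd, `/`)
  attr(z, "zstats") <- stats
  z
}
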