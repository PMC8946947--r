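# Shape descriptors. The 3D surface is meshed by marching tetrahedra on the
# binary ROI (iso-level 0.5, so mesh vertices sit at voxel-edge midpoints);
# the 2D boundary of the largest axial slice by marching squares. Case
# tables are built programmatically with numerically checked outward
# orientation, and per-cell contributions are accumulated in closed form so
# the whole mesh is never materialized.

cube_tets <- function() {
  # 6-tetrahedra decomposition of the unit cube around the 000-111 diagonal
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  v <- function(x, y, z) which(corners[, 1] == x & corners[, 2] == y &
                                 corners[, 3] == z)
  tets <- rbind(c(v(0,0,0), v(1,0,0), v(1,1,0), v(1,1,1)),
                c(v(0,0,0), v(1,1,0), v(0,1,0), v(1,1,1)),
                c(v(0,0,0), v(0,1,0), v(0,1,1), v(1,1,1)),
                c(v(0,0,0), v(0,1,1), v(0,0,1), v(1,1,1)),
                c(v(0,0,0), v(0,0,1), v(1,0,1), v(1,1,1)),
                c(v(0,0,0), v(1,0,1), v(1,0,0), v(1,1,1)))
  list(corners = corners, tets = tets)
}

orient_outward <- function(tri, inside_centroid) {
  n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  if (sum(n * (inside_centroid - colMeans(tri))) > 0) tri[c(1, 3, 2), ] else tri
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

tet_case_edges <- function(inside) {
  # triangles as ordered triples of corner-pair edges; orientation fixed at
  # the canonical (midpoint) configuration so normals point outward
  k <- sum(inside)
  if (k == 0 || k == 4) return(list())
  if (k == 1 || k == 3) {
    apex <- if (k == 1) which(inside) else which(!inside)
    others <- setdiff(1:4, apex)
    list(lapply(others, function(o) c(apex, o)))
  } else {
    ins <- which(inside); outs <- which(!inside)
    list(list(c(ins[1], outs[1]), c(ins[1], outs[2]), c(ins[2], outs[2])),
         list(c(ins[1], outs[1]), c(ins[2], outs[2]), c(ins[2], outs[1])))
  }
}

build_tet_tables <- function(spacing) {
  ct <- cube_tets()
  tabs <- vector("list", 6)
  for (t in 1:6) {
    verts <- sweep(ct$corners[ct$tets[t, ], , drop = FALSE], 2, spacing, `*`)
    cases <- vector("list", 16)
    for (code in 1:14) {
      inside <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L)))
      tris <- tet_case_edges(inside)
      cin <- colMeans(verts[inside, , drop = FALSE])
      tris <- lapply(tris, function(tri) {
        mids <- t(vapply(tri, function(e) (verts[e[1], ] + verts[e[2], ]) / 2,
                         numeric(3)))
        n <- pracma_cross(mids[2, ] - mids[1, ], mids[3, ] - mids[1, ])
        if (sum(n * (cin - colMeans(mids))) > 0) tri[c(1, 3, 2)] else tri
      })
      cases[[code + 1]] <- tris
    }
    tabs[[t]] <- list(corners = ct$tets[t, ], verts = verts, cases = cases)
  }
  tabs
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

mesh_area_volume <- function(sel, spacing, iso = 0.5, smooth_passes = 2) {
  # surface of the lightly smoothed indicator field at iso-level 0.5 via
  # marching tetrahedra with linear edge interpolation; pad generously so
  # the smoothed field decays to 0 before the array edge
  pad <- smooth_passes + 1L
  d <- dim(sel) + 2L * pad
  B <- array(0, d)
  B[(pad + 1):(d[1] - pad), (pad + 1):(d[2] - pad),
    (pad + 1):(d[3] - pad)] <- sel
  for (p in seq_len(smooth_passes)) B <- smooth3(B)
  nc <- d - 1L
  corner_vals <- function(off) {
    as.numeric(B[off[1]:(off[1] + nc[1] - 1),
                 off[2]:(off[2] + nc[2] - 1),
                 off[3]:(off[3] + nc[3] - 1)])
  }
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  vals <- lapply(seq_len(8), function(k) corner_vals(corners[k, ] + 1L))
  idx <- which(array(TRUE, nc), arr.ind = TRUE)
  origin <- sweep(idx - 1L, 2, spacing, `*`)
  tabs <- build_tet_tables(spacing)
  area <- 0; vol6 <- 0
  for (t in 1:6) {
    cv <- tabs[[t]]$corners
    verts <- tabs[[t]]$verts
    ins <- lapply(cv, function(k) vals[[k]] > iso)
    code <- ins[[1]] + 2L * ins[[2]] + 4L * ins[[3]] + 8L * ins[[4]]
    for (cd in 1:14) {
      cells <- which(code == cd)
      if (!length(cells)) next
      fv <- lapply(1:4, function(k) vals[[cv[k]]][cells])
      o <- origin[cells, , drop = FALSE]
      edge_pos <- function(e) {
        a <- fv[[e[1]]]; b <- fv[[e[2]]]
        tt <- (iso - a) / (b - a)
        outer(rep(1, length(tt)), verts[e[1], ]) +
          tt * outer(rep(1, length(tt)), verts[e[2], ] - verts[e[1], ])
      }
      for (tri in tabs[[t]]$cases[[cd + 1]]) {
        r1 <- edge_pos(tri[[1]]); r2 <- edge_pos(tri[[2]])
        r3 <- edge_pos(tri[[3]])
        n <- row_cross(r2 - r1, r3 - r1)
        area <- area + sum(sqrt(rowSums(n^2))) / 2
        det0 <- rowSums(r1 * row_cross(r2, r3))
        vol6 <- vol6 + sum(det0) + sum(o * n)
      }
    }
  }
  list(area = area, volume = vol6 / 6)
}

square_case_segments <- function(inside) {
  # unit-square corners in cycle order (0,0),(1,0),(1,1),(0,1)
  verts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  k <- sum(inside)
  if (k == 0 || k == 4) return(list())
  segs <- list()
  orient2 <- function(a, b, cin) {
    if ((b[1] - a[1]) * (cin[2] - a[2]) - (b[2] - a[2]) * (cin[1] - a[1]) > 0)
      rbind(a, b) else rbind(b, a)
  }
  mid <- function(e) (verts[edges[e, 1], ] + verts[edges[e, 2], ]) / 2
  cut <- which(xor(inside[edges[, 1]], inside[edges[, 2]]))
  if (length(cut) == 2) {
    cin <- colMeans(verts[inside, , drop = FALSE])
    segs[[1]] <- orient2(mid(cut[1]), mid(cut[2]), cin)
  } else {
    # two diagonal inside corners: cut each off separately
    for (ci in which(inside)) {
      adj <- which(edges[, 1] == ci | edges[, 2] == ci)
      segs[[length(segs) + 1]] <- orient2(mid(adj[1]), mid(adj[2]),
                                          verts[ci, ])
    }
  }
  segs
}

slice_perimeter_area <- function(sel2, spacing2) {
  d <- dim(sel2) + 2L
  B <- matrix(0L, d[1], d[2])
  B[2:(d[1] - 1), 2:(d[2] - 1)] <- sel2
  nc <- d - 1L
  v00 <- as.integer(B[1:nc[1], 1:nc[2]])
  v10 <- as.integer(B[2:d[1], 1:nc[2]])
  v11 <- as.integer(B[2:d[1], 2:d[2]])
  v01 <- as.integer(B[1:nc[1], 2:d[2]])
  code <- v00 + 2L * v10 + 4L * v11 + 8L * v01
  idx <- which(matrix(TRUE, nc[1], nc[2]), arr.ind = TRUE)
  origin <- sweep(idx - 1L, 2, spacing2, `*`)
  per <- 0; a2 <- 0
  cases <- lapply(0:15, function(cd)
    square_case_segments(as.logical(bitwAnd(cd, c(1L, 2L, 4L, 8L)))))
  active <- code > 0L & code < 15L
  if (any(active)) {
    code_a <- code[active]
    cnt <- tabulate(code_a, 15L)
    osum <- rowsum(origin[active, , drop = FALSE], code_a)
    for (ci in seq_along(rownames(osum))) {
      cd <- as.integer(rownames(osum))[ci]
      for (seg in cases[[cd + 1]]) {
        s <- sweep(seg, 2, spacing2, `*`)
        a <- s[1, ]; b <- s[2, ]
        per <- per + cnt[cd] * sqrt(sum((b - a)^2))
        # Green's theorem: 2A = sum cross(a, b); translation adds
        # cross(o, b - a) per segment
        a2 <- a2 + cnt[cd] * (a[1] * b[2] - a[2] * b[1]) +
          osum[ci, 1] * (b[2] - a[2]) - osum[ci, 2] * (b[1] - a[1])
      }
    }
  }
  list(perimeter = per, area = a2 / 2)
}

boundary_voxels <- function(sel) {
  d <- dim(sel)
  inner <- sel
  shift_and <- function(s, off) {
    out <- array(FALSE, d)
    src <- lapply(1:3, function(k) {
      i <- seq_len(d[k]) + off[k]
      i[i >= 1 & i <= d[k]]
    })
    dst <- lapply(1:3, function(k) {
      i <- seq_len(d[k])
      i[i + off[k] >= 1 & i + off[k] <= d[k]]
    })
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      s[src[[1]], src[[2]], src[[3]], drop = FALSE]
    out
  }
  all6 <- sel
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    all6 <- all6 & shift_and(sel, off)
  }
  sel & !all6
}

max_pairwise_dist <- function(coords) {
  if (nrow(coords) < 2) return(0)
  # distance to the centroid prunes candidates before the quadratic scan
  if (nrow(coords) > 1500) {
    ctr <- colMeans(coords)
    r <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
    coords <- coords[r >= stats::quantile(r, 0.6), , drop = FALSE]
  }
  g <- tcrossprod(coords)
  sq <- diag(g)
  sqrt(max(outer(sq, sq, `+`) - 2 * g))
}

#' Shape descriptors of one structure
#'
#' The 16-feature 3D set (marching-tetrahedra mesh volume and surface area,
#' sphericity and compactness, PCA axis lengths, maximum diameters) plus the
#' 10-feature 2D set evaluated on the largest-area axial slice. Maximum
#' diameters are measured between boundary-voxel centers.
#'
#' @param mask a [label_mask()].
#' @param structure structure name.
#' @return named numeric vector of 26 features (prefixes `shape_`,
#'   `shape2D_`).
#' @export
shape_features <- function(mask, structure = "putamen") {
  sel <- structure_mask(mask, structure)
  if (!any(sel)) stop("empty structure '", structure, "'")
  spacing <- mask$grid$spacing
  cr <- crop_to_roi(sel, sel)
  sel <- cr$sel
  mesh <- mesh_area_volume(sel, spacing)
  if (mesh$volume <= 0 || mesh$area <= 0) {
    # ROIs of a few voxels vanish under pre-smoothing; mesh them binary
    mesh <- mesh_area_volume(sel, spacing, smooth_passes = 0)
  }
  A <- mesh$area; V <- mesh$volume
  n <- sum(sel)
  coords <- sweep(which(sel, arr.ind = TRUE), 2, spacing, `*`)
  cov3 <- if (n > 1) stats::cov(coords) * (n - 1) / n else matrix(0, 3, 3)
  ev <- sort(pmax(eigen(cov3, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  bsel <- boundary_voxels(sel)
  bc <- sweep(which(bsel, arr.ind = TRUE), 2, spacing, `*`)
  bidx <- which(bsel, arr.ind = TRUE)
  max_plane <- function(drop_axis) {
    keep <- setdiff(1:3, drop_axis)
    planes <- split.data.frame(bc[, keep, drop = FALSE], bidx[, drop_axis])
    max(vapply(planes, function(p) max_pairwise_dist(as.matrix(p)),
               numeric(1)))
  }
  out3 <- c(MeshVolume = V,
            VoxelVolume = n * prod(spacing),
            SurfaceArea = A,
            SurfaceVolumeRatio = A / V,
            Sphericity = (36 * pi * V^2)^(1 / 3) / A,
            Compactness1 = V / (sqrt(pi) * A^1.5),
            Compactness2 = 36 * pi * V^2 / A^3,
            Maximum3DDiameter = max_pairwise_dist(bc),
            Maximum2DDiameterSlice = max_plane(3),
            Maximum2DDiameterColumn = max_plane(1),
            Maximum2DDiameterRow = max_plane(2),
            MajorAxisLength = 4 * sqrt(ev[1]),
            MinorAxisLength = 4 * sqrt(ev[2]),
            LeastAxisLength = 4 * sqrt(ev[3]),
            Elongation = if (ev[1] == 0) 0 else sqrt(ev[2] / ev[1]),
            Flatness = if (ev[1] == 0) 0 else sqrt(ev[3] / ev[1]))
  names(out3) <- paste0("shape_", names(out3))
  # 2D set on the largest axial slice
  zcounts <- apply(sel, 3, sum)
  z <- which.max(zcounts)
  s2 <- sel[, , z, drop = FALSE]
  dim(s2) <- dim(sel)[1:2]
  sp2 <- spacing[1:2]
  pa <- slice_perimeter_area(s2, sp2)
  n2 <- sum(s2)
  c2 <- sweep(which(s2, arr.ind = TRUE), 2, sp2, `*`)
  cov2 <- if (n2 > 1) stats::cov(c2) * (n2 - 1) / n2 else matrix(0, 2, 2)
  e2 <- sort(pmax(eigen(cov2, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  b2 <- s2
  if (n2 > 1) {
    full <- array(FALSE, c(dim(s2), 1)); full[, , 1] <- s2
    b2 <- boundary_voxels(full)[, , 1]
  }
  bc2 <- sweep(which(b2, arr.ind = TRUE), 2, sp2, `*`)
  sph2 <- if (pa$perimeter == 0) 0 else
    2 * sqrt(pi * pa$area) / pa$perimeter
  out2 <- c(MeshSurface = pa$area,
            PixelSurface = n2 * prod(sp2),
            Perimeter = pa$perimeter,
            PerimeterSurfaceRatio = if (pa$area == 0) NA_real_ else
              pa$perimeter / pa$area,
            Sphericity = sph2,
            SphericalDisproportion = if (sph2 == 0) NA_real_ else 1 / sph2,
            MaximumDiameter = max_pairwise_dist(bc2),
            MajorAxisLength = 4 * sqrt(e2[1]),
            MinorAxisLength = 4 * sqrt(e2[2]),
            Elongation = if (e2[1] == 0) 0 else sqrt(e2[2] / e2[1]))
  names(out2) <- paste0("shape2D_", names(out2))
  c(out3, out2)
}
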