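#' Polyline arc on a surface
#'
#' An ordered 3D polyline with cumulative arc length, the carrier for
#' sagittal/coronal contour cuts and their sub-arcs.  Consecutive duplicate
#' points (closer than `1e-9` times the polyline extent) are merged.
#'
#' @param points `n x 3` matrix of ordered points (mm).
#' @param closed Logical; `TRUE` when the polyline is a loop (the segment from
#'   the last point back to the first is implied, not repeated).
#' @return An object of class `polyline_arc` with elements `points`, `closed`,
#'   `cumlen` (cumulative length up to each point, starting at 0) and `total`
#'   (total length including the closing segment when `closed`).
#' @export
polyline_arc <- function(points, closed = FALSE) {
  points <- as_points_matrix(points, "arc points")
  if (nrow(points) < 2L) stop("an arc needs at least 2 points", call. = FALSE)
  rng <- apply(points, 2L, range)
  scale <- max(vnorm(rng[2L, ] - rng[1L, ]), .Machine$double.eps)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-9 * scale)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) stop("arc degenerates to a single point", call. = FALSE)
  if (closed && vnorm(points[nrow(points), ] - points[1L, ]) <= 1e-9 * scale) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  cumlen <- c(0, cumsum(seg))
  total <- if (closed) {
    cumlen[length(cumlen)] + vnorm(points[nrow(points), ] - points[1L, ])
  } else {
    cumlen[length(cumlen)]
  }
  structure(list(points = points, closed = isTRUE(closed),
                 cumlen = cumlen, total = total),
            class = "polyline_arc")
}

#' @export
print.polyline_arc <- function(x, ...) {
  cat(sprintf("<polyline_arc> %d points, %s, length %.4g\n",
              nrow(x$points), if (x$closed) "closed" else "open", x$total))
  invisible(x)
}

#' Total length of an arc
#' @param arc A [polyline_arc()].
#' @return Numeric scalar (mm).
#' @export
arc_length <- function(arc) {
  stopifnot(inherits(arc, "polyline_arc"))
  arc$total
}

#' Reverse the traversal direction of an arc
#' @param arc A [polyline_arc()].
#' @return A [polyline_arc()] with the same points in opposite order.
#' @export
arc_reverse <- function(arc) {
  stopifnot(inherits(arc, "polyline_arc"))
  polyline_arc(arc$points[rev(seq_len(nrow(arc$points))), , drop = FALSE],
               closed = arc$closed)
}

# Point at arc-length coordinate s (wrapping when closed).
arc_point_at <- function(arc, s) {
  if (arc$closed) s <- s %% arc$total
  s <- min(max(s, 0), arc$total)
  pts <- arc$points
  n <- nrow(pts)
  idx <- findInterval(s, arc$cumlen, rightmost.closed = FALSE)
  if (idx >= n) {
    if (!arc$closed) return(pts[n, ])
    a <- pts[n, ]; b <- pts[1L, ]
    s0 <- arc$cumlen[n]
  } else {
    a <- pts[idx, ]; b <- pts[idx + 1L, ]
    s0 <- arc$cumlen[idx]
  }
  seglen <- vnorm(b - a)
  if (seglen == 0) return(a)
  a + (b - a) * ((s - s0) / seglen)
}

# Orthogonal projection of p onto the polyline: returns the arc-length
# coordinate of the closest point and its distance.
arc_project <- function(arc, p) {
  p <- as_point3(p)
  pts <- arc$points
  n <- nrow(pts)
  ia <- seq_len(if (arc$closed) n else n - 1L)
  ib <- c(seq_len(n)[-1L], 1L)[ia]
  a <- pts[ia, , drop = FALSE]
  d <- pts[ib, , drop = FALSE] - a
  seg2 <- rowSums(d^2)
  ap <- sweep(-a, 2L, p, "+")
  tt <- pmin(pmax(rowSums(ap * d) / pmax(seg2, .Machine$double.eps), 0), 1)
  q <- a + d * tt
  dist2 <- rowSums((q - matrix(p, n_seg <- length(ia), 3L, byrow = TRUE))^2)
  k <- which.min(dist2)
  s <- arc$cumlen[k] + tt[k] * sqrt(seg2[k])
  list(s = s, distance = sqrt(dist2[k]), point = q[k, ])
}

#' Ray-mesh intersection
#'
#' Casts a ray from `origin` along `direction` and returns the nearest or
#' farthest intersection with the mesh surface (Moller-Trumbore test over all
#' faces).  Hits with ray parameter `t <= t_min` are rejected so a ray whose
#' origin lies on the surface does not return its own start point.
#'
#' @param mesh A [tri_mesh()].
#' @param origin,direction Numeric 3-vectors; `direction` need not be unit
#'   length but must be nonzero.
#' @param select `"farthest"` or `"nearest"` hit along the ray.
#' @param t_min Minimum admissible ray parameter, in mm along the normalized
#'   direction (default `1e-9`).
#' @return The intersection point as a numeric 3-vector.
#' @export
#' @examples
#' s <- sphere_mesh(1, 3)
#' ray_mesh_intersect(s, c(0, 0, 0), c(1, 0, 0), "farthest")
ray_mesh_intersect <- function(mesh, origin, direction,
                               select = c("farthest", "nearest"),
                               t_min = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  select <- match.arg(select)
  origin <- as_point3(origin, "ray origin")
  direction <- unitize(as_point3(direction, "ray direction"), "ray direction")
  v <- mesh$vertices; f <- mesh$faces
  p0 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - p0
  e2 <- v[f[, 3L], , drop = FALSE] - p0
  h <- cbind(direction[2L] * e2[, 3L] - direction[3L] * e2[, 2L],
             direction[3L] * e2[, 1L] - direction[1L] * e2[, 3L],
             direction[1L] * e2[, 2L] - direction[2L] * e2[, 1L])
  det <- rowSums(e1 * h)
  s <- sweep(-p0, 2L, origin, "+")
  q <- cbind(s[, 2L] * e1[, 3L] - s[, 3L] * e1[, 2L],
             s[, 3L] * e1[, 1L] - s[, 1L] * e1[, 3L],
             s[, 1L] * e1[, 2L] - s[, 2L] * e1[, 1L])
  eps_det <- 1e-12 * max(abs(det))
  ok <- abs(det) > eps_det
  u <- rowSums(s * h) / det
  w <- (q[, 1L] * direction[1L] + q[, 2L] * direction[2L] +
          q[, 3L] * direction[3L]) / det
  tt <- rowSums(e2 * q) / det
  bar_eps <- 1e-9
  ok <- ok & is.finite(u) & is.finite(w) & is.finite(tt) &
    u >= -bar_eps & w >= -bar_eps & (u + w) <= 1 + bar_eps & tt > t_min
  if (!any(ok)) stop("ray misses surface", call. = FALSE)
  t_hit <- if (select == "farthest") max(tt[ok]) else min(tt[ok])
  origin + direction * t_hit
}

#' Plane-mesh intersection contour
#'
#' Cuts the mesh with a plane and returns the single connected intersection
#' contour closest to `anchor`, as an ordered polyline.  Plane-edge crossings
#' are computed once per mesh edge (and on-plane vertices kept as exact
#' nodes), so segments from adjacent triangles stitch exactly; vertices lying
#' in the cutting plane are handled without duplication.
#'
#' @param mesh A [tri_mesh()].
#' @param plane_point,plane_normal Plane through `plane_point` with normal
#'   `plane_normal` (nonzero).
#' @param anchor 3D point selecting the contour component: the component with
#'   the smallest distance to `anchor` is returned (ties broken by larger
#'   total length).
#' @param anchor_tol Maximum admissible anchor-to-contour distance, as a
#'   fraction of the mesh bounding-box diagonal (default 0.25).
#' @return A [polyline_arc()]; `closed` is set when the contour is a loop.
#' @export
plane_mesh_contour <- function(mesh, plane_point, plane_normal, anchor,
                               anchor_tol = 0.25) {
  stopifnot(inherits(mesh, "tri_mesh"))
  plane_point <- as_point3(plane_point, "plane point")
  normal <- unitize(as_point3(plane_normal, "plane normal"), "plane normal")
  anchor <- as_point3(anchor, "anchor")
  v <- mesh$vertices; f <- mesh$faces
  diag_len <- mesh_bbox_diag(mesh)
  tol <- 1e-9 * diag_len
  d <- drop(sweep(v, 2L, plane_point) %*% normal)
  sgn <- ifelse(abs(d) <= tol, 0L, ifelse(d > 0, 1L, -1L))
  s1 <- sgn[f[, 1L]]; s2 <- sgn[f[, 2L]]; s3 <- sgn[f[, 3L]]
  nz <- (s1 == 0L) + (s2 == 0L) + (s3 == 0L)
  np <- (s1 > 0L) + (s2 > 0L) + (s3 > 0L)
  nn <- (s1 < 0L) + (s2 < 0L) + (s3 < 0L)
  cand <- which((np > 0L & nn > 0L) | (nz == 2L & (np + nn) == 1L))
  if (length(cand) == 0L) stop("plane misses mesh", call. = FALSE)

  # Node ids: "v<i>" for an on-plane vertex, "e<i>_<j>" for an edge crossing.
  edge_key <- function(i, j) paste0("e", min(i, j), "_", max(i, j))
  node_pos <- new.env(parent = emptyenv())
  vertex_node <- function(i) {
    key <- paste0("v", i)
    if (is.null(node_pos[[key]])) node_pos[[key]] <- v[i, ]
    key
  }
  crossing_node <- function(i, j) {
    key <- edge_key(i, j)
    if (is.null(node_pos[[key]])) {
      a <- min(i, j); b <- max(i, j)
      tt <- d[a] / (d[a] - d[b])
      node_pos[[key]] <- v[a, ] + (v[b, ] - v[a, ]) * tt
    }
    key
  }
  seg_from <- character(0); seg_to <- character(0)
  for (k in cand) {
    idx <- f[k, ]
    s <- sgn[idx]
    zero <- idx[s == 0L]
    pos <- idx[s > 0L]
    neg <- idx[s < 0L]
    nodes <- NULL
    if (length(zero) == 2L) {
      nodes <- c(vertex_node(zero[1L]), vertex_node(zero[2L]))
    } else if (length(zero) == 1L && length(pos) == 1L && length(neg) == 1L) {
      nodes <- c(vertex_node(zero[1L]), crossing_node(pos[1L], neg[1L]))
    } else if (length(zero) == 0L) {
      if (length(pos) == 1L) {
        nodes <- c(crossing_node(pos[1L], neg[1L]), crossing_node(pos[1L], neg[2L]))
      } else {
        nodes <- c(crossing_node(neg[1L], pos[1L]), crossing_node(neg[1L], pos[2L]))
      }
    }
    if (!is.null(nodes) && nodes[1L] != nodes[2L]) {
      seg_from <- c(seg_from, nodes[1L]); seg_to <- c(seg_to, nodes[2L])
    }
  }
  if (length(seg_from) == 0L) stop("plane misses mesh", call. = FALSE)
  # Deduplicate segments shared between adjacent faces.
  key <- ifelse(seg_from < seg_to,
                paste(seg_from, seg_to), paste(seg_to, seg_from))
  keep <- !duplicated(key)
  seg_from <- seg_from[keep]; seg_to <- seg_to[keep]

  # Build adjacency and walk chains/loops.
  nodes <- unique(c(seg_from, seg_to))
  adj <- new.env(parent = emptyenv())
  for (i in seq_along(seg_from)) {
    adj[[seg_from[i]]] <- c(adj[[seg_from[i]]], seg_to[i])
    adj[[seg_to[i]]] <- c(adj[[seg_to[i]]], seg_from[i])
  }
  degree <- vapply(nodes, function(nm) length(adj[[nm]]), integer(1L))
  if (any(degree > 2L)) {
    stop("non-manifold plane contour (branching intersection)", call. = FALSE)
  }
  visited <- new.env(parent = emptyenv())
  # Walk a chain starting at `start`; returns node names in order plus a
  # closed flag (TRUE when the walk returns to `start`).
  walk_chain <- function(start) {
    visited[[start]] <- TRUE
    chain <- start
    prev <- ""
    cur <- start
    closed <- FALSE
    repeat {
      nbrs <- setdiff(adj[[cur]], prev)
      nxt <- NULL
      for (nb in nbrs) {
        if (nb == start && length(chain) > 2L) { closed <- TRUE; break }
        if (is.null(visited[[nb]])) { nxt <- nb; break }
      }
      if (closed || is.null(nxt)) break
      visited[[nxt]] <- TRUE
      chain <- c(chain, nxt)
      prev <- cur
      cur <- nxt
    }
    list(chain = chain, closed = closed)
  }
  components <- list()
  # Open chains first (from degree-1 endpoints), then remaining loops.
  for (start in c(nodes[degree == 1L], nodes[degree == 2L])) {
    if (!is.null(visited[[start]])) next
    res <- walk_chain(start)
    if (length(res$chain) >= 2L) {
      pts <- do.call(rbind, lapply(res$chain, function(nm) node_pos[[nm]]))
      components[[length(components) + 1L]] <-
        list(points = pts, closed = res$closed)
    }
  }
  if (length(components) == 0L) stop("plane misses mesh", call. = FALSE)
  arcs <- lapply(components, function(cm) polyline_arc(cm$points, cm$closed))
  dists <- vapply(arcs, function(a) arc_project(a, anchor)$distance, numeric(1L))
  lens <- vapply(arcs, arc_length, numeric(1L))
  if (min(dists) > anchor_tol * diag_len) {
    stop("anchor is farther than tolerance from every contour component",
         call. = FALSE)
  }
  best <- order(dists, -lens)[1L]
  arcs[[best]]
}

#' Extract the sub-arc between two points, passing near a third
#'
#' Returns the open sub-arc of `contour` running from the contour point
#' closest to `start` to the point closest to `end`, traversed in the
#' direction that passes closest to `via`.  Endpoints are projected onto the
#' polyline (not snapped to vertices).
#'
#' @param contour A [polyline_arc()] (open or closed).
#' @param start,via,end 3D points, each within `point_tol` (fraction of the
#'   contour length) of the contour.
#' @param point_tol Maximum admissible point-to-contour distance as a fraction
#'   of total contour length (default 0.25).
#' @return An open [polyline_arc()] from `start` to `end`.
#' @export
arc_between <- function(contour, start, via, end, point_tol = 0.25) {
  stopifnot(inherits(contour, "polyline_arc"))
  pr_s <- arc_project(contour, start)
  pr_v <- arc_project(contour, via)
  pr_e <- arc_project(contour, end)
  max_d <- point_tol * contour$total
  if (pr_s$distance > max_d || pr_v$distance > max_d || pr_e$distance > max_d) {
    stop("start/via/end must lie within tolerance of the contour", call. = FALSE)
  }
  tol <- 1e-9 * contour$total
  if (abs(pr_s$s - pr_e$s) <= tol ||
      (contour$closed && abs(abs(pr_s$s - pr_e$s) - contour$total) <= tol)) {
    stop("zero-length arc: start equals end on the contour", call. = FALSE)
  }
  extract <- function(s0, s1, forward) {
    # Walk from s0 to s1 in the given direction (wrapping when closed).
    total <- contour$total
    len <- if (forward) (s1 - s0) %% total else (s0 - s1) %% total
    if (!contour$closed) {
      len <- abs(s1 - s0)
      if ((forward && s1 < s0) || (!forward && s1 > s0)) return(NULL)
    }
    # Interior vertices strictly between s0 and s1 along the walk.
    svals <- contour$cumlen
    if (contour$closed) {
      rel <- if (forward) (svals - s0) %% total else (s0 - svals) %% total
    } else {
      rel <- if (forward) svals - s0 else s0 - svals
    }
    inside <- which(rel > tol & rel < len - tol)
    inside <- inside[order(rel[inside])]
    pts <- rbind(arc_point_at(contour, s0),
                 contour$points[inside, , drop = FALSE],
                 arc_point_at(contour, s1))
    list(arc = polyline_arc(pts, closed = FALSE), length = len)
  }
  via_inside <- function(s0, s1, forward, sv) {
    total <- contour$total
    if (contour$closed) {
      len <- if (forward) (s1 - s0) %% total else (s0 - s1) %% total
      rel <- if (forward) (sv - s0) %% total else (s0 - sv) %% total
      rel <= len + tol
    } else {
      if (forward) sv >= s0 - tol && sv <= s1 + tol
      else sv <= s0 + tol && sv >= s1 - tol
    }
  }
  fwd_ok <- via_inside(pr_s$s, pr_e$s, TRUE, pr_v$s)
  bwd_ok <- via_inside(pr_s$s, pr_e$s, FALSE, pr_v$s)
  if (!contour$closed) {
    fwd_ok <- fwd_ok && pr_e$s > pr_s$s
    bwd_ok <- bwd_ok && pr_e$s < pr_s$s
  }
  if (!fwd_ok && !bwd_ok) {
    stop("via point does not lie between start and end on either traversal",
         call. = FALSE)
  }
  forward <- if (fwd_ok && bwd_ok) {
    # Both traversals contain via (possible on closed loops when via sits at
    # an endpoint); pick the shorter one through via.
    dv_f <- (pr_v$s - pr_s$s) %% contour$total
    dv_b <- (pr_s$s - pr_v$s) %% contour$total
    dv_f <= dv_b
  } else {
    fwd_ok
  }
  extract(pr_s$s, pr_e$s, forward)$arc
}

#' Subdivide an arc at cumulative length fractions
#'
#' Returns points at the stated cumulative arc-length fractions, linearly
#' interpolated within polyline segments.  Fraction 0 maps to the first point
#' and fraction 1 to the last point exactly.
#'
#' @param arc A [polyline_arc()] with positive length.
#' @param fractions Numeric vector of fractions in `[0, 1]`.
#' @return A `length(fractions) x 3` matrix of points.
#' @export
#' @examples
#' a <- polyline_arc(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
#' subdivide_arc(a, c(0.25, 0.5, 1))
subdivide_arc <- function(arc, fractions) {
  stopifnot(inherits(arc, "polyline_arc"))
  if (arc$total <= 0) stop("arc has zero length", call. = FALSE)
  fractions <- as.numeric(fractions)
  if (length(fractions) == 0L) return(matrix(numeric(0), 0L, 3L))
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    stop("fractions must lie within [0, 1]", call. = FALSE)
  }
  out <- matrix(0, length(fractions), 3L)
  n <- nrow(arc$points)
  for (i in seq_along(fractions)) {
    fr <- fractions[i]
    out[i, ] <- if (fr == 0) {
      arc$points[1L, ]
    } else if (fr == 1 && !arc$closed) {
      arc$points[n, ]
    } else {
      arc_point_at(arc, fr * arc$total)
    }
  }
  out
}
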