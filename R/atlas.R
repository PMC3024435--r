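#' Named polygon atlas
#'
#' A cortical atlas as a set of named simple polygons in atlas
#' coordinates, plus two midline landmarks: the junction between the
#' olfactory bulb and the cerebrum, and the fissure between the cerebrum
#' and the superior colliculus (lambda). The two landmarks anchor the
#' similarity transform into image coordinates. Gaps between polygons are
#' intentional; pixels falling in a gap stay unassigned.
#'
#' @param regions named list of n x 2 matrices (columns row, col — or any
#'   planar coordinates) with at least 3 vertices each.
#' @param landmarks 2 x 2 matrix, one landmark per row, in the same
#'   coordinates.
#' @return object of class `polygon_atlas`.
#' @export
polygon_atlas <- function(regions, landmarks) {
  landmarks <- as.matrix(landmarks)
  if (!is.list(regions) || is.null(names(regions)) || length(regions) == 0)
    stop_fcois("regions must be a named list of polygons",
               class = "fcois_input_error")
  regions <- lapply(regions, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 3) stop_fcois("polygons need at least 3 vertices",
                                class = "fcois_input_error")
    if (!polygon_is_simple(p))
      stop_fcois("polygon is self-intersecting", class = "fcois_input_error")
    p
  })
  if (nrow(landmarks) != 2 || all(landmarks[1, ] == landmarks[2, ]))
    stop_fcois("two distinct landmarks required", class = "fcois_input_error")
  structure(list(regions = regions, landmarks = landmarks),
            class = "polygon_atlas")
}

# Simplicity check: no two non-adjacent edges intersect.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Read a polygon atlas from JSON
#'
#' Expected structure: `regions` as a map from region name to a list of
#' `[row, col]` vertex pairs, and `landmarks` as two `[row, col]` pairs
#' (olfactory-cerebrum junction first, lambda second).
#'
#' @param path JSON file.
#' @return a [polygon_atlas()].
#' @export
read_polygon_atlas <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  regions <- lapply(cfg$regions, function(v) {
    m <- if (is.matrix(v)) v else do.call(rbind, v)
    storage.mode(m) <- "double"
    m
  })
  lm <- cfg$landmarks
  if (!is.matrix(lm)) lm <- do.call(rbind, lm)
  polygon_atlas(regions, lm)
}

#' Schematic demonstration atlas
#'
#' A synthetic schematic atlas bundled for tests and demonstrations: simple
#' polygons named after the major dorsal-cortex regions, with intentional
#' gaps between them and the two midline landmarks. It is not a digitized
#' histological atlas; users supply real atlases as JSON.
#'
#' @return a [polygon_atlas()].
#' @export
schematic_atlas <- function() {
  read_polygon_atlas(system.file("extdata", "atlas_schematic.json",
                                 package = "fcois"))
}

#' Fit the two-landmark similarity transform
#'
#' The unique similarity transform (rotation, uniform scale, translation)
#' mapping the two atlas landmarks exactly onto the two image landmarks.
#' Using a single stretch component means the anterior-posterior scale is
#' also used medial-laterally, so circles map to circles.
#'
#' @param src 2 x 2 matrix of atlas landmarks (one per row).
#' @param dst 2 x 2 matrix of the corresponding image landmarks.
#' @return object of class `landmark_transform` with fields
#'   `rotation_rad`, `scale`, `translation`.
#' @export
fit_landmark_transform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- complex(real = dst[, 1], imaginary = dst[, 2])
  if (z[1] == z[2] || w[1] == w[2])
    stop_fcois("landmarks are coincident", class = "fcois_degenerate_error")
  a <- (w[2] - w[1]) / (z[2] - z[1])
  b <- w[1] - a * z[1]
  structure(list(rotation_rad = Arg(a), scale = Mod(a),
                 translation = c(Re(b), Im(b))),
            class = "landmark_transform")
}

#' Apply or invert a landmark transform
#'
#' @param transform a `landmark_transform`.
#' @param points n x 2 matrix of coordinates.
#' @param inverse map image coordinates back to atlas coordinates.
#' @return transformed n x 2 matrix.
#' @export
apply_transform <- function(transform, points, inverse = FALSE) {
  points <- rbind(points)
  z <- complex(real = points[, 1], imaginary = points[, 2])
  a <- complex(modulus = transform$scale, argument = transform$rotation_rad)
  b <- complex(real = transform$translation[1],
               imaginary = transform$translation[2])
  w <- if (inverse) (z - b) / a else a * z + b
  cbind(Re(w), Im(w))
}

# Ray-casting point-in-polygon with on-edge counting as inside.
# `pts` n x 2, `poly` m x 2. Returns logical vector.
point_in_polygon <- function(pts, poly) {
  n <- nrow(pts); m <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) ((px - xi) * dx + (py - yi) * dy) / len2 else 0
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | d2 < 1e-18
    # crossing test on the horizontal ray
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Assign brain pixels to atlas regions
#'
#' Transforms the atlas polygons into image coordinates and assigns every
#' in-mask pixel center to its containing polygon. Pixels falling in the
#' intentional gaps between regions stay unassigned (label 0); a pixel
#' inside two polygons means the atlas overlaps and is an error. A pixel
#' center exactly on a polygon edge counts as inside (ray-casting with an
#' explicit on-edge test).
#'
#' @param atlas a [polygon_atlas()].
#' @param transform a `landmark_transform` from [fit_landmark_transform()].
#' @param mask a `brain_mask`.
#' @return a [label_map()] with one slot per region, named by region.
#' @export
assign_pixels_to_regions <- function(atlas, transform, mask) {
  px <- mask_pixels(mask)
  pts <- cbind(px$row, px$col)
  lab <- integer(nrow(pts))
  for (k in seq_along(atlas$regions)) {
    poly <- apply_transform(transform, atlas$regions[[k]])
    hit <- point_in_polygon(pts, poly)
    clash <- hit & lab > 0
    if (any(clash))
      stop_fcois(sprintf(
        "pixel (%d, %d) lies inside both region %s and region %s",
        pts[which(clash)[1], 1], pts[which(clash)[1], 2],
        names(atlas$regions)[lab[which(clash)[1]]],
        names(atlas$regions)[k]), class = "fcois_overlap_error")
    lab[hit] <- k
  }
  label_map(lab, px, dim(mask), n_slots = length(atlas$regions),
            names = names(atlas$regions),
            pixel_pitch_um = attr(mask, "pixel_pitch_um") %||% 80)
}
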