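#' Extraction settings for root-crown trait computation
#'
#' Defaults mirror a whole-root batch analysis of binary crown images:
#' grayscale threshold 200, skeleton spur pruning at 2 px, and three
#' diameter classes with pixel-unit breakpoints at 10 and 20 px (range 1:
#' diameter <= 10 px, range 2: 11-20 px, range 3: >= 21 px). Diameter
#' ranges are binned in PIXELS, before mm conversion, so a crown imaged at a
#' different working distance bins differently — intentional, matching how
#' the ranges were configured on pixel images.
#'
#' @param binarize_threshold Grayscale threshold (0-255).
#' @param pruning_threshold_px Skeleton spurs of at most this many pixels
#'   are removed.
#' @param diameter_range_bounds_px Two increasing positive breakpoints.
#' @param orientation_window_px Window (in px) over which local skeleton
#'   orientation is estimated; single-pixel orientations are unstable.
#' @param lower_area_fraction Depth fraction from the top above which
#'   foreground is excluded from the "lower root area" trait.
#' @return A list of class `extraction_settings`.
#' @export
extraction_settings <- function(binarize_threshold = 200L,
                                pruning_threshold_px = 2L,
                                diameter_range_bounds_px = c(10, 20),
                                orientation_window_px = 7L,
                                lower_area_fraction = 1 / 3) {
  b <- diameter_range_bounds_px
  if (length(b) != 2 || any(b <= 0) || diff(b) <= 0)
    stop("diameter_range_bounds_px must be two increasing positive values")
  structure(list(binarize_threshold = binarize_threshold,
                 pruning_threshold_px = as.integer(pruning_threshold_px),
                 diameter_range_bounds_px = b,
                 orientation_window_px = as.integer(orientation_window_px),
                 lower_area_fraction = lower_area_fraction,
                 mode = "whole-root"),
            class = "extraction_settings")
}

#' Names of the 38 extracted root traits, in column order
#' @return Character vector of length 38.
#' @export
trait_names <- function() {
  c("median_root_count", "max_root_count", "tip_count",
    "branch_point_count", "branching_density", "total_length_mm",
    "depth_mm", "max_width_mm", "width_depth_ratio", "network_area_mm2",
    "convex_hull_area_mm2", "solidity", "lower_root_area_mm2",
    "perimeter_mm", "surface_area_mm2", "volume_mm3", "hole_count",
    "total_hole_area_mm2", "avg_hole_size_mm2", "avg_orientation_deg",
    "shallow_angle_freq", "medium_angle_freq", "steep_angle_freq",
    "avg_diameter_mm", "median_diameter_mm", "max_diameter_mm",
    paste0(rep(c("length_r", "projected_area_r", "surface_area_r",
                 "volume_r"), 3),
           rep(1:3, each = 4),
           rep(c("_mm", "_mm2", "_mm2", "_mm3"), 3)))
}

pad1 <- function(m) {
  out <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out
}
unpad1 <- function(m) m[2:(nrow(m) - 1L), 2:(ncol(m) - 1L), drop = FALSE]

# 8-neighbour degree of every pixel of a 0/1 matrix (padded internally).
neighbor_count <- function(m) {
  p <- pad1(m)
  nr <- nrow(p); nc <- ncol(p)
  acc <- matrix(0L, nr - 2L, nc - 2L)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    acc <- acc + p[(2:(nr - 1)) + di, (2:(nc - 1)) + dj]
  }
  acc * m
}

# Remove skeleton spurs: branches from a graph endpoint up to (not
# including) the nearest junction, of path length <= threshold pixels.
# Degrees come from the shortcut-free skeleton pixel graph, not raw
# 8-neighbour counts, so a spur hugging a thick limb is still an endpoint.
# Iterates to a fixed point so nested short spurs vanish too.
prune_spurs <- function(skel, threshold) {
  if (threshold <= 0) return(skel)
  repeat {
    g <- skeleton_edges(skel)
    if (nrow(g$edges) == 0) break
    np <- nrow(g$pixels)
    deg <- tabulate(c(g$edges[, "from"], g$edges[, "to"]), nbins = np)
    nb <- split(c(g$edges[, "to"], g$edges[, "from"]),
                c(g$edges[, "from"], g$edges[, "to"]))
    neighbors <- function(i) nb[[as.character(i)]]
    removed <- FALSE
    for (e in which(deg == 1)) {
      path <- e; cur <- e; prev <- 0L
      hit_junction <- FALSE
      while (length(path) <= threshold) {
        nxt <- setdiff(neighbors(cur), prev)
        if (length(nxt) == 0) break           # isolated segment
        if (deg[nxt[1]] >= 3) { hit_junction <- TRUE; break }
        prev <- cur; cur <- nxt[1]
        path <- c(path, cur)
      }
      if (hit_junction && length(path) <= threshold) {
        skel[g$pixels[path, , drop = FALSE]] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Skeletonize a root mask and attach distance-transform radii
#'
#' Computes the topology-preserving 1-px medial axis (Zhang-Suen thinning),
#' removes spur branches up to `pruning_threshold_px` long, and records at
#' every skeleton pixel the local root radius taken from the Euclidean
#' distance transform (distance to background minus half a pixel).
#'
#' @param img A [root_image()] or 0/1 matrix.
#' @param pruning_threshold_px Spur-length threshold in pixels.
#' @return `list(skeleton = 0/1 matrix, radius = matrix of radii in px
#'   (NA off-skeleton))`.
#' @export
skeletonize_and_prune <- function(img, pruning_threshold_px = 2L) {
  m <- if (inherits(img, "root_image")) img$pixels else img
  if (sum(m) == 0) stop("empty foreground")
  sk <- unpad1(zs_thin_cpp(pad1(m)))
  sk <- prune_spurs(sk, pruning_threshold_px)
  dm <- EBImage::distmap(m, metric = "euclidean")
  rad <- matrix(NA_real_, nrow(m), ncol(m))
  on_sk <- sk == 1L
  rad[on_sk] <- pmax(dm[on_sk] - 0.5, 0.5)
  list(skeleton = sk, radius = rad)
}

# Skeleton pixel graph: orthogonal edges plus diagonal edges that do not
# shortcut an orthogonal connection. Returns per-edge endpoints (indices
# into `idx`), lengths (1 or sqrt 2) and a pixel-id matrix.
skeleton_edges <- function(sk) {
  idx <- which(sk == 1L, arr.ind = TRUE)
  id <- matrix(0L, nrow(sk), ncol(sk))
  id[idx] <- seq_len(nrow(idx))
  p <- pad1(sk)
  pid <- pad1(id)
  shift <- function(di, dj) pid[(2:(nrow(p) - 1)) + di, (2:(ncol(p) - 1)) + dj]
  sk1 <- sk == 1L
  edges <- list()
  for (d in list(c(0, 1), c(1, 0))) {
    nb <- shift(d[1], d[2])
    keep <- sk1 & nb > 0
    edges[[length(edges) + 1]] <-
      cbind(from = id[keep], to = nb[keep], len = rep(1, sum(keep)))
  }
  for (d in list(c(1, 1), c(1, -1))) {
    nb <- shift(d[1], d[2])
    # skip the diagonal when either orthogonal stepping stone exists
    s1 <- shift(d[1], 0); s2 <- shift(0, d[2])
    keep <- sk1 & nb > 0 & s1 == 0 & s2 == 0
    edges[[length(edges) + 1]] <-
      cbind(from = id[keep], to = nb[keep], len = rep(sqrt(2), sum(keep)))
  }
  e <- do.call(rbind, edges)
  list(pixels = idx, edges = e, id = id)
}

# Length-weighted local orientation (degrees from horizontal, in [0, 90])
# of each skeleton pixel, from a PCA of skeleton pixels inside a
# window x window neighbourhood.
skeleton_orientation <- function(sk, window = 7L) {
  idx <- which(sk == 1L, arr.ind = TRUE)
  h <- window %/% 2L
  nr <- nrow(sk); nc <- ncol(sk)
  ang <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    sub <- sk[max(1, i - h):min(nr, i + h), max(1, j - h):min(nc, j + h),
              drop = FALSE]
    pts <- which(sub == 1L, arr.ind = TRUE)
    if (nrow(pts) < 2) { ang[k] <- NA_real_; next }
    # closed-form principal axis of the 2x2 scatter; y = row (vertical)
    y <- pts[, 1] - mean(pts[, 1]); x <- pts[, 2] - mean(pts[, 2])
    th <- 0.5 * atan2(2 * sum(x * y), sum(x * x) - sum(y * y))
    ang[k] <- abs(th) * 180 / pi
  }
  list(pixels = idx, angle_deg = ang)
}

#' Extract the 38-trait feature vector from a binary root-crown image
#'
#' Traits cover counts (tips, branch points, per-row root counts, holes),
#' global geometry (depth, width, convex hull, solidity, lower root area,
#' perimeter), skeleton-derived totals (length, surface area, volume,
#' branching density), local diameters from the distance transform, angle
#' frequencies in three bins (shallow \[0,30), medium \[30,60), steep
#' \[60,90\] degrees from horizontal), and length/projected area/surface
#' area/volume within three pixel-diameter ranges. Pixel quantities are
#' converted to mm / mm^2 / mm^3 with the image's scale.
#'
#' @param img A [root_image()].
#' @param settings An [extraction_settings()].
#' @return Named numeric vector of length 38 (see [trait_names()]); a
#'   degenerate (single-pixel-skeleton) image carries attribute
#'   `degenerate = TRUE` with length traits 0 and angle frequencies 0.
#' @export
extract_traits <- function(img, settings = extraction_settings()) {
  stopifnot(inherits(img, "root_image"))
  m <- img$pixels
  if (sum(m) == 0) stop("empty foreground")
  s <- img$px_per_mm
  tn <- trait_names()
  out <- stats::setNames(numeric(38), tn)

  fg <- m == 1L
  rows_any <- which(rowSums(fg) > 0)
  cols_any <- which(colSums(fg) > 0)
  depth_px <- diff(range(rows_any)) + 1
  width_px <- diff(range(cols_any)) + 1
  out["depth_mm"] <- depth_px / s
  out["max_width_mm"] <- width_px / s
  out["width_depth_ratio"] <- width_px / depth_px
  out["network_area_mm2"] <- sum(fg) / s^2

  # per-row foreground run counts, over the rows of the bounding box
  runs <- rowSums(fg[rows_any, , drop = FALSE] &
                  !cbind(FALSE, fg[rows_any, -ncol(fg), drop = FALSE]))
  out["median_root_count"] <- stats::median(runs)
  out["max_root_count"] <- max(runs)

  # convex hull over pixel corners (guarantees hull area >= pixel area)
  bound <- fg & (neighbor_count(m) < 8L)
  bp <- which(bound, arr.ind = TRUE)
  corners <- rbind(bp + 0.5, bp - 0.5,
                   cbind(bp[, 1] + 0.5, bp[, 2] - 0.5),
                   cbind(bp[, 1] - 0.5, bp[, 2] + 0.5))
  h <- grDevices::chull(corners)
  hx <- corners[h, 2]; hy <- corners[h, 1]
  hull_px <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  hull_px <- max(hull_px, sum(fg))
  out["convex_hull_area_mm2"] <- hull_px / s^2
  out["solidity"] <- sum(fg) / hull_px

  lower_from <- min(rows_any) + settings$lower_area_fraction * depth_px
  out["lower_root_area_mm2"] <- sum(fg[rows_any[rows_any >= lower_from], ,
                                       drop = FALSE]) / s^2

  # perimeter: foreground/background 4-adjacent pixel edges
  p <- pad1(m)
  per <- sum(p[-1, ] != p[-nrow(p), ]) + sum(p[, -1] != p[, -ncol(p)])
  out["perimeter_mm"] <- per / s

  # holes: 4-connected background components not touching the border
  bglab <- label_components_cpp(1L - m, 4L)
  border_ids <- unique(c(bglab[1, ], bglab[nrow(bglab), ],
                         bglab[, 1], bglab[, ncol(bglab)]))
  tab <- tabulate(bglab)
  hole_ids <- setdiff(which(tab > 0), border_ids[border_ids > 0])
  out["hole_count"] <- length(hole_ids)
  hole_px <- sum(tab[hole_ids])
  out["total_hole_area_mm2"] <- hole_px / s^2
  out["avg_hole_size_mm2"] <- if (length(hole_ids))
    hole_px / length(hole_ids) / s^2 else 0

  # skeleton, radii, edges
  skp <- skeletonize_and_prune(m, settings$pruning_threshold_px)
  sk <- skp$skeleton
  g <- skeleton_edges(sk)
  degenerate <- nrow(g$edges) == 0
  if (!degenerate) {
    rad_px <- skp$radius[g$pixels]
    e_rad <- (rad_px[g$edges[, "from"]] + rad_px[g$edges[, "to"]]) / 2
    e_len <- g$edges[, "len"]
    deg <- tabulate(c(g$edges[, "from"], g$edges[, "to"]),
                    nbins = nrow(g$pixels))
    out["tip_count"] <- sum(deg == 1)
    branch_mask <- matrix(0L, nrow(sk), ncol(sk))
    branch_mask[g$pixels[deg >= 3, , drop = FALSE]] <- 1L
    out["branch_point_count"] <- if (any(branch_mask == 1L))
      max(label_components_cpp(branch_mask, 8L)) else 0

    total_len_px <- sum(e_len)
    out["total_length_mm"] <- total_len_px / s
    out["branching_density"] <-
      out["branch_point_count"] / out["total_length_mm"]
    out["surface_area_mm2"] <- sum(2 * pi * e_rad * e_len) / s^2
    out["volume_mm3"] <- sum(pi * e_rad^2 * e_len) / s^3

    d_px <- 2 * rad_px
    out["avg_diameter_mm"] <- mean(d_px) / s
    out["median_diameter_mm"] <- stats::median(d_px) / s
    out["max_diameter_mm"] <- max(d_px) / s

    b <- settings$diameter_range_bounds_px
    rng <- 1L + (2 * e_rad > b[1]) + (2 * e_rad > b[2])
    for (r in 1:3) {
      sel <- rng == r
      out[sprintf("length_r%d_mm", r)] <- sum(e_len[sel]) / s
      out[sprintf("projected_area_r%d_mm2", r)] <-
        sum(2 * e_rad[sel] * e_len[sel]) / s^2
      out[sprintf("surface_area_r%d_mm2", r)] <-
        sum(2 * pi * e_rad[sel] * e_len[sel]) / s^2
      out[sprintf("volume_r%d_mm3", r)] <-
        sum(pi * e_rad[sel]^2 * e_len[sel]) / s^3
    }

    orient <- skeleton_orientation(sk, settings$orientation_window_px)
    # per-pixel weight: half the length of incident edges
    w <- numeric(nrow(g$pixels))
    half <- e_len / 2
    for (colk in c("from", "to")) {
      agg <- rowsum(half, g$edges[, colk])
      w[as.integer(rownames(agg))] <- w[as.integer(rownames(agg))] + agg[, 1]
    }
    ok <- !is.na(orient$angle_deg) & w > 0
    a <- orient$angle_deg[ok]; wa <- w[ok]
    if (length(a)) {
      out["avg_orientation_deg"] <- sum(a * wa) / sum(wa)
      out["shallow_angle_freq"] <- sum(wa[a < 30]) / sum(wa)
      out["medium_angle_freq"] <- sum(wa[a >= 30 & a < 60]) / sum(wa)
      out["steep_angle_freq"] <- sum(wa[a >= 60]) / sum(wa)
    }
  } else {
    # single-pixel skeleton: length-type traits are 0, frequencies 0
    rad_px <- skp$radius[sk == 1L]
    out["tip_count"] <- sum(sk)
    if (length(rad_px)) {
      out["avg_diameter_mm"] <- mean(2 * rad_px) / s
      out["median_diameter_mm"] <- stats::median(2 * rad_px) / s
      out["max_diameter_mm"] <- max(2 * rad_px) / s
    }
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Batch trait extraction over a list of images
#'
#' Failures are collected and reported, not silently dropped: the returned
#' table has one row per successful image (input order preserved) and the
#' `failures` attribute lists image ids with their error messages.
#'
#' @param images List of [root_image()] objects.
#' @param settings An [extraction_settings()].
#' @return `data.frame` with `image_id` plus the 38 trait columns; attribute
#'   `failures` is a data.frame of (image_id, error).
#' @export
batch_extract <- function(images, settings = extraction_settings()) {
  rows <- list(); fails <- list()
  for (img in images) {
    tv <- tryCatch(extract_traits(img, settings), error = function(e) e)
    if (inherits(tv, "error")) {
      fails[[length(fails) + 1]] <-
        data.frame(image_id = img$image_id, error = conditionMessage(tv))
    } else {
      rows[[length(rows) + 1]] <-
        cbind(data.frame(image_id = img$image_id),
              as.data.frame(as.list(tv)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else cbind(data.frame(image_id = character(0)),
                    stats::setNames(as.data.frame(
                      matrix(numeric(0), 0, 38)), trait_names()))
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails)
                           else data.frame(image_id = character(0),
                                           error = character(0))
  out
}
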