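#' Phenotype specification for the synthetic root-crown generator
#'
#' Encodes the class definitions used in divergent selection for alfalfa root
#' architecture: the branch type (B) carries 4-6 thick lateral roots at
#' 1-2 cm intervals along the taproot; the taproot type (T) fewer than four
#' thin laterals spaced 3-4 cm apart; the intermediate type (TB) four or more
#' laterals spaced more than 2 cm apart with intermediate thickness. Defaults
#' may be overridden field-by-field.
#'
#' @param label One of `"B"`, `"T"`, `"TB"`.
#' @param ... Named overrides for any spec field (e.g.
#'   `lateral_count_range = c(0, 0)`, `fine_root_density = 0`).
#' @return A list of class `phenotype_spec` with fields `label`,
#'   `lateral_count_range`, `lateral_spacing_range_mm`,
#'   `lateral_thickness_mm`, `lateral_length_range_mm`,
#'   `lateral_angle_range_deg`, `taproot_diameter_mm`, `taproot_length_mm`,
#'   `fine_root_density` (rootlets per cm of main-axis length).
#' @export
phenotype_spec <- function(label = c("B", "T", "TB"), ...) {
  label <- match.arg(label)
  base <- switch(label,
    B = list(lateral_count_range = c(4L, 6L),
             lateral_spacing_range_mm = c(10, 20),
             lateral_thickness_mm = c(2.0, 3.2),
             lateral_length_range_mm = c(25, 45),
             taproot_diameter_mm = c(5, 8),
             fine_root_density = 0.5),
    T = list(lateral_count_range = c(0L, 3L),
             lateral_spacing_range_mm = c(30, 40),
             lateral_thickness_mm = c(0.5, 1.2),
             lateral_length_range_mm = c(15, 30),
             taproot_diameter_mm = c(9, 13),
             fine_root_density = 0.2),
    # the residual class: wide, straddling both extremes so it is the
    # hardest to tell apart, as it is for human raters
    TB = list(lateral_count_range = c(4L, 5L),
              lateral_spacing_range_mm = c(21, 25),
              lateral_thickness_mm = c(1.0, 2.4),
              lateral_length_range_mm = c(18, 42),
              taproot_diameter_mm = c(6, 12),
              fine_root_density = 0.35))
  spec <- c(list(label = label), base,
            list(lateral_angle_range_deg = c(20, 70),
                 taproot_length_mm = 110))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(spec))
    if (length(bad)) stop("unknown phenotype_spec fields: ",
                          paste(bad, collapse = ", "))
    spec[names(dots)] <- dots
  }
  for (f in c("lateral_count_range", "lateral_spacing_range_mm",
              "lateral_thickness_mm", "lateral_length_range_mm",
              "taproot_diameter_mm"))
    if (diff(range(spec[[f]])) < 0 || any(!is.finite(spec[[f]])))
      stop("invalid interval in field ", f)
  if (spec$fine_root_density < 0) stop("fine_root_density must be >= 0")
  class(spec) <- "phenotype_spec"
  spec
}

# Points along a straight stroke at ~0.4 px steps with linear radius taper.
stroke_points <- function(r0, c0, r1, c1, rad_start, rad_end) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  n <- max(2L, ceiling(len / 0.4))
  t <- seq(0, 1, length.out = n)
  list(row = r0 + t * (r1 - r0), col = c0 + t * (c1 - c0),
       r = rad_start + t * (rad_end - rad_start))
}

# Lateral-origin gap sampler: redraw until the set fits along the taproot,
# falling back to minimum spacing (which the default specs always fit).
draw_gaps <- function(n_gaps, rng, offset, max_arc) {
  if (n_gaps == 0L) return(numeric(0))
  for (k in 1:300) {
    g <- runif_range(n_gaps, rng)
    if (offset + sum(g) <= max_arc) return(g)
  }
  rep(rng[1], n_gaps)
}

#' Generate one synthetic binary root-crown image
#'
#' Renders a vertically descending taproot with quadratic diameter taper and
#' mild sinusoidal wobble, lateral roots emerging at class-rule spacing with
#' downward-oblique angles on alternating sides, and fine 1-px rootlets at
#' the spec's density. Output is deterministic given
#' `(spec, canvas, px_per_mm, seed)`.
#'
#' @param spec A [phenotype_spec()].
#' @param canvas Integer `c(rows, cols)` canvas size in pixels.
#' @param px_per_mm Pixel scale.
#' @param seed Integer seed.
#' @return `list(image = root_image, truth = list(label, lateral_count,
#'   lateral_spacing_mm, rng_seed))`.
#' @export
generate_root_image <- function(spec, canvas = c(1200L, 900L),
                                px_per_mm = 10, seed = 1L) {
  stopifnot(inherits(spec, "phenotype_spec"))
  s <- px_per_mm
  need_rows <- ceiling((spec$taproot_length_mm + 10) * s)
  if (canvas[1] < need_rows)
    stop(sprintf(
      "canvas too small: %d rows given, >= %d required for a %.0f mm taproot at %.3g px/mm",
      canvas[1], need_rows, spec$taproot_length_mm, s))
  with_seed(seed, {
    L <- spec$taproot_length_mm
    max_arc <- L - 5
    crown_rad <- runif_range(1, spec$taproot_diameter_mm) / 2
    tip_rad <- 0.3
    # taproot centreline (in mm, origin at crown)
    step_mm <- 0.3 / s * s  # 0.3 mm steps
    t_arc <- seq(0, L, by = 0.3)
    amp <- stats::runif(1, 0, 1.5)
    freq <- stats::runif(1, 0.5, 1.5)
    phase <- stats::runif(1, 0, 2 * pi)
    wob <- amp * sin(2 * pi * freq * t_arc / L + phase)
    wob <- wob - wob[1]
    top_mm <- 5
    cx_mm <- ncol_mm <- canvas[2] / s / 2
    tap_row <- (top_mm + t_arc) * s
    tap_col <- (cx_mm + wob) * s
    frac <- t_arc / L
    tap_rad <- (tip_rad + (crown_rad - tip_rad) * (1 - frac)^2) * s
    pts_row <- tap_row; pts_col <- tap_col; pts_rad <- tap_rad

    # laterals
    n_lat <- if (diff(spec$lateral_count_range) == 0)
      as.integer(spec$lateral_count_range[1])
    else sample(spec$lateral_count_range[1]:spec$lateral_count_range[2], 1)
    offset <- stats::runif(1, 5, 12)
    gaps <- draw_gaps(max(0L, n_lat - 1L), spec$lateral_spacing_range_mm,
                      offset, max_arc)
    arcs <- offset + cumsum(c(0, gaps))
    arcs <- arcs[arcs <= max_arc]
    n_lat <- length(arcs) * (n_lat > 0)
    side <- if (n_lat > 0) (sample(0:1, 1) + seq_len(n_lat)) %% 2 * 2 - 1
            else integer(0)
    lat_origin <- lapply(seq_len(n_lat), function(i) {
      idx <- which.min(abs(t_arc - arcs[i]))
      ang <- runif_range(1, spec$lateral_angle_range_deg) * pi / 180
      len <- runif_range(1, spec$lateral_length_range_mm)
      thick <- runif_range(1, spec$lateral_thickness_mm)
      dr <- sin(ang) * len * s
      dc <- cos(ang) * len * s * side[i]
      stroke_points(tap_row[idx], tap_col[idx],
                    tap_row[idx] + dr, tap_col[idx] + dc,
                    thick / 2 * s, thick / 2 * 0.4 * s)
    })

    # fine 1-px rootlets along taproot and laterals
    main_len_cm <- (L + if (n_lat > 0)
      sum(vapply(lat_origin, function(p)
        sqrt(diff(range(p$row))^2 + diff(range(p$col))^2), 0)) / s
      else 0) / 10
    n_fine <- stats::rpois(1, spec$fine_root_density * main_len_cm)
    anchors_row <- c(tap_row, unlist(lapply(lat_origin, `[[`, "row")))
    anchors_col <- c(tap_col, unlist(lapply(lat_origin, `[[`, "col")))
    # anchor rootlets only on in-canvas stretches so the crown stays one
    # connected component even when long laterals clip at the frame
    in_canvas <- anchors_row >= 1 & anchors_row <= canvas[1] - 2 &
                 anchors_col >= 1 & anchors_col <= canvas[2] - 2
    anchors_row <- anchors_row[in_canvas]
    anchors_col <- anchors_col[in_canvas]
    fine <- lapply(seq_len(n_fine), function(i) {
      k <- sample(length(anchors_row), 1)
      ang <- stats::runif(1, 10, 85) * pi / 180
      len <- stats::runif(1, 3, 8) * s
      sd_ <- sample(c(-1, 1), 1)
      stroke_points(anchors_row[k], anchors_col[k],
                    anchors_row[k] + sin(ang) * len,
                    anchors_col[k] + cos(ang) * len * sd_, 0.5, 0.5)
    })

    for (p in c(lat_origin, fine)) {
      pts_row <- c(pts_row, p$row); pts_col <- c(pts_col, p$col)
      pts_rad <- c(pts_rad, p$r)
    }
    canvas_m <- matrix(0L, canvas[1], canvas[2])
    m <- stamp_discs_cpp(canvas_m, pts_row + 1, pts_col + 1, pts_rad)
    img <- root_image(m, s, sprintf("%s_seed%d", spec$label, seed))
    truth <- list(label = spec$label, lateral_count = as.integer(n_lat),
                  lateral_spacing_mm = gaps, rng_seed = as.integer(seed))
    list(image = img, truth = truth)
  })
}

#' Generate a labelled synthetic root-crown dataset
#'
#' Draws a per-image pixel scale uniformly from `px_per_mm_range` (emulating
#' variable camera working distance), shuffles the class sequence
#' deterministically, and renders each crown with [generate_root_image()].
#'
#' @param n_per_class Named integer vector, e.g. `c(B = 237, T = 245,
#'   TB = 135)`.
#' @param px_per_mm_range Interval the per-image scale is drawn from.
#' @param canvas Canvas size `c(rows, cols)` in pixels.
#' @param seed Integer master seed.
#' @param spec_overrides Optional named list of per-class argument lists
#'   passed on to [phenotype_spec()].
#' @return `list(images = list of root_image, truths = list of ground-truth
#'   records)`.
#' @export
generate_dataset <- function(n_per_class = c(B = 237L, T = 245L, TB = 135L),
                             px_per_mm_range = c(8, 10),
                             canvas = c(1200L, 900L), seed = 1L,
                             spec_overrides = list()) {
  stopifnot(all(names(n_per_class) %in% CLASS_LEVELS), all(n_per_class >= 0))
  labels <- rep(names(n_per_class), times = n_per_class)
  n <- length(labels)
  if (n == 0) return(list(images = list(), truths = list()))
  ord <- with_seed(seed, sample.int(n))
  labels <- labels[ord]
  sub <- derive_seeds(seed + 1L, n)
  scales <- with_seed(seed + 2L, runif_range(n, px_per_mm_range))
  out <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    ov <- spec_overrides[[labels[i]]]
    sp <- do.call(phenotype_spec, c(list(label = labels[i]), ov))
    g <- generate_root_image(sp, canvas = canvas, px_per_mm = scales[i],
                             seed = sub[i])
    g$image$image_id <- sprintf("root%04d", i)
    g$truth$image_id <- g$image$image_id
    g$truth$px_per_mm <- scales[i]
    out[[i]] <- g$image
    truths[[i]] <- g$truth
  }
  list(images = out, truths = truths)
}

#' Write a dataset as PNGs plus a CSV manifest
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(
    image_id = vapply(dataset$images, `[[`, "", "image_id"),
    label = vapply(dataset$truths, `[[`, "", "label"),
    px_per_mm = vapply(dataset$images, `[[`, 0, "px_per_mm"),
    seed = vapply(dataset$truths, function(t) t$rng_seed, 0L),
    lateral_count = vapply(dataset$truths, function(t) t$lateral_count, 0L))
  for (img in dataset$images)
    write_root_image(img, file.path(dir, paste0(img$image_id, ".png")))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
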