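#' Random constrained rotation + scale of a root-crown image
#'
#' Rotation is drawn uniformly from \[-20, 20\] degrees about the image
#' centre and isotropic scale uniformly from \[0.8, 1.2\]; both bounds keep
#' the crown's overall vertical orientation meaningful for angle traits.
#' The transform is applied by nearest-neighbour inverse mapping (so a
#' binary mask stays binary), the output canvas is enlarged to hold the
#' whole transformed frame (no foreground clipping), and the pixel scale is
#' inherited unchanged from the source — a scale factor therefore changes
#' measured mm sizes, emulating variable camera working distance.
#'
#' @param img A [root_image()].
#' @param rotation_deg,scale_factor Optional forced values; when `NULL`
#'   (default) they are drawn from the constrained distributions using the
#'   current RNG state. Values outside the constraint bounds are rejected.
#' @return `list(image = transformed root_image, record = list(
#'   source_image_id, rotation_deg, scale_factor))`.
#' @export
random_transform <- function(img, rotation_deg = NULL, scale_factor = NULL) {
  stopifnot(inherits(img, "root_image"))
  if (sum(img$pixels) == 0) stop("empty image")
  if (is.null(rotation_deg)) rotation_deg <- stats::runif(1, -20, 20)
  if (is.null(scale_factor)) scale_factor <- stats::runif(1, 0.8, 1.2)
  if (rotation_deg < -20 || rotation_deg > 20)
    stop("rotation_deg out of bounds [-20, 20]")
  if (scale_factor < 0.8 || scale_factor > 1.2)
    stop("scale_factor out of bounds [0.8, 1.2]")
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  th <- abs(rotation_deg) * pi / 180
  out_nr <- ceiling(scale_factor * (nr * cos(th) + nc * sin(th)))
  out_nc <- ceiling(scale_factor * (nc * cos(th) + nr * sin(th)))
  m <- affine_nn_cpp(img$pixels, rotation_deg, scale_factor, out_nr, out_nc)
  list(image = root_image(m, img$px_per_mm, img$image_id),
       record = list(source_image_id = img$image_id,
                     rotation_deg = rotation_deg,
                     scale_factor = scale_factor))
}

# n_aug transforms of one source under its own seed; shared by
# augment_dataset and augment_and_extract so both yield identical images.
augment_one <- function(img, n_aug, seed) {
  with_seed(seed, {
    imgs <- vector("list", n_aug)
    logs <- vector("list", n_aug)
    for (k in seq_len(n_aug)) {
      tr <- random_transform(img)
      tr$image$image_id <- sprintf("%s_aug%02d", img$image_id, k)
      imgs[[k]] <- tr$image
      logs[[k]] <- data.frame(source_image_id = tr$record$source_image_id,
                              replicate_index = k,
                              rotation_deg = tr$record$rotation_deg,
                              scale_factor = tr$record$scale_factor,
                              seed = seed)
    }
    list(images = imgs, log = do.call(rbind, logs))
  })
}

empty_aug_log <- function() {
  data.frame(source_image_id = character(0), replicate_index = integer(0),
             rotation_deg = numeric(0), scale_factor = numeric(0),
             seed = integer(0))
}

#' Augment a dataset with n constrained random transforms per image
#'
#' @param images List of [root_image()] objects.
#' @param n_aug Replicates per source image (default 10).
#' @param seed Integer seed; the whole augmentation is reproducible from it.
#' @param labels Optional class labels of the sources, inherited by the
#'   augmented copies.
#' @param return_images Keep the transformed rasters (default). With
#'   `FALSE` only the transform log is returned — every image is still
#'   created and immediately discarded, which bounds memory on large runs.
#' @return `list(images = list of n_aug * length(images) root_images (or
#'   empty when `return_images = FALSE`),
#'   log = data.frame(source_image_id, replicate_index, rotation_deg,
#'   scale_factor, seed, label?))`. Augmented image ids are
#'   `<source_id>_aug<k>`.
#' @export
augment_dataset <- function(images, n_aug = 10L, seed = 1L, labels = NULL,
                            return_images = TRUE) {
  stopifnot(n_aug >= 1)
  n <- length(images)
  out <- if (return_images) vector("list", n * n_aug) else list()
  logs <- vector("list", n)
  sub <- if (n) derive_seeds(seed, n) else integer(0)
  for (i in seq_len(n)) {
    a <- augment_one(images[[i]], n_aug, sub[i])
    logs[[i]] <- a$log
    if (return_images)
      out[(i - 1L) * n_aug + seq_len(n_aug)] <- a$images
  }
  log <- if (length(logs)) do.call(rbind, logs) else empty_aug_log()
  rownames(log) <- NULL
  if (!is.null(labels) && length(labels) == n)
    log$label <- rep(labels, each = n_aug)
  list(images = out, log = log)
}

#' Augment and re-extract traits source by source (memory-bounded)
#'
#' Equivalent to [augment_dataset()] followed by [batch_extract()] on the
#' result (identical images and trait values under the same seed), but
#' each source's transformed rasters are extracted and discarded before
#' the next source is processed, so peak memory stays at a handful of
#' images regardless of the dataset size.
#'
#' @inheritParams augment_dataset
#' @param settings An [extraction_settings()].
#' @return `list(traits = data.frame(image_id, source_image_id, 38 traits,
#'   label?), log = transform log, failures = per-image error report)`.
#' @export
augment_and_extract <- function(images, n_aug = 10L, seed = 1L,
                                labels = NULL,
                                settings = extraction_settings()) {
  n <- length(images)
  sub <- if (n) derive_seeds(seed, n) else integer(0)
  rows <- vector("list", n)
  logs <- vector("list", n)
  fails <- vector("list", n)
  for (i in seq_len(n)) {
    a <- augment_one(images[[i]], n_aug, sub[i])
    tr <- batch_extract(a$images, settings)
    fails[[i]] <- attr(tr, "failures")
    tr <- cbind(image_id = tr$image_id,
                source_image_id = images[[i]]$image_id,
                tr[, -1, drop = FALSE])
    if (!is.null(labels)) tr$label <- labels[i]
    rows[[i]] <- tr
    logs[[i]] <- a$log
  }
  traits <- if (n) do.call(rbind, rows) else NULL
  failures <- do.call(rbind, c(fails, list(
    data.frame(image_id = character(0), error = character(0)))))
  log <- if (n) do.call(rbind, logs) else empty_aug_log()
  rownames(log) <- NULL
  if (!is.null(labels) && length(labels) == n)
    log$label <- rep(labels, each = n_aug)
  list(traits = traits, log = log, failures = failures)
}
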