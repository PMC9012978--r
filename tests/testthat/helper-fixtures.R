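# Analytic shapes with hand-enumerable topology, plus a lazily built shared
# synthetic benchmark dataset (cached so the expensive stages run once).

make_bar <- function(nr = 120, nc = 40, len = 100, width = 5,
                     px_per_mm = 10) {
  m <- matrix(0L, nr, nc)
  r0 <- (nr - len) %/% 2; c0 <- (nc - width) %/% 2
  m[r0 + seq_len(len), c0 + seq_len(width)] <- 1L
  root_image(m, px_per_mm, "bar")
}

make_plus <- function(arm = 15, px_per_mm = 10) {
  n <- 2 * arm + 1
  m <- matrix(0L, n + 10, n + 10)
  c_ <- arm + 6
  m[c_, 6:(6 + n - 1)] <- 1L
  m[6:(6 + n - 1), c_] <- 1L
  root_image(m, px_per_mm, "plus")
}

make_annulus <- function(outer = 30, inner = 18, px_per_mm = 10) {
  n <- outer + 12
  m <- matrix(0L, n, n)
  half_o <- outer %/% 2; half_i <- inner %/% 2
  c_ <- n %/% 2
  sq_o <- (c_ - half_o):(c_ + half_o)
  sq_i <- (c_ - half_i):(c_ + half_i)
  m[sq_o, sq_o] <- 1L
  m[sq_i, sq_i] <- 0L
  root_image(m, px_per_mm, "annulus")
}

make_L <- function(px_per_mm = 10) {
  m <- matrix(0L, 80, 60)
  m[10:70, 10:14] <- 1L   # vertical limb
  m[66:70, 10:50] <- 1L   # horizontal foot
  root_image(m, px_per_mm, "L")
}

# tilted thick bar at a given angle below horizontal (for orientation tests)
make_tilted_bar <- function(angle_deg, len_px = 90, width_px = 5,
                            canvas = 160, px_per_mm = 10) {
  m <- matrix(0L, canvas, canvas)
  th <- angle_deg * pi / 180
  t <- seq(0, len_px, by = 0.4)
  rows <- canvas / 4 + t * sin(th)
  cols <- canvas / 2 - len_px / 2 * cos(th) + t * cos(th)
  m <- rootarch:::stamp_discs_cpp(m, rows, cols,
                                  rep(width_px / 2, length(t)))
  root_image(m, px_per_mm, sprintf("tilt%d", angle_deg))
}

# --- shared quick benchmark dataset (built on first use, then cached) -----
.fixture_env <- new.env(parent = emptyenv())

quick_counts <- c(B = 48L, T = 49L, TB = 27L)

quick_dataset <- function() {
  if (is.null(.fixture_env$quick)) {
    ds <- generate_dataset(quick_counts, px_per_mm_range = c(3, 4),
                           canvas = c(480L, 360L), seed = 101)
    labels <- vapply(ds$truths, `[[`, "", "label")
    traits <- batch_extract(ds$images)
    stopifnot(nrow(attr(traits, "failures")) == 0)
    .fixture_env$quick <- list(ds = ds, labels = labels, traits = traits)
  }
  .fixture_env$quick
}

quick_augmented <- function() {
  if (is.null(.fixture_env$quick_aug)) {
    q <- quick_dataset()
    aug <- augment_and_extract(q$ds$images, n_aug = 10L, seed = 202,
                               labels = q$labels)
    stopifnot(nrow(aug$failures) == 0)
    .fixture_env$quick_aug <- list(traits = aug$traits, log = aug$log,
                                   source = aug$traits$source_image_id)
  }
  .fixture_env$quick_aug
}

quick_cv <- function(method, ...) {
  key <- paste0("cv_", method)
  if (is.null(.fixture_env[[key]])) {
    q <- quick_dataset()
    .fixture_env[[key]] <- suppressWarnings(evaluate_model(
      q$traits[, trait_names()], q$labels, method,
      plan = cv_plan(seed = 7), ...))
  }
  .fixture_env[[key]]
}

macro_ba <- function(cv) cv$pooled$balanced_accuracy[cv$pooled$class == "mu"]

# augmented-arm benchmark: originals + augmented copies, grouped CV folds,
# scored on the original images only (augmented siblings train-side)
quick_cv_aug <- function(method) {
  key <- paste0("cvaug_", method)
  if (is.null(.fixture_env[[key]])) {
    q <- quick_dataset(); qa <- quick_augmented()
    tn <- trait_names()
    x <- rbind(q$traits[, tn], qa$traits[, tn])
    lab <- c(q$labels, qa$traits$label)
    grp <- c(q$traits$image_id, qa$source)
    cv <- suppressWarnings(evaluate_model(
      x, lab, method, plan = cv_plan(seed = 7), groups = grp))
    orig <- cv$predictions[cv$predictions$row <= nrow(q$traits), ]
    cm <- confusion_matrix(orig$truth, orig$predicted_class)
    .fixture_env[[key]] <- list(cv = cv,
                                original_metrics = compute_metrics(cm))
  }
  .fixture_env[[key]]
}

extdata <- function(f) system.file("extdata", f, package = "rootarch")
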