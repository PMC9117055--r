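#' Segment a tumor from a grayscale brain image
#'
#' End-to-end pipeline: full-range intensity enhancement, colour labelling
#' through the fixed lookup table, flattening into per-pixel RGB features,
#' ABC search for the K cluster centroids (bounds \[0, 255\] per channel),
#' a final nearest-centroid labelling with the best centroids found, and
#' selection of the tumor cluster as the one with the brightest centroid.
#' No Lloyd polish is applied after the search: the ABC supplies the
#' centroids, the labelling is a single assignment pass.
#'
#' The search minimises [segmentation_objective()]: the clustering objective
#' with two safeguards that make it well posed in a d-dimensional bounded
#' feature box (see that function's documentation and the package vignette
#' for the geometry).
#'
#' @param img numeric matrix of intensities in \[0, 255\], or a
#'   `brain_phantom` (its image is used).
#' @param k number of clusters (default 2: background vs tumor).
#' @param variant ABC variant, `"modified"` (default) or `"basic"`.
#' @param objective `"multi"` (compactness + separation, default) or
#'   `"single"` (compactness only).
#' @param weights objective weights `c(y1, y2)` for the multi objective.
#' @param color colour-label the image before clustering (default `TRUE`;
#'   `FALSE` clusters raw intensities).
#' @param enhance apply full-range intensity adjustment first (default
#'   `TRUE`).
#' @param sn,t_max,limit ABC colony size, cycle budget and abandonment
#'   threshold (limit defaults to `sn * k * d`).
#' @param seed optional integer seed; the whole pipeline is then
#'   deterministic.
#' @return Object of class `tumor_segmentation` with components
#'   `label_map` (integer matrix of cluster indices), `tumor_mask` (logical
#'   matrix), `centroids`, `sizes`, `tumor_cluster`, `objective_value`,
#'   `objective_history`, `features`, `settings` and `elapsed` (seconds,
#'   reported only).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' fit <- segment_tumor(ph, seed = 1, t_max = 30)
#' dice_coefficient(fit$tumor_mask, ph$mask)
segment_tumor <- function(img, k = 2, variant = c("modified", "basic"),
                          objective = c("multi", "single"),
                          weights = c(0.5, 0.5), color = TRUE, enhance = TRUE,
                          sn = 20, t_max = 100, limit = NULL, seed = NULL) {
  variant <- match.arg(variant)
  objective <- match.arg(objective)
  if (inherits(img, "brain_phantom")) img <- img$image
  if (!is.matrix(img) || any(img < 0 | img > 255))
    stop("stage preprocess: img must be a matrix with values in [0, 255]",
         call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(seed)) set.seed(seed)

  work <- if (enhance) auto_enhance(img) else img
  work_img <- if (color) color_label(work) else work
  feats <- extract_features(work_img)
  d <- feats$d
  if (k < 2 || k > nrow(feats$features))
    stop("stage clustering: k must be in [2, number of pixels]", call. = FALSE)
  w <- if (objective == "single") c(1, 0) else weights

  tZ <- t(feats$features)
  z_max <- feats$z_max
  obj_fn <- function(position) {
    segmentation_objective_core(matrix(position, nrow = k, byrow = TRUE),
                                tZ, z_max, w)
  }

  fit <- abc_optim(obj_fn, lower = rep(0, k * d), upper = rep(255, k * d),
                   sn = sn, limit = limit, t_max = t_max, variant = variant)
  centroids <- decode_centroids(fit$par, k, d)
  labels <- assign_pixels(feats, centroids)
  sizes <- tabulate(labels, nbins = k)
  tumor_cluster <- select_tumor_cluster(centroids)
  label_map <- reshape_to_image(labels, feats$origin_shape)
  tumor_mask <- label_map == tumor_cluster
  if (!any(tumor_mask) || sum(sizes > 0) < 2)
    warning("degenerate segmentation: ",
            if (!any(tumor_mask)) "empty tumor mask" else "single occupied cluster",
            call. = FALSE)

  structure(list(
    label_map = label_map, tumor_mask = tumor_mask,
    centroids = centroids, sizes = sizes, tumor_cluster = tumor_cluster,
    objective_value = fit$value, objective_history = fit$history,
    features = feats, abc = fit,
    settings = list(k = k, variant = variant, objective = objective,
                    weights = w, color = color, enhance = enhance,
                    sn = sn, t_max = t_max, limit = fit$limit, seed = seed),
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "tumor_segmentation")
}

# transposed-features variant of the assignment kernel (avoids re-transposing
# inside the optimisation loop)
nearest_centroid_t <- function(tZ, centroids) {
  k <- nrow(centroids)
  d2min <- colSums((tZ - centroids[1, ])^2)
  labels <- rep.int(1L, ncol(tZ))
  if (k > 1) {
    for (j in 2:k) {
      d2 <- colSums((tZ - centroids[j, ])^2)
      upd <- d2 < d2min
      d2min[upd] <- d2[upd]
      labels[upd] <- j
    }
  }
  list(labels = labels, d2 = d2min)
}

#' Pick the tumor cluster among fitted centroids
#'
#' The tumor is the bright region of the scan, so the cluster whose centroid
#' has the highest mean channel intensity is selected; ties go to the lowest
#' index.
#'
#' @param centroids K x d centroid matrix.
#' @return Cluster index in 1..K.
#' @export
select_tumor_cluster <- function(centroids) {
  m <- rowMeans(as.matrix(centroids))
  which(m == max(m))[1]
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  s <- x$settings
  cat(sprintf("tumor segmentation (%s ABC, %s objective, k = %d)\n",
              s$variant, s$objective, s$k))
  cat(sprintf("  image: %d x %d, tumor cluster: %d, tumor pixels: %d\n",
              nrow(x$label_map), ncol(x$label_map), x$tumor_cluster,
              sum(x$tumor_mask)))
  cat(sprintf("  objective: %.4f after %d cycles, elapsed %.2f s\n",
              x$objective_value, length(x$objective_history), x$elapsed))
  invisible(x)
}

#' @export
summary.tumor_segmentation <- function(object, ...) {
  cat(sprintf("Tumor segmentation summary (%s ABC, %s objective)\n",
              object$settings$variant, object$settings$objective))
  df <- data.frame(cluster = seq_len(object$settings$k),
                   size = object$sizes,
                   round(object$centroids, 2))
  names(df)[-(1:2)] <- paste0("centroid_", seq_len(ncol(object$centroids)))
  df$tumor <- df$cluster == object$tumor_cluster
  print(df, row.names = FALSE)
  cat(sprintf("objective value: %.4f (elapsed %.2f s)\n",
              object$objective_value, object$elapsed))
  invisible(df)
}

#' @export
coef.tumor_segmentation <- function(object, ...) object$centroids

#' Apply fitted centroids to a new image
#'
#' Runs the stored preprocessing settings on `newdata` and labels its pixels
#' with the fitted centroids (one nearest-centroid pass), returning the new
#' label map and tumor mask.
#'
#' @param object a `tumor_segmentation`.
#' @param newdata grayscale matrix (or `brain_phantom`); defaults to
#'   refitting on nothing, which returns the training labelling.
#' @param ... unused.
#' @return List with `label_map` and `tumor_mask`.
#' @export
predict.tumor_segmentation <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(list(label_map = object$label_map, tumor_mask = object$tumor_mask))
  if (inherits(newdata, "brain_phantom")) newdata <- newdata$image
  s <- object$settings
  work <- if (s$enhance) auto_enhance(newdata) else newdata
  work_img <- if (s$color) color_label(work) else work
  feats <- extract_features(work_img)
  labels <- assign_pixels(feats, object$centroids)
  label_map <- reshape_to_image(labels, feats$origin_shape)
  list(label_map = label_map, tumor_mask = label_map == object$tumor_cluster)
}

#' @export
residuals.tumor_segmentation <- function(object, ...) {
  nc <- nearest_centroid(object$features$features, object$centroids)
  reshape_to_image(sqrt(nc$d2), object$features$origin_shape)
}

#' @export
plot.tumor_segmentation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  img_plot <- function(m, main) {
    graphics::image(t(m)[, nrow(m):1], axes = FALSE, main = main,
                    col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE)
  }
  img_plot(x$label_map, "cluster labels")
  img_plot(x$tumor_mask * 1, "tumor mask")
  invisible(x)
}

#' Compare segmentation variants on a set of images
#'
#' Runs each configured variant on each image, evaluates the predicted tumor
#' masks against the ground-truth masks, and assembles a per-run metrics
#' table plus a per-variant mean/min/max summary.
#'
#' @param images list of grayscale matrices or `brain_phantom`s.
#' @param truths list of logical ground-truth masks; may be omitted when all
#'   `images` are phantoms (their masks are used).
#' @param variants list of configuration lists, each with elements `label`,
#'   `variant`, `objective` (and optionally any [segment_tumor()] argument).
#'   Default: the three standard configurations (multiobjective modified,
#'   single-objective modified, single-objective basic).
#' @param seed integer seed; run r gets seed `seed + r`.
#' @param file,summary_file optional CSV output paths.
#' @param ... further arguments passed to [segment_tumor()].
#' @return Object of class `segmentation_comparison`: list with `results`
#'   (one row per image x variant: confusion metrics, Dice, elapsed) and
#'   `summary` (mean/min/max per variant and metric).
#' @export
run_comparison <- function(images, truths = NULL, variants = standard_variants(),
                           seed = 1, file = NULL, summary_file = NULL, ...) {
  if (is.null(truths)) {
    if (!all(vapply(images, inherits, TRUE, "brain_phantom")))
      stop("truths must be supplied unless all images are phantoms",
           call. = FALSE)
    truths <- lapply(images, `[[`, "mask")
  }
  if (length(images) != length(truths))
    stop("images and truths must have equal length", call. = FALSE)
  rows <- list()
  run <- 0L
  for (v in variants) {
    for (i in seq_along(images)) {
      run <- run + 1L
      args <- c(list(img = images[[i]], seed = seed + run), v[setdiff(names(v), "label")],
                list(...))
      fit <- do.call(segment_tumor, args)
      met <- compute_metrics(confusion_counts(fit$tumor_mask, truths[[i]]))
      rows[[run]] <- data.frame(
        sample = i, variant = v$label,
        precision = met$precision, sensitivity = met$sensitivity,
        f_measure = met$f_measure, accuracy = met$accuracy,
        specificity = met$specificity,
        dice = dice_coefficient(fit$tumor_mask, truths[[i]]),
        time_s = fit$elapsed)
    }
  }
  results <- do.call(rbind, rows)
  summaries <- do.call(rbind, lapply(split(results, results$variant),
                                     summarize_metrics))
  summaries <- cbind(variant = rep(names(split(results, results$variant)),
                                   each = 3), summaries)
  rownames(summaries) <- NULL
  if (!is.null(file)) utils::write.csv(results, file, row.names = FALSE)
  if (!is.null(summary_file))
    utils::write.csv(summaries, summary_file, row.names = FALSE)
  structure(list(results = results, summary = summaries),
            class = "segmentation_comparison")
}

#' The three standard pipeline configurations
#'
#' Multiobjective modified ABC (the proposed method), single-objective
#' modified ABC, and single-objective basic ABC (the baseline).
#'
#' @return List of configuration lists for [run_comparison()].
#' @export
standard_variants <- function() {
  list(
    list(label = "multiobjective_modified", variant = "modified", objective = "multi"),
    list(label = "single_objective_modified", variant = "modified", objective = "single"),
    list(label = "single_objective_basic", variant = "basic", objective = "single")
  )
}

#' @export
print.segmentation_comparison <- function(x, ...) {
  cat("segmentation comparison:", nrow(x$results), "runs\n\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
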