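#' Segment every image of an on-disk dataset
#'
#' Reads `manifest.csv` under `dir`, runs the mode's segmentation algorithm on
#' every image, writes one mask PNG per image next to `out_dir`, and returns a
#' per-image summary including IoU against the ground-truth mask when the
#' manifest provides one. Images where no pepper is found get an empty mask
#' and an NA area.
#'
#' @param dir dataset directory containing `manifest.csv` and images
#'   (see [make_dataset()]).
#' @param out_dir output directory for mask PNGs (created if needed).
#' @param config a [seg_config()]; its `mode` selects the algorithm.
#' @return data.frame: `pepper_id`, `viewpoint`, `mask_path`, `area`,
#'   `iou_vs_truth`. Also written as `segmentation.csv` under `out_dir`.
#' @export
segment_dataset <- function(dir, out_dir, config = seg_config("photocell")) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    rgb <- read_rgb_png(file.path(dir, r$rgb_path))
    sm <- tryCatch({
      if (config$mode == "photocell") segment_photocell(rgb, config)
      else segment_robotic(rgb,
                           read_depth_tiff(file.path(dir, r$depth_path)),
                           config)
    }, pepperview_no_pepper = function(e) NULL)
    mask <- if (is.null(sm)) array(FALSE, dim(rgb)[1:2]) else sm$mask
    mask_path <- sprintf("%s_%s_segmask.png", r$pepper_id, r$viewpoint)
    write_mask_png(mask, file.path(out_dir, mask_path))
    iou <- if (nzchar(r$mask_path %||% ""))
      mask_iou(mask, read_mask_png(file.path(dir, r$mask_path)))
    else NA_real_
    data.frame(pepper_id = r$pepper_id, viewpoint = r$viewpoint,
               mask_path = mask_path,
               area = if (is.null(sm)) NA_integer_ else sm$area,
               iou_vs_truth = iou, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(out_dir, "segmentation.csv"), row.names = FALSE)
  out
}

#' Pooled feature table for an on-disk dataset
#'
#' Computes the 18 color statistics for every (pepper, viewpoint combination)
#' by pooling the segmented pixels of the combination's viewpoints
#' ([pool_and_extract()]). Masks are either the dataset's ground-truth masks
#' or the output of [segment_dataset()].
#'
#' @param dir dataset directory with `manifest.csv`.
#' @param masks `"truth"` to use the manifest's mask files, or the directory
#'   written by [segment_dataset()].
#' @param combinations `"all"`, `"singles"`, or a data.frame from
#'   [enumerate_combinations()].
#' @param hue hue convention for [collect_pixels()]; default follows the
#'   dataset mode (rotated iff depth images are present).
#' @return data.frame with `pepper_id`, `combo_id`, `n_pixels`, the 18
#'   feature columns, `color` and `class` label columns.
#' @export
extract_feature_table <- function(dir, masks = "truth",
                                  combinations = "all", hue = NULL) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  viewpoints <- sort(unique(manifest$viewpoint))
  mode <- if ("bottom" %in% viewpoints) "photocell" else "robotic"
  hue <- hue %||% if (mode == "robotic") "rotated" else "unrotated"
  combos <- if (is.data.frame(combinations)) combinations else {
    cc <- enumerate_combinations(mode)
    if (identical(combinations, "singles"))
      cc <- cc[cc$n_viewpoints %in% c(1L, max(cc$n_viewpoints)), ]
    cc
  }

  seg_tab <- if (!identical(masks, "truth"))
    read.csv(file.path(masks, "segmentation.csv"), stringsAsFactors = FALSE)

  samples <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    rgb <- read_rgb_png(file.path(dir, r$rgb_path))
    mask <- if (identical(masks, "truth")) {
      read_mask_png(file.path(dir, r$mask_path))
    } else {
      j <- which(seg_tab$pepper_id == r$pepper_id &
                   seg_tab$viewpoint == r$viewpoint)
      read_mask_png(file.path(masks, seg_tab$mask_path[j[1]]))
    }
    samples[[r$pepper_id]][[r$viewpoint]] <- if (any(mask))
      collect_pixels(rgb, mask, hue = hue)
    else structure(list(hue = numeric(0), red = numeric(0),
                        red_minus_green = numeric(0), n = 0,
                        hue_convention = hue), class = "pixel_sample")
  }

  peppers <- unique(manifest[, c("pepper_id", "color", "class")])
  rows <- list()
  for (pid in peppers$pepper_id) {
    for (k in seq_len(nrow(combos))) {
      sel <- samples[[pid]][combos$viewpoints[[k]]]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(pepper_id = pid, combo_id = combos$combo_id[k],
                   n_pixels = pool_pixels(sel)$n, stringsAsFactors = FALSE),
        as.data.frame(as.list(pool_and_extract(sel))))
    }
  }
  merge(do.call(rbind, rows), peppers, by = "pepper_id", sort = TRUE)
}

#' Scenario and agreement analysis of a prediction table
#'
#' Summarises per-combination predictions against the manifest's ground
#' truth: per-combination CA, optimistic/pessimistic bounds per combination
#' size, VCA over single viewpoints, and Light's kappa between viewpoint
#' ground truths (classes 2-3 peppers only; requires the manifest's
#' `visible_colored_fraction`).
#'
#' @param preds data.frame with `pepper_id`, `combo_id`, `pred` (predictions
#'   for one pepper color).
#' @param manifest dataset manifest rows for the same peppers.
#' @return list with `per_combination_ca`, `scenario_by_size`, `vca`,
#'   `light_kappa`.
#' @export
analyze_predictions <- function(preds, manifest) {
  peppers <- unique(manifest[, c("pepper_id", "class")])
  cm <- correctness_matrix(preds, peppers)
  viewpoints <- sort(unique(manifest$viewpoint))
  combos <- unique(preds$combo_id)
  sizes <- lengths(strsplit(combos, "+", fixed = TRUE))
  by_size <- lapply(split(combos, sizes), function(cc)
    scenario_bounds(cm, cc))

  singles <- preds[preds$combo_id %in% viewpoints, ]
  vca <- NA_real_
  if (nrow(singles) > 0 &&
      !all(is.na(manifest$visible_colored_fraction))) {
    key <- setNames(classify_viewpoint(manifest$visible_colored_fraction),
                    paste(manifest$pepper_id, manifest$viewpoint))
    vca <- viewpoint_classification_accuracy(
      singles$pred, key[paste(singles$pepper_id, singles$combo_id)])
  }

  kappa <- NA_real_
  if (!all(is.na(manifest$visible_colored_fraction))) {
    man <- manifest[order(manifest$pepper_id, manifest$viewpoint), ]
    agree <- matrix(classify_viewpoint(man$visible_colored_fraction),
                    ncol = length(viewpoints), byrow = TRUE,
                    dimnames = list(unique(man$pepper_id), viewpoints))
    whole <- peppers$class[match(rownames(agree), peppers$pepper_id)]
    kappa <- tryCatch(light_kappa(agree, whole),
                      error = function(e) NA_real_)
  }

  list(per_combination_ca = as.list(colMeans(cm)),
       scenario_by_size = lapply(by_size, function(s)
         list(optimistic_ca = s$optimistic_ca,
              pessimistic_ca = s$pessimistic_ca)),
       vca = vca, light_kappa = kappa)
}
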