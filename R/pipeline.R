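#' Configuration of a full analysis run
#'
#' Bundles every knob of the simulate -> segment -> features -> train ->
#' predict -> analyze chain so that a run is reproducible from the
#' configuration alone. All randomness is funnelled through the three seeds.
#'
#' @param mode `"photocell"` or `"robotic"`.
#' @param n_per_class_per_color peppers per maturity class per color.
#' @param sim_seed,split_seed,forest_seed seeds for dataset generation, the
#'   train/test split, and the random forest.
#' @param masks `"segment"` to run the mode's segmentation algorithm, or
#'   `"truth"` to use the generator's ground-truth masks (isolates the
#'   viewpoint analysis from segmentation error).
#' @param render a [render_options()].
#' @param seg a [seg_config()] for the chosen mode.
#' @param split a [split_spec()] (its seed is overridden by `split_seed`).
#' @param forest a [forest_spec()] (seed overridden by `forest_seed`).
#' @param hue_features `"unrotated"` (photocell chain) or `"rotated"`
#'   (robotic chain); defaults by mode.
#' @param combination_set `"all"` analyses every combination of the mode's
#'   protocol; `"singles"` restricts to the single viewpoints plus the
#'   all-viewpoints combination (which is always kept, as training pools all
#'   viewpoints) — useful for replicate studies of single-viewpoint accuracy.
#' @param out_dir optional output directory for artifacts (features,
#'   predictions, report); `NULL` keeps everything in memory.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("photocell", "robotic"),
                       n_per_class_per_color = 10,
                       sim_seed = 101L, split_seed = 102L,
                       forest_seed = 103L,
                       masks = c("segment", "truth"),
                       render = render_options(),
                       seg = NULL, split = split_spec(),
                       forest = forest_spec(),
                       hue_features = NULL,
                       combination_set = c("all", "singles"),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  masks <- match.arg(masks)
  combination_set <- match.arg(combination_set)
  seg <- seg %||% seg_config(mode)
  hue_features <- hue_features %||%
    if (mode == "robotic") "rotated" else "unrotated"
  split$seed <- as.integer(split_seed)
  forest$seed <- as.integer(forest_seed)
  structure(list(mode = mode,
                 n_per_class_per_color = n_per_class_per_color,
                 sim_seed = as.integer(sim_seed),
                 split_seed = as.integer(split_seed),
                 forest_seed = as.integer(forest_seed),
                 masks = masks, render = render, seg = seg, split = split,
                 forest = forest, hue_features = hue_features,
                 combination_set = combination_set,
                 out_dir = out_dir), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the nested
#' `render`, `seg`, `split` and `forest` maps mirror [render_options()],
#' [seg_config()], [split_spec()] and [forest_spec()].
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  nested <- list(render = render_options, split = split_spec,
                 forest = forest_spec)
  for (nm in names(nested))
    if (!is.null(y[[nm]])) y[[nm]] <- do.call(nested[[nm]], y[[nm]])
  if (!is.null(y$seg)) y$seg <- do.call(seg_config, c(list(y$mode), y$seg))
  do.call(run_config, y)
}

segment_render <- function(rv, mode, seg) {
  tryCatch({
    if (mode == "photocell") segment_photocell(rv$rgb, seg)$mask
    else segment_robotic(rv$rgb, rv$depth, seg)$mask
  }, pepperview_no_pepper = function(e) rv$truth_mask & FALSE)
}

#' Run the full viewpoint-analysis pipeline on synthetic data
#'
#' Generates a synthetic dataset, obtains per-viewpoint masks (segmentation
#' or ground truth), extracts pooled color features for every viewpoint
#' combination of the mode, splits peppers into train/test strata, fits one
#' random forest per pepper color on the all-viewpoints features of the
#' training peppers, predicts every combination for the test peppers, and
#' summarises: per-combination classification accuracy (CA), optimistic and
#' pessimistic scenario bounds per combination size, viewpoint classification
#' accuracy (VCA) against the per-viewpoint ground truth, and Light's kappa
#' of agreement between viewpoint ground truths (classes 2-3 only).
#'
#' @param config a [run_config()].
#' @return report list (also written as JSON/CSV when `out_dir` is set):
#'   per-color results, the correctness matrices, overall all-viewpoint CA,
#'   and mean segmentation IoU against ground truth when segmenting.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf(...))

  log_stage("[simulate] %s, %d peppers/class/color, seed %d", config$mode,
            config$n_per_class_per_color, config$sim_seed)
  manifest <- make_dataset(NULL, config$n_per_class_per_color, config$mode,
                           seed = config$sim_seed, opts = config$render,
                           write_images = FALSE)
  renders <- attr(manifest, "renders")
  viewpoints <- if (config$mode == "photocell") VIEWPOINTS_PHOTOCELL else
    VIEWPOINTS_ROBOTIC

  log_stage("[segment] masks = %s", config$masks)
  ious <- c()
  samples <- list()  # samples[[pepper]][[viewpoint]]
  for (pid in names(renders)) {
    samples[[pid]] <- list()
    for (vp in viewpoints) {
      rv <- renders[[pid]][[vp]]
      mask <- if (config$masks == "truth") rv$truth_mask else {
        m <- segment_render(rv, config$mode, config$seg)
        ious <- c(ious, mask_iou(m, rv$truth_mask))
        m
      }
      samples[[pid]][[vp]] <- if (any(mask))
        collect_pixels(rv$rgb, mask, hue = config$hue_features) else
        structure(list(hue = numeric(0), red = numeric(0),
                       red_minus_green = numeric(0), n = 0,
                       hue_convention = config$hue_features),
                  class = "pixel_sample")
    }
  }

  combos <- enumerate_combinations(config$mode)
  if (config$combination_set == "singles")
    combos <- combos[combos$n_viewpoints %in%
                       c(1L, max(combos$n_viewpoints)), ]
  log_stage("[features] pooling %d viewpoint combinations", nrow(combos))
  peppers <- unique(manifest[, c("pepper_id", "color", "class")])
  feat_rows <- list()
  for (pid in peppers$pepper_id) {
    for (k in seq_len(nrow(combos))) {
      sel <- samples[[pid]][combos$viewpoints[[k]]]
      fv <- pool_and_extract(sel)
      feat_rows[[length(feat_rows) + 1L]] <- cbind(
        data.frame(pepper_id = pid, combo_id = combos$combo_id[k],
                   n_pixels = pool_pixels(sel)$n,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(fv)))
    }
  }
  features <- do.call(rbind, feat_rows)
  features <- merge(features, peppers, by = "pepper_id", sort = TRUE)

  log_stage("[split] %d test peppers/class/color, seed %d",
            config$split$n_test_per_class_per_color, config$split$seed)
  sp <- split_dataset(peppers, config$split)

  all_combo <- combos$combo_id[which.max(combos$n_viewpoints)]
  report_colors <- list()
  pred_rows <- list()
  for (color in c("red", "yellow")) {
    ids_tr <- intersect(sp$train_ids, peppers$pepper_id[peppers$color == color])
    ids_te <- intersect(sp$test_ids, peppers$pepper_id[peppers$color == color])
    tr <- features[features$pepper_id %in% ids_tr &
                     features$combo_id == all_combo, ]
    log_stage("[train] %s: %d training peppers, %d trees", color, nrow(tr),
              config$forest$n_trees)
    model <- train_maturity_forest(tr[, feature_names()], tr$class,
                                   config$forest, ids = tr$pepper_id)

    te <- features[features$pepper_id %in% ids_te, ]
    te <- te[order(te$pepper_id, te$combo_id), ]
    te$pred <- predict_maturity(model, te[, feature_names()])
    pred_rows[[color]] <- te

    cm <- correctness_matrix(
      data.frame(pepper_id = te$pepper_id, combo_id = te$combo_id,
                 pred = te$pred),
      peppers)
    by_size <- lapply(split(combos$combo_id, combos$n_viewpoints),
                      function(cc) scenario_bounds(cm, cc))

    # VCA on single viewpoints of the test peppers
    singles <- te[te$combo_id %in% viewpoints, ]
    vp_truth <- manifest[manifest$pepper_id %in% ids_te &
                           manifest$color == color, ]
    key <- setNames(classify_viewpoint(vp_truth$visible_colored_fraction),
                    paste(vp_truth$pepper_id, vp_truth$viewpoint))
    vca <- viewpoint_classification_accuracy(
      singles$pred, key[paste(singles$pepper_id, singles$combo_id)])

    # agreement between viewpoint ground truths, all peppers of this color
    man_c <- manifest[manifest$color == color, ]
    agree <- matrix(classify_viewpoint(man_c$visible_colored_fraction)[
      order(man_c$pepper_id, man_c$viewpoint)],
      ncol = length(viewpoints), byrow = TRUE,
      dimnames = list(sort(unique(man_c$pepper_id)), sort(viewpoints)))
    whole <- peppers$class[match(rownames(agree), peppers$pepper_id)]
    kappa <- tryCatch(light_kappa(agree, whole), error = function(e) NA_real_)

    report_colors[[color]] <- list(
      n_train = length(ids_tr), n_test = length(ids_te),
      per_combination_ca = as.list(colMeans(cm)),
      scenario_by_size = lapply(by_size, function(s)
        list(optimistic_ca = s$optimistic_ca,
             pessimistic_ca = s$pessimistic_ca)),
      all_viewpoints_ca = unname(colMeans(cm)[all_combo]),
      vca = vca, light_kappa = kappa,
      correctness = cm)
  }

  preds <- do.call(rbind, pred_rows)
  overall_correct <- preds$combo_id == all_combo
  report <- list(
    mode = config$mode,
    n_peppers = nrow(peppers),
    n_test_peppers = length(sp$test_ids),
    masks = config$masks,
    mean_segmentation_iou = if (length(ious)) mean(ious) else NA_real_,
    colors = report_colors,
    overall_all_viewpoints_ca = classification_accuracy(
      preds$pred[overall_correct], preds$class[overall_correct]),
    config_fingerprint = rlang::hash(unclass(config)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(features, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(preds[, c("pepper_id", "color", "class", "combo_id", "pred")],
              file.path(config$out_dir, "predictions.csv"), row.names = FALSE)
    writeable <- report
    writeable$elapsed_s <- NULL
    for (color in names(writeable$colors))
      writeable$colors[[color]]$correctness <- NULL
    jsonlite::write_json(writeable, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    flat <- do.call(rbind, lapply(names(report_colors), function(color)
      data.frame(color = color,
                 combo_id = names(report_colors[[color]]$per_combination_ca),
                 ca = unlist(report_colors[[color]]$per_combination_ca))))
    write.csv(flat, file.path(config$out_dir, "report_ca.csv"),
              row.names = FALSE)
  }
  report
}

#' Normalise an external dataset folder into a manifest
#'
#' Adapter for a locally downloaded copy of a deposited pepper image dataset.
#' Expected layout: a `labels.csv` with columns `pepper_id,color,class` at the
#' root, and an `images/` folder with files named
#' `<pepper_id>_<viewpoint>.png`, optionally accompanied by
#' `<pepper_id>_<viewpoint>_depth.tif` and `<pepper_id>_<viewpoint>_mask.png`.
#' Nothing is downloaded. Unrecognised layouts give an error describing the
#' expected structure.
#'
#' @param path dataset root directory.
#' @return manifest data.frame with the standard columns.
#' @export
load_mendeley_adapter <- function(path) {
  expected <- paste(
    "expected layout:",
    "<root>/labels.csv with columns pepper_id,color,class and",
    "<root>/images/<pepper_id>_<viewpoint>.png",
    "[+ _depth.tif, + _mask.png]")
  if (!dir.exists(path)) stop("not a directory: ", path, "; ", expected)
  labels_file <- file.path(path, "labels.csv")
  img_dir <- file.path(path, "images")
  if (!file.exists(labels_file) || !dir.exists(img_dir))
    stop("unrecognised dataset layout under ", path, "; ", expected)
  labels <- read.csv(labels_file, stringsAsFactors = FALSE)
  need <- c("pepper_id", "color", "class")
  if (!all(need %in% names(labels)))
    stop("labels.csv lacks columns ", paste(setdiff(need, names(labels)),
                                            collapse = ", "), "; ", expected)
  pngs <- sort(list.files(img_dir, pattern = "\\.png$"))
  pngs <- pngs[!grepl("_mask\\.png$", pngs)]
  if (length(pngs) == 0) stop("no images under ", img_dir, "; ", expected)
  rows <- lapply(pngs, function(f) {
    stem <- sub("\\.png$", "", f)
    pid <- sub("_[^_]+$", "", stem)
    vp <- sub("^.*_", "", stem)
    if (!pid %in% labels$pepper_id)
      stop("image ", f, " has no row in labels.csv; ", expected)
    lr <- labels[labels$pepper_id == pid, ][1, ]
    depth <- file.path("images", paste0(stem, "_depth.tif"))
    mask <- file.path("images", paste0(stem, "_mask.png"))
    data.frame(pepper_id = pid, color = lr$color, class = lr$class,
               viewpoint = vp, rgb_path = file.path("images", f),
               depth_path = ifelse(file.exists(file.path(path, depth)),
                                   depth, ""),
               mask_path = ifelse(file.exists(file.path(path, mask)),
                                  mask, ""),
               visible_colored_fraction = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
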