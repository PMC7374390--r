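#' Specification of a synthetic pepper
#'
#' A simulated fruit is an axis-aligned ellipsoid whose surface carries a
#' contiguous ripe-colored cap; the cap is a spherical cap in the angular
#' parameterisation of the surface, so one number (`colored_fraction`) fixes
#' the ripe surface share and one unit vector (`front_orientation`) fixes
#' where ripening started. This is a deliberate idealisation of the
#' nonuniform ripening pattern of real sweet peppers: real fruit are
#' irregular, but the ellipsoid gives analytic ground-truth masks and an
#' exactly convex silhouette.
#'
#' @param pepper_id character id.
#' @param color `"red"` or `"yellow"`.
#' @param colored_fraction fraction of the surface bearing the ripe color,
#'   in \[0,1\].
#' @param front_orientation length-3 numeric, the axis of the colored cap in
#'   world coordinates (x,y horizontal, z up); normalised internally.
#' @param shape ellipsoid semi-axes in pixels, length 3 (x, y, z). Default is
#'   an upright fruit longer than wide, as sweet peppers are.
#' @param seed integer seed controlling all stochastic rendering detail
#'   (hue jitter, clutter layout, depth holes).
#' @return an object of class `pepper_spec`.
#' @export
pepper_spec <- function(pepper_id, color = c("red", "yellow"),
                        colored_fraction, front_orientation = c(1, 0, 0),
                        shape = c(55, 55, 85), seed = 1L) {
  color <- match.arg(color)
  if (!is.numeric(colored_fraction) || length(colored_fraction) != 1 ||
      is.na(colored_fraction) || colored_fraction < 0 || colored_fraction > 1)
    stop("colored_fraction must be a single number in [0,1]")
  if (length(shape) != 3 || any(!is.finite(shape)) || any(shape <= 0))
    stop("shape must be three positive semi-axes (pixels)")
  fo <- as.numeric(front_orientation)
  if (length(fo) != 3 || sqrt(sum(fo^2)) < 1e-12)
    stop("front_orientation must be a non-zero length-3 vector")
  structure(list(
    pepper_id = as.character(pepper_id), color = color,
    colored_fraction = colored_fraction,
    front_orientation = fo / sqrt(sum(fo^2)),
    shape = as.numeric(shape), seed = as.integer(seed)
  ), class = "pepper_spec")
}

#' Instantiate a synthetic pepper and its surface color field
#'
#' Resolves a [pepper_spec()] into a renderable pepper: the cap half-angle is
#' chosen so that a spherical cap of that angular extent covers exactly
#' `colored_fraction` of the surface (cap area fraction `(1-cos(theta))/2`),
#' and the whole-pepper maturity class is derived with [classify_whole()].
#'
#' @param spec a [pepper_spec()].
#' @return object of class `synthetic_pepper`: the spec plus `class`
#'   (whole-pepper maturity class) and `cap_cos` (cosine of the cap
#'   half-angle; a surface direction `u` is ripe-colored iff
#'   `dot(u, front_orientation) >= cap_cos`).
#' @export
generate_pepper <- function(spec) {
  if (!inherits(spec, "pepper_spec")) spec <- do.call(pepper_spec, spec)
  f <- spec$colored_fraction
  # cap fraction (1-cos)/2 = f  =>  cos(theta) = 1 - 2f; exact 0/1 handled
  # separately so class-1 and class-4 fruit are literally single-colored
  cap_cos <- if (f <= 0) Inf else if (f >= 1) -Inf else 1 - 2 * f
  structure(c(unclass(spec), list(
    class = classify_whole(f),
    cap_cos = cap_cos
  )), class = "synthetic_pepper")
}

# ripe/green hue bands (degrees, unrotated 0-360 circle)
HUE_RED <- 5
HUE_YELLOW <- 55
HUE_GREEN <- 110
HUE_JITTER_SD <- 2.5

#' Rendering options for synthetic scenes
#'
#' Collects the knobs of the orthographic renderer. Depth geometry places the
#' fruit centre at `fruit_depth_mm` and, in robotic mode, adds elliptical
#' green foliage blobs: in-range foliage at `foliage_depth_mm` (inside the
#' default segmentation depth window) and far clutter at `clutter_depth_mm`
#' (beyond it), in front of a wall at `wall_depth_mm`. One pixel corresponds
#' to one millimetre at the fruit plane.
#'
#' @param width,height raster size in pixels.
#' @param fruit_shape default ellipsoid semi-axes (pixels) given to
#'   [pepper_spec()] by [make_dataset()]; scale it with the raster so the
#'   fruit keeps filling about three quarters of the frame height.
#' @param noise_sd standard deviation of additive Gaussian RGB noise (on the
#'   \[0,1\] scale) applied before 8-bit quantisation; 0 disables it.
#' @param fruit_depth_mm,foliage_depth_mm,clutter_depth_mm,wall_depth_mm
#'   scene depths, millimetres.
#' @param n_foliage,n_clutter number of in-range / far green blobs (robotic).
#' @param depth_hole_rate fraction of depth pixels zeroed out to emulate
#'   sensor dropout.
#' @param background_value photocell background intensity (dark floor).
#' @return list of class `render_options`.
#' @export
render_options <- function(width = 320, height = 240,
                           fruit_shape = c(55, 55, 85), noise_sd = 0,
                           fruit_depth_mm = 500, foliage_depth_mm = 550,
                           clutter_depth_mm = 900, wall_depth_mm = 1200,
                           n_foliage = 4, n_clutter = 4,
                           depth_hole_rate = 0.02,
                           background_value = 0.04) {
  structure(as.list(environment()), class = "render_options")
}

VIEWPOINTS_PHOTOCELL <- c("side1", "side2", "side3", "bottom")
VIEWPOINTS_ROBOTIC <- c("side1", "side2", "side3")

viewpoint_basis <- function(viewpoint_id) {
  side <- c(side1 = 0, side2 = 120, side3 = 240)
  if (viewpoint_id %in% names(side)) {
    a <- side[[viewpoint_id]] * pi / 180
    list(v = c(-cos(a), -sin(a), 0),      # viewing direction, into the scene
         r = c(-sin(a), cos(a), 0),       # image x axis (world)
         u = c(0, 0, 1))                  # image y axis (world up)
  } else if (viewpoint_id == "bottom") {
    list(v = c(0, 0, 1), r = c(1, 0, 0), u = c(0, 1, 0))
  } else stop("unknown viewpoint id: ", viewpoint_id)
}

#' Render one viewpoint of a synthetic pepper
#'
#' Orthographic projection of the ellipsoid color field. Photocell mode puts
#' the fruit on a uniform dark background with no depth channel; robotic mode
#' adds green foliage clutter (never overlapping the fruit silhouette) plus a
#' far wall, renders an aligned depth raster in millimetres with simulated
#' dropout holes (value 0), and applies Gaussian pixel noise if requested.
#' Identical pepper + options + viewpoint always yields bit-identical rasters.
#'
#' @param pepper a [generate_pepper()] result.
#' @param viewpoint_id one of `"side1"`, `"side2"`, `"side3"`, `"bottom"`.
#' @param mode `"photocell"` or `"robotic"`.
#' @param opts a [render_options()] list.
#' @return list of class `rendered_viewpoint` with elements `viewpoint_id`,
#'   `rgb` (H x W x 3, \[0,1\], 8-bit quantised), `depth` (H x W mm, robotic
#'   only, else `NULL`), `truth_mask` (logical), `plant_mask` (logical,
#'   in-depth-range foliage pixels; robotic only), and
#'   `visible_colored_fraction` (ripe share of the truth-mask pixels).
#' @export
render_viewpoint <- function(pepper, viewpoint_id,
                             mode = c("photocell", "robotic"),
                             opts = render_options()) {
  mode <- match.arg(mode)
  stopifnot(inherits(pepper, "synthetic_pepper"))
  basis <- viewpoint_basis(viewpoint_id)
  W <- opts$width; H <- opts$height
  seed <- derive_seed(pepper$seed,
                      match(viewpoint_id, VIEWPOINTS_PHOTOCELL) +
                        10L * (mode == "robotic"))

  with_seed(seed, {
    s <- pepper$shape
    xs <- (seq_len(W) - (W + 1) / 2)
    ys <- ((H + 1) / 2 - seq_len(H))
    X <- matrix(xs, H, W, byrow = TRUE)   # image-plane x per pixel
    Y <- matrix(ys, H, W)                 # image-plane y per pixel

    v <- basis$v; r <- basis$r; u <- basis$u
    # ray: q + t*v with q = X*r + Y*u; intersect (p1/s1)^2+... = 1
    A <- sum((v / s)^2)
    Bq <- 2 * (X * (r[1] * v[1] / s[1]^2 + r[2] * v[2] / s[2]^2 +
                      r[3] * v[3] / s[3]^2) +
               Y * (u[1] * v[1] / s[1]^2 + u[2] * v[2] / s[2]^2 +
                      u[3] * v[3] / s[3]^2))
    Cq <- (X * r[1] + Y * u[1])^2 / s[1]^2 +
          (X * r[2] + Y * u[2])^2 / s[2]^2 +
          (X * r[3] + Y * u[3])^2 / s[3]^2 - 1
    disc <- Bq^2 - 4 * A * Cq
    hit <- disc >= 0
    t1 <- matrix(NA_real_, H, W)
    t1[hit] <- (-Bq[hit] - sqrt(disc[hit])) / (2 * A)

    # surface point and its direction in the scaled (unit-sphere) frame
    px <- X * r[1] + Y * u[1] + t1 * v[1]
    py <- X * r[2] + Y * u[2] + t1 * v[2]
    pz <- X * r[3] + Y * u[3] + t1 * v[3]
    wx <- px / s[1]; wy <- py / s[2]; wz <- pz / s[3]
    wn <- sqrt(wx^2 + wy^2 + wz^2)
    fo <- pepper$front_orientation
    dotf <- (wx * fo[1] + wy * fo[2] + wz * fo[3]) / wn
    colored <- hit & !is.na(dotf) & (dotf >= pepper$cap_cos)

    # Lambertian-ish shading, light at the camera
    nx <- px / s[1]^2; ny <- py / s[2]^2; nz <- pz / s[3]^2
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    ndotv <- -(nx * v[1] + ny * v[2] + nz * v[3]) / nn
    shade <- 0.35 + 0.6 * pmax(0, ndotv)

    ripe_hue <- if (pepper$color == "red") HUE_RED else HUE_YELLOW
    hue <- matrix(0, H, W); sat <- matrix(0, H, W); val <- matrix(0, H, W)
    jit <- matrix(pmin(7.5, pmax(-7.5, rnorm(H * W, 0, HUE_JITTER_SD))), H, W)

    depth <- NULL; plant_mask <- matrix(FALSE, H, W)
    if (mode == "photocell") {
      hue[] <- 30; sat[] <- 0.05; val[] <- opts$background_value
    } else {
      # wall
      hue[] <- 30; sat[] <- 0.05; val[] <- 0.25
      depth <- matrix(opts$wall_depth_mm, H, W)
      # foliage blobs, kept clear of the fruit's projected bounding box by
      # more than the blob radius plus the net edge dilation of segmentation
      half_w <- max(abs(xs)) ; half_h <- max(abs(ys))
      proj_w <- sqrt(sum((s * basis$r)^2)); proj_h <- sqrt(sum((s * basis$u)^2))
      n_blobs <- opts$n_foliage + opts$n_clutter
      depths <- c(rep(opts$foliage_depth_mm, opts$n_foliage),
                  rep(opts$clutter_depth_mm, opts$n_clutter))
      for (b in seq_len(n_blobs)) {
        for (try in 1:200) {
          cx <- runif(1, -half_w, half_w); cy <- runif(1, -half_h, half_h)
          if (abs(cx) > proj_w + 55 || abs(cy) > proj_h + 55) break
        }
        ax <- runif(1, 15, 40); ay <- runif(1, 15, 40)
        th <- runif(1, 0, pi)
        dx <- X - cx; dy <- Y - cy
        e <- ((dx * cos(th) + dy * sin(th)) / ax)^2 +
             ((-dx * sin(th) + dy * cos(th)) / ay)^2
        inb <- e <= 1
        hue[inb] <- HUE_GREEN
        sat[inb] <- 0.8
        val[inb] <- 0.3 + 0.35 * pmax(0, 1 - e[inb])
        depth[inb] <- depths[b]
      }
      # overlapping blobs overwrite each other, so read foliage off the final
      # depth buffer
      plant_mask <- depth == opts$foliage_depth_mm & !hit
    }

    # fruit on top of everything (it is the nearest object)
    hue[hit] <- ifelse(colored[hit], ripe_hue, HUE_GREEN) + jit[hit]
    sat[hit] <- 0.88
    val[hit] <- shade[hit]
    if (mode == "robotic") {
      depth[hit] <- opts$fruit_depth_mm +
        (px * v[1] + py * v[2] + pz * v[3])[hit]
      if (opts$depth_hole_rate > 0) {
        holes <- runif(H * W) < opts$depth_hole_rate
        depth[matrix(holes, H, W)] <- 0
      }
      depth <- round(depth)
    }

    rgb <- hsv_to_rgb_raster(hue, sat, val)
    if (opts$noise_sd > 0)
      rgb <- rgb + array(rnorm(length(rgb), 0, opts$noise_sd), dim = dim(rgb))
    rgb <- quantize8(rgb)

    structure(list(
      viewpoint_id = viewpoint_id, rgb = rgb, depth = depth,
      truth_mask = hit, plant_mask = if (mode == "robotic") plant_mask,
      visible_colored_fraction = mean(colored[hit])
    ), class = "rendered_viewpoint")
  })
}

#' Render all viewpoints of a pepper
#'
#' @inheritParams render_viewpoint
#' @param viewpoints character vector of viewpoint ids; defaults to the
#'   acquisition protocol of the mode (photocell: three sides plus bottom;
#'   robotic: three sides at equal height, no bottom).
#' @return named list of `rendered_viewpoint` objects.
#' @export
render_viewpoints <- function(pepper, mode = c("photocell", "robotic"),
                              viewpoints = NULL, opts = render_options()) {
  mode <- match.arg(mode)
  viewpoints <- viewpoints %||%
    if (mode == "photocell") VIEWPOINTS_PHOTOCELL else VIEWPOINTS_ROBOTIC
  if (anyDuplicated(viewpoints)) stop("duplicate viewpoint ids")
  setNames(lapply(viewpoints, function(vp)
    render_viewpoint(pepper, vp, mode, opts)), viewpoints)
}

#' Sample a uniformly random unit vector
#' @keywords internal
runif_sphere <- function() {
  z <- runif(1, -1, 1); a <- runif(1, 0, 2 * pi)
  rr <- sqrt(1 - z^2)
  c(rr * cos(a), rr * sin(a), z)
}

#' Draw the colored fraction for a maturity class
#'
#' Class 1 is exactly 0, class 4 exactly 1; the mixed classes draw uniformly
#' from \[0.10, 0.45\] (class 2) and \[0.55, 0.90\] (class 3).
#' @keywords internal
sample_colored_fraction <- function(class) {
  switch(as.character(class),
         "1" = 0, "2" = runif(1, 0.10, 0.45),
         "3" = runif(1, 0.55, 0.90), "4" = 1,
         stop("class must be 1..4"))
}

#' Generate a synthetic multi-viewpoint pepper dataset on disk
#'
#' Emulates the acquisition campaigns the analysis is designed for: balanced
#' red/yellow peppers across maturity classes (photocell: classes 1-4 and a
#' bottom viewpoint; robotic: classes 2-4, three side viewpoints, RGB-D with
#' cluttered green background), with front orientations drawn uniformly on
#' the sphere. Writes RGB PNGs, ground-truth mask PNGs, depth TIFFs (robotic)
#' and a CSV manifest; regeneration with the same arguments is byte-identical.
#'
#' @param out_dir output directory (created if missing).
#' @param n_per_class_per_color peppers per maturity class per color.
#' @param mode `"photocell"` or `"robotic"`.
#' @param seed master seed; every pepper gets a derived seed.
#' @param opts [render_options()].
#' @param write_images if `FALSE`, renders nothing and returns the manifest
#'   with in-memory renders attached (used by the in-memory pipeline).
#' @return the manifest as a data.frame (invisibly if written): columns
#'   `pepper_id,color,class,viewpoint,rgb_path,depth_path,mask_path,`
#'   `visible_colored_fraction`, plus `colored_fraction` per pepper.
#' @export
make_dataset <- function(out_dir, n_per_class_per_color,
                         mode = c("photocell", "robotic"), seed = 1L,
                         opts = render_options(), write_images = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_per_class_per_color >= 1)
  classes <- if (mode == "photocell") 1:4 else 2:4
  viewpoints <- if (mode == "photocell") VIEWPOINTS_PHOTOCELL else
    VIEWPOINTS_ROBOTIC
  if (write_images) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  specs <- with_seed(seed, {
    out <- list()
    for (color in c("red", "yellow")) for (cl in classes)
      for (i in seq_len(n_per_class_per_color)) {
        pid <- sprintf("%s_c%d_%02d", color, cl, i)
        out[[pid]] <- pepper_spec(
          pepper_id = pid, color = color,
          colored_fraction = sample_colored_fraction(cl),
          front_orientation = runif_sphere(),
          shape = opts$fruit_shape,
          seed = derive_seed(seed, length(out) + 1L))
      }
    out
  })

  rows <- list(); renders <- list()
  for (spec in specs) {
    pep <- generate_pepper(spec)
    views <- render_viewpoints(pep, mode, viewpoints, opts)
    for (vp in viewpoints) {
      rv <- views[[vp]]
      rgb_path <- sprintf("%s_%s.png", pep$pepper_id, vp)
      mask_path <- sprintf("%s_%s_mask.png", pep$pepper_id, vp)
      depth_path <- if (mode == "robotic")
        sprintf("%s_%s_depth.tif", pep$pepper_id, vp) else ""
      if (write_images) {
        write_rgb_png(rv$rgb, file.path(out_dir, rgb_path))
        write_mask_png(rv$truth_mask, file.path(out_dir, mask_path))
        if (mode == "robotic")
          write_depth_tiff(rv$depth, file.path(out_dir, depth_path))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pepper_id = pep$pepper_id, color = pep$color, class = pep$class,
        viewpoint = vp, rgb_path = rgb_path, depth_path = depth_path,
        mask_path = mask_path,
        visible_colored_fraction = rv$visible_colored_fraction,
        colored_fraction = pep$colored_fraction,
        stringsAsFactors = FALSE)
    }
    if (!write_images) renders[[pep$pepper_id]] <- views
  }
  manifest <- do.call(rbind, rows)
  if (write_images) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    invisible(manifest)
  } else {
    attr(manifest, "renders") <- renders
    manifest
  }
}
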