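#' Pipeline configuration
#'
#' A single auditable object holding every tunable of the extraction pipeline,
#' serializable to JSON with round-trip equality. Flags on the command line
#' override config values.
#'
#' @param points_per_region random points sampled per ROI (default 400).
#' @param gamma camera linearization exponent.
#' @param gray_reflectance gray-standard reflectance.
#' @param dense_threshold,midline_threshold pattern-classifier thresholds.
#' @param seed top-level pipeline seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(points_per_region = 400, gamma = 2.2,
                            gray_reflectance = 0.18, dense_threshold = 0.10,
                            midline_threshold = 0.5, seed = 1L) {
  check_that(points_per_region >= 1, "points_per_region must be >= 1")
  check_that(gamma > 0, "gamma must be positive")
  check_that(gray_reflectance > 0 && gray_reflectance < 1,
             "gray_reflectance must be in (0, 1)")
  structure(list(points_per_region = as.integer(points_per_region),
                 gamma = gamma, gray_reflectance = gray_reflectance,
                 dense_threshold = dense_threshold,
                 midline_threshold = midline_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @param config a [pipeline_config()].
#' @return \code{read_config} returns a [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ROI set from JSON
#'
#' Format: \code{{"image": name, "rois": [{"label": ..., "vertices":
#' [[col,row], ...]}, ...]}} with 0-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return named list of [polygon_roi()] keyed by label, with the image name
#'   as attribute \code{"image"}.
#' @export
read_rois <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$rois)) stop("malformed ROI JSON (no 'rois'): ", path, call. = FALSE)
  rois <- lapply(j$rois, function(r) {
    if (is.null(r$label) || is.null(r$vertices)) {
      stop("malformed ROI JSON (roi missing label/vertices): ", path,
           call. = FALSE)
    }
    polygon_roi(r$label, lapply(r$vertices, unlist))
  })
  names(rois) <- vapply(rois, function(r) r$label, character(1))
  attr(rois, "image") <- j$image
  rois
}

#' Write a ROI set to JSON
#' @param rois named list of [polygon_roi()].
#' @param image_name image file name the ROIs refer to.
#' @param path output JSON path.
#' @export
write_rois <- function(rois, image_name, path) {
  out <- list(image = image_name,
              rois = lapply(rois, function(r)
                list(label = r$label,
                     vertices = lapply(seq_len(nrow(r$vertices)),
                                       function(i) as.numeric(r$vertices[i, ])))))
  names(out$rois) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Extract calibrated region colors and contrasts from one image + ROI set.
# Returns a one-row tibble, or a skip sentinel naming the reason when the
# gray standard or background is absent.
skip_record <- function(reason) structure(list(reason = reason), class = "skip_record")

extract_image_record <- function(image, rois, id, config = pipeline_config()) {
  if (!"gray_standard" %in% names(rois)) {
    return(skip_record("missing gray_standard ROI"))
  }
  npt <- config$points_per_region
  seed_for <- function(label) derive_seed(config$seed, paste0(id, "/", label))
  raw <- lapply(names(rois), function(lb)
    region_mean_color(image, rois[[lb]], n = npt, seed = seed_for(lb)))
  names(raw) <- names(rois)
  gray_lin <- linearize(raw$gray_standard, config$gamma)
  cal <- lapply(raw, function(v)
    equalize(linearize(v, config$gamma), gray_lin, config$gray_reflectance))
  if (all(c("background_1", "background_2") %in% names(cal))) {
    bg <- (cal$background_1[1:3] + cal$background_2[1:3]) / 2
  } else if ("background_1" %in% names(cal)) {
    bg <- cal$background_1[1:3]
  } else {
    return(skip_record("missing background ROI"))
  }
  row <- tibble::tibble(id = id)
  put <- function(row, reg, rgb3) {
    row[[paste0(reg, "_R")]] <- rgb3[1]
    row[[paste0(reg, "_G")]] <- rgb3[2]
    row[[paste0(reg, "_B")]] <- rgb3[3]
    row
  }
  for (reg in c("dorsal", "ventral", "ventral_tail")) {
    row <- put(row, reg,
               if (reg %in% names(cal)) cal[[reg]][1:3] else rep(NA_real_, 3))
  }
  row <- put(row, "background", bg)
  augment_records(row)
}

#' Extract a record from an in-memory scene bundle
#'
#' Runs the full extraction chain (point sampling, linearization,
#' equalization, color metrics, contrasts) on a rendered [render_scene()]
#' bundle, plus the pattern classification and vegetation-cover score from its
#' masks.
#'
#' @param bundle a \code{scene_bundle}.
#' @param id record identifier.
#' @param config a [pipeline_config()].
#' @return one-row tibble.
#' @export
extract_scene_record <- function(bundle, id = "scene", config = NULL) {
  check_that(inherits(bundle, "scene_bundle"), "bundle must be a scene_bundle")
  if (is.null(config)) {
    config <- pipeline_config(gamma = bundle$params$gamma,
                              gray_reflectance = bundle$params$gray_reflectance)
  }
  row <- extract_image_record(bundle$image, bundle$rois, id, config)
  if (inherits(row, "skip_record")) stop(row$reason, call. = FALSE)
  row$pattern <- classify_pattern(bundle$pattern_map,
                                  dense_threshold = config$dense_threshold,
                                  midline_threshold = config$midline_threshold)
  row$vegetation_cover <- total_cover(bundle$vegetation_mask)$total
  row
}

#' Write a scene bundle to disk
#'
#' Emits \code{<id>.png} (scene), \code{<id>.json} (ROIs), and mask PNGs
#' (\code{<id>_veg.png}, \code{<id>_body.png}, \code{<id>_speckle.png},
#' \code{<id>_midline.png}) under \code{dir}.
#'
#' @param bundle a \code{scene_bundle}.
#' @param dir output directory (created if needed).
#' @param id basename for the files.
#' @return invisibly, the image path.
#' @export
write_scene_bundle <- function(bundle, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(id, ".png"))
  png::writePNG(bundle$image, img_path)
  write_rois(bundle$rois, paste0(id, ".png"), file.path(dir, paste0(id, ".json")))
  wr_mask <- function(m, suffix)
    png::writePNG(m * 1.0, file.path(dir, paste0(id, "_", suffix, ".png")))
  wr_mask(bundle$vegetation_mask, "veg")
  wr_mask(bundle$pattern_map$body_mask, "body")
  wr_mask(bundle$pattern_map$speckle_mask, "speckle")
  wr_mask(bundle$pattern_map$midline_mask, "midline")
  invisible(img_path)
}

#' Simulate a scene set and population to disk
#'
#' Generates a population table, renders each record's scene, and writes
#' scenes, ROI JSONs, masks, and \code{population.csv} under \code{out_dir}.
#'
#' @param n number of individuals.
#' @param seed top-level seed.
#' @param out_dir output directory.
#' @param ... extra arguments to [population_params()].
#' @return the population tibble, invisibly.
#' @export
simulate_scenes <- function(n, seed, out_dir, ...) {
  pop <- generate_population(population_params(n = n, seed = seed, ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(pop))) {
    b <- scene_from_record(pop[i, ], seed = derive_seed(seed, pop$id[i]))
    write_scene_bundle(b, out_dir, pop$id[i])
  }
  utils::write.csv(pop, file.path(out_dir, "population.csv"), row.names = FALSE)
  invisible(pop)
}

# Scene PNGs in a directory, excluding the generator's mask files.
list_scene_images <- function(image_dir) {
  imgs <- sort(list.files(image_dir, pattern = "\\.png$"))
  imgs[!grepl("_(veg|body|speckle|midline)\\.png$", imgs)]
}

#' Validate a pipeline input set
#'
#' Cross-checks images, ROI files, and metadata without mutating anything:
#' missing ROI files, ROI vertices out of image bounds, missing gray-standard
#' regions, metadata ids without images and vice versa, duplicate metadata
#' ids.
#'
#' @param image_dir directory of PNG images.
#' @param roi_dir directory of ROI JSONs (same basenames).
#' @param metadata_csv optional CSV with an \code{id} column.
#' @return tibble of issues with columns \code{image, issue}; zero rows when
#'   the set is consistent.
#' @export
validate_inputs <- function(image_dir, roi_dir, metadata_csv = NULL) {
  issues <- list()
  note <- function(image, issue)
    issues[[length(issues) + 1]] <<- tibble::tibble(image = image, issue = issue)
  imgs <- list_scene_images(image_dir)
  ids <- sub("\\.png$", "", imgs)
  for (k in seq_along(imgs)) {
    roi_path <- file.path(roi_dir, paste0(ids[k], ".json"))
    if (!file.exists(roi_path)) {
      note(imgs[k], "missing ROI file")
      next
    }
    rois <- tryCatch(read_rois(roi_path), error = function(e) NULL)
    if (is.null(rois)) {
      note(imgs[k], "malformed ROI JSON")
      next
    }
    if (!"gray_standard" %in% names(rois)) note(imgs[k], "missing gray_standard ROI")
    dm <- dim(png::readPNG(file.path(image_dir, imgs[k])))
    for (r in rois) {
      v <- r$vertices
      if (any(v[, 1] < -1 | v[, 1] > dm[2] | v[, 2] < -1 | v[, 2] > dm[1])) {
        note(imgs[k], paste0("ROI '", r$label, "' vertex out of image bounds"))
      }
    }
  }
  if (!is.null(metadata_csv) && file.exists(metadata_csv)) {
    md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
    if (!"id" %in% names(md)) {
      note(NA_character_, "metadata has no id column")
    } else {
      dup <- unique(md$id[duplicated(md$id)])
      for (d in dup) note(d, "duplicate id in metadata")
      for (m in setdiff(md$id, ids)) note(m, "metadata id without image")
      for (m in setdiff(ids, md$id)) note(m, "image without metadata row")
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    tibble::tibble(image = character(0), issue = character(0))
}

#' Run the extraction pipeline over a directory of images
#'
#' For every PNG in \code{image_dir} with a matching ROI JSON in
#' \code{roi_dir}: samples each ROI, calibrates against the in-frame gray
#' standard, computes color metrics and contrasts, joins per-image metadata,
#' and writes \code{records.csv} plus a run manifest (config, seed, processed
#' and skipped images) to \code{out_dir}. Images lacking a gray standard are
#' skipped with a logged reason; every input is accounted for in the manifest.
#' A malformed ROI JSON is a hard error naming the file. Reruns with the same
#' inputs, config, and seed produce byte-identical records.
#'
#' @param image_dir directory of scene PNGs (mask PNGs named
#'   \code{*_veg/_body/_speckle/_midline.png} are ignored).
#' @param roi_dir directory of ROI JSONs.
#' @param metadata_csv optional per-individual metadata CSV keyed by
#'   \code{id}.
#' @param config a [pipeline_config()].
#' @param out_dir output directory; when \code{NULL} nothing is written.
#' @return the records tibble, invisibly; attribute \code{"manifest"} carries
#'   the run manifest.
#' @export
run_pipeline <- function(image_dir, roi_dir, metadata_csv = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  imgs <- list_scene_images(image_dir)
  ids <- sub("\\.png$", "", imgs)
  records <- list()
  skipped <- list()
  for (k in seq_along(imgs)) {
    id <- ids[k]
    roi_path <- file.path(roi_dir, paste0(id, ".json"))
    if (!file.exists(roi_path)) {
      skipped[[id]] <- "missing ROI file"
      message("skip ", id, ": missing ROI file")
      next
    }
    rois <- read_rois(roi_path)  # malformed JSON is a hard error
    image <- png::readPNG(file.path(image_dir, imgs[k]))
    row <- extract_image_record(image, rois, id, config)
    if (inherits(row, "skip_record")) {
      skipped[[id]] <- row$reason
      message("skip ", id, ": ", row$reason)
      next
    }
    records[[id]] <- row
  }
  out <- if (length(records)) do.call(rbind, records) else
    augment_records(tibble::tibble(
      id = character(0),
      dorsal_R = numeric(0), dorsal_G = numeric(0), dorsal_B = numeric(0),
      ventral_R = numeric(0), ventral_G = numeric(0), ventral_B = numeric(0),
      ventral_tail_R = numeric(0), ventral_tail_G = numeric(0),
      ventral_tail_B = numeric(0),
      background_R = numeric(0), background_G = numeric(0),
      background_B = numeric(0)))
  if (nrow(out) == 0) warning("no images processed", call. = FALSE)
  if (!is.null(metadata_csv) && file.exists(metadata_csv) && nrow(out) > 0) {
    md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
    keep <- setdiff(names(md), setdiff(names(out), "id"))
    out <- merge(out, md[keep], by = "id", all.x = TRUE, sort = TRUE)
    out <- tibble::as_tibble(out[order(out$id), ])
  }
  manifest <- list(config = unclass(config),
                   n_processed = nrow(out),
                   processed = as.list(setdiff(ids, names(skipped))),
                   skipped = skipped)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "records.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(out, "manifest") <- manifest
  invisible(out)
}
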