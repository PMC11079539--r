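#' Write / read a fringe stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 16-bit grayscale TIFF pages, scaled by the
#' `intensity_scale` recorded in the sidecar (`<path>.json`), so the
#' quantization step is `intensity_scale / 65535` intensity units. The
#' sidecar carries the frequency id, phase offsets, noise level, seed and
#' the full rig configuration; reading without it is an error, as is a
#' frame-count mismatch.
#'
#' @param stack a `fringe_stack`.
#' @param path TIFF file path; the sidecar is written beside it.
#' @param intensity_scale full-scale intensity mapped to 65535.
#' @return `read_fringe_stack` returns a `fringe_stack`.
#' @export
write_fringe_stack <- function(stack, path, intensity_scale = 256) {
  stopifnot(inherits(stack, "fringe_stack"))
  imgs <- lapply(stack$images, function(fr) {
    # quantize explicitly so the stored value is the *rounded* 16-bit code
    round(pmin(pmax(fr / intensity_scale, 0), 1) * 65535) / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  meta <- list(schema_version = 1L,
               n_frames = length(stack$images),
               frequency_id = stack$frequency_id,
               phase_offsets = stack$phase_offsets,
               noise_sd = stack$noise_sd, seed = stack$seed,
               mean_intensity = stack$mean_intensity,
               modulation = stack$modulation,
               intensity_scale = intensity_scale,
               bits_per_sample = 16L,
               rig = unclass(stack$rig))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_fringe_stack
#' @export
read_fringe_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing sidecar metadata file: ", sp, call. = FALSE)
  }
  meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                   error = function(e) {
                     stop("corrupt sidecar file ", sp, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_frames) {
    stop(sprintf("frame count mismatch: TIFF has %d pages, sidecar says %d",
                 length(pages), meta$n_frames), call. = FALSE)
  }
  rig <- do.call(make_default_rig, meta$rig)
  images <- lapply(pages, function(p) p * meta$intensity_scale)
  new_fringe_stack(images, rig, meta$frequency_id, meta$noise_sd,
                   meta$seed, meta$mean_intensity, meta$modulation)
}

#' Write / read a height map as 32-bit float TIFF plus JSON sidecar
#'
#' The height field `h` (mm) is stored as a float TIFF with invalid pixels
#' zeroed; the validity mask is run-length encoded in the sidecar along
#' with the rig and the provenance chain. Lateral coordinate fields are
#' recomputed from `h` and the rig on read.
#'
#' @param hm a `height_map`.
#' @param path TIFF file path.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  h <- hm$h
  h[!hm$valid_mask] <- 0
  # float TIFF stores raw values; heights fit comfortably in float range
  tiff::writeTIFF(h / 64 + 0.5, path, bits.per.sample = 32L)
  r <- rle(as.logical(hm$valid_mask))
  meta <- list(schema_version = 1L, height_scale = 64, height_offset = 0.5,
               mask_rle = list(lengths = r$lengths, values = r$values),
               provenance = unlist(hm$provenance),
               rig = unclass(hm$rig))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar: ", sp, call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  h <- (tiff::readTIFF(path) - meta$height_offset) * meta$height_scale
  valid <- matrix(inverse.rle(list(lengths = meta$mask_rle$lengths,
                                   values = meta$mask_rle$values)),
                  nrow(h), ncol(h))
  h[!valid] <- NA_real_
  rig <- do.call(make_default_rig, meta$rig)
  # recompute per-pixel lateral coordinates from z = L - h
  lat <- lateral_grids(rig)
  L <- rig$standard_height_mm
  hz <- ifelse(valid, h, 0)
  z <- L - hz
  new_height_map(h, lat$x * z / L, lat$y * z / L, valid, rig,
                 as.list(meta$provenance))
}

#' Export a height map as a point cloud
#'
#' One vertex per valid pixel, coordinates in mm in the camera frame.
#' `ply` writes binary little-endian PLY with float `x y z` properties;
#' `xyz` writes whitespace-separated text.
#'
#' @param hm a `height_map`.
#' @param path output file path.
#' @param format `"ply"` or `"xyz"`.
#' @export
export_point_cloud <- function(hm, path, format = c("ply", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(hm, "height_map"))
  m <- hm$valid_mask
  if (!any(m)) stop("height map has no valid pixels", call. = FALSE)
  L <- hm$rig$standard_height_mm
  pts <- cbind(hm$x[m], hm$y[m], L - hm$h[m])
  if (format == "xyz") {
    utils::write.table(pts, path, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- c("ply", "format binary_little_endian 1.0",
                paste("element vertex", nrow(pts)),
                "property float x", "property float y", "property float z",
                "end_header")
    writeLines(header, con, sep = "\n")
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read back an exported point cloud
#'
#' Supports the binary PLY layout written by [export_point_cloud()] and
#' plain XYZ text.
#'
#' @param path file path.
#' @param format `"ply"` or `"xyz"`.
#' @return an n x 3 numeric matrix (mm).
#' @export
read_point_cloud <- function(path, format = c("ply", "xyz")) {
  format <- match.arg(format)
  if (format == "xyz") {
    return(as.matrix(utils::read.table(path)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  n <- NA_integer_
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header", call. = FALSE)
    if (grepl("^element vertex", line)) {
      n <- as.integer(strsplit(line, " ")[[1]][3])
    }
    if (line == "end_header") break
  }
  vals <- readBin(con, "numeric", n = 3L * n, size = 4L, endian = "little")
  matrix(vals, ncol = 3L, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
}

#' Export a profile as CSV
#'
#' Columns `arc_mm, x_mm, y_mm, z_mm, h_mm`.
#'
#' @param profile a [extract_profile()] result.
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "surface_profile"))
  utils::write.csv(data.frame(arc_mm = profile$arc_coordinate,
                              x_mm = profile$points[, 1],
                              y_mm = profile$points[, 2],
                              z_mm = profile$points[, 3],
                              h_mm = profile$h),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a lesion mask as a 0/255 PNG-style TIFF-free matrix
#'
#' Writes the mask aligned to the height-map grid as an 8-bit PNG.
#'
#' @param mask a `lesion_mask`.
#' @param path PNG path.
#' @export
write_lesion_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write mask images", call. = FALSE)
  }
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Write a lesion measurement as JSON
#'
#' @param lm a `lesion_measurement`.
#' @param path JSON path.
#' @export
write_lesion_measurement <- function(lm, path) {
  stopifnot(inherits(lm, "lesion_measurement"))
  jsonlite::write_json(unclass(lm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' The resolved configuration of a full simulate/reconstruct/measure run:
#' rig, scene descriptor, noise, seed and processing options. Serializes
#' losslessly to JSON; every command writes its resolved config next to its
#' outputs so any result is reproducible from config + seed.
#'
#' @param rig a `rig_config`.
#' @param scene a `surface_scene` (its descriptor is stored).
#' @param noise_sd,seed simulation noise and seed.
#' @param unwrap_method,smooth_mm,surface_degree,lesion_threshold_mm
#'   processing options.
#' @export
run_config <- function(rig = make_default_rig(),
                       scene = stomach_lesion_scene(),
                       noise_sd = 2, seed = 1L,
                       unwrap_method = "temporal", smooth_mm = 0.3,
                       surface_degree = 2, lesion_threshold_mm = 0.5) {
  structure(list(schema_version = 1L, rig = rig,
                 scene = scene$descriptor, noise_sd = noise_sd,
                 seed = as.integer(seed), unwrap_method = unwrap_method,
                 smooth_mm = smooth_mm, surface_degree = surface_degree,
                 lesion_threshold_mm = lesion_threshold_mm),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$rig <- unclass(out$rig)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(rig = do.call(make_default_rig, x$rig),
                    scene = scene_from_descriptor(x$scene),
                    noise_sd = x$noise_sd, seed = x$seed,
                    unwrap_method = x$unwrap_method,
                    smooth_mm = x$smooth_mm,
                    surface_degree = x$surface_degree,
                    lesion_threshold_mm = x$lesion_threshold_mm)
  cfg$scene <- x$scene
  cfg
}
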