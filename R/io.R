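#' Write a labeled tile as paired PNG files (plus nucleus ledger)
#'
#' `<name>.png` holds the RGB image and `<name>_mask.png` the class-index
#' mask as a single-channel PNG with raw values 0/1/2; the nucleus ledger
#' goes to `<name>_nuclei.csv`.
#'
#' @param tile a `labeled_tile`
#' @param dir output directory (created)
#' @param name file stem
#' @export
write_tile <- function(tile, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(aperm(tile$image / 255, c(1, 2, 3)),
                file.path(dir, paste0(name, ".png")))
  png::writePNG(tile$mask / 255, file.path(dir, paste0(name, "_mask.png")))
  if (!is.null(tile$nuclei) && nrow(tile$nuclei) > 0)
    write.csv(tile$nuclei, file.path(dir, paste0(name, "_nuclei.csv")),
              row.names = FALSE)
  invisible(file.path(dir, paste0(name, ".png")))
}

#' Read a tile written by [write_tile()]
#' @param dir directory
#' @param name file stem
#' @return list(image 0..255 array, mask integer matrix, nuclei or NULL)
#' @export
read_tile <- function(dir, name) {
  img <- png::readPNG(file.path(dir, paste0(name, ".png"))) * 255
  msk <- round(png::readPNG(file.path(dir, paste0(name, "_mask.png"))) * 255)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  nuc_path <- file.path(dir, paste0(name, "_nuclei.csv"))
  nuclei <- if (file.exists(nuc_path)) read.csv(nuc_path) else NULL
  list(image = img, mask = matrix(as.integer(msk), nrow(msk), ncol(msk)),
       nuclei = nuclei)
}

#' Write a class mask as an indexed PNG (values 0/1/2)
#' @param mask integer matrix
#' @param path output file
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a class mask written by [write_mask_png()]
#' @param path PNG file
#' @export
read_mask_png <- function(path) {
  m <- round(png::readPNG(path) * 255)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Export a class mask as a QuPath-compatible GeoJSON FeatureCollection
#'
#' One polygon feature per connected component per class, with the class
#' name in `properties$classification$name`. Coordinates are in level-0
#' pixels (x = column, y = row), scaled by the mask stride.
#'
#' @param mask integer class matrix (or `label_mask`)
#' @param path output .geojson file
#' @param stride pixel scale of the mask (taken from a `label_mask`)
#' @param class_names names for classes 1, 2, ...
#' @export
mask_to_geojson <- function(mask, path, stride = 1L,
                            class_names = c("DCIS", "IC")) {
  if (inherits(mask, "label_mask")) { stride <- mask$stride; mask <- mask$mask }
  features <- list()
  for (cls in seq_along(class_names)) {
    bin <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)  # pad so rings close
    bin[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- (mask == cls) * 1
    lines <- grDevices::contourLines(
      x = seq_len(nrow(bin)) - 1.5, y = seq_len(ncol(bin)) - 1.5, z = bin,
      levels = 0.5)
    for (ln in lines) {
      coords <- cbind(ln$y, ln$x) * stride  # x = column axis, y = row axis
      coords <- rbind(coords, coords[1, ])  # close the ring
      features[[length(features) + 1]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(coords)),
                                                  function(i) coords[i, ]))),
        properties = list(classification = list(name = class_names[cls]),
                          isLocked = FALSE)
      )
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 4)
  invisible(path)
}

#' Write a pseudo-WSI (image PNG + mask PNG + nucleus ledger CSV + truth JSON)
#' @param wsi a `pseudo_wsi`
#' @param dir output directory
#' @param name file stem
#' @export
write_pseudo_wsi <- function(wsi, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(wsi$image / 255, file.path(dir, paste0(name, ".png")))
  png::writePNG(wsi$mask / 255, file.path(dir, paste0(name, "_mask.png")))
  write.csv(wsi$nuclei, file.path(dir, paste0(name, "_nuclei.csv")),
            row.names = FALSE)
  jsonlite::write_json(wsi$truth, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
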