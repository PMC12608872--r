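# Annotation formats. Package-wide coordinate conventions:
#   * internal boxes: 0-based, half-open, float (x_min, y_min, x_max, y_max);
#   * Pascal-VOC (LabelImg dialect): 1-based inclusive integer corners, so
#     voc_xmin = round(x_min) + 1 and voc_xmax = round(x_max);
#   * YOLO txt: normalized floating-point centre/width/height, 0-based.
# Conversions are lossless up to the +/-0.5 px integer re-quantization of the
# VOC edge.

#' Read and write Pascal-VOC XML annotations (LabelImg dialect)
#'
#' The writer emits the folder/filename/size/object/bndbox layout produced by
#' LabelImg; the reader validates coordinate order and bounds and reports the
#' offending object on failure. Class names (including `"Phoca largha"`) are
#' preserved byte-exact. `read_voc()` after `write_voc()` is the identity on
#' valid annotations.
#'
#' @param path XML file path.
#' @return `read_voc()` returns a `voc_annotation`: list with `filename`,
#'   `width`, `height`, `depth` and `objects` (data frame of class names and
#'   1-based inclusive integer corners).
#' @export
read_voc <- function(path) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "size")
  ann <- list(
    filename = xml2::xml_text(xml2::xml_find_first(doc, "filename")),
    width = as.integer(xml2::xml_text(xml2::xml_find_first(size, "width"))),
    height = as.integer(xml2::xml_text(xml2::xml_find_first(size, "height"))),
    depth = as.integer(xml2::xml_text(xml2::xml_find_first(size, "depth"))))
  objs <- xml2::xml_find_all(doc, "object")
  rows <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    bb <- xml2::xml_find_first(o, "bndbox")
    v <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(tag)
      as.numeric(xml2::xml_text(xml2::xml_find_first(bb, tag))), numeric(1))
    name <- xml2::xml_text(xml2::xml_find_first(o, "name"))
    if (!nzchar(name))
      stop(sprintf("%s: object %d has an empty class name", path, i), call. = FALSE)
    if (v["xmin"] > v["xmax"] || v["ymin"] > v["ymax"])
      stop(sprintf("%s: object %d has reversed coordinates (xmin > xmax or ymin > ymax)",
                   path, i), call. = FALSE)
    if (v["xmin"] < 1 || v["ymin"] < 1 || v["xmax"] > ann$width || v["ymax"] > ann$height)
      stop(sprintf("%s: object %d box exceeds the %dx%d image bounds",
                   path, i, ann$width, ann$height), call. = FALSE)
    data.frame(name = name, xmin = v["xmin"], ymin = v["ymin"],
               xmax = v["xmax"], ymax = v["ymax"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  ann$objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), xmin = numeric(0), ymin = numeric(0),
               xmax = numeric(0), ymax = numeric(0), stringsAsFactors = FALSE)
  structure(ann, class = "voc_annotation")
}

#' @rdname read_voc
#' @param ann a `voc_annotation` (or compatible list).
#' @export
write_voc <- function(ann, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", dirname(ann$filename %||% "images"))
  xml2::xml_add_child(doc, "filename", basename(ann$filename))
  xml2::xml_add_child(doc, "path", ann$filename)
  src <- xml2::xml_add_child(doc, "source")
  xml2::xml_add_child(src, "database", "Unknown")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", as.character(ann$depth %||% 3L))
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(nrow(ann$objects))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ann$objects$name[i])
    xml2::xml_add_child(o, "pose", "Unspecified")
    xml2::xml_add_child(o, "truncated", "0")
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(as.integer(ann$objects$xmin[i])))
    xml2::xml_add_child(bb, "ymin", as.character(as.integer(ann$objects$ymin[i])))
    xml2::xml_add_child(bb, "xmax", as.character(as.integer(ann$objects$xmax[i])))
    xml2::xml_add_child(bb, "ymax", as.character(as.integer(ann$objects$ymax[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Convert between internal boxes and annotation formats
#'
#' `boxes_to_voc()`/`voc_to_boxes()` map internal 0-based half-open float
#' boxes to the 1-based inclusive integer VOC edge (and back);
#' `voc_to_yolo()`/`yolo_to_voc()` bridge the two file formats through the
#' internal convention. A VOC -> YOLO -> VOC round trip reproduces integer
#' corners exactly; arbitrary float boxes re-quantize within 0.5 px.
#' Zero-area boxes are dropped with a warning.
#'
#' @param boxes internal ground-truth data frame.
#' @param width,height image size in pixels.
#' @param filename image file name stored in the annotation.
#' @return see each converter.
#' @export
boxes_to_voc <- function(boxes, width, height, filename = "image.png") {
  objs <- data.frame(name = boxes$class_id,
                     xmin = round(boxes$x_min) + 1, ymin = round(boxes$y_min) + 1,
                     xmax = round(boxes$x_max), ymax = round(boxes$y_max),
                     stringsAsFactors = FALSE)
  keep <- objs$xmax >= objs$xmin & objs$ymax >= objs$ymin
  if (any(!keep)) warning(sum(!keep), " zero-area box(es) dropped")
  structure(list(filename = filename, width = as.integer(width),
                 height = as.integer(height), depth = 3L,
                 objects = objs[keep, , drop = FALSE]),
            class = "voc_annotation")
}

#' @rdname boxes_to_voc
#' @param ann a `voc_annotation`.
#' @export
voc_to_boxes <- function(ann) {
  o <- ann$objects
  ground_truth(o$xmin - 1, o$ymin - 1, o$xmax, o$ymax, class_id = o$name)
}

#' @rdname boxes_to_voc
#' @param classes character vector mapping YOLO class indices (0-based) to
#'   names.
#' @export
voc_to_yolo <- function(ann, classes = "Phoca largha") {
  b <- voc_to_boxes(ann)
  boxes_to_yolo(b, ann$width, ann$height, classes)
}

#' @rdname boxes_to_voc
#' @export
boxes_to_yolo <- function(boxes, width, height, classes = "Phoca largha") {
  w <- boxes$x_max - boxes$x_min
  h <- boxes$y_max - boxes$y_min
  keep <- w > 0 & h > 0
  if (any(!keep)) warning(sum(!keep), " zero-area box(es) dropped")
  data.frame(class = match(boxes$class_id[keep], classes) - 1L,
             cx = (boxes$x_min[keep] + boxes$x_max[keep]) / 2 / width,
             cy = (boxes$y_min[keep] + boxes$y_max[keep]) / 2 / height,
             w = w[keep] / width, h = h[keep] / height)
}

#' @rdname boxes_to_voc
#' @param yolo YOLO label data frame (`class cx cy w h`, normalized).
#' @export
yolo_to_boxes <- function(yolo, width, height, classes = "Phoca largha") {
  ground_truth(x_min = (yolo$cx - yolo$w / 2) * width,
               y_min = (yolo$cy - yolo$h / 2) * height,
               x_max = (yolo$cx + yolo$w / 2) * width,
               y_max = (yolo$cy + yolo$h / 2) * height,
               class_id = classes[yolo$class + 1L])
}

#' @rdname boxes_to_voc
#' @export
yolo_to_voc <- function(yolo, width, height, classes = "Phoca largha",
                        filename = "image.png") {
  boxes_to_voc(yolo_to_boxes(yolo, width, height, classes), width, height, filename)
}

#' Read and write YOLO-format label files
#'
#' Plain-text label files: one `class cx cy w h` line per box (normalized
#' coordinates), with an optional sixth confidence column for detection
#' files.
#'
#' @param path txt file path.
#' @return data frame with columns `class`, `cx`, `cy`, `w`, `h` and, when
#'   present, `conf`.
#' @export
read_yolo_txt <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  m <- utils::read.table(path, header = FALSE)
  names(m) <- c("class", "cx", "cy", "w", "h", "conf")[seq_len(ncol(m))]
  m
}

#' @rdname read_yolo_txt
#' @param labels YOLO label data frame.
#' @export
write_yolo_txt <- function(labels, path) {
  cols <- intersect(c("class", "cx", "cy", "w", "h", "conf"), names(labels))
  lines <- if (nrow(labels))
    apply(labels[, cols, drop = FALSE], 1, function(r)
      paste(formatC(r, format = "fg", digits = 8), collapse = " "))
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

# round-half-up
rhu <- function(x) floor(x + 0.5)

#' Split a dataset manifest into disjoint train/validation parts
#'
#' Deterministic seeded shuffle followed by a partition at the requested
#' `train:val` ratio; the validation size is round-half-up of the validation
#' share, so 3036 images at 9:1 give 304 validation and 2732 training
#' frames. The two parts are disjoint and their union is the input.
#'
#' @param manifest data frame with one row per image.
#' @param ratio integer `c(train, val)` ratio.
#' @param seed shuffle seed.
#' @return the manifest with a `split` column (`"train"`/`"val"`).
#' @export
split_dataset <- function(manifest, ratio = c(9L, 1L), seed = 0L) {
  n <- nrow(manifest)
  if (n == 0L) stop("empty manifest", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_val <- rhu(n * ratio[2] / sum(ratio))
  ord <- sample.int(n)
  manifest$split <- "train"
  manifest$split[ord[seq_len(n_val)]] <- "val"
  manifest
}

#' Generate an annotated synthetic dataset on disk
#'
#' Renders `n_images` scenes (per-image seeds derived from the master seed by
#' counter, so any subset regenerates identically), writes PNG images,
#' Pascal-VOC XML and YOLO txt labels, splits train/validation and records
#' everything in a CSV manifest (path, label paths, split, condition,
#' target count).
#'
#' @param n_images number of frames (>= 10 for a 9:1 split).
#' @param out_dir output directory (created).
#' @param spec_fn function `(index, seed)` returning the [scene_spec()] for
#'   one frame; the default cycles the four weather conditions with 0-6
#'   targets at 15 m and 20 m altitudes.
#' @param ratio train:val integer ratio.
#' @param seed master seed.
#' @return the dataset manifest data frame (invisibly written to
#'   `manifest.csv`).
#' @export
make_dataset <- function(n_images, out_dir, spec_fn = NULL, ratio = c(9L, 1L),
                         seed = 0L) {
  stopifnot(n_images >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels_voc"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels_yolo"), showWarnings = FALSE)
  conds <- c("sunny", "reflective", "foggy", "overcast")
  if (is.null(spec_fn)) spec_fn <- function(i, s)
    scene_spec(n_targets = (i * 3L) %% 7L, weather = conds[(i - 1L) %% 4L + 1L],
               altitude = c("15m", "20m")[(i %% 2L) + 1L], seed = s)
  rows <- lapply(seq_len(n_images), function(i) {
    spec <- spec_fn(i, seed + i)
    sc <- generate_scene(spec)
    img_path <- file.path(out_dir, "images", sprintf("img_%05d.png", i))
    xml_path <- file.path(out_dir, "labels_voc", sprintf("img_%05d.xml", i))
    txt_path <- file.path(out_dir, "labels_yolo", sprintf("img_%05d.txt", i))
    png::writePNG(sc$image, img_path)
    write_voc(boxes_to_voc(sc$boxes, spec$canvas, spec$canvas,
                           basename(img_path)), xml_path)
    write_yolo_txt(boxes_to_yolo(sc$boxes, spec$canvas, spec$canvas), txt_path)
    data.frame(image = img_path, label_voc = xml_path, label_yolo = txt_path,
               condition = spec$weather, n_targets = nrow(sc$boxes),
               stringsAsFactors = FALSE)
  })
  manifest <- split_dataset(do.call(rbind, rows), ratio, seed)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
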