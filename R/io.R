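## File formats: 8-bit grayscale PNG, CVAT-dialect ("images 1.1") annotation
## XML with labeled polygons and points, paired-reading CSV, and the YAML run
## configuration. Every writer has a reader that round-trips.

.structure_labels <- c("ilium", "acetabulum", "labrum")

#' Write an 8-bit grayscale image as PNG
#'
#' @param image numeric/integer matrix with values 0-255 (rows = y).
#' @param path output file.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#'
#' Color images are collapsed to grayscale by channel averaging.
#'
#' @param path PNG file.
#' @return integer matrix with values 0-255 (rows = y).
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3])], c(1, 2), mean)
  img <- round(x * 255)
  storage.mode(img) <- "integer"
  img
}

#' Annotation document for one or more images
#'
#' @param images list; each element a list with `name`, `width`, `height`,
#'   `polygons` (named list, labels among ilium/acetabulum/labrum, each an
#'   n x 2 matrix of x,y vertices) and `points` (named list, labels among
#'   the five landmark names, each `c(x, y)`).
#' @return object of class `annotation_document`.
#' @export
annotation_document <- function(images) {
  for (im in images) {
    stopifnot(!is.null(im$name), !is.null(im$width), !is.null(im$height))
    for (lab in names(im$polygons)) {
      if (!lab %in% .structure_labels) {
        stop("annotation_document: unknown polygon label '", lab, "'",
             call. = FALSE)
      }
    }
    for (lab in names(im$points)) {
      if (!lab %in% landmark_names()) {
        stop("annotation_document: unknown point label '", lab, "'",
             call. = FALSE)
      }
      p <- im$points[[lab]]
      if (p[1] < 0 || p[1] > im$width - 1 || p[2] < 0 || p[2] > im$height - 1) {
        stop("annotation_document: point '", lab, "' outside image bounds",
             call. = FALSE)
      }
    }
  }
  structure(list(images = images), class = "annotation_document")
}

.fmt_pts <- function(m) {
  m <- matrix(m, ncol = 2)
  paste(sprintf("%.3f,%.3f", m[, 1], m[, 2]), collapse = ";")
}

.parse_pts <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) as.numeric(p)))
}

#' Write annotations as CVAT-dialect XML
#'
#' Emits the "images 1.1" layout: an `<annotations>` root with one `<image>`
#' element per image carrying labeled `<polygon>` and `<points>` children
#' whose `points` attributes hold semicolon-separated `x,y` pairs.
#'
#' @param doc an [annotation_document()].
#' @param path output XML file.
#' @export
write_annotations <- function(doc, path) {
  stopifnot(inherits(doc, "annotation_document"))
  root <- xml2::xml_new_root("annotations")
  xml2::xml_add_child(root, "version", "1.1")
  for (i in seq_along(doc$images)) {
    im <- doc$images[[i]]
    node <- xml2::xml_add_child(root, "image", id = as.character(i - 1),
                                name = im$name,
                                width = as.character(im$width),
                                height = as.character(im$height))
    for (lab in names(im$polygons)) {
      xml2::xml_add_child(node, "polygon", label = lab, occluded = "0",
                          points = .fmt_pts(im$polygons[[lab]]))
    }
    for (lab in names(im$points)) {
      xml2::xml_add_child(node, "points", label = lab, occluded = "0",
                          points = .fmt_pts(im$points[[lab]]))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a CVAT-dialect annotation XML
#'
#' @param path XML file written by [write_annotations()] or exported by a
#'   compatible annotation tool.
#' @return an [annotation_document()]; unknown labels raise a parse error
#'   naming the label.
#' @export
read_annotations <- function(path) {
  root <- xml2::read_xml(path)
  images <- lapply(xml2::xml_find_all(root, ".//image"), function(node) {
    polygons <- list()
    points <- list()
    for (pg in xml2::xml_find_all(node, "./polygon")) {
      lab <- xml2::xml_attr(pg, "label")
      if (!lab %in% .structure_labels) {
        stop("read_annotations: unknown polygon label '", lab, "'",
             call. = FALSE)
      }
      polygons[[lab]] <- .parse_pts(xml2::xml_attr(pg, "points"))
    }
    for (pt in xml2::xml_find_all(node, "./points")) {
      lab <- xml2::xml_attr(pt, "label")
      if (!lab %in% landmark_names()) {
        stop("read_annotations: unknown point label '", lab, "'",
             call. = FALSE)
      }
      points[[lab]] <- as.numeric(.parse_pts(xml2::xml_attr(pt, "points"))[1, ])
    }
    list(name = xml2::xml_attr(node, "name"),
         width = as.numeric(xml2::xml_attr(node, "width")),
         height = as.numeric(xml2::xml_attr(node, "height")),
         polygons = polygons, points = points)
  })
  annotation_document(images)
}

#' Build an annotation entry from phantom ground truth
#'
#' Structure polygons are the convex hulls of the truth masks; points are the
#' five exact landmarks.
#'
#' @param truth a [phantom_truth()].
#' @param name image file name recorded in the annotation.
#' @return a single-image list suitable for [annotation_document()].
#' @export
annotation_from_truth <- function(truth, name) {
  stopifnot(inherits(truth, "phantom_truth"))
  polys <- lapply(truth$masks, function(m) {
    idx <- which(m)
    H <- nrow(m)
    xy <- cbind((idx - 1) %/% H, (idx - 1) %% H)
    xy[chull(xy), , drop = FALSE]
  })
  pts <- lapply(landmark_names(), function(nm) unname(truth$landmarks[[nm]]))
  names(pts) <- landmark_names()
  list(name = name, width = truth$spec$width_px, height = truth$spec$height_px,
       polygons = polys, points = pts)
}

#' Landmark set from an annotation image entry
#'
#' @param im one element of `annotation_document()$images` carrying all five
#'   labeled points.
#' @return a [landmark_set()].
#' @export
landmarks_from_annotation <- function(im) {
  missing <- setdiff(landmark_names(), names(im$points))
  if (length(missing) > 0) {
    stop("landmarks_from_annotation: missing points: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  landmark_set(im$points$check_upper, im$points$triradiate,
               im$points$lower_ilium, im$points$bone_edge,
               im$points$labrum_end)
}

#' Convert paired readings to the long CSV data frame dialect
#'
#' @param readings list of [paired_reading()] objects.
#' @return data.frame with columns `image_id`, `rater`, `detectable`,
#'   `check_deg`, `alpha_deg`, `beta_deg` (angles `NA` when undetectable).
#' @export
readings_to_df <- function(readings) {
  rows <- lapply(readings, function(r) {
    do.call(rbind, lapply(c("ai", "human"), function(who) {
      rd <- r[[who]]
      data.frame(image_id = r$image_id, rater = who,
                 detectable = rd$detectable,
                 check_deg = rd$check_deg, alpha_deg = rd$alpha_deg,
                 beta_deg = rd$beta_deg, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Reconstruct paired readings from the long CSV data frame dialect
#'
#' @param df data.frame as produced by [readings_to_df()].
#' @return list of [paired_reading()] objects.
#' @export
readings_from_df <- function(df) {
  need <- c("image_id", "rater", "detectable", "check_deg", "alpha_deg",
            "beta_deg")
  if (!all(need %in% names(df))) {
    stop("readings_from_df: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  ids <- unique(df$image_id)
  lapply(ids, function(id) {
    sub <- df[df$image_id == id, ]
    get_reading <- function(who) {
      row <- sub[sub$rater == who, ]
      if (nrow(row) != 1) {
        stop("readings_from_df: image '", id, "' needs exactly one '", who,
             "' row", call. = FALSE)
      }
      if (isTRUE(row$detectable)) {
        rater_reading(TRUE, row$check_deg, row$alpha_deg, row$beta_deg)
      } else {
        rater_reading(FALSE)
      }
    }
    paired_reading(id, get_reading("ai"), get_reading("human"))
  })
}

#' Write paired readings as CSV
#' @param readings list of [paired_reading()] objects.
#' @param path output CSV file.
#' @export
write_readings <- function(readings, path) {
  write.csv(readings_to_df(readings), path, row.names = FALSE)
  invisible(path)
}

#' Read paired readings from CSV
#' @param path CSV written by [write_readings()].
#' @return list of [paired_reading()] objects.
#' @export
read_readings <- function(path) {
  readings_from_df(read.csv(path, stringsAsFactors = FALSE))
}

#' Pipeline run configuration
#'
#' @param detector `"classical"` or `"neural"`.
#' @param threshold_quantile segmentation threshold quantile.
#' @param tolerance check-angle gate half-width, degrees.
#' @param alpha_cutoff Graf dichotomy threshold, degrees.
#' @param seed integer seed.
#' @param neural a [neural_config()] (used when `detector = "neural"`).
#' @return object of class `run_config`.
#' @export
run_config <- function(detector = c("classical", "neural"),
                       threshold_quantile = 0.85, tolerance = 5,
                       alpha_cutoff = 60, seed = 1L, neural = neural_config()) {
  detector <- match.arg(detector)
  stopifnot(threshold_quantile > 0, threshold_quantile < 1, tolerance >= 0)
  structure(list(detector = detector,
                 threshold_quantile = threshold_quantile,
                 tolerance = tolerance, alpha_cutoff = alpha_cutoff,
                 seed = as.integer(seed), neural = neural),
            class = "run_config")
}

#' Read a YAML run configuration, merging user values onto defaults
#' @param path YAML file; top-level keys mirror [run_config()] arguments and
#'   a `neural` block mirrors [neural_config()] field names.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  nc <- do.call(neural_config, y$neural %||% list())
  y$neural <- NULL
  do.call(run_config, c(y, list(neural = nc)))
}

#' Write a run configuration as YAML
#' @param cfg a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$neural <- unclass(cfg$neural)
  yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
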