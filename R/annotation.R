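# Labeled pixel annotations of container rims, and their JSON on-disk
# format.

CONTAINER_TYPES <- c("circular_plate", "square_plate", "bowl", "rect_box")

#' Construct a container annotation
#'
#' One annotated container inside an image: its type, the pixel points
#' marked on its mouth/rim, and (for raised containers) the height pair -
#' a rim point and the point on the inner wall/base vertically beneath
#' it.
#'
#' @param type One of `"circular_plate"`, `"square_plate"`, `"bowl"`,
#'   `"rect_box"`.
#' @param rim Data frame with pixel columns `x, y` (>= 2 points).
#'   Circular containers need either exactly 2 points marked as a
#'   diameter or at least 5 for circle fitting.
#' @param height_pair For bowls and boxes, a list
#'   `list(top = c(x, y), base = c(x, y))` in pixels.
#' @return A list of class `container_annotation`.
#' @export
container_annotation <- function(type, rim, height_pair = NULL) {
  type <- match.arg(type, CONTAINER_TYPES)
  rim <- tibble::as_tibble(rim)
  stopifnot(all(c("x", "y") %in% names(rim)))
  if (nrow(rim) < 2) stop("annotation needs at least 2 rim points", call. = FALSE)
  if (type == "circular_plate" && !(nrow(rim) == 2 || nrow(rim) >= 5)) {
    stop("circular containers need exactly 2 rim points (a diameter) or >= 5",
         call. = FALSE)
  }
  if (type %in% c("bowl", "rect_box")) {
    if (is.null(height_pair)) {
      stop("annotation error: ", type, " requires a height_pair", call. = FALSE)
    }
    stopifnot(all(c("top", "base") %in% names(height_pair)),
              length(height_pair$top) == 2, length(height_pair$base) == 2)
  }
  structure(list(type = type, rim = rim[, c("x", "y")],
                 height_pair = height_pair),
            class = "container_annotation")
}

#' Construct an image annotation
#'
#' @param image_id Identifier of the annotated image.
#' @param t_image Image timestamp in seconds (matches the sensor log).
#' @param containers List of [container_annotation()] objects.
#' @return A list of class `image_annotation`.
#' @export
image_annotation <- function(image_id, t_image, containers) {
  stopifnot(is.character(image_id), is.finite(t_image), is.list(containers))
  if (!all(vapply(containers, inherits, logical(1), "container_annotation"))) {
    stop("`containers` must be a list of container_annotation objects",
         call. = FALSE)
  }
  structure(list(image_id = image_id, t_image = t_image,
                 containers = containers),
            class = "image_annotation")
}

#' @export
print.image_annotation <- function(x, ...) {
  cat(sprintf("<image_annotation> %s @ %.3f s, %d container(s): %s\n",
              x$image_id, x$t_image, length(x$containers),
              paste(vapply(x$containers, `[[`, "", "type"), collapse = ", ")))
  invisible(x)
}

#' Read or write an annotation JSON file
#'
#' The schema is
#' `{image_id, t_image, containers: [{type, rim: [{x, y}, ...],
#' height_pair: {top: {x, y}, base: {x, y}}}]}`; `height_pair` is present
#' only for bowls and boxes. Files are validated on read.
#'
#' @param path JSON file path.
#' @return `read_annotation()` returns an [image_annotation()];
#'   `write_annotation()` returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("image_id", "t_image", "containers")) {
    if (is.null(j[[key]])) {
      stop("annotation is missing field `", key, "`", call. = FALSE)
    }
  }
  containers <- lapply(j$containers, function(cj) {
    if (is.null(cj$type) || is.null(cj$rim)) {
      stop("container annotation needs `type` and `rim`", call. = FALSE)
    }
    rim <- tibble::tibble(
      x = vapply(cj$rim, function(p) as.numeric(p$x), numeric(1)),
      y = vapply(cj$rim, function(p) as.numeric(p$y), numeric(1))
    )
    hp <- NULL
    if (!is.null(cj$height_pair)) {
      hp <- list(
        top = c(as.numeric(cj$height_pair$top$x),
                as.numeric(cj$height_pair$top$y)),
        base = c(as.numeric(cj$height_pair$base$x),
                 as.numeric(cj$height_pair$base$y))
      )
    }
    container_annotation(cj$type, rim, hp)
  })
  image_annotation(j$image_id, as.numeric(j$t_image), containers)
}

#' @rdname read_annotation
#' @param ann An [image_annotation()].
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "image_annotation"))
  j <- list(
    image_id = ann$image_id,
    t_image = ann$t_image,
    containers = lapply(ann$containers, function(cc) {
      out <- list(
        type = cc$type,
        rim = lapply(seq_len(nrow(cc$rim)), function(i) {
          list(x = cc$rim$x[i], y = cc$rim$y[i])
        })
      )
      if (!is.null(cc$height_pair)) {
        out$height_pair <- list(
          top = list(x = cc$height_pair$top[1], y = cc$height_pair$top[2]),
          base = list(x = cc$height_pair$base[1], y = cc$height_pair$base[2])
        )
      }
      out
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
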