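#' Simulate an image of shapes on a black background
#'
#' Starts from an all-zero (black) square grid and, independently with
#' probabilities `v`, `c`, `r` and `h`, overlays a Vertical bar, a Circle,
#' a Rectangle and a Horizontal bar at random positions and sizes within
#' the grid. Overlaid pixels are set to intensity 1; everything else stays
#' exactly 0. The scalar probabilities are the metadata variables that
#' control the image content, which makes the simulated images a ground
#' truth for methods that try to explain image predictors.
#'
#' A pixel belongs to the circle iff its centre lies within the radius
#' (Euclidean distance from the circle centre at most `radius`).
#'
#' @param v,c,r,h Probabilities in `[0, 1]` of overlaying a vertical bar,
#'   circle, rectangle and horizontal bar respectively.
#' @param size Side length of the square grid (default 64).
#' @return An object of class `shape_image`: a list with `pixels` (a
#'   `size` x `size` numeric matrix in `[0, 1]`) and `fired`, a named list
#'   recording, for each shape that was overlaid, its sampled geometry
#'   (for testability).
#' @examples
#' set.seed(1)
#' img <- shape_image(v = 0, c = 1, r = 0, h = 0)
#' names(img$fired)
#' @export
shape_image <- function(v, c, r, h, size = 64L) {
  for (p in list(v = v, c = c, r = r, h = h))
    check_probability(p, "shape probability")
  if (size < 16L) sim_abort("simdag_domain_error", "size must be at least 16")
  img <- matrix(0, size, size)
  fired <- list()

  if (stats::runif(1L) < v) {
    w <- rand_int(2L, max(2L, size %/% 12L))
    len <- rand_int(size %/% 2L, size - 2L)
    x0 <- rand_int(1L, size - w + 1L)
    y0 <- rand_int(1L, size - len + 1L)
    img[y0:(y0 + len - 1L), x0:(x0 + w - 1L)] <- 1
    fired$vertical_bar <- list(x0 = x0, y0 = y0, width = w, length = len)
  }
  if (stats::runif(1L) < c) {
    rad <- rand_int(max(2L, size %/% 12L), size %/% 5L)
    cx <- rand_int(rad + 1L, size - rad)
    cy <- rand_int(rad + 1L, size - rad)
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    inside <- (rows - cy)^2 + (cols - cx)^2 <= rad^2
    img[inside] <- 1
    fired$circle <- list(cx = cx, cy = cy, radius = rad)
  }
  if (stats::runif(1L) < r) {
    w <- rand_int(size %/% 8L, size %/% 3L)
    ht <- rand_int(size %/% 8L, size %/% 3L)
    x0 <- rand_int(1L, size - w + 1L)
    y0 <- rand_int(1L, size - ht + 1L)
    img[y0:(y0 + ht - 1L), x0:(x0 + w - 1L)] <- 1
    fired$rectangle <- list(x0 = x0, y0 = y0, width = w, height = ht)
  }
  if (stats::runif(1L) < h) {
    ht <- rand_int(2L, max(2L, size %/% 12L))
    len <- rand_int(size %/% 2L, size - 2L)
    x0 <- rand_int(1L, size - len + 1L)
    y0 <- rand_int(1L, size - ht + 1L)
    img[y0:(y0 + ht - 1L), x0:(x0 + len - 1L)] <- 1
    fired$horizontal_bar <- list(x0 = x0, y0 = y0, height = ht, length = len)
  }

  structure(list(pixels = img, fired = fired), class = "shape_image")
}

#' @export
print.shape_image <- function(x, ...) {
  cat(sprintf("<shape_image %dx%d: shapes {%s}, %d lit pixels>\n",
              nrow(x$pixels), ncol(x$pixels),
              paste(names(x$fired), collapse = ", "), sum(x$pixels > 0)))
  invisible(x)
}

#' The shape-image example graph
#'
#' Four metadata nodes drawn uniformly on `[0, 1]` control the shape
#' probabilities of the image node.
#'
#' @param size Image side length.
#' @return A `dag_graph`.
#' @export
shape_image_graph <- function(size = 64L) {
  u <- function(nm) node(nm, func = "simdag::rand_uniform",
                         args = list(min = 0, max = 1))
  build_graph(list(
    u("V"), u("C"), u("R"), u("H"),
    node("image", func = "simdag::shape_image",
         args = list(v = node_ref("V"), c = node_ref("C"),
                     r = node_ref("R"), h = node_ref("H"), size = size))
  ), name = "shape_images")
}
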