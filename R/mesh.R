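#' Triangulated cortical surface patch
#'
#' A minimal triangle-mesh container: vertex coordinates in mm and 1-based
#' triangle index triples. Degenerate (zero-area) triangles and
#' out-of-range indices are rejected.
#'
#' @param vertices Numeric matrix or data frame, n x 3 (x, y, z in mm).
#' @param faces Integer matrix or data frame, m x 3 of 1-based vertex
#'   indices.
#' @return An object of class `surface_patch`.
#' @export
surface_patch <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cross2 <- (a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
    (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
    (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2
  if (any(cross2 < 1e-18)) {
    stop("mesh contains degenerate (zero-area) triangles", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Region of interest on a surface patch
#'
#' An ROI with its two "end" borders: the manually drawn lines at the
#' lowest- and highest-preference edges of a topographic map. Borders must
#' be disjoint, non-empty subsets of the member set.
#'
#' @param members Integer vector of member vertex indices (1-based).
#' @param low_border,high_border Integer vectors of border vertex indices.
#' @return An object of class `roi_map`.
#' @export
roi_map <- function(members, low_border, high_border) {
  members <- as.integer(members)
  low_border <- as.integer(low_border)
  high_border <- as.integer(high_border)
  if (length(low_border) == 0L || length(high_border) == 0L) {
    stop("borders must be non-empty", call. = FALSE)
  }
  if (!all(low_border %in% members) || !all(high_border %in% members)) {
    stop("borders must be subsets of the member set", call. = FALSE)
  }
  if (length(intersect(low_border, high_border)) > 0L) {
    stop("borders must be disjoint", call. = FALSE)
  }
  structure(list(members = members, low_border = low_border,
                 high_border = high_border), class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("<roi_map> %d members, borders %d (low) / %d (high)\n",
              length(x$members), length(x$low_border),
              length(x$high_border)))
  invisible(x)
}

#' Write and read OFF-format meshes
#'
#' Plain-text Object File Format: a header line `OFF`, counts, vertex
#' coordinates, then faces as `3 i j k` with 0-based indices (converted
#' to/from the package's 1-based convention).
#'
#' @param patch A [surface_patch()].
#' @param path File path.
#' @return `write_off()` returns `path` invisibly; `read_off()` a
#'   [surface_patch()].
#' @export
write_off <- function(patch, path) {
  stopifnot(inherits(patch, "surface_patch"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(patch$vertices), nrow(patch$faces)), con)
  utils::write.table(format(patch$vertices, digits = 10, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, patch$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") {
    stop("not an OFF file", call. = FALSE)
  }
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]
  nf <- counts[2]
  vx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]][2:4])))
  surface_patch(vx, fc + 1L)
}

#' Write and read ROI vertex lists
#'
#' One vertex index per line, 0-based on disk (the common convention of
#' surface tools), converted to the package's 1-based indices in memory.
#'
#' @param indices Integer vector of 1-based vertex indices.
#' @param path File path.
#' @return `write_vertex_list()` returns `path` invisibly;
#'   `read_vertex_list()` an integer vector of 1-based indices.
#' @export
write_vertex_list <- function(indices, path) {
  writeLines(as.character(as.integer(indices) - 1L), path)
  invisible(path)
}

#' @rdname write_vertex_list
#' @export
read_vertex_list <- function(path) {
  as.integer(readLines(path)) + 1L
}
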