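#' Read an XYZ point cloud
#'
#' Standard XYZ format: atom count, comment line, then one
#' `symbol x y z` line per atom (coordinates in Angstrom).  Point weights
#' are taken from the same standard-atomic-weight table the composition
#' calculus uses, so mass-weighted descriptors are consistent across the
#' package.
#'
#' @param path File path.
#' @return A [conformer_cloud()] (unit `"A"`) with a `comment` attribute.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("XYZ file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ file ", path, ": line 1 must be the atom count", call. = FALSE)
  if (length(lines) < n + 2L)
    stop("XYZ file ", path, ": expected ", n, " atom lines, found ",
         length(lines) - 2L, call. = FALSE)
  body <- lines[3:(n + 2L)]
  fields <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0L)
    stop("XYZ file ", path, ": malformed atom line ", bad[1L] + 2L,
         call. = FALSE)
  sym <- vapply(fields, `[[`, "", 1L)
  xyz <- suppressWarnings(
    t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3))))
  if (anyNA(xyz))
    stop("XYZ file ", path, ": non-numeric coordinates", call. = FALSE)
  weights <- vapply(sym, atomic_weight, numeric(1))
  cloud <- conformer_cloud(xyz, weights = weights, unit = "A")
  cloud$elements <- sym
  attr(cloud, "comment") <- lines[2L]
  cloud
}

#' Write a point cloud to XYZ
#'
#' @param cloud A [conformer_cloud()]; if it lacks element symbols the
#'   points are written as carbon.
#' @param path Output path.
#' @param comment Comment line (line 2).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path, comment = "") {
  stopifnot(inherits(cloud, "conformer_cloud"))
  sym <- if (!is.null(cloud$elements)) cloud$elements
         else rep("C", nrow(cloud$points))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(cloud$points)), comment), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", sym,
                     cloud$points[, 1], cloud$points[, 2],
                     cloud$points[, 3]), con)
  invisible(path)
}
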