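# Plain-text readers and writers for the pipeline's table formats. Landmark
# files use 0-based landmark ids, micrometre units and right-handed
# coordinates; trees are Newick with branch lengths.

#' Read a landmark CSV
#'
#' Expected columns: `specimen,species,landmark_id,x,y,z` with 0-based
#' landmark ids; every specimen must carry the same landmark ids.
#'
#' @param path CSV file.
#' @param subsets optional named list of 1-based landmark index vectors.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path, subsets = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "species", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ","))
  ids <- unique(d$specimen)
  lms <- sort(unique(d$landmark_id))
  p <- length(lms)
  A <- array(NA_real_, c(p, 3L, length(ids)),
             dimnames = list(NULL, c("x", "y", "z"), ids))
  species <- character(length(ids))
  for (i in seq_along(ids)) {
    di <- d[d$specimen == ids[i], ]
    if (!identical(sort(di$landmark_id), lms))
      stop("specimen ", ids[i], " has mismatched landmark ids")
    di <- di[order(di$landmark_id), ]
    A[, , i] <- as.matrix(di[, c("x", "y", "z")])
    species[i] <- di$species[1L]
  }
  landmark_set(A, species, subsets)
}

#' Write a landmark CSV (0-based landmark ids)
#'
#' @param landmarks a `landmark_set`.
#' @param path output file.
#' @export
write_landmarks <- function(landmarks, path) {
  A <- landmarks$coords
  p <- dim(A)[1L]; n <- dim(A)[3L]
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(specimen = dimnames(A)[[3L]][i],
               species = landmarks$specimens$species[i],
               landmark_id = seq_len(p) - 1L,
               x = A[, 1L, i], y = A[, 2L, i], z = A[, 3L, i])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
}

#' Read a species -> locomotor-mode table
#' @param path CSV with columns `species,mode`.
#' @return named character vector.
#' @export
read_modes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(d$mode), d$species)
}

#' Read a volume CSV (`species,brain_mm3,cerebellum_mm3[,mode]`)
#' @param path CSV file.
#' @param modes optional named mode map if the file lacks a mode column.
#' @return a `volume_table`.
#' @export
read_volumes <- function(path, modes = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  mode <- if ("mode" %in% names(d)) d$mode else modes[d$species]
  volume_table(d$species, d$brain_mm3, d$cerebellum_mm3, mode)
}

#' Read a cell-depth CSV
#' (`species,cell_id,dist_gcl_um,ml_thickness_um`)
#' @param path CSV file.
#' @return a `cell_depth_table`.
#' @export
read_depths <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cell_depth_table(d$species, d$cell_id, d$dist_gcl_um, d$ml_thickness_um)
}

#' Read an expression TSV (genes x species, first column `gene`)
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a GO annotation TSV (`gene,go_id[,term]`)
#' @param path TSV file.
#' @return data.frame with columns `gene`, `go_id`, `term`.
#' @export
read_go <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"term" %in% names(d)) d$term <- d$go_id
  d[, c("gene", "go_id", "term")]
}

#' Read vertices from an ASCII PLY mesh
#'
#' Minimal reader for the vertex block of an ASCII Polygon File Format
#' mesh; faces and extra vertex properties are ignored.
#'
#' @param path PLY file.
#' @return numeric `m x 3` matrix of vertex coordinates.
#' @export
read_ply_vertices <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    stop("not a PLY file")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header not terminated")
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1L]))
    stop("only ASCII PLY supported")
  vline <- grep("^element vertex ", header, value = TRUE)
  if (!length(vline)) stop("no vertex element in PLY header")
  nv <- as.integer(strsplit(vline[1L], "\\s+")[[1L]][3L])
  # vertex properties, in declaration order
  el_lines <- grep("^element ", header)
  vstart <- grep("^element vertex ", header)[1L]
  after <- el_lines[el_lines > vstart]
  vprop_end <- if (length(after)) min(after) - 1L else end - 1L
  props <- header[(vstart + 1L):vprop_end]
  props <- props[grepl("^property ", props)]
  pnames <- vapply(strsplit(props, "\\s+"), function(x) x[length(x)], "")
  xyz <- match(c("x", "y", "z"), pnames)
  if (any(is.na(xyz))) stop("PLY vertex element lacks x/y/z properties")
  body <- lines[(end + 1L):(end + nv)]
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                                function(x) as.numeric(x[xyz])))
  colnames(vals) <- c("x", "y", "z")
  vals
}

#' Export a shape space to TSV (scores plus percent variance)
#' @param space a `shape_space`.
#' @param path output file.
#' @export
write_shape_space <- function(space, path) {
  d <- data.frame(specimen = rownames(space$scores), space$scores,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  pv <- file.path(dirname(path),
                  sub("(\\.[^.]+)?$", "_percent_variance\\1",
                      basename(path)))
  utils::write.table(data.frame(component = colnames(space$scores),
                                percent_variance = space$percent_variance),
                     pv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(path, pv))
}
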