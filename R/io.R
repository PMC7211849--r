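# File formats: long CSV for 3D trajectories, tps-dialect and wide CSV for
# 2D landmarks, CSV for bending measurements, newick for trees. Coordinates
# are millimetres in files; headers are mandatory; decimal point is '.'.

#' Write a flight recording to long-format CSV
#'
#' Columns: `frame`, `time_s`, `point_id`, `x_mm`, `y_mm`, `z_mm`. If the
#' recording carries ground truth, it is written to a sidecar JSON file
#' `<path base>_truth.json`.
#'
#' @param recording a `flight_recording`.
#' @param path output CSV path.
#' @param sidecar write the ground-truth sidecar JSON when available.
#' @return `path`, invisibly.
#' @export
write_flight_csv <- function(recording, path, sidecar = TRUE) {
  pts <- recording$points
  labs <- dimnames(pts)[[2L]]
  nfr <- dim(pts)[1L]
  df <- data.frame(
    frame = rep(seq_len(nfr), times = length(labs)),
    time_s = rep(recording$times, times = length(labs)),
    point_id = rep(labs, each = nfr),
    x_mm = as.vector(pts[, , 1L]),
    y_mm = as.vector(pts[, , 2L]),
    z_mm = as.vector(pts[, , 3L]))
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar && !is.null(recording$ground_truth)) {
    jsonlite::write_json(recording$ground_truth,
                         paste0(sub("\\.csv$", "", path), "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a landmark-trajectory CSV into a flight recording
#'
#' Expects columns `frame`, `time_s`, `point_id`, `x_mm`, `y_mm`, `z_mm`.
#' Frames are sorted deterministically (a warning is emitted if the file
#' was out of order); duplicate `(frame, point_id)` rows are an error.
#'
#' @param path CSV path.
#' @return A `flight_recording` (without ground truth).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "point_id", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trajectory CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[c("frame", "point_id")])) {
    stop("duplicate (frame, point_id) rows in trajectory CSV", call. = FALSE)
  }
  if (any(vapply(split(df$frame, df$point_id), is.unsorted, logical(1L)))) {
    warning("frames out of order; sorting deterministically")
  }
  labs <- unique(df$point_id)   # preserve the file's point order
  df <- df[order(df$frame, df$point_id), ]
  frames <- sort(unique(df$frame))
  nfr <- length(frames)
  per_point <- table(df$point_id)
  if (any(per_point != nfr)) {
    stop("missing frames for point(s): ",
         paste(names(per_point)[per_point != nfr], collapse = ", "), call. = FALSE)
  }
  pts <- array(NA_real_, c(nfr, length(labs), 3L),
               dimnames = list(NULL, labs, c("x", "y", "z")))
  times <- numeric(nfr)
  for (j in seq_along(labs)) {
    sub <- df[df$point_id == labs[j], ]
    pts[, j, ] <- as.matrix(sub[c("x_mm", "y_mm", "z_mm")])
    times <- sub$time_s
  }
  out <- list(times = times, points = pts, ground_truth = NULL, params = NULL)
  class(out) <- "flight_recording"
  out
}

#' Write a shape set to a tps-dialect landmark file
#'
#' One block per specimen: `LM=<k>`, k coordinate lines, `ID=<species>_<specimen>`
#' and optionally `SCALE=<s>` (coordinates are divided by the scale on
#' write so that reading with the scale applied restores them).
#'
#' @param shapes a [shape_set()].
#' @param path output path.
#' @param scale optional scale factor recorded per specimen.
#' @return `path`, invisibly.
#' @export
write_tps <- function(shapes, path, scale = NULL) {
  stopifnot(inherits(shapes, "shape_set"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(shapes$configurations)[1L]
  k <- dim(shapes$configurations)[2L]
  for (i in seq_len(n)) {
    conf <- shapes$configurations[i, , ]
    if (!is.null(scale)) conf <- conf / scale
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.10g %.10g", conf[, 1L], conf[, 2L]), con)
    writeLines(sprintf("ID=%s", shapes$specimen_ids[i]), con)
    if (!is.null(scale)) writeLines(sprintf("SCALE=%.10g", scale), con)
  }
  invisible(path)
}

#' Read a tps-dialect landmark file
#'
#' Parses `LM=` blocks of coordinate pairs with `ID=` keys; `SCALE=` lines,
#' when present, multiply the block's coordinates. Species labels are taken
#' as the part of the ID before the last underscore (the whole ID if there
#' is none). All blocks must have the same landmark count.
#'
#' @param path tps file path.
#' @return A [shape_set()].
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines)
  if (!length(starts)) stop("no LM= blocks in tps file", call. = FALSE)
  confs <- list(); ids <- character(0)
  for (bi in seq_along(starts)) {
    s <- starts[bi]
    e <- if (bi < length(starts)) starts[bi + 1L] - 1L else length(lines)
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[s]))
    coords <- lines[(s + 1L):(s + k)]
    xy <- t(vapply(strsplit(coords, "\\s+"),
                   function(p) as.numeric(p[1:2]), numeric(2L)))
    rest <- lines[(s + k + 1L):e]
    id_line <- grep("^ID\\s*=", rest, value = TRUE)
    id <- if (length(id_line)) sub("^ID\\s*=\\s*", "", id_line[1L]) else
      sprintf("specimen_%02d", bi)
    sc_line <- grep("^SCALE\\s*=", rest, value = TRUE)
    if (length(sc_line)) xy <- xy * as.numeric(sub("^SCALE\\s*=\\s*", "", sc_line[1L]))
    confs[[bi]] <- xy
    ids[bi] <- id
  }
  ks <- vapply(confs, nrow, integer(1L))
  if (length(unique(ks)) != 1L) {
    stop("inconsistent landmark counts in tps file for: ",
         paste(ids[ks != ks[1L]], collapse = ", "), call. = FALSE)
  }
  arr <- array(NA_real_, c(length(confs), ks[1L], 2L))
  for (i in seq_along(confs)) arr[i, , ] <- confs[[i]]
  species <- sub("_[^_]*$", "", ids)
  shape_set(arr, ids, species)
}

#' Write/read shape sets as wide CSV
#'
#' Wide layout: `specimen_id`, `species`, then `x1, y1, ..., xk, yk`.
#' @param shapes a [shape_set()].
#' @param path CSV path.
#' @return `path` (write) or a [shape_set()] (read).
#' @export
write_shapes_csv <- function(shapes, path) {
  stopifnot(inherits(shapes, "shape_set"))
  flat <- flatten_shapes(shapes$configurations)
  df <- data.frame(specimen_id = shapes$specimen_ids, species = shapes$species,
                   flat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shapes_csv
#' @export
read_shapes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("specimen_id", "species")
  if (!all(need %in% names(df))) {
    stop("shape CSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  coord_cols <- setdiff(names(df), need)
  shape_set(unflatten_shapes(as.matrix(df[coord_cols])),
            df$specimen_id, df$species)
}

#' Write/read static-bending measurement tables
#'
#' Columns: `point_id`, `side` (dorsal/ventral or 1/2), `support`
#' (WB/WBLE), `F_N`, `beta_m`, `l_m`.
#' @param records a `bending_record` data frame.
#' @param path CSV path.
#' @return `path` (write) or a `bending_record` data frame (read).
#' @export
write_bending_csv <- function(records, path) {
  df <- data.frame(point_id = records$point_id, side = records$side,
                   support = records$support, F_N = records$force_F,
                   beta_m = records$displacement_beta, l_m = records$distance_l)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bending_csv
#' @export
read_bending_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_id", "side", "support", "F_N", "beta_m", "l_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bending CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(point_id = df$point_id, side = normalize_side(df$side),
                    support = df$support, force_F = df$F_N,
                    displacement_beta = df$beta_m, distance_l = df$l_m,
                    flagged = df$F_N < 1e-6)
  class(out) <- c("bending_record", "data.frame")
  out
}

#' Read a newick tree with branch lengths
#'
#' Thin wrapper over `ape::read.tree` that enforces the requirements of the
#' comparative analyses: rooted topology and branch lengths present.
#'
#' @param path newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_wing_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file", call. = FALSE)
  check_tree(tree)
  tree
}
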