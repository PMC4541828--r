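# Readers and writers for the small set of interchange formats the tool
# speaks: PLY (ascii and binary_little_endian) and whitespace XYZ point
# sets, skeleton/camera JSON, pose JSON, joints CSV, and 16-bit depth
# images as PGM (P2/P5) or PNG.

#' Read a 3D point set
#'
#' Dispatches on extension: `.ply` (ascii or binary_little_endian, with
#' optional `label` / `segment` and `visible` properties), `.xyz` / `.txt`
#' (whitespace columns x y z \[label\], `#` comments tolerated).
#'
#' @param path input file.
#' @return A `labeled_point_set`.
#' @export
read_point_set <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(read_ply(path))
  read_xyz(path)
}

#' Write a 3D point set
#'
#' @param ps a `labeled_point_set` (or matrix).
#' @param path output file; `.ply` writes PLY, anything else XYZ.
#' @param binary write binary_little_endian PLY (default ascii).
#' @return `path`, invisibly.
#' @export
write_point_set <- function(ps, path, binary = FALSE) {
  ps <- as_labeled_point_set(ps)
  if (grepl("\\.ply$", path, ignore.case = TRUE))
    return(write_ply(ps, path, binary = binary))
  df <- as.data.frame(ps$points)
  if (!is.null(ps$labels)) df$label <- ps$labels
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_xyz <- function(path) {
  df <- utils::read.table(path, comment.char = "#")
  if (ncol(df) < 3L) stop("XYZ file needs at least 3 columns")
  labels <- if (ncol(df) >= 4L) as.integer(df[[4]]) else NULL
  labeled_point_set(as.matrix(df[, 1:3]), labels = labels)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file")
  fmt <- NULL; n_vertex <- 0L
  props <- character(); ptypes <- character()
  in_vertex <- FALSE
  repeat {
    line <- trimws(readLines(con, n = 1L))
    if (length(line) == 0L) stop("unexpected end of PLY header")
    if (line == "end_header") break
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "comment" || tok[1] == "obj_info" || line == "") next
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    }
    if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop("list properties on vertices unsupported")
      ptypes <- c(ptypes, tok[2])
      props <- c(props, tok[3])
    }
  }
  np <- length(props)
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (identical(fmt, "ascii")) {
    dat <- scan(con, what = numeric(), n = n_vertex * np, quiet = TRUE,
                comment.char = "#")
    mat <- matrix(dat, ncol = np, byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    mat <- matrix(0, n_vertex, np)
    for (i in seq_len(n_vertex)) {
      for (k in seq_len(np)) {
        tp <- ptypes[k]
        sz <- sizes[[tp]]
        mat[i, k] <- if (tp %in% c("float", "float32", "double", "float64")) {
          readBin(con, "double", 1L, size = sz, endian = "little")
        } else {
          readBin(con, "integer", 1L, size = sz, endian = "little",
                  signed = !(tp %in% c("uchar", "uint8", "ushort", "uint16")))
        }
      }
    }
  } else stop("unsupported PLY format: ", fmt)
  colnames(mat) <- props
  want <- c("x", "y", "z")
  if (!all(want %in% props)) stop("PLY vertex element lacks x/y/z")
  lab_col <- intersect(c("label", "segment"), props)
  vis_col <- intersect("visible", props)
  labeled_point_set(mat[, want, drop = FALSE],
                    labels = if (length(lab_col)) as.integer(mat[, lab_col[1]]),
                    visible = if (length(vis_col)) mat[, vis_col[1]] != 0)
}

write_ply <- function(ps, path, binary = FALSE) {
  n <- nrow(ps$points)
  props <- c("property float x", "property float y", "property float z")
  if (!is.null(ps$labels)) props <- c(props, "property int label")
  if (!is.null(ps$visible)) props <- c(props, "property uchar visible")
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           paste("element vertex", n), props, "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    for (i in seq_len(n)) {
      writeBin(as.numeric(ps$points[i, ]), con, size = 4L, endian = "little")
      if (!is.null(ps$labels))
        writeBin(as.integer(ps$labels[i]), con, size = 4L, endian = "little")
      if (!is.null(ps$visible))
        writeBin(as.integer(ps$visible[i]), con, size = 1L, endian = "little")
    }
  } else {
    rows <- apply(ps$points, 1L, function(r) paste(format(r, digits = 9),
                                                   collapse = " "))
    if (!is.null(ps$labels)) rows <- paste(rows, ps$labels)
    if (!is.null(ps$visible)) rows <- paste(rows, as.integer(ps$visible))
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

#' Write / read a skeleton (with labels) as JSON
#'
#' Serialises joints, the joint parent tree, the segment table and the
#' per-point segment map.
#'
#' @param skeleton a `skeleton_model`.
#' @param path JSON file.
#' @return `path` (write) or a `skeleton_model` (read).
#' @export
write_skeleton_json <- function(skeleton, path) {
  obj <- list(joint_positions = unname(skeleton$joint_positions),
              parent = skeleton$parent,
              segment_joint = unname(skeleton$segment_joint),
              segment_parent = skeleton$segment_parent,
              segment_of_point = skeleton$segment_of_point,
              joint_names = skeleton$joint_names)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_skeleton_json
#' @export
read_skeleton_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  sj <- as.matrix(o$segment_joint)
  storage.mode(sj) <- "integer"
  skeleton_model(as.matrix(o$joint_positions),
                 as.integer(o$parent),
                 segment_of_point = o$segment_of_point,
                 segment_joint = sj,
                 segment_parent = as.integer(o$segment_parent),
                 joint_names = o$joint_names)
}

#' Write / read a subject model as JSON
#' @param subject a `subject_model`.
#' @param path JSON file.
#' @return `path` (write) or a `subject_model` (read).
#' @export
write_subject_json <- function(subject, path) {
  obj <- list(points = unname(subject$points$points),
              labels = subject$points$labels,
              skeleton = list(
                joint_positions = unname(subject$skeleton$joint_positions),
                parent = subject$skeleton$parent,
                segment_joint = unname(subject$skeleton$segment_joint),
                segment_parent = subject$skeleton$segment_parent,
                joint_names = subject$skeleton$joint_names))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_subject_json
#' @export
read_subject_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  sk <- o$skeleton
  labels <- as.integer(o$labels)
  sj <- as.matrix(sk$segment_joint)
  storage.mode(sj) <- "integer"
  skel <- skeleton_model(as.matrix(sk$joint_positions),
                         as.integer(sk$parent), segment_of_point = labels,
                         segment_joint = sj,
                         segment_parent = as.integer(sk$segment_parent),
                         joint_names = sk$joint_names)
  pts <- as.matrix(o$points)
  subject_model(labeled_point_set(pts, labels = labels,
                                  n_segments = skel$P), skel)
}

#' Write / read a camera model as JSON
#' @param camera a `camera_model`.
#' @param path JSON file.
#' @return `path` (write) or a `camera_model` (read).
#' @export
write_camera_json <- function(camera, path) {
  jsonlite::write_json(unclass(camera), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  camera_model(position = o$position, fx = o$fx, fy = o$fy,
               cx = o$cx, cy = o$cy,
               width = o$width %||% 176, height = o$height %||% 144)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an articulated pose as JSON
#'
#' Per-segment local and world rotations (row-major) and translations,
#' plus posed joint positions.
#'
#' @param pose an `articulated_pose`.
#' @param skeleton the reference `skeleton_model`.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_pose_json <- function(pose, skeleton, path) {
  seg <- lapply(seq_along(pose$local), function(p) list(
    segment = p - 1L,
    local_R = as.numeric(t(pose$local[[p]]$R)),
    local_t = pose$local[[p]]$t,
    world_R = as.numeric(t(pose$world[[p]]$R)),
    world_t = pose$world[[p]]$t))
  jsonlite::write_json(list(segments = seg,
                            joints = unname(posed_joints(pose, skeleton))),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write estimated joints of a tracked sequence as CSV
#'
#' Long format: frame, joint, x, y, z.
#'
#' @param result a `track_result` (or its `joints_df`).
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_joints_csv <- function(result, path) {
  df <- if (inherits(result, "track_result")) result$joints_df else result
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write 16-bit depth images
#'
#' PGM P2 (ascii) and P5 (binary) with maxval up to 65535, or 16-bit
#' grayscale PNG. Values are depth in millimeters; 0 = no return.
#'
#' @param path image file (`.pgm` or `.png`).
#' @return Numeric matrix of depth values (rows = image rows).
#' @export
read_depth_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(round(img * 65535))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- trimws(readLines(con, n = 1L))
  toks <- integer()
  while (length(toks) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    toks <- c(toks, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
    toks <- toks[!is.na(toks)]
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE,
                 comment.char = "#")
  } else if (magic == "P5") {
    sz <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", w * h, size = sz, signed = FALSE,
                    endian = "big")
  } else stop("unsupported PGM magic: ", magic)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_depth_image
#' @param depth numeric matrix of millimeter depths.
#' @param ascii write ascii P2 instead of binary P5 (PGM only).
#' @export
write_depth_image <- function(depth, path, ascii = TRUE) {
  depth <- round(depth)
  depth[!is.finite(depth)] <- 0
  depth[depth < 0] <- 0
  depth[depth > 65535] <- 65535
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    # 8-bit grayscale PNG: a preview format (quantisation step ~257 depth
    # units, i.e. ~26 cm over the 65.5 m range); PGM is the lossless format
    png::writePNG(depth / 65535, path)
    return(invisible(path))
  }
  h <- nrow(depth); w <- ncol(depth)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "65535"), con)
    utils::write.table(depth, con, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(w, h), "65535"), con)
    v <- as.integer(t(depth))          # row-major pixel order
    writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)  # 16-bit big-endian
  }
  invisible(path)
}

#' Render a posed point cloud to a depth image
#'
#' Projects points through the camera intrinsics keeping the nearest return
#' per pixel; depths in millimeters, 0 where no point projects.
#'
#' @param points point set or matrix (world frame).
#' @param camera a [camera_model()].
#' @return Numeric depth matrix (height x width).
#' @export
points_to_depth <- function(points, camera) {
  X <- pts_of(points)
  rel <- sweep(X, 2L, camera$position)
  depth <- -rel[, 3]
  ok <- depth > 0
  img <- matrix(0, camera$height, camera$width)
  u <- round(camera$fx * rel[ok, 1] / depth[ok] + camera$cx) + 1L
  v <- round(camera$fy * rel[ok, 2] / depth[ok] + camera$cy) + 1L
  d <- depth[ok] * 1000
  inb <- u >= 1L & u <= camera$width & v >= 1L & v <= camera$height
  u <- u[inb]; v <- v[inb]; d <- d[inb]
  ord <- order(d, decreasing = TRUE)  # nearest written last wins
  img[cbind(v[ord], u[ord])] <- d[ord]
  img
}
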