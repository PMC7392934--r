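#' Named anatomical landmark set
#'
#' Landmarks are named 3D points in mm.  The package works in a right-ear
#' convention: left-ear sets are mirrored (`x -> -x`) at construction so all
#' downstream frame logic assumes one handedness; the flip is recorded in the
#' `mirrored` field.
#'
#' Required names by ossicle: malleus `head_tip`, `umbo_tip`,
#' `lateral_process_tip`, `anterior_process`; incus `short_process_tip`;
#' stapes patches are carried as meshes, not points.
#'
#' @param points named list of 3-vectors, or an n x 3 matrix with rownames.
#' @param side `"left"` or `"right"`.
#' @param mirror mirror left ears to the right-ear convention (default TRUE).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, side = c("right", "left"), mirror = TRUE) {
  side <- match.arg(side)
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) as.numeric(points[i, ]))
    names(points) <- nm
  }
  nm <- names(points)
  if (is.null(nm) || any(nm == "")) stop("all landmarks must be named")
  if (anyDuplicated(nm)) stop("duplicate landmark names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  points <- lapply(points, as.numeric)
  if (any(vapply(points, length, 1L) != 3L) ||
      any(!vapply(points, function(p) all(is.finite(p)), TRUE)))
    stop("landmarks must be finite 3-vectors")
  mirrored <- FALSE
  if (side == "left" && mirror) {
    points <- lapply(points, function(p) c(-p[1], p[2], p[3]))
    mirrored <- TRUE
  }
  structure(list(points = points, side = side, mirrored = mirrored),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks, %s ear%s\n",
              length(x$points), x$side,
              if (x$mirrored) " (mirrored to right-ear convention)" else ""))
  for (nm in names(x$points))
    cat(sprintf("  %-22s (%8.4f, %8.4f, %8.4f) mm\n", nm,
                x$points[[nm]][1], x$points[[nm]][2], x$points[[nm]][3]))
  invisible(x)
}

#' Fetch a landmark, erroring with its name if absent
#' @param lms a `landmark_set`.
#' @param name landmark name.
#' @export
get_landmark <- function(lms, name) {
  stopifnot(inherits(lms, "landmark_set"))
  p <- lms$points[[name]]
  if (is.null(p)) stop("missing required landmark: ", name)
  p
}

#' Read landmarks from JSON or CSV
#'
#' JSON: `{"side": "right", "landmarks": {"umbo_tip": [x, y, z], ...}}`.
#' CSV: columns `name, x, y, z, side` (one side value for the whole file).
#'
#' @param path file path (`.json` or `.csv`).
#' @param mirror mirror left ears to the right-ear convention.
#' @return A `landmark_set`.
#' @export
load_landmarks <- function(path, mirror = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$side))
      stop("landmark file lacks required field `side`: ", path)
    pts <- lapply(obj$landmarks, as.numeric)
    landmark_set(pts, side = obj$side, mirror = mirror)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z", "side")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("landmark CSV lacks required field(s): ",
           paste(miss, collapse = ", "))
    if (anyDuplicated(df$name))
      stop("duplicate landmark names: ",
           paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
    pts <- lapply(seq_len(nrow(df)), function(i) c(df$x[i], df$y[i], df$z[i]))
    names(pts) <- df$name
    landmark_set(pts, side = unique(df$side)[1], mirror = mirror)
  } else stop("unsupported landmark format: .", ext)
}

#' Write landmarks to JSON
#' @param lms a `landmark_set`.
#' @param path output `.json` path.
#' @export
save_landmarks <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  jsonlite::write_json(list(side = lms$side, mirrored = lms$mirrored,
                            landmarks = lms$points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
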