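#' Repeated landmark annotations for a balanced study
#'
#' Container for landmark coordinates indexed by portrait x operator x
#' session x landmark, as produced by a balanced repeated-annotation design
#' (every operator annotates every portrait in every session). Coordinates
#' are in mm.
#'
#' @param coords numeric array with dimensions
#'   `(n_portraits, n_operators, n_sessions, n_landmarks, 3)`; no missing
#'   cells are allowed.
#' @param portrait_ids,operator_ids,session_ids optional axis labels.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(coords, portrait_ids = NULL, operator_ids = NULL,
                           session_ids = NULL) {
  if (length(dim(coords)) != 5L || dim(coords)[5] != 3L)
    stop("coords must be a (portrait, operator, session, landmark, 3) array")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("annotation_set must be complete and finite (balanced design)")
  dm <- dim(coords)
  lab <- function(ids, n, prefix) {
    if (is.null(ids)) sprintf("%s%d", prefix, seq_len(n))
    else { stopifnot(length(ids) == n); as.character(ids) }
  }
  structure(list(coords = coords,
                 portrait_ids = lab(portrait_ids, dm[1], "portrait"),
                 operator_ids = lab(operator_ids, dm[2], "operator"),
                 session_ids = lab(session_ids, dm[3], "session")),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf(
    "annotation_set: %d portraits x %d operators x %d sessions x %d landmarks\n",
    dm[1], dm[2], dm[3], dm[4]))
  invisible(x)
}

#' Dimensions of an annotation set
#' @param set an [annotation_set()].
#' @return named integer vector (portraits, operators, sessions, landmarks).
#' @export
design_dims <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  dm <- dim(set$coords)
  c(portraits = dm[1], operators = dm[2], sessions = dm[3], landmarks = dm[4])
}

#' Read / write a landmark coordinate file
#'
#' The on-disk format is plain ASCII, one row per landmark:
#' `index x y z`, with 1-based landmark indices and coordinates in mm.
#' Rows may appear in any order in the file; they are returned sorted by
#' index. Missing or duplicate indices are rejected.
#'
#' @param path file path.
#' @return for `read_landmarks`, a data frame with columns `index`, `x`,
#'   `y`, `z`, sorted by index.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) stop("parse error in ", path, ": empty landmark file")
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("parse error in ", path, " row ", bad[1], ": expected 'index x y z'")
  m <- suppressWarnings(t(vapply(parts, as.numeric, numeric(4))))
  if (anyNA(m))
    stop("parse error in ", path, ": non-numeric coordinate or index")
  idx <- m[, 1]
  if (any(idx != as.integer(idx)) || any(idx < 1))
    stop("parse error in ", path, ": landmark indices must be positive ",
         "integers (1-based)")
  idx <- as.integer(idx)
  if (anyDuplicated(idx))
    stop("parse error in ", path, ": duplicate landmark index ",
         idx[duplicated(idx)][1])
  full <- seq_len(max(idx))
  if (!setequal(idx, full))
    stop("parse error in ", path, ": missing landmark index ",
         paste(setdiff(full, idx), collapse = ", "))
  o <- order(idx)
  data.frame(index = idx[o], x = m[o, 2], y = m[o, 3], z = m[o, 4])
}

#' @rdname read_landmarks
#' @param landmarks numeric L x 3 matrix (or data frame with x, y, z).
#' @export
write_landmarks <- function(landmarks, path) {
  if (is.data.frame(landmarks)) landmarks <- as.matrix(landmarks[, c("x", "y", "z")])
  landmarks <- as.matrix(landmarks)
  stopifnot(ncol(landmarks) == 3L)
  writeLines(sprintf("%d %.9g %.9g %.9g", seq_len(nrow(landmarks)),
                     landmarks[, 1], landmarks[, 2], landmarks[, 3]), path)
  invisible(path)
}
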