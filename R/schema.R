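#' The 73-landmark facial annotation scheme
#'
#' Returns the built-in facial landmark scheme: 73 landmarks, of which 24 are
#' anatomical (distinct facial features such as canthi, pupil centers, oral
#' commissures) and 49 are pseudo-landmarks spaced along the curves of the
#' eyebrows, eyes, nose, mouth and jaw. Landmarks 35--45 (nose) and 63--73
#' (jaw line and ear attachments) sit in high-curvature regions and are the
#' ones adjusted in profile/top-down views during manual annotation.
#'
#' @return a data frame of class `landmark_scheme` with columns `index`
#'   (1..73), `name`, `category` (`"anatomical"` or `"pseudo"`), `group`
#'   (one of eyebrow_right, eyebrow_left, eye_right, eye_left, pupil, nose,
#'   mouth, jaw, ear), `high_curvature` (logical) and `in_selection`
#'   (semicolon-separated ids of the built-in selections containing the
#'   landmark, possibly empty).
#' @export
load_schema <- function() {
  schema <- .landmark_table()
  class(schema) <- c("landmark_scheme", "data.frame")
  schema
}

.anatomical_names <- c(
  "1" = "Right eyebrow lateral point",
  "5" = "Right eyebrow medial point",
  "9" = "Left eyebrow lateral point",
  "13" = "Left eyebrow medial point",
  "17" = "Right eye lateral canthus",
  "21" = "Right eye medial canthus",
  "25" = "Left eye lateral canthus",
  "29" = "Left eye medial canthus",
  "33" = "Right pupil center",
  "34" = "Left pupil center",
  "37" = "The outer left alar-facial groove",
  "38" = "The inner left alar-labial groove",
  "40" = "The columellars connection to the upper lip",
  "42" = "The inner right alar-labial groove",
  "43" = "The outer right alar-facial groove",
  "46" = "Tip of the nose",
  "47" = "Right oral commissure",
  "49" = "The right philtrum column connection to the vermillion border",
  "50" = "Midpoint on the cupid's bow",
  "51" = "The left philtrum column connection to the vermillion border",
  "53" = "Left oral commissure",
  "63" = "Right ear attachment",
  "68" = "Lowest point of the central jaw",
  "73" = "Left ear attachment")

# membership of the four built-in landmark selections, one string per landmark
.in_selection <- c(
  "4", "4", "2;3;4", "3;4", "1;4", "4", "3;4", "4",                  # 1-8
  "4", "4", "4", "4", "1;4", "4", "2;3;4", "4",                      # 9-16
  "1;3;4", "3;4", "3;4", "3;4", "1;3", "3;4", "3;4", "3;4",          # 17-24
  "1;4", "3;4", "3;4", "3;4", "1", "3;4", "3;4", "3;4",              # 25-32
  "1;2;3;4", "1;2;3;4",                                              # 33-34
  "3;4", "", "1", "4", "", "4", "", "1;4", "", "", "3;4", "1;2;4",   # 35-46
  "1;2;4", "4", "1;3;4", "1;2;3;4", "1;3;4", "4", "1;2;4",           # 47-53
  "4", "1;2;3;4", "4", "3;4", "1;2;3;4", "3;4", "3;4", "1;2;3;4",    # 54-61
  "3;4",                                                             # 62
  "1;2;4", "", "", "", "", "1;2;4", "", "", "", "", "1;2;4")         # 63-73

.landmark_table <- function() {
  group <- character(73)
  group[1:8] <- "eyebrow_right"
  group[9:16] <- "eyebrow_left"
  group[17:24] <- "eye_right"
  group[25:32] <- "eye_left"
  group[33:34] <- "pupil"
  group[35:46] <- "nose"
  group[47:62] <- "mouth"
  group[63:73] <- "jaw"
  group[c(63, 73)] <- "ear"
  anat <- as.integer(names(.anatomical_names))
  category <- ifelse(seq_len(73) %in% anat, "anatomical", "pseudo")
  pretty <- c(eyebrow_right = "Right eyebrow", eyebrow_left = "Left eyebrow",
              eye_right = "Right eye", eye_left = "Left eye", pupil = "Pupil",
              nose = "Nose", mouth = "Mouth", jaw = "Jaw", ear = "Ear")
  name <- sprintf("%s pseudo-landmark %d", pretty[group], seq_len(73))
  name[anat] <- .anatomical_names
  high_curvature <- seq_len(73) %in% c(35:45, 63:73)
  data.frame(index = seq_len(73), name = unname(name), category = category,
             group = group, high_curvature = high_curvature,
             in_selection = .in_selection, stringsAsFactors = FALSE)
}

#' Built-in sparse landmark selections
#'
#' Four sparse subsets of the 73-landmark scheme, evaluated for the quality of
#' the dense point correspondence they drive. Selections 1 and 2 were chosen
#' for low mean error and variation while covering the central and all facial
#' features respectively; selection 3 collects landmarks with mean error below
#' 1 mm and selection 4 those with operator standard deviation below 0.5 mm.
#' The encoded memberships follow the published per-landmark listing verbatim
#' (they are intentionally not regenerated from the threshold rules, which
#' the listing does not reproduce exactly; see the package vignette).
#'
#' @param id integer in 1..4.
#' @return a `landmark_selection`: list with `name` and sorted integer
#'   `indices`.
#' @export
get_selection <- function(id) {
  if (length(id) != 1L || !is.finite(id) || id != as.integer(id) || !(id %in% 1:4))
    stop("unknown selection id: ", deparse(substitute(id)),
         " (built-in selections are 1..4)")
  schema <- .landmark_table()
  member <- vapply(strsplit(schema$in_selection, ";", fixed = TRUE),
                   function(x) as.character(id) %in% x, logical(1))
  landmark_selection(sprintf("selection_%d", id), schema$index[member])
}

#' Construct a landmark selection
#' @param name selection label.
#' @param indices integer landmark indices, subset of 1..73, no duplicates.
#' @return a `landmark_selection` object.
#' @export
landmark_selection <- function(name, indices) {
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > 73L))
    stop("selection indices must lie in 1..73")
  if (anyDuplicated(indices)) stop("duplicate landmark indices in selection")
  structure(list(name = as.character(name), indices = sort(indices)),
            class = "landmark_selection")
}

#' @export
print.landmark_selection <- function(x, ...) {
  cat(sprintf("landmark_selection '%s': %d landmarks\n  %s\n",
              x$name, length(x$indices), paste(x$indices, collapse = " ")))
  invisible(x)
}

#' Select landmarks by an error-summary threshold
#'
#' Returns the landmarks whose summary statistic falls strictly below the
#' threshold, mirroring the exclusion rules "mean error > 1 mm" and
#' "operator SD > 0.5 mm" used to form the rule-based selections.
#'
#' @param summary data frame with a column `landmark` (1..73, complete) and
#'   the metric columns, e.g. the output of [error_summary()].
#' @param metric `"mean_error"` or `"operator_sd"` (column name in `summary`).
#' @param threshold positive scalar in mm; landmarks with metric strictly
#'   below it are kept.
#' @return a `landmark_selection` (possibly empty, with a warning).
#' @export
selection_from_thresholds <- function(summary,
                                      metric = c("mean_error", "operator_sd"),
                                      threshold) {
  metric <- match.arg(metric)
  if (!is.data.frame(summary) || !"landmark" %in% names(summary))
    stop("summary must be a data frame with a 'landmark' column")
  if (!setequal(summary$landmark, 1:73))
    stop("summary must cover all 73 landmarks; missing: ",
         paste(setdiff(1:73, summary$landmark), collapse = ", "))
  if (!metric %in% names(summary))
    stop("summary has no column '", metric, "'")
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("threshold must be a non-negative scalar (mm); +Inf keeps everything")
  keep <- summary$landmark[summary[[metric]] < threshold]
  if (length(keep) == 0L)
    warning("threshold ", threshold, " mm excludes every landmark; ",
            "returning an empty selection")
  sel <- structure(list(name = sprintf("%s<%g", metric, threshold),
                        indices = sort(as.integer(keep))),
                   class = "landmark_selection")
  sel
}

#' Export / import the landmark scheme and selections
#'
#' `write_schema_csv()` writes the landmark table (index, name, category,
#' group, high_curvature) as CSV. `write_selection_config()` /
#' `read_selection_config()` round-trip one or more selections through a YAML
#' config file.
#'
#' @param schema a `landmark_scheme` (default the built-in one).
#' @param path output file path.
#' @return the path, invisibly (`read_selection_config` returns a list of
#'   `landmark_selection`s).
#' @export
write_schema_csv <- function(path, schema = load_schema()) {
  utils::write.csv(schema[, c("index", "name", "category", "group",
                              "high_curvature")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schema_csv
#' @param selections a list of `landmark_selection` objects.
#' @export
write_selection_config <- function(selections, path) {
  if (inherits(selections, "landmark_selection")) selections <- list(selections)
  payload <- lapply(selections, function(s) list(name = s$name,
                                                 indices = as.integer(s$indices)))
  yaml::write_yaml(list(selections = payload), path)
  invisible(path)
}

#' @rdname write_schema_csv
#' @export
read_selection_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg$selections, function(s) landmark_selection(s$name, s$indices))
}
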