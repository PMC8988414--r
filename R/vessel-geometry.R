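# Vessel-tree data model and I/O. A tree is a forest of rooted segment chains
# under the aortic root, one subtree family per main coronary artery.
# All geometry is stored in cm; files never carry mm.

TREE_COLUMNS <- c("segment_id", "parent_id", "artery", "length_cm",
                  "mean_radius_cm", "has_stenosis", "is_measurement_site",
                  "site_distance_cm")

#' Construct and validate a coronary tree
#'
#' A coronary tree is a data frame of vessel segments: tube elements with a
#' length, a mean lumen radius (measured as the mean along a stenosis for
#' diseased segments), a parent link (`NA` = attaches at the aortic root), an
#' artery label (LAD/LCX/RCA) and optional stenosis / measurement-site flags.
#' Measurement sites carry the ostium-to-site distance `site_distance_cm`.
#'
#' Validation enforces: unique non-empty segment ids; positive lengths and
#' radii; parent links forming an acyclic forest with artery labels constant
#' along each lineage; `site_distance_cm` present iff the segment is a
#' measurement site and not exceeding the cumulative root-to-segment length.
#'
#' @param segments data frame with columns `segment_id`, `parent_id`,
#'   `artery`, `length_cm`, `mean_radius_cm`, `has_stenosis`,
#'   `is_measurement_site`, `site_distance_cm`.
#' @return An object of class `coronary_tree` (list with element `segments`).
#' @export
coronary_tree <- function(segments) {
  if (!is.data.frame(segments)) format_error("`segments` must be a data frame")
  missing_cols <- setdiff(TREE_COLUMNS, names(segments))
  if (length(missing_cols)) {
    format_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  seg <- as.data.frame(segments)[TREE_COLUMNS]
  seg$segment_id <- as.character(seg$segment_id)
  seg$parent_id <- as.character(seg$parent_id)
  seg$parent_id[!is.na(seg$parent_id) & seg$parent_id == ""] <- NA_character_
  seg$artery <- as.character(seg$artery)
  seg$length_cm <- as.numeric(seg$length_cm)
  seg$mean_radius_cm <- as.numeric(seg$mean_radius_cm)
  seg$has_stenosis <- as.logical(seg$has_stenosis)
  seg$is_measurement_site <- as.logical(seg$is_measurement_site)
  seg$site_distance_cm <- as.numeric(seg$site_distance_cm)
  rownames(seg) <- NULL
  validate_segments(seg)
  structure(list(segments = seg), class = "coronary_tree")
}

validate_segments <- function(seg) {
  if (nrow(seg) == 0L) value_error("tree has no segments")
  if (anyNA(seg$segment_id) || any(seg$segment_id == "")) {
    value_error("segment ids must be non-empty")
  }
  if (anyDuplicated(seg$segment_id)) {
    dup <- unique(seg$segment_id[duplicated(seg$segment_id)])
    value_error(sprintf("duplicate segment id(s): %s", paste(dup, collapse = ", ")))
  }
  if (!all(seg$artery %in% ARTERY_LABELS)) {
    value_error("artery labels must be LAD, LCX or RCA")
  }
  if (anyNA(seg$length_cm) || any(seg$length_cm <= 0)) {
    value_error("length_cm must be positive for every segment")
  }
  if (anyNA(seg$mean_radius_cm) || any(seg$mean_radius_cm <= 0)) {
    value_error("mean_radius_cm must be positive for every segment")
  }
  if (anyNA(seg$has_stenosis) || anyNA(seg$is_measurement_site)) {
    format_error("has_stenosis / is_measurement_site must be true or false")
  }

  known <- is.na(seg$parent_id) | seg$parent_id %in% seg$segment_id
  if (!all(known)) {
    topology_error(sprintf(
      "segment(s) reference unknown parent(s): %s",
      paste(seg$segment_id[!known], collapse = ", ")
    ))
  }

  # cycle check + depth via iterative parent chase
  idx <- match(seg$parent_id, seg$segment_id)  # NA for roots
  n <- nrow(seg)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    seen <- integer(0)
    j <- i
    while (!is.na(j) && is.na(depth[j])) {
      if (j %in% seen) {
        topology_error(sprintf("cycle detected through segment '%s'", seg$segment_id[j]))
      }
      seen <- c(seen, j)
      j <- idx[j]
    }
    base <- if (is.na(j)) 0L else depth[j]
    # walk back down the recorded chain assigning depths
    for (k in rev(seq_along(seen))) {
      base <- base + 1L
      depth[seen[k]] <- base
    }
  }

  mismatch <- !is.na(idx) & seg$artery != seg$artery[idx]
  if (any(mismatch)) {
    topology_error(sprintf(
      "artery label changes along lineage at segment(s): %s",
      paste(seg$segment_id[mismatch], collapse = ", ")
    ))
  }

  is_site <- seg$is_measurement_site
  if (any(is_site & is.na(seg$site_distance_cm))) {
    value_error("site_distance_cm is required for measurement sites")
  }
  if (any(!is_site & !is.na(seg$site_distance_cm))) {
    value_error("site_distance_cm must be empty for non-site segments")
  }
  if (any(is_site & seg$site_distance_cm < 0)) {
    value_error("site_distance_cm must be non-negative")
  }
  if (any(is_site)) {
    cum <- cumulative_length(seg)
    over <- is_site & seg$site_distance_cm > cum + 1e-9
    if (any(over)) {
      value_error(sprintf(
        "site_distance_cm exceeds the ostium-to-segment path length at: %s",
        paste(seg$segment_id[over], collapse = ", ")
      ))
    }
  }
  invisible(seg)
}

# total length from the ostium through each segment (inclusive)
cumulative_length <- function(seg) {
  idx <- match(seg$parent_id, seg$segment_id)
  cum <- rep(NA_real_, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    chain <- integer(0)
    j <- i
    while (!is.na(j) && is.na(cum[j])) {
      chain <- c(chain, j)
      j <- idx[j]
    }
    base <- if (is.na(j)) 0 else cum[j]
    for (k in rev(chain)) {
      base <- base + seg$length_cm[k]
      cum[k] <- base
    }
  }
  cum
}

#' @export
print.coronary_tree <- function(x, ...) {
  seg <- x$segments
  cat(sprintf(
    "<coronary_tree> %d segments (%s); %d stenosed, %d measurement site(s)\n",
    nrow(seg),
    paste(sprintf("%s: %d", ARTERY_LABELS, tabulate(match(seg$artery, ARTERY_LABELS), 3L)),
          collapse = ", "),
    sum(seg$has_stenosis), sum(seg$is_measurement_site)
  ))
  invisible(x)
}

#' Number of segments in a tree
#' @param tree a `coronary_tree`.
#' @return Integer count.
#' @export
n_segments <- function(tree) nrow(tree$segments)

parse_strict_logical <- function(x, column) {
  out <- rep(NA, length(x))
  out[tolower(x) == "true"] <- TRUE
  out[tolower(x) == "false"] <- FALSE
  if (anyNA(out)) {
    format_error(sprintf("column '%s' must contain only 'true'/'false'", column))
  }
  out
}

parse_strict_numeric <- function(x, column, allow_empty = FALSE) {
  empty <- is.na(x) | x == ""
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !empty
  if (any(bad)) format_error(sprintf("column '%s' contains non-numeric values", column))
  if (!allow_empty && any(empty)) {
    format_error(sprintf("column '%s' has missing values", column))
  }
  out
}

#' Read a coronary tree from CSV or JSON
#'
#' CSV dialect: UTF-8, comma-separated, header row exactly
#' `segment_id,parent_id,artery,length_cm,mean_radius_cm,has_stenosis,is_measurement_site,site_distance_cm`,
#' `.` decimal separator, empty string for a null parent / site distance,
#' booleans written `true`/`false`. JSON dialect: an object with key
#' `segments` holding an array of objects with the same field names.
#'
#' @param path input file path.
#' @param format `"csv"` or `"json"`.
#' @return A validated [coronary_tree()].
#' @export
load_tree <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  if (format == "csv") {
    header <- readLines(path, n = 1L, warn = FALSE)
    if (!identical(header, paste(TREE_COLUMNS, collapse = ","))) {
      format_error("CSV header does not match the vessel-tree dialect")
    }
    raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                           check.names = FALSE)
    if (nrow(raw) == 0L) format_error("CSV contains no segment rows")
    seg <- data.frame(
      segment_id = raw$segment_id,
      parent_id = ifelse(raw$parent_id == "", NA_character_, raw$parent_id),
      artery = raw$artery,
      length_cm = parse_strict_numeric(raw$length_cm, "length_cm"),
      mean_radius_cm = parse_strict_numeric(raw$mean_radius_cm, "mean_radius_cm"),
      has_stenosis = parse_strict_logical(raw$has_stenosis, "has_stenosis"),
      is_measurement_site = parse_strict_logical(raw$is_measurement_site,
                                                 "is_measurement_site"),
      site_distance_cm = parse_strict_numeric(raw$site_distance_cm,
                                              "site_distance_cm", allow_empty = TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    obj <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = TRUE),
      error = function(e) format_error(sprintf("cannot parse JSON: %s", conditionMessage(e)))
    )
    if (!is.list(obj) || is.null(obj$segments)) {
      format_error("JSON must be an object with key 'segments'")
    }
    seg <- as.data.frame(obj$segments)
    missing_cols <- setdiff(setdiff(TREE_COLUMNS, "site_distance_cm"), names(seg))
    if (length(missing_cols)) {
      format_error(sprintf("missing field(s): %s", paste(missing_cols, collapse = ", ")))
    }
    if (is.null(seg$site_distance_cm)) seg$site_distance_cm <- NA_real_
  }
  coronary_tree(seg)
}

fmt_full <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a coronary tree to CSV or JSON
#'
#' Numbers are written at full double precision so that
#' `load_tree(save_tree(tree))` reproduces the tree exactly in either dialect.
#'
#' @param tree a `coronary_tree`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_tree <- function(tree, path, format = c("csv", "json")) {
  stopifnot(inherits(tree, "coronary_tree"))
  format <- match.arg(format)
  seg <- tree$segments
  res <- tryCatch({
    if (format == "csv") {
      rows <- paste(
        seg$segment_id,
        ifelse(is.na(seg$parent_id), "", seg$parent_id),
        seg$artery,
        fmt_full(seg$length_cm),
        fmt_full(seg$mean_radius_cm),
        tolower(as.character(seg$has_stenosis)),
        tolower(as.character(seg$is_measurement_site)),
        fmt_full(seg$site_distance_cm),
        sep = ","
      )
      writeLines(c(paste(TREE_COLUMNS, collapse = ","), rows), path, useBytes = TRUE)
    } else {
      # I(17) significant digits guarantees an exact double round trip
      jsonlite::write_json(list(segments = seg), path,
                           dataframe = "rows", na = "null", digits = I(17),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) {
    io_error(sprintf("cannot write %s: %s", path, conditionMessage(res)))
  }
  invisible(path)
}

segment_row <- function(tree, segment_id) {
  i <- match(segment_id, tree$segments$segment_id)
  if (is.na(i)) lookup_error(sprintf("unknown segment id '%s'", segment_id))
  i
}

#' Ostium-to-site segment chain
#'
#' Traces parent links from a measurement-site segment back to its artery
#' root and returns the chain root-first: the segments whose Poiseuille
#' resistances sum along the pressure-wire path from ostium to measurement
#' location.
#'
#' @param tree a `coronary_tree`.
#' @param segment_id id of a measurement-site segment.
#' @return Data frame of segments, root first, ending at `segment_id`.
#' @export
path_to_site <- function(tree, segment_id) {
  stopifnot(inherits(tree, "coronary_tree"))
  i <- segment_row(tree, segment_id)
  seg <- tree$segments
  if (!seg$is_measurement_site[i]) {
    lookup_error(sprintf("segment '%s' is not a measurement site", segment_id))
  }
  idx <- match(seg$parent_id, seg$segment_id)
  chain <- integer(0)
  j <- i
  while (!is.na(j)) {
    chain <- c(j, chain)
    j <- idx[j]
  }
  out <- seg[chain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Measurement-site ids of a tree
#' @param tree a `coronary_tree`.
#' @return Character vector of segment ids flagged as measurement sites.
#' @export
measurement_sites <- function(tree) {
  tree$segments$segment_id[tree$segments$is_measurement_site]
}
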