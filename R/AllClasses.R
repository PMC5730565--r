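#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ParkSet: a collection of identified park polygons
#'
#' Holds one polygon or multipolygon per park (WGS84 lon/lat) together with
#' the park identifier, display name and ISO-3166 alpha-2 country code. The
#' park is the unit of every aggregation in the package: posts are assigned to
#' parks, user-days and visitor statistics are counted per park.
#'
#' Geometries are stored as nested lists: one element per park, each a list of
#' polygon parts, each part a list of rings, each ring an un-closed
#' two-column lon/lat matrix (first ring outer, later rings holes).
#'
#' @slot meta data.frame with columns `park_id`, `name`, `country`.
#' @slot geoms list of multipolygon geometries, parallel to `meta`.
#' @seealso [readParks()], [simulateParks()], [assignPosts()]
#' @export
setClass("ParkSet",
  representation(meta = "data.frame", geoms = "list"))

setValidity("ParkSet", function(object) {
  msgs <- character()
  m <- object@meta
  if (!all(c("park_id", "name", "country") %in% names(m)))
    msgs <- c(msgs, "meta must have park_id, name, country columns")
  else {
    if (anyDuplicated(m$park_id))
      msgs <- c(msgs, "park_id values must be unique")
    if (any(is.na(m$park_id) | m$park_id == ""))
      msgs <- c(msgs, "park_id must be non-empty")
  }
  if (length(object@geoms) != nrow(m))
    msgs <- c(msgs, "one geometry per metadata row required")
  for (g in object@geoms) {
    if (!is.list(g) || length(g) == 0L) {
      msgs <- c(msgs, "empty geometry"); break
    }
    ok <- vapply(g, function(part)
      is.list(part) && length(part) >= 1L &&
        all(vapply(part, function(r) is.matrix(r) && ncol(r) == 2L &&
                     nrow(r) >= 3L && !anyNA(r), logical(1L))), logical(1L))
    if (!all(ok)) { msgs <- c(msgs, "malformed polygon ring"); break }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ParkSet
#'
#' @param park_id character vector of unique park identifiers.
#' @param name park display names (defaults to `park_id`).
#' @param country ISO-3166 alpha-2 codes.
#' @param geoms list of multipolygon geometries (see [ParkSet-class]).
#' @return a [ParkSet-class] object.
#' @export
ParkSet <- function(park_id, name = park_id, country = NA_character_, geoms) {
  meta <- data.frame(park_id = as.character(park_id),
                     name = as.character(name),
                     country = as.character(country),
                     stringsAsFactors = FALSE)
  new("ParkSet", meta = meta, geoms = unname(geoms))
}

#' @describeIn ParkSet-class number of parks
#' @param x a `ParkSet`.
#' @export
setMethod("length", "ParkSet", function(x) nrow(x@meta))

#' Park accessors
#'
#' `parkIds()` returns the identifiers, `parkMeta()` the metadata table and
#' `parkGeoms()` the geometry list of a [ParkSet-class].
#'
#' @param x a `ParkSet`.
#' @return character vector, data.frame, or list respectively.
#' @export
parkIds <- function(x) x@meta$park_id

#' @rdname parkIds
#' @export
parkMeta <- function(x) x@meta

#' @rdname parkIds
#' @export
parkGeoms <- function(x) x@geoms

#' @describeIn ParkSet-class subset by index or park_id
#' @param i index, logical or character (park_id) subscript.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ParkSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@meta$park_id)
  if (anyNA(i)) stop("unknown park_id in subscript")
  new("ParkSet", meta = x@meta[i, , drop = FALSE], geoms = x@geoms[i])
})

setMethod("show", "ParkSet", function(object) {
  cat("ParkSet with", length(object), "park(s)\n")
  m <- object@meta
  n <- min(5L, nrow(m))
  if (n > 0L) {
    ex <- paste0(m$park_id[seq_len(n)], collapse = ", ")
    cat("  park_id:", ex, if (nrow(m) > n) "..." else "", "\n")
    cat("  countries:", paste(unique(m$country), collapse = ", "), "\n")
  }
})

#' MonthlyMatrix: park-by-month counts per source
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose rows are (park, year, month) cells and whose columns are count
#' sources: one per social-media platform, optionally a `combined` column
#' (elementwise sum of the platforms) and an `official` column (visitor
#' statistics). The single assay, `"counts"`, holds non-negative counts.
#' Every park present carries all 12 months of a year, zero-filled.
#'
#' @seealso [monthlySUD()], [combinePlatforms()], [attachOfficial()],
#'   [annualTotals()]
#' @export
setClass("MonthlyMatrix", contains = "SummarizedExperiment")

setValidity("MonthlyMatrix", function(object) {
  msgs <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("park_id", "year", "month") %in% colnames(rd)))
    return("rowData must have park_id, year, month")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0, na.rm = TRUE)) msgs <- c(msgs, "counts must be >= 0")
  if (any(rd$month < 1L | rd$month > 12L))
    msgs <- c(msgs, "month must be in 1..12")
  cd <- SummarizedExperiment::colData(object)
  if (!"type" %in% colnames(cd))
    return("colData must have a 'type' column")
  if ("combined" %in% colnames(object)) {
    plat <- colnames(object)[cd$type == "platform"]
    if (length(plat)) {
      delta <- cnt[, "combined"] - rowSums(cnt[, plat, drop = FALSE])
      if (any(abs(delta) > 1e-8))
        msgs <- c(msgs, "combined column must equal the sum of platform columns")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MonthlyMatrix
#'
#' @param counts numeric matrix, rows = park-month cells, columns = sources.
#' @param park_id,year,month row keys, recycled to `nrow(counts)`.
#' @param type character vector classifying each column as `"platform"`,
#'   `"combined"` or `"official"`; defaults to `"platform"` for all columns.
#' @return a [MonthlyMatrix-class].
#' @export
MonthlyMatrix <- function(counts, park_id, year, month, type = NULL) {
  counts <- as.matrix(counts)
  if (is.null(type)) type <- rep("platform", ncol(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = DataFrame(park_id = as.character(park_id),
                        year = as.integer(year), month = as.integer(month)),
    colData = DataFrame(type = type, row.names = colnames(counts)))
  new("MonthlyMatrix", se)
}

#' MonthlyMatrix accessors
#'
#' `sudCounts()` returns the counts matrix, `sources()` the column (source)
#' labels and `monthKeys()` the (park_id, year, month) row-key table.
#'
#' @param x a [MonthlyMatrix-class].
#' @return matrix, character vector, or data.frame respectively.
#' @export
sudCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname sudCounts
#' @export
sources <- function(x) colnames(x)

#' @rdname sudCounts
#' @export
monthKeys <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x)[, c("park_id", "year", "month")])

setMethod("show", "MonthlyMatrix", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("MonthlyMatrix:", length(unique(rd$park_id)), "park(s) x",
      length(unique(paste(rd$year, rd$month))), "month(s);",
      "sources:", paste(colnames(object), collapse = ", "), "\n")
})
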