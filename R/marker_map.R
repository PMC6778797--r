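#' Construct a marker map
#'
#' A marker map is an ordered set of visible-marker names along one
#' chromosome arm (telomere to centromere), defining the k-1 scoring
#' intervals of a multi-marker testcross. The canonical example is the
#' *net ho dp b pr cn* map spanning Drosophila chromosome arm 2L and the
#' centromere, with intervals net-ho, ho-dp, dp-b, b-pr, pr-cn.
#'
#' @param markers character vector of at least two unique marker names,
#'   in chromosomal order.
#' @param chromosome label for the chromosome (arm), e.g. "2L".
#' @return An object of class `marker_map` with elements `chromosome`,
#'   `markers` and `intervals` (labels `"m1-m2"`, ...).
#' @export
#' @examples
#' marker_map(c("net", "ho", "dp", "b", "pr", "cn"), chromosome = "2L")
marker_map <- function(markers, chromosome = "chr") {
  markers <- as.character(markers)
  if (length(markers) < 2L)
    stop("a marker map needs at least 2 markers", call. = FALSE)
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(markers)) || anyNA(markers))
    stop("marker names must be non-empty", call. = FALSE)
  k <- length(markers)
  structure(
    list(
      chromosome = as.character(chromosome)[1L],
      markers = markers,
      intervals = paste(markers[-k], markers[-1L], sep = "-")
    ),
    class = "marker_map"
  )
}

#' Read a marker map from a key: value config file
#'
#' The config is plain text with `key: value` lines; recognised keys are
#' `markers` (comma-separated, ordered telomere to centromere, required)
#' and `chromosome` (optional label). Lines starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  if (!"markers" %in% keys)
    stop("marker map config must contain a 'markers' line", call. = FALSE)
  markers <- trimws(strsplit(vals[match("markers", keys)], ",")[[1L]])
  chrom <- if ("chromosome" %in% keys) vals[match("chromosome", keys)] else "chr"
  marker_map(markers, chromosome = chrom)
}

#' @export
print.marker_map <- function(x, ...) {
  cat("Marker map (", x$chromosome, "): ",
      paste(x$markers, collapse = " "), "\n", sep = "")
  cat(length(x$intervals), "intervals:",
      paste(x$intervals, collapse = ", "), "\n")
  invisible(x)
}

n_markers <- function(map) length(map$markers)
n_intervals <- function(map) length(map$intervals)

#' Resolve interval labels to interval indices on a map
#'
#' @param map a [marker_map()].
#' @param which interval labels (e.g. `"ho-dp"`), or `"total"` which is
#'   passed through, or already-numeric indices.
#' @return integer indices into `map$intervals`.
#' @keywords internal
interval_index <- function(map, which) {
  if (is.numeric(which)) {
    idx <- as.integer(which)
    if (any(idx < 1L | idx > n_intervals(map)))
      stop("interval index out of range", call. = FALSE)
    return(idx)
  }
  idx <- match(which, map$intervals)
  if (anyNA(idx))
    stop("unknown interval label(s): ",
         paste(which[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}
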