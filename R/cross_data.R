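#' Build a cross collection from a genotype matrix
#'
#' A cross collection holds the progeny of one or more replicate crosses of
#' a single maternal genotype. Because the design is a testcross (the
#' mother heterozygous over a fully marked chromosome, the father
#' homozygous recessive), each progeny's phenotype vector over the markers
#' equals the allele vector of the maternal chromatid it received, so the
#' phenotype states "M" (mutant/recessive visible) and "W" (wildtype) are
#' stored directly as chromatid states.
#'
#' @param genotypes character matrix, one row per progeny, one column per
#'   marker (in map order), entries "M"/"W".
#' @param cross_id character vector, the replicate cross each progeny
#'   belongs to.
#' @param progeny_id character vector of progeny identifiers, unique
#'   within a cross; generated if missing.
#' @param map a [marker_map()].
#' @param genotype_label label of the maternal genotype assayed
#'   (e.g. "mei-217/-218^pse").
#' @return An object of class `cross_collection`: list with `genotype_label`,
#'   `map`, and `crosses`, a named list of character genotype matrices.
#' @export
cross_collection <- function(genotypes, cross_id, progeny_id = NULL,
                             map, genotype_label = "unlabeled") {
  stopifnot(inherits(map, "marker_map"))
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != n_markers(map))
    stop("genotype matrix has ", ncol(genotypes), " columns; map has ",
         n_markers(map), " markers", call. = FALSE)
  if (nrow(genotypes) == 0L) stop("no progeny", call. = FALSE)
  if (length(cross_id) != nrow(genotypes))
    stop("cross_id length must match progeny count", call. = FALSE)
  if (!all(genotypes %in% c("M", "W")))
    stop("genotype states must be 'M' or 'W'", call. = FALSE)
  cross_id <- as.character(cross_id)
  if (is.null(progeny_id)) {
    progeny_id <- stats::ave(cross_id, cross_id,
                             FUN = function(x) paste0("p", seq_along(x)))
  }
  progeny_id <- as.character(progeny_id)
  colnames(genotypes) <- map$markers
  crosses <- lapply(split(seq_len(nrow(genotypes)), factor(cross_id, levels = unique(cross_id))),
                    function(i) {
                      m <- genotypes[i, , drop = FALSE]
                      rn <- progeny_id[i]
                      if (anyDuplicated(rn))
                        stop("duplicate progeny_id within a cross", call. = FALSE)
                      rownames(m) <- rn
                      m
                    })
  structure(
    list(genotype_label = as.character(genotype_label)[1L],
         map = map, crosses = crosses),
    class = "cross_collection"
  )
}

#' @export
print.cross_collection <- function(x, ...) {
  np <- vapply(x$crosses, nrow, 0L)
  cat("Cross collection '", x$genotype_label, "': ",
      length(x$crosses), " crosses, ", sum(np), " progeny (",
      paste(range(np), collapse = "-"), " per cross), ",
      n_markers(x$map), " markers\n", sep = "")
  invisible(x)
}

#' Number of progeny in a collection
#' @param coll a [cross_collection()].
#' @return integer total progeny count.
#' @export
n_progeny <- function(coll) {
  stopifnot(inherits(coll, "cross_collection"))
  sum(vapply(coll$crosses, nrow, 0L))
}

# Stack all crosses into one genotype matrix (rows keep cross order).
all_genotypes <- function(coll) {
  do.call(rbind, unname(coll$crosses))
}

#' Read a progeny genotype table
#'
#' Reads a TSV with header columns `cross_id`, `progeny_id`, then one
#' column per marker in the map's order. States are coded `M`/`W`
#' (synonyms `m` and `+` are accepted and normalised). Rows with states
#' outside that set, or missing values, are rejected rather than imputed
#' -- classical testcross scoring cannot phase a gap -- and the count of
#' rejected rows is reported in the load report.
#'
#' @param path path to the TSV file.
#' @param map a [marker_map()]; the table's marker columns must match.
#' @param genotype_label label for the maternal genotype.
#' @return A [cross_collection()] with attribute `load_report`, a list with
#'   `n_input`, `n_accepted`, `n_rejected` and `rejected_rows` (input row
#'   numbers). `n_accepted + n_rejected == n_input` always.
#' @export
read_progeny_table <- function(path, map, genotype_label = "unlabeled") {
  stopifnot(inherits(map, "marker_map"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  needed <- c("cross_id", "progeny_id", map$markers)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("progeny table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), needed)
  if (length(extra))
    stop("unknown column(s) in progeny table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("no progeny in table", call. = FALSE)

  geno <- as.matrix(df[, map$markers, drop = FALSE])
  geno[geno == "m"] <- "M"
  geno[geno == "+"] <- "W"
  ok_state <- !is.na(geno) & (geno == "M" | geno == "W")
  ok_row <- rowSums(ok_state) == ncol(geno) &
    !is.na(df$cross_id) & nzchar(df$cross_id)
  rejected <- which(!ok_row)
  if (length(rejected))
    message(length(rejected), " row(s) rejected at load (bad state or id): ",
            paste(utils::head(rejected, 10L), collapse = ", "))
  if (!any(ok_row)) stop("no progeny (all rows rejected)", call. = FALSE)

  coll <- cross_collection(geno[ok_row, , drop = FALSE],
                           cross_id = df$cross_id[ok_row],
                           progeny_id = df$progeny_id[ok_row],
                           map = map, genotype_label = genotype_label)
  attr(coll, "load_report") <- list(
    n_input = nrow(df),
    n_accepted = sum(ok_row),
    n_rejected = length(rejected),
    rejected_rows = rejected
  )
  coll
}

#' Write a progeny genotype table
#'
#' Inverse of [read_progeny_table()]: writes the `cross_id`, `progeny_id`,
#' marker-state TSV so that reading the file back reproduces the
#' collection field-for-field. Crosses with zero progeny are omitted with
#' a warning.
#'
#' @param coll a [cross_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_progeny_table <- function(coll, path) {
  stopifnot(inherits(coll, "cross_collection"))
  keep <- vapply(coll$crosses, nrow, 0L) > 0L
  if (!all(keep))
    warning("omitting ", sum(!keep), " cross(es) with 0 progeny")
  crosses <- coll$crosses[keep]
  rows <- lapply(names(crosses), function(cid) {
    m <- crosses[[cid]]
    data.frame(cross_id = cid, progeny_id = rownames(m),
               m, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
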