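#' Allele tokens for spore calls
#'
#' `P1`/`P2` are the two parental alleles, `BOTH` marks a disomic spore
#' carrying both homologs of the marker's chromosome (e.g. a chromosome-III
#' disome that is a non-mater because it carries MATa and MATalpha), and
#' `NONE` marks a missing call (dead or nullisomic spores).
#' @keywords internal
ALLELE_TOKENS <- c("P1", "P2", "BOTH", "NONE")

SPORE_IDS <- c("a", "b", "c", "d")

#' Construct a tetrad dataset
#'
#' A tetrad dataset holds one strain's dissection results: a marker map plus a
#' spore table with one row per spore clone (four per tetrad) and one allele
#' column per marker.
#'
#' @param strain Strain label.
#' @param marker_map A [marker_map()].
#' @param spores A `data.frame` with columns `tetrad_id`, `spore_id` (one of
#'   a/b/c/d), `viable` (logical or 0/1), and one column per marker in
#'   `marker_map` holding tokens `P1`, `P2`, `BOTH`, `NONE`.
#'
#' @return An object of class `tetrad_dataset`.
#' @export
tetrad_dataset <- function(strain, marker_map, spores) {
  validate_marker_map(marker_map)
  spores <- as.data.frame(spores, stringsAsFactors = FALSE)
  spores$tetrad_id <- as.character(spores$tetrad_id)
  spores$spore_id <- as.character(spores$spore_id)
  spores$viable <- as.logical(spores$viable)
  obj <- structure(
    list(strain = as.character(strain), marker_map = marker_map,
         spores = spores),
    class = "tetrad_dataset"
  )
  validate_tetrad_dataset(obj)
  obj
}

validate_tetrad_dataset <- function(x) {
  stopifnot(inherits(x, "tetrad_dataset"))
  sp <- x$spores
  markers <- x$marker_map$marker
  base_cols <- c("tetrad_id", "spore_id", "viable")
  missing_cols <- setdiff(c(base_cols, markers), names(sp))
  if (length(missing_cols) > 0L) {
    stop("spore table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(sp), c(base_cols, markers))
  if (length(extra) > 0L) {
    stop("unknown marker columns in spore table: ",
         paste(extra, collapse = ", "))
  }
  if (nrow(sp) > 0L) {
    counts <- table(sp$tetrad_id)
    bad <- names(counts)[counts != 4L]
    if (length(bad) > 0L) {
      stop("tetrad(s) without exactly 4 spore rows: ",
           paste(bad, collapse = ", "))
    }
    key <- paste(sp$tetrad_id, sp$spore_id)
    if (anyDuplicated(key)) {
      stop("duplicate (tetrad_id, spore_id): ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    }
    if (!all(sp$spore_id %in% SPORE_IDS)) {
      stop("spore_id must be one of a, b, c, d")
    }
    for (m in markers) {
      bad_tok <- !(sp[[m]] %in% ALLELE_TOKENS)
      if (any(bad_tok)) {
        stop("invalid allele token(s) at marker ", m, ": ",
             paste(unique(sp[[m]][bad_tok]), collapse = ", "))
      }
      if (any(!sp$viable & sp[[m]] != "NONE")) {
        stop("dead spores must have NONE calls (marker ", m, ")")
      }
    }
  }
  invisible(x)
}

#' Number of tetrads in a dataset
#' @param dataset A `tetrad_dataset`.
#' @return Integer count.
#' @export
n_tetrads <- function(dataset) {
  length(unique(dataset$spores$tetrad_id))
}

#' Tetrad ids in input order
#' @param dataset A `tetrad_dataset`.
#' @return Character vector.
#' @export
tetrad_ids <- function(dataset) {
  unique(dataset$spores$tetrad_id)
}

#' @export
print.tetrad_dataset <- function(x, ...) {
  cat("<tetrad_dataset> strain:", x$strain, "\n")
  cat("  ", n_tetrads(x), "tetrads,", nrow(x$marker_map), "markers on",
      length(unique(x$marker_map$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' Read a tetrad dissection table
#'
#' The dissection table is a TSV with header
#' `tetrad_id<TAB>spore_id<TAB>viable<TAB><marker1>...<markerK>`; `viable` is
#' 0/1 and allele tokens are `P1`, `P2`, `BOTH`, `NONE`. Malformed rows,
#' unknown marker columns, tetrads without exactly four spores and duplicated
#' spore ids raise errors naming the offender.
#'
#' @param path Path to the dissection TSV.
#' @param map_path Path to the marker-map TSV (see [read_marker_map()]), or a
#'   `marker_map` object.
#' @param strain Strain label to attach; defaults to the file name.
#' @return A [tetrad_dataset()].
#' @export
read_tetrad_table <- function(path, map_path, strain = NULL) {
  if (!file.exists(path)) stop("dissection table not found: ", path)
  map <- if (inherits(map_path, "marker_map")) map_path else read_marker_map(map_path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  base_cols <- c("tetrad_id", "spore_id", "viable")
  missing_cols <- setdiff(base_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("dissection table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(raw), c(base_cols, map$marker))
  if (length(unknown) > 0L) {
    stop("unknown marker column(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  if (!all(raw$viable %in% c("0", "1"))) {
    bad <- which(!(raw$viable %in% c("0", "1")))[1L]
    stop("malformed viability flag on data line ", bad, " of ", path)
  }
  raw$viable <- raw$viable == "1"
  if (is.null(strain)) strain <- sub("\\.[^.]*$", "", basename(path))
  tetrad_dataset(strain, map, raw)
}

#' Write a tetrad dissection table
#'
#' Emits the canonical TSV dialect consumed by [read_tetrad_table()];
#' round-trips bit-identically.
#'
#' @param dataset A `tetrad_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tetrad_table <- function(dataset, path) {
  validate_tetrad_dataset(dataset)
  out <- dataset$spores
  out$viable <- as.integer(out$viable)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
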