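#' Construct and validate a marker map
#'
#' A marker map is an ordered table of scored loci: one row per marker with its
#' chromosome, genetic position (cM), and flags for centromere linkage and the
#' mating-type locus. Marker order within a chromosome defines the intervals
#' available for tetrad linkage analysis.
#'
#' @param marker Character vector of unique marker names.
#' @param chromosome Character vector of chromosome labels.
#' @param position_cM Numeric, non-negative map positions; must be
#'   non-decreasing within each chromosome.
#' @param is_centromere_linked Logical; markers tight to the centromere, used
#'   for sister-spore inference.
#' @param is_mating_type Logical; at most one marker may be flagged (the MAT
#'   locus, used for non-mater nondisjunction signatures).
#'
#' @return A `data.frame` of class `marker_map`.
#' @export
#' @examples
#' marker_map(c("HIS4", "LEU2"), c("III", "III"), c(0, 13.8),
#'            c(FALSE, FALSE), c(FALSE, FALSE))
marker_map <- function(marker, chromosome, position_cM,
                       is_centromere_linked = rep(FALSE, length(marker)),
                       is_mating_type = rep(FALSE, length(marker))) {
  map <- data.frame(
    marker = as.character(marker),
    chromosome = as.character(chromosome),
    position_cM = as.numeric(position_cM),
    is_centromere_linked = as.logical(is_centromere_linked),
    is_mating_type = as.logical(is_mating_type),
    stringsAsFactors = FALSE
  )
  validate_marker_map(map)
  class(map) <- c("marker_map", "data.frame")
  map
}

validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map))
  required <- c("marker", "chromosome", "position_cM",
                "is_centromere_linked", "is_mating_type")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0L) {
    stop("marker map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(map$marker)) {
    stop("marker names must be unique; duplicated: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  }
  if (any(map$position_cM < 0)) stop("marker positions must be non-negative")
  for (chr in unique(map$chromosome)) {
    pos <- map$position_cM[map$chromosome == chr]
    if (is.unsorted(pos)) {
      stop("marker positions must be non-decreasing within chromosome ", chr)
    }
  }
  if (sum(map$is_mating_type) > 1L) {
    stop("at most one mating-type marker is allowed per map")
  }
  invisible(map)
}

#' Read a marker map from a tab-separated file
#'
#' Expects the header `marker chromosome position_cM is_centromere_linked
#' is_mating_type`, flags coded 0/1.
#'
#' @param path Path to the TSV file.
#' @return A `marker_map`.
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("marker map file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("marker", "chromosome", "position_cM",
                "is_centromere_linked", "is_mating_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("marker map ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  marker_map(raw$marker, raw$chromosome, raw$position_cM,
             raw$is_centromere_linked == 1, raw$is_mating_type == 1)
}

#' Write a marker map as TSV
#'
#' @param map A `marker_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  out <- map
  out$is_centromere_linked <- as.integer(out$is_centromere_linked)
  out$is_mating_type <- as.integer(out$is_mating_type)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default NHY-style marker map (chromosomes III, VII, VIII)
#'
#' Ten markers on three chromosomes, matching the classical SK1 dissection
#' panel: HIS4-LEU2-CEN3-MAT on the small chromosome III, TRP5-CYH2-MET13-LYS5
#' on the large chromosome VII, and CEN8-THR1-CUP1 on the medium chromosome
#' VIII. Interval sizes equal the wild-type tetrad map distances; markers sit
#' inside longer chromosomes (full genetic lengths of roughly 115, 350, and
#' 180 cM) so that the simulator also places crossovers outside the marked
#' region, as real meioses do.
#'
#' @return A `marker_map` with 10 markers.
#' @export
nhy_marker_map <- function() {
  marker_map(
    marker = c("HIS4", "LEU2", "CEN3", "MAT",
               "TRP5", "CYH2", "MET13", "LYS5",
               "CEN8", "THR1", "CUP1"),
    chromosome = c(rep("III", 4), rep("VII", 4), rep("VIII", 3)),
    position_cM = c(40.0, 53.8, 59.9, 74.8,
                    120.0, 156.0, 165.3, 186.4,
                    60.0, 81.5, 106.2),
    is_centromere_linked = c(FALSE, FALSE, TRUE, FALSE,
                             FALSE, FALSE, FALSE, FALSE,
                             TRUE, FALSE, FALSE),
    is_mating_type = c(FALSE, FALSE, FALSE, TRUE,
                       FALSE, FALSE, FALSE, FALSE,
                       FALSE, FALSE, FALSE)
  )
}

#' Standard interval list for a marker map
#'
#' Consecutive marker pairs within each chromosome, in map order.
#'
#' @param map A `marker_map`.
#' @return A `data.frame` with columns `chromosome`, `markerA`, `markerB`.
#' @export
marker_intervals <- function(map) {
  validate_marker_map(map)
  out <- do.call(rbind, lapply(unique(map$chromosome), function(chr) {
    mk <- map$marker[map$chromosome == chr]
    if (length(mk) < 2L) return(NULL)
    data.frame(chromosome = chr,
               markerA = mk[-length(mk)],
               markerB = mk[-1L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
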