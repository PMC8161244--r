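# Ballesteros-Weinstein generic numbering support.
#
# A BW map is a named integer vector: names are generic labels like "2.43",
# values are 0-based protein residue indices.

#' Read a Ballesteros-Weinstein map
#'
#' Reads a whitespace-delimited two-column table (`label  residue_number`),
#' with `#` comments.  When a topology is supplied, the second column is
#' interpreted as a PDB residue number (`resseq`) and translated to the
#' topology's 0-based protein residue index; otherwise the numbers are taken
#' to be 0-based residue indices already.
#'
#' @param path path to the map file.
#' @param topology optional `red_topology` used to translate PDB residue
#'   numbers to residue indices.
#' @return a `red_bwmap`: named integer vector of 0-based residue indices.
#' @export
read_bw_map <- function(path, topology = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BW map: ", path, call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed BW map lines: ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  labels <- vapply(parts, `[[`, "", 1L)
  nums <- as.integer(vapply(parts, `[[`, "", 2L))
  if (anyDuplicated(labels))
    stop("duplicate BW labels in map: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  idx <- nums
  if (!is.null(topology)) {
    prot <- topology$atoms[topology$atoms$component_class == "protein", ]
    lut <- prot$residue_index[!duplicated(prot$residue_index)]
    names(lut) <- prot$resseq[!duplicated(prot$residue_index)]
    idx <- unname(lut[as.character(nums)])
    if (anyNA(idx))
      stop("BW map references PDB residue numbers absent from the topology: ",
           paste(nums[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(as.integer(idx), labels), class = "red_bwmap")
}

#' Build a BW map from labels and indices
#'
#' @param labels character vector of generic labels ("2.43", "6.30", ...).
#' @param indices 0-based residue indices, same length.
#' @return a `red_bwmap`.
#' @export
bw_map <- function(labels, indices) {
  stopifnot(length(labels) == length(indices))
  if (anyDuplicated(labels)) stop("duplicate BW labels", call. = FALSE)
  structure(stats::setNames(as.integer(indices), labels), class = "red_bwmap")
}

#' Resolve a generic residue label to a residue index
#'
#' @param map a `red_bwmap`.
#' @param label a single generic label, e.g. `"2.43"`.
#' @return the mapped 0-based residue index.
#' @export
#' @examples
#' m <- bw_map(c("2.43", "6.30"), c(55, 200))
#' resolve_bw(m, "2.43")
resolve_bw <- function(map, label) {
  stopifnot(length(label) == 1L)
  if (!label %in% names(map))
    stop("unknown Ballesteros-Weinstein label: ", label, call. = FALSE)
  unname(map[[label]])
}

#' Resolve a contiguous generic-label range to residue indices
#'
#' Both endpoints must be on the same helix and present in the map; the
#' returned indices run from the first to the second endpoint inclusive.
#'
#' @param map a `red_bwmap`.
#' @param from,to endpoint labels, e.g. `"5.37"`, `"5.63"`.
#' @return integer vector of 0-based residue indices.
#' @export
bw_range <- function(map, from, to) {
  a <- resolve_bw(map, from)
  b <- resolve_bw(map, to)
  if (a > b) stop("BW range endpoints out of order: ", from, " > ", to, call. = FALSE)
  a:b
}
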