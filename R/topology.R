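# PDB topology parsing and component classification.
#
# No installed R package in this stack reads PDB coordinate files, so the
# fixed-column parser below is written here.  It understands ATOM/HETATM
# records only, which is all the pipeline needs.

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common force-field protonation-state variants
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

.default_water <- c("HOH", "TIP3", "TIP", "WAT", "SPC", "TIP4", "SOL")
.default_lipid <- c("POPC", "CHL1", "POPE", "POPS", "DPPC", "CHOL")

#' Load a PDB topology
#'
#' Parses ATOM/HETATM records of a PDB file into a topology: one row per atom
#' with its residue assignment and a component class (`protein`, `water`,
#' `lipid`, `ligand` or `other`) inferred from the residue name.  Protein
#' residues receive contiguous 0-based indices `0 .. n_residues - 1` in order
#' of appearance; non-protein residues are numbered after them.
#'
#' @param path path to a PDB file.
#' @param ligand_resnames character vector of residue names to class as
#'   ligand (default none).
#' @param lipid_resnames,water_resnames residue-name lists for the lipid and
#'   water classes; defaults cover the common CHARMM/AMBER names
#'   (POPC/CHL1..., HOH/TIP3...).
#' @return an object of class `red_topology`: a list with `atoms` (data frame
#'   with columns `atom_id`, `atom_name`, `element`, `residue_index`,
#'   `residue_name`, `resseq`, `component_class`) and `n_residues`, the
#'   number of protein residues.
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  ALA A   2       3.000   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' top <- load_topology(pdb)
#' top$n_residues
load_topology <- function(path,
                          ligand_resnames = character(),
                          lipid_resnames = .default_lipid,
                          water_resnames = .default_water) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  # stop at the first model so multi-model files give a single topology
  endmdl <- which(trimws(substr(readLines(path, warn = FALSE), 1, 6)) == "ENDMDL")
  if (length(endmdl)) {
    all_lines <- readLines(path, warn = FALSE)
    first_model <- all_lines[seq_len(endmdl[1L] - 1L)]
    lines <- first_model[trimws(substr(first_model, 1, 6)) %in% c("ATOM", "HETATM")]
  }

  atom_name <- trimws(substr(lines, 13L, 16L))
  res_name <- trimws(substr(lines, 18L, 21L))
  chain <- substr(lines, 22L, 22L)
  resseq <- suppressWarnings(as.integer(substr(lines, 23L, 26L)))
  x <- as.numeric(substr(lines, 31L, 38L))
  y <- as.numeric(substr(lines, 39L, 46L))
  z <- as.numeric(substr(lines, 47L, 54L))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("unparseable coordinates in ", path, call. = FALSE)
  element <- trimws(substr(lines, 77L, 78L))
  no_elem <- element == ""
  element[no_elem] <- substr(gsub("[0-9]", "", atom_name[no_elem]), 1L, 1L)

  cls <- rep("other", length(lines))
  cls[res_name %in% .standard_aa] <- "protein"
  cls[res_name %in% water_resnames] <- "water"
  cls[res_name %in% lipid_resnames] <- "lipid"
  cls[res_name %in% ligand_resnames] <- "ligand"

  # residue identity: (chain, resseq, resname) runs in file order
  res_key <- paste(chain, resseq, res_name, sep = "|")
  prot_keys <- unique(res_key[cls == "protein"])
  other_keys <- setdiff(unique(res_key), prot_keys)
  if (length(prot_keys) == 0L)
    stop("empty system: no protein residues found in ", path, call. = FALSE)
  res_index_map <- stats::setNames(
    seq_along(c(prot_keys, other_keys)) - 1L, c(prot_keys, other_keys))
  residue_index <- unname(res_index_map[res_key])

  atoms <- data.frame(
    atom_id = seq_along(lines) - 1L,
    atom_name = atom_name,
    element = element,
    residue_index = residue_index,
    residue_name = res_name,
    resseq = resseq,
    chain = chain,
    component_class = cls,
    stringsAsFactors = FALSE
  )
  atoms$xyz0 <- NULL
  top <- structure(
    list(atoms = atoms, n_residues = length(prot_keys),
         first_frame = cbind(x = x, y = y, z = z)),
    class = "red_topology")
  top
}

#' @export
print.red_topology <- function(x, ...) {
  tab <- table(x$atoms$component_class)
  cat("MD topology:", nrow(x$atoms), "atoms,", x$n_residues, "protein residues\n")
  cat("  atoms by class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

# atoms belonging to protein residue r (0-based); used by the contact builder
.protein_atom_rows <- function(topology) {
  which(topology$atoms$component_class == "protein")
}

# Write a topology + coordinate matrix to a PDB file (single model).
write_pdb <- function(topology, coords, path, model = NULL) {
  a <- topology$atoms
  stopifnot(nrow(a) == nrow(coords))
  con <- file(path, if (is.null(model) || model == 1L) "w" else "a")
  on.exit(close(con))
  if (!is.null(model)) writeLines(sprintf("MODEL     %4d", model), con)
  nm <- a$atom_name
  # PDB convention: names shorter than 4 chars start in column 14
  nm_fmt <- ifelse(nchar(nm) >= 4L, sprintf("%-4s", nm), sprintf(" %-3s", nm))
  writeLines(sprintf(
    "%-6s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$component_class == "protein", "ATOM", "HETATM"),
    (a$atom_id %% 99999L) + 1L, nm_fmt, a$residue_name, a$chain,
    a$resseq, coords[, 1L], coords[, 2L], coords[, 3L], 1, 0, a$element), con)
  if (!is.null(model)) writeLines("ENDMDL", con) else writeLines("END", con)
  invisible(path)
}
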