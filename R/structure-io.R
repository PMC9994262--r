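# Minimal coordinate-file IO. Atom tables are plain data.frames with columns
#   atom (name), resid (integer), resname, chain, element, x, y, z, occ
# which is all the shell builder needs; no bonds, altlocs or anisou.

#' Read a PDB or mmCIF coordinate file into an atom table
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A data.frame atom table (columns `atom`, `resid`, `resname`,
#'   `chain`, `element`, `x`, `y`, `z`, `occ`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (format == "pdb") read_pdb(path) else read_mmcif(path)
}

read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  lines <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (!length(lines)) stop("no ATOM records in ", path, call. = FALSE)
  fx <- function(a, b) trimws(substr(lines, a, b))
  out <- data.frame(
    atom = fx(13, 16),
    resid = as.integer(fx(23, 26)),
    resname = fx(18, 20),
    chain = fx(22, 22),
    element = fx(77, 78),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    occ = as.numeric(fx(55, 60)),
    stringsAsFactors = FALSE)
  if (anyNA(out$x) || anyNA(out$y) || anyNA(out$z))
    stop("malformed coordinates in ", path, call. = FALSE)
  out$occ[is.na(out$occ)] <- 1
  out$element[out$element == ""] <- substr(out$atom[out$element == ""], 1, 1)
  out
}

read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  idx <- grep("^_atom_site\\.", lines)
  if (!length(idx)) stop("no _atom_site loop in ", path, call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[idx]))
  body_start <- max(idx) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    body <- c(body, ln)
  }
  if (!length(body)) stop("empty atom_site loop in ", path, call. = FALSE)
  toks <- strsplit(body, "[[:space:]]+")
  nf <- length(fields)
  if (any(lengths(toks) != nf))
    stop("ragged atom_site loop in ", path, call. = FALSE)
  m <- matrix(unlist(toks), ncol = nf, byrow = TRUE)
  colnames(m) <- fields
  pick <- function(nm, alt = NULL) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else stop("atom_site field missing: ", nm, call. = FALSE)
  }
  data.frame(
    atom = pick("label_atom_id", "auth_atom_id"),
    resid = as.integer(pick("label_seq_id", "auth_seq_id")),
    resname = pick("label_comp_id", "auth_comp_id"),
    chain = pick("auth_asym_id", "label_asym_id"),
    element = pick("type_symbol"),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    occ = suppressWarnings(as.numeric(pick("occupancy"))),
    stringsAsFactors = FALSE)
}

#' Write an atom table to a PDB file
#'
#' PDB is a fixed-column format: single-character chain identifiers and at
#' most 99,999 atoms. Larger models must go to mmCIF.
#'
#' @param atoms Atom table (see [read_structure()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  if (!nrow(atoms)) stop("empty atom table", call. = FALSE)
  if (nrow(atoms) > 99999L)
    stop("PDB format limit exceeded (> 99,999 atoms); use mmCIF", call. = FALSE)
  if (any(nchar(atoms$chain) > 1L))
    stop("PDB format limit: chain identifiers must be one character; use mmCIF",
         call. = FALSE)
  name <- ifelse(nchar(atoms$atom) < 4L, sprintf(" %-3s", atoms$atom),
                 atoms$atom)
  occ <- if ("occ" %in% names(atoms)) atoms$occ else 1
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000L, name,
    substr(atoms$resname, 1, 3), atoms$chain, atoms$resid,
    atoms$x, atoms$y, atoms$z, occ, 0,
    toupper(substr(atoms$element, 1, 2)))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an atom table to an mmCIF file
#'
#' mmCIF has no atom-count limit and supports multi-character chain
#' identifiers, so complete vesicle models are always written in this
#' format.
#'
#' @inheritParams write_pdb
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(atoms, path) {
  if (!nrow(atoms)) stop("empty atom table", call. = FALSE)
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, nrow(atoms))
  hdr <- c("data_gvshell", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_comp_id",
                                   "label_seq_id", "auth_asym_id",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy")))
  body <- sprintf("ATOM %d %s %s %s %d %s %.3f %.3f %.3f %.2f",
                  seq_len(nrow(atoms)), toupper(atoms$element), atoms$atom,
                  substr(atoms$resname, 1, 3), atoms$resid, atoms$chain,
                  atoms$x, atoms$y, atoms$z, occ)
  writeLines(c(hdr, body, "#"), path)
  invisible(path)
}

#' Write a shell model or atom table to disk
#'
#' Shell models are expanded to full atom tables first. Complete vesicles
#' exceed every PDB format limit and must be written as mmCIF; requesting
#' PDB output beyond the format's capacity is an error, not a truncation.
#'
#' @param x A `shell_model` or an atom table.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- if (inherits(x, "shell_model")) model_atoms(x) else x
  if (is.null(atoms) || !nrow(atoms)) stop("empty model", call. = FALSE)
  if (format == "pdb") write_pdb(atoms, path) else write_mmcif(atoms, path)
}
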