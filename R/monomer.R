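# Monomer templates: an atom table plus validated landmark atoms. The four
# correction rotations of the shell builder pivot on these landmarks:
#   - carbonyl O of residues 28 and 42 (their midpoint is the placement pivot)
#   - carbonyl O of residue 36 (hairpin turn)
#   - C-alpha of every residue 23..49 (hairpin plane fit, hinge axis 23->49)
#   - C-beta of residues 24..33 (sheet plane fit)
#   - at least one atom per residue 2..23 (the N-arm/alpha1 block moved by
#     the N-terminal hinge)

landmark_requirements <- function() {
  list(
    list(atom = "O",  resid = c(28L, 42L, 36L)),
    list(atom = "CA", resid = 23:49),
    list(atom = "CB", resid = 24:33))
}

missing_landmarks <- function(atoms) {
  miss <- character()
  for (req in landmark_requirements()) {
    have <- atoms$resid[atoms$atom == req$atom]
    gone <- setdiff(req$resid, have)
    if (length(gone)) miss <- c(miss, paste(req$atom, gone))
  }
  res_any <- unique(atoms$resid)
  gone <- setdiff(2:23, res_any)
  if (length(gone)) miss <- c(miss, paste("residue", gone))
  miss
}

#' Construct and validate a monomer template
#'
#' @param atoms Atom table (see [read_structure()]); may carry a `mass`
#'   column (Dalton per atom).
#' @param mass Optional total monomer mass in Dalton (overrides per-atom
#'   masses for [model_mass()]).
#' @return An object of class `monomer_template` (the atom table with a
#'   `monomer_mass` attribute).
#' @export
monomer_template <- function(atoms, mass = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("atom", "resid", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  if (anyDuplicated(atoms[, c("atom", "resid")]))
    stop("duplicate (atom name, residue) records", call. = FALSE)
  miss <- missing_landmarks(atoms)
  if (length(miss))
    stop("missing landmark atoms: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(atoms$resname)) atoms$resname <- "GLY"
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$element)) atoms$element <- substr(atoms$atom, 1, 1)
  if (is.null(atoms$occ)) atoms$occ <- 1
  structure(atoms, class = c("monomer_template", "data.frame"),
            monomer_mass = mass)
}

#' Load a monomer template from a coordinate file
#'
#' Reads a PDB or mmCIF file and validates that every landmark atom the
#' correction rotations reference is present; missing landmarks are listed
#' in the error.
#'
#' @inheritParams read_structure
#' @param chain Optional chain identifier to select (first chain otherwise).
#' @param mass Optional total monomer mass in Dalton.
#' @return A `monomer_template`.
#' @export
load_monomer <- function(path, format = c("auto", "pdb", "mmcif"),
                         chain = NULL, mass = NULL) {
  atoms <- read_structure(path, format)
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  monomer_template(atoms, mass = mass)
}

#' @export
print.monomer_template <- function(x, ...) {
  cat(sprintf("Monomer template: %d atoms, residues %d..%d\n",
              nrow(x), min(x$resid), max(x$resid)))
  m <- attr(x, "monomer_mass")
  if (!is.null(m)) cat(sprintf("  monomer mass %.1f Da\n", m))
  invisible(x)
}

# coordinates of one named landmark atom
landmark_xyz <- function(atoms, name, resid) {
  i <- which(atoms$atom == name & atoms$resid == resid)
  if (length(i) != 1L)
    stop("landmark not found: ", name, " ", resid, call. = FALSE)
  c(atoms$x[i], atoms$y[i], atoms$z[i])
}

# placement pivot: midpoint of carbonyl O 28 and O 42
template_pivot <- function(atoms) {
  (landmark_xyz(atoms, "O", 28L) + landmark_xyz(atoms, "O", 42L)) / 2
}

as_xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

set_xyz <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}
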