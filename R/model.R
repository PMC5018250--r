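# Atomic model container and coordinate I/O (PDB via bio3d, mmCIF).

#' Atomic model
#'
#' A light hierarchical coordinate container: one row per atom with chain,
#' residue (1-based author numbering), atom name, element, position
#' (Angstrom), occupancy and B-factor; optional `strand` and `unit` columns
#' record filament-assembly provenance.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z` and optionally `o`, `b`, `strand`, `unit`.
#' @return Object of class `"atomic_model"`.
#' @export
atomic_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(xyz)))
    stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom-name) triples")
  structure(list(atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Atomic model: %d atoms, %d chains, %d residues\n",
              nrow(a), length(unique(a$chain)),
              length(unique(paste(a$chain, a$resno)))))
  invisible(x)
}

#' Chain identifiers of a model
#' @param model An [atomic_model()].
#' @return Character vector of chain ids in order of appearance.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' Coordinates of a model (optionally one chain / atom selection)
#' @param model An [atomic_model()].
#' @param chain Optional chain id filter.
#' @param elety Optional atom-name filter (e.g. "CA").
#' @return n x 3 coordinate matrix.
#' @export
model_coords <- function(model, chain = NULL, elety = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  if (!is.null(elety)) a <- a[a$elety %in% elety, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Apply a rigid transform to a model
#' @param model An [atomic_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector.
#' @return Transformed [atomic_model()].
#' @export
transform_model <- function(model, rotation, translation = c(0, 0, 0)) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rotation)
  a$x <- xyz[, 1] + translation[1]
  a$y <- xyz[, 2] + translation[2]
  a$z <- xyz[, 3] + translation[3]
  model$atoms <- a
  model
}

# element -> atomic number (common protein/lipid elements)
atomic_number <- function(element) {
  tab <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
  z <- tab[toupper(element)]
  if (anyNA(z))
    stop("unknown element: ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  as.numeric(z)
}

# element -> van der Waals radius (Angstrom)
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
  r <- tab[toupper(element)]
  if (anyNA(r))
    stop("unknown element: ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  as.numeric(r)
}

# deterministic mapping of arbitrary chain names into PDB's 1-char space
chain_id_map <- function(chains) {
  pool <- c(LETTERS, letters, as.character(0:9))
  u <- unique(chains)
  if (length(u) > length(pool))
    stop(sprintf("chain-id space exhausted: %d chains exceed the %d PDB ids",
                 length(u), length(pool)))
  stats::setNames(pool[seq_along(u)], u)
}

#' Write an atomic model to PDB or mmCIF
#'
#' Format chosen by extension: `.pdb` (via bio3d; chain names are mapped
#' deterministically into the single-character PDB space, erroring when more
#' than 62 chains are present) or `.cif` (minimal mmCIF `atom_site` loop
#' carrying the full chain names).
#'
#' @param model An [atomic_model()].
#' @param path Output path ending in `.pdb` or `.cif`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    map <- chain_id_map(a$chain)
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                     resid = a$resid, chain = unname(map[a$chain]),
                     elety = a$elety, o = a$o, b = a$b,
                     elesy = a$element)
  } else if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_model", "#", "loop_",
                 "_atom_site.group_PDB", "_atom_site.id",
                 "_atom_site.type_symbol", "_atom_site.label_atom_id",
                 "_atom_site.label_comp_id", "_atom_site.label_asym_id",
                 "_atom_site.label_seq_id", "_atom_site.Cartn_x",
                 "_atom_site.Cartn_y", "_atom_site.Cartn_z",
                 "_atom_site.occupancy", "_atom_site.B_iso_or_equiv"), con)
    writeLines(sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f",
                       seq_len(nrow(a)), a$element, a$elety, a$resid,
                       a$chain, a$resno, a$x, a$y, a$z, a$o, a$b), con)
    writeLines("#", con)
  } else stop("unsupported model format: ", path)
  invisible(path)
}

#' Read an atomic model from PDB or mmCIF
#'
#' @param path Path ending in `.pdb` or `.cif` (read with bio3d).
#' @return An [atomic_model()].
#' @export
read_model <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    p <- bio3d::read.pdb(path)
    a <- p$atom
    atomic_model(data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                            elety = a$elety,
                            element = ifelse(is.na(a$elesy) | a$elesy == "",
                                             substr(trimws(a$elety), 1, 1),
                                             trimws(a$elesy)),
                            x = a$x, y = a$y, z = a$z, o = a$o, b = a$b))
  } else if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    rows <- grep("^(ATOM|HETATM) ", ln, value = TRUE)
    if (length(rows) == 0) stop("no atom_site records in ", path)
    f <- utils::read.table(text = rows, stringsAsFactors = FALSE)
    atomic_model(data.frame(chain = as.character(f$V6), resno = f$V7,
                            resid = f$V5, elety = f$V4, element = f$V3,
                            x = f$V8, y = f$V9, z = f$V10,
                            o = f$V11, b = f$V12))
  } else stop("unsupported model format: ", path)
}
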