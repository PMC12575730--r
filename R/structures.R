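#' @useDynLib ensemblefit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans optim rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Construct a structure model from an atom table
#'
#' A `structure_model` is the unit every pipeline stage transforms: an
#' ordered atom table with residue/chain identity and Cartesian coordinates
#' in Angstrom. Residue identity is the key (chain, residue number,
#' insertion code); topology comparisons use these keys plus atom names,
#' never coordinates.
#'
#' @param atoms data.frame with columns `element`, `name`, `resno`,
#'   `resname`, `chain`, `insert`, `x`, `y`, `z`, and optionally `het`
#'   (logical, HETATM flag) and `occ` (occupancy).
#' @param validate check invariants (every residue holding any backbone
#'   atom has exactly one CA; finite coordinates; non-empty elements).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, validate = TRUE) {
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  rownames(atoms) <- NULL
  m <- structure(list(atoms = atoms), class = "structure_model")
  if (validate) validate_structure_model(m)
  m
}

validate_structure_model <- function(m) {
  a <- m$atoms
  need <- c("element", "name", "resno", "resname", "chain", "insert",
            "x", "y", "z")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(c(a$x, a$y, a$z))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(a$element) | is.na(a$element)))
    stop("empty element symbol in atom table")
  prot <- a[!a$het, , drop = FALSE]
  if (nrow(prot)) {
    for (ch in unique(prot$chain)) {
      if (!any(prot$name[prot$chain == ch] == "CA"))
        stop("topology error: chain '", ch, "' has no CA atoms")
    }
    key <- paste(prot$chain, prot$resno, prot$insert)
    has_bb <- tapply(prot$name %in% BACKBONE_NAMES, key, any)
    n_ca <- tapply(prot$name == "CA", key, sum)
    bad <- names(has_bb)[has_bb & n_ca != 1]
    if (length(bad))
      stop("topology error: residue(s) without exactly one CA: ",
           paste(utils::head(bad, 5), collapse = "; "))
  }
  invisible(m)
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %d atoms, %d residues, chains: %s\n",
              nrow(a), n_residues(x),
              paste(unique(a$chain[!a$het]), collapse = ",")))
  invisible(x)
}

# protein residues in file order, keyed by (chain, resno, insert)
residue_table <- function(model) {
  a <- model$atoms
  prot <- a[!a$het, , drop = FALSE]
  key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  idx <- !duplicated(key)
  data.frame(chain = prot$chain[idx], resno = prot$resno[idx],
             insert = prot$insert[idx], resname = prot$resname[idx],
             stringsAsFactors = FALSE)
}

#' Number of protein residues in a model
#'
#' Residues are counted by distinct (chain, residue number, insertion code)
#' among non-HETATM records; this is the sequence length used to scale
#' geometry scores.
#' @param model a `structure_model`.
#' @return integer count.
#' @export
n_residues <- function(model) nrow(residue_table(model))

#' Extract C-alpha coordinates
#'
#' One row per protein residue, in residue order as read from the file.
#'
#' @param model a `structure_model`.
#' @return numeric matrix (n_residues x 3), Angstrom.
#' @export
ca_coordinates <- function(model) {
  a <- model$atoms
  ca <- a[!a$het & a$name == "CA", , drop = FALSE]
  ord <- order(match(paste(ca$chain, ca$resno, ca$insert, sep = "\r"),
                     with(residue_table(model),
                          paste(chain, resno, insert, sep = "\r"))))
  out <- as.matrix(ca[ord, c("x", "y", "z")])
  dimnames(out) <- NULL
  out
}

#' One-letter sequence per chain
#' @param model a `structure_model`.
#' @return named character vector, one string per chain.
#' @export
model_sequence <- function(model) {
  rt <- residue_table(model)
  vapply(split(rt$resname, rt$chain),
         function(r) paste(bio3d::aa321(r), collapse = ""), "")
}

# topology signature: residue keys + atom names, coordinates excluded
topology_signature <- function(model) {
  a <- model$atoms
  paste(a$chain, a$resno, a$insert, a$name, a$het, sep = "\r")
}

same_topology <- function(a, b) {
  identical(topology_signature(a), topology_signature(b))
}

atom_coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

set_atom_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

heavy_mask <- function(model) !(toupper(model$atoms$element) %in% c("H", "D"))

# convert a bio3d pdb object to a structure_model, resolving altlocs to
# the highest-occupancy conformer (first wins on ties)
model_from_bio3d <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(gsub("[^A-Za-z].*", "", trimws(a$elety)), 1, 1)
  elem <- trimws(elem)
  fallback <- substr(trimws(a$elety), 1, 1)
  elem[is.na(elem) | !nzchar(elem)] <- fallback[is.na(elem) | !nzchar(elem)]
  atoms <- data.frame(
    element = elem, name = trimws(a$elety), resno = a$resno,
    resname = trimws(a$resid), chain = ifelse(is.na(a$chain), " ", a$chain),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    occ = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name,
                 sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      i[which.max(atoms$occ[i])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms$alt <- NULL
  structure_model(atoms)
}

#' Read a protein structure (PDB or mmCIF)
#'
#' All heavy atoms are returned (hydrogens retained if present); author
#' residue numbering is preserved. Alternate locations are collapsed to
#' the highest-occupancy conformer (first on ties). HETATM records are
#' kept but flagged non-protein and excluded from C-alpha operations.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE,
                                         verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  model_from_bio3d(pdb)
}

#' Write a structure model (PDB or minimal mmCIF)
#'
#' PDB output uses fixed-width ATOM/HETATM records; coordinates outside
#' the %8.3f field range or residue numbers above 9999 raise an explicit
#' overflow error rather than writing a corrupt file.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    xyz <- c(a$x, a$y, a$z)
    if (any(xyz > 9999.999) || any(xyz < -999.999))
      stop("coordinate overflow: PDB %8.3f field cannot hold values ",
           "outside [-999.999, 9999.999]")
    if (any(a$resno > 9999) || any(a$resno < -999))
      stop("residue number overflow: PDB resSeq field holds at most 4 ",
           "characters")
    writeLines(pdb_atom_lines(a), path)
  } else {
    writeLines(cif_atom_lines(a), path)
  }
  invisible(path)
}

pdb_atom_lines <- function(a) {
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  c(sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$het, "HETATM", "ATOM"),
            (seq_len(nrow(a)) - 1L) %% 99999L + 1L,
            name4, "", sprintf("%3s", a$resname),
            substr(paste0(a$chain, " "), 1, 1), a$resno,
            substr(paste0(a$insert, " "), 1, 1),
            a$x, a$y, a$z, a$occ, 0,
            toupper(a$element)),
    "END")
}

cif_atom_lines <- function(a) {
  chain <- ifelse(nzchar(trimws(a$chain)), a$chain, "A")
  c("data_model",
    "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id",
                            "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "pdbx_formal_charge", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("%-6s %d %s %s . %s %s 1 %d %s %.4f %.4f %.4f %.2f %.2f ? %d %s %s %s 1",
            ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
            toupper(a$element), a$name, a$resname, chain, a$resno,
            ifelse(nzchar(a$insert), a$insert, "?"),
            a$x, a$y, a$z, a$occ, 0,
            a$resno, a$resname, chain, a$name),
    "#")
}

#' Construct an ensemble of topology-identical models
#'
#' @param models list of `structure_model`s sharing chain/residue/atom-name
#'   topology (checked).
#' @param source_labels optional character labels, one per model.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(models, source_labels = NULL) {
  stopifnot(length(models) >= 1)
  sig <- topology_signature(models[[1]])
  for (i in seq_along(models)[-1]) {
    if (!identical(topology_signature(models[[i]]), sig))
      stop("topology error: model ", i,
           " differs from model 1 in chain/residue/atom topology")
  }
  if (!is.null(source_labels) && length(source_labels) != length(models))
    stop("source_labels length must match number of models")
  structure(list(models = models, source_labels = source_labels),
            class = "ensemble")
}

#' @export
length.ensemble <- function(x) length(x$models)

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d models, %d residues each\n", length(x$models),
              n_residues(x$models[[1]])))
  invisible(x)
}

#' Construct a trajectory of topology-identical frames
#' @param frames list of `structure_model`s.
#' @param frame_interval abstract step count between stored frames.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, frame_interval = 1L) {
  ens <- ensemble(frames)  # reuse the topology check
  structure(list(frames = ens$models, frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$frames)

split_pdb_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts))
    ends <- c(ends, length(lines))
  Map(function(s, e) lines[(s + 1):(e - 1)], starts, ends)
}

read_model_from_lines <- function(lines) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(lines, "END"), tmp)
  read_structure(tmp, "pdb")
}

#' Read a trajectory from a multi-model PDB or a list of PDB files
#'
#' Frames are returned in file order; identical topology across frames is
#' enforced. This is the import channel for externally produced
#' density-guided simulation output (converted to multi-model PDB).
#'
#' @param paths one multi-model PDB path, or a character vector of
#'   single-model PDB paths taken in order.
#' @param frame_interval abstract step count between stored frames.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(paths, frame_interval = 1L) {
  if (length(paths) == 1) {
    chunks <- split_pdb_models(readLines(paths))
    frames <- lapply(chunks, read_model_from_lines)
  } else {
    frames <- lapply(paths, read_structure, format = "pdb")
  }
  trajectory(frames, frame_interval = frame_interval)
}

#' Write a trajectory as a multi-model PDB
#' @param traj a `trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  out <- unlist(lapply(seq_along(traj$frames), function(i) {
    body <- pdb_atom_lines(traj$frames[[i]]$atoms)
    c(sprintf("MODEL     %4d", i), body[-length(body)], "ENDMDL")
  }))
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB
#' @param ens an `ensemble`.
#' @param path output path.
#' @export
write_ensemble <- function(ens, path) {
  write_trajectory(structure(list(frames = ens$models, frame_interval = 1L),
                             class = "trajectory"), path)
}

#' Read an ensemble from a multi-model PDB
#' @param path multi-model PDB path.
#' @param source_labels optional labels per model.
#' @return an `ensemble`.
#' @export
read_ensemble <- function(path, source_labels = NULL) {
  tr <- read_trajectory(path)
  ensemble(tr$frames, source_labels = source_labels)
}
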