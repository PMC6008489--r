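#' Read a protein-ligand structure from a PDB file
#'
#' Loads ATOM/HETATM records (fixed-column PDB via bio3d) into a flat
#' atom table. The element symbol is taken from the PDB element column
#' when present, otherwise inferred from the atom name (leading digits
#' stripped, first letter; two-letter halogens CL/BR recognised on
#' hetero atoms). Alternate locations are resolved per atom site by
#' keeping the highest occupancy, ties going to altLoc 'A'.
#'
#' @param path path to a PDB-format coordinate file.
#' @return object of class `structure_model`: list with `atoms`, a
#'   data.frame of `serial, atom_name, element, residue_name,
#'   residue_number, chain, x, y, z, occupancy, is_hetero`.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) fs_stop(
                    sprintf("cannot read PDB file '%s': %s", path, conditionMessage(e)),
                    "fragscreen_input_error"))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) {
    fs_stop(sprintf("no atoms in '%s'", path), "fragscreen_input_error")
  }
  atoms <- data.frame(
    serial = a$eleno,
    atom_name = trimws(a$elety),
    element = toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy))),
    residue_name = trimws(a$resid),
    residue_number = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    is_hetero = a$type == "HETATM",
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE
  )
  need <- !nzchar(atoms$element)
  atoms$element[need] <- infer_element(atoms$atom_name[need], atoms$is_hetero[need])
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    warning(sprintf("skipping %d atom record(s) with non-finite coordinates", sum(bad)),
            call. = FALSE)
    atoms <- atoms[!bad, ]
  }
  if (!nrow(atoms)) fs_stop(sprintf("no usable atoms in '%s'", path),
                            "fragscreen_input_error")
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = path), class = "structure_model")
}

# element from atom name: strip leading digits ("1HB" -> H); hetero-atom
# names starting CL/BR are halogens; otherwise the first letter
infer_element <- function(name, is_hetero) {
  nm <- toupper(sub("^[0-9']+", "", name))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  halo <- is_hetero & two %in% c("CL", "BR")
  el[halo] <- two[halo]
  el
}

# one atom per (chain, residue, insert-free site, atom name):
# max occupancy wins, ties to altLoc 'A' (then first record)
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$residue_number, atoms$residue_name,
               atoms$atom_name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$alt != "A", atoms$alt,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(key[ord]), ]
  atoms[order(atoms$serial), ]
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms (%d hetero), chains: %s\n",
              nrow(x$atoms), sum(x$atoms$is_hetero),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Select atoms from a structure model
#'
#' Conjunctive filter over residue name, chain, residue number range and
#' hetero flag; `NULL` criteria match everything.
#'
#' @param model a [read_structure()] result.
#' @param resname residue/ligand 3-letter code(s).
#' @param chain chain label(s).
#' @param resno residue number(s).
#' @param hetero `TRUE` for HETATM records only, `FALSE` for ATOM only.
#' @return data.frame of matching atom records.
#' @export
select_atoms <- function(model, resname = NULL, chain = NULL, resno = NULL,
                         hetero = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resname)) keep <- keep & a$residue_name %in% resname
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$residue_number %in% resno
  if (!is.null(hetero)) keep <- keep & a$is_hetero == hetero
  a[keep, , drop = FALSE]
}

#' Euclidean distance between two atom records
#'
#' @param a,b one-row atom data.frames (or any list with `x, y, z` in Å).
#' @return distance in Å.
#' @examples
#' measure_distance(list(x = 1, y = 2, z = 2), list(x = 0, y = 0, z = 0)) # 3
#' @export
measure_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

# all-pairs distance matrix between two atom tables
cross_distances <- function(a, b) {
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-"); dz <- outer(a$z, b$z, "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

# donor/acceptor role of a protein N/O atom, by name convention:
# backbone O and side-chain carbonyl/carboxylate O accept; backbone N
# and the H-bearing side-chain nitrogens (Lys NZ, Arg, Trp NE1, amide
# ND2/NE2) donate; hydroxyls and His ring N are ambiguous
protein_hbond_role <- function(atom_name, residue_name) {
  n <- toupper(atom_name); r <- toupper(residue_name)
  ifelse(n %in% c("O", "OXT", "OD1", "OD2", "OE1", "OE2"), "acceptor",
  ifelse(n == "N", "donor",
  ifelse(n == "NZ" & r == "LYS", "donor",
  ifelse(n %in% c("NE", "NH1", "NH2") & r == "ARG", "donor",
  ifelse(n == "NE1" & r == "TRP", "donor",
  ifelse(n == "ND2" & r == "ASN", "donor",
  ifelse(n == "NE2" & r == "GLN", "donor", "undetermined")))))))
}

#' Find ligand-protein hydrogen-bond contacts
#'
#' Distance-only criterion: every ligand N/O paired with every protein
#' N/O within `max_dist` Å is reported, sorted by distance. Crystal
#' structures at typical kinase resolutions carry no hydrogen positions,
#' so donor/acceptor assignment is heuristic from atom identity
#' (backbone carbonyl O accepts, backbone amide N and Lys NZ donate,
#' etc.); pairs whose polarity cannot be called are labelled
#' `"undetermined"`.
#'
#' @param model a [read_structure()] result.
#' @param ligand_selector,protein_selector lists of arguments for
#'   [select_atoms()], e.g. `list(resname = "LIG")` and
#'   `list(hetero = FALSE)`.
#' @param max_dist donor-acceptor distance cutoff in Å (default 3.5).
#' @return data.frame `ligand_atom, ligand_element, protein_chain,
#'   protein_residue, protein_resno, protein_atom, distance, donor`
#'   (`"ligand"`, `"protein"` or `"undetermined"`), sorted by distance.
#' @export
find_hbonds <- function(model, ligand_selector, protein_selector,
                        max_dist = 3.5) {
  lig <- do.call(select_atoms, c(list(model), ligand_selector))
  pro <- do.call(select_atoms, c(list(model), protein_selector))
  if (!nrow(lig) || !nrow(pro)) {
    fs_stop("empty ligand or protein selection", "fragscreen_input_error")
  }
  lig <- lig[lig$element %in% c("N", "O"), , drop = FALSE]
  pro <- pro[pro$element %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(ligand_atom = character(), ligand_element = character(),
                      protein_chain = character(), protein_residue = character(),
                      protein_resno = integer(), protein_atom = character(),
                      distance = numeric(), donor = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(lig) || !nrow(pro)) return(empty)
  d <- cross_distances(lig, pro)
  hit <- which(d <= max_dist, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  role <- protein_hbond_role(pro$atom_name[hit[, 2]], pro$residue_name[hit[, 2]])
  out <- data.frame(
    ligand_atom = lig$atom_name[hit[, 1]],
    ligand_element = lig$element[hit[, 1]],
    protein_chain = pro$chain[hit[, 2]],
    protein_residue = pro$residue_name[hit[, 2]],
    protein_resno = pro$residue_number[hit[, 2]],
    protein_atom = pro$atom_name[hit[, 2]],
    distance = d[hit],
    donor = ifelse(role == "acceptor", "ligand",
                   ifelse(role == "donor", "protein", "undetermined")),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$distance, out$protein_resno, out$protein_atom,
                   out$ligand_atom), ]
  rownames(out) <- NULL
  out
}

#' Find ligand-protein hydrophobic contacts
#'
#' Carbon-carbon pairs within `max_dist` Å (default 4.5, the usual
#' nonpolar packing cutoff), grouped by protein residue.
#'
#' @inheritParams find_hbonds
#' @param max_dist C-C distance cutoff in Å.
#' @return data.frame `protein_chain, protein_residue, protein_resno,
#'   n_pairs, min_distance`, one row per contacting residue, sorted by
#'   minimum distance.
#' @export
find_hydrophobic_contacts <- function(model, ligand_selector, protein_selector,
                                      max_dist = 4.5) {
  lig <- do.call(select_atoms, c(list(model), ligand_selector))
  pro <- do.call(select_atoms, c(list(model), protein_selector))
  if (!nrow(lig) || !nrow(pro)) {
    fs_stop("empty ligand or protein selection", "fragscreen_input_error")
  }
  lig <- lig[lig$element == "C", , drop = FALSE]
  pro <- pro[pro$element == "C", , drop = FALSE]
  empty <- data.frame(protein_chain = character(), protein_residue = character(),
                      protein_resno = integer(), n_pairs = integer(),
                      min_distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(lig) || !nrow(pro)) return(empty)
  d <- cross_distances(lig, pro)
  hit <- which(d <= max_dist, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  key <- paste(pro$chain[hit[, 2]], pro$residue_number[hit[, 2]],
               pro$residue_name[hit[, 2]], sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(hit)), key), function(ii) {
    j <- hit[ii[1], 2]
    data.frame(protein_chain = pro$chain[j],
               protein_residue = pro$residue_name[j],
               protein_resno = pro$residue_number[j],
               n_pairs = length(ii),
               min_distance = min(d[hit[ii, , drop = FALSE]]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$min_distance), ]
  rownames(out) <- NULL
  out
}

#' Compare pocket residues between two structures
#'
#' Given a user-supplied residue-number correspondence (e.g. MPS1
#' gatekeeper M602 vs Aurora A L210), reports the residue identity at
#' each mapped position in both models and whether the amino acid is
#' conserved. Positions absent from a model are reported with `NA`, not
#' raised.
#'
#' @param model_a,model_b [read_structure()] results.
#' @param alignment_map named integer vector: names are residue numbers
#'   in `model_a`, values the corresponding numbers in `model_b`.
#' @param chain_a,chain_b optional chain restriction per model.
#' @return data.frame `resno_a, residue_a, resno_b, residue_b,
#'   same_amino_acid` (`NA` when a position is unmapped in either model).
#' @export
compare_pocket_residues <- function(model_a, model_b, alignment_map,
                                    chain_a = NULL, chain_b = NULL) {
  if (is.null(names(alignment_map))) {
    fs_stop("alignment_map must be named by model_a residue numbers",
            "fragscreen_input_error")
  }
  resname_at <- function(model, resno, chain) {
    a <- select_atoms(model, resno = resno, chain = chain, hetero = FALSE)
    if (!nrow(a)) NA_character_ else a$residue_name[1]
  }
  ra <- as.integer(names(alignment_map))
  rb <- as.integer(alignment_map)
  na <- vapply(ra, resname_at, "", model = model_a, chain = chain_a)
  nb <- vapply(rb, resname_at, "", model = model_b, chain = chain_b)
  data.frame(resno_a = ra, residue_a = na, resno_b = rb, residue_b = nb,
             same_amino_acid = ifelse(is.na(na) | is.na(nb), NA, na == nb),
             stringsAsFactors = FALSE)
}
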