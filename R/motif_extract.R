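# Ligand-contact motif extraction. A motif is an ordered tuple of protein
# atoms that make non-hydrophobic contacts with a bound ligand, ordered by
# ascending contact distance, and characterised downstream by its pairwise
# distance matrix (Angstrom) and pairwise potential differences (kT/e).

# Accepted element pairs (protein-ligand): hydrophobic (carbon) contacts
# are excluded. Hydrogens are normally stripped on parse, so in practice
# O/N/S pairings dominate.
.ACCEPTED_PAIRS <- c("O-N", "N-O", "O-H", "H-O", "O-O", "N-N", "N-H",
                     "H-N", "S-H", "H-S")

.pair_ok <- function(elem_prot, elem_lig, whitelist = .ACCEPTED_PAIRS) {
  paste0(elem_prot, "-", elem_lig) %in% whitelist
}

#' Extract the ligand-contact motif from a holoenzyme
#'
#' Finds the `n` protein atoms closest to any ligand atom under an
#' expanding-radius schedule: the search starts at `radius_start` (2.5
#' Angstrom) and grows in `radius_step` (0.1 Angstrom) increments until `n`
#' accepted contacts are collected or `radius_cap` is reached. Only
#' non-hydrophobic element pairings are accepted (O/N/S/H on both sides;
#' carbon contacts are excluded), at most one atom per protein residue is
#' kept (the closest), and within a radius shell candidates are taken in
#' ascending exact distance with ties broken by (chain, resno, atom name).
#'
#' @param protein A `structure3d` (hetero atoms are ignored as contact
#'   partners).
#' @param ligand A `ligand3d`.
#' @param n Number of contact atoms to collect (>= 3; default 5).
#' @param radius_start,radius_step,radius_cap Expanding-radius schedule in
#'   Angstrom (defaults 2.5, 0.1, 8.0).
#' @param whitelist Accepted element pairs as `"P-L"` strings.
#' @return A `contact_set`: data frame with one row per contact, columns
#'   `chain`, `resno`, `insert`, `resid`, `name`, `elem` (protein atom),
#'   `lig_name`, `lig_elem` (ligand atom) and `distance`, sorted by
#'   ascending distance; attribute `source_id`.
#' @export
get_motif <- function(protein, ligand, n = 5,
                      radius_start = 2.5, radius_step = 0.1,
                      radius_cap = 8.0, whitelist = .ACCEPTED_PAIRS) {
  stopifnot(inherits(protein, "structure3d"), inherits(ligand, "ligand3d"))
  if (n < 3) stop("n must be >= 3")
  if (nrow(ligand$atoms) == 0) stop("ligand has no atoms")

  cand <- .contact_candidates(protein, ligand, radius_cap, mode = "strict",
                              whitelist = whitelist)
  picked <- integer(0)
  seen_res <- character(0)
  radius <- radius_start
  while (length(picked) < n && radius <= radius_cap + 1e-9) {
    shell <- which(cand$distance <= radius + 1e-9)
    shell <- setdiff(shell, picked)
    for (i in shell) {                    # cand is pre-sorted by distance
      rk <- cand$res_key[i]
      if (rk %in% seen_res) next          # one atom per residue: keep closest
      picked <- c(picked, i)
      seen_res <- c(seen_res, rk)
      if (length(picked) == n) break
    }
    radius <- radius + radius_step
  }
  if (length(picked) < n) {
    stop("insufficient contacts: found ", length(picked),
         " accepted contact atoms within ", radius_cap,
         " Angstrom, needed ", n)
  }
  out <- cand[picked, setdiff(names(cand), "res_key"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contact_set", "data.frame"),
            source_id = protein$id, het_code = ligand$het_code)
}

# All protein-ligand contact candidates within `cap`, filtered by mode,
# sorted by (distance, chain, resno, name); one row per (protein atom,
# closest qualifying ligand atom).
.contact_candidates <- function(protein, ligand, cap, mode,
                                whitelist = .ACCEPTED_PAIRS) {
  prot <- protein$atoms[!protein$atoms$het, , drop = FALSE]
  lig <- ligand$atoms
  if (nrow(prot) == 0) stop("structure has no protein atoms")
  d <- .cross_dist(as.matrix(prot[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  if (mode == "strict") {
    ok <- outer(prot$elem, lig$elem, function(p, l) .pair_ok(p, l, whitelist))
  } else {                                 # reporting: ligand atom N/O/S
    ok <- matrix(rep(lig$elem %in% c("N", "O", "S"), each = nrow(prot)),
                 nrow = nrow(prot))
  }
  d[!ok] <- Inf
  # closest qualifying ligand partner per protein atom
  jbest <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(prot)), jbest)]
  keep <- is.finite(dist) & dist <= cap + 1e-9
  res <- data.frame(
    chain = prot$chain[keep], resno = prot$resno[keep],
    insert = prot$insert[keep], resid = prot$resid[keep],
    name = prot$name[keep], elem = prot$elem[keep],
    lig_name = lig$name[jbest[keep]], lig_elem = lig$elem[jbest[keep]],
    distance = dist[keep], stringsAsFactors = FALSE)
  res$res_key <- paste(res$chain, res$resno, res$insert, sep = "/")
  res[order(res$distance, res$chain, res$resno, res$name), , drop = FALSE]
}

.cross_dist <- function(a, b) {
  # n x m Euclidean distance matrix
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Protein-ligand contact table
#'
#' Like [get_motif()] but with a selectable acceptance rule. `"strict"`
#' applies the non-hydrophobic pair whitelist used for motif extraction;
#' `"reporting"` accepts any contact whose *ligand* atom is N, O or S
#' (allowing protein carbon partners, as published contact tables do).
#' Both modes keep at most one atom per protein residue and sort by
#' ascending distance.
#'
#' @inheritParams get_motif
#' @param mode `"strict"` or `"reporting"`.
#' @param radius_cap Distance cap in Angstrom (default 8).
#' @return A `contact_set` data frame (see [get_motif()]).
#' @export
contact_table <- function(protein, ligand, n = 10,
                          mode = c("strict", "reporting"),
                          radius_cap = 8.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(protein, "structure3d"), inherits(ligand, "ligand3d"))
  cand <- .contact_candidates(protein, ligand, radius_cap, mode = mode)
  cand <- cand[!duplicated(cand$res_key), , drop = FALSE]
  cand <- utils::head(cand, n)
  out <- cand[, setdiff(names(cand), "res_key"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contact_set", "data.frame"),
            source_id = protein$id, het_code = ligand$het_code,
            mode = mode)
}

#' @export
print.contact_set <- function(x, ...) {
  cat("<contact_set> ", attr(x, "source_id"), " : ",
      attr(x, "het_code"), ", ", nrow(x), " contacts\n", sep = "")
  lab <- paste0(x$resid, x$resno, x$insert, "/", x$name, "/", x$lig_name,
                "/", format(round(x$distance, 1)))
  print(data.frame(`R/A/LA/D` = lab, check.names = FALSE))
  invisible(x)
}

#' Write a contact table as TSV
#'
#' Columns mirror the R/A/LA/D convention: residue, residue atom, ligand
#' atom, distance.
#'
#' @param contacts A `contact_set`.
#' @param path Output path.
#' @param header Optional character vector of comment lines (prefixed `#`).
#' @return Invisibly, `path`.
#' @export
write_contacts <- function(contacts, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(residue = paste0(contacts$resid, contacts$resno,
                                    contacts$insert),
                   chain = contacts$chain,
                   atom = contacts$name,
                   ligand_atom = contacts$lig_name,
                   distance = round(contacts$distance, 2))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a motif from contact records
#'
#' Builds an ordered motif (default position order = ascending contact
#' distance) with its pairwise distance matrix and, when potentials are
#' supplied, its pairwise potential-difference matrix.
#'
#' The motif positions are the *residues* of the contact records, in
#' contact order; the atom representing each position is, by default, the
#' residue's designated functional atom (see [functional_atoms()]) rather
#' than the raw contact atom. A tyrosine may contact the ligand through
#' OH, but its comparable, precompiled motif feature is CZ; using the
#' designated atom makes query and database motifs commensurable. Contact
#' atoms can be requested instead with `atom_choice = "contact"`; either
#' way a residue type without a designation falls back to the contact
#' atom.
#'
#' @param contacts A `contact_set` (rows in motif-position order), or an
#'   atom data frame with the same protein-atom columns.
#' @param structure The `structure3d` the contacts refer to (coordinates
#'   are looked up here).
#' @param potentials Optional `potentials` object for the PD matrix.
#' @param source_id Identifier recorded on the motif.
#' @param atom_choice `"functional"` (default) or `"contact"`.
#' @param atom_table Functional-atom designation table (default
#'   [functional_atoms()]).
#' @return A `motif` object: list with `atoms` (data frame incl. coords),
#'   `keys`, `distances` (k x k), `pds` (k x k or NULL), `groups`
#'   (per-position residue sets or NULL), `source_id`.
#' @export
as_motif <- function(contacts, structure, potentials = NULL,
                     source_id = attr(contacts, "source_id"),
                     atom_choice = c("functional", "contact"),
                     atom_table = functional_atoms()) {
  atom_choice <- match.arg(atom_choice)
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms
  key_all <- paste(a$chain, a$resno, a$insert, a$name, sep = "/")
  nm <- contacts$name
  if (atom_choice == "functional") {
    des <- unname(atom_table[contacts$resid])
    use <- !is.na(des) &
      paste(contacts$chain, contacts$resno, contacts$insert, des,
            sep = "/") %in% key_all
    nm[use] <- des[use]
  }
  key_c <- paste(contacts$chain, contacts$resno, contacts$insert, nm,
                 sep = "/")
  idx <- match(key_c, key_all)
  if (anyNA(idx)) stop("contact atoms not found in structure: ",
                       paste(key_c[is.na(idx)], collapse = ", "))
  atoms <- a[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  k <- nrow(atoms)
  if (k < 3) stop("a motif needs at least 3 atoms")
  if (anyDuplicated(paste(atoms$chain, atoms$resno, atoms$insert))) {
    stop("motif atoms must come from distinct residues")
  }
  D <- as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
  dimnames(D) <- NULL
  pds <- NULL
  if (!is.null(potentials)) {
    pds <- unname(pairwise_pd(potentials, atom_keys(atoms)))
  }
  structure(list(atoms = atoms, keys = atom_keys(atoms), distances = D,
                 pds = pds, groups = NULL,
                 source_id = if (is.null(source_id)) structure$id
                             else source_id),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif> ", x$source_id, ": ", nrow(x$atoms), " atoms [",
      paste(paste0(.aa1(x$atoms$resid), x$atoms$resno, x$atoms$name),
            collapse = ","), "]",
      if (!is.null(x$pds)) " +PD",
      if (!is.null(x$groups)) " +groups", "\n", sep = "")
  invisible(x)
}

#' Enumerate k-atom sub-motifs of a contact set
#'
#' All `choose(m, k)` combinations of the `m` contact atoms, each
#' preserving the ascending-distance order of the parent set.
#'
#' @param contacts A `contact_set` of `m` rows.
#' @param structure The parent `structure3d`.
#' @param k Sub-motif size (3 <= k <= m; default 4).
#' @param potentials Optional `potentials` for PD matrices.
#' @param atom_choice,atom_table Passed to [as_motif()].
#' @return List of `motif` objects, in `utils::combn` order.
#' @export
enumerate_submotifs <- function(contacts, structure, k = 4,
                                potentials = NULL,
                                atom_choice = "functional",
                                atom_table = functional_atoms()) {
  m <- nrow(contacts)
  if (k > m) stop("k (", k, ") exceeds number of contacts (", m, ")")
  if (k < 3) stop("k must be >= 3")
  combos <- utils::combn(m, k)
  lapply(seq_len(ncol(combos)), function(j) {
    as_motif(contacts[combos[, j], , drop = FALSE], structure,
             potentials = potentials,
             source_id = attr(contacts, "source_id"),
             atom_choice = atom_choice, atom_table = atom_table)
  })
}

# Residue-group schemes: stereochemically equivalent side chains allowed at
# each motif position.
.GROUP_SCHEMES <- list(
  default = list(c("ASP", "GLU"), c("ASN", "GLN"), c("SER", "THR"),
                 c("LYS", "ARG"), c("TYR", "TRP", "PHE"), c("HIS"),
                 c("CYS"), c("GLY", "ALA")),
  identity = list()
)

.aa1 <- function(res3) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- map[res3]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Assign per-position residue groups to a motif
#'
#' Each motif position receives the set of amino-acid types accepted as a
#' stereochemically equivalent match at that position. The native type is
#' always included. The `"default"` scheme groups \{Asp, Glu\},
#' \{Asn, Gln\}, \{Ser, Thr\}, \{Lys, Arg\}, \{Tyr, Trp, Phe\},
#' \{Gly, Ala\}; His and Cys stay singletons, as does any other type. The
#' `"identity"` scheme restricts every position to its native type.
#'
#' @param motif A `motif`.
#' @param scheme `"default"` or `"identity"`, or a list of character
#'   vectors of 3-letter codes defining custom equivalence classes.
#' @return The motif with `groups` filled (list of character vectors of
#'   3-letter codes, one per position).
#' @export
assign_groups <- function(motif, scheme = "default") {
  stopifnot(inherits(motif, "motif"))
  if (is.character(scheme)) {
    if (!scheme %in% names(.GROUP_SCHEMES)) {
      stop("unknown group scheme '", scheme, "'; available: ",
           paste(names(.GROUP_SCHEMES), collapse = ", "))
    }
    classes <- .GROUP_SCHEMES[[scheme]]
  } else if (is.list(scheme)) {
    classes <- scheme
  } else stop("scheme must be a name or a list of residue-type classes")
  motif$groups <- lapply(motif$atoms$resid, function(r) {
    for (cl in classes) if (r %in% cl) return(cl)
    r
  })
  motif
}

#' Serialize a motif to JSON
#'
#' @param motif A `motif`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
motif_to_json <- function(motif, path = NULL) {
  stopifnot(inherits(motif, "motif"))
  obj <- list(
    format = "motifdock/motif", version = 1L,
    source_id = motif$source_id,
    atoms = motif$atoms[, c("chain", "resno", "insert", "resid", "name",
                            "elem", "x", "y", "z")],
    groups = motif$groups,
    distances = motif$distances,
    pds = motif$pds
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a motif back from JSON
#'
#' @param path File path or JSON string from [motif_to_json()].
#' @return A `motif` object.
#' @export
motif_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "motifdock/motif")) {
    stop("not a motif JSON file")
  }
  atoms <- as.data.frame(obj$atoms, stringsAsFactors = FALSE)
  atoms$het <- FALSE
  atoms$serial <- seq_len(nrow(atoms))
  groups <- if (is.null(obj$groups)) NULL else {
    if (is.list(obj$groups)) lapply(obj$groups, as.character)
    else as.list(as.character(obj$groups))
  }
  structure(list(atoms = atoms, keys = atom_keys(atoms),
                 distances = matrix(unlist(obj$distances),
                                    nrow = nrow(atoms)),
                 pds = if (is.null(obj$pds)) NULL
                       else matrix(unlist(obj$pds), nrow = nrow(atoms)),
                 groups = groups, source_id = obj$source_id),
            class = "motif")
}
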