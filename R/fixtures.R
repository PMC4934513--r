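# Synthetic structure generators with known ground truth. These emulate
# just enough of a protein-ligand complex for the pipeline to act on: a
# shell of residues (each a CA plus its designated functional side-chain
# atom) around a small rigid ligand, with a few residues placed at
# hydrogen-bonding distance to form a known contact motif. Geometry is
# idealised -- no backbone, no rotamers -- which is exactly what makes the
# ground truth (true motif, true transform, true docked coordinates)
# computable by construction.

# Residues usable as synthetic binding/background residues.
.FIXTURE_TYPES <- c("SER", "ASP", "GLU", "TYR", "LYS", "ARG", "HIS",
                    "ASN", "GLN", "THR", "TRP", "CYS", "PHE")

.unit_sphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Default synthetic ligand template
#'
#' A small rigid ligand with polar (O/N) and apolar (C) atoms.
#'
#' @return Data frame: `name`, `elem`, `x`, `y`, `z`.
#' @export
ligand_template <- function() {
  data.frame(
    name = c("C1", "C2", "O1", "N1", "O2", "C3"),
    elem = c("C", "C", "O", "N", "O", "C"),
    x = c(0.0, 1.5, 2.1, -0.8, -0.5, 2.2),
    y = c(0.0, 0.0, 1.1, 1.1, -1.2, -1.2),
    z = c(0.0, 0.0, 0.0, 0.3, 0.6, -0.7),
    stringsAsFactors = FALSE
  )
}

#' Random proper rotation + translation
#'
#' @param max_shift Translation magnitude bound per axis, Angstrom.
#' @return A `rigid_transform` with `det(R) = +1`.
#' @export
random_transform <- function(max_shift = 20) {
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))   # unique Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, stats::runif(3, -max_shift, max_shift))
}

#' Generate a holo/apo/target fixture with known ground truth
#'
#' Builds a synthetic holoenzyme (residue shell + ligand), its apo form
#' (same protein without the ligand) and a target (the protein rigidly
#' moved by a known transform, optionally with residue substitutions drawn
#' from the default group scheme, e.g. Glu -> Asp). The first
#' `n_binding` residues are placed with their functional atoms at
#' hydrogen-bond distance (2.6-3.4 A) of ligand polar atoms and constitute
#' the true contact motif; background residues sit on a shell well outside
#' contact range.
#'
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @param n_residues Total residues (default 20).
#' @param n_binding Number of binding-site residues (default 5).
#' @param types Residue types to draw from (default a mix of polar types).
#' @param binding_types Types of the binding residues, recycled
#'   (default `c("SER","GLU","TYR","GLU","TYR")`).
#' @param ligand Ligand template data frame (default [ligand_template()]).
#' @param transform `rigid_transform` applied to make the target, or
#'   `NULL` to draw a random one.
#' @param substitutions Named character vector of residue substitutions
#'   applied to the *target* (e.g. `c(GLU = "ASP")`); functional atom
#'   names are renamed accordingly.
#' @param shell_radius Background shell radius in Angstrom (default 16).
#' @return List: `holo`, `apo`, `target` (`structure3d`), `ligand`
#'   (`ligand3d` in the holo frame), `truth` (list: `transform`,
#'   `motif_keys` in ascending contact-distance order, `docked_xyz` the
#'   true ligand coordinates in the target frame, `seed`).
#' @export
make_binding_fixture <- function(seed, n_residues = 20, n_binding = 5,
                                 types = .FIXTURE_TYPES,
                                 binding_types = c("SER", "GLU", "TYR",
                                                   "GLU", "TYR"),
                                 ligand = ligand_template(),
                                 transform = NULL,
                                 substitutions = NULL,
                                 shell_radius = 16) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  if (n_binding < 3 || n_binding > n_residues) {
    stop("n_binding must be in [3, n_residues]")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)

  fat <- functional_atoms()
  btypes <- rep_len(binding_types, n_binding)
  n_bg <- n_residues - n_binding
  bg_types <- if (n_bg) sample(types, n_bg, replace = TRUE) else character(0)

  polar <- which(ligand$elem %in% c("O", "N"))
  lig_xyz <- as.matrix(ligand[, c("x", "y", "z")])
  # polar contact atom of each binding residue type (the atom that can
  # hydrogen-bond the ligand; for aromatics this differs from the
  # designated functional atom, as in real side chains)
  contact_atom <- c(SER = "OG", THR = "OG1", ASP = "OD1", GLU = "OE1",
                    TYR = "OH", TRP = "NE1", LYS = "NZ", ARG = "NH1",
                    HIS = "NE2", ASN = "OD1", GLN = "OE1", CYS = "SG")
  # binding residues: contact atom at 2.6 + 0.2*(i-1) A from a polar
  # ligand atom in a distinct outward direction; the designated
  # functional atom 1.4 A further out (same atom when the designations
  # coincide); CA further out still
  rows <- list()
  serial <- 0L
  placed <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n_binding)) {
    anchor <- lig_xyz[polar[1 + (i - 1) %% length(polar)], ]
    dd <- 2.6 + 0.2 * (i - 1)
    rt <- btypes[i]
    if (is.na(contact_atom[rt])) {
      stop("residue type ", rt, " has no polar contact atom; ",
           "not usable as a binding residue")
    }
    cn <- unname(contact_atom[rt]); fn <- unname(fat[rt])
    # rejection-sample an outward direction: the contact atom's nearest
    # ligand atom must be its own anchor (at exactly dd), the outer atoms
    # must stay clear of the ligand, and residues must not overlap
    xyz <- NULL
    for (try in 1:200) {
      u <- .unit_sphere(1)[1, ] + (anchor - colMeans(lig_xyz)) / 4
      u <- u / sqrt(sum(u^2))
      cx <- anchor + dd * u
      ox <- rbind(anchor + (dd + 1.4) * u, anchor + (dd + 2.9) * u)
      d_c <- sqrt(colSums((t(lig_xyz) - cx)^2))
      d_o <- apply(ox, 1, function(p)
        min(sqrt(colSums((t(lig_xyz) - p)^2))))
      sep <- if (nrow(placed)) min(sqrt(colSums(
        (t(placed) - cx)^2))) else Inf
      if (abs(min(d_c) - dd) < 1e-9 && all(d_o > dd + 0.3) && sep > 3) {
        xyz <- rbind(cx, ox)
        break
      }
    }
    if (is.null(xyz)) stop("could not place binding residue ", i,
                           "; try another seed")
    nm <- c(cn, if (fn != cn) fn, "CA")
    keep <- c(1L, if (fn != cn) 2L, 3L)
    xyz <- xyz[keep, , drop = FALSE]
    placed <- rbind(placed, xyz)
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial + seq_along(nm), name = nm,
      alt = "", resid = rt, chain = "A", resno = i, insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = 1, b = 20, elem = .elem_from_name(nm), het = FALSE,
      stringsAsFactors = FALSE)
    serial <- serial + length(nm)
  }
  if (n_bg) {
    shell <- .unit_sphere(n_bg) * (shell_radius +
                                     stats::runif(n_bg, 0, 6))
    for (j in seq_len(n_bg)) {
      rt <- bg_types[j]
      fx <- shell[j, ]
      ca <- fx * (1 + 1.5 / sqrt(sum(fx^2)))
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = c(serial, serial + 1L), name = c("CA", unname(fat[rt])),
        alt = "", resid = rt, chain = "A", resno = n_binding + j,
        insert = "",
        x = c(ca[1], fx[1]), y = c(ca[2], fx[2]), z = c(ca[3], fx[3]),
        o = 1, b = 20, elem = c("C", substr(fat[rt], 1, 1)), het = FALSE,
        stringsAsFactors = FALSE)
      serial <- serial + 1L
    }
  }
  prot <- do.call(rbind, rows)

  lig_atoms <- data.frame(
    serial = serial + seq_len(nrow(ligand)), name = ligand$name, alt = "",
    resid = "LIG", chain = "A", resno = 900L, insert = "",
    x = ligand$x, y = ligand$y, z = ligand$z, o = 1, b = 30,
    elem = ligand$elem, het = TRUE, stringsAsFactors = FALSE)

  holo <- new_structure3d(rbind(prot, lig_atoms), id = "FIXH")
  apo <- new_structure3d(prot, id = "FIXA")

  if (is.null(transform)) transform <- random_transform()
  tgt <- prot
  tgt[, c("x", "y", "z")] <- apply_transform(
    transform, as.matrix(prot[, c("x", "y", "z")]))
  if (!is.null(substitutions)) {
    for (from in names(substitutions)) {
      to <- substitutions[[from]]
      hit <- tgt$resid == from
      tgt$name[hit & tgt$name == unname(fat[from])] <- unname(fat[to])
      if (!is.na(contact_atom[from]) && !is.na(contact_atom[to])) {
        tgt$name[hit & tgt$name == unname(contact_atom[from])] <-
          unname(contact_atom[to])
      }
      tgt$resid[hit] <- to
      tgt$elem[hit] <- .elem_from_name(tgt$name[hit])
    }
  }
  target <- new_structure3d(tgt, id = "FIXT")

  lig_inst <- select_ligand(holo, "LIG")
  truth_motif <- get_motif(holo, lig_inst, n = n_binding)
  docked_xyz <- apply_transform(transform, lig_xyz)

  list(holo = holo, apo = apo, target = target, ligand = lig_inst,
       truth = list(transform = transform,
                    motif_keys = paste(truth_motif$chain, truth_motif$resno,
                                       truth_motif$insert, truth_motif$resid,
                                       truth_motif$name, sep = "/"),
                    docked_xyz = docked_xyz, seed = seed))
}

#' Generate a per-atom potential fixture with closed-form ground truth
#'
#' @param s A `structure3d`.
#' @param rule `"constant"` (all atoms `value`), `"ramp"` (potential =
#'   `slope` times the coordinate along `axis`), or `"charges"`
#'   (screened-Coulomb surrogate over the supplied charge table).
#' @param value Constant value (default 5).
#' @param slope,axis Ramp parameters (default slope 1 along `"x"`).
#' @param charges Charge table for `"charges"` (default
#'   [default_charges()]).
#' @return Data frame usable as a table source for [assign_potentials()]:
#'   `chain`, `resno`, `resname`, `atomname`, `potential`.
#' @export
make_potential_fixture <- function(s, rule = c("constant", "ramp",
                                               "charges"),
                                   value = 5, slope = 1, axis = "x",
                                   charges = default_charges()) {
  rule <- match.arg(rule)
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  pot <- switch(rule,
    constant = rep(value, nrow(a)),
    ramp = slope * a[[axis]],
    charges = as.numeric(assign_potentials(s, "surrogate",
                                           charges = charges)))
  data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
             atomname = a$name, potential = pot, stringsAsFactors = FALSE)
}

#' Write an OpenDX scalar grid file
#'
#' Emits the APBS dialect read by [read_opendx()]; useful for grid-based
#' tests and for exporting surrogate fields.
#'
#' @param values Array of dim `counts` (x, y, z order).
#' @param origin Grid origin (3-vector, Angstrom).
#' @param delta Grid spacing per axis (3-vector, Angstrom).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_opendx <- function(values, origin, delta, path) {
  counts <- dim(values)
  stopifnot(length(counts) == 3, length(origin) == 3, length(delta) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by motifdock",
    sprintf("object 1 class gridpositions counts %d %d %d",
            counts[1], counts[2], counts[3]),
    sprintf("origin %g %g %g", origin[1], origin[2], origin[3]),
    sprintf("delta %g 0.0 0.0", delta[1]),
    sprintf("delta 0.0 %g 0.0", delta[2]),
    sprintf("delta 0.0 0.0 %g", delta[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            counts[1], counts[2], counts[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(counts))), con)
  # z fastest
  vals <- as.numeric(aperm(values, c(3, 2, 1)))
  n3 <- (length(vals) %/% 3) * 3
  if (n3) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.10e", r),
                                             collapse = " ")), con)
  }
  if (n3 < length(vals)) {
    writeLines(paste(sprintf("%.10e", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
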