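# Independent oracles and small builders used across the suite. These are
# deliberately naive (sort / enumerate / closed form) and share no code
# with the package internals they check.

# Brute-force contact-motif oracle: list all protein-ligand atom pairs,
# filter by the element-pair whitelist, sort by distance, keep one atom
# per residue (the closest), take the first n.
oracle_motif <- function(protein, ligand, n, cap = 8.0) {
  wl <- c("O-N", "N-O", "O-H", "H-O", "O-O", "N-N", "N-H", "H-N",
          "S-H", "H-S")
  prot <- protein$atoms[!protein$atoms$het, ]
  lig <- ligand$atoms
  pairs <- expand.grid(i = seq_len(nrow(prot)), j = seq_len(nrow(lig)))
  pairs$d <- sqrt(rowSums((as.matrix(prot[pairs$i, c("x", "y", "z")]) -
                           as.matrix(lig[pairs$j, c("x", "y", "z")]))^2))
  pairs$ok <- paste0(prot$elem[pairs$i], "-", lig$elem[pairs$j]) %in% wl
  pairs <- pairs[pairs$ok & pairs$d <= cap + 1e-9, ]
  pairs <- pairs[order(pairs$d, prot$chain[pairs$i], prot$resno[pairs$i],
                       prot$name[pairs$i]), ]
  res <- paste(prot$chain[pairs$i], prot$resno[pairs$i],
               prot$insert[pairs$i], sep = "/")
  pairs <- pairs[!duplicated(res), ]
  if (nrow(pairs) < n) return(NULL)
  pairs <- head(pairs, n)
  list(keys = atom_keys(prot[pairs$i, ]), dist = pairs$d)
}

# Brute-force k-subset enumeration with a pairwise distance cutoff.
oracle_cliques <- function(xyz, k, cutoff) {
  n <- nrow(xyz)
  if (n < k) return(matrix(integer(0), nrow = k))
  D <- as.matrix(dist(xyz))
  cmb <- combn(n, k)
  ok <- apply(cmb, 2, function(ix) all(D[ix, ix] <= cutoff + 1e-9))
  cmb[, ok, drop = FALSE]
}

# All permutations of 1..k, as a matrix with one permutation per column.
oracle_perms <- function(k) {
  if (k == 1) return(matrix(1L))
  do.call(cbind, lapply(seq_len(k), function(i) {
    rbind(i, matrix(seq_len(k)[-i][oracle_perms(k - 1)], nrow = k - 1))
  }))
}

# Brute-force congruence search: score every group-compatible ordered
# arrangement of every k-subset within the cutoff.
oracle_search <- function(db_atoms, query, k, cutoff, s_thresh,
                          lambda = 1, deadzone = 100, potentials = NULL) {
  xyz <- as.matrix(db_atoms[, c("x", "y", "z")])
  combos <- oracle_cliques(xyz, k, cutoff)
  perms <- oracle_perms(k)
  ut <- upper.tri(matrix(0, k, k))
  dq <- query$distances[ut]
  pdq <- if (!is.null(query$pds) && !is.null(potentials))
    abs(query$pds[ut]) else NULL
  out <- list()
  for (ci in seq_len(ncol(combos))) {
    for (pi in seq_len(ncol(perms))) {
      ord <- combos[perms[, pi], ci]
      types_ok <- all(mapply(function(r, g) r %in% g,
                             db_atoms$resid[ord], query$groups))
      if (!types_ok) next
      D <- as.matrix(dist(xyz[ord, , drop = FALSE]))
      dc <- D[ut]
      sc <- sum(abs(dq - dc) / dq)
      if (!is.null(pdq)) {
        pd <- outer(as.numeric(potentials)[match(atom_keys(db_atoms[ord, ]),
                                                 names(potentials))],
                    as.numeric(potentials)[match(atom_keys(db_atoms[ord, ]),
                                                 names(potentials))], "-")
        dpd <- abs(pdq - abs(pd[ut]))
        sc <- sc + lambda * sum(ifelse(dpd < deadzone, 0,
                                       (dpd - deadzone) /
                                         pmax(pdq, deadzone)))
      }
      if (sc <= s_thresh) {
        out[[length(out) + 1]] <- list(keys = atom_keys(db_atoms[ord, ]),
                                       score = sc)
      }
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "score"))]
}

# A bare motif stub with given atoms/distance matrix (for scoring tests
# that exercise the matrix formulas directly).
motif_stub <- function(D, resids = NULL, pds = NULL, xyz = NULL) {
  k <- nrow(D)
  if (is.null(resids)) resids <- rep("SER", k)
  if (is.null(xyz)) xyz <- matrix(0, k, 3)
  atoms <- data.frame(serial = seq_len(k), name = paste0("A", seq_len(k)),
                      alt = "", resid = resids, chain = "A",
                      resno = seq_len(k), insert = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      o = 1, b = 0, elem = "O", het = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, keys = atom_keys(atoms), distances = D,
                 pds = pds, groups = NULL, source_id = "stub"),
            class = "motif")
}

# A structure3d made of bare atoms at given coordinates.
atoms_at <- function(xyz, name, resid, elem = NULL, resno = NULL,
                     het = FALSE, chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(serial = seq_len(n), name = name, alt = "", resid = resid,
             chain = chain, resno = resno, insert = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             elem = if (is.null(elem)) substr(name, 1, 1) else elem,
             het = het, stringsAsFactors = FALSE)
}

# Minimal hand-written PDB text (fixed columns), for parser tests that
# must not depend on the package's own writer.
pdb_line <- function(type, serial, name, resid, chain, resno, x, y, z,
                     o = 1, b = 0, elem = substr(name, 1, 1), alt = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resid, chain, resno, x, y, z, o, b, elem)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
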