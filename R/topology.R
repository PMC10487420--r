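#' Default amino-acid topology
#'
#' Packaged internal-coordinate topology for the 20 standard amino acids:
#' ideal bond lengths (Angstrom) and bond angles (degrees), atom
#' connectivity, rotatable torsion definitions (phi, psi, omega,
#' chi1..chi4), per-element contact radii, a per-element solvation
#' preference table for the contact-burial solvation surrogate, and the
#' PDBv3/CHARMM atom-name dialect table. Side-chain geometry derives from
#' chemical-component-dictionary ideal residues.
#'
#' @return an object of class \code{nmr_topology}.
#' @export
default_topology <- function() {
  structure(list(
    residues = ..aa_topology,
    standard_aa = names(..aa_topology),
    radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10),
    solvation = c(C = -0.02, S = -0.02, N = 0.01, O = 0.01, H = 0),
    dialect = ..dialect_table
  ), class = "nmr_topology")
}

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Accept a one-letter string or a vector of 3-letter codes.
as_sequence3 <- function(sequence) {
  if (length(sequence) == 1 && !sequence %in% names(..aa_topology) &&
      nchar(sequence) > 1) {
    letters1 <- strsplit(toupper(sequence), "")[[1]]
    bad <- setdiff(letters1, names(AA1TO3))
    if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
    return(unname(AA1TO3[letters1]))
  }
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, names(..aa_topology))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  sequence
}

# Chi torsion quadruples defined for a residue type.
chi_defs <- function(resname, topology) {
  topology$residues[[resname]]$chis
}

# --- placement compilation -------------------------------------------------

# Flatten per-residue placement records for a sequence into parallel arrays
# for cpp_rebuild, a torsion registry, and the bond list. Atom order is
# residue by residue in placement order; OXT is appended to the final
# residue. Returns a "compiled placement" list.
compile_placement <- function(sequence, topology = default_topology()) {
  seq3 <- as_sequence3(sequence)
  n <- length(seq3)

  # torsion registry
  tor <- list()
  for (i in seq_len(n)) {
    res <- seq3[i]
    if (i > 1) tor[[length(tor) + 1]] <- c(i, "phi", "backbone")
    tor[[length(tor) + 1]] <- c(i, "psi", "backbone")
    if (i < n) tor[[length(tor) + 1]] <- c(i, "omega", "omega")
    for (cn in names(chi_defs(res, topology)))
      tor[[length(tor) + 1]] <- c(i, cn, "sidechain")
  }
  tors <- data.frame(resi = as.integer(vapply(tor, `[`, "", 1)) - 1L,
                     name = vapply(tor, `[`, "", 2),
                     class = vapply(tor, `[`, "", 3),
                     stringsAsFactors = FALSE)
  tkey <- paste(tors$resi, tors$name)

  rows <- vector("list", n)
  offset <- 0L
  index <- list()  # per residue: named atom index vector
  for (i in seq_len(n)) {
    res <- seq3[i]
    pl <- topology$residues[[res]]$place
    if (i == 1) pl <- pl[pl$name != "H", , drop = FALSE]
    if (i == n) {
      pl <- rbind(pl, data.frame(name = "OXT", element = "O", r1 = "C",
                                 r2 = "CA", r3 = "N", bond = 1.25,
                                 angle = 117, dkind = "tor", dvalue = 0,
                                 dtor = "psi", stringsAsFactors = FALSE))
    }
    pl$resi <- i - 1L
    pl$resname <- res
    rows[[i]] <- pl
    index[[i]] <- setNames(offset + seq_len(nrow(pl)), pl$name)
    offset <- offset + nrow(pl)
  }
  atoms <- do.call(rbind, rows)
  natom <- nrow(atoms)

  resolve <- function(i, name) {
    if (startsWith(name, "-")) {
      if (i == 1) return(0L)
      idx <- index[[i - 1]][substring(name, 2)]
    } else {
      idx <- index[[i]][name]
    }
    if (is.na(idx)) 0L else as.integer(idx)
  }
  ref1 <- ref2 <- ref3 <- integer(natom)
  toridx <- integer(natom)
  k <- 0L
  for (i in seq_len(n)) {
    pl <- rows[[i]]
    for (r in seq_len(nrow(pl))) {
      k <- k + 1L
      ref1[k] <- resolve(i, pl$r1[r])
      ref2[k] <- resolve(i, pl$r2[r])
      ref3[k] <- resolve(i, pl$r3[r])
      if (pl$dkind[r] == "tor") {
        dt <- pl$dtor[r]
        ri <- i - 1L
        if (dt == "psi_prev") { dt <- "psi"; ri <- ri - 1L }
        if (dt == "omega_prev") { dt <- "omega"; ri <- ri - 1L }
        # residue 1 has no phi; its C is a seed atom (in-plane placement)
        m <- match(paste(ri, dt), tkey)
        toridx[k] <- if (is.na(m)) 0L else m
      }
    }
  }

  # bonds: template bonds per residue + peptide bonds
  bnd <- list()
  for (i in seq_len(n)) {
    bt <- topology$residues[[seq3[i]]]$bonds
    ii <- index[[i]]
    keep <- bt[, 1] %in% names(ii) & bt[, 2] %in% names(ii)
    bt <- bt[keep, , drop = FALSE]
    bnd[[length(bnd) + 1]] <- cbind(ii[bt[, 1]], ii[bt[, 2]])
    if ("OXT" %in% names(ii))
      bnd[[length(bnd) + 1]] <- cbind(ii["C"], ii["OXT"])
    if (i > 1)
      bnd[[length(bnd) + 1]] <- cbind(index[[i - 1]]["C"], ii["N"])
  }
  bonds <- do.call(rbind, bnd)
  dimnames(bonds) <- NULL

  list(sequence = seq3,
       atoms = data.frame(name = atoms$name, element = atoms$element,
                          resname = atoms$resname, resi = atoms$resi,
                          resno = atoms$resi + 1L, chain = "A",
                          stringsAsFactors = FALSE),
       ref1 = ref1, ref2 = ref2, ref3 = ref3,
       bond = atoms$bond, angle = atoms$angle * pi / 180,
       dbase = atoms$dvalue * pi / 180, toridx = toridx,
       torsions = tors, bonds = bonds, index = index)
}

# Default torsion values (degrees) for a compiled placement: extended
# backbone, trans omega, common side-chain rotamer.
default_theta <- function(cp) {
  th <- numeric(nrow(cp$torsions))
  th[cp$torsions$name == "phi"] <- -120
  th[cp$torsions$name == "psi"] <- 130
  th[cp$torsions$name == "omega"] <- 180
  th[cp$torsions$name == "chi1"] <- -60
  th[grepl("^chi[234]$", cp$torsions$name)] <- 180
  th
}

# Rebuild coordinates from a compiled placement and torsion vector (deg).
rebuild_coords <- function(cp, theta) {
  cpp_rebuild(cp$ref1, cp$ref2, cp$ref3, cp$bond, cp$angle, cp$dbase,
              cp$toridx, theta * pi / 180)
}

# --- bond graphs on models -------------------------------------------------

# Bond index pairs (2-col matrix) for a model's atoms, from template
# connectivity + peptide bonds + disulfides. Atoms with names unknown to
# the topology are left unbonded.
model_bonds <- function(model, topology = default_topology()) {
  at <- model$atoms
  bnd <- list()
  key <- split(seq_len(nrow(at)), list(at$chain, at$resi), drop = TRUE)
  for (idx in key) {
    res <- at$resname[idx[1]]
    tpl <- topology$residues[[res]]
    if (is.null(tpl)) next
    ii <- setNames(idx, at$name[idx])
    bt <- tpl$bonds
    keep <- bt[, 1] %in% names(ii) & bt[, 2] %in% names(ii)
    bt <- bt[keep, , drop = FALSE]
    if (nrow(bt)) bnd[[length(bnd) + 1]] <- cbind(ii[bt[, 1]], ii[bt[, 2]])
    if ("OXT" %in% names(ii))
      bnd[[length(bnd) + 1]] <- cbind(ii["C"], ii["OXT"])
  }
  # peptide bonds: consecutive residues within a chain
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch & !at$het
    resis <- sort(unique(at$resi[sel]))
    for (i in seq_along(resis)[-1]) {
      if (resis[i] - resis[i - 1] != 1) next
      ci <- which(sel & at$resi == resis[i - 1] & at$name == "C")
      ni <- which(sel & at$resi == resis[i] & at$name == "N")
      if (length(ci) == 1 && length(ni) == 1)
        bnd[[length(bnd) + 1]] <- cbind(ci, ni)
    }
  }
  if (!is.null(model$disulfides) && nrow2(model$disulfides) > 0) {
    ss <- model$disulfides
    for (r in seq_len(nrow(ss))) {
      a <- which(at$resno == ss[r, 1] & at$name == "SG")
      b <- which(at$resno == ss[r, 2] & at$name == "SG")
      if (length(a) == 1 && length(b) == 1)
        bnd[[length(bnd) + 1]] <- cbind(a, b)
    }
  }
  out <- if (length(bnd)) do.call(rbind, bnd) else matrix(0L, 0, 2)
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

nrow2 <- function(x) if (is.null(x) || is.null(nrow(x))) 0L else nrow(x)

# Unordered atom pairs with bond-graph distance > 3, as a list
# (i, j, rmin) where rmin is the summed contact radius. Two standard
# attenuations apply to the contact limit: pairs that can hydrogen-bond
# (polar H or donor N/O against an acceptor N/O/S) are reduced by
# hb_allowance so H-bonded geometry is not penalised as a steric
# overlap, and 1-4 pairs (graph distance exactly 4) are scaled by
# scale14, the usual force-field treatment of torsion-adjacent contacts.
# Used by the soft-core stereochemical term and the clash score.
nonbonded_pairs <- function(n, bonds, elements, radii, max_sep = 3L,
                            hb_allowance = 0.8, scale14 = 0.8) {
  adj <- Matrix::sparseMatrix(i = c(bonds[, 1], bonds[, 2]),
                              j = c(bonds[, 2], bonds[, 1]),
                              x = 1, dims = c(n, n))
  reach <- adj
  acc <- adj
  for (k in seq_len(max_sep - 1L)) {
    reach <- reach %*% adj
    acc <- acc + reach
  }
  excl <- as.matrix(acc > 0)
  pair14 <- as.matrix((reach %*% adj) > 0) & !excl
  keep <- upper.tri(matrix(0, n, n)) & !excl
  idx <- which(keep, arr.ind = TRUE)
  r <- radii[elements]
  r[is.na(r)] <- 1.7
  rmin <- r[idx[, 1]] + r[idx[, 2]]
  rmin[pair14[idx]] <- rmin[pair14[idx]] * scale14
  # polar H: hydrogen bonded to N or O
  polar_h <- rep(FALSE, n)
  if (nrow(bonds)) {
    hsel <- elements[bonds[, 1]] == "H" & elements[bonds[, 2]] %in% c("N", "O")
    polar_h[bonds[hsel, 1]] <- TRUE
    hsel <- elements[bonds[, 2]] == "H" & elements[bonds[, 1]] %in% c("N", "O")
    polar_h[bonds[hsel, 2]] <- TRUE
  }
  donorish <- polar_h | elements %in% c("N", "O")
  acceptor <- elements %in% c("N", "O", "S")
  hb <- (donorish[idx[, 1]] & acceptor[idx[, 2]]) |
    (donorish[idx[, 2]] & acceptor[idx[, 1]])
  rmin[hb] <- rmin[hb] - hb_allowance
  list(i = idx[, 1], j = idx[, 2], rmin = rmin)
}
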