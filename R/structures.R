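#' Construct a structure model
#'
#' A model is a table of atoms plus an optional list of disulfide pairs.
#' Coordinates are in Angstrom; \code{resi} is the 0-based residue index
#' within the chain while \code{resno} keeps the author (PDB) residue
#' number used by restraint files.
#'
#' @param atoms data frame with columns \code{serial, name, element,
#'   resname, chain, resno, resi, x, y, z, het}.
#' @param disulfides integer matrix (2 columns of \code{resno}) or NULL.
#' @return object of class \code{nmr_model}.
#' @export
structure_model <- function(atoms, disulfides = NULL) {
  need <- c("serial", "name", "element", "resname", "chain", "resno",
            "resi", "x", "y", "z", "het")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates")
  if (any(!nzchar(atoms$name))) stop("empty atom name")
  structure(list(atoms = atoms, disulfides = disulfides),
            class = "nmr_model")
}

#' @export
print.nmr_model <- function(x, ...) {
  cat(sprintf("<nmr_model> %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), n_residues(x),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of (non-hetero) residues in a model
#' @param model an \code{nmr_model}.
#' @return integer count.
#' @export
n_residues <- function(model) {
  at <- model$atoms[!model$atoms$het, ]
  nrow(unique(at[, c("chain", "resi")]))
}

coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

# Residue sequence (3-letter codes) of the polymer part, in resi order.
model_sequence <- function(model) {
  at <- model$atoms[!model$atoms$het, ]
  at <- at[order(at$resi), ]
  at$resname[!duplicated(at$resi)]
}

#' Construct an ensemble
#'
#' All members must share the same topology (atom count, names, residue
#' sequence), one member per NMR MODEL record.
#'
#' @param models list of \code{nmr_model}.
#' @param entry_id optional identifier string.
#' @return object of class \code{nmr_ensemble}.
#' @export
ensemble <- function(models, entry_id = "") {
  if (!length(models)) stop("empty ensemble")
  ref <- models[[1]]$atoms
  for (k in seq_along(models)[-1]) {
    at <- models[[k]]$atoms
    if (nrow(at) != nrow(ref) || any(at$name != ref$name) ||
        any(at$resname != ref$resname))
      stop("topology error: model ", k,
           " does not match model 1 (atom count/names/residues)")
  }
  structure(list(models = models, entry_id = entry_id),
            class = "nmr_ensemble")
}

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat(sprintf("<nmr_ensemble> '%s': %d models x %d atoms\n", x$entry_id,
              length(x$models), nrow(x$models[[1]]$atoms)))
  invisible(x)
}

# --- PDB I/O ---------------------------------------------------------------

#' Read a (multi-model) PDB file as an ensemble
#'
#' One model per MODEL record; a file without MODEL records yields a
#' single-model ensemble. HETATM records are retained and flagged
#' \code{het}. SSBOND records populate the disulfide list.
#'
#' @param path path to a PDB file.
#' @return an \code{nmr_ensemble}.
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  ss <- NULL
  ssl <- lines[startsWith(rec, "SSBOND")]
  if (length(ssl)) {
    ss <- cbind(as.integer(substring(ssl, 18, 21)),
                as.integer(substring(ssl, 32, 35)))
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_of <- cumsum(startsWith(rec, "MODEL "))
  if (max(model_of) == 0) model_of <- model_of + 1L
  models <- list()
  for (m in sort(unique(model_of[is_atom]))) {
    sel <- which(is_atom & model_of == m)
    al <- lines[sel]
    x <- suppressWarnings(as.numeric(substring(al, 31, 38)))
    y <- suppressWarnings(as.numeric(substring(al, 39, 46)))
    z <- suppressWarnings(as.numeric(substring(al, 47, 54)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad))
      stop("malformed ATOM record at line ", sel[bad[1]], " of ", path)
    name <- trimws(substring(al, 13, 16))
    elem <- trimws(substring(al, 77, 78))
    elem[!nzchar(elem)] <- substring(gsub("[^A-Za-z].*", "",
                                          gsub("^[0-9]*", "", name[!nzchar(elem)])), 1, 1)
    resno <- as.integer(substring(al, 23, 26))
    chain <- substring(al, 22, 22)
    atoms <- data.frame(
      serial = as.integer(substring(al, 7, 11)),
      name = name, element = toupper(elem),
      resname = trimws(substring(al, 18, 20)),
      chain = chain, resno = resno,
      resi = stats::ave(resno, chain, FUN = function(r) match(r, unique(r)) - 1L),
      x = x, y = y, z = z,
      het = substring(al, 1, 6) == "HETATM",
      stringsAsFactors = FALSE)
    models[[length(models) + 1]] <- structure_model(atoms, disulfides = ss)
  }
  ensemble(models, entry_id = sub("\\.pdb$", "", basename(path)))
}

#' Write a model or ensemble to PDB
#'
#' Emits ATOM/HETATM records (MODEL/ENDMDL for ensembles) and SSBOND
#' headers for recorded disulfides.
#'
#' @param x an \code{nmr_model} or \code{nmr_ensemble}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(x, path) {
  models <- if (inherits(x, "nmr_ensemble")) x$models else list(x)
  out <- character(0)
  ss <- models[[1]]$disulfides
  if (nrow2(ss) > 0) {
    for (r in seq_len(nrow(ss)))
      out <- c(out, sprintf(
        "SSBOND %3d CYS A %4d    CYS A %4d", r, ss[r, 1], ss[r, 2]))
  }
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    at <- models[[m]]$atoms
    nm <- ifelse(nchar(at$name) < 4 & nchar(at$element) == 1,
                 paste0(" ", at$name), at$name)
    out <- c(out, sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      ifelse(at$het, "HETATM", "ATOM"), at$serial, nm, at$resname,
      at$chain, at$resno, at$x, at$y, at$z, at$element))
    out <- c(out, "TER")
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

# --- preprocessing ---------------------------------------------------------

#' Entry filter on ensemble size and sequence length
#'
#' Keeps entries with strictly more than \code{min_models} members and
#' strictly more than \code{min_residues} residues (the strict reading of
#' "more than 10 models" / "over 20 residues"; set \code{strict = FALSE}
#' for the inclusive variant).
#'
#' @param ens an \code{nmr_ensemble}.
#' @param min_models,min_residues thresholds (defaults 10 and 20).
#' @param strict logical; strict inequality (default TRUE).
#' @return logical scalar.
#' @export
passes_entry_filter <- function(ens, min_models = 10, min_residues = 20,
                                strict = TRUE) {
  nm <- length(ens$models)
  nr <- n_residues(ens$models[[1]])
  if (strict) nm > min_models && nr > min_residues
  else nm >= min_models && nr >= min_residues
}

#' Detect disulfide bridges
#'
#' Greedy nearest-first pairing of CYS SG atoms within the cutoff; each
#' residue joins at most one pair.
#'
#' @param model an \code{nmr_model}.
#' @param cutoff SG-SG distance cutoff in Angstrom (default 2.5).
#' @return integer matrix with two columns of residue numbers (resno);
#'   zero rows when no bridge is found.
#' @export
detect_disulfides <- function(model, cutoff = 2.5) {
  at <- model$atoms
  sg <- which(at$resname == "CYS" & at$name == "SG")
  out <- matrix(integer(0), 0, 2)
  if (length(sg) < 2) return(out)
  xyz <- coords(model)[sg, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  repeat {
    k <- which.min(d)
    if (!length(k) || min(d) > cutoff) break
    ij <- arrayInd(k, dim(d))
    out <- rbind(out, sort(at$resno[sg[ij]]))
    d[ij[1], ] <- Inf; d[, ij[1]] <- Inf
    d[ij[2], ] <- Inf; d[, ij[2]] <- Inf
  }
  out[order(out[, 1]), , drop = FALSE]
}

#' Remove non-standard residues and atoms
#'
#' Drops residues outside the 20 standard amino acids (optionally keeping
#' hetero ligands) and atoms whose names are absent from the topology for
#' their residue; atom order is preserved. Idempotent.
#'
#' @param model an \code{nmr_model}.
#' @param keep_ligands keep hetero residues (default FALSE).
#' @param topology an \code{nmr_topology}.
#' @return the filtered \code{nmr_model}.
#' @export
strip_nonstandard <- function(model, keep_ligands = FALSE,
                              topology = default_topology()) {
  at <- model$atoms
  std <- at$resname %in% topology$standard_aa
  keep <- std | (keep_ligands & at$het)
  known <- rep(TRUE, nrow(at))
  for (res in unique(at$resname[std])) {
    names_ok <- c(topology$residues[[res]]$place$name, "OXT")
    sel <- std & at$resname == res
    known[sel] <- at$name[sel] %in% names_ok
  }
  keep <- keep & (known | !std)
  structure_model(at[keep, , drop = FALSE], model$disulfides)
}

#' Translate atom names between PDBv3 and CHARMM dialects
#'
#' Bijective renaming over the packaged dialect table (e.g. amide
#' \code{H} <-> \code{HN}, ILE \code{CD1} <-> \code{CD}, terminal
#' \code{OXT} <-> \code{OT2}). Names not covered by the table that are
#' unknown to the topology trigger a warning and pass through unchanged.
#'
#' @param model an \code{nmr_model}.
#' @param dialect target dialect, \code{"pdb3"} or \code{"charmm"}.
#' @param topology an \code{nmr_topology}.
#' @return the renamed \code{nmr_model}.
#' @export
map_atom_names <- function(model, dialect = c("charmm", "pdb3"),
                           topology = default_topology()) {
  dialect <- match.arg(dialect)
  tab <- topology$dialect
  from <- if (dialect == "charmm") tab$pdb3 else tab$charmm
  to <- if (dialect == "charmm") tab$charmm else tab$pdb3
  at <- model$atoms
  new <- at$name
  for (k in seq_len(nrow(tab))) {
    sel <- at$name == from[k] &
      (tab$resname[k] == "*" | at$resname == tab$resname[k])
    # residue-specific rows take precedence over "*" rows
    if (tab$resname[k] == "*")
      sel <- sel & !(paste(at$resname, at$name) %in%
                       paste(tab$resname, from)[tab$resname != "*"])
    new[sel] <- to[k]
  }
  # warn on names unknown in the source dialect
  std <- at$resname %in% topology$standard_aa
  src_known <- rep(TRUE, nrow(at))
  for (res in unique(at$resname[std])) {
    pdb3_names <- c(topology$residues[[res]]$place$name, "OXT")
    rows <- tab$resname %in% c("*", res)
    known <- if (dialect == "charmm") pdb3_names
             else unique(c(setdiff(pdb3_names, tab$pdb3[rows]), tab$charmm[rows]))
    sel <- std & at$resname == res
    src_known[sel] <- at$name[sel] %in% known
  }
  if (any(!src_known))
    warning("unmappable atom name(s) passed through: ",
            paste(unique(at$name[!src_known]), collapse = ", "))
  at$name <- new
  structure_model(at, model$disulfides)
}

# --- torsion <-> Cartesian -------------------------------------------------

#' Measure the rotatable torsions of a model
#'
#' Computes phi, psi, omega and chi1..chi4 for every residue following the
#' IUPAC sign convention, wrapped to \code{[-180, 180)}. The final
#' residue's psi is measured against its carbonyl O (psi = dihedral
#' N-CA-C-O - 180), which makes the mapping invertible by
#' \code{\link{rebuild_from_torsions}}. Torsions with missing atoms are
#' omitted.
#'
#' @param model an \code{nmr_model} (single chain of standard residues).
#' @param topology an \code{nmr_topology}.
#' @return a data frame (class \code{torsion_set}) with columns
#'   \code{resi}, \code{resno}, \code{name}, \code{angle}.
#' @export
torsions_of <- function(model, topology = default_topology()) {
  at <- model$atoms[!model$atoms$het, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  resis <- sort(unique(at$resi))
  n <- length(resis)
  aidx <- function(ri, name) {
    w <- which(at$resi == ri & at$name == name)
    if (length(w) == 1) w else NA_integer_
  }
  quads <- list()
  add <- function(ri, nm, a, b, c, d, shift = 0) {
    q <- c(a, b, c, d)
    if (!anyNA(q))
      quads[[length(quads) + 1]] <<- list(ri = ri, nm = nm, q = q,
                                          shift = shift)
  }
  for (i in seq_len(n)) {
    ri <- resis[i]
    res <- at$resname[match(ri, at$resi)]
    N <- aidx(ri, "N"); CA <- aidx(ri, "CA"); C <- aidx(ri, "C")
    if (i > 1) {
      Cp <- aidx(resis[i - 1], "C")
      add(ri, "phi", Cp, N, CA, C)
    }
    if (i < n) {
      Nn <- aidx(resis[i + 1], "N")
      add(ri, "psi", N, CA, C, Nn)
      CAn <- aidx(resis[i + 1], "CA")
      add(ri, "omega", CA, C, Nn, CAn)
    } else {
      O <- aidx(ri, "O")
      add(ri, "psi", N, CA, C, O, shift = -180)
    }
    for (cn in names(chi_defs(res, topology))) {
      qn <- chi_defs(res, topology)[[cn]]
      add(ri, cn, aidx(ri, qn[1]), aidx(ri, qn[2]), aidx(ri, qn[3]),
          aidx(ri, qn[4]))
    }
  }
  if (!length(quads)) {
    return(structure(data.frame(resi = integer(0), resno = integer(0),
                                name = character(0), angle = numeric(0)),
                     class = c("torsion_set", "data.frame")))
  }
  qm <- do.call(rbind, lapply(quads, function(x) x$q))
  ang <- cpp_dihedrals(xyz, qm[, 1], qm[, 2], qm[, 3], qm[, 4]) * 180 / pi
  ang <- wrap180(ang + vapply(quads, function(x) x$shift, 0))
  out <- data.frame(resi = vapply(quads, function(x) x$ri, 0L),
                    resno = at$resno[match(vapply(quads, function(x) x$ri, 0L),
                                           at$resi)],
                    name = vapply(quads, function(x) x$nm, ""),
                    angle = ang, stringsAsFactors = FALSE)
  structure(out, class = c("torsion_set", "data.frame"))
}

#' Rebuild Cartesian coordinates from torsions
#'
#' Chain extension with ideal bond lengths and angles (natural-extension
#' reference frames); the resulting model reproduces the input torsions to
#' high precision: \code{torsions_of(rebuild_from_torsions(T))} equals
#' \code{T} within 1e-6 degrees.
#'
#' @param torsions a \code{torsion_set} data frame (columns \code{resi},
#'   \code{name}, \code{angle}); missing torsions fall back to defaults
#'   (extended backbone, trans omega, chi1 -60 / higher chis 180).
#' @param sequence residue codes (one-letter string or 3-letter vector).
#' @param topology an \code{nmr_topology}.
#' @return an \code{nmr_model} with ideal internal geometry.
#' @export
rebuild_from_torsions <- function(torsions, sequence,
                                  topology = default_topology()) {
  cp <- compile_placement(sequence, topology)
  theta <- default_theta(cp)
  if (!is.null(torsions) && nrow(torsions)) {
    m <- match(paste(cp$torsions$resi, cp$torsions$name),
               paste(torsions$resi, torsions$name))
    theta[!is.na(m)] <- torsions$angle[m[!is.na(m)]]
  }
  model_from_theta(cp, theta)
}

model_from_theta <- function(cp, theta) {
  xyz <- rebuild_coords(cp, theta)
  at <- cp$atoms
  at$serial <- seq_len(nrow(at))
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$het <- FALSE
  structure_model(at[, c("serial", "name", "element", "resname", "chain",
                         "resno", "resi", "x", "y", "z", "het")])
}
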