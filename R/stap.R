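#' Build a statistical torsion-angle potential (STAP) table
#'
#' A STAP table is the negative log of a smoothed 2-D periodic histogram
#' of observed torsion pairs, shifted so the minimum over the grid is 0.
#' Pair types correspond to the torsion pairs refined by the protocol:
#' phi-psi, phi-chi1, psi-chi1 and chi1-chi2.
#'
#' @param models list of \code{nmr_model} supplying the observations.
#' @param pair_type one of \code{"phi_psi"}, \code{"phi_chi1"},
#'   \code{"psi_chi1"}, \code{"chi1_chi2"}.
#' @param bin_width histogram bin width in degrees (must divide 360;
#'   default 10).
#' @param pseudocount count added to every bin before smoothing
#'   (default 1).
#' @param smoothing_sigma periodic Gaussian smoothing width in degrees
#'   (default 10; 0 disables smoothing).
#' @param residue_class 3-letter residue code, or \code{"ALL"}.
#' @param topology an \code{nmr_topology}.
#' @return object of class \code{stap_table}.
#' @export
build_stap_table <- function(models, pair_type = c("phi_psi", "phi_chi1",
                                                   "psi_chi1", "chi1_chi2"),
                             bin_width = 10, pseudocount = 1,
                             smoothing_sigma = 10, residue_class = "ALL",
                             topology = default_topology()) {
  pair_type <- match.arg(pair_type)
  stopifnot(360 %% bin_width == 0)
  nb <- as.integer(360 / bin_width)
  parts <- strsplit(pair_type, "_")[[1]]
  counts <- matrix(0, nb, nb)
  if (inherits(models, "nmr_model")) models <- list(models)
  for (mdl in models) {
    tors <- torsions_of(mdl, topology)
    if (residue_class != "ALL") {
      at <- mdl$atoms
      rn <- at$resname[match(tors$resi, at$resi)]
      tors <- tors[rn == residue_class, , drop = FALSE]
    }
    t1 <- tors[tors$name == parts[1], c("resi", "angle")]
    t2 <- tors[tors$name == parts[2], c("resi", "angle")]
    mm <- merge(t1, t2, by = "resi")
    if (!nrow(mm)) next
    i <- angle_bin(mm$angle.x, bin_width, nb)
    j <- angle_bin(mm$angle.y, bin_width, nb)
    for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
  }
  stap_from_counts(counts, pair_type, residue_class, bin_width, pseudocount,
                   smoothing_sigma,
                   provenance = sprintf("%d model(s)", length(models)))
}

angle_bin <- function(theta, bin_width, nb) {
  i <- floor((wrap180(theta) + 180) / bin_width) + 1
  pmin(pmax(i, 1), nb)
}

stap_from_counts <- function(counts, pair_type, residue_class, bin_width,
                             pseudocount, smoothing_sigma, provenance = "") {
  nb <- nrow(counts)
  h <- counts + pseudocount
  if (smoothing_sigma > 0) {
    kern <- circular_gaussian(nb, bin_width, smoothing_sigma)
    h <- kern %*% h %*% t(kern)
  }
  tot <- sum(h)
  if (tot <= 0) {
    grid <- matrix(0, nb, nb)
  } else {
    p <- h / tot
    grid <- -log(p)
    grid <- grid - min(grid)
  }
  structure(list(pair_type = pair_type, residue_class = residue_class,
                 bin_width = bin_width, grid = grid,
                 pseudocount = pseudocount,
                 smoothing_sigma = smoothing_sigma,
                 provenance = provenance),
            class = "stap_table")
}

# circulant periodic Gaussian smoothing matrix (rows normalised)
circular_gaussian <- function(nb, bin_width, sigma) {
  off <- 0:(nb - 1)
  d <- pmin(off, nb - off) * bin_width
  w <- exp(-d^2 / (2 * sigma^2))
  w <- w / sum(w)
  k <- matrix(0, nb, nb)
  for (i in seq_len(nb)) k[i, ] <- w[((off - i + 1) %% nb) + 1]
  k
}

#' @export
print.stap_table <- function(x, ...) {
  cat(sprintf("<stap_table> %s/%s: %dx%d grid (%g deg bins), range [0, %.3f]\n",
              x$pair_type, x$residue_class, nrow(x$grid), ncol(x$grid),
              x$bin_width, max(x$grid)))
  invisible(x)
}

#' Evaluate a STAP table at a torsion pair
#'
#' Periodic bilinear interpolation of the table grid at the angle pair; a
#' query exactly at a bin centre returns that bin's value.
#'
#' @param angles numeric length-2 vector \code{(theta1, theta2)} in
#'   degrees, or an n x 2 matrix for a vectorised call.
#' @param table a \code{stap_table}.
#' @return interpolated energy value(s) (>= 0; min over the grid is 0).
#' @export
stap_energy <- function(angles, table) {
  if (is.null(dim(angles))) angles <- matrix(angles, ncol = 2)
  g <- table$grid
  nb <- nrow(g)
  bw <- table$bin_width
  u <- (wrap180(angles[, 1]) + 180) / bw - 0.5
  v <- (wrap180(angles[, 2]) + 180) / bw - 0.5
  i0 <- floor(u); f1 <- u - i0
  j0 <- floor(v); f2 <- v - j0
  i0 <- (i0 %% nb) + 1; i1 <- (i0 %% nb) + 1
  j0 <- (j0 %% nb) + 1; j1 <- (j0 %% nb) + 1
  idx <- function(i, j) g[cbind(i, j)]
  (1 - f1) * (1 - f2) * idx(i0, j0) + f1 * (1 - f2) * idx(i1, j0) +
    (1 - f1) * f2 * idx(i0, j1) + f1 * f2 * idx(i1, j1)
}

# Sum STAP energy over all residues of a torsion set, matching tables by
# pair type and residue class (specific class beats "ALL").
stap_model_energy <- function(tors, atoms, tables) {
  if (!length(tables)) return(0)
  total <- 0
  key <- split(tors$angle, paste(tors$resi, tors$name))
  getang <- function(resi, nm) {
    v <- key[[paste(resi, nm)]]
    if (is.null(v)) NA_real_ else v
  }
  resis <- unique(tors$resi)
  rn <- atoms$resname[match(resis, atoms$resi)]
  types <- vapply(tables, `[[`, "", "pair_type")
  classes <- vapply(tables, `[[`, "", "residue_class")
  for (pt in unique(types)) {
    parts <- strsplit(pt, "_")[[1]]
    for (ri in seq_along(resis)) {
      a1 <- getang(resis[ri], parts[1])
      a2 <- getang(resis[ri], parts[2])
      if (is.na(a1) || is.na(a2)) next
      cand <- which(types == pt & classes == rn[ri])
      if (!length(cand)) cand <- which(types == pt & classes == "ALL")
      if (!length(cand)) next
      total <- total + stap_energy(c(a1, a2), tables[[cand[1]]])
    }
  }
  total
}

#' Serialise a STAP table to a plain-text file
#'
#' Header lines (\code{# key: value}) carry pair type, residue class, bin
#' width, pseudocount, smoothing sigma and provenance, followed by the
#' grid, one row per line.
#'
#' @param table a \code{stap_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stap_table <- function(table, path) {
  hdr <- c(paste0("# pair_type: ", table$pair_type),
           paste0("# residue_class: ", table$residue_class),
           paste0("# bin_width: ", format(table$bin_width)),
           paste0("# pseudocount: ", format(table$pseudocount)),
           paste0("# smoothing_sigma: ", format(table$smoothing_sigma)),
           paste0("# provenance: ", table$provenance))
  rows <- apply(table$grid, 1, function(r)
    paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Load a STAP table written by \code{write_stap_table}
#' @param path input file path.
#' @return a \code{stap_table}.
#' @export
read_stap_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(m)) stop("missing header '", key, "' in ", path)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  grid <- do.call(rbind, lapply(grep("^#", lines, invert = TRUE,
                                     value = TRUE), function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  structure(list(pair_type = get("pair_type"),
                 residue_class = get("residue_class"),
                 bin_width = as.numeric(get("bin_width")),
                 grid = grid,
                 pseudocount = as.numeric(get("pseudocount")),
                 smoothing_sigma = as.numeric(get("smoothing_sigma")),
                 provenance = get("provenance")),
            class = "stap_table")
}

#' Default STAP tables from a packaged toy conformer library
#'
#' Builds the four pair-type tables from a deterministic library of
#' ideal-geometry helical and extended peptides with jittered torsions
#' and common side-chain rotamers. These toy tables stand in for tables
#' derived from large structure databases; users refining real data
#' should supply tables built from a curated structure set via
#' \code{\link{build_stap_table}}.
#'
#' @param n_conformers conformers per motif (default 25).
#' @param jitter_sigma torsion jitter in degrees (default 8).
#' @param seed RNG seed (default 42).
#' @param topology an \code{nmr_topology}.
#' @return named list of four \code{stap_table}s.
#' @export
default_stap_tables <- function(n_conformers = 25, jitter_sigma = 8,
                                seed = 42, topology = default_topology()) {
  seqs <- c("LKELQKFLEMLRKEVS", "KTVTLEWKVDYSITNR")
  motifs <- c("helix", "strand")
  models <- list()
  set.seed(seed)
  rotamers <- c(-60, 60, 180)
  for (s in seq_along(seqs)) {
    base <- motif_torsions(seqs[s], motifs[s], topology)
    for (k in seq_len(n_conformers)) {
      t2 <- base
      t2$angle <- wrap180(t2$angle + rnorm(nrow(t2), 0, jitter_sigma))
      chi <- grepl("^chi", t2$name)
      t2$angle[chi] <- wrap180(sample(rotamers, sum(chi), replace = TRUE) +
                                 rnorm(sum(chi), 0, jitter_sigma))
      t2$angle[t2$name == "omega"] <- 180
      models[[length(models) + 1]] <- rebuild_from_torsions(
        t2, seqs[s], topology)
    }
  }
  types <- c("phi_psi", "phi_chi1", "psi_chi1", "chi1_chi2")
  setNames(lapply(types, function(pt)
    build_stap_table(models, pt, topology = topology)), types)
}
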