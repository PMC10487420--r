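# Shared helpers: tiny hand-built models and PDB text, constructed in code.

# Minimal model from an atom table; fills defaults for omitted columns.
toy_model <- function(name, element, resname, resno, xyz, chain = "A",
                      het = FALSE) {
  n <- length(name)
  structure_model(data.frame(
    serial = seq_len(n), name = name, element = element,
    resname = resname, chain = rep_len(chain, n), resno = resno,
    resi = resno - 1L, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = rep_len(het, n), stringsAsFactors = FALSE))
}

# Two isolated CYS residues with SG atoms at a chosen separation.
two_cys_model <- function(sg_dist) {
  xyz <- rbind(c(0, 0, 0), c(1.8, 0, 0),
               c(20, 0, 0), c(20 - 1.8 + sg_dist + 1.8, 0, 0))
  # place SGs exactly sg_dist apart
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0),
               c(1.5 + sg_dist, 0, 0), c(3 + sg_dist, 0, 0))
  toy_model(name = c("CB", "SG", "SG", "CB"),
            element = c("C", "S", "S", "C"),
            resname = "CYS", resno = c(1L, 1L, 2L, 2L), xyz = xyz)
}

# A 3-model toy PDB file (identical topology) written to a temp path.
toy_pdb_text <- function(n_models = 3, drop_atom_in_model = NA) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0
    for (r in 1:2) {
      for (nm in c("N", "CA", "C", "O")) {
        if (!is.na(drop_atom_in_model) && m == drop_atom_in_model &&
            r == 1 && nm == "O") next
        serial <- serial + 1
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, nm, r,
          serial * 1.3 + m * 0.01, r * 2.0, 0.5 * serial,
          substr(nm, 1, 1)))
      }
    }
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

write_tmp <- function(lines, ext = ".pdb") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Simple NOE restraint on two single atoms.
simple_noe <- function(resid_a, name_a, resid_b, name_b, d, dminus = 0.5,
                       dplus = 0.5, line = NA_integer_) {
  noe_restraint(data.frame(resid = resid_a, name = name_a),
                data.frame(resid = resid_b, name = name_b),
                d = d, dminus = dminus, dplus = dplus, source_line = line)
}

# The packaged fixture plus derived objects, computed once per test run.
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fix <- packaged_fixture()
      cache <<- c(fix, list(tables = default_stap_tables()))
    }
    cache
  }
})

model_xyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

# random rigid-body transform of a model
rigid_transform <- function(model, seed = 1) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[2]), -sin(ang[2]), 0,
                 sin(ang[2]), cos(ang[2]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- rx %*% rz
  shift <- runif(3, -20, 20)
  xyz <- model_xyz(model) %*% rot
  m2 <- model
  m2$atoms$x <- xyz[, 1] + shift[1]
  m2$atoms$y <- xyz[, 2] + shift[2]
  m2$atoms$z <- xyz[, 3] + shift[3]
  m2
}
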