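#' Construct an NOE distance restraint
#'
#' An NOE restraint links two selection groups (OR-combined atom
#' selections) with a target distance \code{d} and asymmetric margins:
#' \code{lower = d - dminus}, \code{upper = d + dplus}.
#'
#' @param group_a,group_b data frames with columns \code{resid},
#'   \code{name} (atom-name pattern, optionally ending in a wildcard
#'   \code{#}, \code{*} or \code{\%}) and optional \code{segid}.
#' @param d,dminus,dplus target distance and margins in Angstrom.
#' @param source_line originating line number in the restraint file.
#' @return object of class \code{noe_restraint}.
#' @export
noe_restraint <- function(group_a, group_b, d, dminus, dplus,
                          source_line = NA_integer_) {
  if (dminus < 0 || dplus < 0) stop("negative dminus/dplus")
  group_a <- as_selection(group_a)
  group_b <- as_selection(group_b)
  if (!nrow(group_a) || !nrow(group_b)) stop("empty selection group")
  lower <- max(0, d - dminus)
  upper <- d + dplus
  if (lower > upper) stop("lower bound exceeds upper bound")
  structure(list(group_a = group_a, group_b = group_b, d = d,
                 dminus = dminus, dplus = dplus, lower = lower,
                 upper = upper, source_line = source_line),
            class = "noe_restraint")
}

as_selection <- function(g) {
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  if (is.null(g$segid)) g$segid <- NA_character_
  stopifnot(all(nzchar(g$name)))
  # wildcard only terminal
  if (any(grepl("[#*%]", substr(g$name, 1, nchar(g$name) - 1))))
    stop("wildcard allowed only in terminal position")
  g[, c("resid", "name", "segid")]
}

#' Construct a dihedral restraint record
#'
#' Flat-bottom harmonic restraint on the dihedral of four named atoms:
#' zero penalty within \code{delta} degrees of \code{theta0}, harmonic
#' with force constant \code{k} (energy per squared degree) beyond.
#'
#' @param atoms data frame of exactly 4 selections (\code{resid},
#'   \code{name}; no wildcards).
#' @param theta0 target angle in degrees (wrapped to \code{[-180, 180)}).
#' @param delta flat-bottom half width in degrees, in \code{[0, 180]}.
#' @param k force constant, energy deg^-2.
#' @param source_line originating line number.
#' @return object of class \code{dihedral_restraint}.
#' @export
dihedral_restraint <- function(atoms, theta0, delta, k = 1,
                               source_line = NA_integer_) {
  atoms <- as_selection(atoms)
  if (nrow(atoms) != 4) stop("dihedral restraint needs exactly 4 atoms")
  if (any(grepl("[#*%]$", atoms$name)))
    stop("wildcard not allowed in dihedral selection")
  if (delta < 0 || delta > 180) stop("delta outside [0, 180]")
  structure(list(atoms = atoms, theta0 = wrap180(theta0), delta = delta,
                 k = k, source_line = source_line),
            class = "dihedral_restraint")
}

#' Bundle NOE and dihedral restraints
#'
#' @param noes list of \code{noe_restraint}.
#' @param dihedrals list of \code{dihedral_restraint}.
#' @param provenance free-text source description.
#' @return object of class \code{restraint_set}.
#' @export
restraint_set <- function(noes = list(), dihedrals = list(),
                          provenance = "") {
  structure(list(noes = noes, dihedrals = dihedrals,
                 provenance = provenance), class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d NOE + %d dihedral restraints (%s)\n",
              length(x$noes), length(x$dihedrals), x$provenance))
  if (length(x$noes)) {
    tab <- table(factor(vapply(x$noes, classify_noe, ""),
                        levels = c("intraresidual", "sequential", "medium",
                                   "long")))
    cat("  NOE categories:", paste(names(tab), tab, sep = "=",
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

# --- XPLOR/CNS dialect -----------------------------------------------------

# Strip ! comments, keep line structure for error reporting. Returns a
# character vector of tokens and a parallel vector of line numbers.
xplor_tokens <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  lines <- sub("!.*$", "", lines)
  toks <- list()
  lns <- list()
  for (i in seq_along(lines)) {
    # make parentheses standalone tokens
    ll <- gsub("([()])", " \\1 ", lines[i])
    tk <- strsplit(trimws(ll), "[[:space:]]+")[[1]]
    tk <- tk[nzchar(tk)]
    if (length(tk)) {
      toks[[length(toks) + 1]] <- tk
      lns[[length(lns) + 1]] <- rep(i, length(tk))
    }
  }
  list(tok = unlist(toks) %||% character(0),
       line = unlist(lns) %||% integer(0))
}

# Extract one balanced-paren selection starting at position p (which must
# be "("). Returns list(sels = data.frame, next_pos).
parse_selection <- function(tk, p, line) {
  if (p > length(tk$tok) || tk$tok[p] != "(")
    stop("expected '(' at line ", tk$line[min(p, length(tk$tok))])
  depth <- 0
  q <- p
  repeat {
    if (q > length(tk$tok))
      stop("unbalanced parentheses from line ", tk$line[p])
    if (tk$tok[q] == "(") depth <- depth + 1
    if (tk$tok[q] == ")") depth <- depth - 1
    if (depth == 0) break
    q <- q + 1
  }
  inner <- tk$tok[(p + 1):(q - 1)]
  low <- tolower(inner)
  resids <- which(low == "resid")
  if (!length(resids))
    stop("selection without 'resid' at line ", tk$line[p])
  sels <- list()
  for (r in resids) {
    resid <- suppressWarnings(as.integer(inner[r + 1]))
    if (is.na(resid)) stop("bad resid at line ", tk$line[p + r])
    # find the matching 'name' after this resid (before the next resid)
    stopat <- if (any(resids > r)) min(resids[resids > r]) else length(inner) + 1
    nm <- which(low == "name" & seq_along(inner) > r &
                  seq_along(inner) < stopat)
    if (!length(nm)) stop("selection without 'name' at line ", tk$line[p])
    sg <- which(low == "segid" & seq_along(inner) < stopat)
    sels[[length(sels) + 1]] <- data.frame(
      resid = resid, name = inner[nm[1] + 1],
      segid = if (length(sg)) inner[sg[1] + 1] else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(sels = unique(do.call(rbind, sels)), next_pos = q + 1)
}

parse_number <- function(tk, p, what) {
  v <- suppressWarnings(as.numeric(tk$tok[p]))
  if (is.na(v))
    stop("expected ", what, " at line ", tk$line[min(p, length(tk$tok))])
  v
}

#' Parse an XPLOR/CNS NOE restraint table
#'
#' Accepts \code{assign (sel) (sel) d dminus dplus} statements with
#' optional \code{or (sel) (sel)} continuations (ambiguous restraints) and
#' \code{!} comments. Selections are \code{(resid N and name X)} with an
#' optional terminal wildcard in the atom name; \code{or} within a
#' selection contributes additional members to the same group.
#'
#' @param text character: the file content (or a vector of lines).
#' @return list of \code{noe_restraint}.
#' @export
parse_xplor_noe <- function(text) {
  tk <- xplor_tokens(text)
  p <- 1
  out <- list()
  n <- length(tk$tok)
  while (p <= n) {
    if (tolower(tk$tok[p]) != "assign")
      stop("unexpected token '", tk$tok[p], "' at line ", tk$line[p])
    ln <- tk$line[p]
    a <- parse_selection(tk, p + 1, tk$line)
    b <- parse_selection(tk, a$next_pos, tk$line)
    p <- b$next_pos
    d <- parse_number(tk, p, "distance")
    dminus <- parse_number(tk, p + 1, "dminus")
    dplus <- parse_number(tk, p + 2, "dplus")
    if (dminus < 0 || dplus < 0)
      stop("negative margin at line ", tk$line[p + 1])
    p <- p + 3
    ga <- a$sels
    gb <- b$sels
    while (p <= n && tolower(tk$tok[p]) == "or") {
      a2 <- parse_selection(tk, p + 1, tk$line)
      b2 <- parse_selection(tk, a2$next_pos, tk$line)
      ga <- unique(rbind(ga, a2$sels))
      gb <- unique(rbind(gb, b2$sels))
      p <- b2$next_pos
    }
    out[[length(out) + 1]] <- noe_restraint(ga, gb, d, dminus, dplus,
                                            source_line = ln)
  }
  out
}

#' Parse an XPLOR/CNS dihedral restraint table
#'
#' Accepts \code{assign (s1) (s2) (s3) (s4) k theta0 delta ed}
#' statements; angles are wrapped to \code{[-180, 180)}. Wildcards in
#' dihedral selections are an error.
#'
#' @param text character: the file content.
#' @return list of \code{dihedral_restraint}.
#' @export
parse_dihedral_table <- function(text) {
  tk <- xplor_tokens(text)
  p <- 1
  out <- list()
  n <- length(tk$tok)
  while (p <= n) {
    if (tolower(tk$tok[p]) != "assign")
      stop("unexpected token '", tk$tok[p], "' at line ", tk$line[p])
    ln <- tk$line[p]
    sels <- list()
    p <- p + 1
    for (k in 1:4) {
      s <- parse_selection(tk, p, tk$line)
      if (nrow(s$sels) != 1)
        stop("dihedral selection must name one atom (line ", ln, ")")
      sels[[k]] <- s$sels
      p <- s$next_pos
    }
    kf <- parse_number(tk, p, "force constant")
    th0 <- parse_number(tk, p + 1, "theta0")
    dl <- parse_number(tk, p + 2, "delta")
    parse_number(tk, p + 3, "exponent")
    p <- p + 4
    out[[length(out) + 1]] <- dihedral_restraint(do.call(rbind, sels),
                                                 theta0 = th0, delta = dl,
                                                 k = kf, source_line = ln)
  }
  out
}

sel_text <- function(g) {
  one <- function(i) {
    s <- sprintf("resid %d and name %s", g$resid[i], g$name[i])
    if (!is.na(g$segid[i])) s <- paste0("segid ", g$segid[i], " and ", s)
    s
  }
  paste(vapply(seq_len(nrow(g)), one, ""), collapse = " or ")
}

#' Write NOE restraints in the XPLOR/CNS dialect
#'
#' @param noes list of \code{noe_restraint}.
#' @return character vector of lines; \code{parse_xplor_noe} on the output
#'   reproduces selections and bounds exactly (3-decimal precision).
#' @export
write_xplor_noe <- function(noes) {
  c("! NOE distance restraints (XPLOR/CNS dialect)",
    vapply(noes, function(r) sprintf("assign (%s) (%s) %.3f %.3f %.3f",
                                     sel_text(r$group_a), sel_text(r$group_b),
                                     r$d, r$dminus, r$dplus), ""))
}

#' Write dihedral restraints in the XPLOR/CNS dialect
#' @param dihedrals list of \code{dihedral_restraint}.
#' @return character vector of lines.
#' @export
write_xplor_dihedral <- function(dihedrals) {
  c("! dihedral restraints (XPLOR/CNS dialect)",
    vapply(dihedrals, function(r) {
      sels <- vapply(1:4, function(i) sprintf("(resid %d and name %s)",
                                              r$atoms$resid[i],
                                              r$atoms$name[i]), "")
      sprintf("assign %s %.3f %.3f %.3f 2", paste(sels, collapse = " "),
              r$k, r$theta0, r$delta)
    }, ""))
}

# --- classification and deduplication --------------------------------------

#' Sequence-separation category of an NOE restraint
#'
#' Uses the minimum residue separation over all selection pairs (an
#' ambiguous restraint is as local as its closest interpretation; set
#' \code{rule = "max"} for the alternative): 0 = intraresidual,
#' 1 = sequential, 2-4 = medium, >= 5 = long.
#'
#' @param restraint an \code{noe_restraint}.
#' @param rule \code{"min"} (default) or \code{"max"} over selection pairs.
#' @return one of \code{"intraresidual"}, \code{"sequential"},
#'   \code{"medium"}, \code{"long"}.
#' @export
classify_noe <- function(restraint, rule = c("min", "max")) {
  rule <- match.arg(rule)
  seps <- abs(outer(restraint$group_a$resid, restraint$group_b$resid, "-"))
  s <- if (rule == "min") min(seps) else max(seps)
  if (s == 0) "intraresidual"
  else if (s == 1) "sequential"
  else if (s <= 4) "medium"
  else "long"
}

sel_key <- function(g) {
  paste(sort(paste(g$resid, toupper(g$name),
                   ifelse(is.na(g$segid), "", g$segid), sep = "|")),
        collapse = ";")
}

#' Remove duplicate NOE restraints
#'
#' Restraints with identical selection sets (order- and a/b
#' swap-insensitive) are merged. \code{conflict = "tightest"} keeps the
#' tightest bounds (max lower, min upper) and raises an error when the
#' merged interval is empty; \code{"first"} keeps the first occurrence;
#' \code{"error"} fails on any duplicate with differing bounds.
#'
#' @param noes list of \code{noe_restraint}.
#' @param conflict duplicate resolution policy.
#' @return deduplicated list, in order of first occurrence.
#' @export
deduplicate_noes <- function(noes, conflict = c("tightest", "first",
                                                "error")) {
  conflict <- match.arg(conflict)
  keys <- vapply(noes, function(r)
    paste(sort(c(sel_key(r$group_a), sel_key(r$group_b))), collapse = "//"),
    "")
  out <- list()
  seen <- character(0)
  for (k in seq_along(noes)) {
    r <- noes[[k]]
    m <- match(keys[k], seen)
    if (is.na(m)) {
      seen <- c(seen, keys[k])
      out[[length(out) + 1]] <- r
      next
    }
    prev <- out[[m]]
    same <- isTRUE(all.equal(c(prev$lower, prev$upper),
                             c(r$lower, r$upper)))
    if (conflict == "first" || same) next
    if (conflict == "error")
      stop("duplicate restraint with differing bounds (lines ",
           prev$source_line, " and ", r$source_line, ")")
    lower <- max(prev$lower, r$lower)
    upper <- min(prev$upper, r$upper)
    if (lower > upper)
      stop("conflicting duplicate restraints: merged bounds empty (lines ",
           prev$source_line, " and ", r$source_line, ")")
    out[[m]] <- noe_restraint(prev$group_a, prev$group_b,
                              d = (lower + upper) / 2,
                              dminus = (upper - lower) / 2,
                              dplus = (upper - lower) / 2,
                              source_line = prev$source_line)
  }
  out
}

# --- CHARMM NOE dialect ----------------------------------------------------

charmm_sel <- function(g) {
  paste(vapply(seq_len(nrow(g)), function(i)
    sprintf("ATOM %s %d %s", ifelse(is.na(g$segid[i]), "A", g$segid[i]),
            g$resid[i], g$name[i]), ""), collapse = " .OR. ")
}

#' Write a CHARMM-style NOE restraint block
#'
#' One ASSIGN per restraint, carrying the soft-asymptote parameters: KMIN
#' and KMAX are the harmonic force constants on the short and long side,
#' RMIN/RMAX are the restraint bounds (lower/upper) and FMAX the maximum
#' asymptotic slope.
#'
#' @param restraints a \code{restraint_set} (or list of
#'   \code{noe_restraint}).
#' @param params an \code{\link{noe_params}} object.
#' @return character vector of lines; \code{\link{parse_charmm_noe}}
#'   recovers bounds exactly at 3-decimal precision.
#' @export
write_charmm_noe <- function(restraints, params = noe_params()) {
  noes <- if (inherits(restraints, "restraint_set")) restraints$noes
          else restraints
  body <- vapply(noes, function(r) {
    paste0("ASSIGN SELE ", charmm_sel(r$group_a), " END SELE ",
           charmm_sel(r$group_b), " END -\n",
           sprintf("  KMIN %.3f RMIN %.3f KMAX %.3f RMAX %.3f FMAX %.3f",
                   params$k_noe, r$lower, params$k_noe, r$upper,
                   params$f_max))
  }, "")
  c("NOE", "RESET", body, "END")
}

#' Parse a CHARMM-style NOE block written by \code{write_charmm_noe}
#'
#' @param text character: block content.
#' @return list of \code{noe_restraint} (bounds encoded via RMIN/RMAX).
#' @export
parse_charmm_noe <- function(text) {
  txt <- paste(paste(text, collapse = "\n"))
  txt <- gsub("-\n", " ", txt)
  lines <- strsplit(txt, "\n")[[1]]
  lines <- trimws(lines)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!grepl("^ASSIGN", ln, ignore.case = TRUE)) next
    m <- regmatches(ln, gregexpr("SELE (.*?) END", ln))[[1]]
    if (length(m) != 2) stop("malformed ASSIGN at line ", i)
    parse_group <- function(s) {
      s <- sub("^SELE ", "", sub(" END$", "", s))
      parts <- strsplit(s, "\\.OR\\.")[[1]]
      do.call(rbind, lapply(parts, function(p) {
        f <- strsplit(trimws(p), "[[:space:]]+")[[1]]
        if (length(f) != 4 || toupper(f[1]) != "ATOM")
          stop("malformed CHARMM selection at line ", i)
        data.frame(resid = as.integer(f[3]), name = f[4], segid = f[2],
                   stringsAsFactors = FALSE)
      }))
    }
    num <- function(key) {
      mm <- regmatches(ln, regexpr(paste0(key, " +[-0-9.eE+]+"), ln))
      if (!length(mm)) stop("missing ", key, " at line ", i)
      as.numeric(strsplit(mm, " +")[[1]][2])
    }
    lower <- num("RMIN")
    upper <- num("RMAX")
    out[[length(out) + 1]] <- noe_restraint(
      parse_group(m[1]), parse_group(m[2]), d = (lower + upper) / 2,
      dminus = (upper - lower) / 2, dplus = (upper - lower) / 2,
      source_line = i)
  }
  out
}
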