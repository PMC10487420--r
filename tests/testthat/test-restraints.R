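test_that("XPLOR NOE parsing handles bounds, comments and ambiguity", {
  txt <- c("! toy NOE table",
           "assign (resid 3 and name HA) (resid 10 and name HN) 4.0 2.2 1.0",
           "assign (resid 5 and name HB#) (resid 5 and name HN) 3.0 1.2 0.3",
           "assign (resid 1 and name HA) (resid 8 and name HN) 5.0 2.0 0.5",
           "   or (resid 2 and name HA) (resid 8 and name HN)")
  noes <- parse_xplor_noe(txt)
  expect_length(noes, 3)
  expect_equal(noes[[1]]$lower, 1.8)
  expect_equal(noes[[1]]$upper, 5.0)
  expect_equal(noes[[1]]$source_line, 2)
  # wildcard stored verbatim; expansion deferred to the model
  expect_equal(noes[[2]]$group_a$name, "HB#")
  # or-continuation appends to both groups
  expect_equal(sort(noes[[3]]$group_a$resid), c(1, 2))
  expect_equal(noes[[3]]$group_b$resid, 8)
  # in-selection or
  amb <- parse_xplor_noe(
    "assign (resid 1 and name HA or resid 4 and name HA) (resid 9 and name HN) 4 2 1")
  expect_equal(nrow(amb[[1]]$group_a), 2)

  expect_length(parse_xplor_noe(""), 0)
  expect_error(parse_xplor_noe("assign (resid 1 and name HA) (resid 2 and name HN) 4 -1 1"),
               "negative")
  expect_error(parse_xplor_noe("assign (resid 1) (resid 2 and name HN) 4 1 1"),
               "name")
  expect_error(parse_xplor_noe("bogus (resid 1 and name H) (resid 2 and name H) 1 0 0"),
               "line 1")
})

test_that("wildcard selections expand against the model topology", {
  fix <- fixture_bundle()
  at <- fix$truth$atoms
  val <- unique(at$resno[at$resname == "VAL"])[1]
  r <- simple_noe(val, "HG#", val, "HA", 3)
  pairs <- nmrefine:::resolve_noe_pairs(at, r)
  got <- sort(unique(at$name[pairs[, 1]]))
  expect_true(all(startsWith(got, "HG")))
  expect_gte(length(got), 6)  # VAL HG11..HG23
  expect_error(effective_distance(fix$truth, simple_noe(val, "QQ#", val, "HA", 3)),
               "unresolvable")
})

test_that("dihedral table parsing wraps angles and rejects wildcards", {
  txt <- paste("assign (resid 4 and name C) (resid 5 and name N)",
               "(resid 5 and name CA) (resid 5 and name C) 1.0 -60.0 20.0 2")
  recs <- parse_dihedral_table(txt)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$theta0, -60)
  expect_equal(recs[[1]]$delta, 20)
  wrapped <- parse_dihedral_table(sub("-60.0", "300.0", txt))
  expect_equal(wrapped[[1]]$theta0, -60)
  expect_length(parse_dihedral_table(""), 0)
  expect_error(parse_dihedral_table(sub("name C\\)", "name C#)", txt)),
               "wildcard")
})

test_that("sequence-separation classification uses the minimum pair rule", {
  expect_equal(classify_noe(simple_noe(7, "HA", 7, "HN", 3)), "intraresidual")
  expect_equal(classify_noe(simple_noe(3, "HA", 4, "HN", 3)), "sequential")
  expect_equal(classify_noe(simple_noe(3, "HA", 7, "HN", 3)), "medium")
  expect_equal(classify_noe(simple_noe(3, "HA", 12, "HN", 3)), "long")
  amb <- noe_restraint(data.frame(resid = c(5, 12), name = "HA"),
                       data.frame(resid = 3, name = "HN"), 4, 2, 1)
  expect_equal(classify_noe(amb), "medium")       # min(|5-3|, |12-3|) = 2
  expect_equal(classify_noe(amb, rule = "max"), "long")
  # stable under group swap
  swp <- noe_restraint(amb$group_b, amb$group_a, 4, 2, 1)
  expect_equal(classify_noe(swp), classify_noe(amb))
})

test_that("deduplication merges to tightest bounds and surfaces conflicts", {
  a <- simple_noe(1, "HA", 9, "HN", 4.5, 0.5, 0.5, line = 1)  # [4.0, 5.0]
  b <- simple_noe(1, "HA", 9, "HN", 4.0, 0.5, 0.2, line = 2)  # [3.5, 4.2]
  swapped <- simple_noe(9, "HN", 1, "HA", 4.5, 0.5, 0.5, line = 3)
  other <- simple_noe(2, "HB1", 3, "HN", 3.0, 1.0, 1.0, line = 4)

  merged <- deduplicate_noes(list(a, b))
  expect_length(merged, 1)
  expect_equal(merged[[1]]$lower, 4.0)
  expect_equal(merged[[1]]$upper, 4.2)

  expect_length(deduplicate_noes(list(a, swapped)), 1)
  expect_length(deduplicate_noes(list(a, other)), 2)
  expect_equal(deduplicate_noes(list(a, b), conflict = "first")[[1]]$upper, 5.0)
  expect_error(deduplicate_noes(list(a, b), conflict = "error"),
               "lines 1 and 2")
  conflicting <- simple_noe(1, "HA", 9, "HN", 9.0, 0.5, 0.5, line = 5)
  expect_error(deduplicate_noes(list(a, conflicting)), "lines 1 and 5")
})

test_that("deduplication matches a brute-force merge oracle on random sets", {
  oracle <- function(noes) {
    # pairwise quadratic merge, tightest bounds
    key <- function(r) paste(sort(c(nmrefine:::sel_key(r$group_a),
                                    nmrefine:::sel_key(r$group_b))),
                             collapse = "//")
    ks <- vapply(noes, key, "")
    out <- list()
    for (k in unique(ks)) {
      grp <- noes[ks == k]
      lo <- max(vapply(grp, `[[`, 0, "lower"))
      up <- min(vapply(grp, `[[`, 0, "upper"))
      out[[length(out) + 1]] <- c(lo, up)
    }
    out
  }
  for (trial in 1:20) {
    set.seed(trial)
    n <- sample(5:50, 1)
    noes <- lapply(seq_len(n), function(i) {
      ra <- sample(1:6, 1); rb <- sample(1:6, 1)
      d <- runif(1, 3, 6)
      simple_noe(ra, "HA", rb, "HN", d, runif(1, 0, 0.3), runif(1, 0, 0.3),
                 line = i)
    })
    got <- tryCatch(deduplicate_noes(noes), error = function(e) NULL)
    if (is.null(got)) next  # conflicting random bounds; covered above
    want <- oracle(noes)
    expect_length(got, length(want))
    expect_lte(length(got), n)
    gb <- t(vapply(got, function(r) c(r$lower, r$upper), c(0, 0)))
    wb <- do.call(rbind, want)
    expect_equal(gb[order(gb[, 1], gb[, 2]), ], wb[order(wb[, 1], wb[, 2]), ],
                 tolerance = 1e-12, ignore_attr = TRUE)
    # idempotent
    expect_length(deduplicate_noes(got), length(got))
  }
})

test_that("XPLOR and CHARMM writers round-trip numeric fields", {
  set.seed(99)
  noes <- lapply(1:100, function(i) {
    d <- round(runif(1, 2, 6), 3)
    simple_noe(sample(1:20, 1), sample(c("HA", "HN", "HB#"), 1),
               sample(1:20, 1), "HN", d, round(runif(1, 0, 2), 3),
               round(runif(1, 0, 2), 3), line = i)
  })
  back <- parse_xplor_noe(write_xplor_noe(noes))
  expect_length(back, 100)
  for (i in seq_along(noes)) {
    expect_equal(back[[i]]$d, noes[[i]]$d, tolerance = 5e-4)
    expect_equal(back[[i]]$lower, noes[[i]]$lower, tolerance = 1e-3)
    expect_equal(back[[i]]$upper, noes[[i]]$upper, tolerance = 1e-3)
    expect_equal(back[[i]]$group_a$name, noes[[i]]$group_a$name)
  }
  cback <- parse_charmm_noe(write_charmm_noe(noes))
  expect_length(cback, 100)
  for (i in seq_along(noes)) {
    expect_equal(cback[[i]]$lower, noes[[i]]$lower, tolerance = 1e-3)
    expect_equal(cback[[i]]$upper, noes[[i]]$upper, tolerance = 1e-3)
  }
  # field mapping and empty set
  one <- parse_charmm_noe(write_charmm_noe(list(simple_noe(3, "HA", 10, "HN",
                                                           3.4, 1.6, 1.6))))
  expect_equal(one[[1]]$lower, 1.8)
  expect_equal(one[[1]]$upper, 5.0)
  empty <- write_charmm_noe(list())
  expect_equal(empty, c("NOE", "RESET", "END"))

  dihe <- lapply(1:20, function(i) dihedral_restraint(
    dihedral_quad <- data.frame(resid = c(i, i + 1, i + 1, i + 1),
                                name = c("C", "N", "CA", "C")),
    theta0 = round(runif(1, -180, 179), 3), delta = round(runif(1, 0, 60), 3),
    k = round(runif(1, 0.01, 2), 3)))
  dback <- parse_dihedral_table(write_xplor_dihedral(dihe))
  for (i in seq_along(dihe)) {
    expect_equal(dback[[i]]$theta0, dihe[[i]]$theta0, tolerance = 1e-3)
    expect_equal(dback[[i]]$delta, dihe[[i]]$delta, tolerance = 1e-3)
    expect_equal(dback[[i]]$k, dihe[[i]]$k, tolerance = 1e-3)
  }
})
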