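test_that("PDB fixtures round-trip coordinates at format precision", {
  td <- withr::local_tempdir()
  fx <- makeFixture(file.path(td, "h.pdb"), form = "alpha", nResidues = 10)
  st <- readStructure(fx$file)
  seg <- extractSegment(st, segmentDefinition("h", "A", 1, 10))
  expect_equal(seg@coords, fx$segment@coords, tolerance = 2e-3,
               ignore_attr = TRUE)
  expect_lt(max(abs(seg@coords - fx$segment@coords)), 5.1e-4)
})

test_that("segment extraction honors ranges, incompleteness and errors", {
  td <- withr::local_tempdir()
  fx <- makeFixture(file.path(td, "h.pdb"), nResidues = 20, startRes = 201)
  st <- readStructure(fx$file)
  seg <- extractSegment(st, segmentDefinition("TM5m", "A", 207, 215))
  expect_length(seg@resno, 9)          # inclusive on both ends
  expect_equal(seg@resno, 207:215)
  expect_error(extractSegment(st, segmentDefinition("x", "B", 207, 215)),
               "chain 'B' not found")
  expect_error(extractSegment(st, segmentDefinition("x", "A", 900, 950)),
               "no residues")
  expect_error(extractSegment(st, segmentDefinition("x", "*", 207, 215)),
               "wildcard")

  # drop a residue's O atom: that residue is excluded with a warning
  lines <- readLines(fx$file)
  drop <- grep("^ATOM", lines)
  oLine <- drop[grepl(" O  ", substring(lines[drop], 13, 17)) &
                  grepl(" 210 ", substring(lines[drop], 21, 28))][1]
  writeLines(lines[-oLine], file.path(td, "incomplete.pdb"))
  st2 <- readStructure(file.path(td, "incomplete.pdb"))
  expect_warning(
    seg2 <- extractSegment(st2, segmentDefinition("TM5m", "A", 207, 215)),
    "incomplete backbone")
  expect_length(seg2@resno, 8)
  expect_false(210 %in% seg2@resno)
})

test_that("ill-formed and empty structure files are rejected loudly", {
  td <- withr::local_tempdir()
  fx <- makeFixture(file.path(td, "h.pdb"), nResidues = 8)
  lines <- readLines(fx$file)
  atom1 <- grep("^ATOM", lines)[5]
  lines[atom1] <- substring(lines[atom1], 1, 40)   # truncated mid-record
  writeLines(lines, file.path(td, "trunc.pdb"))
  expect_error(readStructure(file.path(td, "trunc.pdb")),
               "truncated ATOM record at line")
  writeLines(c("HEADER junk", "END"), file.path(td, "empty.pdb"))
  expect_error(readStructure(file.path(td, "empty.pdb")), "empty structure")
  expect_error(readStructure(file.path(td, "missing.pdb")), "not found")
})

test_that("altloc resolution keeps the highest occupancy, ties to A", {
  td <- withr::local_tempdir()
  fx <- makeFixture(file.path(td, "h.pdb"), nResidues = 6)
  lines <- readLines(fx$file)
  atoms <- grep("^ATOM", lines)
  caLine <- lines[atoms[2]]             # CA of residue 1
  mkAlt <- function(line, alt, occ, x, eleno = NULL) {
    substring(line, 17, 17) <- alt
    substring(line, 31, 38) <- sprintf("%8.3f", x)
    substring(line, 55, 60) <- sprintf("%6.2f", occ)
    if (!is.null(eleno)) substring(line, 7, 11) <- sprintf("%5d", eleno)
    line
  }
  # B has the higher occupancy and a shifted x: B must win
  lines2 <- append(lines, mkAlt(caLine, "B", 0.70, 99.0, eleno = 900), after = atoms[2])
  lines2[atoms[2]] <- mkAlt(caLine, "A", 0.30, 11.0)
  writeLines(lines2, file.path(td, "alt.pdb"))
  st <- readStructure(file.path(td, "alt.pdb"))
  ca <- st@atoms[st@atoms$resno == 1 & st@atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 99.0)
  # equal occupancy: altloc A wins
  lines3 <- append(lines, mkAlt(caLine, "B", 0.50, 99.0, eleno = 900), after = atoms[2])
  lines3[atoms[2]] <- mkAlt(caLine, "A", 0.50, 11.0)
  writeLines(lines3, file.path(td, "alt2.pdb"))
  st2 <- readStructure(file.path(td, "alt2.pdb"))
  ca2 <- st2@atoms[st2@atoms$resno == 1 & st2@atoms$elety == "CA", ]
  expect_equal(ca2$x, 11.0)
})

test_that("mmCIF atom_site parsing matches the PDB route", {
  td <- withr::local_tempdir()
  fx <- makeFixture(file.path(td, "h.pdb"), nResidues = 8)
  stPdb <- readStructure(fx$file)
  a <- stPdb@atoms
  cif <- c("data_fixture", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "label_atom_id", "label_alt_id",
                    "label_comp_id", "auth_asym_id", "auth_seq_id",
                    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                    "occupancy", "B_iso_or_equiv", "pdbx_PDB_model_num")),
           sprintf("ATOM %d %s . ALA A %d ? %.3f %.3f %.3f 1.00 0.00 1",
                   a$eleno, a$elety, a$resno, a$x, a$y, a$z),
           "#")
  writeLines(cif, file.path(td, "h.cif"))
  stCif <- readStructure(file.path(td, "h.cif"))
  expect_equal(stCif@atoms[, c("elety", "chain", "resno", "x", "y", "z")],
               a[, c("elety", "chain", "resno", "x", "y", "z")],
               ignore_attr = TRUE)
  segP <- extractSegment(stPdb, segmentDefinition("h", "A", 1, 8))
  segC <- extractSegment(stCif, segmentDefinition("h", "A", 1, 8))
  expect_equal(segC@coords, segP@coords)
  # malformed row is rejected with its line number
  cifBad <- cif
  cifBad[20] <- "ATOM 3 C ."
  writeLines(cifBad, file.path(td, "bad.cif"))
  expect_error(readStructure(file.path(td, "bad.cif")), "line 20")
})

test_that("dihedrals match an independent four-point torsion oracle", {
  td <- withr::local_tempdir()
  fx <- makeFixture(file.path(td, "h.pdb"), form = "alpha", nResidues = 12)
  st <- readStructure(fx$file)
  dh <- computeDihedrals(st, "A")
  coords <- extractSegment(st, segmentDefinition("h", "A", 1, 12))@coords
  for (i in 2:11) {
    phiOracle <- oracleDihedral(coords[i - 1, "C", ], coords[i, "N", ],
                                coords[i, "CA", ], coords[i, "C", ])
    psiOracle <- oracleDihedral(coords[i, "N", ], coords[i, "CA", ],
                                coords[i, "C", ], coords[i + 1, "N", ])
    expect_equal(dh$phi[i], phiOracle, tolerance = 1e-9)
    expect_equal(dh$psi[i], psiOracle, tolerance = 1e-9)
  }
  # termini are undefined
  expect_true(is.na(dh$phi[1]))
  expect_true(is.na(dh$psi[12]))
  # ideal alpha backbone: interior dihedral sums near -105 degrees
  mid <- 3:10
  expect_lt(max(abs(dh$phi[mid] + dh$psi[mid] - (-103))), 3)
})

test_that("chain breaks and too-short chains yield undefined dihedrals", {
  td <- withr::local_tempdir()
  # two 6-residue helices 30 A apart in one chain: a break in the middle
  p1 <- idealHelixParameters("alpha")
  p2 <- idealHelixParameters("alpha", P = c(30, 0, 0))
  c1 <- generateHelixCoordinates(p1, residueIndices = 0:5)
  c2 <- generateHelixCoordinates(p2, residueIndices = 0:5)
  seg <- list(list(coords = c1, resno = 1:6, chain = "A"),
              list(coords = c2, resno = 7:12, chain = "A"))
  f <- file.path(td, "break.pdb")
  helixforge:::.writeBackbonePDB(f, seg)
  dh <- computeDihedrals(readStructure(f), "A")
  expect_true(is.na(dh$psi[6]))   # psi spanning the break
  expect_true(is.na(dh$phi[7]))   # phi spanning the break
  expect_false(is.na(dh$psi[3]))

  fx <- makeFixture(file.path(td, "short.pdb"), nResidues = 5)
  st <- readStructure(fx$file)
  two <- st@atoms[st@atoms$resno <= 2, ]
  st2 <- methods::new("HelixStructure", structureId = "two", atoms = two)
  dh2 <- computeDihedrals(st2, "A")
  expect_true(all(is.na(dh2$phi)) && all(is.na(dh2$psi)))
})

test_that("parameter tables are complete, ordered and round-trippable", {
  td <- withr::local_tempdir()
  set.seed(2)
  fits <- list()
  for (id in c("bb01", "aa02", "cc03")) {
    fx <- makeFixture(file.path(td, paste0(id, ".pdb")), nResidues = 10,
                      structureId = id)
    st <- readStructure(file.path(td, paste0(id, ".pdb")))
    fits[[id]] <- fitHelix(extractSegment(st, segmentDefinition("seg", "A", 1, 10)))
  }
  groups <- list(list(id = 1L, description = "", members = list(list(pdb = "cc03"))),
                 list(id = 2L, description = "", members = list(list(pdb = "aa02"))))
  tbl <- parameterTable(fits[c(2, 3, 1)], groups)   # shuffled input
  expect_equal(names(tbl)[1:7],
               c("structure_id", "chain", "segment", "group_id", "diameter",
                 "omega", "s"))
  # sorted by (group, structure, chain); ungrouped last
  expect_equal(tbl$structure_id, c("cc03", "aa02", "bb01"))
  expect_equal(tbl$group_id, c(1L, 2L, NA))
  out <- file.path(td, "params.tsv")
  writeParameterTable(fits, out, groups)
  back <- utils::read.delim(out)
  expect_equal(back$omega, tbl$omega, tolerance = 1e-6)
  expect_equal(back$rmsd, tbl$rmsd, tolerance = 1e-6)
  expect_equal(nrow(back), 3L)
  expect_error(parameterTable(list()), "no fits")
})

test_that("segment and group configs parse and validate", {
  td <- withr::local_tempdir()
  cfg <- file.path(td, "seg.yaml")
  writeLines(c("segments:",
               "  - {name: TM5m, chain: 'A', start: 207, end: 215}",
               "  - {name: all, chain: '*', start: 1, end: 99}"), cfg)
  sdefs <- readSegmentConfig(cfg)
  expect_length(sdefs, 2)
  expect_equal(sdefs[[1]]$start, 207L)
  expect_equal(sdefs[[2]]$chain, "*")
  bad <- file.path(td, "bad.yaml")
  writeLines(c("segments:", "  - {name: x, chain: A, start: 9, end: 5}"), bad)
  expect_error(readSegmentConfig(bad), "start <= end")

  gcfg <- file.path(td, "grp.json")
  writeLines('{"groups":[{"id":1,"members":[{"pdb":"1u19"}]},
               {"id":2,"members":[{"pdb":"3cap","chain":"A"}]}]}', gcfg)
  groups <- readGroupConfig(gcfg)
  expect_length(groups, 2)
  dup <- file.path(td, "dup.yaml")
  writeLines(c("groups:",
               "  - id: 1",
               "    members: [{pdb: 1U19}]",
               "  - id: 2",
               "    members: [{pdb: 1u19}]"), dup)
  expect_error(readGroupConfig(dup), "more than one group")

  # the shipped rhodopsin configs are valid
  segShip <- readSegmentConfig(system.file("extdata", "rhodopsin_segments.yaml",
                                           package = "helixforge"))
  expect_true(any(vapply(segShip, function(s) s$name == "TM5m" &&
                           s$start == 207 && s$end == 215, TRUE)))
  expect_true(any(vapply(segShip, function(s) s$name == "TM7m" &&
                           s$start == 294 && s$end == 301, TRUE)))
  grpShip <- readGroupConfig(system.file("extdata", "rhodopsin_groups.yaml",
                                         package = "helixforge"))
  expect_equal(vapply(grpShip, `[[`, 0L, "id"), 1:3)
})
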