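# Multi-model PDB I/O, segment maps and atom selection.

pdb_line <- function(serial, name, resname, resseq, x, y, z, element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resseq, x, y, z, element)
}

test_that("parsing reads atoms, models and elements", {
  ens <- parse_structure(pdb_line(1, "CA", "ALA", 1, 1, 2, 3))
  expect_equal(n_frames(ens), 1L)
  expect_equal(nrow(ens$atoms), 1L)
  expect_equal(as.numeric(ens$frames[[1]]), c(1, 2, 3))
  expect_equal(ens$atoms$atom_name, "CA")

  block <- c(pdb_line(1, "N", "ALA", 1, 0, 0, 0),
             pdb_line(2, "CA", "ALA", 1, 1, 0, 0),
             pdb_line(3, "C", "ALA", 1, 2, 0, 0))
  txt <- paste(c("MODEL     1", block, "ENDMDL",
                 "MODEL     2", block, "ENDMDL", "END"), collapse = "\n")
  ens2 <- parse_structure(txt)
  expect_equal(n_frames(ens2), 2L)
  expect_equal(nrow(ens2$atoms), 3L)
})

test_that("parse errors carry line numbers and consistency is enforced", {
  bad <- c(pdb_line(1, "CA", "ALA", 1, 0, 0, 0),
           "ATOM      2  CB  ALA A   1      xxx.000   0.000   0.000")
  err <- expect_error(parse_structure(paste(bad, collapse = "\n")),
                      class = "parse_error")
  expect_match(conditionMessage(err), "line 2")

  txt <- paste(c("MODEL     1", pdb_line(1, "CA", "ALA", 1, 0, 0, 0), "ENDMDL",
                 "MODEL     2", pdb_line(1, "CA", "GLY", 1, 0, 0, 0), "ENDMDL"),
               collapse = "\n")
  expect_error(parse_structure(txt), class = "ensemble_consistency_error")
  expect_error(parse_structure("HEADER only\nEND"), class = "parse_error")
})

test_that("first altloc is kept, the rest dropped with a warning", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  0.50  0.00           C",
    pdb_line(3, "CB", "ALA", 1, 1, 1, 1))
  expect_warning(ens <- parse_structure(paste(lines, collapse = "\n")),
                 class = "altloc_warning")
  expect_equal(nrow(ens$atoms), 2L)
  expect_equal(as.numeric(ens$frames[[1]][1, ]), c(0, 0, 0))
})

test_that("writing uses fixed columns, MODEL wrappers only for multi-frame", {
  atoms <- data.frame(atom_name = "CA", element = "C", chain = "A",
                      resseq = 1L, icode = "", resname = "ALA")
  one <- structure_ensemble(atoms, list(matrix(c(1.5, -2.25, 3), 1)))
  txt1 <- write_structure(one)
  expect_equal(length(grep("^ATOM", strsplit(txt1, "\n")[[1]])), 1L)
  expect_false(grepl("MODEL", txt1))
  expect_match(txt1, "END")

  two <- structure_ensemble(atoms, list(matrix(c(1, 2, 3), 1),
                                        matrix(c(4, 5, 6), 1)))
  txt2 <- write_structure(two)
  expect_match(txt2, "MODEL     1")
  expect_match(txt2, "MODEL     2")

  big <- structure_ensemble(atoms, list(matrix(c(10000, 0, 0), 1)))
  expect_error(write_structure(big), class = "format_overflow_error")
})

test_that("parse/write round trips reproduce coordinates to 3 decimals", {
  set.seed(7)
  atoms <- data.frame(atom_name = rep(c("N", "CA", "C", "O", "CB"), 10),
                      element = rep(c("N", "C", "C", "O", "C"), 10),
                      chain = "A", resseq = rep(1:10, each = 5), icode = "",
                      resname = "ALA")
  xyz <- matrix(round(runif(150, -50, 50), 3), 50, 3)
  ens <- structure_ensemble(atoms, list(xyz, xyz + 0.25))
  back <- parse_structure(write_structure(ens))
  expect_equal(back$frames[[1]], ens$frames[[1]], tolerance = 1e-12)
  expect_equal(back$frames[[2]], ens$frames[[2]], tolerance = 1e-12)
  expect_equal(back$atoms, ens$atoms)

  # write(parse(t)) reproduces a conforming file up to trailing whitespace
  txt <- write_structure(ens)
  expect_identical(write_structure(parse_structure(txt)), txt)
  # parse o write o parse is a fixed point
  again <- parse_structure(write_structure(back))
  expect_identical(again$frames, back$frames)
})

test_that("bio3d reads back what write_structure emits", {
  b <- small_bundle()
  f <- tempfile(fileext = ".pdb")
  writeLines(write_structure(b$frame), f)
  pdb <- bio3d::read.pdb(f)
  expect_equal(nrow(pdb$atom), nrow(b$frame$atoms))
  expect_equal(unname(cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)),
               unname(round(b$frame$xyz, 3)), tolerance = 1e-9)
})

test_that("atom selection follows domain ranges and atom classes", {
  spec <- data.frame(
    atom_name = c("N", "CA", "C", "O", "N", "CA", "C", "CB", "HB1"),
    element = c("N", "C", "C", "O", "N", "C", "C", "C", "H"),
    resseq = c(1, 1, 1, 1, 2, 2, 2, 2, 2),
    resname = c(rep("GLY", 4), rep("ALA", 5)),
    x = 1:9, y = 0, z = 0)
  fr <- tiny_frame(spec)
  sm <- segment_map(list(R1 = data.frame(chain = "A", start = 1, end = 1),
                         R2 = data.frame(chain = "A", start = 2, end = 2),
                         TM1 = data.frame(chain = "A", start = 1, end = 2),
                         TM2 = data.frame(chain = "A", start = 1, end = 1),
                         TM3 = data.frame(chain = "A", start = 1, end = 1),
                         TM4 = data.frame(chain = "A", start = 1, end = 1),
                         TM5 = data.frame(chain = "A", start = 1, end = 1),
                         TM6 = data.frame(chain = "A", start = 1, end = 1),
                         TM7 = data.frame(chain = "A", start = 1, end = 1),
                         T4L = data.frame(chain = "A", start = 2, end = 2)),
                    tm_names = paste0("TM", 1:7), fusion_name = "T4L")
  # glycine backbone: exactly N, CA, C
  bb <- select_atoms(fr, sm, "R1", "backbone")
  expect_equal(nrow(bb), 3L)
  # hydrogens excluded from heavy selections
  hv <- select_atoms(fr, sm, "R2", "heavy")
  expect_equal(nrow(hv), 4L)
  expect_error(select_atoms(fr, sm, "TM9"), class = "unknown_domain_error")
})

test_that("an 11-residue helix has 33 backbone atoms and disjoint segments do not double-select", {
  b <- make_bundle(n_helices = 7, residues_per_helix = 11,
                   fusion_residues = 8, seed = 3)
  bb <- select_atoms(b$frame, b$segmap, "TM1", "backbone")
  expect_equal(nrow(bb), 33L)
  all_idx <- unlist(lapply(names(b$segmap$segments), function(nm)
    select_atom_indices(b$frame$atoms, b$segmap, nm, "backbone")))
  expect_false(any(duplicated(all_idx)))
  # selection is deterministic and frame-ordered
  idx <- select_atom_indices(b$frame$atoms, b$segmap, "TM3", "heavy")
  expect_identical(idx, sort(idx))
  expect_identical(idx, select_atom_indices(b$frame$atoms, b$segmap, "TM3",
                                            "heavy"))
})

test_that("segment-map config files round trip", {
  b <- small_bundle()
  f <- tempfile(fileext = ".cfg")
  write_segment_map(b$segmap, f)
  sm <- read_segment_map(f)
  expect_equal(sm$tm_names, b$segmap$tm_names)
  expect_equal(sm$fusion_name, b$segmap$fusion_name)
  expect_equal(sm$segments, b$segmap$segments)

  cfg <- c("tm_order = TM1 TM2 TM3 TM4 TM5 TM6 TM7", "fusion = T4L",
           paste0("[TM", 1:7, "]"))
  expect_error(read_segment_map(text = c("fusion = T4L", "[TM1]",
                                         "chain = A", "start = 1", "end = 2")),
               class = "parse_error")
  expect_error(segment_map(list(TM1 = data.frame(chain = "A", start = 5,
                                                 end = 2)),
                           tm_names = "TM1", fusion_name = "TM1"),
               class = "invalid_segment_map_error")
})
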