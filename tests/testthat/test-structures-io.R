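test_that("rna_structure validates and orders its atom table", {
  atoms <- data.frame(chain = "A", resno = c(2, 1), resname = c("G", "C"),
                      elety = "C1'", x = c(1, 0), y = 0, z = 0)
  s <- rna_structure(atoms)
  expect_s3_class(s, "rna_structure")
  expect_equal(s$atoms$resno, c(1, 2))
  expect_equal(chain_sequences(s), c(A = "CG"))

  bad <- atoms; bad$x[1] <- NA
  expect_error(rna_structure(bad), "finite")
  bad <- atoms; bad$resname[1] <- "XYZ"
  expect_error(rna_structure(bad), "residue")
})

test_that("PDB write/read round trip preserves coordinates to format precision", {
  s <- fixture_duplex()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_rna_pdb(s, path)
  back <- read_rna_pdb(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$atoms$elety, s$atoms$elety)
  expect_lt(max(abs(as.matrix(back[[1]]$atoms[, c("x", "y", "z")]) -
                      as.matrix(s$atoms[, c("x", "y", "z")]))), 5e-4 + 1e-12)
})

test_that("multi-model files give one structure per model", {
  s <- fixture_duplex()
  nd <- fixture_nodes()
  ens <- rna_ensemble(rbind(.row <- as.numeric(t(nd$xyz)), .row + 0.5),
                      nd$labels, aligned = FALSE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_rna_pdb(ens, path)
  back <- suppressMessages(read_rna_pdb(path))
  expect_length(back, 2)
})

test_that("solvent records are dropped and all-solvent files error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  C1'   C A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C1'   G A   2       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  expect_message(st <- read_rna_pdb(path), "non-RNA")
  expect_equal(nrow(st[[1]]$atoms), 2)

  writeLines(lines[3:4], path)
  expect_error(suppressMessages(read_rna_pdb(path)), "[Nn]o RNA")
})

test_that("altloc conformers resolve to highest occupancy", {
  # build valid records with the package writer, then splice in altloc marks
  tiny <- rna_structure(data.frame(chain = "A", resno = c(1, 1, 2),
                                   resname = c("C", "C", "G"), elety = "C1'",
                                   x = c(0, 5, 3), y = 0, z = 0,
                                   o = c(0.4, 0.6, 1.0)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_rna_pdb(tiny, path)
  lines <- readLines(path)
  substr(lines[1], 17, 17) <- "A"
  substr(lines[2], 17, 17) <- "B"
  writeLines(lines, path)
  st <- suppressMessages(read_rna_pdb(path))[[1]]
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$x[st$atoms$resno == 1], 5.0)
})

test_that("unknown residue names error unless aliased", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1' 5MC A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C1'   G A   2       3.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_error(read_rna_pdb(path), "5MC")
  st <- read_rna_pdb(path, aliases = c("5MC" = "C"))[[1]]
  expect_equal(chain_sequences(st)[["A"]], "CG")
})
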