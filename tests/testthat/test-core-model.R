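# Domain types, organism parsing, and table I/O round-trips.

test_that("parse_organism extracts genus, species and family from OS fields", {
  res <- parse_organism(c(
    "Alcohol dehydrogenase OS=Komagataeibacter europaeus OX=33995",
    "Something OS=Acetobacter pasteurianus subsp. pasteurianus OX=481145 GN=adh",
    "hypothetical protein",
    "Protein OS=Gluconobacter oxydans",
    NA))
  expect_equal(res$genus,
               c("Komagataeibacter", "Acetobacter", NA, "Gluconobacter", NA))
  expect_equal(res$species,
               c("Komagataeibacter europaeus", "Acetobacter pasteurianus",
                 NA, "Gluconobacter oxydans", NA))
  expect_equal(res$family[1:2], rep("Acetobacteraceae", 2))
  expect_true(is.na(res$family[3]))
})

test_that("parse_organism is total and deterministic on arbitrary strings", {
  set.seed(11)
  junk <- replicate(50, paste(sample(c(LETTERS, letters, "=", " ", "OS="),
                                     20, replace = TRUE), collapse = ""))
  expect_no_error(r1 <- parse_organism(junk))
  expect_identical(r1, parse_organism(junk))
  expect_equal(nrow(r1), 50)
})

test_that("protein-group TSV parsing handles fixtures, blanks and duplicates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.tsv")
  writeLines(c(
    "Accession\tDescription\tScore\tPeptides\tConfidence\tAbundance: S1\tAbundance: S2",
    "P001\tA OS=Komagataeibacter europaeus\t5\t4\tHigh\t10\t20",
    "P002\tB OS=Acetobacter aceti\t3\t3\tHigh\t\t5",
    "P003\tC\t2\t3\tMedium\t0\t7"), path)
  tab <- read_protein_table(path)
  expect_equal(nrow(tab$records), 3)
  expect_equal(ncol(tab$abundance), 2)
  expect_true(is.na(tab$abundance["P002", "S1"]))
  # zero treated as not detected
  expect_true(is.na(tab$abundance["P003", "S1"]))
  expect_equal(tab$records$fdr_confidence, c("high", "high", "medium"))
  expect_equal(tab$records$genus[1], "Komagataeibacter")

  # all-blank abundances: missing everywhere, no error
  writeLines(c(
    "Accession\tDescription\tScore\tPeptides\tConfidence\tAbundance: S1",
    "P001\tA\t5\t4\tHigh\t",
    "P002\tB\t3\t3\tHigh\t"), path)
  blank <- read_protein_table(path)
  expect_true(all(is.na(blank$abundance)))

  # duplicate accession is an integrity error
  writeLines(c(
    "Accession\tDescription\tScore\tPeptides\tConfidence\tAbundance: S1",
    "P001\tA\t5\t4\tHigh\t1",
    "P001\tB\t3\t3\tHigh\t2"), path)
  expect_error(read_protein_table(path), class = "acetoprot_integrity_error")

  # missing mandatory column names the column
  writeLines(c("Accession\tDescription\tScore\tConfidence\tAbundance: S1",
               "P001\tA\t5\tHigh\t1"), path)
  expect_error(read_protein_table(path), "Peptides",
               class = "acetoprot_format_error")
})

test_that("write then read round-trips records and abundances", {
  design <- make_design(reps = 2)
  ab <- matrix(c(1.5, NA, 3, 4, NA, 6, 7.25, 8, 9, 10, NA, 12,
                 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24),
               nrow = 4, ncol = 6,
               dimnames = list(sprintf("P%03d", 1:4), design$sample_id))
  tab <- make_table(ab, design,
                    score = c(2.5, 7, 3.25, 9),
                    peptides = c(3L, 5L, 8L, 4L),
                    confidence = c("high", "high", "medium", "low"))
  tab$provenance <- c(tab$provenance, "unit-test fixture")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, path)
  back <- read_protein_table(path, design = design)
  expect_equal(back$records$accession, tab$records$accession)
  expect_equal(back$records$score, tab$records$score)
  expect_equal(back$records$num_peptides, tab$records$num_peptides)
  expect_equal(back$records$fdr_confidence, tab$records$fdr_confidence)
  expect_equal(back$abundance, tab$abundance)
})

test_that("design reading validates phases and counts samples", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "design.tsv")
  write_design(make_design(phases = c("FL", "DL", "UL"), reps = 3), path)
  d <- read_design(path)
  expect_equal(nrow(d), 9)
  expect_s3_class(d, "study_design")

  bad <- data.frame(sample_id = "s1", profile = "SY", phase = "XX",
                    replicate = 1)
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_design(path), "FL, DL, EL, UL",
               class = "acetoprot_validation_error")
  # config-extendable labels
  expect_no_error(read_design(path, extra_phases = "XX"))
})

test_that("GO annotation reading validates aspects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgo_id\taspect",
               "P001\tGO:0003824\tmolecular_function",
               "P001\tGO:0008152\tbiological_process"), path)
  ann <- read_go_annotations(path)
  expect_equal(nrow(ann), 2)
  writeLines(c("accession\tgo_id\taspect", "P001\tGO:1\tbogus"), path)
  expect_error(read_go_annotations(path), class = "acetoprot_validation_error")
})
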