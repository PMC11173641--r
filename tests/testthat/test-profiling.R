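# Taxon and GO-term frequency profiles, accession-list export.

test_that("taxon frequencies are proportions of proteins per taxon", {
  design <- make_design(phases = "FL", reps = 2)
  ab <- matrix(1, 4, 2, dimnames = list(NULL, design$sample_id))
  tab <- make_table(ab, design, description = c(
    rep("X OS=Komagataeibacter europaeus", 3),
    "Y OS=Acetobacter aceti"))
  prof <- taxon_frequency(tab, rank = "genus", scope = NULL)
  expect_equal(prof$taxon, c("Komagataeibacter", "Acetobacter"))
  expect_equal(prof$frequency, c(75, 25))
  expect_equal(sum(prof$count), 4)

  # all-same-genus degenerate case
  one <- make_table(ab, design,
                    description = rep("X OS=Asaia bogorensis", 4))
  pone <- taxon_frequency(one, rank = "genus", scope = NULL)
  expect_equal(pone$frequency, 100)
})

test_that("planted multinomial genus counts are recovered by an independent tally", {
  set.seed(21)
  design <- make_design(phases = c("FL", "DL"), reps = 2)
  genera <- sample(c("Komagataeibacter", "Acetobacter", "Gluconacetobacter",
                     "Gluconobacter"), 50, replace = TRUE,
                   prob = c(0.9, 0.05, 0.03, 0.02))
  ab <- matrix(1, 50, 4, dimnames = list(NULL, design$sample_id))
  tab <- make_table(ab, design,
                    description = sprintf("P OS=%s sp. X", genera))
  prof <- taxon_frequency(tab, rank = "genus", scope = NULL)
  # independent tally loop
  tally <- integer()
  for (g in genera) tally[g] <- (if (g %in% names(tally)) tally[g] else 0L) + 1L
  for (g in names(tally)) {
    expect_equal(prof$count[prof$taxon == g], unname(tally[g]))
    expect_equal(prof$frequency[prof$taxon == g], unname(100 * tally[g] / 50))
  }
})

test_that("profile invariants hold: sums, genus/species consistency, normalization invariance", {
  set.seed(5)
  design <- make_design(phases = c("FL", "DL", "UL"), reps = 3)
  tab <- random_table(40, design, p_missing = 0.3)
  sp <- paste(sample(c("Komagataeibacter europaeus", "Komagataeibacter xylinus",
                       "Acetobacter aceti", "Gluconobacter oxydans"),
                     40, replace = TRUE))
  tab$records$description <- sprintf("P OS=%s OX=1", sp)
  tab$records[c("genus", "species", "family")] <-
    parse_organism(tab$records$description)

  for (scope in list(NULL, c("profile", "phase"))) {
    pg <- taxon_frequency(tab, "genus", scope = scope)
    ps <- taxon_frequency(tab, "species", scope = scope)
    for (s in unique(pg$scope)) {
      expect_equal(sum(pg$frequency[pg$scope == s]), 100)
      expect_equal(sum(ps$frequency[ps$scope == s]), 100)
      # genus frequency equals the sum of its species frequencies
      for (g in pg$taxon[pg$scope == s]) {
        if (g == "unassigned") next
        expect_equal(pg$frequency[pg$scope == s & pg$taxon == g],
                     sum(ps$frequency[ps$scope == s &
                                        startsWith(ps$taxon, g)]))
      }
    }
  }
  # counts depend only on detection, not abundance scale
  norm <- normalize_global_intensity(tab)
  expect_equal(as.data.frame(taxon_frequency(norm, "genus")),
               as.data.frame(taxon_frequency(tab, "genus")))
})

test_that("GO frequencies count distinct proteins against the annotated total", {
  design <- make_design(phases = "FL", reps = 2)
  ab <- matrix(1, 3, 2, dimnames = list(NULL, design$sample_id))
  tab <- make_table(ab, design)
  ann <- data.frame(
    accession = c("P001", "P002", "P002"),
    go_id = c("T1", "T1", "T2"),
    aspect = "molecular_function", stringsAsFactors = FALSE)
  prof <- go_frequency(tab, ann, aspect = "molecular_function", scope = NULL)
  # 2 annotated proteins: T1 in both (100%), T2 in one (50%)
  expect_equal(prof$count[prof$term == "T1"], 2L)
  expect_equal(prof$frequency[prof$term == "T1"], 100)
  expect_equal(prof$frequency[prof$term == "T2"], 50)
  expect_equal(unique(prof$n_unannotated), 1L)

  # no annotations: empty profile, all proteins unannotated
  none <- go_frequency(tab, ann[0, ], aspect = "molecular_function", scope = NULL)
  expect_equal(nrow(none), 0)
  expect_error(go_frequency(tab, ann, aspect = "bogus"),
               class = "acetoprot_validation_error")
})

test_that("GO frequencies match a brute-force membership count", {
  set.seed(13)
  design <- make_design(phases = c("FL", "DL"), reps = 2)
  tab <- random_table(30, design, p_missing = 0)
  terms <- sprintf("GO:%04d", 1:6)
  ann <- do.call(rbind, lapply(tab$records$accession, function(a) {
    k <- sample(0:3, 1)
    if (!k) return(NULL)
    data.frame(accession = a, go_id = sample(terms, k),
               aspect = "biological_process", stringsAsFactors = FALSE)
  }))
  prof <- go_frequency(tab, ann, aspect = "biological_process", scope = NULL)
  annotated <- unique(ann$accession)
  for (t in unique(ann$go_id)) {
    n_t <- length(unique(ann$accession[ann$go_id == t]))
    expect_equal(prof$count[prof$term == t], n_t)
    expect_equal(prof$frequency[prof$term == t],
                 100 * n_t / length(annotated))
  }
})

test_that("accession lists export one per line and round-trip a selection", {
  path <- withr::local_tempfile()
  export_accession_list(c("P005", "P001", "P003"), path)
  expect_equal(readLines(path), c("P001", "P003", "P005"))
  export_accession_list(character(), path)
  expect_equal(readLines(path), character())

  design <- make_design(phases = "FL", reps = 2)
  tab <- make_table(matrix(1, 5, 2, dimnames = list(NULL, design$sample_id)),
                    design)
  export_accession_list(tab, path, subset = c("P002", "P004"))
  sel <- readLines(path)
  expect_setequal(tab$records$accession[tab$records$accession %in% sel],
                  c("P002", "P004"))
})
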