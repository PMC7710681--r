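test_that("the packaged matrix matches the published table cell-for-cell spot checks", {
  m <- laophontodes_matrix()
  expect_s3_class(m, "character_matrix")
  expect_equal(dim(m), c(39L, 12L))
  expect_equal(m$taxa, names(laophontodes_taxa()))
  # character 1 derived in every species
  expect_true(all(m$cells["1", ] == "1"))
  # the five special cells, exactly where the table prints them
  expect_equal(m$cells["2", "sarsi"], "?")
  expect_equal(m$cells["2", "spongiosus"], "1?")
  expect_equal(m$cells["2", "macclintocki"], "0?")
  expect_equal(m$cells["30", "georgei"], "?")
  expect_equal(m$cells["3", "whitsoni"], "0*")
  expect_equal(m$cells["26", "whitsoni"], "0*")
  # bold convergence annotations
  expect_setequal(paste(m$convergences$char_id, m$convergences$taxon),
                  c("4 macclintocki", "5 macclintocki", "17 spongiosus"))
})

test_that("polarity policies resolve the uncertainty codes as documented", {
  m <- laophontodes_matrix()
  argued <- apply_polarity_policy(m, "as-argued")
  expect_equal(argued$cells["3", "whitsoni"], 0L)      # 0* scored plesiomorphic
  expect_equal(argued$cells["2", "spongiosus"], 1L)    # 1? scored derived
  expect_equal(argued$cells["2", "macclintocki"], 0L)  # 0? scored plesiomorphic
  expect_true(is.na(argued$cells["2", "sarsi"]))
  cons <- apply_polarity_policy(m, "conservative")
  expect_true(is.na(cons$cells["2", "spongiosus"]))
  expect_true(is.na(cons$cells["3", "whitsoni"]))
  expect_error(apply_polarity_policy(m, "nonsense"))
  # identity on a matrix without uncertainty codes
  plain <- character_matrix(c("A", "B"),
                            data.frame(id = 1:2, description = c("x [y]", "z [w]")),
                            matrix(c("0", "1", "1", "0"), nrow = 2))
  expect_identical(apply_polarity_policy(plain, "as-argued")$cells,
                   apply_polarity_policy(plain, "conservative")$cells)
})

test_that("derived taxon sets reproduce the published group sizes", {
  r <- fixture_resolved()
  sizes <- c(`1` = 12, `3` = 9, `6` = 8, `7` = 8, `8` = 6, `9` = 4,
             `10` = 3, `12` = 2, `15` = 1)
  for (id in names(sizes)) {
    expect_length(derived_taxon_set(r, as.integer(id)), sizes[[id]])
  }
  expect_equal(derived_taxon_set(r, 15), "sarsi")
  # character 1 is the only all-derived row
  for (id in 2:39) {
    expect_lt(length(derived_taxon_set(r, id)), 12)
  }
  expect_error(derived_taxon_set(r, 99), "unknown character")
})

test_that("load/write round-trips preserve all six state codes in every dialect", {
  cells <- matrix(c("0", "1", "?", "1?",
                    "0?", "0*", "1", "0"), nrow = 2, byrow = TRUE)
  m <- character_matrix(
    taxa = c("alpha", "beta", "gamma", "delta"),
    characters = data.frame(id = c(1L, 2L),
                            description = c("spine lost [spine present]",
                                            "seta with STE [plain seta]")),
    cells = cells,
    convergences = data.frame(char_id = 1L, taxon = "beta"))
  for (d in c("csv", "tsv")) {
    f <- tempfile(fileext = paste0(".", d))
    write_matrix(m, f, d)
    back <- load_matrix(f)
    expect_identical(back$cells, m$cells)
    expect_identical(back$characters$description, m$characters$description)
    expect_identical(back$characters$plesiomorphic_description,
                     m$characters$plesiomorphic_description)
    expect_identical(back$convergences, m$convergences)
  }
  f <- tempfile(fileext = ".nex")
  write_nexus(m, f)
  back <- load_matrix(f)
  expect_identical(unname(back$cells), unname(m$cells))
  expect_identical(back$characters$description, m$characters$description)
  expect_identical(back$convergences, m$convergences)
  # a 1x1 matrix with 0*: the annotation block carries exactly one CODE entry
  one <- character_matrix("solo", data.frame(id = 1L, description = "v [w]"),
                          matrix("0*", 1, 1))
  f1 <- tempfile(fileext = ".nex")
  write_nexus(one, f1)
  expect_length(grep("^  CODE ", readLines(f1)), 1)
  expect_identical(unname(load_matrix(f1)$cells), unname(one$cells))
})

test_that("malformed inputs are rejected with located errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,description,A,B", "1,char one,0,2"), f)
  expect_error(load_matrix(f), "invalid state token '2'.*character 1.*'B'")
  writeLines(c("id,description,A,B", "1,char one,0", "2,char two,1,0"), f)
  expect_error(load_matrix(f), "dimension error.*line 2")
  writeLines(c("taxon,stuff,A,B", "1,x,0,1"), f)
  expect_error(load_matrix(f), "malformed header")
  expect_error(load_matrix(tempfile()), "not found")
  # degenerate writes
  expect_error(character_matrix(character(0),
                                data.frame(id = 1L, description = "d"),
                                matrix(character(0), 1, 0)),
               "at least one taxon")
  expect_error(character_matrix(c("A", "A"),
                                data.frame(id = 1L, description = "d"),
                                matrix(c("0", "1"), 1)),
               "duplicate taxon")
  m <- laophontodes_matrix()
  expect_error(write_nexus(m, file.path(tempdir(), "no/such/dir/x.nex")),
               "cannot write")
})

test_that("two-taxon one-character matrices and transposed layouts load", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,description,A,B", "1,tiny,0,1"), f)
  m <- load_matrix(f)
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(derived_taxon_set(apply_polarity_policy(m), 1), "B")
  ft <- tempfile(fileext = ".csv")
  writeLines(c("taxon,1,2", "A,0,1", "B,1,0"), ft)
  mt <- load_matrix(ft, taxa_as_rows = TRUE)
  expect_equal(dim(mt), c(2L, 2L))
  expect_equal(mt$cells["1", "B"], "1")
})
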