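test_that("compound flavor/property cells parse exactly, incl. positional 'plain'", {
  fp <- parseFlavorProperty(c("Sweet and pungent; warm",
                              "Sweet; plain",
                              "Sweet and plain; plain"))
  expect_equal(fp[[1]]$flavors, c("sweet", "pungent"))
  expect_equal(fp[[1]]$property, "warm")
  # 'plain' after the semicolon is a property, not a flavor
  expect_equal(fp[[2]]$flavors, "sweet")
  expect_equal(fp[[2]]$property, "plain")
  # 'plain' on both sides: flavor set keeps it, property too
  expect_equal(fp[[3]]$flavors, c("sweet", "plain"))
  expect_equal(fp[[3]]$property, "plain")

  expect_error(parseFlavorProperty("sweet"), "flavor\\(s\\); property")
  expect_error(parseFlavorProperty("umami; warm"), "row 1.*umami")
  expect_error(parseFlavorProperty("sweet; lukewarm"), "lukewarm")
})

test_that("registry loading validates schema, vocabulary and uniqueness", {
  reg <- loadRegistry(extdataPath("galactagogue_registry.csv"))
  expect_equal(nrow(reg), 19L)
  expect_true(all(reg$tcm_property %in% tcmVocabulary()$property))
  as <- reg[reg$material_id == "angelica_sinensis", ]
  expect_equal(as$tcm_flavors[[1]], c("sweet", "pungent"))
  expect_equal(as$tcm_property, "warm")
  expect_equal(as$rfc_precomputed, 0.93)

  # empty file with valid header -> empty registry
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("material_id,scientific_name,local_name,family,kingdom,",
                   "part_used,flavor_and_property,traditional_usage,",
                   "pharmacology_tags,rfc_precomputed", sep = ""), f)
  expect_equal(nrow(loadRegistry(f)), 0L)

  # missing column named in the error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("material_id,scientific_name", f2)
  expect_error(loadRegistry(f2), "schema error.*family")

  # duplicate id is an integrity error
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("material_id,scientific_name,local_name,family,kingdom,part_used,flavor_and_property,traditional_usage,pharmacology_tags,rfc_precomputed",
               "x,A,a,F,plant,radix,Sweet; warm,,,0.5",
               "x,B,b,F,plant,radix,Sweet; warm,,,0.5"), f3)
  expect_error(loadRegistry(f3), "integrity error.*duplicate.*x")
})

test_that("synonym standardization maps, dedups and reports the unmappable", {
  reg <- loadRegistry(extdataPath("galactagogue_registry.csv"))
  syn <- loadSynonyms(extdataPath("toy_synonyms.csv"))
  expect_equal(attr(syn, "match_policy"), "normalized")

  # three raw spellings of one material collapse to a single set member
  corpus <- loadPrescriptions(extdataPath("toy_prescriptions.csv"), syn, reg)
  p2 <- prescriptionSets(corpus)[["P2"]]
  expect_setequal(p2, c("angelica_sinensis", "tetrapanax_papyrifer"))
  expect_equal(sum(incidence(corpus)["P2", ]), 2)

  # normalized matching folds case and whitespace runs only
  expect_equal(standardizeNames(c("TANG KUEI", " tang  kuei"), syn, reg),
               rep("angelica_sinensis", 2))
  # canonical ids pass through untouched (idempotence)
  expect_equal(standardizeNames("poria_cocos", syn, reg), "poria_cocos")
  # unmappable names all listed, never dropped
  expect_error(standardizeNames(c("Tang kuei", "mystery herb", "other"), syn, reg),
               "standardization error.*mystery herb.*other")
})

test_that("dedup invariant: |materials| <= raw rows per prescription", {
  reg <- loadRegistry(extdataPath("galactagogue_registry.csv"))
  syn <- loadSynonyms(extdataPath("toy_synonyms.csv"))
  raw <- read.csv(extdataPath("toy_prescriptions.csv"))
  corpus <- loadPrescriptions(extdataPath("toy_prescriptions.csv"), syn, reg)
  rowsPer <- table(raw$prescription_id)
  sets <- prescriptionSets(corpus)
  for (pid in names(sets)) {
    expect_lte(length(sets[[pid]]), rowsPer[[pid]])
  }
})

test_that("write/load round-trip reproduces the corpus field-wise", {
  reg <- loadRegistry(extdataPath("galactagogue_registry.csv"))
  syn <- loadSynonyms(extdataPath("toy_synonyms.csv"))
  corpus <- loadPrescriptions(extdataPath("toy_prescriptions.csv"), syn, reg)

  dir <- withr::local_tempdir()
  writeCorpus(corpus, dir)
  back <- readCorpus(dir)

  expect_equal(incidence(back), incidence(corpus))
  expect_equal(prescriptionInfo(back), prescriptionInfo(corpus))
  r1 <- registry(corpus); r2 <- registry(back)
  for (col in names(r1)) expect_equal(r2[[col]], r1[[col]], label = col)
  # unicode local names survive ("Kuei yüan")
  expect_true("Kuei yüan" %in% r2$local_name)

  # byte-stable across repeated writes
  dir2 <- withr::local_tempdir()
  writeCorpus(corpus, dir2)
  for (f in c("registry.csv", "prescriptions.csv", "synonyms.csv")) {
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
})

test_that("corpus invariants are enforced", {
  reg <- testRegistry(c("a", "b"))
  expect_error(makeCorpus(reg, list(P1 = character(0))), "empty prescription")
  expect_error(makeCorpus(reg, list(P1 = "zz")), "not in registry")
  expect_error(makeCorpus(reg, setNames(list("a", "b"), c("P1", "P1"))),
               "unique")
  ok <- makeCorpus(reg, list(P1 = c("a", "a", "b")))
  expect_equal(sum(incidence(ok)), 2)  # duplicates collapsed
})
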