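test_that("shorthand labels parse to class, carbons, double bonds and OH flag", {
  cases <- list(
    list("PC aa C36:4", "PC_AA", 36L, 4L, FALSE),
    list("PC ae C40:0", "PC_AE", 40L, 0L, FALSE),
    list("lyso-PC C22:6", "LYSO_PC", 22L, 6L, FALSE),
    list("SM C16:1", "SM", 16L, 1L, FALSE),
    list("TAG 48:0", "TAG", 48L, 0L, FALSE),
    list("C0", "CARNITINE", 0L, 0L, FALSE),
    list("C2", "CARNITINE", 2L, 0L, FALSE),
    list("C03 OH", "CARNITINE", 3L, 0L, TRUE),
    list("C10:1", "CARNITINE", 10L, 1L, FALSE),
    list("Cholesterol total", "CHOLESTEROL_TOTAL", 0L, 0L, FALSE),
    list("Cholesterol free", "CHOLESTEROL_FREE", 0L, 0L, FALSE)
  )
  for (cs in cases) {
    sp <- parse_species(cs[[1]])
    expect_equal(sp$lipid_class, cs[[2]], info = cs[[1]])
    expect_equal(sp$carbons, cs[[3]], info = cs[[1]])
    expect_equal(sp$double_bonds, cs[[4]], info = cs[[1]])
    expect_equal(sp$hydroxylated, cs[[5]], info = cs[[1]])
  }
  # leading zeros are normalized away in the canonical label
  expect_equal(parse_species("C03 OH")$canonical_label, "C3 OH")
})

test_that("unparseable or impossible labels are rejected by name", {
  expect_error(parse_species("PE 38:4"), "PE 38:4")
  expect_error(parse_species("PC aa C0:1"), "double bonds")
  expect_error(parse_species(character(0)))
  expect_error(parse_species(""), "non-empty")
})

test_that("parse then format is the identity on every default panel label", {
  panel <- build_default_panel()
  sp <- parse_species(panel$species$canonical_label)
  expect_identical(
    format_species(sp$lipid_class, sp$carbons, sp$double_bonds, sp$hydroxylated),
    panel$species$canonical_label
  )
})

test_that("range expansion covers double-bond and carbon ranges", {
  db_range <- expand_range("C36:0-5", "PC_AE")
  expect_equal(nrow(db_range), 6)
  expect_equal(db_range$double_bonds, 0:5)
  expect_true(all(db_range$carbons == 36))

  c_range <- expand_range("C30-42:2", "PC_AA")
  expect_equal(c_range$carbons, seq(30, 42, by = 2))
  expect_true(all(c_range$double_bonds == 2))

  single <- expand_range("C44:0", "PC_AA")
  expect_equal(nrow(single), 1)
  expect_equal(single$canonical_label, "PC aa C44:0")

  expect_error(expand_range("C36:5-2", "PC_AE"), "empty range")
  expect_error(expand_range("36:0-5", "PC_AE"), "unparseable")
  # output size formulas
  expect_equal(nrow(expand_range("C38:0-6", "PC_AE")), 6 - 0 + 1)
  expect_equal(nrow(expand_range("C30-42:1", "PC_AE")), (42 - 30) / 2 + 1)
})

test_that("the PC ae chain-length legend expands to the 39-species roster", {
  ranges <- c("C30:0-2", "C32:1-2", "C34:0-3", "C36:0-5",
              "C38:0-6", "C40:0-6", "C42:0-5", "C44:3-6")
  roster <- expand_ranges(ranges, "PC_AE")
  expect_equal(nrow(roster), 39)
  expect_false(any(duplicated(roster$canonical_label)))
})

test_that("overlapping ranges are rejected", {
  expect_error(expand_ranges(c("C36:0-5", "C36:3-6"), "PC_AE"), "overlap")
})

test_that("the default panel has the declared class sizes and one standard per class", {
  panel <- build_default_panel()
  counts <- table(panel$species$lipid_class)
  expect_equal(counts[["PC_AA"]], 43)
  expect_equal(counts[["PC_AE"]], 39)
  expect_equal(counts[["LYSO_PC"]], 22)
  expect_equal(counts[["SM"]], 15)
  expect_equal(counts[["TAG"]], 17)
  expect_equal(counts[["CARNITINE"]], 41)
  expect_setequal(names(panel$standards), unique(panel$species$lipid_class))
  expect_false(any(duplicated(panel$species$canonical_label)))
  # species the workflow reports individually are on the roster
  expect_true(all(c("PC aa C36:4", "PC ae C40:0", "lyso-PC C22:6",
                    "SM C24:0", "TAG 48:0", "C10", "C3 OH") %in%
                    panel$species$canonical_label))
})

test_that("roster overrides must keep the declared class size", {
  expect_error(build_default_panel(rosters = list(SM = c("SM C16:0", "SM C18:0"))),
               "declared panel size")
  swapped <- build_default_panel(
    rosters = list(TAG = paste0("TAG ", 40:56, ":0"))
  )
  expect_equal(sum(swapped$species$lipid_class == "TAG"), 17)
})

test_that("panels round-trip through the TSV format", {
  panel <- build_default_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back$species$canonical_label, panel$species$canonical_label)
  expect_equal(back$standards[names(panel$standards)], panel$standards)
})

test_that("the packaged default panel file matches the constructed panel", {
  path <- system.file("extdata", "default_panel.tsv", package = "lipidelta")
  skip_if(path == "", "packaged panel not installed")
  expect_equal(read_panel(path)$species$canonical_label,
               build_default_panel()$species$canonical_label)
})
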