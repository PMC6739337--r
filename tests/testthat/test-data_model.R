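test_that("matrix TSV and matrix-market round-trips are identity on values and labels", {
  m <- random_matrix(10, 8, seed = 42)
  for (dialect in c("tsv", "matrix-market")) {
    path <- withr::local_tempfile(fileext = if (dialect == "tsv") ".tsv" else ".mtx")
    save_matrix(m, path, dialect)
    m2 <- load_matrix(path, dialect)
    expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
    expect_identical(dimnames(m2), dimnames(m))
  }
})

test_that("a hand-written TSV loads with shape and labels preserved in file order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tP1\tP2", "C1\t0.5\t1", "C2\t2\t3", "C3\t4\t5"), path)
  m <- load_matrix(path, "tsv")
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("c1", "c2", "c3"))
  expect_identical(colnames(m), c("p1", "p2"))
  expect_equal(unname(m["c1", ]), c(0.5, 1))
})

test_that("duplicate and missing entries are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tP1", "C1\t0.5", "C1\t1"), path)
  expect_error(load_matrix(path, "tsv"), "c1")
  bad <- matrix(c(1, NA, 3, 4), 2, 2,
                dimnames = list(c("a", "b"), c("p", "q")))
  expect_error(interaction_matrix(bad), "compound 'b', protein 'p'")
  # case-folded collision is also a duplicate
  mm <- matrix(1:4, 2, 2, dimnames = list(c("X", " x"), c("p", "q")))
  expect_error(interaction_matrix(mm), "duplicate compound")
})

test_that("metadata loads, cross-validates, and is order-independent", {
  m <- random_matrix(5, 3, seed = 1)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  ipath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tname\tsmiles\tis_psychoactive\tchem_class",
               "c01\tdrug a\tNA\tFALSE\tnone",
               "c02\tdrug b\tNA\tFALSE\tnone",
               "c03\tpsy c\tNA\tTRUE\ttryptamine",
               "c04\tdrug d\tNA\tFALSE\tnone",
               "c05\tpsy e\tNA\tTRUE\tother"), cpath)
  writeLines(c("mesh_id\tname\tis_mental_health\tapproved_compound_ids",
               "d001\tind one\tTRUE\tc01;c02",
               "d002\tind two\tFALSE\t"), ipath)
  meta <- load_metadata(cpath, ipath, m)
  expect_equal(nrow(meta$compounds), 5)
  expect_equal(nrow(meta$indications), 2)
  expect_identical(meta$compounds$is_psychoactive,
                   c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_false(meta$indications$usable[meta$indications$mesh_id == "d002"])
  expect_true(meta$indications$usable[meta$indications$mesh_id == "d001"])

  # permuting input rows yields identical record sets
  cl <- readLines(cpath)
  writeLines(c(cl[1], cl[c(4, 2, 6, 3, 5)]), cpath)
  meta2 <- load_metadata(cpath, ipath, m)
  expect_identical(meta2$compounds, meta$compounds)
  expect_identical(meta2$indications, meta$indications)
})

test_that("a psychoactive in an approved list and unknown approved ids are errors", {
  m <- random_matrix(3, 2, seed = 2)
  cmp <- compound_table(c("c01", "c02"), is_psychoactive = c(TRUE, FALSE))
  expect_error(
    indication_table("d1", approved = list(c("c01")), compounds = cmp,
                     matrix = m),
    "psychoactive compound 'c01'.*'d1'")
  expect_error(
    indication_table("d1", approved = list("nope"), compounds = cmp,
                     matrix = m),
    "absent from interaction matrix")
})

test_that("compound table enforces the class/psychoactive invariant", {
  expect_error(compound_table("a", is_psychoactive = FALSE,
                              chem_class = "tryptamine"),
               "requires is_psychoactive")
  expect_error(compound_table(c("a", "A "), is_psychoactive = FALSE),
               "duplicate")
  expect_error(compound_table("a", chem_class = "opioid"), "unknown chem_class")
})

test_that("analysis config validates thresholds and round-trips through YAML", {
  expect_error(analysis_config(topx_values = c(10, 25),
                               association_thresholds = c("40" = 4)),
               "must appear in topx_values")
  expect_error(analysis_config(association_thresholds = c("10" = 0, "25" = 3,
                                                          "40" = 4, "100" = 6)),
               ">= 1")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("topx_values: [10, 25]",
               "association_thresholds:", "  '10': 2", "  '25': 3",
               "n_randomizations: 50", "seed: 9"), path)
  cfg <- read_config(path)
  expect_equal(cfg$topx_values, c(10L, 25L))
  expect_equal(unname(cfg$association_thresholds[c("10", "25")]), c(2L, 3L))
  expect_equal(cfg$n_randomizations, 50L)
  expect_equal(cfg$seed, 9L)
})
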