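test_that("metadata validation enforces the domain constraints", {
  good <- stub_metadata("x")
  good$population <- "Etelä-Lappi"
  expect_silent(validate_metadata(good))

  bad <- good; bad$status <- "wild_forest"   # tarandus cannot be wild_forest
  expect_error(validate_metadata(bad), "contradiction")

  bad <- good; bad$wear_class <- 5L
  expect_error(validate_metadata(bad), "wear_class")

  bad <- good[, setdiff(names(good), "sex")]
  expect_error(validate_metadata(bad), "missing column")

  # archaeological rows may carry unknown tokens; modern rows may not
  arch <- good
  arch$provenance <- "archaeological"
  arch$subspecies <- "?"; arch$status <- "?"; arch$sex <- "?"
  out <- validate_metadata(arch)
  expect_equal(out$subspecies, "unknown")
  expect_equal(out$sex, "ND")
  modern_bad <- good; modern_bad$subspecies <- "?"
  expect_error(validate_metadata(modern_bad), "Unrecognised subspecies")
})

test_that("read_metadata round-trips through CSV", {
  md <- stub_metadata(c("a", "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(md, f)
  out <- read_metadata(f)
  expect_equal(out$specimen_id, c("a", "b"))
  expect_type(out$wear_class, "integer")
})

test_that("assemble_dataset joins, validates and reports mismatches", {
  shapes <- replicate(3, matrix(rnorm(8), 4, 2), simplify = FALSE)
  coords <- coords_from_list(shapes, ids = c("a", "b", "c"))
  md <- stub_metadata(c("a", "b", "c"))
  ds <- assemble_dataset(coords, md)
  expect_s3_class(ds, "mm_dataset")
  expect_equal(nrow(ds$metadata), 3L)
  expect_equal(nrow(ds$metadata), length(unique(ds$landmarks$specimen_id)))

  # config without metadata names the id
  expect_error(assemble_dataset(coords, md[1:2, ]), "c")
  # extra metadata rows are dropped with a message
  expect_message(assemble_dataset(coords, stub_metadata(c("a", "b", "c", "d"))),
                 "Dropping 1")
  # heterogeneous K
  coords_bad <- dplyr::bind_rows(
    coords, tibble::tibble(specimen_id = "d", point = 1:5,
                           x = rnorm(5), y = rnorm(5))
  )
  expect_error(assemble_dataset(coords_bad, stub_metadata(c("a", "b", "c", "d"))),
               "heterogeneous")
})

test_that("semilandmark allocation splits evenly, remainder to longest arcs", {
  expect_equal(semilandmark_allocation(9, 66), c(8, 8, 8, 7, 7, 7, 7, 7, 7))
  expect_equal(sum(semilandmark_allocation(9, 66)), 66)
  alloc <- semilandmark_allocation(4, 6, arc_lengths = c(1, 5, 2, 4))
  expect_equal(alloc, c(1, 2, 1, 2))
  lay <- landmark_layout(4, 4)
  expect_equal(nrow(lay), 8L)
  expect_equal(sum(lay$role == "semi"), 4L)
  # semis of one segment are contiguous between their bounding fixed points
  expect_equal(lay$role, rep(c("fixed", "semi"), 4))
})

test_that("filter_analysis_set applies the wear-class exclusion rules", {
  shapes <- replicate(10, matrix(rnorm(8), 4, 2), simplify = FALSE)
  ids <- sprintf("s%02d", 1:10)
  coords <- coords_from_list(shapes, ids)
  md <- stub_metadata(ids)
  md$wear_class <- rep(0:4, each = 2)
  ds <- assemble_dataset(coords, md)

  m1 <- suppressMessages(filter_analysis_set(ds, "m1"))
  expect_equal(nrow(m1$metadata), 6L)                 # classes 1,2,3 kept
  expect_setequal(unique(m1$metadata$wear_class), 1:3)

  md2 <- md; md2$tooth <- "m2"; md2$wear_class <- rep(1:3, length.out = 10)
  ds2 <- assemble_dataset(coords, md2)
  m2 <- suppressMessages(filter_analysis_set(ds2, "m2"))
  expect_setequal(unique(m2$metadata$wear_class), 1:2)  # class 3 dropped

  # idempotent, and retained configurations are untouched
  again <- filter_analysis_set(m1, "m1")
  expect_identical(again$landmarks, m1$landmarks)
  expect_identical(again$metadata, m1$metadata)

  md3 <- md; md3$wear_class <- 0L
  ds3 <- assemble_dataset(coords, md3)
  expect_error(suppressMessages(filter_analysis_set(ds3, "m1")),
               "No m1 specimens")
})
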