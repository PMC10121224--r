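test_that("intensity and layout tables join into a plate set", {
  dir <- withr::local_tempdir()
  ints <- file.path(dir, "plate.csv")
  lay <- file.path(dir, "layout.csv")
  writeLines(c("plate_id,row,col,gfp,dapi",
               "D1,0,0,38,480", "D1,1,0,42,520",
               "D1,0,1,110,900", "D1,1,1,130,1100"), ints)
  writeLines(c(
    "plate_id,row,col,cell_line,treatment,compound_id,concentration_molar,masked",
    "D1,0,0,RD16,DMSO,,,false", "D1,1,0,RD16,DMSO,,,false",
    "D1,0,1,WT,DMSO,,,false", "D1,1,1,WT,DMSO,,,false",
    "D1,2,1,RD16,COMPOUND,CPD1,1e-5,false"), lay)
  ps <- read_plate_table(ints, lay)
  expect_s3_class(ps, "plate_set")
  expect_equal(nrow(ps), 5L)
  expect_equal(sum(!ps$masked), 4L)
  # layout-only well becomes a masked placeholder
  ghost <- dplyr::filter(ps, row == 2, col == 1)
  expect_true(ghost$masked)
  expect_identical(ghost$compound_id, "CPD1")
})

test_that("A1-style coordinates normalize to 0-based integers", {
  dir <- withr::local_tempdir()
  ints <- file.path(dir, "plate.csv")
  lay <- file.path(dir, "layout.csv")
  writeLines(c("plate_id,row,col,gfp,dapi",
               "D1,A,1,38,480", "D1,AF,48,42,520", "D1,2,5,50,500"), ints)
  writeLines(c(
    "plate_id,row,col,cell_line,treatment,compound_id,concentration_molar,masked",
    "D1,A,1,RD16,DMSO,,,false", "D1,AF,48,RD16,DMSO,,,false",
    "D1,2,5,RD16,DMSO,,,false"), lay)
  ps <- read_plate_table(ints, lay)
  expect_setequal(paste(ps$row, ps$col), c("0 0", "31 47", "2 5"))
  expect_equal(well_label(c(0L, 31L), c(0L, 47L)), c("A1", "AF48"))
})

test_that("malformed rows raise parse errors naming file, line and field", {
  dir <- withr::local_tempdir()
  ints <- file.path(dir, "plate.csv")
  lay <- file.path(dir, "layout.csv")
  writeLines(c("plate_id,row,col,cell_line,treatment,compound_id,concentration_molar,masked",
               "D1,0,0,RD16,DMSO,,,false"), lay)
  # out-of-range column (col = 48 in 0-based dialect)
  writeLines(c("plate_id,row,col,gfp,dapi", "D1,0,48,10,10"), ints)
  expect_error(read_plate_table(ints, lay), "line 2.*row/col")
  # negative intensity
  writeLines(c("plate_id,row,col,gfp,dapi", "D1,0,0,-5,10"), ints)
  expect_error(read_plate_table(ints, lay), "gfp")
  # duplicate well
  writeLines(c("plate_id,row,col,gfp,dapi", "D1,0,0,5,10", "D1,0,0,6,10"), ints)
  expect_error(read_plate_table(ints, lay), "duplicate")
  # bad enum in layout
  writeLines(c("plate_id,row,col,gfp,dapi", "D1,0,0,5,10"), ints)
  writeLines(c("plate_id,row,col,cell_line,treatment,compound_id,concentration_molar,masked",
               "D1,0,0,HELA,DMSO,,,false"), lay)
  expect_error(read_plate_table(ints, lay), "cell_line")
  # intensity row without layout row
  writeLines(c("plate_id,row,col,gfp,dapi", "D1,0,0,5,10", "D1,5,5,7,10"), ints)
  writeLines(c("plate_id,row,col,cell_line,treatment,compound_id,concentration_molar,masked",
               "D1,0,0,RD16,DMSO,,,false"), lay)
  expect_error(read_plate_table(ints, lay), "no layout row")
})

test_that("well-record invariants are enforced", {
  base <- tibble::tibble(
    plate_id = "P", row = 0L, col = 0L, cell_line = "RD16",
    treatment = "DMSO", compound_id = NA_character_,
    concentration = NA_real_, gfp = 1, dapi = 1, masked = FALSE)
  expect_s3_class(plate_set(base), "plate_set")
  expect_error(plate_set(dplyr::mutate(base, treatment = "COMPOUND")),
               "compound wells")
  expect_error(plate_set(dplyr::mutate(base, compound_id = "X")), "DMSO wells")
  expect_error(plate_set(dplyr::mutate(base, gfp = -1)), "non-negative")
  expect_error(plate_set(dplyr::mutate(base, row = 32L)), "out of range")
  expect_error(plate_set(dplyr::bind_rows(base, base)), "duplicate")
})

test_that("plate-set serialization round-trips losslessly", {
  sim <- simulate_campaign(sim_config(n_compounds = 25, seed = 42))
  ps <- sim$plates
  # randomized mask flags must survive the trip too
  set.seed(9)
  ps$masked[sample(nrow(ps), 40)] <- TRUE
  dir <- withr::local_tempdir()
  f <- file.path(dir, "plates.csv")
  write_plate_table(ps, f)
  back <- read_plate_table(f, file.path(dir, "plates_layout.csv"))
  ord <- function(x) dplyr::arrange(tibble::as_tibble(x), plate_id, row, col)
  a <- ord(ps)
  b <- ord(back)
  expect_identical(b[names(a)], a)
})

test_that("empty plate set writes header-only files", {
  empty <- simulate_campaign(sim_config(n_compounds = 2, seed = 1))$plates[0, ]
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.csv")
  write_plate_table(empty, f)
  expect_equal(readLines(f), "plate_id,row,col,gfp,dapi")
  back <- read_plate_table(f, file.path(dir, "empty_layout.csv"))
  expect_equal(nrow(back), 0L)
})

test_that("dilution series follows the serial-dilution contract", {
  # seven-point and eleven-point 1:3 series from a 10 mM stock
  s7 <- dilution_series(1e-2, 3, 7)
  s11 <- dilution_series(1e-2, 3, 11)
  expect_length(s11, 11L)
  expect_equal(s11[1], 1e-2)
  expect_equal(s11[11], 1e-2 / 3^10)
  expect_equal(s11[11], 1.694e-7, tolerance = 1e-3)
  expect_equal(dilution_series(1e-2, 3, 1), 1e-2)
  expect_equal(dilution_series(1e-2, 2, 4), c(1e-2, 5e-3, 2.5e-3, 1.25e-3))
  # successive ratios equal the factor to near machine precision
  for (s in list(s7, s11)) {
    expect_true(all(diff(s) < 0))
    expect_equal(s[-length(s)] / s[-1], rep(3, length(s) - 1),
                 tolerance = 1e-12)
  }
  expect_error(dilution_series(1e-2, 1, 5), "factor")
  expect_error(dilution_series(1e-2, 3, 0), "n_points")
  expect_error(dilution_series(-1, 3, 5), "positive")
})
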