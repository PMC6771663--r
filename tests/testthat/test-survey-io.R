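test_that("reading survey files preserves counts and validates fields", {
  p <- write_tiny_files()
  sv <- read_survey(p$transects, p$nests, p$covariates)
  expect_s3_class(sv, "survey_data")
  expect_equal(nrow(sv$transects), 3)
  expect_equal(nrow(sv$observations), 5)
  expect_equal(nrow(sv$covariates), 3)
  expect_equal(sort(sv$transects$id), c("T1", "T2", "T3"))

  # transects-only reading is allowed
  sv2 <- read_survey(p$transects)
  expect_null(sv2$observations)
})

test_that("header matching is case-insensitive and order-free", {
  dir <- withr::local_tempdir()
  tr <- tiny_transects()[, c(3, 1, 2)]
  names(tr) <- c("Length_KM", "ID", "Habitat")
  tp <- file.path(dir, "tr.csv")
  write.csv(tr, tp, row.names = FALSE)
  sv <- read_survey(tp)
  expect_equal(sv$transects$length_km, c(1.5, 2.0, 1.0))
})

test_that("invalid rows are rejected with informative errors", {
  tr <- tiny_transects(); ob <- tiny_nests()

  bad <- ob; bad$perp_distance_m[2] <- -1
  expect_error(survey_data(tr, bad), "perp_distance_m")

  bad <- ob; bad$decay_class[1] <- "F"
  expect_error(survey_data(tr, bad), "decay class")

  bad <- ob; bad$transect_id[5] <- "T9"
  expect_error(survey_data(tr, bad), "T9")

  expect_error(survey_data(tr[, c("id", "habitat")]), "length_km")
  expect_error(survey_data(rbind(tr, tr[1, ])), "duplicate")
  bad <- tr; bad$habitat[1] <- "primary_forest"
  expect_error(survey_data(bad), "primary_forest")

  dir <- withr::local_tempdir()
  tp <- file.path(dir, "t.csv")
  write.csv(tiny_transects()[, c("id", "habitat")], tp, row.names = FALSE)
  expect_error(read_survey(tp), "length_km")
})

test_that("bundled Sabah survey carries 28 transects totalling 594 nests", {
  sv <- sabah_survey()
  expect_equal(nrow(sv$transects), 28)
  expect_equal(sum(sv$transects$n_nests), 594)
  expect_equal(sum(sv$transects$habitat == "logged_forest"), 12)
  expect_equal(sum(sv$transects$habitat == "salvage_logged"), 10)
  expect_equal(sum(sv$transects$habitat == "oil_palm_remnant"), 6)
})

test_that("design validation warns on thin strata without altering data", {
  sv <- sabah_survey()
  v <- validate_survey(sv)
  # the oil-palm stratum holds 52 nests, below the 60-nest guideline
  expect_true(any(v$check == "n_nests" & v$habitat == "oil_palm_remnant"))
  expect_match(v$message[v$habitat == "oil_palm_remnant" &
                           v$check == "n_nests"], "below the 60-nest")
  # every stratum exceeds 3 km of effort
  expect_false(any(v$check == "effort_km"))

  short <- tiny_transects()
  short$length_km <- c(1.0, 0.9, 1.0)   # 2.9 km in a single habitat
  short$habitat <- "logged_forest"
  short$id <- c("A", "B", "C")
  v2 <- validate_survey(survey_data(short))
  expect_true(any(v2$check == "effort_km"))

  # a comfortable design yields an empty report
  big <- data.frame(id = paste0("X", 1:6),
                    habitat = rep(c("logged_forest", "salvage_logged",
                                    "oil_palm_remnant"), 2),
                    length_km = 2, n_nests = 40)
  expect_equal(nrow(validate_survey(survey_data(big))), 0)

  # validation is report-only: estimates identical either way
  est <- estimate_density(sv)
  invisible(validate_survey(sv))
  expect_identical(est, estimate_density(sv))
})

test_that("write_results is deterministic and round-trips exactly", {
  dir <- withr::local_tempdir()
  est <- estimate_density(sabah_survey())
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  f1 <- write_results(list(density = as.data.frame(est)), out1,
                      summary = list(seed = 1))
  f2 <- write_results(list(density = as.data.frame(est)), out2,
                      summary = list(seed = 1))
  expect_equal(length(readLines(file.path(out1, "density.csv"))), 29) # header + 28
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # empty table -> header-only file
  write_results(list(empty = est[0, ]), out1)
  expect_equal(length(readLines(file.path(out1, "empty.csv"))), 1)

  # full-precision round trip of survey tables
  sv <- survey_data(tiny_transects(), tiny_nests())
  write_results(list(transects = sv$transects,
                     nests = sv$observations), out1)
  back <- read_survey(file.path(out1, "transects.csv"),
                      file.path(out1, "nests.csv"))
  expect_equal(back$transects, sv$transects)
  expect_equal(back$observations, sv$observations)
})
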