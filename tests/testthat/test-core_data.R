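test_that("read_panel parses a toy file and preserves the missing mask", {
  schema <- panel_schema(list(
    hs = list(orientation = "higher"),
    sprint_40m = list(orientation = "lower")))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,timepoint,hs,sprint_40m",
               "A,1,2.5,6.7", "B,1,,6.9", "C,1,1.5,7.1",
               "A,2,2.6,6.6", "B,2,1.0,6.8", "C,2,NA,7.0"), f)
  p <- read_panel(f, schema)
  expect_s3_class(p, "raw_panel")
  expect_equal(sum(is.na(p$data$hs)), 2L)   # empty field and NA token
  expect_equal(sum(is.na(p$data$sprint_40m)), 0L)
  expect_equal(nrow(p$data), 6L)
})

test_that("read_panel rejects documented malformed inputs", {
  schema <- panel_schema(list(hs = list(orientation = "higher")))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,timepoint,hs",
               "A,1,2.0", "A,1,2.1"), f)
  expect_error(read_panel(f, schema), "duplicate")
  writeLines(c("person_id,timepoint,hs,extra",
               "A,1,2.0,9"), f)
  expect_error(read_panel(f, schema), "undeclared")
  writeLines(c("person_id,timepoint,hs",
               "A,1,two"), f)
  expect_error(read_panel(f, schema), "non-numeric")
  writeLines(c("person_id,timepoint,hs",
               "A,1,2.0", "A,3,2.1"), f)
  expect_error(read_panel(f, schema), "consecutive")
})

test_that("outcome must be constant within person", {
  schema <- panel_schema(list(hs = list(orientation = "higher")))
  d <- data.frame(person_id = c("A", "A"), timepoint = 1:2,
                  hs = c(1, 2), outcome = c(1L, 2L))
  expect_error(raw_panel(d, schema), "constant")
})

test_that("write/read round-trip is the identity on values, mask, outcome", {
  sim <- generate_panel(generator_config(n_persons = 25, seed = 7,
                                         raw_mode = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim$panel, f)
  back <- read_panel(f, sim$panel$schema)
  expect_equal(back$data, sim$panel$data)

  sim2 <- generate_panel(generator_config(n_persons = 25, seed = 8))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim2$panel, f2)
  back2 <- read_panel(f2)
  expect_equal(as.data.frame(back2), as.data.frame(sim2$panel))
})

test_that("a fully missing variable round-trips as an empty column", {
  schema <- panel_schema(list(hs = list(orientation = "higher"),
                              ff = list(orientation = "lower")))
  d <- data.frame(person_id = c("A", "B"), timepoint = 1L,
                  hs = c(1.5, 2.25), ff = NA_real_)
  p <- raw_panel(d, schema)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  txt <- readLines(f)
  expect_true(all(grepl(",$|,\"\"$", txt[-1])))
  expect_equal(read_panel(f, schema)$data, p$data)
})

test_that("factor panel export has the four factor columns plus ids", {
  sim <- generate_panel(generator_config(n_persons = 20, seed = 3,
                                         missing_rate = 0, n_outliers = 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim$panel, f)
  expect_equal(names(read.csv(f)),
               c("person_id", "timepoint", "net_hope", "technical_skills",
                 "physical_fitness", "biological_maturity", "outcome"))
})

test_that("schema JSON round-trips", {
  f <- withr::local_tempfile(fileext = ".json")
  write_schema(default_schema(), f)
  expect_equal(read_schema(f), default_schema())
})
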