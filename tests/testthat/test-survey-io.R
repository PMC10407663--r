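test_that("survey files parse detects, ND tokens and censored flags", {
  path <- write_tiny_survey()
  recs <- read_survey(path)

  expect_equal(nrow(recs), 5)
  expect_equal(sum(recs$censored), 2)
  # high-residue detect row survives verbatim
  expect_equal(recs$concentration[1], 110)
  expect_false(recs$censored[1])
  # ND token and empty-concentration-with-flag both censor
  expect_true(recs$censored[2])
  expect_true(recs$censored[4])
  expect_true(all(is.na(recs$concentration[recs$censored])))
  expect_equal(recs$year, c(2014L, 2014L, 2015L, 2016L, 2017L))
})

test_that("censoring bijection: censored records equal ND/flagged rows in the file", {
  path <- write_tiny_survey()
  raw <- readLines(path)[-1]
  n_nd <- sum(grepl(",ND,", raw, fixed = TRUE) | grepl(",,TRUE,", raw, fixed = TRUE))
  expect_equal(sum(read_survey(path)$censored), n_nd)
})

test_that("malformed survey input is rejected, not coerced", {
  bad_num <- tempfile(fileext = ".csv")
  writeLines(c(
    "food,category,province,year,source,concentration,censored,lod,loq",
    "rice,cereal,JX,2015,market,not-a-number,FALSE,0.01,0.01"
  ), bad_num)
  expect_error(read_survey(bad_num), "Malformed numeric.*concentration.*row 1")

  no_col <- tempfile(fileext = ".csv")
  writeLines(c(
    "food,category,province,year,concentration,censored,lod,loq",
    "rice,cereal,JX,2015,0.02,FALSE,0.01,0.01"
  ), no_col)
  expect_error(read_survey(no_col), "missing mandatory column.*source")

  bad_cat <- tempfile(fileext = ".csv")
  writeLines(c(
    "food,category,province,year,source,concentration,censored,lod,loq",
    "rice,grain,JX,2015,market,0.02,FALSE,0.01,0.01"
  ), bad_cat)
  expect_error(read_survey(bad_cat), "Unknown category 'grain' at row 1")

  neg <- tempfile(fileext = ".csv")
  writeLines(c(
    "food,category,province,year,source,concentration,censored,lod,loq",
    "rice,cereal,JX,2015,market,-0.5,FALSE,0.01,0.01"
  ), neg)
  expect_error(read_survey(neg), "Negative concentration at row 1")

  expect_error(read_survey(tempfile()), "not found")
})

test_that("tab-delimited surveys are auto-detected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("food", "category", "province", "year", "source",
          "concentration", "censored", "lod", "loq", sep = "\t"),
    paste("tea", "tea", "ZJ", "2017", "market", "0.04", "FALSE", "0.001", "0.01", sep = "\t")
  ), path)
  recs <- read_survey(path)
  expect_equal(recs$concentration, 0.04)
})

test_that("write/read round-trips a generated survey exactly and bit-identically", {
  specs <- default_specs()
  survey <- generate_survey(specs[specs$food %in% c("Tea", "Wheat", "Plum"), ],
                            seed = 5)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_survey(survey, f1)
  back <- read_survey(f1)
  expect_equal(as.data.frame(back), as.data.frame(survey))
  write_survey(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("validate_survey enforces the censoring invariant", {
  recs <- make_records(c(0.5, NA))
  recs$censored <- c(TRUE, TRUE) # detect flagged censored
  expect_error(validate_survey(recs), "censoring invariant")
  recs2 <- make_records(c(0.5, NA), lod = 0.05, loq = 0.01)
  expect_error(validate_survey(recs2), "lod <= loq")
})

test_that("MRL tables read limits, absent limits, and reject duplicates", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "food,mrl,authority",
    "rice,2,national_standard",
    "water chestnut,,",
    "shitake,3,ministry_guideline"
  ), path)
  mrl <- read_mrl_table(path)
  expect_equal(mrl$mrl[mrl$food == "rice"], 2)
  expect_true(is.na(mrl$mrl[mrl$food == "water chestnut"]))
  expect_equal(mrl$authority[mrl$food == "shitake"], "ministry_guideline")

  hdr_only <- tempfile(fileext = ".csv")
  writeLines("food,mrl,authority", hdr_only)
  expect_equal(nrow(read_mrl_table(hdr_only)), 0)
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(read_mrl_table(empty)), 0)

  dup <- tempfile(fileext = ".csv")
  writeLines(c("food,mrl,authority", "rice,2,a", "rice,1,b"), dup)
  expect_error(read_mrl_table(dup), "Duplicate food 'rice'")
})

test_that("consumption profiles read all five populations with cv defaulting to 0.10", {
  path <- tempfile(fileext = ".csv")
  pops <- c("children_2_7", "adolescent_male", "adolescent_female",
            "adult_male", "adult_female")
  rows <- unlist(lapply(seq_along(pops), function(i) {
    sprintf("%s,%s,%s,%d", pops[i],
            c("vegetables", "fruits", "cereals", "potatoes"),
            c("0.19", "0.14", "0.22", "0.04"), 20 + 10 * i)
  }))
  writeLines(c("population,category,intake_mean_kg_day,body_weight_kg", rows), path)
  profs <- read_consumption(path)
  expect_named(profs, pops)
  expect_equal(profs$children_2_7$intake_mean[["vegetables"]], 0.19)
  expect_equal(profs$children_2_7$intake_mean[["cereals"]], 0.22)
  expect_equal(profs$adult_male$body_weight_mean, 60)
  expect_equal(profs$children_2_7$cv, 0.10)

  partial <- tempfile(fileext = ".csv")
  writeLines(c("population,category,intake_mean_kg_day,body_weight_kg",
               rows[1:8]), partial)
  expect_error(read_consumption(partial), "missing population.*adult_male")
})

test_that("usage tables parse and reject impossible values", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "province,year,pesticide_usage_t,production_t",
    "SD,2015,150000,39000000",
    "HEN,2015,120000,",
    "HN,2016,30000,9000000"
  ), path)
  u <- read_usage(path)
  expect_equal(nrow(u), 3)
  expect_true(is.na(u$production_t[2]))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("province,year,pesticide_usage_t,production_t",
               "SD,2015,10,0"), bad)
  expect_error(read_usage(bad), "positive")
})
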