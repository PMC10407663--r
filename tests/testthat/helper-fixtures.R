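# Build a record tibble from a concentration vector; NA means censored (ND).
make_records <- function(conc, lod = 0.01, loq = 0.01, food = "spinach",
                         category = "vegetable", province = "SD",
                         year = 2015L, source = "market") {
  tibble::tibble(
    food = food, category = category, province = province,
    year = year, source = source,
    concentration = conc, censored = is.na(conc),
    lod = lod, loq = loq
  )
}

# A 5-row survey file with 2 ND rows, in the documented dialect.
write_tiny_survey <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "food,category,province,year,source,concentration,censored,lod,loq",
    "spinach,vegetable,SD,2014,market,110,FALSE,0.001,0.01",
    "spinach,vegetable,HEN,2014,market,ND,TRUE,0.001,0.01",
    "rice,cereal,JX,2015,production,0.02,FALSE,0.01,0.01",
    "rice,cereal,JX,2016,production,,TRUE,0.01,0.01",
    "tea,tea,ZJ,2017,market,0.04,FALSE,0.001,0.01"
  ), path)
  path
}

# Conservative two-sided order-statistic confidence interval for a median.
median_order_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  m <- length(x)
  alpha <- (1 - conf) / 2
  lo <- max(1L, stats::qbinom(alpha, m, 0.5))
  hi <- m - lo + 1L
  c(x[lo], x[hi])
}

# One-category profile wrapper for closed-form checks.
flat_profile <- function(population = "children_2_7", intake = 0.2, bw = 20, cv = 0) {
  consumption_profile(
    population = population,
    intake_mean = stats::setNames(rep(intake, 4),
                                  c("vegetables", "fruits", "cereals", "potatoes")),
    body_weight_mean = bw, cv = cv
  )
}
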