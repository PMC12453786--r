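test_that("default cohort has the published class sizes and total", {
  coh <- generate_cohort(default_generator_config(seed = 5))
  expect_equal(nrow(coh), 12085)
  tab <- table(coh$Class)
  expect_equal(unname(tab[["RA"]]), 2848)
  expect_equal(unname(tab[["ReA"]]), 516)
  expect_equal(unname(tab[["AS"]]), 2127)
  expect_equal(sort(names(tab)), sort(c("RA", "ReA", "AS", "SS", "SLE", "PA", "N")))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  cfg <- default_generator_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- default_generator_config(seed = 8)
  c <- generate_cohort(cfg2)
  expect_true(any(as.matrix(a[names(a) != "Class"]) !=
                    as.matrix(c[names(c) != "Class"])))
})

test_that("single-class config yields constant labels and respects n", {
  cfg <- generator_config(
    list(feature_spec("x", "numeric", 0, 10, 5, 1),
         feature_spec("b", "binary", mean = 0.5)),
    list(class_profile("only", 5)), seed = 3)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 5)
  expect_true(all(coh$Class == "only"))
  expect_true(all(coh$x >= 0 & coh$x <= 10))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(feature_spec("x", "numeric", lo = 5, hi = 1, mean = 3, sd = 1), "lo/hi")
  expect_error(feature_spec("x", "numeric", 0, 1, 0.5, sd = -1), "'sd'")
  expect_error(feature_spec("x", "numeric", 0, 1, 0.5, 0.1, missing_rate = 1), "missing_rate")
  expect_error(class_profile("c", 0), "'n'")
  expect_error(generator_config(
    list(feature_spec("x", "numeric", 0, 1, 0.5, 0.1)),
    list(class_profile("c", 2, num_shifts = c(zz = 1)))), "unknown feature")
})

test_that("numeric values stay in range and marginal means recover within 10%", {
  cfg <- default_generator_config(seed = 31)
  coh <- generate_cohort(cfg)
  for (f in cfg$feature_specs) {
    if (f$kind != "numeric") next
    x <- coh[[f$name]]
    expect_true(all(x >= f$lo & x <= f$hi), label = paste(f$name, "in range"))
    expect_lt(abs(mean(x) - f$mean) / f$mean, 0.10,
              label = paste(f$name, "marginal mean within 10%"))
  }
})

test_that("MCAR masking hits the configured rates and spares complete features", {
  cfg <- default_generator_config(seed = 41)
  coh <- generate_cohort(cfg)
  miss <- inject_missingness(coh, cfg$feature_specs, seed = 42)
  ## published completeness: age and gender fully observed
  expect_equal(sum(is.na(miss$Age)), 0)
  expect_equal(sum(is.na(miss$Gender)), 0)
  ## anti-Sm at its 43% missing fraction, within +-0.02 at n = 12,085
  frac <- mean(is.na(miss$`Anti-Sm`))
  expect_lt(abs(frac - 0.43), 0.02)
  ## labels never masked, label values untouched by composition
  expect_false(anyNA(miss$Class))
  expect_identical(miss$Class, coh$Class)
})

test_that("zero rates leave the table unchanged and a 50% rate is binomial", {
  cfg <- generator_config(
    list(feature_spec("x", "numeric", 0, 10, 5, 1, missing_rate = 0)),
    list(class_profile("c", 100)), seed = 1)
  coh <- generate_cohort(cfg)
  expect_identical(inject_missingness(coh, cfg$feature_specs, seed = 9), coh)

  cfg2 <- generator_config(
    list(feature_spec("x", "numeric", 0, 10, 5, 1, missing_rate = 0.5)),
    list(class_profile("c", 10000)), seed = 2)
  coh2 <- generate_cohort(cfg2)
  masked <- sum(is.na(inject_missingness(coh2, cfg2$feature_specs, seed = 10)$x))
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)  # binomial 99% interval oracle
  expect_gte(masked, ci[1])
  expect_lte(masked, ci[2])
})

test_that("cohort summaries report counts, moments and missingness consistently", {
  cfg <- default_generator_config(seed = 51)
  coh <- inject_missingness(generate_cohort(cfg), cfg$feature_specs, seed = 52)
  s <- summarize_cohort(coh)
  expect_equal(nrow(s), 14)
  expect_true(all(s$count + s$missing == nrow(coh)))
  expect_equal(s$missing_pct[s$feature == "Age"], 0)

  one <- data.frame(v = 3.5, Class = "c")
  s1 <- summarize_cohort(one)
  expect_equal(s1$mean, 3.5)
  expect_equal(s1$sd, 0)

  tri <- data.frame(v = c(1, 2, 3), Class = "c")
  s3 <- summarize_cohort(tri)
  expect_equal(s3$mean, 2)
  expect_equal(s3$min, 1)
  expect_equal(s3$max, 3)
  expect_error(summarize_cohort(data.frame(v = numeric(0), Class = character(0))),
               "empty")
})

test_that("the shipped configuration file encodes the default study conditions", {
  shipped <- read_generator_config(ext_fixture("generator_config.yaml"))
  ref <- default_generator_config(seed = 1)
  expect_equal(shipped$feature_specs, ref$feature_specs)
  expect_equal(shipped$class_profiles, ref$class_profiles)
})

test_that("cohorts and configurations round-trip through their file formats", {
  cfg <- default_generator_config(seed = 61)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$feature_specs, cfg$feature_specs)
  expect_equal(cfg2$class_profiles, cfg$class_profiles)

  small <- generator_config(cfg$feature_specs,
                            list(class_profile("RA", 40), class_profile("N", 30)),
                            seed = 62)
  coh <- inject_missingness(generate_cohort(small), small$feature_specs, seed = 63)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, csv)
  back <- read_cohort(csv)
  expect_equal(dim(back), dim(coh))
  expect_equal(sum(is.na(back)), sum(is.na(coh)))
  expect_equal(back$Class, coh$Class)
})
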