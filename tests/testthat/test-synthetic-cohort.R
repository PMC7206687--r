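test_that("caliper formula converts diameters to volume", {
  expect_equal(diameters_to_volume(10, 10), pi / 6, tolerance = 1e-12)
  expect_equal(diameters_to_volume(12.4, 9.9), pi * 1.24 * 0.99^2 / 6,
               tolerance = 1e-12)
  expect_lt(diameters_to_volume(1, 1e-3), 1e-8)
  expect_error(diameters_to_volume(8, 10), "swapped")
  expect_error(diameters_to_volume(5, 0), "b_mm")
})

test_that("zero dispersion reproduces group means exactly; draws are positive", {
  hyper0 <- default_hyperparams(cv = list(alpha = 0, beta = 0, i0 = 0, gamma = 0))
  set.seed(5)
  ap <- sample_animal_params("TG2", "F", hyper0)
  expect_equal(ap$alpha, 0.490)
  expect_equal(ap$beta, 0.055)
  expect_equal(ap$i0, 4.061)
  expect_equal(ap$gamma, 12.890)
  hyper <- default_hyperparams()
  set.seed(6)
  for (rep in 1:50) {
    ap <- sample_animal_params("TG5", "M", hyper)
    expect_true(all(unlist(ap[c("alpha", "beta", "i0", "gamma")]) > 0))
    expect_gte(ap$latency, hyper$latency_floor)
  }
})

test_that("sample means converge to gender-specific growth rates", {
  set.seed(7)
  aF <- replicate(3000, sample_animal_params("CG2", "F")$alpha)
  aM <- replicate(3000, sample_animal_params("CG2", "M")$alpha)
  expect_equal(mean(aF), 0.490, tolerance = 0.01)
  expect_equal(mean(aM), 0.422, tolerance = 0.01)
  expect_gt(mean(aF), mean(aM))
})

test_that("noise-free untreated observations lie exactly on the model curve", {
  hyper <- default_hyperparams(noise_cv = 0,
                               cv = list(alpha = 0, beta = 0, i0 = 0, gamma = 0),
                               hazard_pre = 0, p_death_post = 0,
                               censor_volume = 1e9)
  design <- small_design(seed = 2)
  set.seed(2)
  ap <- sample_animal_params("CG1", "F", hyper)
  rec <- simulate_mouse(ap, design$groups[1, ], "F", design, hyper, "x1")
  p <- gompertz_params(
    ap$V_treat / exp((ap$alpha / ap$beta) *
                       (1 - exp(-ap$beta * (31 - ap$latency)))),
    ap$alpha, ap$beta)
  expect_equal(rec$observations$volume_cm3,
               gompertz_volume(rec$observations$day - ap$latency, p),
               tolerance = 1e-12)
  # diameters are consistent with the ellipsoid formula
  expect_equal(diameters_to_volume(rec$observations$a_mm,
                                   rec$observations$b_mm),
               rec$observations$volume_cm3, tolerance = 1e-12)
  expect_true(all(rec$observations$a_mm >= rec$observations$b_mm))
  # volume at the treatment day equals the drawn anchor
  expect_equal(rec$observations$volume_cm3[rec$observations$day == 31],
               ap$V_treat, tolerance = 1e-12)
})

test_that("tumors reaching the ethics limit are censored with no later data", {
  hyper <- default_hyperparams(hazard_pre = 0, p_death_post = 0)
  design <- study_design(groups = default_group_table()[1, ], seed = 9)
  set.seed(9)
  hits <- 0
  for (rep in 1:40) {
    ap <- sample_animal_params("CG1", "M", hyper)
    rec <- simulate_mouse(ap, design$groups[1, ], "M", design, hyper, "m")
    v <- rec$observations$volume_cm3
    over <- which(v >= hyper$censor_volume)
    if (length(over)) {
      hits <- hits + 1
      expect_identical(rec$fate, "censored_large_tumor")
      expect_identical(over, length(v))  # the trigger is the last record
      expect_true(all(rec$observations$day <= rec$fate_day))
    }
  }
  expect_gt(hits, 0)  # fast-growing controls do reach the limit
})

test_that("cohorts are seed-deterministic and have the designed size", {
  d1 <- study_design(seed = 123)
  c1 <- simulate_cohort(d1)
  c2 <- simulate_cohort(study_design(seed = 123))
  expect_identical(c1$table, c2$table)
  expect_length(c1$records, 160)  # 8 groups x 2 genders x 10
  c3 <- simulate_cohort(study_design(seed = 124))
  expect_false(identical(c1$table, c3$table))
  # flat table round-trips through CSV identically (schema check)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(c1$table, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$volume_cm3, c1$table$volume_cm3, tolerance = 1e-12)
  expect_identical(names(back), names(c1$table))
  unlink(f)
})

test_that("pre-treatment mortality calibrates to about a quarter of animals", {
  g <- default_group_table()[c(1, 2), ]  # hazards are group-independent
  g$n_per_gender <- 10L
  fracs <- vapply(1:150, function(s) {
    co <- simulate_cohort(study_design(groups = g, seed = 7000 + s))
    fates <- vapply(co$records, `[[`, "", "fate")
    mean(fates == "died_pre_treatment")
  }, numeric(1))
  expect_equal(mean(fracs), 0.244, tolerance = 0.05)
})

test_that("control group-mean curves rise before treatment", {
  for (s in 1:5) {
    co <- simulate_cohort(study_design(groups = default_group_table()[2, ],
                                       seed = 40 + s))
    tab <- co$table
    pre <- tab[tab$day <= 31, ]
    m <- tapply(pre$volume_cm3, pre$day, mean)
    expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))
  }
})
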