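test_that("the symmetric limit reproduces the worked temperature case", {
  lim <- required_symmetric_limit(17.5, 27.5, 26.02)
  expect_equal(lim$d1, 1.48)
  expect_equal(lim$d2, 8.52)
  expect_equal(lim$expansion_side, "right")
  expect_equal(lim$required_limit, 34.54)
  expect_equal(round(expansion_factor(lim$d1, lim$d2,
                                      lim$expansion_side), 2), 5.76)
})

test_that("symmetric and left-shifted modes are handled", {
  mid <- required_symmetric_limit(0, 10, 5)
  expect_equal(mid$expansion_side, "none")
  expect_equal(mid$d1, mid$d2)
  expect_equal(expansion_factor(mid$d1, mid$d2, "none"), 1)

  left <- required_symmetric_limit(0, 10, 2)
  expect_equal(left$expansion_side, "left")
  expect_equal(left$required_limit, -6)
  expect_equal(expansion_factor(left$d1, left$d2, "left"), -4)
})

test_that("a mode on a range extreme gives an undefined factor", {
  lim <- required_symmetric_limit(0, 10, 0)
  expect_equal(lim$d1, 0)
  expect_true(is.na(expansion_factor(lim$d1, lim$d2,
                                     lim$expansion_side)))
})

test_that("expansion classification respects the natural domain", {
  precip <- variable_domain("mean_annual_precipitation", lower = 0)
  temp <- variable_domain("mean_annual_temperature")
  ratio <- variable_domain("ratio", lower = 0, upper = 1)

  expect_equal(classify_expansion(-6, "left", precip,
                                  relDis = -20, d1 = 2),
               "expansion_impossible")
  expect_equal(classify_expansion(34.54, "right", temp,
                                  relDis = 35.2, d1 = 1.48),
               "expansion_possible")
  expect_equal(classify_expansion(0.83, "right", ratio,
                                  relDis = 10, d1 = 0.1),
               "expansion_possible")
  # truncated variable whose required limit stays inside the bound
  expect_equal(classify_expansion(120, "left", precip,
                                  relDis = -5, d1 = 40),
               "expansion_possible")
  # boundary equality: the bound itself is attainable
  expect_equal(classify_expansion(1, "right", ratio,
                                  relDis = 12, d1 = 0.2),
               "expansion_possible")
  expect_equal(classify_expansion(-6, "left", precip,
                                  relDis = 0, d1 = 2), "centered")
  expect_equal(classify_expansion(-6, "left", precip,
                                  relDis = -30, d1 = 0),
               "undefined_d1_zero")
})

test_that("relaxing a bound never turns possible into impossible", {
  set.seed(19)
  bounded <- variable_domain("v", lower = 0)
  free <- variable_domain("v")
  for (rep in 1:100) {
    required <- stats::runif(1, -50, 50)
    side <- sample(c("left", "right"), 1)
    rel <- stats::runif(1, -40, 40)
    d1 <- stats::runif(1, 0.1, 5)
    c_bounded <- classify_expansion(required, side, bounded, rel, d1)
    c_free <- classify_expansion(required, side, free, rel, d1)
    if (c_bounded == "expansion_possible") {
      expect_equal(c_free, "expansion_possible")
    }
    if (c_free == "expansion_impossible") {
      expect_equal(c_bounded, "expansion_impossible")
    }
  }
})

test_that("assessments assign exactly one category each", {
  dom <- variable_domain("v", lower = 0)
  set.seed(29)
  cats <- character(0)
  for (rep in 1:100) {
    r <- sort(stats::runif(2, 0, 100))
    mode <- stats::runif(1, r[1L], r[2L])
    rel <- sample(c(0, stats::runif(1, -40, 40)), 1)
    a <- assess_symmetry("sp", "v", r[1L], r[2L], mode, dom, rel)
    expect_true(a$category %in% c("centered", "expansion_possible",
                                  "expansion_impossible",
                                  "undefined_d1_zero"))
    expect_length(a$category, 1L)
    if (!is.na(a$expansion_factor) && a$expansion_factor != 1) {
      expect_equal(sign(a$expansion_factor),
                   if (a$expansion_side == "right") 1 else -1)
    }
    cats <- c(cats, a$category)
  }
  expect_equal(length(cats), 100L)
})

test_that("required limits compare against the study-wide range", {
  expect_true(compare_required_to_observed(107, "left", c(72, 4390)))
  expect_false(compare_required_to_observed(34.5, "right", c(13, 29.5)))
  expect_true(compare_required_to_observed(29.5, "right", c(13, 29.5)))
})
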