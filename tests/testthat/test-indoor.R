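test_that("steady-state concentration matches hand-computed cases", {
  # no sources, perfect penetration, no deposition: indoor equals outdoor
  r <- steady_state_concentration(c_out = 10, emission = 0, volume = 100,
                                  ach = 0.5)
  expect_equal(r$total, 10)
  expect_equal(r$indoor_origin, 0)
  # infiltration only: 0.9 * 0.5 * 10 / (0.5 + 0.2) = 6.4286
  r <- steady_state_concentration(10, 0, 100, 0.5, penetration = 0.9,
                                  deposition = 0.2)
  expect_equal(r$total, 6.428571, tolerance = 1e-6)
  # add an indoor source: E/V / loss = (1000/100)/0.7 = 14.286
  r <- steady_state_concentration(10, 1000, 100, 0.5, penetration = 0.9,
                                  deposition = 0.2)
  expect_equal(r$indoor_origin, 14.28571, tolerance = 1e-6)
  expect_equal(r$total, 20.71429, tolerance = 1e-6)
  expect_error(steady_state_concentration(10, 0, 100, 0), "loss")
})

test_that("total is exactly the sum of indoor- and outdoor-origin parts", {
  set.seed(4)
  for (i in 1:50) {
    r <- steady_state_concentration(runif(1, 0, 50), runif(1, 0, 5000),
                                    runif(1, 30, 500), runif(1, 0.1, 3),
                                    runif(1), runif(1, 0, 1), runif(1, 0, 200))
    expect_identical(r$total, r$outdoor_origin + r$indoor_origin)
  }
})

test_that("closed form agrees with an ODE time-stepping oracle", {
  skip_if_not_installed("deSolve")
  set.seed(12)
  for (i in 1:20) {
    p <- list(c_out = runif(1, 1, 50), E = runif(1, 0, 5000),
              V = runif(1, 30, 500), a = runif(1, 0.1, 3),
              P = runif(1), k = runif(1, 0, 1), cadr = runif(1, 0, 200))
    loss <- p$a + p$k + p$cadr / p$V
    deriv <- function(t, y, parms)
      list(p$P * p$a * p$c_out + p$E / p$V - loss * y)
    out <- deSolve::ode(y = c(C = 0), times = c(0, 30 / loss), func = deriv,
                        parms = NULL)
    numeric_ss <- out[nrow(out), "C"]
    closed <- steady_state_concentration(p$c_out, p$E, p$V, p$a, p$P, p$k,
                                         p$cadr)$total
    expect_equal(unname(numeric_ss), closed, tolerance = 1e-3)
  }
})

test_that("indoor concentration is monotone in its drivers", {
  base <- steady_state_concentration(10, 1000, 100, 0.5, 0.9, 0.2, 0)$total
  expect_lt(steady_state_concentration(10, 1000, 100, 0.5, 0.9, 0.2,
                                       cadr = 80)$total, base)
  expect_lt(steady_state_concentration(10, 1000, 100, 0.5, 0.9,
                                       deposition = 0.5)$total, base)
  expect_gt(steady_state_concentration(10, 2000, 100, 0.5, 0.9, 0.2)$total,
            base)
  expect_gt(steady_state_concentration(20, 1000, 100, 0.5, 0.9, 0.2)$total,
            base)
})

test_that("I/O ratio reflects sources and cleaning", {
  expect_equal(io_ratio(10, 10), 1)
  expect_gt(io_ratio(20.7, 10), 1)        # heavy indoor sources
  # cleaner-equipped, source-free home sits below 1
  cleaned <- steady_state_concentration(10, 0, 100, 0.5, penetration = 1,
                                        deposition = 0, cadr = 89)$total
  expect_lt(io_ratio(cleaned, 10), 1)
  expect_warning(r <- io_ratio(5, 0), "undefined")
  expect_true(is.na(r))
})

test_that("emission inventory follows household activity and ERFs", {
  hh0 <- list(smoking_cigarettes_per_day = 0,
              fuel_use = c(coal = 0, biomass = 0, lpg = 0), cooking_erf = 1)
  ef <- read_emission_factors()
  inv <- build_emission_inventory(hh0, ef)
  expect_true(all(inv$total == 0))
  # rural coal user, 2 kg/day, chimney ERF 0.10: E = 2 * EF * 0.10 / 24
  hh <- list(smoking_cigarettes_per_day = 0,
             fuel_use = c(coal = 2), cooking_erf = 0.10)
  inv <- build_emission_inventory(hh, ef)
  ef_bap <- sum(ef$ng_per_unit[ef$source == "cooking_coal" &
                               ef$congener == "BaP"])
  expect_equal(sum(inv$total["BaP", ]), 2 * ef_bap * 0.10 / 24)
  # smoking-free flag zeroes only the smoking component
  hh2 <- list(smoking_cigarettes_per_day = 10,
              fuel_use = c(coal = 2), cooking_erf = 0.10)
  inv_all <- build_emission_inventory(hh2, ef)
  inv_sf <- build_emission_inventory(hh2, ef, remove_smoking = TRUE)
  expect_true(all(inv_sf$by_source[, , "smoking"] == 0))
  expect_equal(inv_sf$by_source[, , "cooking_coal"],
               inv_all$by_source[, , "cooking_coal"])
  expect_error(build_emission_inventory(
    list(smoking_cigarettes_per_day = 0, fuel_use = c(peat = 1),
         cooking_erf = 1), ef), "peat")
})
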