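test_that("survival to 85 with an exponential tail gives e0 = 85 + 1/m", {
  D <- c(rep(0, 18), 100)
  PY <- c(rep(1000, 18), 100 / 0.02)
  lt <- life_table(D, PY)
  expect_equal(lt$e[1], 135, tolerance = 1e-9)
  expect_equal(lt$l[19], 1e5)
})

test_that("zero deaths in a mid-life interval are handled, not fatal", {
  ex <- expected_tract()
  D <- ex$deaths; D[8] <- 0
  lt <- life_table(D, ex$person_years)
  expect_equal(lt$q[8], 0)
  expect_equal(lt$l[9], lt$l[8])
  expect_true(is.finite(lt$e[1]))
})

test_that("constant-hazard table matches the independent arithmetic oracle", {
  sched <- age_schedule()
  for (m in c(0.0125, 0.003, 0.05)) {
    PY <- rep(1000, 19)
    D <- m * PY
    lt <- life_table(D, PY, sched)
    expect_equal(lt$e[1],
                 oracle_e0(D, PY, sched$width),
                 tolerance = 1e-9)
  }
})

test_that("random tables match the oracle and conserve persons", {
  sched <- age_schedule()
  set.seed(42)
  for (rep in 1:20) {
    PY <- runif(19, 500, 50000)
    D <- rpois(19, pmin(PY * exp(runif(19, -9, -2)), PY * 0.5)) + c(rep(0, 18), 1)
    lt <- life_table(D, PY, sched)
    expect_equal(lt$e[1], oracle_e0(D, PY, sched$width), tolerance = 1e-9)
    expect_equal(sum(lt$d), 1e5, tolerance = 1e-6)
    expect_equal(lt$T[1], sum(lt$L), tolerance = 1e-6)
    expect_equal(lt$e[1], lt$T[1] / 1e5, tolerance = 1e-12)
    expect_true(all(diff(lt$l) <= 1e-9))
    expect_true(all(lt$q >= 0 & lt$q <= 1))
    expect_true(all(lt$e >= 0))
  }
})

test_that("adding deaths to any interval never increases e0", {
  set.seed(7)
  ex <- expected_tract()
  base <- life_table(ex$deaths, ex$person_years)$e[1]
  for (i in sample(1:19, 8)) {
    D2 <- ex$deaths
    D2[i] <- D2[i] + 10
    expect_lte(life_table(D2, ex$person_years)$e[1], base + 1e-9)
  }
})

test_that("degenerate inputs raise the documented errors", {
  D <- rep(0, 19); PY <- rep(1000, 19)
  D[5] <- 3; PY[5] <- 0
  expect_error(life_table(D, PY), "zero person-years")
  # survivors reach 85+ but no terminal rate: no floor is substituted
  D2 <- rep(0, 19); PY2 <- rep(1000, 19)
  expect_error(life_table(D2, PY2), "open interval")
  # empty stratum (0 deaths, 0 person-years) is rate zero, not NaN
  D3 <- c(rep(0, 18), 50); PY3 <- c(rep(1000, 18), 1000)
  PY3[4] <- 0
  lt <- life_table(D3, PY3)
  expect_equal(lt$m[4], 0)
  expect_true(is.finite(lt$e[1]))
})

test_that("closed-interval variance vanishes when all closed deaths are zero", {
  D <- c(rep(0, 18), 500)
  PY <- c(rep(1000, 18), 5000)
  lt <- life_table(D, PY)
  est <- life_expectancy(lt)
  # only the open-interval term contributes: (l/r)^2/(m^2 D) with l = r
  expect_equal(est$se, sqrt(1 / (0.1^2 * 500)), tolerance = 1e-12)
  expect_true(est$ci_low <= est$e0 && est$e0 <= est$ci_high)
})

test_that("standard error shrinks as 1/sqrt(n) under exposure scaling", {
  ex <- expected_tract()
  lt1 <- life_table(ex$deaths, ex$person_years)
  lt2 <- life_table(ex$deaths * 100, ex$person_years * 100)
  se1 <- life_expectancy(lt1)$se
  se2 <- life_expectancy(lt2)$se
  expect_equal(life_expectancy(lt1)$e0, life_expectancy(lt2)$e0,
               tolerance = 1e-9)
  expect_gt(se1 / se2, 10 * 0.85)
  expect_lt(se1 / se2, 10 * 1.15)
})

test_that("reliability screen applies strict inequalities with all reasons", {
  crit <- reliability_criteria()
  est <- data.frame(total_deaths = c(49, 200, 50, 10),
                    total_person_years = c(10000, 4999, 5000, 100),
                    se = c(1, 1, 2, 3))
  v <- assess_reliability(est, crit)
  expect_equal(v$retained, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(v$reasons[1], "deaths")
  expect_equal(v$reasons[2], "person_years")
  expect_equal(v$reasons[3], "")
  expect_equal(v$reasons[4], "deaths;person_years;se")
  # pure function: applying it twice yields identical verdicts
  v2 <- assess_reliability(v, crit)
  expect_equal(v2$retained, v$retained)
  expect_equal(v2$reasons, v$reasons)
})

test_that("tract-level wrapper joins, estimates and screens", {
  w <- lattice_weights(3, 3)$w
  X <- simulate_covariates(w, 1, rho = 0, seed = 5)
  sim <- simulate_mortality(X, seed = 9)
  le <- tract_life_expectancy(sim$mortality, sim$population)
  expect_equal(nrow(le), 9)
  expect_equal(le$tract_id, sort(sim$mortality$tract_id, method = "radix"))
  expect_true(all(is.finite(le$e0)))
  expect_true(all(le$ci_low <= le$e0 & le$e0 <= le$ci_high))
  expect_true(all(le$total_person_years == sum(ex <- round(age_pyramid() * 5000)) * 5))
})
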