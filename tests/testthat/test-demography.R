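test_that("life expectancy follows the class-sum quadrature", {
  expect_equal(life_expectancy(flat_table(50)), 50)
  expect_equal(life_expectancy(life_table(c(1, 0.5))), 1.5)
  # geometric-series limit of constant 10% mortality
  expect_equal(life_expectancy(life_table_type2(300)), 10, tolerance = 1e-8)
  # trapezoid averages the class endpoints
  expect_equal(life_expectancy(life_table(c(1, 0.5)), rule = "trapezoid"), 0.75)
})

test_that("Keyfitz entropy separates rectangular from exponential survival", {
  rect <- flat_table(60)
  ke <- keyfitz_entropy(rect)
  expect_equal(ke$H, 0)
  expect_equal(ke$edag, 0)

  # constant mortality: closed-form discrete sums
  # edag = -ln(q) q/(1-q)^2, e0 = 1/(1-q) (k large), H = -ln(q) q/(1-q)
  lt <- life_table_type2(300)
  ke <- keyfitz_entropy(lt)
  q <- 0.9
  expect_equal(ke$H, -log(q) * q / (1 - q), tolerance = 1e-8)
  expect_equal(ke$equality, log(1 / ke$H), tolerance = 1e-12)

  # trapezoid quadrature converges on the continuous exponential value 1
  expect_equal(keyfitz_entropy(life_table_type2(100), rule = "trapezoid")$H, 1,
               tolerance = 0.02)
  expect_error(keyfitz_entropy(life_table(1)), "single-class")
})

test_that("longevity is the adult 95% death age and shape its ratio to e0", {
  # constant mortality: first class with 0.9^(x-1) <= 0.05, brute force
  lt <- life_table_type2(100)
  brute <- min(which(0.9^(0:99) <= 0.05))
  om <- longevity_omega(lt, maturity_age = 1)
  expect_equal(om$omega, brute)
  expect_equal(om$omega, 30)
  expect_equal(om$shape, 30 / life_expectancy(lt))

  # quantile 0: longevity collapses to the maturity age
  expect_equal(longevity_omega(lt, quantile = 0, maturity_age = 5)$omega, 5)

  # rectangular survival never crosses: last age returned with a warning
  expect_warning(om <- longevity_omega(flat_table(80), maturity_age = 1),
                 "never falls")
  expect_equal(om$omega, 80)
  expect_equal(om$shape, 1)
})

test_that("net reproduction gives mean mother age and zero growth when R0 = 1", {
  lt <- flat_table(6)
  fs <- fecundity_schedule(lt, c(0, 1, 1, 1, 0, 0))
  nr <- net_reproduction(lt, fs)
  expect_equal(nr$T, 3)
  expect_equal(nr$R0, 1, tolerance = 1e-12)
  expect_equal(nr$r, 0, tolerance = 1e-12)

  fs <- fecundity_schedule(lt, c(0, 0, 0, 0, 1, 0))
  expect_equal(net_reproduction(lt, fs)$T, 5)

  # weighted-mean cross-check on an asymmetric configuration
  lt <- life_table_type2(80)
  fs <- gaussian_fecundity(lt)
  w <- lt$l * fs$m
  expect_equal(net_reproduction(lt, fs)$T, stats::weighted.mean(lt$ages, w),
               tolerance = 1e-9)
})

test_that("reproductive value modes agree with their defining sums", {
  lt <- life_table(c(1, 0.8, 0.4, 0.2))
  fs <- fecundity_schedule(lt, c(0, 1, 1, 0))
  # as-printed: v = R0 / l = 1 / l for normalized schedules
  expect_equal(reproductive_value(lt, fs, "as_printed"), 1 / lt$l,
               tolerance = 1e-12, ignore_attr = TRUE)
  v <- reproductive_value(lt, fs)
  expect_equal(v[1], 1, tolerance = 1e-12)       # newborn: all reproduction ahead
  expect_equal(v[4], 0)                          # post-reproductive: empty sum
  # explicit loop oracle
  vloop <- sapply(1:4, function(x) sum(lt$l[x:4] * fs$m[x:4]) / lt$l[x])
  expect_equal(as.numeric(v), vloop, tolerance = 1e-12)
})

test_that("effective size reduces to Nnb * T when no deaths precede the last class", {
  lt <- flat_table(10)
  fs <- fecundity_schedule(lt, c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0))
  ne <- felsenstein_ne(lt, fs, N_total = 1000)
  expect_equal(as.numeric(ne), attr(ne, "Nnb") * attr(ne, "T"), tolerance = 1e-12)
})

test_that("modular effective size matches a single-expression evaluation", {
  set.seed(202)
  for (i in 1:10) {
    lt <- random_life_table(6)
    fs <- random_schedule(lt)
    k <- lt$k
    n_exact <- 500 * lt$l / sum(lt$l)       # stable age counts, lambda = 1
    d <- c(lt$l[-k] - lt$l[-1], lt$l[k])
    for (sm in c("survival", "counts")) for (vm in c("fisher", "as_printed")) {
      v <- sapply(1:k, function(x) {
        lo <- if (vm == "fisher") x else 1
        sum(lt$l[lo:k] * fs$m[lo:k]) / lt$l[x]
      })
      vnext <- c(v[-1], 0)
      s <- if (sm == "survival") lt$P else n_exact
      Tg <- sum(lt$ages * lt$l * fs$m) / sum(lt$l * fs$m)
      oracle <- n_exact[1] * Tg / (1 + sum(lt$l * s * d * vnext^2))
      ne <- felsenstein_ne(lt, fs, N_total = 500, s_mode = sm, v_mode = vm)
      expect_equal(as.numeric(ne), oracle, tolerance = 1e-9)
    }
  }
})

test_that("pace/shape metrics cluster the survivorship types as expected", {
  t1 <- make_type1_modern()
  t2 <- life_table_type2(101)
  t3 <- life_table_type3(101)
  shape <- function(lt) longevity_omega(lt, maturity_age = 1)$shape
  # Type-II and Type-III share a shape score; modern Type-I stands apart
  expect_lt(abs(shape(t2) - shape(t3)), abs(shape(t1) - shape(t2)))
  eq <- function(lt) keyfitz_entropy(lt)$equality
  expect_lt(abs(eq(t2) - eq(t3)), abs(eq(t1) - eq(t2)))
  # life expectancy rises from Type-III to Type-II to Type-I
  expect_lt(life_expectancy(t3), life_expectancy(t2))
  expect_lt(life_expectancy(t2), life_expectancy(t1))
})

test_that("demography summary assembles consistent fields", {
  lt <- life_table_type2(80)
  fs <- gaussian_fecundity(lt)
  s <- demography_summary(lt, fs)
  expect_equal(s$H, s$edag / s$e0, tolerance = 1e-12)
  expect_equal(s$R0, 1, tolerance = 1e-12)
  expect_equal(s$Ne, as.numeric(felsenstein_ne(lt, fs)), tolerance = 1e-9)
  expect_lte(s$Ne, s$Nnb * s$T)
  expect_equal(s$s_mode, "survival")
})
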