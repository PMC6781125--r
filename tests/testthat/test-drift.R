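test_that("newborn resampling is multinomial at Hardy-Weinberg proportions", {
  set.seed(401)
  expect_equal(resample_newborns(1, 13), c(13, 0, 0))
  expect_equal(resample_newborns(0, 13), c(0, 0, 13))
  expect_error(resample_newborns(1.2, 13), "\\[0, 1\\]")
  expect_error(resample_newborns(0.5, 0), "positive")

  # cohort-size-13 draws: genotype frequencies converge on (p^2, 2pq, q^2)
  draws <- matrix(0, 1e4, 3)
  for (i in 1:1e4) draws[i, ] <- resample_newborns(0.5, 13)
  expect_equal(rowSums(draws)[1], 13)  # counts always sum to the cohort size
  freq <- colMeans(draws) / 13
  mc_se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / (13 * 1e4))
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * mc_se))
})

test_that("the between-class cull respects survival in both modes", {
  for (mode in c("binomial", "faithful")) {
    expect_equal(cull_age_class(c(5, 8, 3), 1, mode), c(5, 8, 3),
                 ignore_attr = TRUE)
    expect_equal(cull_age_class(c(5, 8, 3), 0, mode), c(0, 0, 0),
                 ignore_attr = TRUE)
  }
  expect_error(cull_age_class(c(1, 1, 1), 1.5), "\\[0, 1\\]")

  set.seed(402)
  tot <- replicate(500, sum(cull_age_class(c(40, 40, 40), 0.7, "binomial")))
  se <- sqrt(120 * 0.7 * 0.3 / 500)
  expect_lt(abs(mean(tot) - 84), 3 * se)

  # faithful mode: class total is the rounded expectation, deterministically
  tot_f <- replicate(50, sum(cull_age_class(c(40, 40, 40), 0.7, "faithful")))
  expect_true(all(tot_f == 84))
})

test_that("recessive viability selection reduces BB survival on breeding classes", {
  lt <- life_table(c(1, 0.99, 0.5, 0.25))
  fs <- fecundity_schedule(lt, c(0, 1, 1, 0))
  Pm <- survival_with_selection(lt, fs, s = 0.01)
  expect_equal(Pm["AA", ], lt$P, ignore_attr = TRUE)
  expect_equal(Pm["AB", ], lt$P, ignore_attr = TRUE)
  expect_equal(Pm["BB", 2:3], lt$P[2:3] * 0.99, ignore_attr = TRUE)
  expect_equal(Pm["BB", c(1, 4)], lt$P[c(1, 4)], ignore_attr = TRUE)
  # s = 1: no BB survives a breeding-class transition
  expect_equal(survival_with_selection(lt, fs, 1)["BB", 2:3], c(0, 0),
               ignore_attr = TRUE)
  # s = 0: all genotypes identical
  expect_equal(survival_with_selection(lt, fs, 0)["BB", ], lt$P,
               ignore_attr = TRUE)
})

test_that("heterozygosity measures agree in the many-newborn limit", {
  expect_equal(heterozygosity(c(0, 10, 0)), 0.5)
  expect_equal(heterozygosity(c(20, 0, 0)), 0)
  expect_equal(heterozygosity(c(0, 10, 0), "observed"), 1)
  set.seed(403)
  big <- resample_newborns(0.5, 1e4)
  expect_lt(abs(heterozygosity(big, "observed") - heterozygosity(big)), 0.02)
})

test_that("seeded simulations are exactly reproducible", {
  lt <- life_table_type2(20)
  fs <- gaussian_fecundity(lt, mean = 8, sd = 3)
  cfg <- sim_config(N_total = 200, years = 40, replicates = 10, seed = 99)
  a <- run_simulation(lt, fs, cfg)
  b <- run_simulation(lt, fs, cfg)
  expect_identical(a$het, b$het)
  expect_identical(a$final_p, b$final_p)
  c <- run_simulation(lt, fs, sim_config(N_total = 200, years = 40,
                                         replicates = 10, seed = 100))
  expect_false(identical(a$het, c$het))
})

test_that("simulations do not disturb the caller's RNG stream", {
  lt <- life_table_type2(10)
  fs <- gaussian_fecundity(lt, mean = 5, sd = 2)
  set.seed(7)
  before <- runif(3)
  set.seed(7)
  run_simulation(lt, fs, sim_config(N_total = 100, years = 5, replicates = 2))
  expect_identical(runif(3), before)
})

test_that("neutral drift conserves mean allele frequency (martingale)", {
  lt <- life_table_type2(30)
  fs <- gaussian_fecundity(lt, mean = 10, sd = 4)
  cfg <- sim_config(N_total = 200, years = 60, replicates = 1000, seed = 17)
  res <- run_simulation(lt, fs, cfg)
  se <- stats::sd(res$final_p) / sqrt(cfg$replicates)
  expect_lt(abs(mean(res$final_p) - 0.5), 3 * se)
})

test_that("fixation is absorbing: heterozygosity stays zero afterwards", {
  lt <- life_table(1)   # one class: everyone breeds at 1 and dies
  fs <- fecundity_schedule(lt, 1)
  res <- run_simulation(lt, fs, sim_config(N_total = 20, years = 120,
                                           replicates = 100, seed = 23))
  fixed <- which(!is.na(res$fixation_time))
  expect_gt(length(fixed), 50)   # 2N = 40, 120 generations: most runs fix
  for (r in fixed) {
    t0 <- res$fixation_time[r]
    expect_true(all(res$het[r, t0:ncol(res$het)] == 0))
    expect_true(res$final_p[r] %in% c(0, 1))
  }
})

test_that("one-class populations reproduce Wright-Fisher drift variance", {
  lt <- life_table(1)
  fs <- fecundity_schedule(lt, 1)
  res <- run_simulation(lt, fs, sim_config(N_total = 20, years = 1,
                                           replicates = 4000, seed = 31))
  dp <- res$final_p - 0.5
  expect_lt(abs(mean(dp)), 3 * stats::sd(dp) / sqrt(4000))
  v <- stats::var(dp)
  target <- 0.5 * 0.5 / (2 * 20)
  se_v <- stats::sd(dp^2) / sqrt(4000)
  expect_lt(abs(v - target), 3 * se_v)
})

test_that("selection accelerates heterozygosity loss relative to neutrality", {
  lt <- life_table_type2(30)
  fs <- gaussian_fecundity(lt, mean = 10, sd = 4)
  base <- sim_config(N_total = 300, years = 80, replicates = 60, seed = 47)
  neutral <- run_simulation(lt, fs, base)
  sel <- base
  sel$s <- 0.1
  strong <- run_simulation(lt, fs, sel)
  expect_lt(strong$final_summary$mean, neutral$final_summary$mean)
})

test_that("faithful culling holds class totals at the stable distribution", {
  lt <- life_table_type2(15)
  fs <- gaussian_fecundity(lt, mean = 6, sd = 2)
  cfg <- sim_config(N_total = 500, years = 30, replicates = 3, seed = 53,
                    cull_mode = "faithful")
  res <- run_simulation(lt, fs, cfg)
  expect_equal(sum(res$class_totals), 500, tolerance = 0.01)
  expect_equal(res$Nnb, round(500 * lt$l[1] / sum(lt$l)))
})

test_that("implied effective size inverts geometric heterozygosity decay", {
  Ne <- 250
  h <- 0.5 * (1 - 1 / (2 * Ne))^(0:400)
  fit <- fit_implied_ne(h)
  expect_equal(fit$Ne_implied, Ne, tolerance = 1e-9)
  expect_equal(fit_implied_ne(rep(0.4, 50))$rho, 1, tolerance = 1e-12)
  expect_error(fit_implied_ne(c(0.5)), "at least two")
})

test_that("trajectory summaries report notched-boxplot statistics", {
  lt <- life_table_type2(20)
  fs <- gaussian_fecundity(lt, mean = 8, sd = 3)
  cfg <- sim_config(N_total = 200, years = 30, replicates = 40, seed = 61)
  res <- run_simulation(lt, fs, cfg)
  s <- summarize_trajectories(first = res)
  expect_equal(nrow(s), 1)
  expect_equal(s$run, "first")
  expect_equal(s$notch, 1.58 * (s$q3 - s$q1) / sqrt(40), tolerance = 1e-12)
  expect_true(all(res$het >= 0 & res$het <= 0.5))
  expect_true(s$median >= s$q1 && s$median <= s$q3)
})
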