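#' Simulation configuration
#'
#' Collects the knobs of the stochastic drift simulator. Defaults are the
#' full-scale study conditions (census of 1000 females, 1000 replicates of
#' 1000 yearly steps, both alleles starting at frequency 0.5); tests and
#' examples scale `years`/`replicates` down.
#'
#' @param N_total female census size held constant at the stable age
#'   distribution.
#' @param years number of yearly time steps per replicate.
#' @param replicates number of independent replicate runs.
#' @param p0 initial allele-A frequency (B starts at `1 - p0`).
#' @param s recessive viability selection coefficient against BB on
#'   reproductive-age survival (0 = neutral).
#' @param shift fecundity displacement in years applied before simulating.
#' @param seed root RNG seed; per-replicate seeds are derived from it.
#' @param het_mode `"expected"` records `2p(1-p)` from the realized newborn
#'   allele frequency; `"observed"` records the heterozygote fraction among
#'   newborns.
#' @param cull_mode `"binomial"` thins each genotype independently;
#'   `"faithful"` retains a deterministic survivor fraction per genotype and
#'   redraws the remainder multinomially from the class's genotype
#'   frequencies (the literal two-part cull description).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(N_total = 1000, years = 1000, replicates = 1000,
                       p0 = 0.5, s = 0, shift = 0, seed = 1,
                       het_mode = c("expected", "observed"),
                       cull_mode = c("binomial", "faithful")) {
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]", call. = FALSE)
  if (s < 0 || s > 1) stop("s must be in [0, 1]", call. = FALSE)
  if (years < 1 || replicates < 1) stop("years and replicates must be >= 1", call. = FALSE)
  structure(list(N_total = N_total, years = as.integer(years),
                 replicates = as.integer(replicates), p0 = p0, s = s,
                 shift = shift, seed = as.integer(seed),
                 het_mode = match.arg(het_mode),
                 cull_mode = match.arg(cull_mode)),
            class = "sim_config")
}

#' Genotype-specific survival with recessive viability selection
#'
#' Returns the `3 x k` matrix of per-class survival probabilities for the
#' genotypes AA, AB, BB. Selection reduces BB survival to `P_x * (1 - s)`
#' on the breeding age classes (located by [reproductive_classes()]); AA
#' and AB, and all non-breeding classes, keep the baseline `P_x`.
#'
#' @param lt a [life_table()].
#' @param fs a [fecundity_schedule()] (locates the breeding window).
#' @param s selection coefficient in `[0, 1]`.
#' @return `3 x k` matrix with rows `AA`, `AB`, `BB`.
#' @export
survival_with_selection <- function(lt, fs, s = 0) {
  stopifnot(inherits(lt, "life_table"))
  if (s < 0 || s > 1) stop("s must be in [0, 1]", call. = FALSE)
  Pmat <- matrix(lt$P, 3, lt$k, byrow = TRUE,
                 dimnames = list(c("AA", "AB", "BB"), NULL))
  if (s > 0) {
    repro <- reproductive_classes(fs)
    Pmat["BB", repro] <- Pmat["BB", repro] * (1 - s)
  }
  Pmat
}

#' Multinomial resampling of the newborn cohort
#'
#' Draws the genotypes of a fixed-size newborn cohort from Hardy-Weinberg
#' proportions `(p^2, 2pq, q^2)` at the parental allele frequency. This
#' single multinomial draw is the first of the simulator's two sources of
#' drift.
#'
#' @param p allele-A frequency among prospective newborns.
#' @param Nnb newborn cohort size (positive integer).
#' @return integer vector `c(AA, AB, BB)` summing to `Nnb`.
#' @export
resample_newborns <- function(p, Nnb) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (Nnb < 1) stop("Nnb must be a positive integer", call. = FALSE)
  drop(stats::rmultinom(1, Nnb, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
}

#' Stochastic between-class cull
#'
#' Applies one year of mortality to a single age class's genotype counts.
#' `"binomial"` mode thins each genotype independently with its survival
#' probability. `"faithful"` mode follows the two-part description of the
#' cull: the class shrinks deterministically to its expected survivor
#' total, a fraction `P` of which keeps its genotype identity while the
#' remainder is redrawn multinomially from the class's current genotype
#' frequencies.
#'
#' @param counts integer vector `c(AA, AB, BB)`.
#' @param P survival probabilities, scalar or per-genotype vector of 3.
#' @param cull_mode `"binomial"` or `"faithful"`.
#' @return integer vector of surviving counts.
#' @export
cull_age_class <- function(counts, P, cull_mode = c("binomial", "faithful")) {
  cull_mode <- match.arg(cull_mode)
  if (any(P < 0) || any(P > 1)) stop("P must be in [0, 1]", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  P <- rep_len(P, 3)
  if (cull_mode == "binomial")
    return(stats::rbinom(3, counts, P))
  expected <- P * counts
  total <- round(sum(expected))
  if (total == 0) return(c(0L, 0L, 0L))
  kept <- floor(mean(P) * expected)
  redraw <- total - sum(kept)
  if (redraw > 0)
    kept <- kept + drop(stats::rmultinom(1, redraw, expected / sum(expected)))
  as.integer(kept)
}

#' Heterozygosity of a newborn cohort
#'
#' `"expected"` mode returns `2p(1-p)` at the cohort's realized allele
#' frequency; `"observed"` returns the heterozygote fraction. The two agree
#' in the many-newborn limit.
#'
#' @param counts integer vector `c(AA, AB, BB)`.
#' @param het_mode `"expected"` or `"observed"`.
#' @return heterozygosity in `[0, 0.5]` (expected mode).
#' @export
heterozygosity <- function(counts, het_mode = c("expected", "observed")) {
  het_mode <- match.arg(het_mode)
  n <- sum(counts)
  if (n == 0) return(0)
  if (het_mode == "observed") return(counts[2] / n)
  p <- (counts[1] + counts[2] / 2) / n
  2 * p * (1 - p)
}

#' Simulate genetic drift in an age-structured population
#'
#' Two-stage yearly update, replicated independently. Each year: (1) the
#' allele frequency among prospective newborns is computed from the current
#' breeders by Mendelian segregation ([newborn_allele_freq()]) and a
#' fixed-size newborn cohort is drawn multinomially at Hardy-Weinberg
#' proportions ([resample_newborns()]); (2) every older class advances with
#' a stochastic cull at its (genotype-specific, under selection) survival
#' probability ([cull_age_class()]). The newborn cohort size is held
#' constant at the rounded newborn class of the stable age distribution.
#' Expected heterozygosity among newborns is recorded each year; once the
#' whole population is monomorphic the run is absorbed and records zeros
#' for the remaining years.
#'
#' @param lt a [life_table()].
#' @param fs a [fecundity_schedule()]; `config$shift` is applied to it
#'   before simulating.
#' @param config a [sim_config()].
#' @return object of class `trajectory_result`: list with `het`
#'   (`replicates x years` matrix), `mean_het`, `final` (last column),
#'   `final_summary` (see [summarize_trajectories()]), `final_p`
#'   (per-replicate newborn allele-A frequency at the last step; 0 or 1
#'   for fixed replicates), `fixation_time` (first year of whole-population
#'   monomorphism, `NA` if never), `Nnb`, `T`, `config`, and `rng`
#'   (algorithm metadata).
#' @export
#' @examples
#' lt <- life_table_type2(60)
#' fs <- gaussian_fecundity(lt)
#' res <- run_simulation(lt, fs, sim_config(years = 50, replicates = 20, seed = 7))
#' res$final_summary
run_simulation <- function(lt, fs, config = sim_config()) {
  stopifnot(inherits(lt, "life_table"), inherits(fs, "fecundity_schedule"),
            inherits(config, "sim_config"))
  if (config$shift != 0) fs <- shift_fecundity(lt, fs, config$shift)
  k <- lt$k
  L <- build_leslie(lt, fs)
  stable <- stable_age_distribution(L, N_total = config$N_total)
  class_totals <- pmax(round(stable), 0)
  Nnb <- as.integer(class_totals[1])
  if (Nnb < 1) stop("stable age distribution has no newborns (Nnb = 0)", call. = FALSE)
  Pmat <- survival_with_selection(lt, fs, config$s)
  f <- fs$f
  observed <- config$het_mode == "observed"
  binom <- config$cull_mode == "binomial"

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)

  het <- matrix(0, config$replicates, config$years)
  final_p <- numeric(config$replicates)
  fixation_time <- rep(NA_integer_, config$replicates)
  init <- hardy_weinberg_state(class_totals, config$p0)$counts
  for (r in seq_len(config$replicates)) {
    set.seed(rep_seeds[r])
    counts <- init
    p_now <- config$p0
    for (t in seq_len(config$years)) {
      w <- drop(counts %*% f)
      b <- sum(w)
      p_parent <- if (b > 0) (w[1] + w[2] / 2) / b else
        (sum(counts[1, ]) + sum(counts[2, ]) / 2) / max(sum(counts), 1)
      newborns <- resample_newborns(min(max(p_parent, 0), 1), Nnb)
      if (k > 1) {
        old <- counts[, -k, drop = FALSE]
        surv <- if (binom) {
          matrix(stats::rbinom(3L * (k - 1L), old, Pmat[, -k, drop = FALSE]),
                 nrow = 3)
        } else {
          vapply(seq_len(k - 1),
                 function(x) cull_age_class(old[, x], Pmat[, x], "faithful"),
                 numeric(3))
        }
        counts <- cbind(newborns, surv)
      } else {
        counts <- matrix(newborns, 3, 1)
      }
      p_now <- (newborns[1] + newborns[2] / 2) / Nnb
      het[r, t] <- if (observed) newborns[2] / Nnb else 2 * p_now * (1 - p_now)
      # absorbed: no heterozygotes and only one homozygote class left
      if (sum(counts[2, ]) == 0 &&
          (sum(counts[1, ]) == 0 || sum(counts[3, ]) == 0)) {
        fixation_time[r] <- t
        p_now <- if (sum(counts[3, ]) == 0) 1 else 0
        # het among newborns is already 0; remaining years stay fixed
        break
      }
    }
    final_p[r] <- p_now
  }
  mean_het <- colMeans(het)
  structure(list(
    het = het, mean_het = mean_het, final = het[, config$years],
    final_summary = .final_summary(het[, config$years]),
    final_p = final_p, fixation_time = fixation_time,
    Nnb = Nnb, T = net_reproduction(lt, fs)$T,
    class_totals = class_totals, config = config,
    rng = list(kind = RNGkind()[1], replicate_seeds = "sample.int from root seed")
  ), class = "trajectory_result")
}

.final_summary <- function(final) {
  q <- stats::quantile(final, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  data.frame(mean = mean(final), q1 = q[1], median = q[2], q3 = q[3],
             notch = 1.58 * iqr / sqrt(length(final)))
}

#' @export
print.trajectory_result <- function(x, ...) {
  cfg <- x$config
  cat("Drift simulation:", cfg$replicates, "replicates x", cfg$years, "years",
      "(N =", cfg$N_total, ", Nnb =", x$Nnb, ", T =", signif(x$T, 3), ")\n")
  cat("  s =", cfg$s, " shift =", cfg$shift, " p0 =", cfg$p0, "\n")
  cat("  final heterozygosity: median", signif(x$final_summary$median, 4),
      "mean", signif(x$final_summary$mean, 4), "\n")
  invisible(x)
}

#' Implied effective size from a heterozygosity trajectory
#'
#' Fits the geometric decay `H_t = H_0 * rho^t` by least squares on the log
#' scale and inverts the per-step retention rate through
#' `rho = 1 - 1/(2 Ne)`. Zero or negative entries (fixed replicates) are
#' excluded from the fit.
#'
#' @param het numeric heterozygosity series (e.g. `mean_het` of a
#'   [run_simulation()] result).
#' @return list with `rho` (per-step retention), `Ne_implied`.
#' @export
fit_implied_ne <- function(het) {
  t <- seq_along(het)
  keep <- is.finite(het) & het > 0
  if (sum(keep) < 2) stop("need at least two positive heterozygosity values", call. = FALSE)
  fit <- stats::lm(log(het[keep]) ~ t[keep])
  rho <- exp(unname(stats::coef(fit)[2]))
  list(rho = rho,
       Ne_implied = if (rho < 1) 1 / (2 * (1 - rho)) else Inf)
}

#' Summarize and compare drift trajectories
#'
#' One row per named [run_simulation()] result: final-time quartiles,
#' median, notch half-width (`1.58 * IQR / sqrt(n)`, the standard notched
#' boxplot 95% interval for the median), mean, plus the fitted per-year
#' heterozygosity retention rate and its implied effective size.
#'
#' @param ... named `trajectory_result` objects (or one named list of them).
#' @return a `data.frame`, one row per result.
#' @export
summarize_trajectories <- function(...) {
  results <- list(...)
  if (length(results) == 1 && !inherits(results[[1]], "trajectory_result"))
    results <- results[[1]]
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "trajectory_result")))
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("run", seq_along(results))
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    fit <- tryCatch(fit_implied_ne(r$mean_het),
                    error = function(e) list(rho = NA_real_, Ne_implied = NA_real_))
    cbind(data.frame(run = nm[i], T = r$T, Nnb = r$Nnb,
                     s = r$config$s, shift = r$config$shift),
          r$final_summary,
          data.frame(rho = fit$rho, Ne_implied = fit$Ne_implied))
  }))
}
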