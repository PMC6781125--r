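#' Life expectancy at birth
#'
#' Discrete approximation of the integral of survivorship over age. With the
#' default `"rectangle"` rule this is the plain sum of `l_x` over the
#' one-year classes (the convention for 1-year life tables); the
#' `"trapezoid"` rule averages adjacent classes and converges faster for
#' smooth underlying hazards.
#'
#' @param lt a [life_table()].
#' @param rule quadrature rule, `"rectangle"` (default) or `"trapezoid"`.
#' @return life expectancy `e0` in years.
#' @export
#' @examples
#' life_expectancy(life_table(c(1, 0.5)))  # 1.5
life_expectancy <- function(lt, rule = c("rectangle", "trapezoid")) {
  stopifnot(inherits(lt, "life_table"))
  rule <- match.arg(rule)
  .lx_sum(lt$l, rule)
}

.lx_sum <- function(v, rule) {
  if (rule == "rectangle" || length(v) == 1) sum(v)
  else sum((v[-1] + v[-length(v)]) / 2)
}

#' Keyfitz entropy and lifespan equality
#'
#' Keyfitz's life-table entropy
#' `H = -sum(log(l_x) * l_x) / sum(l_x) = edag / e0`
#' measures the shape of the survivorship curve: 0 for a rectangular curve
#' (all deaths at one age), 1 for an exponential (constant-mortality) curve.
#' Lifespan equality is `log(1 / H)`. Classes with zero survivorship are
#' excluded from the integrand (the `l * log(l)` term vanishes there).
#'
#' @inheritParams life_expectancy
#' @return list with `H`, `edag` (life expectancy lost to death, years),
#'   `equality` (`log(1/H)`) and `e0`.
#' @export
keyfitz_entropy <- function(lt, rule = c("rectangle", "trapezoid")) {
  stopifnot(inherits(lt, "life_table"))
  rule <- match.arg(rule)
  if (lt$k < 2)
    stop("entropy is undefined for a single-class table", call. = FALSE)
  l <- lt$l
  g <- ifelse(l > 0, -log(pmax(l, .Machine$double.xmin)) * l, 0)
  e0 <- .lx_sum(l, rule)
  edag <- .lx_sum(g, rule)
  H <- edag / e0
  list(H = H, edag = edag, equality = if (H > 0) log(1 / H) else Inf, e0 = e0)
}

#' Longevity and the shape of ageing
#'
#' The longevity `omega` is the age by which a given fraction (default 95%)
#' of adults have died: the smallest age `x` with
#' `l_x / l_maturity <= 1 - quantile`. The ratio `omega / e0` is a standard
#' "shape" score: 1 for rectangular survival, larger when mortality is
#' spread over a long tail. If the curve never crosses the threshold inside
#' the table, the last age is returned with a warning (the longevity is
#' right-censored).
#'
#' "Adults" default to survivors at the first age with appreciable
#' fecundity (`m > 0.001 * max(m)`) when a schedule is supplied, else age 1.
#'
#' @param lt a [life_table()].
#' @param quantile fraction of adult deaths defining longevity (default 0.95).
#' @param maturity_age age class marking adulthood; overrides `fs`.
#' @param fs optional [fecundity_schedule()] used to locate maturity.
#' @param rule quadrature rule passed to [life_expectancy()].
#' @return list with `omega` (years), `shape` (`omega / e0`), `maturity_age`.
#' @export
longevity_omega <- function(lt, quantile = 0.95, maturity_age = NULL,
                            fs = NULL, rule = c("rectangle", "trapezoid")) {
  stopifnot(inherits(lt, "life_table"))
  rule <- match.arg(rule)
  if (quantile < 0 || quantile > 1) stop("quantile must be in [0, 1]", call. = FALSE)
  if (is.null(maturity_age)) {
    maturity_age <- if (!is.null(fs)) reproductive_classes(fs)[1] else 1L
  }
  if (maturity_age < 1 || maturity_age > lt$k || lt$l[maturity_age] <= 0)
    stop("no survivors at the requested maturity age", call. = FALSE)
  rel <- lt$l / lt$l[maturity_age]
  hit <- which(lt$ages >= maturity_age & rel <= 1 - quantile + 1e-12)
  if (length(hit)) {
    omega <- lt$ages[hit[1]]
  } else {
    warning("survivorship never falls below the longevity threshold; ",
            "returning the table's last age")
    omega <- lt$ages[lt$k]
  }
  e0 <- life_expectancy(lt, rule)
  list(omega = omega, shape = omega / e0, maturity_age = maturity_age)
}

#' Net reproductive rate, generation time and intrinsic growth
#'
#' `R0 = sum(l_x * m_x)` is the expected number of daughters per newborn
#' female per generation; the generation time
#' `T = sum(x * l_x * m_x) / sum(l_x * m_x)` is the mean age of the mothers
#' of newborns; the intrinsic growth rate is `r = log(R0) / T`. For a
#' normalized schedule `R0 = 1` and hence `r = 0`.
#'
#' @param lt a [life_table()].
#' @param fs a [fecundity_schedule()].
#' @return list with `R0`, `T` (years) and `r` (per year).
#' @export
net_reproduction <- function(lt, fs) {
  stopifnot(inherits(lt, "life_table"), inherits(fs, "fecundity_schedule"))
  w <- lt$l * fs$m
  R0 <- sum(w)
  if (R0 <= 0) stop("no reproductive overlap: sum(l * m) = 0", call. = FALSE)
  Tgen <- sum(lt$ages * w) / R0
  list(R0 = R0, T = Tgen, r = log(R0) / Tgen)
}

#' Which age classes breed
#'
#' Classes whose birth rate exceeds a small fraction of the peak rate; used
#' to delimit "breeding individuals" for viability selection and to locate
#' maturity for the longevity ratio.
#'
#' @param fs a [fecundity_schedule()].
#' @param threshold fraction of the peak birth rate (default 0.001).
#' @return integer vector of age classes.
#' @export
reproductive_classes <- function(fs, threshold = 0.001) {
  stopifnot(inherits(fs, "fecundity_schedule"))
  which(fs$m > threshold * max(fs$m))
}

#' Reproductive value by age
#'
#' Two readings are provided. `"fisher"` (default) is Fisher's reproductive
#' value under stationarity, `v_x = sum_{i >= x} l_i m_i / l_x`: the expected
#' future daughters of a female currently of age `x`, in units of her
#' survivorship. `"as_printed"` evaluates the sum from `i = 1`, which
#' collapses to `R0 / l_x`; it is retained because some presentations of the
#' age-structured effective-size formula print the lower bound that way.
#' Classes with `l = 0` get `v = 0`.
#'
#' @param lt a [life_table()].
#' @param fs a [fecundity_schedule()].
#' @param v_mode `"fisher"` or `"as_printed"`.
#' @return numeric vector `v` of length `k`, with the mode in
#'   `attr(v, "v_mode")`.
#' @export
reproductive_value <- function(lt, fs, v_mode = c("fisher", "as_printed")) {
  stopifnot(inherits(lt, "life_table"), inherits(fs, "fecundity_schedule"))
  v_mode <- match.arg(v_mode)
  w <- lt$l * fs$m
  num <- if (v_mode == "fisher") rev(cumsum(rev(w))) else rep(sum(w), lt$k)
  v <- ifelse(lt$l > 0, num / lt$l, 0)
  attr(v, "v_mode") <- v_mode
  v
}

#' Felsenstein's effective population size for overlapping generations
#'
#' Computes
#' `Ne = Nnb * T / (1 + sum_{x=1}^{k} l_x * s_x * d_x * v_{x+1}^2)`
#' where `Nnb` is the yearly number of newborns, `T` the generation time,
#' `d_x` the death fraction between classes and `v` the reproductive value
#' (`v_{k+1} = 0`, there being no class beyond the last). When the summed
#' term vanishes (no deaths before the terminal class) `Ne = Nnb * T`.
#'
#' The weighting term `s_x` admits two readings, both exposed:
#' `"survival"` (default) uses the per-class survival probability `P_x`,
#' Felsenstein's original formulation, which reproduces the canonical
#' behavior of Ne against generation time (linear for Type-I survivorship,
#' plateauing for Type-II); `"counts"` uses the stable-age female count
#' `n_x`, the literal reading of `s_x` as "the number of females that
#' survive each age class".
#'
#' @param lt a [life_table()].
#' @param fs a [fecundity_schedule()].
#' @param N_total census female population size used to scale the stable age
#'   distribution (default 1000).
#' @param Nnb number of newborn females per year; by default the newborn
#'   class of the stable age distribution at size `N_total`.
#' @param s_mode `"survival"` or `"counts"` (see Details).
#' @param v_mode passed to [reproductive_value()].
#' @return `Ne` (individuals), with attributes `Nnb`, `T`, `s_mode`,
#'   `v_mode`.
#' @export
#' @examples
#' lt <- life_table_type2(80)
#' fs <- gaussian_fecundity(lt)
#' felsenstein_ne(lt, fs, N_total = 1000)
felsenstein_ne <- function(lt, fs, N_total = 1000, Nnb = NULL,
                           s_mode = c("survival", "counts"),
                           v_mode = c("fisher", "as_printed")) {
  stopifnot(inherits(lt, "life_table"), inherits(fs, "fecundity_schedule"))
  s_mode <- match.arg(s_mode)
  v_mode <- match.arg(v_mode)
  if (N_total <= 0) stop("N_total must be positive", call. = FALSE)
  counts <- NULL
  if (is.null(Nnb) || s_mode == "counts") {
    counts <- stable_age_distribution(build_leslie(lt, fs), N_total = N_total)
    if (is.null(Nnb)) Nnb <- counts[1]
  }
  if (Nnb <= 0) stop("Nnb must be positive", call. = FALSE)
  Tgen <- net_reproduction(lt, fs)$T
  d <- c(death_fractions(lt), lt$l[lt$k])       # terminal class all die
  v <- reproductive_value(lt, fs, v_mode)
  v_next <- c(v[-1], 0)                         # v_{k+1} = 0
  s <- if (s_mode == "survival") lt$P else counts
  denom <- 1 + sum(lt$l * s * d * v_next^2)
  if (denom <= 0)
    stop("invalid configuration: non-positive denominator in the ",
         "effective-size formula", call. = FALSE)
  ne <- Nnb * Tgen / denom
  structure(ne, Nnb = Nnb, T = Tgen, s_mode = s_mode, v_mode = v_mode)
}

#' One-row demographic summary of a population configuration
#'
#' Bundles the pace/shape descriptors and the effective size for one
#' life table + fecundity schedule pair.
#'
#' @inheritParams felsenstein_ne
#' @param rule quadrature rule for the entropy/life-expectancy integrals.
#' @param quantile adult-death fraction for the longevity ratio.
#' @return a one-row `data.frame` with columns `e0`, `edag`, `H`,
#'   `equality`, `omega`, `shape`, `R0`, `T`, `r`, `Nnb`, `Ne`, `s_mode`,
#'   `v_mode`.
#' @export
demography_summary <- function(lt, fs, N_total = 1000,
                               s_mode = c("survival", "counts"),
                               v_mode = c("fisher", "as_printed"),
                               rule = c("rectangle", "trapezoid"),
                               quantile = 0.95) {
  ke <- keyfitz_entropy(lt, rule = match.arg(rule))
  om <- longevity_omega(lt, quantile = quantile, fs = fs, rule = match.arg(rule))
  nr <- net_reproduction(lt, fs)
  ne <- felsenstein_ne(lt, fs, N_total = N_total,
                       s_mode = match.arg(s_mode), v_mode = match.arg(v_mode))
  data.frame(
    e0 = ke$e0, edag = ke$edag, H = ke$H, equality = ke$equality,
    omega = om$omega, shape = om$shape,
    R0 = nr$R0, T = nr$T, r = nr$r,
    Nnb = attr(ne, "Nnb"), Ne = as.numeric(ne),
    s_mode = attr(ne, "s_mode"), v_mode = attr(ne, "v_mode"),
    stringsAsFactors = FALSE
  )
}
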