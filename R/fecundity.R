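#' Age-specific fecundity schedules
#'
#' A `fecundity_schedule` pairs per-age birth rates of daughters `m_x` with a
#' [life_table()]. Under the post-breeding birth-pulse census the effective
#' fecundity of class `x` is `f_x = P_{x-1} * m_x`, i.e. the birth rate
#' discounted by survival into the class (survival into the newborn class is
#' 1). Schedules are normalized by default so the net reproductive rate
#' `R0 = sum(l_x * m_x)` equals 1, which holds population size stationary.
#'
#' @param lt a [life_table()].
#' @param m numeric vector of per-age daughter birth rates (length `lt$k`,
#'   non-negative).
#' @param normalize rescale `m` so that `sum(l * m) = 1` (default `TRUE`).
#' @param mean,sd optional generating Gaussian parameters, recorded so that
#'   [shift_fecundity()] can re-evaluate the smooth curve rather than roll
#'   the discretized one.
#' @param shift displacement in years already applied (bookkeeping field).
#' @return An object of class `fecundity_schedule` with components `m`, `f`,
#'   `shift` and (when known) `mean`, `sd`.
#' @export
#' @examples
#' lt <- life_table_type2(60)
#' fs <- gaussian_fecundity(lt, mean = 27, sd = 7)
#' sum(lt$l * fs$m)  # 1
fecundity_schedule <- function(lt, m, normalize = TRUE,
                               mean = NA_real_, sd = NA_real_, shift = 0) {
  stopifnot(inherits(lt, "life_table"))
  m <- as.numeric(m)
  if (length(m) != lt$k)
    stop("fecundity vector length must match the life table (", lt$k, ")", call. = FALSE)
  if (any(m < 0)) stop("fecundity rates must be non-negative", call. = FALSE)
  if (normalize) {
    r0 <- sum(lt$l * m)
    if (r0 <= 0)
      stop("fecundity has no overlap with positive survivorship; cannot normalize",
           call. = FALSE)
    m <- m / r0
  }
  # effective fecundity: survival into class x times birth rate at x
  f <- m * c(1, lt$P[-lt$k])
  structure(list(m = m, f = f, shift = shift, mean = mean, sd = sd),
            class = "fecundity_schedule")
}

#' @export
print.fecundity_schedule <- function(x, ...) {
  cat("Fecundity schedule over", length(x$m), "age classes")
  if (!is.na(x$mean)) cat(" (Gaussian, mean ", x$mean, ", sd ", x$sd, ")", sep = "")
  if (x$shift != 0) cat(", shifted", x$shift, "years")
  cat("\n  peak birth rate", signif(max(x$m), 4), "at age", which.max(x$m), "\n")
  invisible(x)
}

#' Gaussian fecundity schedule
#'
#' Births follow a Gaussian-shaped curve over age, evaluated at integer ages
#' and truncated to the life table's range. The defaults (mean 27 y, sd 7 y)
#' mimic a modern human female reproductive distribution. The result is
#' normalized so `sum(l * m) = 1`.
#'
#' @param lt a [life_table()].
#' @param mean mean of the reproductive distribution, years.
#' @param sd standard deviation, years (> 0).
#' @return A [fecundity_schedule()].
#' @export
gaussian_fecundity <- function(lt, mean = 27, sd = 7) {
  stopifnot(inherits(lt, "life_table"))
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  m <- stats::dnorm(lt$ages, mean, sd)
  fecundity_schedule(lt, m, mean = mean, sd = sd)
}

#' Normalize a fecundity schedule to net reproductive rate 1
#'
#' Rescales `m` by the single factor `1 / sum(l * m)` so the population is
#' stationary (`R0 = 1`, intrinsic growth `r = 0`). Idempotent.
#'
#' @param lt a [life_table()].
#' @param fs a [fecundity_schedule()] (or a plain numeric `m` vector).
#' @return A normalized [fecundity_schedule()].
#' @export
normalize_fecundity <- function(lt, fs) {
  if (!inherits(fs, "fecundity_schedule"))
    return(fecundity_schedule(lt, fs))
  fecundity_schedule(lt, fs$m, mean = fs$mean, sd = fs$sd, shift = fs$shift)
}

#' Shift a reproductive distribution in time
#'
#' Displaces the schedule by `delta` whole years (positive = later breeding).
#' Schedules generated by [gaussian_fecundity()] are re-evaluated from the
#' shifted Gaussian mean, so the smooth curve slides along the age axis;
#' other schedules are index-shifted. Mass falling outside classes
#' `1..k` is truncated and the result is re-normalized to `R0 = 1`, so the
#' realized generation time compresses near the boundaries.
#'
#' @param lt a [life_table()].
#' @param fs a [fecundity_schedule()].
#' @param delta displacement in years (signed).
#' @return A shifted, normalized [fecundity_schedule()].
#' @export
#' @examples
#' lt <- make_type1_modern()
#' fs <- gaussian_fecundity(lt)
#' net_reproduction(lt, shift_fecundity(lt, fs, -20))$T  # early breeders
shift_fecundity <- function(lt, fs, delta) {
  stopifnot(inherits(lt, "life_table"), inherits(fs, "fecundity_schedule"))
  if (delta == 0) return(fs)
  if (abs(delta) >= lt$k)
    stop("shift exceeds the age range of the table", call. = FALSE)
  if (!is.na(fs$mean)) {
    m <- stats::dnorm(lt$ages, fs$mean + delta, fs$sd)
    return(fecundity_schedule(lt, m, mean = fs$mean + delta, sd = fs$sd,
                              shift = fs$shift + delta))
  }
  d <- as.integer(round(delta))
  m <- rep(0, lt$k)
  src <- seq_len(lt$k) - d
  ok <- src >= 1 & src <= lt$k
  m[ok] <- fs$m[src[ok]]
  if (sum(lt$l * m) <= 0)
    stop("shift leaves no reproductive mass inside the age range", call. = FALSE)
  fecundity_schedule(lt, m, shift = fs$shift + delta)
}
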