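#' Construct a one-year-class life table
#'
#' A `life_table` stores female survivorship over discrete one-year age
#' classes. Classes are 1-based: class 1 is the newborn class and carries
#' survivorship 1 by convention. `l[x]` is the probability of surviving from
#' birth to class `x`; `P[x]` is the probability that an individual in class
#' `x` survives to class `x + 1`. The last class is terminal (`P[k] = 0`):
#' anyone reaching it dies before class `k + 1`.
#'
#' @param l numeric vector of survivorship values, non-increasing, `l[1] = 1`.
#' @param n optional per-class female counts consistent with `l`
#'   (`l = n / n[1]`).
#' @param extra optional data frame of per-class annotations (carried through
#'   CSV round trips untouched).
#'
#' @return An object of class `life_table` with components `k` (number of
#'   classes), `ages` (integer years `1:k`), `l`, `P` and optionally `n` and
#'   `extra`.
#' @seealso [life_table_from_counts()], [life_table_type2()],
#'   [life_table_type3()], [read_life_table()]
#' @export
#' @examples
#' lt <- life_table(c(1, 0.9, 0.81))
#' lt$P
life_table <- function(l, n = NULL, extra = NULL) {
  l <- as.numeric(l)
  k <- length(l)
  if (k < 1) stop("life table needs at least one age class", call. = FALSE)
  if (any(!is.finite(l))) stop("survivorship contains non-finite values", call. = FALSE)
  if (abs(l[1] - 1) > 1e-9)
    stop("newborn class must have survivorship 1 (got ", l[1], ")", call. = FALSE)
  if (any(l < 0)) stop("survivorship must be non-negative", call. = FALSE)
  rising <- which(diff(l) > 1e-12)
  if (length(rising))
    stop("survivorship must be non-increasing; it rises at row(s) ",
         paste(rising + 1, collapse = ", "), call. = FALSE)
  P <- rep(0, k)
  if (k > 1) {
    ok <- l[-k] > 0
    P[-k][ok] <- l[-1][ok] / l[-k][ok]
  }
  lt <- structure(
    list(k = k, ages = seq_len(k), l = l, P = P),
    class = "life_table"
  )
  if (!is.null(n)) {
    n <- as.numeric(n)
    if (length(n) != k) stop("counts length must match survivorship", call. = FALSE)
    if (max(abs(l - n / n[1])) > 1e-9)
      stop("counts inconsistent with survivorship (l != n/n[1])", call. = FALSE)
    lt$n <- n
  }
  if (!is.null(extra)) lt$extra <- as.data.frame(extra)
  lt
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table:", x$k, "one-year age classes\n")
  cat("  survivorship: l[1] = 1 ... l[", x$k, "] = ", signif(x$l[x$k], 4), "\n", sep = "")
  cat("  crude life expectancy (sum of l):", signif(sum(x$l), 5), "years\n")
  invisible(x)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  df <- data.frame(age = x$ages, l = x$l)
  if (!is.null(x$n)) df$n <- x$n
  if (!is.null(x$extra)) df <- cbind(df, x$extra)
  df
}

#' Life table from cohort counts
#'
#' Converts per-age female counts `n_x` into survivorship `l_x = n_x / n_1`.
#'
#' @param counts numeric vector of non-negative, non-increasing cohort counts;
#'   the first entry (newborns) must be positive.
#' @return A [life_table()] carrying both `l` and `n`.
#' @export
#' @examples
#' life_table_from_counts(c(200, 100, 50, 25))$l
life_table_from_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("empty count vector", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (counts[1] <= 0) stop("newborn count must be positive", call. = FALSE)
  if (any(diff(counts) > 1e-9))
    stop("counts increase with age; a closed cohort cannot grow", call. = FALSE)
  life_table(counts / counts[1], n = counts)
}

#' Idealized Type-II (constant mortality) life table
#'
#' Survivorship declines geometrically: `l[x + 1] = (1 - mortality) * l[x]`,
#' the discrete analogue of an exponential survival curve. The default 10%
#' yearly mortality approximates a wild chimpanzee population.
#'
#' @param k number of age classes (>= 2).
#' @param mortality per-year death probability, strictly between 0 and 1.
#' @return A [life_table()].
#' @export
#' @examples
#' life_table_type2(3)$l   # 1, 0.9, 0.81
life_table_type2 <- function(k, mortality = 0.1) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (mortality <= 0 || mortality >= 1)
    stop("mortality must lie strictly between 0 and 1", call. = FALSE)
  life_table(cumprod(c(1, rep(1 - mortality, k - 1))))
}

#' Idealized Type-III (heavy early mortality) life table
#'
#' Power-law survivorship `l_x = x^-exponent`, anchored so the newborn class
#' (x = 1) has survivorship 1. The default exponent 2.126 gives the steep
#' juvenile decline typical of trees and insects.
#'
#' @param k number of age classes (>= 2).
#' @param exponent positive power-law exponent.
#' @return A [life_table()].
#' @export
life_table_type3 <- function(k, exponent = 2.126) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (exponent <= 0) stop("exponent must be positive", call. = FALSE)
  life_table(seq_len(k)^(-exponent))
}

#' Per-class death fractions
#'
#' Returns `d_x = l_x - l_{x+1}` for the `k - 1` between-class transitions:
#' the fraction of the original cohort dying between class `x` and `x + 1`.
#' Because the last class is terminal, the remaining fraction `l_k` dies
#' there, so `sum(d) + l[k] = 1`.
#'
#' @param lt a [life_table()].
#' @return numeric vector of length `k - 1` (empty for a one-class table).
#' @export
#' @examples
#' death_fractions(life_table(c(1, 0.9, 0.81)))  # 0.1, 0.09
death_fractions <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  if (lt$k < 2) return(numeric(0))
  lt$l[-lt$k] - lt$l[-1]
}

#' Read / write life-table CSV files
#'
#' The on-disk dialect is a plain UTF-8 CSV with a header row, an `age`
#' column (integer years) and at least one of `l` (survivorship) or `n`
#' (female counts). An optional `m` column carries per-age fecundity and any
#' further columns are preserved as annotations, so archived life-table files
#' with extra bookkeeping columns read cleanly.
#'
#' @param path file path.
#' @return `read_life_table()` returns a [life_table()]; a fecundity column,
#'   when present, is available as `lt$extra$m`. `write_life_table()` returns
#'   `path` invisibly.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!"age" %in% names(df))
    stop("life-table CSV must have an 'age' column: ", path, call. = FALSE)
  if (!any(c("l", "n") %in% names(df)))
    stop("life-table CSV must have an 'l' or 'n' column: ", path, call. = FALSE)
  num_cols <- intersect(c("age", "l", "n", "m"), names(df))
  bad <- num_cols[!vapply(df[num_cols], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df <- df[order(df$age), , drop = FALSE]
  extra <- df[setdiff(names(df), c("age", "l", "n"))]
  if (!ncol(extra)) extra <- NULL
  if ("l" %in% names(df)) {
    life_table(df$l, n = if ("n" %in% names(df)) df$n else NULL, extra = extra)
  } else {
    lt <- life_table_from_counts(df$n)
    if (!is.null(extra)) lt$extra <- extra
    lt
  }
}

#' @param lt a [life_table()] to write.
#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
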