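#' Synthetic survivorship families
#'
#' Parametric generators for the survivorship curve shapes the analysis
#' contrasts. Hazards are piecewise: a constant background rate, an
#' optional exponentially decaying juvenile excess, and a Gompertz-type
#' senescent rise after an onset age,
#' `mu(x) = background + juvenile * exp(-x / juvenile_scale) +
#'  senescence * exp(steepness * (x - onset))` (senescent term active from
#' `onset` on). Survivorship is `l_x = exp(-cumsum(mu))` anchored at
#' `l_1 = 1`. The generators are deterministic given their parameters.
#'
#' `make_type1_modern()` emulates a modern industrialized female cohort:
#' near-flat survival through the reproductive span, then a rapid
#' senescent decline from late middle age. `make_type1_preindustrial()`
#' adds elevated juvenile mortality and a higher background rate, the
#' shape of pre-industrial and hunter-gatherer populations; with
#' `juvenile = 0` and matching parameters it reduces exactly to the modern
#' family.
#'
#' @param k number of age classes.
#' @param background constant per-year hazard at all ages.
#' @param onset age at which the senescent hazard switches on (< `k`).
#' @param senescence senescent hazard at the onset age.
#' @param steepness exponential growth rate of the senescent hazard per year.
#' @param juvenile excess hazard at age 1 (decays with `juvenile_scale`).
#' @param juvenile_scale e-folding age of the juvenile excess, years.
#' @return A [life_table()].
#' @name synthetic_life_tables
NULL

.hazard_life_table <- function(k, background, onset, senescence, steepness,
                               juvenile = 0, juvenile_scale = 3) {
  if (onset > k) onset <- k  # senescence beyond the table: no senescent term
  x <- seq_len(k)
  mu <- background +
    juvenile * exp(-x / juvenile_scale) +
    ifelse(x >= onset, senescence * exp(steepness * (x - onset)), 0)
  l <- exp(-c(0, cumsum(mu[-k])))
  life_table(l)
}

#' @rdname synthetic_life_tables
#' @export
make_type1_modern <- function(k = 101, background = 0.001, onset = 55,
                              senescence = 0.01, steepness = 0.12) {
  if (onset < 1) stop("onset must be >= 1", call. = FALSE)
  .hazard_life_table(k, background, onset, senescence, steepness)
}

#' @rdname synthetic_life_tables
#' @export
make_type1_preindustrial <- function(k = 101, juvenile = 0.15,
                                     juvenile_scale = 3, background = 0.004,
                                     onset = 50, senescence = 0.012,
                                     steepness = 0.11) {
  if (onset < 1) stop("onset must be >= 1", call. = FALSE)
  .hazard_life_table(k, background, onset, senescence, steepness,
                     juvenile = juvenile, juvenile_scale = juvenile_scale)
}

#' Analytic and idealized life-table fixtures
#'
#' Convenience dispatcher over the survivorship families used throughout
#' the package and its tests: `"rectangular"` (survivorship 1 at every
#' class, all deaths in the terminal class; `e0 = k`, Keyfitz entropy 0),
#' `"exponential"`/`"type2"` (constant mortality, [life_table_type2()]),
#' `"type3"` ([life_table_type3()]), `"type1_modern"` and
#' `"type1_preindustrial"` (the parametric families above).
#'
#' @param family fixture family name.
#' @param k number of age classes.
#' @param ... passed to the underlying generator (e.g. `mortality`,
#'   `exponent`).
#' @return A [life_table()].
#' @export
#' @examples
#' life_expectancy(make_fixture("rectangular", 50))  # 50
make_fixture <- function(family = c("rectangular", "exponential", "type2",
                                    "type3", "type1_modern",
                                    "type1_preindustrial"),
                         k = 101, ...) {
  family <- match.arg(family)
  switch(family,
         rectangular = life_table(rep(1, k)),
         exponential = life_table_type2(k, ...),
         type2 = life_table_type2(k, ...),
         type3 = life_table_type3(k, ...),
         type1_modern = make_type1_modern(k, ...),
         type1_preindustrial = make_type1_preindustrial(k, ...))
}

#' The three headline study populations
#'
#' Named list of the synthetic life tables standing in for the three
#' populations the drift analysis contrasts: a modern Type-I cohort, a
#' pre-industrial Type-I cohort, and the constant-mortality Type-II
#' population.
#'
#' @param k number of age classes (default 101).
#' @return named list of [life_table()] objects
#'   (`modern`, `preindustrial`, `type2`).
#' @export
study_populations <- function(k = 101) {
  list(modern = make_type1_modern(k),
       preindustrial = make_type1_preindustrial(k),
       type2 = life_table_type2(k))
}
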