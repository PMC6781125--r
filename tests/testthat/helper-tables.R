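# Random valid small life tables + schedules for property-style tests.
random_life_table <- function(k = sample(3:8, 1)) {
  P <- runif(k - 1, 0.3, 0.99)
  life_table(cumprod(c(1, P)))
}

random_schedule <- function(lt) {
  m <- runif(lt$k, 0, 1)
  m[1] <- 0
  fecundity_schedule(lt, m)
}

flat_table <- function(k) life_table(rep(1, k))
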