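# shared fixtures built in code

# hand sums of the published variance-component tables
EX1_C <- 0.90760 + 0.88789 + 0.00000 + 1.06201 + 1.52630 + 0.00000  # 4.38380
EX1_P <- 0.00000 + 0.00000 + 0.00004 + 0.00000 + 0.00000 + 0.00029  # 0.00033
EX2_C <- 0.00000 + 0.00142 + 0.00118 + 0.00749 + 0.00000 + 0.00258  # 0.01267
EX2_P <- 0.01096 + 0.00524 + 0.00048 + 0.00447 + 0.00000 + 0.00000  # 0.02115

ex1_profile <- function() precision_profile(published_components("thiamphenicol_milk"))
ex2_profile <- function() precision_profile(published_components("clopidol_egg"))

# fits are expensive enough to share across tests within a file run
ex_fit <- local({
  memo <- list()
  function(name) {
    if (is.null(memo[[name]]))
      memo[[name]] <<- fit_uncertainty_model(validation_example(name))
    memo[[name]]
  }
})

toy_validation <- function(n_blocks = 4, x = c(1, 10), seed = 1) {
  set.seed(seed)
  d <- expand.grid(block = sprintf("b%d", seq_len(n_blocks)), known_x = x,
                   stringsAsFactors = FALSE)
  d$oper <- ifelse(d$block %in% c("b1", "b2"), "day", "night")
  d$y <- d$known_x + rnorm(nrow(d), 0, 0.05 * d$known_x)
  validation_data(d, factors = "oper")
}

# brute-force oracle: the uncertainty interval as the set of measurands
# whose prediction band covers ym, scanned on a fine grid
grid_interval <- function(ym, rng, ymax, n = 20001) {
  g <- seq(0, ymax, length.out = n)
  pl <- prediction_limits(rng, g)
  inside <- pl$lower <= ym & ym <= pl$upper
  c(min(g[inside]), max(g[inside]))
}
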