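# Small deterministic fixtures built in code.

# Toy table with a left-censored covariate and explicit flags. Donor values
# are free (not forced above the threshold) so donor-based methods can be
# exercised on hand-made cases.
toy_bloq_table <- function() {
  data.frame(
    y = c(10.2, 11.5, 9.8, 12.1, 10.9, 11.7, 9.5, 12.4),
    age = c(50, 52, 54, 56, 51, 53, 55, 57),
    sexmale = c(0, 1, 0, 1, 0, 1, 0, 1),
    crp = c(0.6, 0.9, 0.8, 1.0, 0.6, 0.7, 0.85, 0.95),
    crp_censored = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}

# A calibrated Model 1 / S1 spec shared across tests (memoised per session).
cached_m1_spec <- local({
  memo <- new.env(parent = emptyenv())
  function(setting = "S1", r2 = 0.6) {
    key <- paste(setting, r2)
    if (is.null(memo[[key]])) {
      spec <- model1_spec(setting)
      spec$sigma <- calibrate_sigma(spec, r2, pop_seed = 8101)
      memo[[key]] <- spec
    }
    memo[[key]]
  }
})

cached_m2_spec <- local({
  memo <- new.env(parent = emptyenv())
  function(setting = "S1", r2 = 0.6) {
    key <- paste(setting, r2)
    if (is.null(memo[[key]])) {
      spec <- model2_spec(setting)
      spec$sigma <- calibrate_sigma(spec, r2, pop_seed = 8102)
      memo[[key]] <- spec
    }
    memo[[key]]
  }
})

all_m1_methods <- c("discard", "sub_zero", "sub_lloq", "sub_half",
                    "sub_sqrt2", "knn", "kde", "two_compartment")
all_m2_methods <- c("discard", "sub_zero", "sub_lloq", "sub_half",
                    "sub_sqrt2", "knn", "kde", "tobit")
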