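# Shared fixtures built in code.

# Worked-example inputs bundled with the package: features measured on a
# third system plus reference libraries from a UPLC and an HPLC setup.
example_features <- function() {
  read_feature_table(system.file("extdata", "example_features.csv",
                                 package = "napsri"))
}

example_library <- function(which = c("uplc", "hplc")) {
  which <- match.arg(which)
  df <- utils::read.csv(system.file("extdata",
                                    sprintf("example_library_%s.csv", which),
                                    package = "napsri"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  df
}

# Deterministic NAPS anchor set on the reference system: C1-C3 pile up at
# the void volume, later homologues spread over the gradient.
naps_anchor_fixture <- function() {
  naps <- simulate_naps_series(reference_system())
  data.frame(ri = 100 * naps$n_carbons, rt = naps$rt_min)
}

# Evenly spaced collinear anchors (RI proportional to RT).
collinear_anchors <- function() {
  data.frame(ri = seq(400, 1000, by = 100), rt = seq(4, 10, by = 1))
}

# Three replicate runs over shared linear anchors engineered to yield
# indices 98, 100, 102 for one compound.
replicate_runs_98_100_102 <- function() {
  naps <- data.frame(n_carbons = 1:3, rt_min = c(1, 2, 3))
  rts <- c(0.98, 1.00, 1.02)  # linear anchors: ri = 100 * rt
  lapply(rts, function(rt) {
    standard_run(
      data.frame(compound_id = "X", adduct = "[M+H]+", polarity = "pos",
                 rt_min = rt),
      naps_before = naps, naps_after = naps)
  })
}
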