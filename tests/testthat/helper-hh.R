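# Synthetic representative slow-wave parameter sets found by the
# package's own reduced search (shipped under inst/extdata).

local_swo_sets <- function() {
  path <- system.file("extdata", "hh_swo_sets_synthetic.csv",
                      package = "sleepsyn")
  utils::read.csv(path)
}

local_swo_set <- function(i = 1) local_swo_sets()[i, ]
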