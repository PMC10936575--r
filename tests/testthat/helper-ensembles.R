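# Published final fire sizes (ha) for the ten Las Conchas replicates per
# landscape, retyped independently of the package fixture so the fixture
# test is a genuine cross-check.
published_actual <- c(
  74034, 76379, 78883, 79492, 82179,
  82263, 82428, 83019, 83339, 86471
)
published_counterfactual <- c(
  93697, 97847, 99808, 100588, 103237,
  105645, 105974, 108534, 111411, 112049
)

lognormal_ensemble <- function(n, meanlog = log(5000), sdlog = 0.6,
                               label = "synthetic", seed = 1) {
  set.seed(seed)
  fire_ensemble(rlnorm(n, meanlog, sdlog), label = label)
}

write_sizes_csv <- function(sizes, path = tempfile(fileext = ".csv")) {
  write.csv(data.frame(fire_size_ha = sizes), path, row.names = FALSE)
  path
}
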