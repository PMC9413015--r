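# Shared fixture builders; everything is generated in code.

make_record <- function(x, y, z, rate = 10, range_g = 8) {
  n <- length(x)
  triaxial_record((seq_len(n) - 1) / rate, x, y, z, sample_rate_hz = rate,
                  dynamic_range_g = range_g)
}

constant_record <- function(n = 40, rate = 10, v = c(0, 0, 1)) {
  make_record(rep(v[1], n), rep(v[2], n), rep(v[3], n), rate)
}

random_record <- function(n, rate = 10, seed = 1, scale = 0.5) {
  set.seed(seed)
  make_record(rnorm(n, 0, scale), rnorm(n, 0, scale), 1 + rnorm(n, 0, scale),
              rate)
}

# Short schedule used by the faster pipeline tests.
short_schedule <- function() {
  data.frame(
    category = c("sleep", "sedentary", "light", "moderate", "sedentary",
                 "light", "vigorous", "sedentary"),
    minutes = c(90, 45, 40, 25, 45, 40, 15, 60),
    stringsAsFactors = FALSE
  )
}

# Epoch/label pair drawn from per-class Gaussians with known means, for
# optimizer tests. Classes are the four awake activity levels.
gaussian_epochs <- function(n_per_class, means, sds, seed = 1) {
  set.seed(seed)
  cls <- c("sedentary", "light", "moderate", "vigorous")[seq_along(means)]
  v <- unlist(lapply(seq_along(means),
                     function(i) rnorm(n_per_class, means[i], sds[i])))
  v <- pmax(v, 0)
  lab <- rep(cls, each = n_per_class)
  ord <- sample(length(v))
  t <- (seq_along(v) - 1) * 60
  list(epochs = epoch_series(t, v[ord], "rocam", 10),
       labels = label_series(t, lab[ord]))
}
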