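# fixtures built in code: small labelled datasets and trajectories

# two Gaussian blobs separated by `sep` SDs along every coordinate
make_blobs <- function(n_per = 10, m = 2, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * m), n_per, m),
               matrix(rnorm(n_per * m, mean = sep), n_per, m))
    labeled_dataset(X, rep(c(-1, 1), each = n_per))
  })
}

# informative + noise features: columns 1..m_inf get a +/- effect shift
make_informative <- function(n = 20, m_inf = 1, m_noise = 2, effect = 2.5,
                             seed = 1) {
  withr::with_seed(seed, {
    m <- m_inf + m_noise
    y <- rep(c(1, -1), length.out = n)
    X <- matrix(rnorm(n * m), n, m)
    for (j in seq_len(m_inf)) X[, j] <- X[, j] + y * effect
    labeled_dataset(X, y)
  })
}

# noise-free angle series following a slow exponential approach
make_slow_angles <- function(th_max, ph_max, duration_s = 20, rate_hz = 50,
                             tau = 4) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  pdt_angles(t, th_max * (1 - exp(-t / tau)), ph_max * (1 - exp(-t / tau)),
             rate_hz = rate_hz)
}

# brute-force merit optimum over all feature subsets (incl. empty set)
exhaustive_best_merit <- function(data, spec, seed = 1) {
  m <- ncol(data$X)
  subsets <- unlist(lapply(0:m, function(k)
    utils::combn(m, k, simplify = FALSE)), recursive = FALSE)
  max(vapply(subsets, function(ss)
    evaluate_subset(data, ss, spec, seed = seed), numeric(1)))
}

# AUC oracle: exhaustive concordant-pair count, ties worth 1/2
auc_by_pairs <- function(actual, scores) {
  pos <- scores[actual == 1]
  neg <- scores[actual == -1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

write_sensor_csv <- function(path, t, ax, ay, az) {
  utils::write.csv(data.frame(t = t, ax = ax, ay = ay, az = az), path,
                   row.names = FALSE)
  path
}
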