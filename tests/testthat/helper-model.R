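# shared fixtures and independent oracles for the test suite

default_params <- neuron_parameters()

# cache for expensive shared simulations (pre-integrations, sweeps)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

preint_leak <- function() {
  cached("preint_leak",
         pre_integrate(default_params, trp_parameters("leak"), T_room = 24))
}

preint_dynamic <- function() {
  cached("preint_dynamic",
         pre_integrate(default_params, trp_parameters("dynamic"), T_room = 24))
}

# the full reference rate sweep (shared between the transition-rate and
# rate-monotonicity checks)
reference_rate_sweep <- function() {
  cached("rate_sweep",
         rate_sweep(default_params, trp_parameters("dynamic"),
                    ic = preint_dynamic()))
}

# ---------------------------------------------------------------------------
# independent burst-segmentation oracle: recursive formulation of the
# same rule (maximal short-ISI runs; runs longer than split_over broken
# at interior strict local interval maxima, largest first, refusing
# fragments below min_spikes)

oracle_split <- function(tt, min_spikes, eps = 1e-9) {
  m <- length(tt)
  isi <- diff(tt)
  interior <- setdiff(seq_along(isi), c(1, length(isi)))
  peaks <- interior[isi[interior] > isi[interior - 1] + eps &
                    isi[interior] > isi[interior + 1] + eps]
  if (!length(peaks)) return(list(seq_len(m)))
  # recursive: apply the largest valid peak, then recurse on both halves
  recurse <- function(lo, hi, cand) {
    cand <- cand[cand > lo & cand < hi]
    cand <- cand[(cand - lo) >= min_spikes & (hi - cand) >= min_spikes]
    if (!length(cand)) return(list(seq(lo + 1, hi)))
    best <- cand[order(-isi[cand], cand)][1]
    c(recurse(lo, best, cand), recurse(best, hi, cand))
  }
  recurse(0, m, peaks)
}

oracle_bursts <- function(ts, isi_max = 0.2, min_spikes = 3, split_over = 6) {
  n <- length(ts)
  groups <- list()
  cur <- 1L
  if (n >= 2) for (i in seq_len(n - 1)) {
    if (ts[i + 1] - ts[i] <= isi_max) cur <- c(cur, i + 1L)
    else { groups <- c(groups, list(cur)); cur <- i + 1L }
  }
  groups <- c(groups, list(cur))
  bursts <- list(); pairs <- list(); tonic <- integer(0)
  for (g in groups) {
    if (length(g) == 1) { tonic <- c(tonic, g); next }
    if (length(g) == 2 && min_spikes > 2) { pairs <- c(pairs, list(g)); next }
    if (length(g) < min_spikes) { tonic <- c(tonic, g); next }
    if (length(g) > split_over) {
      for (fr in oracle_split(ts[g], min_spikes))
        bursts <- c(bursts, list(g[fr]))
    } else bursts <- c(bursts, list(g))
  }
  list(bursts = bursts, pairs = pairs, tonic = sort(tonic))
}

# random spike trains mixing tonic, burst and long-run regimes
random_train <- function(n_isi) {
  kind <- sample(c("short", "long"), n_isi, replace = TRUE,
                 prob = c(0.6, 0.4))
  isi <- ifelse(kind == "short", runif(n_isi, 0.01, 0.2),
                runif(n_isi, 0.21, 1.5))
  cumsum(c(runif(1), isi))
}

expect_same_segmentation <- function(train, oracle) {
  got <- classify_bursts(train)
  got_bursts <- lapply(seq_len(nrow(got$bursts)), function(k)
    seq(got$bursts$first[k], got$bursts$last[k]))
  got_pairs <- lapply(seq_len(nrow(got$pairs)), function(k)
    c(got$pairs$first[k], got$pairs$last[k]))
  expect_identical(lapply(got_bursts, as.integer),
                   lapply(oracle$bursts, as.integer))
  expect_identical(lapply(got_pairs, as.integer),
                   lapply(oracle$pairs, as.integer))
  expect_identical(as.integer(got$tonic), as.integer(oracle$tonic))
}

# triangular test spikes for the detector fixtures
triangle_trace <- function(apices, width = 0.002, peak = 30, base = -60,
                           rate = 2000, t_end = NULL) {
  if (is.null(t_end)) t_end <- max(apices) + 0.5
  t <- seq(0, t_end, by = 1 / rate)
  v <- rep(base, length(t))
  for (a in apices) {
    tri <- pmax(0, 1 - abs(t - a) / (width / 2))
    v <- pmax(v, base + (peak - base) * tri)
  }
  data.frame(time = t, Vm = v)
}
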