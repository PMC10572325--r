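# activity maps, trajectory projection, sweeps, census

test_that("map structure: silence at warm/low G, bursting at intermediate G", {
  m <- cached("small_map",
              sweep_map(default_params, g_grid = c(0, 0.1, 0.42, 0.88),
                        t_grid = c(24, 20, 16, 12, 8)))
  cells <- m$cells
  expect_false(any(cells$failed))
  # the G = 0 column is silent everywhere (no TRP drive)
  g0 <- cells[cells$G_LTRP == 0, ]
  expect_true(all(g0$label == "silence"))
  expect_true(all(g0$n_spikes == 0))
  expect_true(all(g0$spiking_rate == 0))
  # the 24 degC row is silent at every conductance up to 0.88 nS
  warm <- cells[cells$temperature == 24, ]
  expect_true(all(warm$label == "silence"))
  # a bursting region exists at intermediate conductance
  expect_gt(sum(cells$label == "bursting"), 0)
  # bursting cells carry at least 3 spikes per burst
  bc <- cells[cells$label == "bursting", ]
  expect_true(all(bc$spikes_per_burst >= 3))
  # silence cells have zero frequency
  expect_true(all(cells$mean_frequency[cells$label == "silence"] == 0))
})

test_that("each column turns on at one threshold temperature", {
  m <- cached("small_map",
              sweep_map(default_params, g_grid = c(0, 0.1, 0.42, 0.88),
                        t_grid = c(24, 20, 16, 12, 8)))
  th <- activity_threshold(m)
  expect_true(is.na(th$threshold_temperature[th$G_LTRP == 0]))
  # silence is contiguous on the warm side of each column's threshold
  for (g in m$g_grid) {
    col <- m$cells[m$cells$G_LTRP == g, ]
    thr <- th$threshold_temperature[th$G_LTRP == g]
    if (is.na(thr)) {
      expect_true(all(col$label == "silence"))
    } else {
      expect_true(all(col$label[col$temperature > thr] == "silence"))
      expect_gt(sum(col$n_spikes[col$temperature <= thr]), 0)
    }
  }
})

test_that("colder cells fire at least as fast at 0.28 nS", {
  ic28 <- cached("preint_g028",
                 pre_integrate(default_params,
                               trp_parameters("leak", G_LTRP = 0.28)))
  a <- run_map_cell(default_params, 0.28, 10, ic28)$metrics
  b <- run_map_cell(default_params, 0.28, 20, ic28)$metrics
  expect_gte(a$spiking_rate, b$spiking_rate)
  expect_gt(a$n_spikes, 0)
})

test_that("trajectory projection pins a zero-conductance model at G = 0", {
  p <- default_params
  trp0 <- trp_parameters("dynamic", G_TRP_max = 0)
  res <- run_protocol(p, trp0, make_trapezoid(24, 10, 3),
                      ic = initial_state(p, trp0))
  traj <- project_trajectory(res)
  expect_true(all(traj$path$G_TRP_inst == 0))
  expect_equal(nrow(traj$spikes), 0)
})

test_that("at constant temperature with settled gates the path is a point", {
  p <- default_params
  trp <- trp_parameters("dynamic")
  ic <- preint_dynamic()
  res <- run_protocol(p, trp, make_hold(24, 5), ic = ic)
  traj <- project_trajectory(res)
  expect_lt(diff(range(traj$path$G_TRP_inst)), 1e-4)
  expect_lt(diff(range(traj$path$temperature)), 1e-9)
})

test_that("a fast-protocol trajectory enters and leaves the active region", {
  m <- cached("small_map",
              sweep_map(default_params, g_grid = c(0, 0.1, 0.42, 0.88),
                        t_grid = c(24, 20, 16, 12, 8)))
  res <- cached("fast_run",
                run_protocol(default_params, trp_parameters("dynamic"),
                             make_experimental_like("fast", 10,
                                                    initial_rate = 4),
                             ic = preint_dynamic()))
  traj <- project_trajectory(res, map = m)
  expect_gt(max(traj$path$G_TRP_inst), 0.5)
  expect_lt(traj$path$G_TRP_inst[1], 0.01)
  expect_lt(traj$path$G_TRP_inst[nrow(traj$path)], 0.1)
  # regime occupancy: starts silent, passes through active labels
  expect_equal(traj$path$regime[1], "silence")
  expect_true(any(traj$path$regime != "silence"))
  # spikes annotated with instantaneous frequency
  expect_gt(nrow(traj$spikes), 10)
  expect_true(all(is.finite(traj$spikes$inst_freq[-1])))
  # parameter mismatch is refused
  m2 <- sweep_map(neuron_parameters(G_SK = 0.5), g_grid = 0.1, t_grid = 10,
                  settle = 1, analyze = 5, ic = preint_leak())
  expect_error(project_trajectory(res, map = m2), "different membrane")
})

test_that("census handles degenerate, duplicated and zero-conductance rows", {
  p <- default_params
  pr <- make_experimental_like("fast", 10, initial_rate = 4)
  tab0 <- data.frame(G_TRP_max = 0)
  cs0 <- phenotype_census(p, tab0, pr)
  expect_equal(unname(cs0$fractions[["non_responsive"]]), 1)
  tab <- coldburst:::exemplar_trp_table()[c(1, 1, 4, 4), ]
  cs <- phenotype_census(p, tab, pr)
  expect_equal(cs$per_row$label[1], cs$per_row$label[2])
  expect_equal(cs$per_row$label[3], cs$per_row$label[4])
  expect_equal(sum(cs$fractions), 1)
})

test_that("census reproduces the worked-example response types", {
  pr <- make_experimental_like("fast", 10, initial_rate = 4)
  cs <- phenotype_census(default_params, coldburst:::exemplar_trp_table(), pr)
  labs <- cs$per_row$label
  # the first two exemplar channels burst during the temperature drop,
  # the last responds with tonic spiking only
  expect_equal(labs[1:2], c("bursting", "bursting"))
  expect_equal(labs[4], "tonic")
  expect_true(labs[3] %in% c("bursting", "tonic"))
})

test_that("maps serialize to per-metric CSV grids with a JSON sidecar", {
  m <- sweep_map(default_params, g_grid = c(0, 0.5), t_grid = c(24, 10),
                 settle = 2, analyze = 5, ic = preint_leak())
  dir <- tempfile()
  write_activity_map(m, dir)
  expect_true(file.exists(file.path(dir, "mean_frequency.csv")))
  grid <- read.csv(file.path(dir, "label.csv"), check.names = FALSE)
  expect_equal(dim(grid), c(2, 3))
  expect_equal(grid$G_LTRP, c(0, 0.5))
  meta <- jsonlite::read_json(file.path(dir, "map_meta.json"))
  expect_equal(unlist(meta$t_grid), c(24, 10))
})
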