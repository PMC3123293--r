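test_that("simulations terminate for the documented reasons", {
  # one initial state: nothing to do
  r1 <- run_simulation(war_config(width = 4, height = 4, n_initial_states = 1,
                                  seed = 5))
  expect_identical(r1$termination, "one_state_left")
  expect_identical(max(r1$series$step), 0L)

  # a hard step cap is a recorded outcome
  r2 <- run_simulation(cfg_small(seed = 3, max_steps = 5))
  expect_true(r2$termination %in% c("one_state_left", "peace", "max_steps"))
  expect_lte(max(r2$series$step), 5L)
})

test_that("full trajectories are bit-identical under a fixed seed", {
  cfg <- cfg_small(width = 12, height = 12, n_initial_states = 10, seed = 17)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$final_world$owner, b$final_world$owner)
  expect_identical(a$final_world$states, b$final_world$states)
})

test_that("run summaries are internally consistent", {
  run <- run_simulation(cfg_small(seed = 23))
  g <- glance(run)
  s <- tidy(run)
  expect_identical(g$steps, max(s$step))
  expect_identical(g$final_n_states, s$n_states[nrow(s)])
  expect_equal(g$final_median_alpha,
               median_confidence(run$final_world))
  expect_s3_class(autoplot(run), "ggplot")
})

test_that("child seeds are deterministic, order-independent and in range", {
  s1 <- child_seed(42, 1:100)
  s2 <- rev(child_seed(42, 100:1))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 < 2^31 - 1))
  expect_false(any(duplicated(s1)))
  expect_false(identical(child_seed(42, 1:10), child_seed(43, 1:10)))
})

test_that("a batch of one run reproduces the single run", {
  cfg <- cfg_small(seed = 29)
  b <- run_batch(cfg, n_runs = 1, base_seed = 7)
  single <- run_simulation(cfg, seed = child_seed(7, 1))
  expect_equal(b$trajectory$median_alpha, single$series$median_alpha)
  expect_identical(glance(b)$median_final_alpha,
                   glance(single)$final_median_alpha)
})

test_that("batches are reproducible and carry terminated runs forward", {
  cfg <- cfg_small(width = 10, height = 10, n_initial_states = 8, seed = 1)
  b1 <- run_batch(cfg, n_runs = 4, base_seed = 99)
  b2 <- run_batch(cfg, n_runs = 4, base_seed = 99)
  expect_identical(b1$runs, b2$runs)
  expect_identical(b1$trajectory, b2$trajectory)
  # trajectory is defined at every step up to the longest run
  expect_identical(nrow(b1$trajectory), max(b1$runs$steps) + 1L)
  expect_false(any(is.na(b1$trajectory$median_alpha)))
  expect_s3_class(autoplot(b1), "ggplot")
})

test_that("the robustness grids have the documented shape", {
  full <- s1_parameter_grid()
  expect_identical(nrow(full), 162L)
  expect_identical(nrow(dplyr::distinct(full)), 162L)
  reduced <- s1_parameter_grid(reduced = TRUE)
  expect_identical(nrow(reduced), 8L)
  # every factor takes both extreme levels in the corner design
  expect_setequal(unique(reduced$grid_size), c(20L, 40L))
  expect_setequal(unique(reduced$torus), c(TRUE, FALSE))
  expect_setequal(unique(reduced$n_initial_states), c(10L, 100L))
  expect_setequal(unique(reduced$k), c(3, 7))
  expect_setequal(unique(reduced$alpha_sigma), c(0.5, 1.5))
})

test_that("a smoke sweep returns one row per cell", {
  grid <- tibble::tibble(grid_size = 8L, n_initial_states = 6L)
  tab <- parameter_sweep(grid, n_runs = 2, base_seed = 5)
  expect_identical(nrow(tab), 1L)
  expect_gt(tab$median_final_alpha, 0)
  expect_identical(tab$n_runs, 2L)
})

test_that("experiment curves exist even at n_runs = 1", {
  cfg <- cfg_small(seed = 2)
  wc <- war_cost_experiment(q_values = c(0, 0.4), n_runs = 1, config = cfg,
                            base_seed = 3)
  expect_identical(nrow(wc), 2L)
  expect_true(all(wc$median_final_alpha > 0))
  expect_s3_class(autoplot(wc), "ggplot")

  th <- threshold_experiment(w_values = c(0.3, 0.7), n_runs = 1, config = cfg,
                             base_seed = 3)
  expect_identical(nrow(th), 2L)
  expect_identical(attr(th, "param"), "w")
})

test_that("aggregate batch statistics are invariant to run execution order", {
  cfg <- cfg_small(width = 6, height = 6, n_initial_states = 4, seed = 1)
  seeds <- child_seed(11, 1:6)
  finals <- vapply(seeds, function(s)
    glance(run_simulation(cfg, seed = s))$final_median_alpha, numeric(1))
  finals_rev <- vapply(rev(seeds), function(s)
    glance(run_simulation(cfg, seed = s))$final_median_alpha, numeric(1))
  expect_identical(sort(finals), sort(finals_rev))
  expect_identical(median(finals),
                   glance(run_batch(cfg, 6, base_seed = 11))$median_final_alpha)
})

test_that("survival favours a middling margin of overconfidence", {
  # lineage survival rate by initial confidence bin: middling overconfidence
  # outlives both underconfidence and extreme overconfidence
  cfg <- war_config(width = 20, height = 20, n_initial_states = 50)
  seeds <- child_seed(77, 1:100)
  res <- lapply(seeds, function(s) {
    run <- run_simulation(cfg, seed = s)
    st <- run$final_world$states
    init <- st$alpha[1:50]
    data.frame(alpha = init, survived = init %in% st$alpha[st$alive])
  })
  pool <- do.call(rbind, res)
  rate <- function(lo, hi) mean(pool$survived[pool$alpha > lo & pool$alpha <= hi])
  expect_gt(rate(1, 8), rate(0, 0.5))     # overconfidence beats underconfidence
  expect_gt(rate(1, 8), rate(8, Inf))     # but the optimum is interior
})
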