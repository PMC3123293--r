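test_that("extraction adds one unit per province", {
  w <- two_state_world(res = c(40, 20))
  e <- extract_resources(w)
  expect_equal(world_states(e)$resources, c(42, 22))

  whole <- build_world(war_config(width = 30, height = 30, n_initial_states = 1,
                                  seed = 1))
  expect_equal(world_states(extract_resources(whole))$resources, 9000 + 900)

  # conservation: total system resources rise by exactly one per cell
  rnd <- build_world(cfg_small(seed = 4))
  gained <- sum(world_states(extract_resources(rnd))$resources) -
    sum(world_states(rnd)$resources)
  expect_equal(gained, 64)
})

test_that("states attack the neighbour with the highest perceived probability", {
  w <- line3_world(res = c(5, 10, 20), alpha_mid = 1)
  atk <- decide_attacks(w)
  mid <- atk[atk$attacker == 2, ]
  expect_identical(mid$target, 1L)
  expect_equal(mid$p_perceived, 10^5 / (10^5 + 5^5), tolerance = 1e-12)
  # the strong flank attacks the middle, the weak flank stays put
  expect_identical(atk$attacker, c(2L, 3L))
  expect_equal(atk$p_perceived[atk$attacker == 3], 32 / 33, tolerance = 1e-12)
})

test_that("the attack threshold is strict and confidence shifts it", {
  # unbiased state facing one equal neighbour: p-hat = 0.5 is not > 0.5
  w <- two_state_world(res = c(20, 20), alpha = c(1, 1))
  expect_identical(nrow(decide_attacks(w)), 0L)

  # underconfident in the same spot: far below threshold
  under <- line3_world(res = c(10, 10, 10), alpha_mid = 0.4)
  atk <- decide_attacks(under)
  expect_false(2L %in% atk$attacker)
  expect_equal(perceived_success_probability(0.4, 10, 10, k = 5),
               0.4^5 / (0.4^5 + 1), tolerance = 1e-12)

  # overconfident attacks despite equal true strength
  over <- line3_world(res = c(10, 10, 10), alpha_mid = 4)
  expect_true(2L %in% decide_attacks(over)$attacker)
})

test_that("attack sets are weakly increasing in confidence", {
  set.seed(31)
  for (i in 1:50) {
    ra <- runif(1, 1, 100)
    rts <- runif(5, 1, 100)
    alphas <- sort(runif(2, 0.2, 5))
    sets <- lapply(alphas, function(a) {
      which(perceived_success_probability(a, ra, rts, k = 5) > 0.5)
    })
    expect_true(all(sets[[1]] %in% sets[[2]]))
  }
})

test_that("an unbiased state never attacks an equal or stronger opponent", {
  set.seed(32)
  ra <- runif(200, 1, 100)
  rt <- ra * runif(200, 1, 3)  # opponent at least as strong
  expect_true(all(perceived_success_probability(1, ra, rt, k = 5) <= 0.5))
})

test_that("fronts deduplicate mutual attacks and split two-on-one wars", {
  mutual <- build_fronts(tibble::tibble(attacker = c(1L, 2L), target = c(2L, 1L)))
  expect_identical(nrow(mutual), 1L)
  expect_true(mutual$mutual)
  expect_identical(mutual$attacker, 1L)  # lower id labelled attacker

  gang <- build_fronts(tibble::tibble(attacker = c(1L, 2L), target = c(3L, 3L)))
  expect_identical(nrow(gang), 2L)
  expect_false(any(gang$mutual))
  expect_identical(sort(gang$attacker), c(1L, 2L))

  none <- build_fronts(tibble::tibble(attacker = integer(), target = integer()))
  expect_identical(nrow(none), 0L)
})

test_that("multi-front states split resources in proportion to opponent size", {
  # state 2 (middle, R = 30) fights both flanks (R = 10 and 20)
  w <- line3_world(res = c(10, 30, 20))
  fronts <- build_fronts(tibble::tibble(attacker = c(1L, 3L), target = c(2L, 2L)))
  al <- allocate_resources(w, fronts)
  d1 <- al$defender_alloc[al$attacker == 1]
  d3 <- al$defender_alloc[al$attacker == 3]
  expect_equal(d1, 30 * 10 / 30)
  expect_equal(d3, 30 * 20 / 30)
  expect_equal(d1 + d3, 30)            # allocations sum to the full stock
  expect_equal(al$attacker_alloc, c(10, 20))  # single-front states go all in

  # symmetric opponents split equally
  w_sym <- line3_world(res = c(15, 30, 15))
  al_sym <- allocate_resources(w_sym, fronts)
  expect_equal(al_sym$defender_alloc, c(15, 15))
})

test_that("province-count allocation weights are available", {
  cfg <- war_config(width = 3, height = 2, n_initial_states = 3,
                    allocation_weights = "provinces")
  owner <- matrix(c(1L, 1L, 2L, 2L, 3L, 2L), 2, 3)  # state2: 3 cells
  w <- as_war_world(owner, data.frame(
    id = 1:3, alpha = c(1, 1, 1), resources = c(10, 60, 10),
    capital_row = c(1, 1, 1), capital_col = c(1, 2, 3)), cfg)
  fronts <- build_fronts(tibble::tibble(attacker = c(1L, 3L), target = c(2L, 2L)))
  al <- allocate_resources(w, fronts)
  # opponents 1 and 3 have 2 and 1 provinces
  expect_equal(al$defender_alloc, c(40, 20))
})

test_that("battle outcomes match the closed-form probability", {
  # equal allocations: empirical win rate near 0.5
  n <- 10000
  eq <- tibble::tibble(attacker = 1L, defender = 2L,
                       attacker_alloc = 15, defender_alloc = 15)[rep(1, n), ]
  w <- two_state_world()
  set.seed(500)
  res <- resolve_battles(w, eq)
  expect_equal(unique(res$p_attacker), 0.5)
  rate <- mean(res$winner == 1L)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n))

  # 20 vs 10 at k = 5: rate near 32/33
  uneq <- tibble::tibble(attacker = 1L, defender = 2L,
                         attacker_alloc = 20, defender_alloc = 10)[rep(1, n), ]
  set.seed(501)
  res2 <- resolve_battles(w, uneq)
  p <- 32 / 33
  expect_equal(unique(res2$p_attacker), p, tolerance = 1e-12)
  expect_lt(abs(mean(res2$winner == 1L) - p), 3 * sqrt(p * (1 - p) / n))

  # determinism under a fixed seed
  set.seed(502); a <- resolve_battles(w, uneq)
  set.seed(502); b <- resolve_battles(w, uneq)
  expect_identical(a, b)
})

test_that("war costs deduct a share of the opponent's allocation, floored at 0", {
  w0 <- two_state_world(res = c(100, 50), q = 0)
  fronts <- tibble::tibble(attacker = 1L, defender = 2L,
                           attacker_alloc = 100, defender_alloc = 50)
  expect_equal(world_states(apply_war_costs(w0, fronts))$resources, c(100, 50))

  w2 <- two_state_world(res = c(100, 50), q = 0.2)
  after <- apply_war_costs(w2, fronts)
  expect_equal(world_states(after)$resources, c(100 - 0.2 * 50, 50 - 0.2 * 100))
  expect_equal(attr(after, "costs_paid"), 30)

  # floor: a weak state cannot go negative
  w3 <- two_state_world(res = c(3, 50), q = 0.5)
  fr3 <- tibble::tibble(attacker = 1L, defender = 2L,
                        attacker_alloc = 3, defender_alloc = 10)
  after3 <- apply_war_costs(w3, fr3)
  expect_equal(world_states(after3)$resources, c(0, 48.5))
})

test_that("a full step equals the five phases composed in order", {
  w <- build_world(cfg_small(seed = 13, q = 0.1))
  set.seed(77)
  stepped <- step_world(w)
  set.seed(77)
  e <- extract_resources(w)
  atk <- decide_attacks(e)
  fr <- allocate_resources(e, build_fronts(atk))
  fr <- resolve_battles(e, fr)
  costed <- apply_war_costs(e, fr)
  manual <- apply_structural_change(costed, fr)
  expect_identical(stepped$owner, manual$owner)
  expect_equal(stepped$states, manual$states)
  rep <- last_step_report(stepped)
  expect_identical(rep$attacks, nrow(atk))
  expect_identical(rep$battles, nrow(fr))
  expect_lte(rep$battles, rep$attacks)
})

test_that("a lone state only extracts and the peace streak accumulates", {
  w <- build_world(war_config(width = 4, height = 4, n_initial_states = 1, seed = 2))
  s <- step_world(w)
  rep <- last_step_report(s)
  expect_identical(rep$attacks, 0L)
  expect_identical(rep$battles, 0L)
  expect_equal(world_states(s)$resources, 160 + 16)
  expect_identical(s$peace_streak, 1L)
  expect_identical(s$t, 1L)
})

test_that("two equal unbiased states stay at peace and the run stops at 50 steps", {
  w <- two_state_world(res = c(20, 20), alpha = c(1, 1))
  run <- run_simulation(world = w, seed = 3)
  expect_identical(run$termination, "peace")
  expect_identical(max(run$series$step), 50L)
  expect_identical(sum(run$series$battles), 0L)
})

test_that("a world of underconfident equals never fights", {
  w <- two_state_world(res = c(20, 20), alpha = c(0.8, 0.6))
  run <- run_simulation(world = w, seed = 9)
  expect_identical(run$termination, "peace")
  expect_identical(sum(run$series$battles), 0L)
})
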