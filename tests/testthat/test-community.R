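test_that("stool profiles are normalized, seeded and lognormal-shaped", {
  spec <- community_spec(seed = 5)
  p1 <- sample_stool_profile(spec)
  p2 <- sample_stool_profile(spec)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  expect_true(all(p1 >= 0))

  # sigma = 0 gives the uniform profile
  u <- sample_stool_profile(community_spec(n_taxa = 10, lognormal_sigma = 0))
  expect_equal(unname(u), rep(0.1, 10))

  # heavy-tailed case: rare taxa dominate in number
  h <- sample_stool_profile(community_spec(n_taxa = 200, lognormal_sigma = 2,
                                           seed = 9))
  expect_gt(sum(h < 0.01), sum(h > 0.01))

  expect_error(community_spec(lognormal_sigma = -1),
               class = "dropcult_invalid")
  expect_error(community_spec(carryover_fraction = 1),
               class = "dropcult_invalid")
})

test_that("droplet culture without growth bias reproduces the inoculum", {
  # equal rates, certain growth: the pooled profile is a multinomial image
  # of the stool profile
  spec <- community_spec(
    n_taxa = 20, lognormal_sigma = 1, growth_rate = 0.2,
    growth_success_prob = 1, n_droplets = 1e5, occupancy_lam = 0.1, seed = 3
  )
  stool <- sample_stool_profile(spec)
  cult <- simulate_droplet_culture(stool, spec)
  n_cells <- nrow(cult$cells)
  for (i in seq_len(spec$n_taxa)) {
    se <- sqrt(stool[i] * (1 - stool[i]) / n_cells)
    expect_lt(abs(cult$profile[i] - stool[i]), 3 * se + 1e-9)
  }

  # a taxon that cannot grow is absent from the grown pool
  spec0 <- community_spec(
    n_taxa = 5, lognormal_sigma = 0.5, growth_rate = 0.2,
    growth_success_prob = c(0, 1, 1, 1, 1), n_droplets = 2e4, seed = 4
  )
  cult0 <- simulate_droplet_culture(sample_stool_profile(spec0), spec0)
  expect_equal(unname(cult0$profile[1]), 0)
})

test_that("capacity caps blunt fast growers in droplets but not on plates", {
  # one 10x-faster taxon: its pooled share under droplet isolation stays
  # below its share under plate competition
  spec <- community_spec(
    n_taxa = 10, lognormal_sigma = 0, growth_rate = c(1.5, rep(0.15, 9)),
    growth_success_prob = 1, n_droplets = 2e4, culture_time = 24, seed = 6
  )
  stool <- sample_stool_profile(spec)
  droplet <- simulate_droplet_culture(stool, spec)
  plate <- simulate_plate_culture(stool, spec)
  expect_lt(droplet$profile[1], plate[1])
  expect_gt(plate[1], 0.5)  # exponential dominance of the fast grower

  # equal rates: plate culture leaves the profile untouched
  eq <- community_spec(n_taxa = 8, lognormal_sigma = 1, growth_rate = 0.3,
                       growth_success_prob = 1, seed = 7)
  st <- sample_stool_profile(eq)
  expect_equal(simulate_plate_culture(st, eq), st, tolerance = 1e-12)
})

test_that("plate bias exceeds droplet bias under a growth-rate spread", {
  wins <- sapply(1:60, function(s) {
    sp <- community_spec(n_taxa = 60, n_droplets = 4000, seed = s)
    st <- sample_stool_profile(sp)
    d <- simulate_droplet_culture(st, sp)
    p <- simulate_plate_culture(st, sp)
    bray_curtis(d$profile, st) < bray_curtis(p, st)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("low-size sorting windows enrich slow-growing taxa", {
  spec <- community_spec(seed = 12)
  stool <- sample_stool_profile(spec)
  cult <- simulate_droplet_culture(stool, spec)

  # full-range window returns the unsorted pool
  full <- simulate_sorting_enrichment(
    cult, range(cult$droplet_sizes[cult$droplet_sizes > 0]), spec
  )
  expect_equal(full, cult$profile, tolerance = 1e-12)

  # sub-capacity window: aggregate share of slow taxa strictly increases
  slow <- spec$growth_rate < log(spec$carrying_capacity) / spec$culture_time
  sorted <- simulate_sorting_enrichment(
    cult, c(1, spec$carrying_capacity / 2), spec
  )
  expect_gt(sum(sorted[slow]), sum(cult$profile[slow]))

  expect_error(
    simulate_sorting_enrichment(cult, c(1e9, 2e9), spec),
    class = "dropcult_empty_selection"
  )
})

test_that("carryover mixes at the read level and sequencing is multinomial", {
  spec <- community_spec(n_taxa = 30, seed = 8)
  stool <- sample_stool_profile(spec)
  grown <- rev(stool)  # any distinct profile
  names(grown) <- names(stool)

  depth <- 1e5
  cnt <- add_carryover_and_sequence(grown, stool, 0.2, depth, seed = 2)
  expect_equal(sum(cnt), depth)
  expect_true(all(cnt >= 0))
  mix <- 0.8 * grown + 0.2 * stool
  for (i in seq_along(mix)) {
    se <- sqrt(mix[i] * (1 - mix[i]) / depth)
    expect_lt(abs(cnt[i] / depth - mix[i]), 3 * se + 1e-9)
  }

  # boundary fractions collapse onto the pure profiles
  c0 <- add_carryover_and_sequence(grown, stool, 0, depth, seed = 3)
  expect_lt(bray_curtis(c0, grown), 0.02)
  c1 <- add_carryover_and_sequence(grown, stool, 1, depth, seed = 3)
  expect_lt(bray_curtis(c1, stool), 0.02)
})
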