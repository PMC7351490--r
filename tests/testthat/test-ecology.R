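test_that("richness, Shannon and rare-taxon richness follow the formulas", {
  stool <- setNames(c(50L, 30L, 15L, 4L, 1L, 0L), paste0("ASV_", 1:6))

  uni <- setNames(c(25L, 25L, 25L, 25L, 0L, 0L), names(stool))
  m <- community_metrics(uni, stool)
  expect_equal(m$richness, 4)
  expect_equal(m$shannon, log(4), tolerance = 1e-12)

  single <- setNames(c(0L, 9L, 0L, 0L, 0L, 0L), names(stool))
  s <- community_metrics(single, stool)
  expect_equal(s$richness, 1)
  expect_equal(s$shannon, 0)

  mix <- setNames(c(50L, 25L, 25L, 0L, 0L, 0L), names(stool))
  expect_equal(community_metrics(mix, stool)$shannon,
               -sum(c(.5, .25, .25) * log(c(.5, .25, .25))),
               tolerance = 1e-12)

  # r_low counts detected ASVs rare (<1%) in stool: ASV_5 (1%? 1/100) and
  # ASV_6 (absent) qualify among the detected
  det <- setNames(c(10L, 10L, 10L, 10L, 10L, 10L), names(stool))
  expect_equal(community_metrics(det, stool, cutoff = 0.02)$r_low, 2)

  expect_error(community_metrics(integer(6), stool),
               class = "dropcult_invalid")
})

test_that("Shannon diversity is bounded by log richness", {
  for (s in 1:20) {
    p <- dropcult:::with_seed(s, as.integer(rmultinom(1, 500, runif(12))))
    names(p) <- paste0("t", 1:12)
    m <- community_metrics(p, p)
    expect_lte(m$shannon, log(m$richness) + 1e-12)
  }
})

test_that("rank-abundance curves are sorted, tie-stable and conserved", {
  p <- c(B = 0.2, A = 0.5, C = 0.3)
  ra <- rank_abundance(p)
  expect_equal(ra$proportion, c(0.5, 0.3, 0.2))
  expect_equal(ra$asv_id, c("A", "C", "B"))
  expect_equal(sum(ra$proportion), 1)

  # ties broken lexicographically by id
  tie <- c(z = 1L, m = 1L, a = 1L)
  expect_equal(rank_abundance(tie)$asv_id, c("a", "m", "z"))
})

test_that("amplification calls compare stool and sample against the cutoff", {
  stool <- c(r1 = 50L, r2 = 80L, common = 9870L)
  smp <- c(r1 = 200L, r2 = 50L, common = 9750L)
  calls <- amplified_asvs(stool, smp, cutoff = 0.01)
  expect_setequal(calls$asv_id, c("r1", "r2"))  # 'common' is not a candidate
  r1 <- calls[calls$asv_id == "r1", ]
  expect_true(r1$amplified)
  expect_equal(r1$ratio, (200 / 10000) / (50 / 10000))
  expect_false(calls[calls$asv_id == "r2", ]$amplified)

  # absent from stool: infinite ratio flag
  st0 <- c(a = 0L, b = 100L)
  expect_equal(amplified_asvs(st0, c(a = 10L, b = 90L))$ratio[1], Inf)
})

test_that("Bray-Curtis behaves as a normalized overlap complement", {
  a <- c(0.5, 0.5, 0)
  b <- c(0.5, 0, 0.5)
  expect_equal(bray_curtis(a, b), 0.5)
  expect_equal(bray_curtis(a, a), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)

  # symmetry, bounds and reorder-invariance on random profiles, plus
  # agreement with the standard ecology implementation
  for (s in 1:10) {
    x <- dropcult:::with_seed(s, runif(8))
    y <- dropcult:::with_seed(s + 100, runif(8))
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
    perm <- dropcult:::with_seed(s + 200, sample(8))
    expect_equal(bray_curtis(x[perm], y[perm]), d)
    ref <- as.numeric(vegan::vegdist(rbind(x / sum(x), y / sum(y)), "bray"))
    expect_equal(d, ref, tolerance = 1e-12)
  }
})

test_that("sample clustering reflects Bray-Curtis similarity structure", {
  tab <- cbind(
    A = c(50L, 30L, 20L, 0L),
    B = c(50L, 30L, 20L, 0L),
    C = c(0L, 5L, 5L, 90L)
  )
  rownames(tab) <- paste0("ASV_", 1:4)
  hc <- cluster_samples(tab)
  # identical samples merge first, at height 0
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- rownames(tab) # not used; keep labels readable
  merged <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(merged, c("A", "B"))

  nwk <- write_dendrogram(hc)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "C")

  expect_error(cluster_samples(tab[, 1, drop = FALSE]),
               class = "dropcult_invalid")
})

test_that("distribution and group comparisons wrap the standard tests", {
  a <- c(0.5, 0.3, 0.2)
  expect_equal(compare_distributions(a, a)$statistic, 0)
  expect_equal(compare_distributions(1:5 / 15, 100 + 1:5)$statistic, 1)
  ks <- compare_distributions(a, c(0.25, 0.25, 0.25, 0.25))
  expect_equal(ks$statistic,
               unname(suppressWarnings(
                 ks.test(a, c(0.25, 0.25, 0.25, 0.25))$statistic
               )))
  mw <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_lt(mw$p_value, 0.2)
})
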