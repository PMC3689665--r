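test_that("simulate_yule_tree: shape, ultrametricity, determinism", {
  expect_error(simulate_yule_tree(1), ">= 2")

  two <- simulate_yule_tree(2, 0.5, seed = 1)
  expect_equal(length(two$tip.label), 2L)
  expect_equal(two$edge.length[1], two$edge.length[2])

  tr <- simulate_yule_tree(54, 0.1, seed = 3)
  expect_equal(length(tr$tip.label), 54L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::is.rooted(tr))

  a <- ape::write.tree(simulate_yule_tree(20, 0.2, seed = 9))
  b <- ape::write.tree(simulate_yule_tree(20, 0.2, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_yule_tree(20, 0.2,
                                                               seed = 10))))

  # Yule expectation: mean crown depth ~ sum_{k=2}^{n} 1/(k b) (coarse)
  depths <- vapply(1:200, function(i) {
    t2 <- simulate_yule_tree(10, 1, seed = 400 + i)
    max(ape::node.depth.edgelength(t2))
  }, numeric(1))
  expected <- sum(1 / (1 * (2:10)))
  expect_lt(abs(mean(depths) - expected) / expected, 0.15)
})

test_that("simulate_trait reproduces the requested covariance structure", {
  tr <- simulate_yule_tree(12, 0.3, seed = 21)
  C <- phylo_vcv(tr)

  # sigma2 -> 0 limit pins traits at the root value
  y0 <- simulate_trait(tr, 1e-18, root_value = 7, lambda = 1, seed = 1)
  expect_equal(unname(y0), rep(7, 12), tolerance = 1e-6)
  expect_error(simulate_trait(tr, 0), "sigma2")

  # Monte-Carlo covariance check at lambda = 1 and lambda = 0
  nrep <- 3000
  Y1 <- sapply(1:nrep, function(i) simulate_trait(tr, 2, 0, 1,
                                                  seed = 5000 + i))
  S1 <- cov(t(Y1))
  scale <- mean(diag(2 * C))
  expect_lt(max(abs(S1 - 2 * C)) / scale, 0.15)

  Y0 <- sapply(1:nrep, function(i) simulate_trait(tr, 2, 0, 0,
                                                  seed = 9000 + i))
  S0 <- cov(t(Y0))
  off <- S0[upper.tri(S0)]
  expect_lt(max(abs(off)), 4 * 2 / sqrt(nrep) * 3) # ~3 SE of zero
})

test_that("simulate_assemblage modes deliver the designed structure", {
  tr <- balanced_tree(5) # 32 tips
  expect_setequal(simulate_assemblage(tr, 32, "random", seed = 1),
                  tr$tip.label)

  cl <- simulate_assemblage(tr, 4, "clustered", seed = 2)
  # members share the smallest clade that can hold them: 4 tips with a
  # common 3-letter prefix in the balanced labelling (an 8-tip subclade
  # at worst)
  D <- patristic_distances(tr)
  expect_lte(max(D[cl, cl]), 6) # within an 8-tip subclade of the 32-tip tree

  od <- simulate_assemblage(tr, 2, "overdispersed", seed = 3)
  expect_equal(D[od[1], od[2]], max(D)) # brute-force max pair

  expect_error(simulate_assemblage(parse_newick("(A:1,B:1);"), 3, "random"))
})

test_that("species table plants the decline-age effect as configured", {
  tr <- simulate_yule_tree(54, 0.1, seed = 12)

  # zero slope, zero noise -> decline constant at baseline
  cfg0 <- study_config(decline_slope_on_bl = 0, decline_noise_sd = 0,
                       seed = 12)
  t0 <- simulate_species_table(tr, cfg0)
  expect_true(all(t0$global_decline == cfg0$decline_baseline))

  # positive slope, zero noise -> decline rank-correlated 1 with BL
  cfg1 <- study_config(decline_slope_on_bl = 2, decline_noise_sd = 0,
                       seed = 12)
  t1 <- simulate_species_table(tr, cfg1)
  bl <- terminal_branch_lengths(tr)[t1$species]
  expect_equal(cor(t1$global_decline, bl, method = "spearman"), 1)

  # use_probability = 0 -> all human_pressure 0
  cfgu <- study_config(use_probability = 0, seed = 12)
  tu <- simulate_species_table(tr, cfgu)
  expect_true(all(tu$human_pressure == 0L))

  # near-zero slope -> BL/decline correlation close to 0 across studies
  cors <- vapply(1:60, function(i) {
    cfg <- study_config(decline_slope_on_bl = 0, decline_noise_sd = 8,
                        seed = 600 + i)
    trx <- simulate_yule_tree(54, 0.1, seed = derive_seed(cfg$seed, 101))
    tt <- simulate_species_table(trx, cfg)
    suppressWarnings(cor(tt$global_decline,
                         terminal_branch_lengths(trx)[tt$species]))
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 3 / sqrt(54) / sqrt(60) * 3 + 0.05)

  expect_true(all(t1$iucn_category %in% c("LC", "NT", "VU", "EN", "CR",
                                          "DD")))
  expect_true(all(t1$h_max > 0), all(t1$propagule_size > 0))
})

test_that("ranges respect bounds, regions and rasterize to >= 1 cell", {
  cfg <- study_config(seed = 33)
  b <- generate_study(cfg)
  r <- b$ranges
  expect_true(all(r$min_lon >= -180 & r$max_lon <= 180))
  expect_true(all(r$min_lat >= -90 & r$max_lat <= 90))
  expect_true(all(r$min_lon < r$max_lon & r$min_lat < r$max_lat))

  # disjoint regions -> disjoint longitude strips
  wa <- r[grepl("WestAmerica", b$species_table$region[
    match(r$species, b$species_table$species)]) &
      r$max_lon <= -90, ]
  expect_true(all(wa$min_lon >= -125))

  g <- make_grid(c(-180, -60, 180, 60), 0.25)
  occ <- rasterize_ranges(r, g)
  expect_setequal(unique(occ$cells$species), b$species_table$species)
})

test_that("generate_study bundles are complete, parseable and bit-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  cfg <- study_config(n_species = 30, seed = 5)
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  generate_study(study_config(n_species = 30, seed = 6), d3)
  files <- c("tree.nwk", "species.csv", "assemblages.csv", "ranges.csv",
             "config.cfg")
  expect_setequal(list.files(d1), files)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_false(identical(readLines(file.path(d1, "tree.nwk")),
                         readLines(file.path(d3, "tree.nwk"))))

  # round-trip through the readers
  tr <- read_phylo(file.path(d1, "tree.nwk"))
  tab <- read_species_table(file.path(d1, "species.csv"))
  asm <- read_assemblages(file.path(d1, "assemblages.csv"))
  expect_setequal(tab$species, tr$tip.label)
  expect_true(all(unlist(asm) %in% tr$tip.label))
  expect_equal(length(asm), 6L)
})
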