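test_that("extinction probability mapping: lookup, policy, monotonicity", {
  map <- read_probability_map()
  expect_true(all(diff(map[c("LC", "NT", "VU", "EN", "CR")]) > 0))
  expect_true(all(map > 0 & map < 1))
  expect_equal(extinction_probability("VU", c(LC = 1e-4, VU = 0.05)), 0.05)
  expect_message(
    p <- extinction_probability(c("DD", "LC"), map, policy = "exclude"),
    "DD")
  expect_true(is.na(p[1]) && !is.na(p[2]))
  expect_error(extinction_probability("DD", map, policy = "error"), "DD")
  # a non-monotone user mapping is rejected at read time
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(category = c("LC", "VU", "EN"),
                       probability = c(0.5, 0.05, 0.42)), tmp,
            row.names = FALSE)
  expect_error(read_probability_map(tmp), "increase")
})

test_that("human_pressure: set semantics over the 16-use vocabulary", {
  expect_length(use_vocabulary(), 16L)
  expect_equal(human_pressure(c("firewood", "medicinal", "forage")), 3L)
  expect_equal(human_pressure(character(0)), 0L)
  expect_equal(human_pressure(c("food", "Food", " food ")), 1L)
  # permutation invariance
  u <- c("building", "dye", "shade", "carving")
  expect_equal(human_pressure(u), human_pressure(rev(u)))
  expect_warning(hp <- human_pressure(c("food", "surfing")), "surfing")
  expect_equal(hp, 1L)
  expect_error(human_pressure("surfing", strict = TRUE), "surfing")
})

test_that("chisq_yates: closed form, boundary floor, oracle agreement", {
  r <- chisq_yates(rbind(c(10, 20), c(20, 10)))
  expect_equal(r$chi_squared, 5.4, tolerance = 1e-12)
  expect_equal(r$df, 1L)

  flat <- chisq_yates(rbind(c(5, 5), c(5, 5)))
  expect_equal(flat$chi_squared, 0)
  expect_equal(flat$p_value, 1)

  expect_error(chisq_yates(rbind(c(0, 0), c(3, 4))), "degenerate margin")

  set.seed(10)
  for (i in 1:300) {
    tb <- matrix(rpois(4, 12), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(chisq_yates(tb)$chi_squared, oracle_chisq_yates(tb),
                 tolerance = 1e-10)
    # and against stats::chisq.test
    expect_equal(chisq_yates(tb)$chi_squared,
                 unname(suppressWarnings(
                   chisq.test(tb, correct = TRUE)$statistic)),
                 tolerance = 1e-10)
  }
})

test_that("use_decline_association builds the right 2x2 table", {
  tab <- data.frame(
    species = paste0("s", 1:8),
    global_decline = c(10, 0, 30, 0, 5, 0, 0, 20),
    uses = c("food", "food", "food;forage", "", "forage", "forage",
             "food", "food"))
  res <- use_decline_association(tab, "food", 0)
  # food users: s1 s2 s3 s7 s8 -> declining 3, stable 2; non-users 1/2
  expect_equal(unname(res$table), rbind(c(3, 2), c(1, 2)))

  all_use <- data.frame(species = c("a", "b"), global_decline = c(1, 0),
                        uses = c("food", "food"))
  expect_error(use_decline_association(all_use, "food"),
               "degenerate margin")

  # wide 0/1 column dialect
  wide <- data.frame(species = paste0("s", 1:6),
                     global_decline = c(9, 9, 9, 0, 0, 0),
                     use_forage = c(1, 1, 0, 0, 0, 1))
  res2 <- use_decline_association(wide, "forage")
  expect_equal(unname(res2$table), rbind(c(2, 1), c(1, 2)))
})

test_that("build_model_frame: listwise deletion, transforms, idempotence", {
  tr <- simulate_yule_tree(12, 0.3, seed = 44)
  sp <- tr$tip.label
  tab <- data.frame(species = c(sp, "ghost"),
                    iucn_category = c(rep(c("LC", "VU", "EN"), 4), "CR"),
                    global_decline = c(0, 5, 10, 20, 0, 3, 7, 9, 11, 2, 6, 8,
                                       50),
                    h_max = c(NA, rlnorm(11, log(10), 0.4), 5),
                    propagule_size = c(rlnorm(12, 1, 0.5), 2),
                    uses = c(rep("food;forage", 6), rep("", 6), "food"))
  fr <- build_model_frame(tab, tr, "global_decline",
                          c("h_max", "human_pressure"))
  # ghost not in tree, sp[1] has missing h_max
  expect_setequal(fr$dropped$species, c("ghost", sp[1]))
  expect_equal(length(fr$y), 11L)
  expect_equal(rownames(fr$X), fr$species)
  expect_equal(rownames(fr$vcv), fr$species)
  # offset policy: zero-capable columns use log10(x + 1)
  hp <- ifelse(tab$uses == "food;forage", 2L, 0L)
  expect_equal(unname(fr$X[, "human_pressure"]),
               log10(hp[match(fr$species, tab$species)] + 1))
  expect_equal(unname(fr$y),
               log10(tab$global_decline[match(fr$species, tab$species)] + 1))
  # strictly positive trait transformed as plain log10
  expect_equal(unname(fr$X[, "h_max"]),
               log10(tab$h_max[match(fr$species, tab$species)]))

  # conservation: retained + dropped = input rows
  expect_equal(length(fr$species) + nrow(fr$dropped), nrow(tab))

  # idempotence: rebuilding from the retained subset changes nothing
  sub <- tab[tab$species %in% fr$species, ]
  fr2 <- build_model_frame(sub, tr, "global_decline",
                           c("h_max", "human_pressure"))
  expect_equal(fr2$y, fr$y)
  expect_equal(fr2$X, fr$X)
  expect_equal(fr2$vcv, fr$vcv)

  expect_error(build_model_frame(tab[1:3, ], tr, "global_decline",
                                 c("h_max", "human_pressure", "fd")),
               "complete cases|missing columns")
})

test_that("use/decline chi-squared calibration under independence", {
  # independent use and decline -> ~5% rejections at alpha = 0.05
  set.seed(123)
  rej <- 0L
  nsim <- 400L
  for (i in seq_len(nsim)) {
    tab <- data.frame(species = paste0("s", 1:54),
                      global_decline = ifelse(runif(54) < 0.5, 0, 10),
                      use_food = rbinom(54, 1, 0.4))
    res <- tryCatch(use_decline_association(tab, "food"),
                    error = function(e) NULL)
    if (!is.null(res) && res$p_value < 0.05) rej <- rej + 1L
  }
  # Yates correction is conservative; accept [0.005, 0.08]
  expect_gte(rej / nsim, 0.005)
  expect_lte(rej / nsim, 0.08)
})
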