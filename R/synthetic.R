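# Synthetic-study generator: emulates the statistical structure of the real
# inputs (a ~54-tip dated tree, six biogeographic regions, coastal-strip
# ranges, IUCN categories, decline increasing with species age) so that
# every pipeline stage can be exercised without any download.

REGION_NAMES <- c("WestAmerica", "EastAmerica", "WestAfrica", "EastAfrica",
                  "IndoMalesia", "Australasia")
# disjoint synthetic coastline strips (lon ranges, degrees)
REGION_LON <- list(WestAmerica = c(-125, -95), EastAmerica = c(-90, -35),
                   WestAfrica = c(-20, 15), EastAfrica = c(25, 60),
                   IndoMalesia = c(65, 130), Australasia = c(135, 179))
# relative regional richness (Indo-Malesia is the diversity centre)
REGION_FRACTION <- c(0.15, 0.19, 0.15, 0.17, 0.65, 0.45)

#' Configuration of a synthetic study
#'
#' Bundles and validates every knob of the generator. Defaults state the
#' emulated world: 54 species (the number with DNA data in the mangrove
#' flora), 6 biogeographic regions with Indo-Malesia richest, a Yule tree at
#' 0.1 births/Myr (54-tip crown depth around 45 Myr), decline (percent of
#' population declining) increasing with species age at 2 percent/Myr over a
#' baseline of 5 with Gaussian noise (sd 8), per-use Bernoulli(0.25) draws
#' over the 16-use vocabulary, and a Red-List mix dominated by Least
#' Concern.
#'
#' @param n_species number of tips (default 54).
#' @param n_regions number of regions, at most 6 (default 6).
#' @param birth_rate Yule speciation rate per Myr (default 0.1).
#' @param assemblage_mode `"random"`, `"clustered"` or `"overdispersed"`.
#' @param decline_slope_on_bl percent decline per Myr of terminal branch
#'   length (default 2).
#' @param decline_noise_sd Gaussian noise sd on decline (default 8).
#' @param decline_baseline decline intercept (default 5).
#' @param use_probability per-use inclusion probability (default 0.25).
#' @param category_probabilities named distribution over IUCN categories.
#' @param use_vocab controlled use list (default [use_vocabulary()]).
#' @param seed master seed (default 1).
#' @return List of class `"study_config"`.
#' @export
study_config <- function(n_species = 54L, n_regions = 6L, birth_rate = 0.1,
                         assemblage_mode = c("random", "clustered",
                                             "overdispersed"),
                         decline_slope_on_bl = 2, decline_noise_sd = 8,
                         decline_baseline = 5, use_probability = 0.25,
                         category_probabilities = c(LC = 0.60, NT = 0.11,
                                                    VU = 0.15, EN = 0.07,
                                                    CR = 0.04, DD = 0.03),
                         use_vocab = use_vocabulary(), seed = 1L) {
  assemblage_mode <- match.arg(assemblage_mode)
  stopifnot(n_species >= 2L, n_regions >= 1L, n_regions <= 6L,
            birth_rate > 0, decline_noise_sd >= 0,
            use_probability >= 0, use_probability <= 1)
  if (abs(sum(category_probabilities) - 1) > 1e-8) {
    stop("category_probabilities must sum to 1", call. = FALSE)
  }
  out <- list(n_species = as.integer(n_species),
              n_regions = as.integer(n_regions), birth_rate = birth_rate,
              assemblage_mode = assemblage_mode,
              decline_slope_on_bl = decline_slope_on_bl,
              decline_noise_sd = decline_noise_sd,
              decline_baseline = decline_baseline,
              use_probability = use_probability,
              category_probabilities = category_probabilities,
              use_vocab = use_vocab, seed = as.integer(seed))
  class(out) <- "study_config"
  out
}

#' Simulate a Yule (pure-birth) ultrametric tree
#'
#' Starts from two lineages at the root; while `k` lineages are active the
#' waiting time to the next split is exponential with rate
#' `k * birth_rate`, and a uniformly chosen lineage splits. After the last
#' split one more waiting time is drawn so tips do not sit on a birth event.
#' The result is ultrametric with `n_tips` tips labelled `sp001, sp002, ...`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate births per lineage per Myr.
#' @param seed integer seed.
#' @return A `"phylo"` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 0.1, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  with_seed(seed, {
    n <- as.integer(n_tips)
    root <- n + 1L
    next_node <- root + 1L
    par <- c(root, root)
    btime <- c(0, 0)
    e1 <- integer(0); e2 <- integer(0); elen <- numeric(0)
    t <- 0
    k <- 2L
    while (k < n) {
      t <- t + stats::rexp(1, birth_rate * k)
      i <- sample.int(k, 1L)
      m <- next_node
      next_node <- next_node + 1L
      e1 <- c(e1, par[i]); e2 <- c(e2, m); elen <- c(elen, t - btime[i])
      par[i] <- m; btime[i] <- t
      par <- c(par, m); btime <- c(btime, t)
      k <- k + 1L
    }
    depth <- t + stats::rexp(1, birth_rate * k)
    e1 <- c(e1, par)
    e2 <- c(e2, seq_len(n))
    elen <- c(elen, depth - btime)
    phy <- list(edge = cbind(e1, e2), edge.length = elen,
                Nnode = n - 1L, tip.label = sprintf("sp%03d", seq_len(n)))
    storage.mode(phy$edge) <- "integer"
    dimnames(phy$edge) <- NULL
    class(phy) <- "phylo"
    ape::reorder.phylo(phy, "cladewise")
  })
}

#' Simulate a Brownian / lambda-structured trait
#'
#' Draws one multivariate-normal trait with mean `root_value` and covariance
#' `sigma2 * V(lambda)`, where `V(lambda)` is the tree's Brownian covariance
#' with off-diagonals scaled by `lambda` (lambda = 0 gives independent tips,
#' 1 full Brownian structure).
#'
#' @param tree a `"phylo"`.
#' @param sigma2 Brownian rate (> 0).
#' @param root_value trait mean.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param seed integer seed.
#' @return Named numeric vector over the tips.
#' @export
simulate_trait <- function(tree, sigma2 = 1, root_value = 0, lambda = 1,
                           seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  stopifnot(lambda >= 0, lambda <= 1)
  C <- phylo_vcv(tree)
  V <- lambda_scale(C, lambda) * sigma2
  n <- nrow(V)
  U <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-10 * mean(diag(V)), n))
  })
  with_seed(seed, {
    stats::setNames(root_value + drop(crossprod(U, stats::rnorm(n))),
                    rownames(V))
  })
}

#' Simulate a regional assemblage of controllable phylogenetic structure
#'
#' * `random`: tips drawn uniformly without replacement.
#' * `clustered`: the smallest clade with at least `size` tips is located
#'   (random tie-break) and the members are sampled inside it, guaranteeing
#'   phylogenetic clustering.
#' * `overdispersed`: greedy max-min selection on patristic distances,
#'   seeded with the most distant tip pair.
#'
#' @param tree a `"phylo"`.
#' @param size assemblage size.
#' @param mode `"random"`, `"clustered"` or `"overdispersed"`.
#' @param seed integer seed.
#' @return Character vector of member species.
#' @export
simulate_assemblage <- function(tree, size,
                                mode = c("random", "clustered",
                                         "overdispersed"),
                                seed = NULL) {
  mode <- match.arg(mode)
  n <- length(tree$tip.label)
  stopifnot(size >= 1L, size <= n)
  if (size == n) return(tree$tip.label)
  with_seed(seed, {
    switch(mode,
      random = sample(tree$tip.label, size),
      clustered = {
        cnt <- node_tip_counts(tree)
        internal <- seq.int(n + 1L, max(tree$edge))
        ok <- internal[cnt[internal] >= size]
        if (!length(ok)) stop("no clade large enough", call. = FALSE)
        small <- ok[cnt[ok] == min(cnt[ok])]
        nd <- if (length(small) > 1L) sample(small, 1L) else small
        tips <- clade_tips(tree, nd)
        sample(tips, size)
      },
      overdispersed = {
        D <- patristic_distances(tree)
        sel <- as.vector(which(D == max(D), arr.ind = TRUE)[1, ])
        while (length(sel) < size) {
          rest <- setdiff(seq_len(n), sel)
          mind <- apply(D[rest, sel, drop = FALSE], 1L, min)
          sel <- c(sel, rest[which.max(mind)])
        }
        tree$tip.label[sel[seq_len(size)]]
      })
  })
}

clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n)) desc[[i]] <- i
  for (i in seq_len(nrow(po))) {
    desc[[po[i, 1]]] <- c(desc[[po[i, 1]]], desc[[po[i, 2]]])
  }
  tree$tip.label[desc[[node]]]
}

#' Simulate a species table tied to the tree
#'
#' Plants the study's headline effect: decline rises with species age,
#' `decline = min(100, max(0, baseline + slope * BL + noise))`. Categories
#' are i.i.d. draws from the configured Red-List mix; uses are independent
#' per-species x per-use Bernoulli draws; `h_max` and propagule volume are
#' log-normal; region memberships come from [simulate_assemblage()] with
#' the configured mode.
#'
#' @param tree a `"phylo"`.
#' @param config a [study_config()].
#' @return Data frame with columns `species, iucn_category, global_decline,
#'   h_max, propagule_size, uses, human_pressure, fd, region`.
#' @export
simulate_species_table <- function(tree, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  sp <- tree$tip.label
  n <- length(sp)
  bl <- terminal_branch_lengths(tree)
  seed <- config$seed
  decline <- with_seed(derive_seed(seed, 105), {
    eps <- stats::rnorm(n, 0, config$decline_noise_sd)
    pmin(100, pmax(0, config$decline_baseline +
                     config$decline_slope_on_bl * unname(bl[sp]) + eps))
  })
  categories <- with_seed(derive_seed(seed, 103), {
    sample(names(config$category_probabilities), n, replace = TRUE,
           prob = config$category_probabilities)
  })
  morph <- with_seed(derive_seed(seed, 102), {
    list(h_max = stats::rlnorm(n, log(15), 0.6),
         propagule_size = stats::rlnorm(n, log(5), 1.2),
         fd = stats::rlnorm(n, 0, 0.5))
  })
  uses <- with_seed(derive_seed(seed, 104), {
    vapply(seq_len(n), function(i) {
      u <- config$use_vocab[stats::runif(length(config$use_vocab)) <
                              config$use_probability]
      paste(u, collapse = ";")
    }, character(1))
  })
  regions <- simulate_region_membership(tree, config)
  df <- data.frame(species = sp, iucn_category = categories,
                   global_decline = decline, h_max = morph$h_max,
                   propagule_size = morph$propagule_size, uses = uses,
                   human_pressure = pressure_from_uses(uses),
                   fd = morph$fd,
                   region = vapply(sp, function(s)
                     paste(regions$by_species[[s]], collapse = ";"),
                     character(1)))
  rownames(df) <- NULL
  attr(df, "assemblages") <- regions$assemblages
  df
}

simulate_region_membership <- function(tree, config) {
  n <- length(tree$tip.label)
  regions <- REGION_NAMES[seq_len(config$n_regions)]
  sizes <- pmax(2L, pmin(n, round(REGION_FRACTION[seq_len(config$n_regions)] *
                                    n / 54 * 54)))
  assemblages <- list()
  for (i in seq_along(regions)) {
    assemblages[[regions[i]]] <- simulate_assemblage(
      tree, sizes[i], config$assemblage_mode,
      seed = derive_seed(config$seed, 110 + i))
  }
  by_species <- stats::setNames(vector("list", n), tree$tip.label)
  for (rg in regions) {
    for (s in assemblages[[rg]]) by_species[[s]] <- c(by_species[[s]], rg)
  }
  orphan <- names(by_species)[vapply(by_species, length, integer(1)) == 0L]
  if (length(orphan)) {
    home <- with_seed(derive_seed(config$seed, 119), {
      sample(regions, length(orphan), replace = TRUE)
    })
    for (j in seq_along(orphan)) {
      by_species[[orphan[j]]] <- home[j]
      assemblages[[home[j]]] <- c(assemblages[[home[j]]], orphan[j])
    }
  }
  list(assemblages = assemblages, by_species = by_species)
}

# range width (deg lon) scales down with threat; strips are latitudinally
# thin, mimicking coastal occupancy
CATEGORY_WIDTH <- c(LC = 18, NT = 14, VU = 10, EN = 6, CR = 4, DD = 8,
                    EW = 4, EX = 4)

#' Simulate rectangular coastal ranges
#'
#' Every species gets one thin rectangle per region membership: a longitude
#' interval inside the region's synthetic coastline strip (wider for
#' less-threatened categories) by a 2-4 degree latitude band in the
#' tropics. All rectangles respect `[-180, 180] x [-90, 90]` and are wide
#' enough to catch grid-cell centers at the default 0.25 degree resolution.
#'
#' @param species_table output of [simulate_species_table()].
#' @param config a [study_config()].
#' @return Rectangle data frame
#'   (`species,min_lon,min_lat,max_lon,max_lat`).
#' @export
simulate_ranges <- function(species_table, config = study_config()) {
  with_seed(derive_seed(config$seed, 120), {
    rows <- list()
    for (i in seq_len(nrow(species_table))) {
      sp <- species_table$species[i]
      cat_i <- species_table$iucn_category[i]
      width <- unname(CATEGORY_WIDTH[cat_i])
      if (is.na(width)) width <- 8
      for (rg in strsplit(species_table$region[i], ";", fixed = TRUE)[[1]]) {
        lon_rng <- REGION_LON[[rg]]
        if (is.null(lon_rng)) next
        w <- min(width, diff(lon_rng))
        lo <- stats::runif(1, lon_rng[1], lon_rng[2] - w)
        lat0 <- stats::runif(1, -24, 20)
        h <- stats::runif(1, 2, 4)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, min_lon = lo, min_lat = lat0,
          max_lon = lo + w, max_lat = lat0 + h)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate and write a full synthetic study
#'
#' Produces the complete input bundle the pipeline reads: `tree.nwk`,
#' `species.csv`, `assemblages.csv`, `ranges.csv` and a `config.cfg` echo,
#' byte-identical for a fixed [study_config()] (seed included).
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed); `NULL` keeps the
#'   bundle in memory only.
#' @return List with `tree`, `species_table`, `assemblages`, `ranges`,
#'   `config` and, when written, `paths`.
#' @export
generate_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                             seed = derive_seed(config$seed, 101))
  tab <- simulate_species_table(tree, config)
  assemblages <- attr(tab, "assemblages")
  ranges <- simulate_ranges(tab, config)
  bundle <- list(tree = tree, species_table = tab,
                 assemblages = assemblages, ranges = ranges, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(tree = file.path(out_dir, "tree.nwk"),
                  species = file.path(out_dir, "species.csv"),
                  assemblages = file.path(out_dir, "assemblages.csv"),
                  ranges = file.path(out_dir, "ranges.csv"),
                  config = file.path(out_dir, "config.cfg"))
    write_phylo(tree, paths$tree)
    tab_out <- tab
    attr(tab_out, "assemblages") <- NULL
    utils::write.csv(tab_out, paths$species, row.names = FALSE)
    asm <- data.frame(
      region = rep(names(assemblages),
                   vapply(assemblages, length, integer(1))),
      species = unlist(assemblages, use.names = FALSE))
    utils::write.csv(asm, paths$assemblages, row.names = FALSE)
    utils::write.csv(ranges, paths$ranges, row.names = FALSE)
    writeLines(config_to_lines(config), paths$config)
    bundle$paths <- paths
  }
  invisible(bundle)
}

config_to_lines <- function(config) {
  scal <- function(x) paste(format(x, digits = 15), collapse = ",")
  c(paste0("n_species=", config$n_species),
    paste0("n_regions=", config$n_regions),
    paste0("birth_rate=", scal(config$birth_rate)),
    paste0("assemblage_mode=", config$assemblage_mode),
    paste0("decline_slope_on_bl=", scal(config$decline_slope_on_bl)),
    paste0("decline_noise_sd=", scal(config$decline_noise_sd)),
    paste0("decline_baseline=", scal(config$decline_baseline)),
    paste0("use_probability=", scal(config$use_probability)),
    paste0("category_probabilities=",
           paste(names(config$category_probabilities),
                 format(config$category_probabilities, digits = 15),
                 sep = ":", collapse = ",")),
    paste0("seed=", config$seed))
}
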