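# Config-driven orchestration: metrics -> grid layers -> regional NRI/NTI ->
# phylogenetic signal -> PGLS tables -> per-use chi-squared, with all
# randomness split from one master seed and every output a plain text file.

#' Read a flat key=value run configuration
#'
#' Relative paths are resolved against the config file's directory.
#' Recognised keys: `tree, species, assemblages, ranges, prob_map, out_dir,
#' seed, n_reps, n_perm, cell_size, decline_threshold, min_richness`.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- stats::setNames(
    lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
    vapply(kv, function(x) trimws(x[1]), character(1)))
  base <- dirname(normalizePath(path))
  for (k in c("tree", "species", "assemblages", "ranges", "prob_map",
              "out_dir")) {
    if (!is.null(cfg[[k]]) && !grepl("^(/|[A-Za-z]:)", cfg[[k]])) {
      cfg[[k]] <- file.path(base, cfg[[k]])
    }
  }
  for (k in c("seed", "n_reps", "n_perm", "min_richness")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  }
  for (k in c("cell_size", "decline_threshold")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  }
  cfg
}

default_run_config <- function(cfg) {
  cfg$seed <- cfg$seed %||% 1L
  cfg$n_reps <- cfg$n_reps %||% 999L
  cfg$n_perm <- cfg$n_perm %||% 999L
  cfg$cell_size <- cfg$cell_size %||% 0.25
  cfg$decline_threshold <- cfg$decline_threshold %||% 0
  cfg$min_richness <- cfg$min_richness %||% 1L
  cfg
}

#' Run the full analysis pipeline
#'
#' Reproduces the complete analysis sequence on one input bundle:
#' (1) per-species ED/BL metrics; (2) equal-area grid layers (species
#' richness, mean decline, mean ED, mean BL) and their pairwise Pearson
#' correlations; (3) regional NRI/NTI against the tip-pool null;
#' (4) Blomberg's K with permutation p for extinction probability and global
#' decline; (5) PGLS tables (univariate per predictor plus the two standard
#' multivariate models, for both responses); (6) Yates-corrected chi-squared
#' per use with raw and Holm-adjusted p; plus a machine-readable manifest.
#' All outputs are CSV / ESRI ASCII / JSON under `out_dir` and are
#' byte-identical across reruns of the same config.
#'
#' @param config named list or path to a key=value config file
#'   (see [read_run_config()]).
#' @return Invisible list with every result table and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- default_run_config(config)
  for (k in c("tree", "species", "assemblages", "ranges", "out_dir")) {
    if (is.null(cfg[[k]])) abort_stage("preflight", paste("missing config key:", k))
  }
  for (k in c("tree", "species", "assemblages", "ranges")) {
    if (!file.exists(cfg[[k]])) {
      abort_stage("preflight", paste("input file not found:", cfg[[k]]))
    }
  }
  tree <- read_phylo(cfg$tree)
  tab <- read_species_table(cfg$species)
  assemblages <- read_assemblages(cfg$assemblages)
  ranges <- if (grepl("\\.(geojson|json)$", cfg$ranges)) {
    read_ranges_geojson(cfg$ranges)
  } else read_ranges(cfg$ranges)
  mapping <- read_probability_map(cfg$prob_map)

  # exhaustive name-consistency check before anything is written
  mism <- character(0)
  tips <- tree$tip.label
  bad <- setdiff(tab$species, tips)
  if (length(bad)) mism <- c(mism, paste("species table not in tree:",
                                         paste(bad, collapse = ", ")))
  bad <- setdiff(unique(unlist(assemblages)), tips)
  if (length(bad)) mism <- c(mism, paste("assemblage species not in tree:",
                                         paste(bad, collapse = ", ")))
  rng_sp <- if (is.data.frame(ranges)) unique(ranges$species) else names(ranges)
  bad <- setdiff(rng_sp, tab$species)
  if (length(bad)) mism <- c(mism, paste("range species not in table:",
                                         paste(bad, collapse = ", ")))
  if (length(mism)) abort_stage("preflight", paste(mism, collapse = "; "))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = cfg)
  res_path <- function(f) file.path(cfg$out_dir, f)

  # (1) per-species metrics
  metrics <- tryCatch(
    export_ed_bl(tree, res_path("metrics.csv")),
    error = function(e) abort_stage("metrics", conditionMessage(e)))
  out$metrics <- metrics

  # (2) spatial layers + correlations
  out <- tryCatch(
    pipeline_spatial(out, tree, tab, ranges, metrics, cfg, res_path),
    error = function(e) abort_stage("spatial", conditionMessage(e)))

  # (3) regional community structure
  out$nri_nti <- tryCatch({
    nn <- regional_structure(tree, assemblages, cfg$n_reps,
                             derive_seed(cfg$seed, 1))
    utils::write.csv(nn, res_path("nri_nti.csv"), row.names = FALSE)
    nn
  }, error = function(e) abort_stage("community", conditionMessage(e)))

  # (4) phylogenetic signal
  out$signal <- tryCatch(
    pipeline_signal(tree, tab, mapping, cfg, res_path),
    error = function(e) abort_stage("signal", conditionMessage(e)))

  # (5) PGLS model tables
  out$pgls <- tryCatch(
    pipeline_pgls(tree, tab, mapping, cfg, res_path),
    error = function(e) abort_stage("pgls", conditionMessage(e)))

  # (6) per-use chi-squared
  out$uses <- tryCatch(
    pipeline_uses(tab, cfg, res_path),
    error = function(e) abort_stage("uses", conditionMessage(e)))

  manifest <- list(
    package = "mangroveED",
    version = as.character(utils::packageVersion("mangroveED")),
    master_seed = cfg$seed,
    stage_seeds = list(community = derive_seed(cfg$seed, 1),
                       signal = derive_seed(cfg$seed, 2)),
    n_reps = cfg$n_reps, n_perm = cfg$n_perm,
    n_species_tree = length(tree$tip.label),
    n_species_table = nrow(tab),
    n_regions = length(assemblages),
    n_grid_cells_occupied = nrow(out$layers$richness$values),
    pgls_rows = nrow(out$pgls),
    dropped = out$dropped %||% list())
  jsonlite::write_json(manifest, res_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

pipeline_spatial <- function(out, tree, tab, ranges, metrics, cfg, res_path) {
  if (is.data.frame(ranges)) {
    ext <- c(floor(min(ranges$min_lon)), floor(min(ranges$min_lat)),
             ceiling(max(ranges$max_lon)), ceiling(max(ranges$max_lat)))
  } else {
    allc <- do.call(rbind, unlist(ranges, recursive = FALSE))
    ext <- c(floor(min(allc[, 1])), floor(min(allc[, 2])),
             ceiling(max(allc[, 1])), ceiling(max(allc[, 2])))
  }
  grid <- make_grid(ext, cfg$cell_size)
  occ <- suppressWarnings(rasterize_ranges(ranges, grid))
  decl <- stats::setNames(tab$global_decline, tab$species)
  ed <- stats::setNames(metrics$ed, metrics$species)
  bl <- stats::setNames(metrics$bl, metrics$species)
  layers <- list(richness = richness_layer(occ),
                 decline = mean_metric_layer(occ, decl),
                 ed = mean_metric_layer(occ, ed),
                 bl = mean_metric_layer(occ, bl))
  for (nm in names(layers)) {
    write_ascii_grid(layers[[nm]], res_path(paste0("layer_", nm, ".asc")))
    write_layer_csv(layers[[nm]], res_path(paste0("layer_", nm, ".csv")))
  }
  prs <- utils::combn(names(layers), 2)
  cor_rows <- lapply(seq_len(ncol(prs)), function(j) {
    lc <- layer_correlation(layers[[prs[1, j]]], layers[[prs[2, j]]],
                            cfg$min_richness, layers$richness)
    data.frame(layer_a = prs[1, j], layer_b = prs[2, j], r = lc$r, p = lc$p,
               n_cells = lc$n_cells)
  })
  cors <- do.call(rbind, cor_rows)
  utils::write.csv(cors, res_path("layer_correlations.csv"),
                   row.names = FALSE)
  out$layers <- layers
  out$layer_correlations <- cors
  out
}

pipeline_signal <- function(tree, tab, mapping, cfg, res_path) {
  rows <- list()
  seed <- derive_seed(cfg$seed, 2)
  # global decline: all species in the tree
  keep <- tab$species[tab$species %in% tree$tip.label &
                        !is.na(tab$global_decline)]
  tr1 <- ape::keep.tip(tree, keep)
  k1 <- k_signal_test(phylo_vcv(tr1),
                      stats::setNames(tab$global_decline,
                                      tab$species)[tr1$tip.label],
                      cfg$n_perm, seed)
  rows[[1]] <- data.frame(trait = "global_decline", k = k1$k_value,
                          p_permutation = k1$p_permutation,
                          n_perm = cfg$n_perm, n_species = length(keep))
  # extinction probability: DD/EW/EX drop out via the mapping policy
  ep <- suppressMessages(extinction_probability(tab$iucn_category, mapping))
  keep2 <- tab$species[!is.na(ep) & tab$species %in% tree$tip.label]
  tr2 <- ape::keep.tip(tree, keep2)
  k2 <- k_signal_test(phylo_vcv(tr2),
                      stats::setNames(ep, tab$species)[tr2$tip.label],
                      cfg$n_perm, derive_seed(cfg$seed, 3))
  rows[[2]] <- data.frame(trait = "extinction_probability", k = k2$k_value,
                          p_permutation = k2$p_permutation,
                          n_perm = cfg$n_perm, n_species = length(keep2))
  sig <- do.call(rbind, rows)
  utils::write.csv(sig, res_path("signal.csv"), row.names = FALSE)
  sig
}

#' The standard model set of the analysis
#'
#' Univariate PGLS models for each predictor plus the two standard
#' multivariate sets (propagule size + height + BL or ED + human pressure),
#' for both responses.
#'
#' @param with_fd include the optional opaque `fd` column.
#' @return List of model specs (`response`, `predictors`).
#' @export
standard_model_set <- function(with_fd = FALSE) {
  uni <- c("human_pressure", "bl", "ed", if (with_fd) "fd", "h_max",
           "propagule_size")
  specs <- list()
  for (resp in c("global_decline", "extinction_probability")) {
    for (p in uni) {
      specs[[length(specs) + 1L]] <- list(response = resp, predictors = p)
    }
    specs[[length(specs) + 1L]] <- list(
      response = resp,
      predictors = c("propagule_size", "h_max", "bl", "human_pressure"))
    specs[[length(specs) + 1L]] <- list(
      response = resp,
      predictors = c("propagule_size", "h_max", "ed", "human_pressure"))
  }
  specs
}

pipeline_pgls <- function(tree, tab, mapping, cfg, res_path) {
  specs <- standard_model_set(with_fd = "fd" %in% names(tab))
  rows <- list()
  for (ms in specs) {
    fr <- build_model_frame(tab, tree, ms$response, ms$predictors, mapping)
    fit <- pgls_fit(fr$vcv, fr$y, fr$X, lambda = "ML")
    model_id <- paste0(ms$response, " ~ ",
                       paste(ms$predictors, collapse = " + "))
    cf <- fit$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      model = model_id, response = ms$response, term = cf$term,
      estimate = cf$estimate, se = cf$se, t = cf$t, p = cf$p,
      lambda = fit$lambda, r2_multiple = fit$r_squared_multiple,
      r2_adjusted = fit$r_squared_adjusted, model_p = fit$model_p,
      n = fit$n_species)
  }
  pg <- do.call(rbind, rows)
  utils::write.csv(pg, res_path("pgls.csv"), row.names = FALSE)
  pg
}

pipeline_uses <- function(tab, cfg, res_path) {
  rows <- list()
  for (u in use_vocabulary()) {
    res <- tryCatch(use_decline_association(tab, u, cfg$decline_threshold),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[u]] <- data.frame(use = u, chi_squared = NA_real_, df = 1L,
                              p_raw = NA_real_,
                              note = conditionMessage(res))
    } else {
      rows[[u]] <- data.frame(use = u, chi_squared = res$chi_squared,
                              df = res$df, p_raw = res$p_value, note = "")
    }
  }
  ut <- do.call(rbind, rows)
  ut$p_holm <- NA_real_
  ok <- !is.na(ut$p_raw)
  ut$p_holm[ok] <- stats::p.adjust(ut$p_raw[ok], method = "holm")
  rownames(ut) <- NULL
  utils::write.csv(ut, res_path("uses_chisq.csv"), row.names = FALSE)
  ut
}
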