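#' Mean pairwise and mean nearest-taxon distance
#'
#' `mpd()` is the mean patristic distance over all unordered pairs of
#' assemblage members; `mntd()` is the mean, over members, of the distance to
#' the nearest other member. `mntd(D, m) <= mpd(D, m)` always.
#'
#' @param dist symmetric patristic distance matrix with species dimnames
#'   (see [patristic_distances()]).
#' @param members character vector of species, all present in `dist`.
#' @return A single distance in the units of `dist`.
#' @export
mpd <- function(dist, members) {
  idx <- member_index(dist, members)
  mpd_idx(dist, idx)
}

#' @rdname mpd
#' @export
mntd <- function(dist, members) {
  idx <- member_index(dist, members)
  mntd_idx(dist, idx)
}

member_index <- function(dist, members) {
  members <- unique(as.character(members))
  if (length(members) < 2L) {
    stop("undefined metric: assemblage has fewer than 2 members", call. = FALSE)
  }
  idx <- match(members, rownames(dist))
  if (anyNA(idx)) {
    stop("species not in distance matrix: ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

mpd_idx <- function(D, idx) {
  sub <- D[idx, idx]
  sum(sub) / (length(idx) * (length(idx) - 1L))
}

mntd_idx <- function(D, idx) {
  sub <- D[idx, idx]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

metric_fun <- function(metric) {
  metric <- match.arg(toupper(metric), c("MPD", "MNTD"))
  if (metric == "MPD") mpd_idx else mntd_idx
}

#' Tip-pool null distribution for a community metric
#'
#' Draws `n_reps` pseudo-assemblages of `k` tips uniformly without
#' replacement from *all* tips of the phylogeny (the "phylogeny pool" null:
#' the species pool is the whole tree, not the sample) and evaluates MPD or
#' MNTD on each.
#'
#' @param dist patristic distance matrix over the full tip pool.
#' @param k assemblage size, `2 <= k <= nrow(dist)`.
#' @param metric `"MPD"` or `"MNTD"`.
#' @param n_reps number of null draws (default 999).
#' @param seed integer seed; fixed seed gives an identical sample.
#' @return Numeric vector of length `n_reps`.
#' @export
phylogeny_pool_null <- function(dist, k, metric = "MPD", n_reps = 999L,
                                seed = NULL) {
  n <- nrow(dist)
  if (k < 2L || k > n) stop("k out of range [2, pool size]", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  f <- metric_fun(metric)
  with_seed(seed, {
    vapply(seq_len(n_reps), function(i) f(dist, sample.int(n, k)),
           numeric(1))
  })
}

#' Standardized effect size of MPD / MNTD (NRI / NTI)
#'
#' Compares the observed metric with the tip-pool null of
#' [phylogeny_pool_null()] and reports the negated standardized effect size:
#' `index = -(obs - null_mean) / null_sd`, i.e. NRI for MPD and NTI for MNTD.
#' Positive values indicate phylogenetic clustering (members more closely
#' related than random draws from the pool), negative values overdispersion.
#'
#' Two rank p-values are reported: `p_clustering`, the one-tailed probability
#' `(1 + #\{null <= obs\}) / (n_reps + 1)` (small when the assemblage is
#' clustered; ties count towards the clustering tail, which is conservative),
#' and a two-sided `p_two_sided = min(1, 2 * min(p_clustering,
#' 1 - p_clustering + 1/(n_reps + 1)))`.
#'
#' @inheritParams phylogeny_pool_null
#' @param members character vector of assemblage members.
#' @return A one-row data frame of class `"null_model_result"` with columns
#'   `metric, observed, null_mean, null_sd, index, p_clustering, p_two_sided,
#'   n_reps, seed, note`. When the null is degenerate (zero variance, e.g.
#'   the assemblage is the full pool) `index` is `NA` and `note` explains.
#' @export
ses_index <- function(dist, members, metric = "MPD", n_reps = 999L,
                      seed = NULL) {
  idx <- member_index(dist, members)
  f <- metric_fun(metric)
  obs <- f(dist, idx)
  null <- phylogeny_pool_null(dist, length(idx), metric, n_reps, seed)
  mu <- mean(null)
  sdv <- stats::sd(null)
  p_cl <- (1 + sum(null <= obs)) / (n_reps + 1)
  p_two <- min(1, 2 * min(p_cl, 1 - p_cl + 1 / (n_reps + 1)))
  if (!is.finite(sdv) || sdv == 0) {
    res <- data.frame(metric = toupper(metric), observed = obs, null_mean = mu,
                      null_sd = sdv, index = NA_real_, p_clustering = NA_real_,
                      p_two_sided = NA_real_, n_reps = n_reps,
                      seed = seed %||% NA_integer_,
                      note = "degenerate null (zero variance)")
  } else {
    res <- data.frame(metric = toupper(metric), observed = obs, null_mean = mu,
                      null_sd = sdv, index = -(obs - mu) / sdv,
                      p_clustering = p_cl, p_two_sided = p_two,
                      n_reps = n_reps, seed = seed %||% NA_integer_, note = "")
  }
  class(res) <- c("null_model_result", class(res))
  res
}

#' Regional NRI / NTI table
#'
#' Runs [ses_index()] for both MPD (NRI) and MNTD (NTI) on every assemblage,
#' with per-region seeds split deterministically from `seed` by
#' [derive_seed()]. Regions with fewer than 2 members get an all-`NA` row
#' flagged in `note`.
#'
#' @param tree a `"phylo"` object; its full tip set is the null pool.
#' @param assemblages named list of character vectors (region -> members) or
#'   a long data frame with columns `region, species`.
#' @param n_reps,seed forwarded to [ses_index()].
#' @return Data frame, one NRI and one NTI row per region.
#' @export
regional_structure <- function(tree, assemblages, n_reps = 999L, seed = 1L) {
  if (is.data.frame(assemblages)) {
    assemblages <- split(as.character(assemblages$species),
                         assemblages$region)
  }
  D <- patristic_distances(tree)
  missing_sp <- setdiff(unique(unlist(assemblages)), rownames(D))
  if (length(missing_sp)) {
    stop("assemblage species not in tree: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  j <- 0L
  for (rg in names(assemblages)) {
    for (metric in c("MPD", "MNTD")) {
      j <- j + 1L
      mem <- unique(assemblages[[rg]])
      if (length(mem) < 2L) {
        row <- data.frame(metric = metric, observed = NA_real_,
                          null_mean = NA_real_, null_sd = NA_real_,
                          index = NA_real_, p_clustering = NA_real_,
                          p_two_sided = NA_real_, n_reps = n_reps,
                          seed = NA_integer_, note = "fewer than 2 members")
      } else {
        row <- ses_index(D, mem, metric, n_reps, derive_seed(seed, j))
      }
      row <- cbind(region = rg, row)
      row$index_name <- if (metric == "MPD") "NRI" else "NTI"
      rows[[j]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("region", "index_name", "metric", "observed", "null_mean",
          "null_sd", "index", "p_clustering", "p_two_sided", "n_reps",
          "seed", "note")]
}

#' Read assemblages from long-format CSV
#'
#' Expects columns `region,species`.
#'
#' @param path CSV path.
#' @return Named list region -> character vector of species.
#' @export
read_assemblages <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "species") %in% names(df))) {
    stop("assemblage CSV needs columns region,species", call. = FALSE)
  }
  split(as.character(df$species), df$region)
}
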