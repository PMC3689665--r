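# ---- IUCN category -> extinction probability --------------------------------

#' The packaged IUCN50 extinction-probability mapping
#'
#' Fifty-year extinction probabilities per IUCN Red List category, as used in
#' phylogenetic conservation prioritisation (the "IUCN50" transformation of
#' Mooers et al. 2008, PLoS ONE 3:e3700). Shipped as a plain CSV so users can
#' substitute their own mapping; nothing downstream hard-codes these numbers.
#'
#' @param path optional path to a `category,probability` CSV; defaults to the
#'   packaged IUCN50 file.
#' @return Named numeric vector (category -> probability), strictly
#'   increasing from LC to CR, all values in (0, 1).
#' @export
read_probability_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "iucn50.csv", package = "mangroveED",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "probability") %in% names(df))) {
    stop("probability map needs columns category,probability", call. = FALSE)
  }
  map <- stats::setNames(as.numeric(df$probability),
                         toupper(trimws(df$category)))
  if (any(map <= 0 | map >= 1)) {
    stop("extinction probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  ord <- c("LC", "NT", "VU", "EN", "CR")
  present <- ord[ord %in% names(map)]
  if (length(present) >= 2 && any(diff(map[present]) <= 0)) {
    stop("probabilities must increase from LC to CR", call. = FALSE)
  }
  map
}

#' Map IUCN categories to extinction probabilities
#'
#' @param category character vector of IUCN codes (`LC,NT,VU,EN,CR` plus
#'   `DD,EW,EX` which are handled by `policy`).
#' @param mapping named probability vector from [read_probability_map()].
#' @param policy what to do with categories absent from the mapping
#'   (typically `DD`, `EW`, `EX`): `"exclude"` (default) returns `NA` for
#'   them with a message, `"error"` aborts.
#' @return Numeric vector of probabilities (`NA` for excluded records).
#' @export
extinction_probability <- function(category, mapping = read_probability_map(),
                                   policy = c("exclude", "error")) {
  policy <- match.arg(policy)
  cat_up <- toupper(trimws(as.character(category)))
  p <- unname(mapping[cat_up])
  unmapped <- unique(cat_up[is.na(p)])
  if (length(unmapped)) {
    if (policy == "error") {
      stop("unmapped IUCN category: ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    message("excluding records with unmapped IUCN categories: ",
            paste(unmapped, collapse = ", "))
  }
  p
}

# ---- human pressure ----------------------------------------------------------

#' The controlled vocabulary of mangrove uses
#'
#' Sixteen use classes covering the ethnobotanical literature on mangroves:
#' fuel (firewood, charcoal), construction (building, carving, fishing gear),
#' cultural/spiritual, food and forage, medicinal, ornamental, shade,
#' chemical products (tannin, dye, other compounds), apiculture and thatch.
#'
#' @return Character vector of 16 canonical use labels.
#' @export
use_vocabulary <- function() {
  c("firewood", "charcoal", "building", "carving", "cultural", "spiritual",
    "food", "forage", "medicinal", "ornamental", "shade", "chemicals",
    "tannin", "dye", "fishing", "apiculture")
}

#' Human pressure as the number of distinct uses
#'
#' The count of distinct canonical uses recorded for a species, used as an
#' indirect measure of human pressure. Input labels are lower-cased, trimmed
#' and de-duplicated before counting; labels outside the controlled
#' vocabulary raise a warning (or an error when `strict = TRUE`) and are not
#' counted.
#'
#' @param uses character vector of use labels (possibly with duplicates).
#' @param vocabulary canonical labels, defaults to [use_vocabulary()].
#' @param strict error (instead of warn) on unknown labels.
#' @return Single non-negative integer.
#' @export
human_pressure <- function(uses, vocabulary = use_vocabulary(),
                           strict = FALSE) {
  if (length(uses) == 0L) return(0L)
  u <- unique(tolower(trimws(as.character(uses))))
  u <- u[nzchar(u)]
  unknown <- setdiff(u, vocabulary)
  if (length(unknown)) {
    msg <- paste("unknown use labels:", paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  length(intersect(u, vocabulary))
}

# ---- Yates-corrected chi-squared --------------------------------------------

#' Pearson's chi-squared test with Yates' continuity correction (2 x 2)
#'
#' Computed in closed form: for a table `[[a,b],[c,d]]` with total `N`,
#' `chi2 = N * (max(0, |ad - bc| - N/2))^2 / (r1 r2 c1 c2)` and the p-value
#' comes from the upper tail of chi-squared with 1 df. The correction is
#' floored at zero, so perfectly balanced tables give `chi2 = 0, p = 1`.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @return List of class `"contingency_result"` with `table`, `chi_squared`,
#'   `df` (always 1) and `p_value`.
#' @export
chisq_yates <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tb < 0) || anyNA(tb)) stop("counts must be non-negative",
                                     call. = FALSE)
  N <- sum(tb)
  r <- rowSums(tb)
  cl <- colSums(tb)
  if (N == 0 || any(r == 0) || any(cl == 0)) {
    stop("degenerate margin: a row or column total is zero", call. = FALSE)
  }
  adbc <- tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1]
  corr <- max(0, abs(adbc) - N / 2)
  chi <- N * corr^2 / (r[1] * r[2] * cl[1] * cl[2])
  out <- list(table = tb, chi_squared = unname(chi), df = 1L,
              p_value = stats::pchisq(unname(chi), df = 1, lower.tail = FALSE))
  class(out) <- "contingency_result"
  out
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Yates-corrected chi-squared = %.4g, df = 1, p = %.4g\n",
              x$chi_squared, x$p_value))
  invisible(x)
}

#' Association between one use and global decline
#'
#' Builds the 2x2 table (has the use x declining) where "declining" means
#' `global_decline > decline_threshold`, and applies [chisq_yates()].
#'
#' @param species_table data frame with columns `species`, `global_decline`
#'   and either a semicolon-delimited `uses` column or a wide 0/1 column
#'   `use_<use>`.
#' @param use a canonical use label.
#' @param decline_threshold decline above this counts as declining
#'   (default 0).
#' @return A `"contingency_result"`.
#' @export
use_decline_association <- function(species_table, use,
                                    decline_threshold = 0) {
  has_use <- species_has_use(species_table, use)
  declining <- species_table$global_decline > decline_threshold
  tb <- rbind(c(sum(has_use & declining), sum(has_use & !declining)),
              c(sum(!has_use & declining), sum(!has_use & !declining)))
  dimnames(tb) <- list(use = c("yes", "no"), declining = c("yes", "no"))
  chisq_yates(tb)
}

pressure_from_uses <- function(uses_col) {
  vapply(as.character(uses_col), function(s) {
    if (is.na(s)) return(NA_integer_)
    u <- strsplit(s, ";", fixed = TRUE)[[1]]
    suppressWarnings(human_pressure(u))
  }, integer(1), USE.NAMES = FALSE)
}

species_has_use <- function(species_table, use) {
  wide <- paste0("use_", use)
  if (wide %in% names(species_table)) {
    return(species_table[[wide]] > 0)
  }
  if (!"uses" %in% names(species_table)) {
    stop("species table has neither 'uses' nor '", wide, "' column",
         call. = FALSE)
  }
  vapply(strsplit(as.character(species_table$uses), ";", fixed = TRUE),
         function(u) use %in% tolower(trimws(u)), logical(1))
}

# ---- model frame assembly -----------------------------------------------------

# which variables may legitimately contain zeros and get the +1 offset
ZERO_CAPABLE <- c("global_decline", "human_pressure")

log10_transform <- function(x, name) {
  if (name %in% ZERO_CAPABLE) return(log10(x + 1))
  if (any(x <= 0, na.rm = TRUE)) {
    warning("variable '", name, "' contains non-positive values; ",
            "using log10(x + 1) offset", call. = FALSE)
    return(log10(x + 1))
  }
  log10(x)
}

#' Assemble an aligned PGLS model frame
#'
#' Produces the response vector, design matrix and pruned phylogenetic
#' covariance for a PGLS model, applying the log10 transform policy
#' (variables that can be zero -- decline, human pressure -- are transformed
#' as `log10(x + 1)`; strictly positive traits as `log10(x)`), deriving
#' `bl`, `ed` (from the tree), `human_pressure` (from `uses`) and
#' `extinction_probability` (from the IUCN mapping) as needed, and dropping
#' species with any missing value (listwise deletion). Species absent from
#' the tree are dropped and logged.
#'
#' @param species_table species data frame (see [read_species_table()]).
#' @param tree `"phylo"` whose tips cover the retained species.
#' @param response `"global_decline"` or `"extinction_probability"`.
#' @param predictors character vector among `human_pressure, bl, ed, fd,
#'   h_max, propagule_size` (or any numeric column of `species_table`).
#' @param mapping IUCN probability map, used when the response or a
#'   predictor needs `extinction_probability`.
#' @param transform apply the log10 policy (default TRUE).
#' @return List with `y` (named response), `X` (design matrix, no
#'   intercept), `vcv` (pruned covariance), `species`, `dropped` (data frame
#'   of dropped species + reason), `response`, `predictors`.
#' @export
build_model_frame <- function(species_table, tree, response,
                              predictors,
                              mapping = read_probability_map(),
                              transform = TRUE) {
  stopifnot(is.data.frame(species_table), "species" %in% names(species_table))
  df <- species_table
  df$species <- as.character(df$species)
  dropped <- data.frame(species = character(), reason = character())

  in_tree <- df$species %in% tree$tip.label
  if (any(!in_tree)) {
    dropped <- rbind(dropped, data.frame(species = df$species[!in_tree],
                                         reason = "not in tree"))
    df <- df[in_tree, , drop = FALSE]
  }

  need <- unique(c(response, predictors))
  if ("human_pressure" %in% need && !"human_pressure" %in% names(df)) {
    df$human_pressure <- pressure_from_uses(df$uses)
  }
  if (any(c("bl", "ed") %in% need)) {
    bl <- terminal_branch_lengths(tree)
    ed <- fair_proportion_ed(tree)
    df$bl <- unname(bl[df$species])
    df$ed <- unname(ed[df$species])
  }
  if ("extinction_probability" %in% need &&
      !"extinction_probability" %in% names(df)) {
    df$extinction_probability <-
      suppressMessages(extinction_probability(df$iucn_category, mapping))
  }
  miss_col <- setdiff(need, names(df))
  if (length(miss_col)) stop("missing columns: ",
                             paste(miss_col, collapse = ", "), call. = FALSE)

  vals <- df[, need, drop = FALSE]
  complete <- stats::complete.cases(vals)
  if (any(!complete)) {
    dropped <- rbind(dropped, data.frame(species = df$species[!complete],
                                         reason = "missing value"))
    df <- df[complete, , drop = FALSE]
    vals <- vals[complete, , drop = FALSE]
  }
  q <- length(predictors)
  if (nrow(df) < q + 2L) stop("fewer than q + 2 complete cases", call. = FALSE)

  if (transform) {
    for (nm in need) vals[[nm]] <- log10_transform(vals[[nm]], nm)
  }
  pruned <- ape::keep.tip(tree, df$species)
  Cfull <- phylo_vcv(pruned)[df$species, df$species]
  y <- stats::setNames(vals[[response]], df$species)
  X <- as.matrix(vals[, predictors, drop = FALSE])
  rownames(X) <- df$species
  list(y = y, X = X, vcv = Cfull, species = df$species, dropped = dropped,
       response = response, predictors = predictors)
}

#' Read a species table CSV
#'
#' Expected columns: `species, iucn_category, global_decline, h_max,
#' propagule_size, uses` (semicolon-delimited) and/or wide `use_<name>` 0/1
#' columns, optional `fd` and `region` (semicolon-delimited memberships).
#'
#' @param path CSV path.
#' @return Data frame with `human_pressure` derived from `uses` when absent.
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("species column required", call. = FALSE)
  if (!"human_pressure" %in% names(df) && "uses" %in% names(df)) {
    df$human_pressure <- pressure_from_uses(df$uses)
  }
  df
}
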