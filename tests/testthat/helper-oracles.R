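# Independent oracles, deliberately sharing no code with the package.

# Minimal recursive-descent Newick parser. Returns the pendant edge length
# of every labelled tip, computed without ape and without the package's
# traversal machinery.
oracle_pendant_lengths <- function(text) {
  s <- gsub("\\s", "", text)
  s <- sub(";.*$", "", s)
  pos <- 1L
  nch <- nchar(s)
  peek <- function() if (pos <= nch) substr(s, pos, pos) else ""
  out <- new.env()
  out$pend <- numeric(0)
  read_label <- function() {
    start <- pos
    while (pos <= nch && !(substr(s, pos, pos) %in% c(",", ")", ":", "(")))
      pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  read_length <- function() {
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    start <- pos
    while (pos <= nch && grepl("[0-9eE.+-]", substr(s, pos, pos)))
      pos <<- pos + 1L
    as.numeric(substr(s, start, pos - 1L))
  }
  parse_clade <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_clade()
        if (peek() == ",") { pos <<- pos + 1L } else break
      }
      stopifnot(peek() == ")")
      pos <<- pos + 1L
      read_label() # internal label, unused
      read_length() # internal edge, unused here
      invisible(NULL)
    } else {
      lab <- read_label()
      len <- read_length()
      out$pend[lab] <- len
      invisible(NULL)
    }
  }
  parse_clade()
  out$pend
}

# Exhaustive tip-pool null: evaluate a metric over all C(n, k) subsets.
oracle_exhaustive_null <- function(D, k, metric = c("MPD", "MNTD")) {
  metric <- match.arg(metric)
  n <- nrow(D)
  sets <- utils::combn(n, k)
  apply(sets, 2, function(idx) {
    sub <- D[idx, idx]
    if (metric == "MPD") {
      mean(sub[upper.tri(sub)])
    } else {
      diag(sub) <- Inf
      mean(apply(sub, 1, min))
    }
  })
}

# Yates-corrected chi-squared via expected frequencies (independent route).
oracle_chisq_yates <- function(tb) {
  e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  sum(pmax(0, abs(tb - e) - 0.5)^2 / e)
}

# shared small fixtures
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n = 6, len = 3) {
  parse_newick(paste0("(", paste0("t", seq_len(n), ":", len, collapse = ","),
                      ");"))
}

balanced_tree <- function(depth) {
  # fully balanced binary tree with unit edges, 2^depth tips
  f <- function(d, p) {
    if (d == 0) return(paste0(p, ":1"))
    paste0("(", f(d - 1, paste0(p, "L")), ",", f(d - 1, paste0(p, "R")),
           "):1")
  }
  parse_newick(paste0(f(depth, "t"), ";"))
}
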