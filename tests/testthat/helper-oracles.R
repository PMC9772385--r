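# Independent brute-force oracles, deliberately written as plain loops over
# the site-type definitions rather than through the package's scanner.

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

oracle_rc <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  paste(rev(unname(comp_base[chars])), collapse = "")
}

# All seed-match sites of one family on one UTR, by checking every core
# window against the four patterns built from first principles.
oracle_sites <- function(utr, seed) {
  utr <- gsub("U", "T", toupper(utr))
  p6 <- oracle_rc(substr(seed, 1, 6))      # complement of mature 2-7
  m8 <- unname(comp_base[substr(seed, 7, 7)])  # complement of mature 8
  n <- nchar(utr)
  out <- list()
  j <- 1L
  while (j + 5L <= n) {
    if (substr(utr, j, j + 5L) == p6) {
      has_m8 <- j > 1L && substr(utr, j - 1L, j - 1L) == m8
      has_a1 <- j + 6L <= n && substr(utr, j + 6L, j + 6L) == "A"
      type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
              else if (has_a1) "7mer-A1" else "6mer"
      s <- if (has_m8) j - 1L else j
      e <- if (has_a1) j + 6L else j + 5L
      out[[length(out) + 1L]] <- c(start = s, end = e, type = type)
    }
    j <- j + 1L
  }
  out
}

# Introduced/removed counts overlapping an edit, from the oracle scanner.
oracle_delta <- function(utr, seed, pos) {
  edited <- utr
  substr(edited, pos, pos) <- "G"
  keyify <- function(sites) {
    keep <- Filter(function(s) {
      as.integer(s[["start"]]) <= pos && pos <= as.integer(s[["end"]])
    }, sites)
    vapply(keep, function(s) paste(s, collapse = "_"), character(1))
  }
  pre <- keyify(oracle_sites(utr, seed))
  post <- keyify(oracle_sites(edited, seed))
  c(introduced = length(setdiff(post, pre)),
    removed = length(setdiff(pre, post)))
}

# The five-clause cascade, restated clause by clause.
oracle_cascade <- function(introduced, removed) {
  if (all(introduced == 0L) && all(removed == 0L)) return("no_overlaps")
  if (all(introduced == removed)) return("site_unchanged")
  gain_all <- all(introduced >= removed)
  gain_some <- any(introduced > removed)
  loss_all <- all(introduced <= removed)
  loss_some <- any(introduced < removed)
  if (gain_all && gain_some) return("gain")
  if (loss_all && loss_some) return("lost")
  "mixed"
}

# Exact signed-rank one-tailed p value by enumerating all sign assignments.
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  if (alternative == "greater") mean(v_all >= v_obs) else mean(v_all <= v_obs)
}

# Exact rank-sum one-tailed p value by enumerating group assignments.
oracle_rank_sum_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}
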