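# Independent brute-force oracles and toy-instance builders. These stay
# deliberately naive (nested loops, string operations, exhaustive
# enumeration) so they share no code path with the implementation.

toy_alphabet <- strsplit("ADEHIKLMNPQRSTVY", "")[[1]]

# chain with a manually imposed region map built from named block lengths
toy_chain <- function(n = 30, blocks = c(FR1 = 8, CDR1 = 4, FR2 = 7,
                                         CDR2 = 3, FR3 = 5, CDR3 = 2,
                                         FR4 = 1),
                      chain_id = "L", seq = NULL) {
  stopifnot(sum(blocks) == n)
  if (is.null(seq)) {
    seq <- paste(sample(toy_alphabet, n, replace = TRUE), collapse = "")
  }
  ch <- parse_chain(seq, chain_id)
  map <- tibble::tibble(
    position = seq_len(n),
    region = rep(names(blocks), blocks)
  )
  delimit_regions(ch, "imgt", region_map = map)
}

identity_mapping <- function(n, chain_id = "L") {
  abscan:::new_query_mapping(
    tibble::tibble(query_position = seq_len(n), column = seq_len(n)),
    anchor = "toy", chain_id = chain_id
  )
}

# random template set over the same columns as the query: each position is
# kept, substituted, or gapped independently per template
toy_set <- function(query_seq, n_templates = 4, p_mut = 0.2, p_gap = 0.05) {
  q <- strsplit(query_seq, "")[[1]]
  seqs <- vapply(seq_len(n_templates), function(t) {
    s <- q
    for (i in seq_along(s)) {
      r <- runif(1)
      if (r < p_gap) {
        s[i] <- "-"
      } else if (r < p_gap + p_mut) {
        s[i] <- sample(setdiff(toy_alphabet, q[i]), 1)
      }
    }
    paste(s, collapse = "")
  }, character(1))
  template_set(sprintf("T%02d", seq_len(n_templates)), seqs)
}

# ---- membership / linear / conformational oracles --------------------------

oracle_rat_unique <- function(query_seq, fr_pos, set) {
  q <- strsplit(query_seq, "")[[1]]
  tem <- strsplit(set$templates$aligned, "")
  out <- integer()
  for (p in fr_pos) {
    if (q[p] == "X") next
    seen <- FALSE
    for (t in tem) {
      if (t[p] == q[p]) seen <- TRUE
    }
    if (!seen) out <- c(out, p)
  }
  out
}

oracle_linear_windows <- function(query_seq, region_map_tbl, set, w = 6,
                                  max_mm = 0) {
  q <- strsplit(query_seq, "")[[1]]
  tem <- strsplit(set$templates$aligned, "")
  starts <- integer()
  for (reg in unique(region_map_tbl$region)) {
    if (!startsWith(reg, "FR")) next
    pos <- region_map_tbl$position[region_map_tbl$region == reg]
    if (length(pos) < w) next
    for (s in seq(min(pos), max(pos) - w + 1)) {
      win <- s:(s + w - 1)
      if (any(q[win] == "X")) next
      matched <- FALSE
      for (t in tem) {
        mm <- 0
        for (i in win) if (t[i] != q[i]) mm <- mm + 1
        if (mm <= max_mm) matched <- TRUE
      }
      if (!matched) starts <- c(starts, s)
    }
  }
  starts
}

# pairwise minimum distance by explicit double loop
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

oracle_conformational <- function(query_seq, fr_pos, set, coords,
                                  cutoff = 5, exclude_adjacent = TRUE) {
  q <- strsplit(query_seq, "")[[1]]
  tem <- strsplit(set$templates$aligned, "")
  out <- list()
  for (ai in seq_along(fr_pos)) {
    for (bi in seq_along(fr_pos)) {
      if (bi <= ai) next
      i <- fr_pos[ai]; j <- fr_pos[bi]
      if (q[i] == "X" || q[j] == "X") next
      if (exclude_adjacent && abs(i - j) <= 1) next
      d <- oracle_min_dist(coords[[as.character(i)]],
                           coords[[as.character(j)]])
      if (d >= cutoff) next
      cooccur <- FALSE
      for (t in tem) {
        if (t[i] == q[i] && t[j] == q[j]) cooccur <- TRUE
      }
      if (!cooccur) out[[length(out) + 1]] <- c(i, j)
    }
  }
  out
}

# ---- global-alignment enumeration oracle -----------------------------------

# exhaustive recursion over all global alignments; linear gap penalty
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -4) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# ---- rigid motions ---------------------------------------------------------

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

apply_rigid <- function(pts, rot, trans) {
  sweep(pts %*% t(rot), 2, trans, "+")
}

# best rmsd over n random rigid motions of `mobile` onto `reference`
# (centroid-aligned translations with jitter), vectorized over rotations
oracle_best_rigid_rmsd <- function(mobile, reference, n_motions = 10000,
                                   jitter = 0.2) {
  n <- nrow(mobile)
  pm <- sweep(mobile, 2, colMeans(mobile))
  pr <- sweep(reference, 2, colMeans(reference))
  rt_all <- matrix(0, 3, 3 * n_motions)
  for (k in seq_len(n_motions)) {
    rt_all[, (3 * k - 2):(3 * k)] <- t(random_rotation())
  }
  moved <- pm %*% rt_all                      # n x 3*n_motions
  jit <- matrix(rnorm(3 * n_motions, sd = jitter), 3)
  jit[, 1] <- 0                               # include the pure centroid fit
  d2 <- (moved - matrix(pr, n, 3 * n_motions) -
           matrix(rep(jit, each = n), n, 3 * n_motions))^2
  per_block <- d2[, seq(1, 3 * n_motions, 3)] +
    d2[, seq(2, 3 * n_motions, 3)] + d2[, seq(3, 3 * n_motions, 3)]
  sqrt(min(colMeans(per_block)))
}

# parental chains carrying the published rat residues at the table positions
parental_for_tables <- function(seed = 11) {
  tab <- mab_1_17_2_substitutions()
  withr::with_seed(seed, {
    seqs <- c(
      L = paste(sample(toy_alphabet, 107, replace = TRUE), collapse = ""),
      H = paste(sample(toy_alphabet, 118, replace = TRUE), collapse = "")
    )
    for (i in seq_len(nrow(tab))) {
      substr(seqs[[tab$chain[i]]], tab$position[i], tab$position[i]) <-
        tab$rat_aa[i]
    }
    seqs
  })
}
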