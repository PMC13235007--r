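# Independent oracles, written before the features they check and kept
# free of the package's own component code paths.

# Breadth-first flood fill over same-label pixels of a 2D integer matrix.
# Returns a list per cluster id: vector of connected-region sizes.
oracle_regions <- function(labels, connectivity = 8) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 4) {
    offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  }
  out <- list()
  queue_r <- integer(nr * nc); queue_c <- integer(nr * nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    lab <- labels[r0, c0]
    if (lab == 0 || seen[r0, c0]) next
    head <- 1L; tail <- 1L
    queue_r[1] <- r0; queue_c[1] <- c0
    seen[r0, c0] <- TRUE
    size <- 0L
    while (head <= tail) {
      r <- queue_r[head]; c <- queue_c[head]; head <- head + 1L
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (seen[rr, cc] || labels[rr, cc] != lab) next
        seen[rr, cc] <- TRUE
        tail <- tail + 1L
        queue_r[tail] <- rr; queue_c[tail] <- cc
      }
    }
    key <- as.character(lab)
    out[[key]] <- c(out[[key]], size)
  }
  out
}

# Direct evaluation of the ITH formula from per-cluster region sizes
# (clusters taken in ascending id order).
oracle_ith <- function(region_sizes) {
  region_sizes <- region_sizes[order(as.integer(names(region_sizes)))]
  s_total <- sum(unlist(region_sizes))
  1 - sum(vapply(region_sizes, function(s) max(s) / length(s),
                 numeric(1))) / s_total
}

# Exhaustive pairwise concordance AUC with 0.5 tie credit (every
# positive-negative pair enumerated via outer).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# Symmetric distance-1 GLCM features of one fully-masked window, by
# exhaustive enumeration of adjacent pixel pairs.
oracle_glcm <- function(win, levels) {
  nr <- nrow(win); nc <- ncol(win)
  dirs <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  pairs <- matrix(0, levels, levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) for (d in dirs) {
    rr <- r + d[1]; cc <- c + d[2]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    a <- win[r, c]; b <- win[rr, cc]
    pairs[a, b] <- pairs[a, b] + 1
    pairs[b, a] <- pairs[b, a] + 1
  }
  p <- pairs / sum(pairs)
  idx <- expand.grid(a = seq_len(levels), b = seq_len(levels))
  pv <- p[cbind(idx$a, idx$b)]
  diff <- idx$a - idx$b
  mu <- sum(pv * (idx$a - 1))
  va <- sum(pv * (idx$a - 1)^2) - mu^2
  corr <- if (va > 1e-12)
    (sum(pv * (idx$a - 1) * (idx$b - 1)) - mu^2) / va else 0
  list(contrast = sum(pv * diff^2),
       homogeneity = sum(pv / (1 + abs(diff))),
       asm = sum(pv^2),
       correlation = corr)
}

# Random label maps with labels 1..k covering the full grid (background
# optional via p0).
random_label_map <- function(nr = 32, nc = 32, k = 3, p0 = 0) {
  probs <- c(p0, rep((1 - p0) / k, k))
  matrix(sample(0:k, nr * nc, replace = TRUE, prob = probs), nr, nc)
}

expect_same_region_stats <- function(labels, connectivity) {
  stats <- connected_regions(labels, connectivity)
  orc <- oracle_regions(labels, connectivity)
  for (i in seq_len(nrow(stats))) {
    sizes <- orc[[as.character(stats$cluster[i])]]
    expect_identical(stats$n_regions[i], length(sizes))
    expect_identical(stats$s_max[i], max(sizes))
    expect_identical(stats$s_i[i], sum(sizes))
  }
  invisible(stats)
}
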