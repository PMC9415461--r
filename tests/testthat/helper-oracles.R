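# independent oracles and small fixture builders used across tests

# O(N^2) direct-summation DFT (the transform's defining sum)
dft_direct <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * k * n / N)), complex(1))
}

# brute-force Pearson correlation from the covariance definition
pearson_bf <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# all 7 unordered two-block partitions of 4 items
two_block_partitions <- function(items) {
  stopifnot(length(items) == 4)
  parts <- list()
  for (sz in 1:2) {
    combs <- utils::combn(items, sz, simplify = FALSE)
    for (a in combs) parts[[length(parts) + 1]] <- list(a, setdiff(items, a))
  }
  # size-2 splits are enumerated twice (block and complement); deduplicate
  keys <- vapply(parts, function(p)
    paste(sort(vapply(p, function(b) paste(sort(b), collapse = ","),
                      character(1))), collapse = "|"), character(1))
  parts[!duplicated(keys)]
}

# mean within-block distance of a partition (blocks of size 1 contribute 0)
partition_cost <- function(partition, d) {
  dm <- as.matrix(d)
  pairs <- 0
  tot <- 0
  for (b in partition) {
    if (length(b) < 2) next
    cmb <- utils::combn(b, 2)
    for (j in seq_len(ncol(cmb))) {
      tot <- tot + dm[cmb[1, j], cmb[2, j]]
      pairs <- pairs + 1
    }
  }
  tot / max(pairs, 1)
}

# frame with a single rasterized disk: uniform RI excess, flat height
disk_frame <- function(radius_um = 10, px = 0.5, n_m = 1.333,
                       dn = 0.02, height = 5, cycle = 1L, npx = 61L) {
  ctr <- (npx + 1) / 2 * px
  xs <- (seq_len(npx) - 0.5) * px
  inside <- outer(xs, xs, function(x, y)
    (x - ctr)^2 + (y - ctr)^2 <= radius_um^2)
  mask <- matrix(0L, npx, npx)
  mask[inside] <- 1L
  ri <- matrix(n_m, npx, npx)
  ri[inside] <- n_m + dn
  hgt <- matrix(0, npx, npx)
  hgt[inside] <- height
  field_frame(cycle, mask, ri, hgt, pixel_size = px, medium_index = n_m)
}

# random 4-connected-ish blob mask (union of random disks), one label
blob_frame <- function(seed, px = 0.5, npx = 61L, n_m = 1.333) {
  set.seed(seed)
  xs <- (seq_len(npx) - 0.5) * px
  inside <- matrix(FALSE, npx, npx)
  for (i in 1:4) {
    cx <- runif(1, 10, npx * px - 10)
    cy <- runif(1, 10, npx * px - 10)
    r <- runif(1, 3, 6)
    inside <- inside | outer(xs, xs, function(x, y)
      (x - cx)^2 + (y - cy)^2 <= r^2)
  }
  mask <- matrix(0L, npx, npx)
  mask[inside] <- 1L
  ri <- matrix(n_m, npx, npx)
  ri[inside] <- n_m + 0.02
  hgt <- matrix(0, npx, npx)
  hgt[inside] <- 4
  field_frame(1L, mask, ri, hgt, pixel_size = px, medium_index = n_m)
}

# all permutations of 1..n (for order-invariance checks)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# noiseless copy of an archetype (degenerate heterogeneity/noise)
noiseless <- function(a) {
  archetype_spec(a$name, a$knots, cell_effect_sd = 0, noise_sd = NULL,
                 noise_autocorr = 0,
                 arrest_onset = a$arrest_onset,
                 division_rate = NULL, death_onset = NULL,
                 death_hazard = NULL,
                 medium_index = a$medium_index,
                 ri_increment = a$ri_increment)
}

# hand-built constant-parameter records: one row per cell per cycle
const_records <- function(values_by_cell, n_cycles, condition = "demo") {
  do.call(rbind, lapply(names(values_by_cell), function(id) {
    v <- values_by_cell[[id]]
    data.frame(condition = condition, cell_id = id,
               cycle = seq_len(n_cycles), alive = TRUE,
               area = v, stringsAsFactors = FALSE)
  }))
}
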