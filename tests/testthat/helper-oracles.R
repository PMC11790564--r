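# Independent brute-force oracles and small fixtures shared across tests.

# all-pairs physical-distance oracle: for every voxel, min distance (mm) to
# any TRUE voxel of `mask`
brute_force_edt <- function(mask, voxel_size_mm) {
  dims <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  src_mm <- sweep(src, 2, voxel_size_mm, `*`)
  all_idx <- arrayInd(seq_len(prod(dims)), dims)
  all_mm <- sweep(all_idx, 2, voxel_size_mm, `*`)
  d <- apply(all_mm, 1, function(p) sqrt(min(colSums((t(src_mm) - p)^2))))
  array(d, dim = dims)
}

# recursive flood-fill connected-components oracle (slow, independent of the
# package's BFS labeling)
flood_fill_labels <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & (connectivity == 26L |
                          (connectivity == 18L & m <= 2) |
                          (connectivity == 6L & m <= 1)), , drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ai <- arrayInd(cur, dims)
      nb <- sweep(offs, 2, as.integer(ai), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      for (j in lin) if (mask[j] && lab[j] == 0L) {
        lab[j] <- nxt
        stack <- c(stack, j)
      }
    }
  }
  lab
}

# a compact cohort spec on a reduced grid for fast end-to-end tests
small_spec <- function(..., seed = 3L) {
  cohort_spec(n_subjects = 2, n_longitudinal = 1,
              grid_shape = c(64L, 64L, 32L),
              ventricle_semi_mm = c(6, 10, 5),
              lesion_count_lambda = 2, lesion_count_min = 3L,
              seed = seed, ...)
}
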