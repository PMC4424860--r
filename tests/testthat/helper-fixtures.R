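# Small shared fixtures, built in code at load time.

tiny_grid <- function(dims = c(8, 8, 8), voxel = c(3, 3, 3)) {
  volume_grid(dims, voxel)
}

# random z-map on a tiny grid
random_map <- function(seed, dims = c(8, 8, 8)) {
  withr::with_seed(seed, stat_map(array(rnorm(prod(dims)), dims), tiny_grid(dims)))
}

random_mask <- function(seed, dims = c(8, 8, 8), p = 0.2) {
  withr::with_seed(seed, binary_mask(array(runif(prod(dims)) < p, dims), tiny_grid(dims)))
}

# independent flood-fill oracle for connected components: iterative label
# propagation to a fixed point (no shared code with find_clusters)
oracle_clusters <- function(mask, connectivity = 6) {
  dims <- mask$grid$dims
  lab <- array(0L, dims)
  lab[mask$membership] <- seq_len(sum(mask$membership))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(offs != 0)
  manh <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = manh == 1, "18" = manh >= 1 & nz <= 2, "26" = manh >= 1), ,
               drop = FALSE]
  repeat {
    changed <- FALSE
    for (i in which(mask$membership)) {
      co <- arrayInd(i, dims)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        j <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (mask$membership[j] && lab[j] < lab[i]) { lab[i] <- lab[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  split(which(mask$membership), lab[mask$membership])
}

# canonical form of a cluster partition for comparison
partition_sets <- function(voxel_lists) {
  unname(lapply(voxel_lists, sort)[order(vapply(voxel_lists, min, numeric(1)))])
}
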