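# Shared fixtures: tiny phantoms and reduced network specifications sized
# for fast unit tests (grids compatible with the pooling schedule).

tiny_phantom_config <- function(grid = c(16, 16, 8)) {
  phantom_config(grid_size = grid)
}

tiny_spec <- function() model_spec(base_filters = 2L, bottom_filters = 8L)

reduced_spec <- function() model_spec(base_filters = 4L, bottom_filters = 32L)

tiny_case <- function(seed = 1, domain = "source", grid = c(16, 16, 8),
                      shift = domain_shift_config()) {
  cs <- generate_case(tiny_phantom_config(grid), domain = domain,
                      shift = shift, seed = seed)
  list(case_id = paste0("case", seed), volume = cs$volume, labels = cs$labels)
}

random_probmap <- function(dim = c(4, 4, 2), C = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- prod(dim)
  p <- matrix(rexp(C * N), C, N)
  p <- sweep(p, 2, colSums(p), "/")
  prob_map(p, dim)
}

random_onehot <- function(dim = c(4, 4, 2), C = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- prod(dim)
  Y <- matrix(0, C, N)
  Y[cbind(sample.int(C, N, replace = TRUE), seq_len(N))] <- 1
  Y
}

# Independent flood-fill component labelling used as an oracle for the C++
# implementation (recursive frontier growth over an adjacency offset set).
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask != 0, arr.ind = TRUE)
  key <- function(ix) paste(ix[, 1], ix[, 2], ix[, 3])
  fg <- new.env()
  for (r in seq_len(nrow(idx_all))) assign(key(idx_all[r, , drop = FALSE]), TRUE, fg)
  for (r in seq_len(nrow(idx_all))) {
    v <- idx_all[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    frontier <- matrix(v, ncol = 3)
    lab[v[1], v[2], v[3]] <- nxt
    while (nrow(frontier) > 0) {
      nbrs <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o) {
        sweep(frontier, 2, -as.numeric(offs[o, ]), "+")
      }))
      ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= d[1] &
        nbrs[, 2] >= 1 & nbrs[, 2] <= d[2] &
        nbrs[, 3] >= 1 & nbrs[, 3] <= d[3]
      nbrs <- nbrs[ok, , drop = FALSE]
      if (nrow(nbrs) == 0) break
      keep <- vapply(seq_len(nrow(nbrs)), function(i) {
        x <- nbrs[i, ]
        mask[x[1], x[2], x[3]] != 0 && lab[x[1], x[2], x[3]] == 0L
      }, TRUE)
      nbrs <- unique(nbrs[keep, , drop = FALSE])
      if (nrow(nbrs) == 0) break
      for (i in seq_len(nrow(nbrs))) lab[nbrs[i, 1], nbrs[i, 2], nbrs[i, 3]] <- nxt
      frontier <- nbrs
    }
  }
  lab
}
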