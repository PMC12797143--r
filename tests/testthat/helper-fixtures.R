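# shared fixtures: everything is generated in code at test time

tiny_grid <- function(shape = c(12, 12, 12), voxel_size = 2) {
  voxel_grid(shape, voxel_size = voxel_size)
}

tiny_mask <- function(shape = c(12, 12, 12), type = "box") {
  toy_mask(shape, type = type)
}

# minimal foci tibble builder
make_foci <- function(study_id, paradigm = "imagery", n_subjects = 12L,
                      xyz, space = "MNI") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  tibble::tibble(
    study_id = study_id, paradigm = paradigm,
    n_subjects = as.integer(n_subjects),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], space = space
  )
}

# three paradigms x two experiments, small coordinates on a toy grid
trio_foci_fixture <- function() {
  dplyr::bind_rows(
    make_foci("exa2001", "execution", 10L, c(0, 0, 0, 4, 0, 0)),
    make_foci("exb2002", "execution", 15L, c(0, 4, 0)),
    make_foci("ima2003", "imagery", 12L, c(0, 0, 4, 4, 4, 0)),
    make_foci("imb2004a", "imagery", 20L, c(0, 0, -4)),
    make_foci("wma2005", "working_memory", 25L, c(-4, 0, 0, 0, -4, 0)),
    make_foci("wmb2006", "working_memory", 18L, c(-4, -4, 0))
  )
}

# network with given retained ALE values on a grid
make_network <- function(values, grid, paradigm = "imagery") {
  aleoverlap:::network_from_values(array(values, dim = grid$shape),
    grid, paradigm)
}

# random sparse network: k voxels with values drawn from `draw`
random_network <- function(grid, k, paradigm = "imagery",
                           draw = function(n) stats::runif(n, 0.01, 0.05)) {
  v <- array(0, dim = grid$shape)
  idx <- sample.int(prod(grid$shape), k)
  v[idx] <- draw(k)
  make_network(v, grid, paradigm)
}

# independent connected-component oracle via igraph on the voxel
# adjacency graph
igraph_components <- function(supra, connectivity) {
  skip_if_not_installed("igraph")
  shape <- dim(supra)
  lin <- which(supra)
  if (!length(lin)) return(integer(0))
  ijk <- arrayInd(lin, shape)
  off <- aleoverlap:::neighbour_offsets(connectivity)
  edges <- c()
  pos <- match(seq_len(prod(shape)), lin)
  for (a in seq_along(lin)) {
    nb_i <- ijk[a, 1] + off[, 1]
    nb_j <- ijk[a, 2] + off[, 2]
    nb_k <- ijk[a, 3] + off[, 3]
    ok <- nb_i >= 1 & nb_i <= shape[1] & nb_j >= 1 & nb_j <= shape[2] &
      nb_k >= 1 & nb_k <= shape[3]
    nb_lin <- nb_i[ok] + (nb_j[ok] - 1) * shape[1] +
      (nb_k[ok] - 1) * shape[1] * shape[2]
    nb_pos <- pos[nb_lin]
    nb_pos <- nb_pos[!is.na(nb_pos) & nb_pos > a]
    if (length(nb_pos)) edges <- c(edges, rbind(a, nb_pos))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# brute-force ALE null by enumerating every tuple of in-mask voxels, one
# per experiment; returns binned probabilities on the same bin grid
enumerate_null <- function(ma_maps, mask, bin_width) {
  vals <- lapply(ma_maps, function(m) m$values[mask$inside])
  combos <- expand.grid(lapply(vals, seq_along))
  scores <- apply(combos, 1, function(ix) {
    1 - prod(vapply(seq_along(vals), function(e) 1 - vals[[e]][ix[e]], 1))
  })
  bins <- floor(scores / bin_width + 1e-12)
  prob <- as.numeric(rowsum(rep(1 / length(scores), length(scores)), bins))
  idx <- sort(unique(bins)) + 1L
  dense <- numeric(max(bins) + 1L)
  dense[idx] <- prob
  dense
}
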