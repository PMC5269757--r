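#' Train a toroidal batch self-organizing map on a tetranucleotide matrix
#'
#' Batch SOM on a rows x cols lattice that wraps on both axes (the map is
#' continuous top-to-bottom and side-to-side, so clusters are never split by
#' a map edge). Each epoch assigns every fragment to its Euclidean
#' best-matching unit (BMU), then replaces each neuron weight with the
#' Gaussian-neighbourhood-weighted mean of the assigned rows. The
#' neighbourhood radius decays linearly from `max(rows, cols)/2` to 1 over
#' the epochs. Training is deterministic given the seed.
#'
#' @param mat A normalized `tetra_matrix` (see [robust_zt_normalize()]).
#' @param som_rows,som_cols Lattice dimensions (default 20 x 30).
#' @param epochs Training epochs (default 30).
#' @param seed Integer seed (weight initialization samples data rows).
#' @return An object of class `som_grid`: list with `weights`
#'   (neurons x 256), `som_rows`, `som_cols`, `bmu` (per-fragment neuron
#'   index), `fragment_id`, `umatrix` (per-neuron mean distance to its 8
#'   toroidal lattice neighbours), `qe` (per-epoch mean quantization error).
#' @export
train_som <- function(mat, som_rows = 20, som_cols = 30, epochs = 30,
                      seed = 1) {
  if (nrow(mat) == 0) abort("empty matrix")
  if (!isTRUE(attr(mat, "normalized"))) {
    warn("matrix does not look normalized; train_som expects robust-ZT input")
  }
  x <- unclass(mat)
  n_neur <- som_rows * som_cols
  # lattice coordinates, row-major
  gr <- (seq_len(n_neur) - 1L) %/% som_cols
  gc <- (seq_len(n_neur) - 1L) %% som_cols
  # toroidal squared lattice distances between all neuron pairs
  dr <- abs(outer(gr, gr, "-")); dr <- pmin(dr, som_rows - dr)
  dc <- abs(outer(gc, gc, "-")); dc <- pmin(dc, som_cols - dc)
  grid_d2 <- dr^2 + dc^2
  w <- withr::with_seed(seed, {
    x[sample.int(nrow(x), n_neur, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(n_neur * ncol(x), sd = 0.01), n_neur)
  })
  r_max <- max(som_rows, som_cols) / 2
  qe <- numeric(epochs)
  bmu <- integer(nrow(x))
  x2 <- rowSums(x^2)
  for (e in seq_len(epochs)) {
    d2 <- outer(x2, rowSums(w^2), "+") - 2 * x %*% t(w)
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(x)), bmu)], 0)))
    radius <- max(1, r_max * (1 - (e - 1) / max(1, epochs - 1)))
    h <- exp(-grid_d2 / (2 * radius^2))   # neurons x neurons kernel
    a <- h[, bmu, drop = FALSE]           # neurons x fragments
    denom <- rowSums(a)
    upd <- (a %*% x) / denom
    ok <- denom > 1e-12
    w[ok, ] <- upd[ok, ]
  }
  d2 <- outer(x2, rowSums(w^2), "+") - 2 * x %*% t(w)
  bmu <- max.col(-d2, ties.method = "first")
  structure(
    list(weights = w, som_rows = som_rows, som_cols = som_cols,
         bmu = bmu, fragment_id = rownames(x) %||% as.character(seq_len(nrow(x))),
         umatrix = .umatrix(w, som_rows, som_cols), qe = qe,
         seed = as.integer(seed)),
    class = "som_grid"
  )
}

# 8-neighbour toroidal neighbour index list, row-major lattice
.som_neighbours <- function(som_rows, som_cols) {
  n <- som_rows * som_cols
  gr <- (seq_len(n) - 1L) %/% som_cols
  gc <- (seq_len(n) - 1L) %% som_cols
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  lapply(seq_len(n), function(i) {
    rr <- (gr[i] + offs$dr) %% som_rows
    cc <- (gc[i] + offs$dc) %% som_cols
    rr * som_cols + cc + 1L
  })
}

.umatrix <- function(w, som_rows, som_cols) {
  nb <- .som_neighbours(som_rows, som_cols)
  vapply(seq_len(nrow(w)), function(i) {
    mean(sqrt(rowSums((w[nb[[i]], , drop = FALSE] -
                         matrix(w[i, ], length(nb[[i]]), ncol(w),
                                byrow = TRUE))^2)))
  }, 0)
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d toroidal, %d fragments, final QE %.4f\n",
              x$som_rows, x$som_cols, length(x$bmu), tail(x$qe, 1)))
  invisible(x)
}

#' Extract composition clusters from a trained map and flag deviant ones
#'
#' Adjacent neurons (8-neighbour toroidal lattice) are connected when the
#' Euclidean distance between their weight vectors falls below the
#' `ridge_quantile` quantile of all adjacent-pair distances; U-matrix ridges
#' above the threshold thus act as cluster boundaries. Connected components
#' define clusters and every fragment inherits its BMU's cluster. Clusters
#' holding fewer than `deviant_frac` of the fragments are flagged deviant
#' (candidate foreign DNA); the largest cluster is never flagged.
#'
#' @param grid A trained `som_grid`.
#' @param ridge_quantile Quantile of adjacent-neuron distances used as the
#'   connection threshold (default 0.6; 1.0 connects everything into one
#'   cluster).
#' @param deviant_frac Fragment-share threshold below which a cluster is
#'   flagged deviant (default 0.10).
#' @return A list of class `som_clusters`: `fragments` (tibble
#'   `fragment_id`, `cluster`, `deviant`), `clusters` (tibble `cluster`,
#'   `n_fragments`, `fraction`, `deviant`), `neuron_cluster`, `threshold`.
#' @export
extract_clusters <- function(grid, ridge_quantile = 0.6, deviant_frac = 0.10) {
  stopifnot(inherits(grid, "som_grid"))
  w <- grid$weights
  nb <- .som_neighbours(grid$som_rows, grid$som_cols)
  edges <- purrr::map_dfr(seq_along(nb), function(i) {
    j <- nb[[i]][nb[[i]] > i]
    if (length(j) == 0) return(NULL)
    tibble(from = i, to = j,
           d = sqrt(rowSums((w[j, , drop = FALSE] -
                               matrix(w[i, ], length(j), ncol(w),
                                      byrow = TRUE))^2)))
  })
  thr <- quantile(edges$d, ridge_quantile, names = FALSE)
  keep <- edges[edges$d <= thr, c("from", "to")]
  g <- igraph::graph_from_data_frame(keep, directed = FALSE,
                                     vertices = seq_len(nrow(w)))
  comp <- igraph::components(g)$membership
  frag_comp <- comp[grid$bmu]
  # relabel clusters by decreasing fragment count
  counts <- sort(table(frag_comp), decreasing = TRUE)
  relab <- setNames(seq_along(counts), names(counts))
  frag_cluster <- as.integer(relab[as.character(frag_comp)])
  clusters <- tibble(
    cluster = as.integer(relab[names(counts)]),
    n_fragments = as.integer(counts),
    fraction = as.integer(counts) / length(frag_cluster)
  ) |>
    mutate(deviant = .data$fraction < deviant_frac &
             .data$cluster != 1L) |>
    arrange(.data$cluster)
  fragments <- tibble(
    fragment_id = grid$fragment_id,
    cluster = frag_cluster
  ) |>
    left_join(select(clusters, "cluster", "deviant"), by = "cluster")
  # neurons in fragment-free components carry NA
  structure(list(fragments = fragments, clusters = clusters,
                 neuron_cluster = unname(as.integer(relab[as.character(comp)])),
                 threshold = thr),
            class = "som_clusters")
}

#' @export
print.som_clusters <- function(x, ...) {
  cat(sprintf("<som_clusters> %d clusters (%d deviant), threshold %.3f\n",
              nrow(x$clusters), sum(x$clusters$deviant), x$threshold))
  invisible(x)
}
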