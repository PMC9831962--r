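# shared in-code fixtures: built fresh per test run, no files on disk

# structured block mesh: n x n x n cube of edge L, single structure label
block_mesh <- function(n = 3L, L = 10, label = "cancellous") {
  g <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  nodes <- as.matrix(g) * (L / n)
  colnames(nodes) <- c("x", "y", "z")
  nid <- function(i, j, k) k * (n + 1)^2 + j * (n + 1) + i + 1
  cell <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  hex <- cbind(nid(cell$i, cell$j, cell$k), nid(cell$i + 1, cell$j, cell$k),
               nid(cell$i + 1, cell$j + 1, cell$k), nid(cell$i, cell$j + 1, cell$k),
               nid(cell$i, cell$j, cell$k + 1), nid(cell$i + 1, cell$j, cell$k + 1),
               nid(cell$i + 1, cell$j + 1, cell$k + 1), nid(cell$i, cell$j + 1, cell$k + 1))
  fsusens:::new_fsu_mesh(nodes, hex, rep(label, nrow(hex)),
                         surface_index = seq_len(min(8, nrow(nodes))))
}

# small phantom cohort, memoised per options so repeated tests stay fast
local({
  cache <- new.env(parent = emptyenv())
  tiny_cohort <<- function(t = 10L, noise_sd = 0.1, size_sd = 0.05,
                           latent_sd = c(2.2, 0.8, 0.6, 0.45), seed = 42L) {
    key <- paste(t, noise_sd, size_sd, paste(latent_sd, collapse = "_"), seed,
                 sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(
        phantom_spec(t = t, latent_sd = latent_sd, noise_sd = noise_sd,
                     size_sd = size_sd, seed = seed))
    }
    cache[[key]]
  }
})

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
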