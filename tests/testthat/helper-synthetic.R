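# Small builders shared across test files.

one_way_config <- function(coupling = 0.8, base_ar = 0.5, seed = 1L,
                           n_nodes = 2L) {
  cpl <- matrix(0, n_nodes, n_nodes)
  cpl[1L, 2L] <- coupling          # node1 -> node2
  simulation_config(n_nodes, base_ar, coupling_schedule = list(task = cpl),
                    noise_sd = 1, seed = seed)
}

# feature matrix with known separable structure for classifier tests;
# rows grouped into 5-sample blocks that never straddle classes
separable_features <- function(n_per_class = 60L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 2, mean = 0), ncol = 2),
             matrix(rnorm(n_per_class * 2, mean = 6), ncol = 2))
  colnames(x) <- c("f1", "f2")
  labels <- rep(c("LH", "RH"), each = n_per_class)
  structure(list(x = x, labels = labels,
                 volume = seq_len(2L * n_per_class),
                 block_id = rep(seq_len(ceiling(2L * n_per_class / 5L)),
                                each = 5L)[seq_len(2L * n_per_class)],
                 feature_names = colnames(x),
                 provenance = rep("dwgc", 2L)),
            class = "feature_matrix")
}
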