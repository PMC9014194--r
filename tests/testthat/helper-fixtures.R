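# Fixtures shared across test files: random frequency matrices and small
# reference graphs, all generated in code under fixed seeds.

rand_freqs <- function(n, S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freq_matrix(matrix(runif(n * S), n, S),
              pop_labels = paste0("P", seq_len(n)))
}

# Three collinear populations: (0,0), (0.5,0.5), (1,1) over two loci.
# Pairwise F2 off-diagonals are 0.25, 0.25, 1.0 and the configuration is
# rank 1, with single positive eigenvalue 0.5 and PC1 coords (+-0.5, 0).
collinear_triple <- function() {
  freq_matrix(rbind(end1 = c(0, 0), mid = c(0.5, 0.5), end2 = c(1, 1)))
}

# Balanced 4-leaf tree ((L1,L2),(L3,L4)) with internal drift tau_int and
# leaf drift tau_leaf.
balanced_tree <- function(tau_int = 0.02, tau_leaf = 0.01) {
  admixture_graph(data.frame(
    parent = c("root", "root", "A", "A", "B", "B"),
    child = c("A", "B", "L1", "L2", "L3", "L4"),
    drift = c(tau_int, tau_int, tau_leaf, tau_leaf, tau_leaf, tau_leaf)))
}

# Standard f4-ratio topology: references R1, R2 nested with the sources
# (((X1,R1)),((X2,R2))), admixed child XY = w*X2 + (1-w)*X1 (weight w on
# the X2 side), observed as XX after post-admixture drift tau_x.
f4_ratio_graph <- function(w, tau_x = 0.01, tau_int = 0.05,
                           tau_leaf = 0.01) {
  admixture_graph(
    edges = data.frame(
      parent = c("root", "root", "U", "U", "V", "V", "XY"),
      child = c("U", "V", "X1", "R1", "X2", "R2", "XX"),
      drift = c(tau_int, tau_int, tau_leaf, tau_leaf, tau_leaf, tau_leaf,
                tau_x)),
    admixtures = data.frame(child = "XY", parent_a = "X2", parent_b = "X1",
                            weight = w),
    leaves = c("R1", "R2", "X1", "X2", "XX"))
}
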