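#' Describe a population tree or admixture graph
#'
#' A graph of populations: drift edges `(parent, child, drift)` with drift
#' amount tau >= 0 (branch length in units of genetic drift), plus optional
#' admixture events `(child, parent_a, parent_b, weight)` where the child's
#' frequencies are the elementwise mixture `w * parent_a + (1 - w) *
#' parent_b`, formed before any of the child's own outgoing drift. Every
#' non-root node has exactly one incoming drift edge or is an admixture
#' child; the graph must be acyclic with a single root.
#'
#' @param edges data.frame with columns `parent`, `child`, `drift`.
#' @param admixtures optional data.frame with columns `child`, `parent_a`,
#'   `parent_b`, `weight`.
#' @param leaves optional character vector of nodes emitted as populations;
#'   defaults to all nodes without descendants.
#' @return an `admixture_graph`.
#' @examples
#' g <- admixture_graph(data.frame(
#'   parent = c("root", "root"), child = c("A", "B"), drift = 0.01))
#' @export
admixture_graph <- function(edges, admixtures = NULL, leaves = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child", "drift") %in% names(edges))) {
    fp_stop_parse("edges needs columns parent, child, drift")
  }
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges$drift <- as.numeric(edges$drift)
  if (any(!is.finite(edges$drift)) || any(edges$drift < 0)) {
    fp_stop_parse("drift amounts must be finite and >= 0")
  }
  if (is.null(admixtures)) {
    admixtures <- data.frame(child = character(), parent_a = character(),
                             parent_b = character(), weight = numeric(),
                             stringsAsFactors = FALSE)
  }
  admixtures <- as.data.frame(admixtures, stringsAsFactors = FALSE)
  if (nrow(admixtures) > 0) {
    if (!all(c("child", "parent_a", "parent_b", "weight") %in%
             names(admixtures))) {
      fp_stop_parse("admixtures needs columns child, parent_a, parent_b, weight")
    }
    admixtures$child <- as.character(admixtures$child)
    admixtures$parent_a <- as.character(admixtures$parent_a)
    admixtures$parent_b <- as.character(admixtures$parent_b)
    admixtures$weight <- as.numeric(admixtures$weight)
    if (any(admixtures$weight < 0) || any(admixtures$weight > 1)) {
      fp_stop_parse("admixture weights must lie in [0, 1]")
    }
  }
  nodes <- unique(c(edges$parent, edges$child, admixtures$child,
                    admixtures$parent_a, admixtures$parent_b))
  incoming <- c(edges$child, admixtures$child)
  if (anyDuplicated(incoming)) {
    fp_stop_parse("node '%s' has more than one origin (edge or admixture)",
                  incoming[anyDuplicated(incoming)])
  }
  roots <- setdiff(nodes, incoming)
  if (length(roots) != 1L) {
    fp_stop_parse("graph must have exactly one root, found: %s",
                  paste(roots, collapse = ", "))
  }
  order <- topo_order(nodes, edges, admixtures, roots)
  has_children <- unique(c(edges$parent, admixtures$parent_a,
                           admixtures$parent_b))
  if (is.null(leaves)) leaves <- setdiff(nodes, has_children)
  leaves <- as.character(leaves)
  if (!all(leaves %in% nodes)) {
    fp_stop_parse("leaves not in graph: %s",
                  paste(setdiff(leaves, nodes), collapse = ", "))
  }
  if (length(leaves) < 1L) fp_stop_parse("graph has no leaves")
  structure(list(nodes = nodes, edges = edges, admixtures = admixtures,
                 root = roots, leaves = leaves, topo_order = order),
            class = "admixture_graph")
}

# Kahn topological sort; errors on cycles / unreachable nodes.
topo_order <- function(nodes, edges, admixtures, root) {
  parents_of <- function(nd) {
    c(edges$parent[edges$child == nd],
      unlist(admixtures[admixtures$child == nd, c("parent_a", "parent_b")],
             use.names = FALSE))
  }
  done <- character()
  pending <- nodes
  while (length(pending) > 0L) {
    ready <- pending[vapply(pending, function(nd) {
      all(parents_of(nd) %in% done)
    }, logical(1L))]
    if (length(ready) == 0L) {
      fp_stop_parse("graph contains a cycle involving: %s",
                    paste(pending, collapse = ", "))
    }
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  done
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat(sprintf("<admixture_graph> %d nodes, %d drift edges, %d admixture events\n",
              length(x$nodes), nrow(x$edges), nrow(x$admixtures)))
  cat("root:", x$root, "; leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' @param S number of SNPs (loci) to simulate.
#' @param root_dist root allele-frequency distribution: `"uniform"` with
#'   `root_params = c(lo, hi)` or `"beta"` with `root_params = c(a, b)`.
#'   Default uniform(0.1, 0.9) keeps frequencies away from the boundaries so
#'   truncation bias of the Gaussian drift model stays negligible.
#' @param root_params numeric length-2 parameter vector for `root_dist`.
#' @param drift_model `"gaussian_truncated"` (default): per locus add
#'   Normal(0, tau * p(1-p)) noise and clip to [0, 1]; matches the
#'   branch-length-in-drift-units intuition and admits analytic
#'   expectations. `"binomial_wright_fisher"`: one collapsed binomial
#'   resampling step with N = round(1/tau).
#' @param seed integer seed; every output records it, and identical
#'   (graph, config) pairs reproduce bit-identical frequencies.
#' @return a `sim_config`.
#' @export
sim_config <- function(S, root_dist = c("uniform", "beta"),
                       root_params = c(0.1, 0.9),
                       drift_model = c("gaussian_truncated",
                                       "binomial_wright_fisher"),
                       seed = 1L) {
  root_dist <- match.arg(root_dist)
  drift_model <- match.arg(drift_model)
  S <- as.integer(S)
  if (S < 1L) fp_stop_parse("S must be >= 1")
  root_params <- as.numeric(root_params)
  if (length(root_params) != 2L || any(!is.finite(root_params))) {
    fp_stop_parse("root_params must be two finite numbers")
  }
  if (root_dist == "uniform" &&
      (root_params[1L] < 0 || root_params[2L] > 1 ||
       root_params[1L] >= root_params[2L])) {
    fp_stop_parse("uniform root_params need 0 <= lo < hi <= 1")
  }
  if (root_dist == "beta" && any(root_params <= 0)) {
    fp_stop_parse("beta root_params must be positive")
  }
  structure(list(S = S, root_dist = root_dist, root_params = root_params,
                 drift_model = drift_model, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-node RNG stream seed: polynomial hash of the node label
# mixed with the global seed, mod a Mersenne prime. Editing one branch of
# the graph therefore never reshuffles draws on unrelated branches.
node_seed <- function(seed, label) {
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% p
  s <- ((as.numeric(seed) %% p) * 69069) %% p
  as.integer((h * 31 + s + 17) %% p)
}

#' Simulate allele frequencies on a tree or admixture graph
#'
#' Root frequencies are drawn i.i.d. from the root distribution; each drift
#' edge perturbs its parent's frequencies per locus according to the
#' configured drift model; an admixture child is the elementwise mixture
#' `w * parent_a + (1 - w) * parent_b`, formed before any subsequent drift
#' of its own. Each node consumes an RNG stream seeded by hashing (seed,
#' node label), so the output is reproducible and robust to topology edits
#' elsewhere in the graph.
#'
#' @param graph an [admixture_graph()].
#' @param cfg a [sim_config()].
#' @return a list with `freqs` (a [freq_matrix()] over the leaves),
#'   `node_freqs` (matrix over all nodes, for oracle checks), `graph`,
#'   `cfg`.
#' @export
sim_freqs <- function(graph, cfg) {
  stopifnot(inherits(graph, "admixture_graph"), inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  S <- cfg$S
  freqs <- matrix(NA_real_, length(graph$nodes), S,
                  dimnames = list(graph$nodes, paste0("snp", seq_len(S))))
  for (nd in graph$topo_order) {
    if (nd == graph$root) {
      set.seed(node_seed(cfg$seed, nd))
      freqs[nd, ] <- switch(cfg$root_dist,
        uniform = stats::runif(S, cfg$root_params[1L], cfg$root_params[2L]),
        beta = stats::rbeta(S, cfg$root_params[1L], cfg$root_params[2L])
      )
    } else if (nd %in% graph$admixtures$child) {
      ev <- graph$admixtures[graph$admixtures$child == nd, ]
      freqs[nd, ] <- ev$weight * freqs[ev$parent_a, ] +
        (1 - ev$weight) * freqs[ev$parent_b, ]
    } else {
      e <- graph$edges[graph$edges$child == nd, ]
      p <- freqs[e$parent, ]
      set.seed(node_seed(cfg$seed, nd))
      freqs[nd, ] <- drift_step(p, e$drift, cfg$drift_model, S)
    }
  }
  list(freqs = freq_matrix(freqs[graph$leaves, , drop = FALSE]),
       node_freqs = freqs, graph = graph, cfg = cfg)
}

drift_step <- function(p, tau, model, S) {
  if (tau == 0) return(p)
  if (model == "gaussian_truncated") {
    pmin(pmax(p + stats::rnorm(S, 0, sqrt(tau * p * (1 - p))), 0), 1)
  } else {
    N <- max(1L, as.integer(round(1 / tau)))
    stats::rbinom(S, N, p) / N
  }
}

#' Expected pairwise F2 under independent Gaussian drift (trees only)
#'
#' For an admixture-free graph with Gaussian drift away from the frequency
#' boundaries, the expected F2 between two leaves is, to first order, the
#' sum of drift amounts tau over the edges on the path between them times
#' the root heterozygosity factor E[p(1-p)]:
#' \deqn{E[F_2(i, j)] \approx E[p(1-p)] \sum_{e \in path(i,j)} \tau_e.}
#' The approximation treats E[p(1-p)] as constant along the path (exact in
#' the limit of small tau, no clipping). E[p(1-p)] is evaluated in closed
#' form under the root distribution: for uniform(lo, hi) it is
#' `(lo+hi)/2 - (hi^3-lo^3)/(3(hi-lo))`; for beta(a, b) it is
#' `ab / ((a+b)(a+b+1))`.
#'
#' @param graph an admixture-free [admixture_graph()].
#' @param cfg a [sim_config()] (supplies the root distribution).
#' @return an [f2_matrix()] over the leaves with `source = "expected"`.
#' @export
expected_f2 <- function(graph, cfg) {
  stopifnot(inherits(graph, "admixture_graph"), inherits(cfg, "sim_config"))
  if (nrow(graph$admixtures) > 0L) {
    fp_stop_capability("expected F2 is only available for admixture-free graphs")
  }
  het <- root_heterozygosity(cfg)
  leaves <- graph$leaves
  n <- length(leaves)
  m <- matrix(0, n, n, dimnames = list(leaves, leaves))
  paths <- lapply(leaves, path_to_root, graph = graph)
  names(paths) <- leaves
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        # symmetric difference of the two root paths = path between leaves
        ei <- paths[[i]]
        ej <- paths[[j]]
        on_path <- c(setdiff(ei, ej), setdiff(ej, ei))
        tau_sum <- sum(graph$edges$drift[match(on_path, graph$edges$child)])
        m[i, j] <- m[j, i] <- het * tau_sum
      }
    }
  }
  f2_matrix(m, source = "expected")
}

# Edges (identified by child node) from a leaf up to the root.
path_to_root <- function(leaf, graph) {
  path <- character()
  nd <- leaf
  while (nd != graph$root) {
    e <- graph$edges[graph$edges$child == nd, ]
    path <- c(path, nd)
    nd <- e$parent
  }
  path
}

# Closed-form E[p(1-p)] under the root distribution.
root_heterozygosity <- function(cfg) {
  pr <- cfg$root_params
  if (cfg$root_dist == "uniform") {
    lo <- pr[1L]; hi <- pr[2L]
    (lo + hi) / 2 - (hi^3 - lo^3) / (3 * (hi - lo))
  } else {
    a <- pr[1L]; b <- pr[2L]
    a * b / ((a + b) * (a + b + 1))
  }
}

#' Read / write a graph description as JSON
#'
#' Serializes the node/edge/admixture structure of an [admixture_graph()]
#' to a small JSON document (arrays `edges`, `admixtures`, `leaves`).
#'
#' @param graph an [admixture_graph()].
#' @param path file path.
#' @return `read_graph_json` returns an [admixture_graph()];
#'   `write_graph_json` returns `path` invisibly.
#' @export
write_graph_json <- function(graph, path) {
  obj <- list(edges = graph$edges,
              admixtures = graph$admixtures,
              leaves = graph$leaves)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  if (!file.exists(path)) fp_stop_parse("graph file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  adm <- obj$admixtures
  if (is.null(adm) || (is.data.frame(adm) && nrow(adm) == 0L) ||
      length(adm) == 0L) {
    adm <- NULL
  }
  leaves <- obj$leaves
  if (length(leaves) == 0L) leaves <- NULL
  admixture_graph(obj$edges, adm, leaves)
}
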