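#' End-to-end recovery benchmark on a planted-partition graph
#'
#' Runs the whole pipeline under fixed, documented study conditions: a
#' 300-node, 3-block attributed SBM (`p_in` 0.1, `p_out` 0.005, 60
#' binary attributes at signal 0.3 / noise 0.02), community detection by
#' [multilevel()], and the community-similarity model variant at d = 32
#' for 50 epochs. It measures
#' \itemize{
#'   \item block recovery: NMI between a 3-way k-means clustering of the
#'     embeddings and the planted blocks, median over three training
#'     seeds;
#'   \item connectivity preservation: ranking AUC of a 50%
#'     connectivity-preserving edge split scored with the trained
#'     embeddings (the same embeddings, trained on the full graph), and
#'     with random Gaussian embeddings as the chance baseline;
#'   \item downstream classification: repeated-split Micro/Macro-F1 with
#'     the planted blocks as labels.
#' }
#' The walk corpus is the test-scale configuration (5 walks of length 20
#' per node, window 5, 5 negatives).
#'
#' @param seed master seed; the graph, training runs, split and baseline
#'   all derive their seeds from it.
#' @param training_seeds how many independent training runs to take the
#'   recovery median over.
#' @return list with `nmi_median`, `nmi_per_seed`, `auc_trained`,
#'   `auc_random`, `micro_f1`, `macro_f1`, `n`, `detected_communities`.
#' @export
recovery_benchmark <- function(seed = 1L, training_seeds = 3L) {
  seed <- as.integer(seed)
  sim <- attributed_sbm(sbm_spec(seed = seed))
  g <- sim$graph
  comm <- multilevel(g, seed = seed)
  base_cfg <- function(s) {
    train_config(d = 32, hidden = 128, variant = "csm", epochs = 50,
                 batch_size = 2048,
                 walk = walk_config(walks_per_node = 5, walk_length = 20,
                                    window = 5, num_negatives = 5),
                 seed = s)
  }
  embs <- lapply(seq_len(training_seeds), function(k) {
    train_embedding(g, comm, base_cfg(seed + k))
  })
  nmis <- vapply(seq_along(embs), function(k) {
    cl <- with_seed(seed + 100L + k, stats::kmeans(embs[[k]]$Y, 3, nstart = 10)$cluster)
    nmi(cl, sim$truth$membership)
  }, 0)
  split <- link_prediction_split(g, 0.5, seed = seed + 200L)
  auc_trained <- auc_ranking(embs[[1]], split)
  Y_rand <- with_seed(seed + 300L,
                      matrix(stats::rnorm(g$n * 32), g$n, 32))
  auc_random <- auc_ranking(Y_rand, split)
  nc <- node_classification_eval(embs[[1]], g$labels, train_frac = 0.3,
                                 repeats = 10, seed = seed + 400L)
  list(
    nmi_median = stats::median(nmis),
    nmi_per_seed = nmis,
    auc_trained = auc_trained,
    auc_random = auc_random,
    micro_f1 = nc$micro_f1,
    macro_f1 = nc$macro_f1,
    n = g$n,
    detected_communities = comm$l
  )
}
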