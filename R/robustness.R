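# Correlation-distance hierarchical clustering with plain bootstrap support
# (BP), used to check that positively and negatively seed-correlated genes
# form exclusive clusters.

#' Correlation distance between gene expression profiles
#'
#' \eqn{d(i, j) = 1 - \rho_{ij}} (Pearson), so d is symmetric with a zero
#' diagonal and values in `[0, 2]`.
#'
#' @param mat Expression matrix restricted to the genes of interest (rows =
#'   genes/probes, columns = samples); >= 2 rows.
#' @return A symmetric numeric matrix of distances.
#' @export
correlation_distance <- function(mat) {
  if (nrow(mat) < 2) stop("correlation distance needs at least 2 genes")
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant gene row(s): %s",
                 paste(rownames(mat)[sds == 0], collapse = ", ")))
  d <- 1 - stats::cor(t(mat))
  diag(d) <- 0
  d
}

clade_key <- function(leaves) paste(sort(leaves), collapse = "\r")

# Leaf sets of every internal node of an hclust tree (excluding singletons).
hclust_clades <- function(hc) {
  labels <- hc$labels
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) labels[-j] else sets[[j]]
    sets[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  sets
}

#' Bootstrap support for correlation-distance clustering
#'
#' Clusters the selected genes with the requested linkage on correlation
#' distance, then resamples the samples (columns) with replacement `nboot`
#' times, reclusters each resample, and scores each observed cluster by the
#' fraction of resamples containing an identical leaf set (the plain
#' bootstrap proportion, BP).
#'
#' @param mat Expression matrix (probes/genes x samples).
#' @param genes Row names to cluster (>= 2).
#' @param nboot Number of bootstrap resamples (>= 1; default 1000).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param rng_seed Integer seed; the run is bit-reproducible given the seed.
#' @return A `cluster_support` object: `hclust` (the observed tree),
#'   `clades` (observed internal-node leaf sets), `support` (named BP per
#'   observed clade, names are semicolon-joined sorted leaf sets), `tally`
#'   (counts over all clades seen in resamples), `nboot`.
#' @export
bootstrap_support <- function(mat, genes, nboot = 1000, linkage = "average",
                              rng_seed = 1L) {
  if (nboot < 1) stop("nboot must be >= 1")
  if (ncol(mat) < 3) stop("bootstrap clustering needs at least 3 samples")
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0)
    stop(sprintf("gene(s) not in matrix: %s", paste(missing, collapse = ", ")))
  sub <- mat[genes, , drop = FALSE]
  hc <- stats::hclust(stats::as.dist(correlation_distance(sub)),
                      method = linkage)
  observed <- hclust_clades(hc)
  obs_keys <- vapply(observed, clade_key, character(1))

  set.seed(rng_seed)
  tally <- new.env(parent = emptyenv())
  n <- ncol(sub)
  for (b in seq_len(nboot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- sub[, idx, drop = FALSE]
      if (all(apply(boot, 1L, stats::sd) > 0)) break
    }
    bhc <- stats::hclust(stats::as.dist(1 - stats::cor(t(boot))),
                         method = linkage)
    keys <- unique(vapply(hclust_clades(bhc), clade_key, character(1)))
    for (k in keys) {
      cur <- tally[[k]]
      tally[[k]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  support <- vapply(obs_keys, function(k) {
    cnt <- tally[[k]]
    if (is.null(cnt)) 0 else cnt / nboot
  }, numeric(1))
  names(support) <- vapply(observed, function(s) paste(sort(s), collapse = ";"),
                           character(1))
  structure(list(hclust = hc, clades = observed, support = support,
                 tally = tally, nboot = nboot, linkage = linkage),
            class = "cluster_support")
}

#' Bootstrap proportion for an arbitrary gene set
#'
#' @param support A `cluster_support` object.
#' @param genes Character vector of leaf names. Singletons are trivially
#'   clusters of every tree and get support 1.
#' @return BP in `[0, 1]`.
#' @export
clade_support <- function(support, genes) {
  if (length(genes) <= 1) return(1)
  cnt <- support$tally[[clade_key(genes)]]
  if (is.null(cnt)) 0 else cnt / support$nboot
}

#' Do positive and negative seed correlates cluster exclusively?
#'
#' Cuts the observed dendrogram into two clusters and checks that the cut
#' reproduces the sign partition of the genes exactly. A single-sign gene set
#' is vacuously separated.
#'
#' @param support A `cluster_support` object from [bootstrap_support()].
#' @param rho Named numeric vector of seed correlations for the clustered
#'   genes.
#' @return List: `separated` (logical), `positive`/`negative` gene sets,
#'   `support_positive`/`support_negative` (BP of the sign clades).
#' @export
sign_separation <- function(support, rho) {
  leaves <- support$hclust$labels
  if (!all(leaves %in% names(rho)))
    stop("every clustered gene needs a signed rho")
  rho <- rho[leaves]
  pos <- leaves[rho > 0]
  neg <- leaves[rho < 0]
  if (length(pos) == 0 || length(neg) == 0) {
    return(list(separated = TRUE, positive = pos, negative = neg,
                support_positive = clade_support(support, pos),
                support_negative = clade_support(support, neg)))
  }
  cut <- stats::cutree(support$hclust, k = 2)
  groups <- split(names(cut), cut)
  sep <- (setequal(groups[[1]], pos) && setequal(groups[[2]], neg)) ||
         (setequal(groups[[1]], neg) && setequal(groups[[2]], pos))
  list(separated = sep, positive = pos, negative = neg,
       support_positive = clade_support(support, pos),
       support_negative = clade_support(support, neg))
}

#' Write the supported dendrogram as a newick tree
#'
#' Internal nodes are labelled with their bootstrap proportion (2 decimal
#' places).
#'
#' @param support A `cluster_support` object.
#' @param path Output file path.
#' @export
write_support_newick <- function(support, path) {
  tree <- ape::as.phylo(support$hclust)
  # map phylo internal nodes to leaf sets by traversing the edge matrix
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  leafset <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], leafset), use.names = FALSE)
  }
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  tree$node.label <- vapply(nodes, function(nd)
    sprintf("%.2f", clade_support(support, leafset(nd))), character(1))
  ape::write.tree(tree, file = path)
  invisible(path)
}
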