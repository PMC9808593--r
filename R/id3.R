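#' @title Entropy-based decision trees for handedness classification
#' @description An ID3-style binary decision tree over the seven torsion
#'   angles: axis-aligned threshold splits chosen by information gain under
#'   Shannon entropy, grown to purity and then reduced by minimal
#'   cost-complexity ("weakest link") pruning with misclassification
#'   impurity. Angles are treated as plain linear features on `[0, 360)` —
#'   the same convention the fitted thresholds (e.g. alpha at 252 degrees)
#'   are quoted in — so no split ever wraps across 360/0.
#' @name id3
NULL

#' Shannon entropy of class counts
#'
#' `-sum p_i log2 p_i` with the `0 * log2(0) = 0` convention. For two
#' classes the value lies in `[0, 1]`: 0 for a pure set, 1 for an even split.
#'
#' @param class_counts nonnegative integer vector (here `(n_LH, n_RH)`);
#'   total must be positive.
#' @return entropy in bits.
#' @examples
#' entropy(c(4, 0))  # 0
#' entropy(c(2, 2))  # 1
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) <= 0) {
    stop("entropy() needs nonnegative counts with a positive total", call. = FALSE)
  }
  p <- class_counts[class_counts > 0] / sum(class_counts)
  -sum(p * log2(p)) + 0  # + 0 normalizes IEEE negative zero
}

# vectorized two-class entropy over parallel count vectors
ent2 <- function(n0, n1) {
  n <- n0 + n1
  p0 <- ifelse(n > 0, n0 / n, 0)
  p1 <- ifelse(n > 0, n1 / n, 0)
  t0 <- ifelse(p0 > 0, -p0 * log2(p0), 0)
  t1 <- ifelse(p1 > 0, -p1 * log2(p1), 0)
  t0 + t1
}

#' Best single-feature threshold split by information gain
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' values of each feature. The split maximizing parent entropy minus the
#' size-weighted mean child entropy wins; ties are broken by the fixed
#' feature order (alpha, beta, gamma, delta, epsilon, zeta, chi), then by the
#' smallest threshold.
#'
#' @param X data frame or matrix of features (degrees).
#' @param y integer labels, 0/1.
#' @param features feature names to consider, in tie-break order.
#' @return list `(feature, threshold, gain)`; `NULL` when no split has
#'   positive gain (the no-gain sentinel).
#' @export
best_split <- function(X, y, features = ANGLE_NAMES) {
  n <- length(y)
  if (n < 2L || length(unique(y)) < 2L) return(NULL)
  n0_tot <- sum(y == 0L)
  n1_tot <- n - n0_tot
  h_parent <- ent2(n0_tot, n1_tot)
  best <- NULL
  for (f in features) {
    v <- X[[f]]
    ord <- order(v)
    vs <- v[ord]
    ys <- y[ord]
    cut <- which(vs[-n] < vs[-1L])       # boundaries between distinct values
    if (!length(cut)) next
    cum0 <- cumsum(ys == 0L)
    l0 <- cum0[cut];   l1 <- cut - l0
    r0 <- n0_tot - l0; r1 <- n1_tot - l1
    gain <- h_parent - (cut / n) * ent2(l0, l1) - ((n - cut) / n) * ent2(r0, r1)
    k <- which.max(gain)                 # thresholds ascend: first max = smallest theta
    if (gain[k] > 0 && (is.null(best) || gain[k] > best$gain)) {
      best <- list(feature = f,
                   threshold = (vs[cut[k]] + vs[cut[k] + 1L]) / 2,
                   gain = gain[k])
    }
  }
  best
}

new_leaf <- function(counts) {
  list(counts = as.integer(counts), feature = NULL, threshold = NULL,
       left = NULL, right = NULL)
}

#' Grow a decision tree to purity
#'
#' Recursively splits with [best_split()] until nodes are pure, no split has
#' positive gain, or the gain falls below `min_gain` (an optional early-stop
#' on the entropy drop; the default 0 grows fully and leaves model-size
#' control to [prune_tree()]).
#'
#' @param ds a `torsion_dataset` or data frame with the feature columns and
#'   `label`.
#' @param features features available to splits (single-angle trees pass one).
#' @param min_gain minimum information gain (bits) required to split.
#' @return an `id3_tree`: nested nodes with `counts = (n_LH, n_RH)` at every
#'   node, plus `feature`/`threshold`/`left`/`right` at internal nodes.
#' @export
grow_tree <- function(ds, features = ANGLE_NAMES, min_gain = 0) {
  stopifnot(nrow(ds) > 0L)
  grow <- function(X, y) {
    counts <- c(sum(y == 0L), sum(y == 1L))
    node <- new_leaf(counts)
    if (all(counts > 0L)) {
      sp <- best_split(X, y, features)
      if (!is.null(sp) && sp$gain >= min_gain && sp$gain > 0) {
        go_left <- X[[sp$feature]] <= sp$threshold
        node$feature <- sp$feature
        node$threshold <- sp$threshold
        node$left <- grow(X[go_left, , drop = FALSE], y[go_left])
        node$right <- grow(X[!go_left, , drop = FALSE], y[!go_left])
      }
    }
    node
  }
  tree <- grow(as.data.frame(ds)[, features, drop = FALSE], as.integer(ds$label))
  structure(tree, class = "id3_tree", features = features)
}

is_leaf <- function(node) is.null(node$feature)

#' Number of leaves / depth of a tree
#' @param tree an `id3_tree` (or internal node).
#' @return integer count.
#' @export
n_leaves <- function(tree) {
  if (is_leaf(tree)) 1L else n_leaves(tree$left) + n_leaves(tree$right)
}

#' @rdname n_leaves
#' @export
tree_depth <- function(tree) {
  if (is_leaf(tree)) 0L else 1L + max(tree_depth(tree$left), tree_depth(tree$right))
}

# misclassification risk of predicting the majority at a node, as a fraction
# of the root sample count
node_risk <- function(node, n_root) min(node$counts) / n_root

subtree_risk <- function(node, n_root) {
  if (is_leaf(node)) node_risk(node, n_root)
  else subtree_risk(node$left, n_root) + subtree_risk(node$right, n_root)
}

# effective alpha of every internal node, with a deterministic preorder index
weakest_links <- function(tree, n_root) {
  acc <- list()
  walk <- function(node, path) {
    if (is_leaf(node)) return()
    g <- (node_risk(node, n_root) - subtree_risk(node, n_root)) /
      (n_leaves(node) - 1L)
    acc[[length(acc) + 1L]] <<- list(path = path, g = g)
    walk(node$left, c(path, "left"))
    walk(node$right, c(path, "right"))
  }
  walk(tree, character())
  acc
}

collapse_at <- function(node, path) {
  if (!length(path)) return(new_leaf(node$counts))
  node[[path[1L]]] <- collapse_at(node[[path[1L]]], path[-1L])
  node
}

#' Minimal cost-complexity pruning
#'
#' Breiman weakest-link pruning with misclassification-rate impurity:
#' repeatedly collapse the internal node whose effective alpha
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)` is smallest, until every
#' remaining subtree has `g(t) > ccp_alpha`. `ccp_alpha = 0` leaves the tree
#' untouched; `ccp_alpha = Inf` collapses it to a single majority leaf.
#'
#' @param tree an `id3_tree` from [grow_tree()].
#' @param ccp_alpha complexity parameter; the default 0.04 is the value used
#'   for the handedness classifier.
#' @return the pruned `id3_tree`. Idempotent at fixed `ccp_alpha`.
#' @export
prune_tree <- function(tree, ccp_alpha = 0.04) {
  if (ccp_alpha < 0) stop("ccp_alpha must be nonnegative", call. = FALSE)
  if (ccp_alpha == 0) return(tree)
  n_root <- sum(tree$counts)
  at <- attributes(tree)
  repeat {
    links <- weakest_links(tree, n_root)
    if (!length(links)) break
    gs <- vapply(links, function(l) l$g, numeric(1L))
    k <- which.min(gs)
    if (gs[k] > ccp_alpha) break
    tree <- collapse_at(tree, links[[k]]$path)
  }
  attributes(tree) <- at
  tree
}

route <- function(node, sample) {
  while (!is_leaf(node)) {
    v <- sample[[node$feature]]
    if (is.null(v) || is.na(v)) {
      stop("predict: sample is missing feature '", node$feature, "'", call. = FALSE)
    }
    node <- if (v <= node$threshold) node$left else node$right
  }
  # leaf majority; tie predicts LH (0)
  if (node$counts[1L] >= node$counts[2L]) 0L else 1L
}

#' Predict handedness labels
#'
#' Routes each sample down the tree (left branch iff feature value is `<=`
#' the node threshold) and returns the leaf's majority label; leaf ties
#' predict 0 (left-handed).
#'
#' @param object an `id3_tree`.
#' @param newdata data frame of samples with all feature columns present.
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
predict.id3_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  feats <- attr(object, "features")
  miss <- setdiff(feats, names(newdata))
  if (length(miss)) {
    stop("predict: sample is missing feature '", miss[1L], "'", call. = FALSE)
  }
  vapply(seq_len(nrow(newdata)),
         function(i) route(object, as.list(newdata[i, feats, drop = FALSE])),
         integer(1L))
}

#' The closed-form alpha/beta handedness rule
#'
#' Classifies a nucleotide as left-handed (0) exactly when its alpha angle is
#' below 252 degrees and its beta angle above 150 degrees; everything else is
#' right-handed (1). This is the two-threshold rule the pruned trees converge
#' to on the quadruplex data.
#'
#' @param samples data frame (or named vector) with `alpha` and `beta`
#'   columns, degrees in `[0,360)`; missing values are an error.
#' @param alpha_max,beta_min the two thresholds, degrees.
#' @return integer vector of 0/1 labels.
#' @examples
#' rule_classifier(data.frame(alpha = c(180, 300, 180), beta = c(200, 200, 100)))
#' @export
rule_classifier <- function(samples, alpha_max = 252, beta_min = 150) {
  samples <- as.data.frame(as.list(samples))
  if (!all(c("alpha", "beta") %in% names(samples)) ||
      anyNA(samples$alpha) || anyNA(samples$beta)) {
    stop("rule_classifier() requires non-missing alpha and beta", call. = FALSE)
  }
  ifelse(samples$alpha < alpha_max & samples$beta > beta_min, 0L, 1L)
}

node_to_list <- function(node) {
  if (is_leaf(node)) {
    list(counts = node$counts)
  } else {
    list(feature = node$feature, threshold = node$threshold, counts = node$counts,
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

list_to_node <- function(x) {
  node <- new_leaf(unlist(x$counts))
  if (!is.null(x$feature)) {
    node$feature <- x$feature
    node$threshold <- x$threshold
    node$left <- list_to_node(x$left)
    node$right <- list_to_node(x$right)
  }
  node
}

#' Serialize / parse a tree
#'
#' `describe()` renders a tree as pretty-printed JSON (feature, threshold and
#' the `(n_LH, n_RH)` counts at every node); `tree_from_json()` parses that
#' text back into an equivalent tree, so render -> parse -> render is a fixed
#' point.
#'
#' @param tree an `id3_tree`.
#' @return `describe`/`tree_to_json`: a JSON string; `tree_from_json`: an
#'   `id3_tree`.
#' @export
describe <- function(tree) tree_to_json(tree)

#' @rdname describe
#' @export
tree_to_json <- function(tree) {
  as.character(jsonlite::toJSON(node_to_list(tree), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE))
}

#' @rdname describe
#' @param json JSON text produced by `tree_to_json()`.
#' @param features feature set recorded on the rebuilt tree.
#' @export
tree_from_json <- function(json, features = ANGLE_NAMES) {
  structure(list_to_node(jsonlite::fromJSON(json, simplifyVector = FALSE)),
            class = "id3_tree", features = features)
}

#' @export
print.id3_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is_leaf(node)) {
      cat(pad, "leaf value=[", node$counts[1L], ", ", node$counts[2L], "] -> ",
          if (node$counts[1L] >= node$counts[2L]) "LH" else "RH", "\n", sep = "")
    } else {
      cat(pad, node$feature, " <= ", format(node$threshold), "  value=[",
          node$counts[1L], ", ", node$counts[2L], "]\n", sep = "")
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  cat("ID3 decision tree (", n_leaves(x), " leaves, depth ", tree_depth(x), ")\n",
      sep = "")
  show(x, 0L)
  invisible(x)
}
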