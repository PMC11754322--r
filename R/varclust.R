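#' Flip the sign of selected measures
#'
#' Squared-correlation clustering is blind to sign, but loadings and
#' similarity displays are easier to read when every measure points the same
#' way (higher = more exploration / more efficiency).  Measures that run the
#' other way (e.g., pausing, revisiting) can be negated here.
#'
#' @param x Numeric data.frame or matrix (subjects x variables).
#' @param invert Character vector of variable names to negate.
#' @return `x` with the named columns multiplied by -1.
#' @export
orient_measures <- function(x, invert = character(0)) {
  x <- as.data.frame(x)
  unknown <- setdiff(invert, names(x))
  if (length(unknown))
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
  for (nm in invert) x[[nm]] <- -x[[nm]]
  x
}

#' Standardize variables to zero mean and unit variance
#'
#' @param x Numeric data.frame or matrix (subjects x variables).
#' @return A numeric matrix with columns of mean 0 and sd 1 (denominator
#'   `n - 1`).  Errors on a constant column, naming it.
#' @export
standardize_measures <- function(x) {
  m <- as.matrix(as.data.frame(x))
  if (!is.numeric(m)) stop("variables must be numeric")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop(sprintf("constant or undefined variable(s): %s",
                 paste(colnames(m)[sds == 0 | is.na(sds)], collapse = ", ")))
  scale(m)[, , drop = FALSE]
}

#' Squared-Pearson similarity matrix of variables
#'
#' @param x Numeric data.frame or matrix (subjects x variables).
#' @return Symmetric variables x variables matrix of squared Pearson
#'   correlations, with unit diagonal.
#' @export
similarity_matrix <- function(x) {
  stats::cor(as.matrix(as.data.frame(x)))^2
}

# homogeneity of a variable cluster: leading eigenvalue of its correlation
# matrix == sum of squared correlations with the cluster's first PC
cluster_homogeneity <- function(m, members) {
  if (length(members) == 1) return(1)
  eigen(stats::cor(m[, members, drop = FALSE]), symmetric = TRUE,
        only.values = TRUE)$values[1]
}

#' Hierarchical clustering of variables by principal-component homogeneity
#'
#' Agglomerative clustering of *variables* (not subjects).  The homogeneity
#' of a cluster is the leading eigenvalue of its correlation matrix — the
#' variance its first principal component explains, equivalently the sum of
#' squared Pearson correlations of the members with that component.  At each
#' step the pair of clusters whose merge loses the least homogeneity,
#' `d(A, B) = H(A) + H(B) - H(A union B)`, is merged, and `d` is recorded as
#' the merge height.  For two single variables the height reduces to
#' `1 - r^2`.  Because the criterion is built on squared correlations, the
#' tree is invariant to sign flips and affine rescaling of any variable.
#' Ties in the merge criterion are broken by the lexicographically smallest
#' member name, so results are platform-stable.
#'
#' @param x Numeric data.frame or matrix (subjects x variables, at least 2
#'   variables, no missing values).
#' @param scale Standardize columns first (recommended; the criterion itself
#'   is scale-free but the synthetic cluster scores are not).
#' @return An object of class `"varclust"` with elements `labels`, `merges`
#'   (list of per-merge member sets and heights), `heights`, `merge` (an
#'   hclust-style merge matrix), `order` (leaf order for dendrograms), and
#'   `data` (the standardized matrix, retained for [varclust_cut()]).
#' @seealso [varclust_cut()], [aggregation_heights()], [suggest_k()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' x[, 2] <- x[, 1] + rnorm(100, sd = 0.3)
#' vc <- varclust(x)
#' vc
#' @export
varclust <- function(x, scale = TRUE) {
  m <- if (scale) standardize_measures(x) else as.matrix(as.data.frame(x))
  if (anyNA(m)) stop("missing values: drop incomplete subjects first")
  if (nrow(m) < 3) stop("need at least 3 subjects")
  p <- ncol(m)
  if (p < 2) stop("need at least 2 variables")
  labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  colnames(m) <- labels

  clusters <- as.list(seq_len(p))          # member column indices
  H <- rep(1, p)                           # homogeneity per active cluster
  hclust_id <- -seq_len(p)                 # hclust coding: negative = leaf
  active <- rep(TRUE, p)
  merges <- vector("list", p - 1)
  merge_mat <- matrix(0L, p - 1, 2)
  heights <- numeric(p - 1)

  for (step in seq_len(p - 1)) {
    act <- which(active)
    best <- NULL
    for (ai in seq_along(act)) for (bi in seq_len(ai - 1L)) {
      a <- act[ai]; b <- act[bi]
      uni <- c(clusters[[a]], clusters[[b]])
      d <- H[a] + H[b] - cluster_homogeneity(m, uni)
      cand <- list(a = a, b = b, d = d,
                   key = sort(labels[uni])[1:2])
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
        best <- cand
    }
    a <- best$a; b <- best$b
    merges[[step]] <- list(a = labels[clusters[[a]]],
                           b = labels[clusters[[b]]],
                           height = best$d)
    heights[step] <- best$d
    merge_mat[step, ] <- c(hclust_id[a], hclust_id[b])
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    H[a] <- cluster_homogeneity(m, clusters[[a]])
    hclust_id[a] <- step
    active[b] <- FALSE
  }

  structure(
    list(labels = labels, merges = merges, heights = heights,
         merge = merge_mat, order = hclust_leaf_order(merge_mat, p),
         n_variables = p, data = m),
    class = "varclust")
}

# leaf order by depth-first traversal of the merge matrix (last merge = root)
hclust_leaf_order <- function(merge_mat, p) {
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge_mat[id, 1]), expand(merge_mat[id, 2]))
  }
  expand(nrow(merge_mat))
}

#' @export
print.varclust <- function(x, ...) {
  cat(sprintf("Variable clustering (squared-Pearson / PC homogeneity), %d variables\n",
              x$n_variables))
  cat("Merge heights (homogeneity loss):\n")
  for (i in seq_along(x$merges)) {
    mg <- x$merges[[i]]
    cat(sprintf("  %2d. {%s} + {%s}  height %.4f\n", i,
                paste(mg$a, collapse = ","), paste(mg$b, collapse = ","),
                mg$height))
  }
  invisible(x)
}

#' @export
as.hclust.varclust <- function(x, ...) {
  structure(list(merge = x$merge, height = x$heights, order = x$order,
                 labels = x$labels, method = "pc-homogeneity",
                 call = match.call(), dist.method = "1 - squared correlation"),
            class = "hclust")
}

#' Plot a variable-clustering tree
#'
#' `type = "dendrogram"` draws the merge tree; `type = "heights"` draws the
#' aggregation levels against the number of clusters (the curve the knee
#' detection runs on).
#'
#' @param x A [varclust()] object.
#' @param type `"dendrogram"` or `"heights"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.varclust <- function(x, type = c("dendrogram", "heights"), ...) {
  type <- match.arg(type)
  if (type == "dendrogram") {
    plot(as.hclust.varclust(x), ylab = "homogeneity loss", sub = "", ...)
  } else {
    ah <- aggregation_heights(x)
    plot(ah$k, ah$height, type = "b", xlab = "number of clusters",
         ylab = "aggregation height", ...)
  }
  invisible(x)
}

#' Aggregation heights by number of clusters
#'
#' @param tree A [varclust()] object.
#' @return Data.frame with `k` (number of clusters, `1` to `p - 1`) and
#'   `height` (the homogeneity loss of the merge that reduced `k + 1`
#'   clusters to `k`).
#' @export
aggregation_heights <- function(tree) {
  p <- tree$n_variables
  data.frame(k = seq_len(p - 1), height = rev(tree$heights))
}

#' Cut a variable-clustering tree into k clusters
#'
#' Undoes the last `p - k` merges, then summarizes each cluster by its
#' synthetic variable: the first principal component of the cluster's
#' standardized members, scaled to unit variance and oriented so the mean
#' correlation with its members is positive.  Loadings are the Pearson
#' correlations of *every* variable with every synthetic score.
#'
#' @param tree A [varclust()] object.
#' @param k Number of clusters, between 1 and the number of variables.
#' @return An object of class `"varclust_solution"`: list with `k`,
#'   `assignment` (named integer vector), `scores` (subjects x k), and
#'   `loadings` (variables x k matrix, with an attribute-free companion
#'   data.frame via [loadings_table()]).
#' @export
varclust_cut <- function(tree, k) {
  p <- tree$n_variables
  if (k < 1 || k > p) stop("k out of range")
  # replay the first p - k merges; hclust coding: negative = leaf, positive =
  # earlier merge.  Slot i holds leaves, slot p + s the result of merge s.
  slot <- function(id) if (id < 0) -id else p + id
  members <- vector("list", 2 * p)
  for (i in seq_len(p)) members[[i]] <- i
  alive <- rep(FALSE, 2 * p); alive[seq_len(p)] <- TRUE
  n_merge <- p - k
  for (s in seq_len(n_merge)) {
    a <- slot(tree$merge[s, 1]); b <- slot(tree$merge[s, 2])
    members[[p + s]] <- c(members[[a]], members[[b]])
    alive[c(a, b)] <- FALSE; alive[p + s] <- TRUE
  }
  live <- which(alive)
  # stable cluster numbering: by smallest member column index
  live <- live[order(vapply(live, function(i) min(members[[i]]), numeric(1)))]
  assignment <- integer(p)
  for (ci in seq_along(live))
    assignment[members[[live[ci]]]] <- ci
  names(assignment) <- tree$labels

  m <- tree$data
  n <- nrow(m)
  scores <- matrix(0, n, k)
  colnames(scores) <- paste0("cluster", seq_len(k))
  for (ci in seq_len(k)) {
    idx <- which(assignment == ci)
    sub <- m[, idx, drop = FALSE]
    if (length(idx) == 1) {
      s <- sub[, 1]
    } else {
      v <- eigen(stats::cor(sub), symmetric = TRUE)$vectors[, 1]
      s <- as.numeric(sub %*% v)
    }
    s <- s / stats::sd(s)
    if (mean(stats::cor(sub, s)) < 0) s <- -s
    scores[, ci] <- s
  }
  loadings <- stats::cor(m, scores)
  structure(list(k = k, assignment = assignment, scores = scores,
                 loadings = loadings),
            class = "varclust_solution")
}

#' @export
print.varclust_solution <- function(x, ...) {
  cat(sprintf("Variable clustering solution, k = %d\n", x$k))
  tab <- loadings_table(x)
  print(format(tab, digits = 2), ...)
  invisible(x)
}

#' Loadings table with own-cluster flags
#'
#' @param solution A [varclust_cut()] solution.
#' @return Data.frame: one row per variable, its cluster, the loading on each
#'   synthetic cluster variable, and `own_cluster` marking the column the
#'   variable belongs to (the bold entries of a loadings table).
#' @export
loadings_table <- function(solution) {
  df <- data.frame(variable = rownames(solution$loadings),
                   cluster = unname(solution$assignment),
                   stringsAsFactors = FALSE)
  for (ci in seq_len(solution$k))
    df[[paste0("cluster", ci)]] <- solution$loadings[, ci]
  df$own_loading <- solution$loadings[cbind(seq_len(nrow(df)), df$cluster)]
  df
}

#' Export a clustering tree as a merge list
#'
#' @param tree A [varclust()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.  The JSON is an array of
#'   `{members_a, members_b, height}` objects in merge order.
#' @export
write_merges_json <- function(tree, path) {
  jsonlite::write_json(
    lapply(tree$merges, function(mg)
      list(members_a = mg$a, members_b = mg$b, height = mg$height)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
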