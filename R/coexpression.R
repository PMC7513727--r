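#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^softpower` (Pearson, unsigned), diagonal 1.
#'
#' @param expr genes x samples matrix (log2-scale expression
#'   recommended).
#' @param softpower soft-thresholding power (default 6).
#' @return gene x gene adjacency matrix.
#' @export
wgcna_adjacency <- function(expr, softpower = 6) {
  stopifnot(softpower >= 1)
  a <- abs(stats::cor(t(expr)))^softpower
  diag(a) <- 1
  a
}

#' Topological overlap matrix (unsigned)
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu * a_uj` over `u != i, j` and `k` the connectivity
#' (row sums excluding the diagonal); `TOM_ii = 1`. Bounded in [0, 1];
#' an isolated perfectly-correlated pair has TOM exactly 1.
#'
#' @param adj adjacency matrix from [wgcna_adjacency()].
#' @return TOM matrix of the same dimension.
#' @export
wgcna_tom <- function(adj) {
  b <- adj
  diag(b) <- 0
  l <- b %*% b
  k <- rowSums(b)
  kmin <- outer(k, k, pmin)
  tom <- (l + b) / (kmin + 1 - b)
  diag(tom) <- 1
  tom
}

## internal: binary cluster tree from an hclust object.
## Returns per-node leaf lists and internal merge heights.
hc_subtrees <- function(hc) {
  n <- length(hc$order) + 0L
  leaves <- vector("list", nrow(hc$merge))
  heights <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    lv <- hv <- list()
    for (k in kids) {
      if (k < 0) {
        lv <- c(lv, list(-k))
        hv <- c(hv, list(numeric(0)))
      } else {
        lv <- c(lv, list(leaves[[k]]))
        hv <- c(hv, list(c(heights[[k]], hc$height[k])))
      }
    }
    leaves[[i]] <- c(lv[[1]], lv[[2]])
    heights[[i]] <- c(hv[[1]], hv[[2]])
  }
  list(leaves = leaves, heights = heights)
}

#' Module detection by average-linkage clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering on the topological overlap
#' dissimilarity, followed by either a simplified top-down dynamic cut
#' (default) or a static height cut; clusters smaller than
#' `min_module_size` go to the background (module 0).
#'
#' The dynamic cut works on the profile of merge heights, which is
#' banded when modular structure exists: a dense band of low
#' within-module merges separated by height gaps from between-branch
#' joins and from the chain of background genes. Each sizeable gap in
#' the upper half of the sorted profile is a candidate cut height; for
#' each candidate the tree is descended from the root, splitting every
#' node above the cut and peeling sub-minimum branches to the
#' background on the way down (single uncorrelated genes chain onto
#' the tree near the root). A terminal cluster is kept as a module
#' only when its median internal merge height sits clearly below the
#' cut (at most `cohesion_ratio` times it): diffuse clusters fill the
#' space right up to the cut and are discarded. The candidate yielding
#' the most valid modules wins (ties: the lowest cut), so a too-high
#' cut (one merged giant) and a too-low cut (incohesive fragments)
#' both lose to the structural boundary, and a pure-noise tree yields
#' no modules at any cut. An over-split cohesive module is recovered
#' by the eigengene merge step rather than discarded. The procedure is
#' fully deterministic.
#'
#' @param tom TOM matrix.
#' @param min_module_size minimum module size (default 30).
#' @param method "dynamic" (default) or "static".
#' @param cut_height static cut height on 1 - TOM (method "static").
#' @param cohesion_ratio module-validation criterion of the dynamic
#'   cut (default 0.9): a module's median internal merge height must
#'   be at most this fraction of the cut height.
#' @return list with integer `module` per gene (0 = background), the
#'   `hclust` tree, the number of modules, and the realised
#'   `cut_height`.
#' @export
detect_modules <- function(tom, min_module_size = 30L,
                           method = c("dynamic", "static"),
                           cut_height = 0.99, cohesion_ratio = 0.9) {
  method <- match.arg(method)
  n <- nrow(tom)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h_star <- cut_height
  if (method == "static") {
    cl <- stats::cutree(hc, h = cut_height)
  } else {
    st <- hc_subtrees(hc)
    med_of <- function(k) {
      if (k < 0) return(0)
      h <- st$heights[[k]]
      if (length(h)) stats::median(h) else 0
    }
    cut_at <- function(h0) {
      cl0 <- integer(n)
      next_label <- 1L
      terminal <- function(k) {
        ## keep as module only if internally cohesive relative to cut
        lab <- if (med_of(k) <= cohesion_ratio * h0) {
          next_label <<- next_label + 1L
          next_label - 1L
        } else 0L
        if (k < 0) cl0[-k] <<- lab else cl0[st$leaves[[k]]] <<- lab
      }
      recurse <- function(k) {
        if (k < 0) { terminal(k); return() }
        if (hc$height[k] <= h0) { terminal(k); return() }
        kids <- hc$merge[k, ]
        sizes <- vapply(kids, function(j)
          if (j < 0) 1L else length(st$leaves[[j]]), integer(1))
        if (all(sizes < min_module_size)) { terminal(k); return() }
        if (any(sizes < min_module_size)) {
          ## peel sub-minimum outlier branches to the background and
          ## keep descending
          small <- kids[sizes < min_module_size]
          if (small < 0) cl0[-small] <<- 0L
          else cl0[st$leaves[[small]]] <<- 0L
          recurse(kids[sizes >= min_module_size])
          return()
        }
        for (j in kids) recurse(j)
      }
      recurse(nrow(hc$merge))
      cl0
    }
    n_valid <- function(cl0) {
      tab <- table(cl0[cl0 > 0])
      sum(tab >= min_module_size)
    }
    ## candidate cuts: the (up to 10) largest height gaps in the upper
    ## half of the merge profile
    hs <- sort(hc$height)
    cl <- integer(n)
    if (length(hs) >= 2) {
      gaps <- diff(hs)
      upper <- which(seq_along(gaps) >= length(gaps) / 2)
      cand <- upper[order(gaps[upper], decreasing = TRUE)]
      cand <- sort(utils::head(cand, 10L))
      best <- 0L
      for (g in cand) {
        h0 <- (hs[g] + hs[g + 1]) / 2
        cl0 <- cut_at(h0)
        nv <- n_valid(cl0)
        if (nv > best) {
          best <- nv
          cl <- cl0
          h_star <- h0
        }
      }
    }
  }
  ## size filter, then relabel modules by decreasing size (ties by
  ## first gene index) so labels are deterministic
  tab <- table(cl[cl > 0])
  keep <- names(tab)[tab >= min_module_size]
  cl[!(cl %in% as.integer(keep))] <- 0L
  if (length(keep)) {
    first_idx <- vapply(keep, function(k) min(which(cl == as.integer(k))),
                        integer(1))
    ord <- keep[order(-tab[keep], first_idx)]
    cl <- match(as.character(cl), ord, nomatch = 0L)
  }
  list(module = as.integer(cl), tree = hc, n_modules = length(keep),
       cut_height = h_star)
}

#' Module eigengene
#'
#' First principal component of the per-gene standardised module
#' submatrix (unit-norm, length = number of samples), sign-oriented to
#' correlate positively with the module's mean standardised profile.
#'
#' @param expr expression submatrix of the module's genes
#'   (genes x samples, log2 scale recommended).
#' @return numeric vector (unit norm), one value per sample.
#' @export
module_eigengene <- function(expr) {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  z <- t(scale(t(expr)))
  z[is.na(z)] <- 0  # constant genes contribute nothing
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  avg <- colMeans(z)
  if (sum(e * avg) < 0) e <- -e
  e
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengene dissimilarity `1 - cor` is below
#' `merge_distance` are merged iteratively, closest pair first (ties
#' broken by label order), recomputing the merged eigengene each step.
#'
#' @param expr full expression matrix (genes x samples).
#' @param module integer module labels (0 = background).
#' @param merge_distance eigengene dissimilarity threshold
#'   (default 0.20).
#' @return list with relabelled `module` vector and the eigengene
#'   matrix (samples x modules) of the merged assignment.
#' @export
merge_modules <- function(expr, module, merge_distance = 0.20) {
  module <- as.integer(module)
  repeat {
    labs <- sort(unique(module[module > 0]))
    if (length(labs) < 2) break
    eg <- sapply(labs, function(m)
      module_eigengene(expr[module == m, , drop = FALSE]))
    dis <- 1 - stats::cor(eg)
    diag(dis) <- Inf
    idx <- which(dis == min(dis), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    if (dis[idx[1], idx[2]] >= merge_distance) break
    from <- labs[max(idx)]; to <- labs[min(idx)]
    module[module == from] <- to
  }
  labs <- sort(unique(module[module > 0]))
  module <- ifelse(module > 0, match(module, labs), 0L)
  eg <- if (length(labs))
    sapply(seq_along(labs), function(m)
      module_eigengene(expr[module == m, , drop = FALSE]))
  else matrix(numeric(0), nrow = ncol(expr), ncol = 0)
  eg <- matrix(eg, nrow = ncol(expr))
  colnames(eg) <- if (length(labs)) paste0("ME", seq_along(labs)) else character(0)
  list(module = module, eigengenes = eg)
}

#' Module-trait correlations
#'
#' Pearson correlation and p-value of each module eigengene against
#' each trait; constant traits are reported missing.
#'
#' @param eigengenes samples x modules matrix.
#' @param traits data.frame of trait values (samples in the same
#'   order; non-numeric columns are dropped).
#' @return list of matrices `r` and `p` (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  tr <- traits[, vapply(traits, is.numeric, logical(1)), drop = FALSE]
  n <- nrow(tr)
  stopifnot(nrow(eigengenes) == n)
  r <- matrix(NA_real_, ncol(eigengenes), ncol(tr),
              dimnames = list(colnames(eigengenes), colnames(tr)))
  p <- r
  for (i in seq_len(ncol(eigengenes))) {
    for (j in seq_len(ncol(tr))) {
      x <- eigengenes[, i]; y <- tr[[j]]
      if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) next
      ct <- stats::cor.test(x, y)
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Hub genes by within-module edge count
#'
#' Within each module, a gene's edge count is the number of
#' within-module partners with TOM at least `edge_threshold`. Genes
#' whose edge count reaches the top `hub_fraction` (count cutoff by
#' ceiling; ties at the boundary included) are hubs.
#'
#' @param tom TOM matrix.
#' @param module integer module labels (0 = background).
#' @param edge_threshold minimum TOM for a biologically significant
#'   edge (default 0.01).
#' @param hub_fraction top fraction by edge count (default 0.15).
#' @return list with logical `hub` flags and per-gene `edge_count`.
#' @export
hub_genes <- function(tom, module, edge_threshold = 0.01,
                      hub_fraction = 0.15) {
  n <- nrow(tom)
  stopifnot(length(module) == n)
  hub <- logical(n)
  edges <- rep(NA_integer_, n)
  for (m in setdiff(unique(module), 0L)) {
    idx <- which(module == m)
    sub <- tom[idx, idx, drop = FALSE]
    diag(sub) <- 0
    cnt <- rowSums(sub >= edge_threshold)
    k <- ceiling(hub_fraction * length(idx))
    cutoff <- sort(cnt, decreasing = TRUE)[k]
    hub[idx] <- cnt >= cutoff
    edges[idx] <- as.integer(cnt)
  }
  list(hub = hub, edge_count = edges)
}

#' One-step co-expression network construction
#'
#' Adjacency, TOM, module detection, eigengene merging and hub calling
#' in one deterministic pass.
#'
#' @param expr FPKM matrix (genes x samples); log2(FPKM + 1) is taken
#'   internally.
#' @param softpower,min_module_size,merge_distance,edge_threshold,hub_fraction
#'   network parameters (defaults 6, 30, 0.20, 0.01, 0.15).
#' @return list with `module` (named by gene), `eigengenes`,
#'   `hub`, `edge_count`, `tom`, `n_modules`.
#' @export
coexpression_network <- function(expr, softpower = 6,
                                 min_module_size = 30L,
                                 merge_distance = 0.20,
                                 edge_threshold = 0.01,
                                 hub_fraction = 0.15) {
  y <- log2(expr + 1)
  adj <- wgcna_adjacency(y, softpower)
  tom <- wgcna_tom(adj)
  det <- detect_modules(tom, min_module_size = min_module_size)
  mg <- merge_modules(y, det$module, merge_distance = merge_distance)
  hubs <- hub_genes(tom, mg$module, edge_threshold = edge_threshold,
                    hub_fraction = hub_fraction)
  module <- stats::setNames(mg$module, rownames(expr))
  list(module = module, eigengenes = mg$eigengenes,
       hub = stats::setNames(hubs$hub, rownames(expr)),
       edge_count = hubs$edge_count, tom = tom,
       n_modules = length(unique(module[module > 0])))
}
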