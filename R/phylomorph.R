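#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion with unit rate, the expected covariance between two
#' tips is the path length from the root to their most recent common
#' ancestor; the diagonal holds root-to-tip depths. Computed with
#' `ape::vcv.phylo` after validating the tree.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @param tip_order optional character vector of tip labels giving the
#'   row/column order; an error lists any labels absent from the tree.
#' @return n x n symmetric positive-semidefinite matrix with tip labels as
#'   dimnames.
#' @export
bm_covariance <- function(tree, tip_order = NULL) {
  check_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(tip_order)) {
    bad <- setdiff(tip_order, rownames(C))
    if (length(bad)) stop("tip label(s) not in tree: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    C <- C[tip_order, tip_order, drop = FALSE]
  }
  C
}

# The stored root of the phylo object is taken as the root: a rooted star
# phylogeny and an "unrooted" basal polytomy are indistinguishable in the
# phylo representation, and star trees are a key analytic reference case.
check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape::phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  invisible(tree)
}

#' Per-species mean shapes from aligned specimens
#'
#' Arithmetic mean of the aligned landmark coordinates within each species,
#' returned as a species x 2k matrix (x/y interleaved) ready for
#' [phylo_pca()].
#'
#' @param aligned an [gpa()] result.
#' @param species optional species labels (defaults to those stored in
#'   `aligned`).
#' @return Matrix with one row per species (rownames = species).
#' @export
species_mean_shapes <- function(aligned, species = aligned$species) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  if (is.null(species)) stop("no species labels available", call. = FALSE)
  X <- flatten_shapes(aligned$aligned)
  f <- factor(species)
  if (any(table(f) == 0L)) stop("species with zero specimens", call. = FALSE)
  M <- rowsum(X, f) / as.vector(table(f))
  rownames(M) <- levels(f)
  M
}

#' Phylogenetically corrected PCA of species mean traits
#'
#' Principal components of the evolutionary covariance matrix under a
#' Brownian-motion model: with `C` the tree covariance, the GLS root state
#' is `a = (1' C^-1 1)^-1 1' C^-1 X`, the evolutionary covariance
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` is eigen-decomposed, and scores
#' are the GLS-centred data projected on the eigenvectors (covariance mode,
#' untransformed projection). On a star phylogeny with equal branch lengths
#' this reduces exactly to ordinary covariance PCA of the species means.
#'
#' @param species_means n x p matrix (rownames = species; for shapes,
#'   flattened aligned coordinates from [species_mean_shapes()]).
#' @param tree rooted `ape::phylo` with branch lengths; tips must match the
#'   rownames.
#' @return Object of class `phylo_shape_space`: `C`, `phylo_mean_a`,
#'   `evolutionary_covariance_R`, `eigenvalues`, `percent_variance`,
#'   `scores`, `loadings`.
#' @export
phylo_pca <- function(species_means, tree) {
  X <- as.matrix(species_means)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 species", call. = FALSE)
  if (is.null(rownames(X))) stop("'species_means' needs species rownames", call. = FALSE)
  C <- bm_covariance(tree, tip_order = rownames(X))
  ch <- tryCatch(chol(C), error = function(e)
    stop(paste0("singular phylogenetic covariance (duplicate or zero-length tips?); ",
                "consider collapsing identical tips or adding a small ridge"),
         call. = FALSE))
  Cinv <- chol2inv(ch)
  one <- rep(1, n)
  denom <- as.numeric(crossprod(one, Cinv %*% one))
  a <- crossprod(one, Cinv %*% X) / denom          # 1 x p GLS root state
  Xc <- X - one %*% a
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1)
  ee <- eigen((R + t(R)) / 2, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  V <- fix_eigen_signs(ee$vectors)
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  out <- list(C = C,
              phylo_mean_a = a,
              evolutionary_covariance_R = R,
              eigenvalues = ev,
              percent_variance = 100 * ev / sum(ev),
              scores = scores,
              loadings = t(V))
  class(out) <- "phylo_shape_space"
  out
}

#' @export
print.phylo_shape_space <- function(x, ...) {
  cat(sprintf("<phylo_shape_space> %d species; phylo-PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), x$percent_variance[1L],
              if (length(x$percent_variance) > 1L) x$percent_variance[2L] else 0))
  invisible(x)
}
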