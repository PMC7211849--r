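#' Reference 25-landmark wing configuration
#'
#' A deterministic, hand-laid configuration of 25 homologous landmarks on a
#' stylized scarab hind wing (mm, base at the origin, span along x):
#' landmarks 1-8 run along the leading edge to the tip, 9-15 back along the
#' trailing edge, and 16-25 mark interior vein junctions. Landmark 25 sits
#' on the distal leading edge and landmark 22 on the vein junction
#' reinforcing the proximal trailing edge -- the two regions where scarab
#' wing venation is most labile.
#'
#' @return 25 x 2 matrix of coordinates.
#' @export
default_wing_landmarks <- function() {
  m <- rbind(
    c(0.0,  0.0),  c(3.0,  1.2),  c(6.0,  1.9),  c(9.0,  2.3),
    c(12.0, 2.4),  c(15.0, 2.1),  c(20.0, 0.0),  c(17.0, -1.6),
    c(14.5, -2.6), c(12.0, -3.3), c(9.5, -3.7),  c(7.0, -3.8),
    c(4.5, -3.4),  c(2.0, -2.4),  c(5.0, -0.8),  c(7.5, -1.2),
    c(10.0, -1.5), c(12.5, -1.5), c(15.0, -1.0), c(4.0, -2.0),
    c(9.0, -2.6),  c(6.5, -2.4),  c(11.5, -2.5), c(3.0, -1.3),
    c(18.0, 1.4))
  rownames(m) <- paste0("lm", 1:25)
  colnames(m) <- c("x", "y")
  m
}

#' Parameters for a Brownian-motion wing-shape radiation
#'
#' @param tree rooted `ape::phylo` with branch lengths; its tips are the
#'   species of the radiation.
#' @param ancestral_shape k x 2 matrix, the root shape (defaults to the
#'   25-landmark reference wing).
#' @param bm_rate_sigma2 Brownian rate, squared shape units per unit branch
#'   length, applied independently to every coordinate.
#' @param clade_offsets optional list; each element is
#'   `list(tips = <character>, offset = <k x 2 matrix or length-2k vector>)`
#'   added to the mean shape of every listed tip (a clade-specific
#'   displacement on top of the Brownian drift).
#' @param n_specimens_per_species specimens drawn per species.
#' @param digitization_noise s.d. of per-coordinate Gaussian noise added to
#'   each specimen (same units as the shape).
#' @param seed RNG seed (private stream).
#' @return Object of class `shape_radiation_params`.
#' @export
shape_radiation_params <- function(tree,
                                   ancestral_shape = default_wing_landmarks(),
                                   bm_rate_sigma2 = 0.1,
                                   clade_offsets = NULL,
                                   n_specimens_per_species = 10L,
                                   digitization_noise = 0.05,
                                   seed = 1L) {
  check_tree(tree)
  ancestral_shape <- as.matrix(ancestral_shape)
  stopifnot(ncol(ancestral_shape) == 2L, nrow(ancestral_shape) >= 3L)
  if (bm_rate_sigma2 < 0) stop("'bm_rate_sigma2' must be >= 0", call. = FALSE)
  if (digitization_noise < 0) stop("'digitization_noise' must be >= 0", call. = FALSE)
  if (n_specimens_per_species < 1L) stop("need >= 1 specimen per species", call. = FALSE)
  if (!is.null(clade_offsets)) {
    for (co in clade_offsets) {
      bad <- setdiff(co$tips, tree$tip.label)
      if (length(bad)) stop("clade offset names unknown tip(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      if (length(as.numeric(co$offset)) != 2L * nrow(ancestral_shape)) {
        stop("clade offset must have one (x, y) displacement per landmark",
             call. = FALSE)
      }
    }
  }
  out <- list(tree = tree, ancestral_shape = ancestral_shape,
              bm_rate_sigma2 = bm_rate_sigma2, clade_offsets = clade_offsets,
              n_specimens_per_species = as.integer(n_specimens_per_species),
              digitization_noise = digitization_noise, seed = seed)
  class(out) <- "shape_radiation_params"
  out
}

#' Simulate a wing-shape radiation on a phylogeny
#'
#' Every landmark coordinate evolves as independent Brownian motion along
#' the tree from the ancestral shape (increments `N(0, sigma2 * branch
#' length)` accumulated root-to-tip), optional clade-specific offsets are
#' added to the affected tips, and each specimen is the species mean plus
#' i.i.d. Gaussian digitization noise. The generating species means are
#' returned as ground truth.
#'
#' @param params a [shape_radiation_params()] object.
#' @return A [shape_set()] with extra fields `species_means` (species x k x
#'   2 array of true means) and `tree`.
#' @export
simulate_shape_radiation <- function(params) {
  stopifnot(inherits(params, "shape_radiation_params"))
  tree <- params$tree
  k <- nrow(params$ancestral_shape)
  p <- 2L * k
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L

  anc <- as.numeric(t(params$ancestral_shape))   # x1, y1, x2, y2, ...
  res <- with_private_seed(params$seed, {
    vals <- matrix(NA_real_, ntip + nnode, p)
    vals[root, ] <- anc
    rt <- ape::reorder.phylo(tree, "postorder")
    for (i in rev(seq_len(nrow(rt$edge)))) {     # preorder: parents first
      par <- rt$edge[i, 1L]; child <- rt$edge[i, 2L]
      vals[child, ] <- vals[par, ] +
        stats::rnorm(p, 0, sqrt(params$bm_rate_sigma2 * rt$edge.length[i]))
    }
    means <- vals[seq_len(ntip), , drop = FALSE]
    rownames(means) <- tree$tip.label
    if (!is.null(params$clade_offsets)) {
      for (co in params$clade_offsets) {
        off <- if (is.matrix(co$offset)) as.numeric(t(co$offset)) else
          as.numeric(co$offset)   # interleaved x1, y1, x2, y2, ...
        means[co$tips, ] <- sweep(means[co$tips, , drop = FALSE], 2L, off, `+`)
      }
    }
    nspec <- params$n_specimens_per_species
    total <- ntip * nspec
    confs <- array(NA_real_, c(total, k, 2L))
    ids <- species <- character(total)
    row <- 0L
    for (s in seq_len(ntip)) {
      for (j in seq_len(nspec)) {
        row <- row + 1L
        noise <- if (params$digitization_noise > 0)
          stats::rnorm(p, 0, params$digitization_noise) else 0
        flat <- means[s, ] + noise
        confs[row, , 1L] <- flat[seq(1L, p, 2L)]
        confs[row, , 2L] <- flat[seq(2L, p, 2L)]
        ids[row] <- sprintf("%s_%02d", tree$tip.label[s], j)
        species[row] <- tree$tip.label[s]
      }
    }
    list(confs = confs, ids = ids, species = species, means = means)
  })

  out <- shape_set(res$confs, res$ids, res$species)
  mean_arr <- array(NA_real_, c(ntip, k, 2L),
                    dimnames = list(tree$tip.label, NULL, c("x", "y")))
  mean_arr[, , 1L] <- res$means[, seq(1L, p, 2L)]
  mean_arr[, , 2L] <- res$means[, seq(2L, p, 2L)]
  out$species_means <- mean_arr
  out$tree <- tree
  out
}
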