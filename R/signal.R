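#' Abouheif topological proximity matrix
#'
#' For tips i != j, the proximity is `1 / prod(dd(v))` over every internal
#' node v on the path between them — the most recent common ancestor and
#' all intermediate internal nodes — where `dd(v)` is the number of direct
#' children of v. Branch lengths play no role: the statistic is purely
#' topological. The diagonal holds the row complement
#' `A_ii = 1 - sum_{j != i} A_ij`, the row-normalized ("oriAbouheif")
#' convention, so each row sums to 1.
#'
#' @param tree An [ape::phylo] tree with >= 3 uniquely labelled tips. The
#'   basal node of the `phylo` encoding acts as the root; a basal
#'   multifurcation (star tree) is a root of higher out-degree.
#' @return A list of class `proximity_matrix`: `labels` (tip order) and
#'   `A` (square matrix).
#' @export
abouheif_proximity <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("tree must have at least 3 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tree tip labels must be unique", call. = FALSE)
  }
  edge <- tree$edge
  parent <- integer(ntip + tree$Nnode)
  parent[edge[, 2]] <- edge[, 1]
  root <- setdiff(edge[, 1], edge[, 2])[1]
  dd <- tabulate(edge[, 1], nbins = ntip + tree$Nnode)  # direct descendants

  # ancestor chains root-ward for every tip
  chains <- lapply(seq_len(ntip), function(i) {
    ch <- integer(0)
    v <- i
    while (v != root) {
      v <- parent[v]
      ch <- c(ch, v)
    }
    ch
  })

  A <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    for (j in (i + 1L):ntip) {
      # internal nodes on the i--j path: symmetric difference of the
      # ancestor chains plus the MRCA
      ci <- chains[[i]]; cj <- chains[[j]]
      mrca <- ci[match(TRUE, ci %in% cj)]
      ci_below <- ci[seq_len(match(mrca, ci) - 1L)]  # strictly below MRCA
      cj_below <- cj[seq_len(match(mrca, cj) - 1L)]
      path_nodes <- c(ci_below, cj_below, mrca)
      A[i, j] <- A[j, i] <- 1 / prod(dd[path_nodes])
    }
  }
  diag(A) <- 1 - rowSums(A)
  structure(list(labels = tree$tip.label, A = A), class = "proximity_matrix")
}

#' Abouheif-Moran Cmean phylogenetic signal test
#'
#' Moran-type autocorrelation of a tip trait using the Abouheif
#' topological proximity matrix, with significance from seeded random
#' permutations of the tip-to-value assignment (one-tailed, greater:
#' phylogenetic signal inflates Cmean). The trait is standardized to mean
#' 0 and unit variance (divisor n); the off-diagonal proximities are
#' row-normalized over their off-diagonal mass and
#' `Cmean = sum_{i != j} W_ij z_i z_j / n`. The permutation p-value uses
#' the add-one estimator `(1 + #{C* >= C_obs}) / (n_permutations + 1)`.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param values Named numeric vector of tip traits (names matched to tip
#'   labels) or unnamed vector in tip-label order.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation generator.
#' @param variable Name recorded in the result.
#' @return A `signal_result` list: `cmean_observed`, `p_value`,
#'   `n_permutations`, `seed`, `variable`.
#' @export
abouheif_cmean <- function(tree, values, n_permutations = 999, seed = 1L,
                           variable = deparse(substitute(values))) {
  prox <- abouheif_proximity(tree)
  n <- length(prox$labels)
  if (!is.null(names(values))) {
    missing_tips <- setdiff(prox$labels, names(values))
    extra <- setdiff(names(values), prox$labels)
    if (length(missing_tips) || length(extra)) {
      stop(sprintf("tip/value mismatch; unmatched: %s",
                   paste(c(missing_tips, extra), collapse = ", ")),
           call. = FALSE)
    }
    values <- values[prox$labels]
  } else if (length(values) != n) {
    stop(sprintf("got %d values for %d tips", length(values), n),
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite trait values", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("trait has zero variance; Cmean is undefined", call. = FALSE)
  }
  W <- prox$A
  diag(W) <- 0
  W <- W / rowSums(W)

  z <- (values - mean(values)) / sqrt(mean((values - mean(values))^2))
  cmean <- function(zv) as.numeric(zv %*% W %*% zv) / n
  c_obs <- cmean(z)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  c_perm <- vapply(seq_len(n_permutations),
                   function(b) cmean(z[sample.int(n)]), numeric(1))
  p <- (1 + sum(c_perm >= c_obs)) / (n_permutations + 1)

  structure(list(cmean_observed = c_obs, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 variable = variable),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Abouheif-Moran Cmean for '%s': %.4f (p = %.4g, %d permutations, seed %d)\n",
              x$variable, x$cmean_observed, x$p_value, x$n_permutations,
              x$seed))
  invisible(x)
}
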