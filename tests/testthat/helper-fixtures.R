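# Shared fixtures built in code.

# minimal two-round PSMC text; last round has theta0 0.002 and two segments
two_round_psmc <- function() {
  paste(
    "RD 0",
    "TR 0.001000 0.000200",
    "RS\t0\t0.0\t1.0\t0\t0",
    "RS\t1\t0.02\t1.5\t0\t0",
    "//",
    "RD 1",
    "LL -12345.6",
    "QD 0.1",
    "TR 0.002000 0.000400",
    "MT 15.0",
    "RS\t0\t0.0\t1.0\t0\t0",
    "RS\t1\t0.01\t2.5\t0\t0",
    "PA 4+25*2+4+6 0.002",
    "//",
    sep = "\n")
}

make_traj <- function(t_years, ne, id = "t") {
  psmcgrowth:::new_trajectory(t_years, ne, id)
}

# independent brute-force oracle: U and exact p by direct pair counting over
# every assignment of pooled values to group labels
brute_force_mw <- function(mig, res) {
  u_pairs <- function(m, r) {
    sum(outer(r, m, ">")) + 0.5 * sum(outer(r, m, "=="))
  }
  u_obs <- u_pairs(mig, res)
  pooled <- c(mig, res)
  n <- length(pooled)
  combos <- utils::combn(n, length(res))
  u_all <- apply(combos, 2, function(idx) u_pairs(pooled[-idx], pooled[idx]))
  list(U = u_obs, p = mean(u_all <= u_obs + 1e-9))
}

# independent proximity oracle: walk tip-to-tip paths with ape::nodepath
proximity_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  dd <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)
  A <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      path <- ape::nodepath(tree, i, j)
      internal <- path[path > ntip]
      A[i, j] <- A[j, i] <- 1 / prod(dd[internal])
    }
  }
  diag(A) <- 1 - rowSums(A)
  A
}
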