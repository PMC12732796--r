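# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately use naive double loops / closed forms so they
# share no code path with the implementation they check.

# a bare structure from explicit atom rows
tiny_structure <- function(chain, resnum, atom, element, xyz,
                           resname = "ALA", id = "tiny") {
  new_structure(id, data.frame(
    chain = chain, resnum = as.integer(resnum), icode = "",
    resname = rep_len(resname, length(chain)), atom = atom,
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    stringsAsFactors = FALSE))
}

# brute-force residue contact detection: explicit double loop over residues
# and atom pairs
brute_contacts <- function(x, group_a, group_b, cutoff = 4.5) {
  a <- x$atoms
  xyz <- coords(x)
  uid <- paste(a$chain, a$resnum, a$icode, sep = "|")
  ga <- group_a[a$element[group_a] != "H"]
  gb <- group_b[a$element[group_b] != "H"]
  out <- list()
  for (ra in unique(uid[ga])) {
    for (rb in unique(uid[gb])) {
      ai <- ga[uid[ga] == ra]; bi <- gb[uid[gb] == rb]
      dmin <- Inf
      for (i in ai) for (j in bi) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d < dmin) dmin <- d
      }
      if (dmin <= cutoff)
        out[[length(out) + 1]] <- data.frame(key_a = ra, key_b = rb,
                                             min_distance = dmin)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# brute-force GROMOS clustering on an F x 3n coordinate matrix,
# positional RMSD, recomputing all neighbour counts every iteration
brute_gromos <- function(X, natoms, cutoff) {
  fcount <- nrow(X)
  D <- matrix(0, fcount, fcount)
  for (i in seq_len(fcount)) for (j in seq_len(fcount)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2) / natoms)
  }
  assign <- integer(fcount)
  cl <- 0L
  medoid <- integer()
  while (any(assign == 0L)) {
    cl <- cl + 1L
    left <- which(assign == 0L)
    counts <- vapply(left, function(i) sum(D[i, left] <= cutoff), integer(1))
    center <- left[which.max(counts)]
    members <- left[D[center, left] <= cutoff]
    assign[members] <- cl
    medoid[cl] <- center
  }
  sizes <- tabulate(assign, cl)
  ord <- order(-sizes, medoid[seq_len(cl)])
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  list(assignments = relabel[assign],
       populations = data.frame(cluster = seq_len(cl), count = sizes[ord],
                                fraction = sizes[ord] / fcount,
                                medoid = medoid[ord]))
}

# closed-form optimal-superposition RMSD via the SVD of the covariance
# (independent of the packaged implementation path)
svd_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((ac %*% t(rot) - bc)^2)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_transform_structure <- function(x, R, t) {
  set_coords(x, sweep(coords(x) %*% t(R), 2, t, "+"))
}

# small planted ensemble used by several suites (cheap)
small_scenario <- function(seed = 5, contacts = NULL, ...) {
  scenario_spec(seed = seed, n_replicates = 3L, frames_per_replicate = 80L,
                planted_contacts = contacts, ...)
}
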